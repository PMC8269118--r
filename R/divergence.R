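#' Build the repeat multiple alignment from a local alignment
#'
#' Cuts the sequence side of a probe alignment at probe-period boundaries:
#' each consensus period becomes one row of the multiple alignment. Probe
#' positions skipped by the sequence (gap-in-sequence columns) become '.'
#' cells; sequence residues inserted relative to the probe (gap-in-probe
#' columns) open extra insertion columns after the probe position at which
#' they occur, so the alignment width n1 may exceed n. Partial first/last
#' periods are kept as rows; sparsely occupied columns are handled later by
#' the divergence column filter.
#'
#' @param local A non-empty \code{local_alignment}.
#' @param seq The \code{recoded_seq} the alignment was computed from (plain
#'   integer symbols are accepted, in which case only group-space output is
#'   available).
#' @return Object of class \code{repeat_alignment}: \code{sym} (k x n1
#'   integer matrix of group symbols, NA = gap), \code{res} (k x n1 character
#'   matrix of original residues, or NULL), \code{n}, \code{n1}, \code{k}.
#' @export
repeats_from_alignment <- function(local, seq) {
  if (length(local$moves) == 0L) stop_invalid("empty alignment")
  n <- local$n
  # complete periods covered by the probe range
  first_full <- (local$probe_start - 1L) %/% n +
    as.integer((local$probe_start - 1L) %% n != 0L) + 1L
  last_full <- local$probe_end %/% n
  if (last_full - first_full + 1L < 2L)
    stop_invalid("fewer than 2 complete repeat periods in the alignment")
  rseq <- if (inherits(seq, "recoded_seq")) seq else NULL

  period_of <- function(j) (j - 1L) %/% n + 1L
  pos_in_period <- function(j) (j - 1L) %% n + 1L

  p0 <- period_of(local$probe_start)
  k <- period_of(local$probe_end) - p0 + 1L
  cells <- matrix(NA_integer_, k, n)       # seq position per (period, probe pos)
  ins <- vector("list", k)                  # insertions per row: list of lists by pos
  for (r in seq_len(k)) ins[[r]] <- vector("list", n)

  cur_period <- NA_integer_
  cur_pos <- NA_integer_
  for (c in seq_along(local$moves)) {
    j <- local$probe_pos[c]
    if (!is.na(j)) {
      cur_period <- period_of(j) - p0 + 1L
      cur_pos <- pos_in_period(j)
      if (local$moves[c] == 1L)
        cells[cur_period, cur_pos] <- local$seq_pos[c]
      # gap_in_seq: probe position consumed with no residue -> stays NA
    } else {
      # gap_in_probe: sequence residue inserted after the last probe position
      ins[[cur_period]][[cur_pos]] <-
        c(ins[[cur_period]][[cur_pos]], local$seq_pos[c])
    }
  }

  ins_width <- integer(n)
  for (p in seq_len(n)) {
    ins_width[p] <- max(0L, vapply(seq_len(k),
                                   function(r) length(ins[[r]][[p]]),
                                   integer(1)))
  }
  n1 <- n + sum(ins_width)

  pos_mat <- matrix(NA_integer_, k, n1)
  col_cursor <- 0L
  for (p in seq_len(n)) {
    col_cursor <- col_cursor + 1L
    pos_mat[, col_cursor] <- cells[, p]
    if (ins_width[p] > 0L) {
      for (s in seq_len(ins_width[p])) {
        col_cursor <- col_cursor + 1L
        for (r in seq_len(k)) {
          v <- ins[[r]][[p]]
          if (length(v) >= s) pos_mat[r, col_cursor] <- v[s]
        }
      }
    }
  }

  sym_src <- if (is.null(rseq)) as.integer(seq) else rseq$symbols
  sym <- matrix(NA_integer_, k, n1)
  ok <- !is.na(pos_mat)
  sym[ok] <- sym_src[pos_mat[ok]]
  res <- NULL
  if (!is.null(rseq)) {
    res <- matrix(NA_character_, k, n1)
    src_chars <- strsplit(rseq$source, "", fixed = TRUE)[[1L]]
    res[ok] <- src_chars[rseq$positions[pos_mat[ok]]]
  }
  structure(list(sym = sym, res = res, n = n, n1 = n1, k = k),
            class = "repeat_alignment")
}

#' @export
print.repeat_alignment <- function(x, ...) {
  cat(sprintf("<repeat_alignment> %d repeats x %d columns (consensus length %d)\n",
              x$k, x$n1, x$n))
  for (r in seq_len(min(x$k, 20L))) {
    cat(sprintf("%3d  %s\n", r,
                paste(symbols_to_letters(x$sym[r, ]), collapse = "")))
  }
  if (x$k > 20L) cat("  ...\n")
  invisible(x)
}

#' Render a repeat multiple alignment as text
#'
#' Rows numbered, gaps as '.', residues as five-group letters or original
#' amino acids.
#'
#' @param rma A \code{repeat_alignment}.
#' @param symbol_space \code{"groups5"} or \code{"residues20"}.
#' @return Character vector, one line per repeat copy.
#' @export
format_repeat_alignment <- function(rma,
                                    symbol_space = c("groups5", "residues20")) {
  symbol_space <- match.arg(symbol_space)
  mat <- if (symbol_space == "residues20") {
    if (is.null(rma$res))
      stop_invalid("no residue-level provenance available in this alignment")
    m <- rma$res; m[is.na(m)] <- "."; m
  } else {
    matrix(symbols_to_letters(rma$sym), rma$k, rma$n1)
  }
  vapply(seq_len(rma$k), function(r)
    sprintf("%d\t%s", r, paste(mat[r, ], collapse = "")), character(1))
}

#' Divergence degree S of a repeat multiple alignment
#'
#' Columns with fewer than k/2 residues are disregarded (a column with
#' exactly k/2 is retained). For the remaining columns a coincidence matrix
#' of symbol counts is built, the consensus takes the modal symbol per
#' column (ties to the smaller fixed symbol index), and
#' \deqn{S = 1 - v / v_1}
#' where v is the number of residues matching their column consensus and v1
#' the total number of retained residues. S = 0 means perfectly conserved
#' repeats; S > 0.5 marks highly divergent ones.
#'
#' @param rma A \code{repeat_alignment} with at least 2 rows.
#' @param symbol_space \code{"residues20"} (default; uses original residues
#'   recovered via provenance) or \code{"groups5"}.
#' @return Object of class \code{divergence_result}: \code{consensus}
#'   (character vector over retained columns), \code{v}, \code{v1}, \code{S},
#'   \code{retained_columns}, \code{M2} (coincidence matrix over all
#'   columns).
#' @export
divergence_degree <- function(rma,
                              symbol_space = c("residues20", "groups5")) {
  symbol_space <- match.arg(symbol_space)
  if (rma$k < 2L) stop_invalid("need at least 2 repeat rows")
  if (symbol_space == "residues20") {
    if (is.null(rma$res))
      stop_invalid("no residue-level provenance available; use symbol_space = 'groups5'")
    alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    mat <- rma$res
  } else {
    alphabet <- group_letters()
    mat <- matrix(NA_character_, rma$k, rma$n1)
    ok <- !is.na(rma$sym)
    mat[ok] <- group_letters()[rma$sym[ok]]
  }
  m2 <- vapply(seq_len(rma$n1), function(j) {
    tabulate(match(mat[, j], alphabet), nbins = length(alphabet))
  }, integer(length(alphabet)))
  rownames(m2) <- alphabet
  occupancy <- colSums(m2)
  retained <- which(occupancy >= rma$k / 2)
  if (!length(retained))
    stop_invalid("all columns filtered out (occupancy below k/2)")
  cons_idx <- apply(m2[, retained, drop = FALSE], 2L, which.max) # ties: smaller index
  v <- sum(vapply(seq_along(retained), function(jj)
    m2[cons_idx[jj], retained[jj]], integer(1)))
  v1 <- sum(occupancy[retained])
  structure(
    list(consensus = alphabet[cons_idx], v = v, v1 = v1, S = 1 - v / v1,
         retained_columns = retained, M2 = m2, symbol_space = symbol_space),
    class = "divergence_result"
  )
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("<divergence_result> S = %.4f (v = %d / v1 = %d, %d columns, %s)\n",
              x$S, x$v, x$v1, length(x$retained_columns), x$symbol_space))
  cat("  consensus:", paste(x$consensus, collapse = ""), "\n")
  invisible(x)
}
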