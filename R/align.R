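#' Local alignment against the cyclic periodic probe
#'
#' Smith-Waterman-style local alignment of a recoded sequence against the
#' periodic probe under an n x 25 pair-correlation weight matrix. A diagonal
#' move consuming sequence position i and probe position j scores
#' \code{mt[probe[j], t(i)]} where \code{t(i) = s(i-1) + 5 (s(i) - 1)} is the
#' adjacent-pair category of the sequence (at i = 1 no previous residue
#' exists and the contribution is 0); insertions and deletions cost
#' \code{del} each. The similarity matrix F is floored at 0 and the traceback
#' runs from the maximum cell mF back to the first zero cell. Ties are broken
#' deterministically: restart, then diagonal, then gap-in-sequence, then
#' gap-in-probe; among equal maxima the lexicographically smallest (i, j)
#' cell is used.
#'
#' @param mt A \code{norm_weight_matrix} (n rows x 25 columns).
#' @param probe A \code{periodic_probe} whose length equals the sequence
#'   length and whose period equals \code{nrow(mt)}.
#' @param seq Integer symbols in 1..5, or a \code{recoded_seq}.
#' @param del Gap penalty (default 25.0).
#' @return Object of class \code{local_alignment}: \code{mF}, \code{n},
#'   per-column vectors \code{moves} (1 = match, 2 = gap-in-sequence,
#'   3 = gap-in-probe), \code{seq_pos}, \code{probe_pos}, \code{seq_symbol},
#'   \code{probe_symbol} (NA at gaps), 1-based inclusive
#'   \code{seq_start}/\code{seq_end}, \code{probe_start}/\code{probe_end},
#'   and \code{aligned_pairs} (number of match columns). \code{mF = 0}
#'   yields an empty alignment. See \code{\link{alignment_columns}} for a
#'   tabular view.
#' @export
local_align <- function(mt, probe, seq, del = 25.0) {
  if (inherits(seq, "recoded_seq")) seq <- seq$symbols
  n <- nrow(mt)
  np <- attr(probe, "n")
  if (!is.null(np) && np != n)
    stop_invalid("matrix rows (%d) do not match probe period (%d)", n, np)
  res <- dp_local_align(unclass(mt), as.integer(unclass(probe)),
                        as.integer(seq), as.double(del))
  seq_pos <- res$seq_pos
  probe_pos <- res$probe_pos
  seq_symbol <- rep(NA_integer_, length(seq_pos))
  ok <- !is.na(seq_pos)
  seq_symbol[ok] <- seq[seq_pos[ok]]
  probe_symbol <- rep(NA_integer_, length(probe_pos))
  ok <- !is.na(probe_pos)
  probe_symbol[ok] <- unclass(probe)[probe_pos[ok]]
  sp <- seq_pos[!is.na(seq_pos)]
  pp <- probe_pos[!is.na(probe_pos)]
  structure(
    list(
      mF = res$mF,
      n = n,
      moves = res$moves,
      seq_pos = seq_pos,
      probe_pos = probe_pos,
      seq_symbol = seq_symbol,
      probe_symbol = probe_symbol,
      seq_start = if (length(sp)) sp[1L] else NA_integer_,
      seq_end = if (length(sp)) sp[length(sp)] else NA_integer_,
      probe_start = if (length(pp)) pp[1L] else NA_integer_,
      probe_end = if (length(pp)) pp[length(pp)] else NA_integer_,
      aligned_pairs = sum(res$moves == 1L),
      del = del
    ),
    class = "local_alignment"
  )
}

#' Tabular view of an alignment path
#'
#' @param local A \code{local_alignment}.
#' @return data.frame with one row per alignment column: \code{move}
#'   ("match", "gap_in_seq", "gap_in_probe"), \code{seq_pos},
#'   \code{probe_pos}, \code{seq_symbol}, \code{probe_symbol}.
#' @export
alignment_columns <- function(local) {
  data.frame(
    move = c("match", "gap_in_seq", "gap_in_probe")[local$moves],
    seq_pos = local$seq_pos,
    probe_pos = local$probe_pos,
    seq_symbol = local$seq_symbol,
    probe_symbol = local$probe_symbol,
    stringsAsFactors = FALSE
  )
}

#' @export
print.local_alignment <- function(x, ...) {
  if (length(x$moves) == 0L) {
    cat("<local_alignment> empty (mF = 0)\n")
  } else {
    cat(sprintf(
      "<local_alignment> mF = %.3f, n = %d, seq %d..%d, probe %d..%d, %d matched columns\n",
      x$mF, x$n, x$seq_start, x$seq_end, x$probe_start, x$probe_end,
      x$aligned_pairs))
  }
  invisible(x)
}

#' Recompute an alignment's score by replaying its path
#'
#' Walks the stored path column by column applying the scoring rule of
#' \code{\link{local_align}}; used to assert that the dynamic program and its
#' traceback agree.
#'
#' @param local A \code{local_alignment}.
#' @param mt The weight matrix it was computed under.
#' @param seq The symbol sequence it was computed against.
#' @return The replayed score.
#' @export
alignment_score <- function(local, mt, seq) {
  if (inherits(seq, "recoded_seq")) seq <- seq$symbols
  m <- length(local$moves)
  if (m == 0L) return(0)
  score <- 0
  for (c in seq_len(m)) {
    if (local$moves[c] == 1L) {
      i <- local$seq_pos[c]
      if (i >= 2L) {
        t <- seq[i - 1L] + 5L * (seq[i] - 1L)
        score <- score + unclass(mt)[local$probe_symbol[c], t]
      }
    } else {
      score <- score - local$del
    }
  }
  score
}

#' Render an alignment in dot notation
#'
#' Two-row text block: probe consensus position digits (gaps as '.') over
#' sequence group letters (gaps as '.'), the convention used for repeat
#' alignment listings.
#'
#' @param local A \code{local_alignment}.
#' @return Character vector of two lines.
#' @export
render_alignment <- function(local) {
  if (length(local$moves) == 0L) return(c("", ""))
  probe_row <- ifelse(is.na(local$probe_symbol), ".",
                      as.character(local$probe_symbol))
  seq_row <- symbols_to_letters(local$seq_symbol)
  c(paste(probe_row, collapse = ""), paste(seq_row, collapse = ""))
}
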