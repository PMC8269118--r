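#' Iteratively refine a weight matrix against one sequence
#'
#' Starting from \code{mt0}, alternates local alignment with re-estimation of
#' the weight matrix from the alignment itself: align, count adjacent pairs
#' along the alignment, convert counts to a standardized weight matrix,
#' normalize to R^2 = 110 n / K_d = -1, re-align. Iterations continue while
#' the alignment score mF strictly increases; the loop stops on a
#' non-increase, on a score seen before (cyclic fluctuation), on a degenerate
#' pair-count matrix, or at \code{max_iter}. The best (mF, alignment, matrix)
#' triple seen is returned.
#'
#' @param mt0 Starting \code{norm_weight_matrix}.
#' @param probe \code{periodic_probe} of the sequence's length.
#' @param seq Integer symbols 1..5 or a \code{recoded_seq}.
#' @param del Gap penalty.
#' @param max_iter Safety cap on accepted refinement steps.
#' @return List with elements \code{mF}, \code{local}, \code{mt},
#'   \code{iterations}.
#' @export
refine_alignment <- function(mt0, probe, seq, del = 25.0, max_iter = 12L) {
  aln <- local_align(mt0, probe, seq, del)
  best <- list(mF = aln$mF, local = aln, mt = mt0, iterations = 0L)
  if (aln$mF <= 0) return(best)
  seen <- aln$mF
  cur <- aln
  repeat {
    m1 <- count_pairs_from_alignment(cur)
    if (attr(m1, "total") < 2 ||
        sum(rowSums(m1) > 0) < 2L || sum(colSums(m1) > 0) < 2L) break
    mt_new <- tryCatch(normalize_matrix(weight_from_counts(m1)),
                       error = function(e) NULL)
    if (is.null(mt_new)) break
    aln_new <- local_align(mt_new, probe, seq, del)
    if (!(aln_new$mF > best$mF)) break
    if (any(abs(seen - aln_new$mF) < 1e-9)) break
    best <- list(mF = aln_new$mF, local = aln_new, mt = mt_new,
                 iterations = best$iterations + 1L)
    seen <- c(seen, aln_new$mF)
    cur <- aln_new
    if (best$iterations >= max_iter) break
  }
  best
}

#' Best refined alignment over a matrix set
#'
#' Runs \code{\link{refine_alignment}} from every member of Q(n) and returns
#' the member achieving the highest refined score F_max(n); ties go to the
#' lowest member index.
#'
#' @param q A \code{matrix_set}.
#' @param probe \code{periodic_probe} of the sequence's length.
#' @param seq Integer symbols or \code{recoded_seq}.
#' @param del Gap penalty.
#' @return Object of class \code{period_result}: \code{n}, \code{F_max},
#'   \code{M_max}, \code{local}, \code{member}, \code{Z} (NA until computed).
#' @export
best_over_set <- function(q, probe, seq, del = 25.0) {
  if (!length(q)) stop_invalid("matrix set is empty")
  best <- NULL
  for (i in seq_along(q)) {
    r <- refine_alignment(q[[i]], probe, seq, del)
    if (is.null(best) || r$mF > best$F_max) {
      best <- list(n = attr(q, "n"), F_max = r$mF, M_max = r$mt,
                   local = r$local, member = i, Z = NA_real_,
                   significance = NULL)
    }
  }
  structure(best, class = "period_result")
}

#' @export
print.period_result <- function(x, ...) {
  cat(sprintf("<period_result> n=%d F_max=%.3f Z=%s span=%s..%s\n",
              x$n, x$F_max,
              if (is.na(x$Z)) "NA" else sprintf("%.2f", x$Z),
              format(x$local$seq_start), format(x$local$seq_end)))
  invisible(x)
}

#' Monte-Carlo significance of a period result
#'
#' Shuffles the sequence \code{shuffles} times; each shuffle is re-aligned
#' with the iterative refinement starting from M_max and its best score is
#' recorded into the null set V_n. The significance is
#' \deqn{Z(n) = (F_{max}(n) - \bar V_n) / \sqrt{D(V_n)}}
#' with \eqn{D(V_n)} the sample variance of the null scores.
#'
#' @param result A \code{period_result} from \code{\link{best_over_set}}.
#' @param seq The original (unshuffled) symbols or \code{recoded_seq}.
#' @param shuffles Number of shuffled replicates (default 200).
#' @param seed Integer seed; shuffle streams are keyed by (seed, n, index).
#' @param del Gap penalty.
#' @return Object of class \code{significance_estimate}: \code{mean},
#'   \code{variance}, \code{shuffles}, \code{Z}, \code{scores}.
#' @export
significance_z <- function(result, seq, shuffles = 200L, seed = 1L,
                           del = 25.0) {
  if (inherits(seq, "recoded_seq")) seq <- seq$symbols
  shuffles <- as.integer(shuffles)
  if (shuffles < 2L) stop_invalid("'shuffles' must be >= 2")
  probe <- build_probe(result$n, length(seq))
  v <- numeric(shuffles)
  for (s in seq_len(shuffles)) {
    set.seed(substream_seed(seed, result$n, s, 7L))
    shuf <- sample(seq)
    v[s] <- refine_alignment(result$M_max, probe, shuf, del)$mF
  }
  dv <- stats::var(v)
  if (!is.finite(dv) || dv <= 0)
    stop_invalid("degenerate null: zero variance across %d shuffles", shuffles)
  structure(
    list(mean = mean(v), variance = dv, shuffles = shuffles,
         Z = (result$F_max - mean(v)) / sqrt(dv), scores = v),
    class = "significance_estimate"
  )
}

#' Scan one sequence over a range of consensus lengths
#'
#' For each n in \code{n_min..n_max}: generate the random matrix set Q(n),
#' take the best refined alignment over the set, and attach its Monte-Carlo
#' significance Z(n). The alignment probe has the sequence's length; the
#' matrix-generation probe has length \code{probe_copies * n}.
#'
#' @param seq A \code{recoded_seq} (or plain integer symbols 1..5).
#' @param n_min,n_max Consensus length range (default 2 to
#'   \code{min(100, floor(length/2))}; a period longer than half the sequence
#'   cannot repeat twice).
#' @param set_size Matrices per Q(n) (default 1000).
#' @param shuffles Monte-Carlo replicates per n (default 200).
#' @param seed Integer seed; all work units derive substreams from it.
#' @param del Gap penalty.
#' @param probe_copies Probe repetitions for matrix generation.
#' @param matrix_sets Optional pre-generated list of \code{matrix_set}s,
#'   named by n (as produced by \code{generate_matrix_set} with the same
#'   seed); useful when scanning many sequences, since Q(n) depends only on
#'   (n, set_size, seed).
#' @param verbose Print one line per n.
#' @return List of \code{period_result} of class \code{period_spectrum},
#'   carrying the scanned sequence as attribute \code{seq}.
#' @export
scan_sequence <- function(seq, n_min = 2L, n_max = NULL, set_size = 1000L,
                          shuffles = 200L, seed = 1L, del = 25.0,
                          probe_copies = 1000L, matrix_sets = NULL,
                          verbose = FALSE) {
  rseq <- if (inherits(seq, "recoded_seq")) seq else NULL
  sym <- if (is.null(rseq)) as.integer(seq) else rseq$symbols
  L <- length(sym)
  if (L < 14L)
    stop_invalid("sequence too short: %d recoded residues (minimum TR size is 14)", L)
  if (is.null(n_max)) n_max <- min(100L, L %/% 2L)
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_min < 2L) stop_invalid("'n_min' must be >= 2")
  if (n_max > L) stop_invalid("'n_max' must be <= sequence length")
  if (n_max < n_min) stop_invalid("'n_max' must be >= 'n_min'")
  out <- vector("list", n_max - n_min + 1L)
  for (idx in seq_along(out)) {
    n <- n_min + idx - 1L
    q <- matrix_sets[[as.character(n)]] %||%
      generate_matrix_set(n, count = set_size, seed = seed,
                          probe_copies = probe_copies)
    probe <- build_probe(n, L)
    res <- best_over_set(q, probe, sym, del)
    if (res$F_max > 0) {
      sig <- significance_z(res, sym, shuffles = shuffles, seed = seed,
                            del = del)
      res$Z <- sig$Z
      res$significance <- sig
    } else {
      res$Z <- 0
    }
    if (verbose)
      message(sprintf("n=%d F_max=%.2f Z=%.2f", n, res$F_max, res$Z))
    out[[idx]] <- res
  }
  structure(out, seq = rseq %||% sym, class = "period_spectrum")
}

span_overlap <- function(a_start, a_end, b_start, b_end) {
  max(0L, min(a_end, b_end) - max(a_start, b_start) + 1L)
}

#' Filter a period spectrum into non-redundant repeat annotations
#'
#' Greedy selection on significance: drop all periods with Z below \code{z0},
#' pick the period with the largest Z, remove every remaining period whose
#' local alignment overlaps the chosen one by more than 50\% of the shorter
#' sequence-side span, and repeat on the remainder. Survivors with a
#' sequence-side span shorter than \code{min_span} residues are discarded.
#' Coordinates are reported 1-based inclusive on the original amino-acid
#' string when the spectrum was computed from a \code{recoded_seq}.
#'
#' @param spectrum A \code{period_spectrum} (or list of
#'   \code{period_result}).
#' @param z0 Significance threshold (default 6.0).
#' @param min_span Minimum repeat span in residues (default 14).
#' @return A \code{tr_annotations} data.frame with columns \code{id},
#'   \code{n0}, \code{l}, \code{r}, \code{Z}, \code{S}, \code{F_max}; the
#'   per-hit \code{period_result}s are kept in attribute \code{details}.
#' @export
filter_periods <- function(spectrum, z0 = 6.0, min_span = 14L) {
  if (!length(spectrum)) stop_invalid("empty spectrum")
  rseq <- attr(spectrum, "seq")
  id <- if (inherits(rseq, "recoded_seq")) rseq$id else "seq"
  cand <- Filter(function(r) {
    is.finite(r$Z) && r$Z >= z0 && !is.na(r$local$seq_start)
  }, spectrum)
  picked <- list()
  while (length(cand)) {
    zs <- vapply(cand, function(r) r$Z, numeric(1))
    best <- cand[[which.max(zs)]]
    picked[[length(picked) + 1L]] <- best
    # the chosen period overlaps itself fully, so this also removes it
    cand <- Filter(function(r) {
      ov <- span_overlap(r$local$seq_start, r$local$seq_end,
                         best$local$seq_start, best$local$seq_end)
      shorter <- min(r$local$seq_end - r$local$seq_start + 1L,
                     best$local$seq_end - best$local$seq_start + 1L)
      ov <= 0.5 * shorter
    }, cand)
  }
  picked <- Filter(function(r)
    r$local$seq_end - r$local$seq_start + 1L >= min_span, picked)
  to_orig <- function(pos) {
    if (inherits(rseq, "recoded_seq")) rseq$positions[pos] else pos
  }
  df <- data.frame(
    id = rep(id, length(picked)),
    n0 = vapply(picked, function(r) r$n, integer(1)),
    l = vapply(picked, function(r) as.integer(to_orig(r$local$seq_start)), integer(1)),
    r = vapply(picked, function(r) as.integer(to_orig(r$local$seq_end)), integer(1)),
    Z = vapply(picked, function(r) r$Z, numeric(1)),
    S = rep(NA_real_, length(picked)),
    F_max = vapply(picked, function(r) r$F_max, numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(df, details = picked, class = c("tr_annotations", "data.frame"))
}

#' False discovery rate from real and shuffled hit counts
#'
#' FDR = FP / (FP + TP), identifying the hit count in the shuffled databank
#' with FP and the hit count in the real databank with FP + TP.
#'
#' @param real_hits Hits in the real sequence set (FP + TP).
#' @param shuffled_hits Hits in the shuffled twin set (FP).
#' @return FDR as a fraction in [0, 1].
#' @examples
#' estimate_fdr(3720, 1284) # 0.345...
#' @export
estimate_fdr <- function(real_hits, shuffled_hits) {
  if (real_hits <= 0) stop_invalid("FDR undefined: no hits in the real set")
  if (shuffled_hits < 0 || shuffled_hits > real_hits)
    stop_invalid("need 0 <= shuffled_hits <= real_hits")
  shuffled_hits / real_hits
}

#' Detect tandem repeats in a protein sequence
#'
#' End-to-end convenience wrapper: re-code, scan consensus lengths, filter to
#' non-redundant annotations, and attach the divergence degree S of each
#' call (computed from the repeat multiple alignment, in 20-letter residue
#' space by default).
#'
#' @param protein Amino-acid string.
#' @param id Sequence identifier.
#' @param ... Passed to \code{\link{scan_sequence}} (n_min, n_max, set_size,
#'   shuffles, seed, del, ...).
#' @param z0 Significance threshold for calls.
#' @param symbol_space Symbol space for S ("residues20" or "groups5").
#' @return A \code{tr_annotations} data.frame (see
#'   \code{\link{filter_periods}}) with S filled in.
#' @export
detect_repeats <- function(protein, id = "seq", ..., z0 = 6.0,
                           symbol_space = "residues20") {
  rseq <- recode_sequence(protein, id = id)
  spec <- scan_sequence(rseq, ...)
  ann <- filter_periods(spec, z0 = z0)
  details <- attr(ann, "details")
  for (i in seq_along(details)) {
    s <- tryCatch({
      rma <- repeats_from_alignment(details[[i]]$local, rseq)
      divergence_degree(rma, symbol_space = symbol_space)$S
    }, error = function(e) NA_real_)
    ann$S[i] <- s
  }
  ann
}
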