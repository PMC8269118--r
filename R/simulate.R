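#' Average amino-acid composition of UniProtKB/Swiss-Prot
#'
#' The standard published average residue composition (percent) of
#' UniProtKB/Swiss-Prot, used as the background model for all simulated
#' sequences. Fully overridable wherever a composition is accepted.
#'
#' @return Named numeric vector over the 20 standard residues, normalized to
#'   sum to 1.
#' @export
swissprot_composition <- function() {
  pct <- c(
    A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38,
    Q = 3.93, E = 6.72, G = 7.07, H = 2.27, I = 5.91,
    L = 9.65, K = 5.80, M = 2.41, F = 3.86, P = 4.74,
    S = 6.63, T = 5.35, W = 1.10, Y = 2.92, V = 6.86
  )
  pct / sum(pct)
}

random_residues <- function(m, composition) {
  sample(names(composition), m, replace = TRUE, prob = composition)
}

#' Specification of one artificial tandem-repeat sequence
#'
#' @param n Repeat unit (consensus) length, >= 2.
#' @param k Number of tandem copies, >= 2.
#' @param substitution_pct Substitution percentage i: floor(i/100 * n*k)
#'   substitution events are applied at uniformly random positions drawn with
#'   replacement (values above 100 are meaningful: positions can mutate more
#'   than once, and a substitution may silently restore the residue).
#' @param indel_rate Indel events per 100 repeat residues (default 1).
#' @param flank Total random flanking residues the mutated repeat array is
#'   inserted into (default 600).
#' @param composition Residue frequency table (default Swiss-Prot average).
#' @param seed Integer seed.
#' @return Object of class \code{artificial_tr_spec}.
#' @export
artificial_tr_spec <- function(n, k, substitution_pct = 0, indel_rate = 1,
                               flank = 600L,
                               composition = swissprot_composition(),
                               seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 2L) stop_invalid("'n' must be >= 2")
  if (k < 2L) stop_invalid("'k' must be >= 2")
  if (substitution_pct < 0) stop_invalid("'substitution_pct' must be >= 0")
  if (flank < 0L) stop_invalid("'flank' must be >= 0")
  if (!setequal(names(composition), names(swissprot_composition())))
    stop_invalid("'composition' must cover exactly the 20 standard residues")
  structure(list(n = n, k = k, substitution_pct = substitution_pct,
                 indel_rate = indel_rate, flank = as.integer(flank),
                 composition = composition / sum(composition),
                 seed = as.integer(seed)),
            class = "artificial_tr_spec")
}

#' Generate one labeled artificial tandem-repeat sequence
#'
#' Draws a random repeat unit from the background composition (homo-repeat
#' units, made of a single residue type, are rejected and redrawn), repeats
#' it k times, applies \code{floor(i/100 * n k)} substitution events
#' (uniform positions with replacement, uniform target residue over the 20),
#' applies \code{round(n k / 100 * indel_rate)} single-residue indel events
#' (insertion or deletion with probability 1/2 each, uniform position,
#' insertions drawn from the composition), and embeds the mutated array at a
#' uniformly random position inside \code{flank} random background residues.
#' The true repeat boundaries are recorded before detection.
#'
#' @param spec An \code{artificial_tr_spec}.
#' @param unit Optional fixed repeat unit (character vector of residues);
#'   when supplied the unit-drawing step is skipped, so one unit can be
#'   reused across several copy numbers or mutation levels.
#' @return Object of class \code{labeled_sequence}: \code{id},
#'   \code{sequence}, true boundaries \code{l0}, \code{r0}, true \code{n},
#'   \code{unit}, \code{spec}.
#' @export
make_artificial_tr_sequence <- function(spec, unit = NULL) {
  stopifnot(inherits(spec, "artificial_tr_spec"))
  set.seed(spec$seed)
  comp <- spec$composition
  if (is.null(unit)) {
    repeat {
      unit <- random_residues(spec$n, comp)
      if (length(unique(unit)) > 1L) break  # homo-repeats excluded
    }
  } else if (length(unit) != spec$n) {
    stop_invalid("'unit' length (%d) must equal spec n (%d)",
                 length(unit), spec$n)
  }
  tr <- rep(unit, spec$k)
  nk <- spec$n * spec$k
  nsub <- floor(spec$substitution_pct / 100 * nk)
  if (nsub > 0L) {
    pos <- sample.int(nk, nsub, replace = TRUE)
    res <- sample(names(swissprot_composition()), nsub, replace = TRUE)
    for (e in seq_len(nsub)) tr[pos[e]] <- res[e]
  }
  nindel <- round(nk / 100 * spec$indel_rate)
  if (nindel > 0L) {
    for (e in seq_len(nindel)) {
      if (stats::runif(1) < 0.5 && length(tr) > 1L) {
        tr <- tr[-sample.int(length(tr), 1L)]
      } else {
        at <- sample.int(length(tr) + 1L, 1L)
        tr <- append(tr, random_residues(1L, comp), after = at - 1L)
      }
    }
  }
  flank <- if (spec$flank > 0L) random_residues(spec$flank, comp) else character(0)
  cut <- if (spec$flank > 0L) sample.int(spec$flank + 1L, 1L) - 1L else 0L
  full <- c(flank[seq_len(cut)], tr,
            if (cut < spec$flank) flank[(cut + 1L):spec$flank] else character(0))
  structure(
    list(
      id = sprintf("tr_n%d_k%d_i%g_s%d", spec$n, spec$k,
                   spec$substitution_pct, spec$seed),
      sequence = paste(full, collapse = ""),
      l0 = cut + 1L,
      r0 = cut + length(tr),
      n = spec$n,
      unit = unit,
      spec = spec
    ),
    class = "labeled_sequence"
  )
}

#' @export
print.labeled_sequence <- function(x, ...) {
  cat(sprintf("<labeled_sequence> %s: %d aa, true TR n=%d at %d..%d\n",
              x$id, nchar(x$sequence), x$n, x$l0, x$r0))
  invisible(x)
}

#' Generate a benchmark set of labeled artificial TR sequences
#'
#' Cartesian construction over unit lengths and copy numbers: for each n,
#' \code{units_per_n} random units are drawn and each unit is repeated at
#' every k, mutated at substitution percentage \code{i} with indels at
#' \code{indel_rate} per 100 residues, and embedded in random flanks. The
#' defaults reproduce the full 9 x 100 x 6 = 5400-sequence design; both
#' grids and \code{units_per_n} scale the set down for desk-scale runs.
#'
#' @param i Substitution percentage applied to every sequence.
#' @param n_values Unit lengths (default c(2,5,7,10,20,40,60,80,100)).
#' @param k_values Copy numbers (default c(4,8,16,24,32,50)).
#' @param units_per_n Random units per n (default 100).
#' @param seed Integer seed; units are keyed by (seed, n, unit), mutations by
#'   (seed, n, unit, k).
#' @param flank,indel_rate,composition Passed to each sequence spec.
#' @return List of \code{labeled_sequence}.
#' @export
make_benchmark_set <- function(i, n_values = c(2L, 5L, 7L, 10L, 20L, 40L,
                                               60L, 80L, 100L),
                               k_values = c(4L, 8L, 16L, 24L, 32L, 50L),
                               units_per_n = 100L, seed = 1L, flank = 600L,
                               indel_rate = 1,
                               composition = swissprot_composition()) {
  if (!length(n_values) || !length(k_values) || units_per_n < 1L)
    stop_invalid("empty benchmark grid")
  out <- vector("list", length(n_values) * units_per_n * length(k_values))
  idx <- 0L
  for (n in n_values) {
    for (u in seq_len(units_per_n)) {
      set.seed(substream_seed(seed, n, u, 3L))
      repeat {
        unit <- random_residues(n, composition)
        if (length(unique(unit)) > 1L) break
      }
      for (k in k_values) {
        spec <- artificial_tr_spec(
          n = n, k = k, substitution_pct = i, indel_rate = indel_rate,
          flank = flank, composition = composition,
          seed = substream_seed(seed, n, u, k, 5L)
        )
        ls <- make_artificial_tr_sequence(spec, unit = unit)
        ls$id <- sprintf("n%d_u%d_k%d_i%g", n, u, k, i)
        idx <- idx + 1L
        out[[idx]] <- ls
      }
    }
  }
  out
}

#' Randomly shuffle the residues of a sequence
#'
#' Uniform permutation; composition and length are preserved.
#'
#' @param seq Amino-acid string.
#' @param seed Integer seed.
#' @return Shuffled string.
#' @export
shuffle_sequence <- function(seq, seed = 1L) {
  set.seed(seed)
  paste(sample(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Score detections against a labeled sequence
#'
#' A detection is correct when some annotation's consensus length exactly
#' equals the true n and the annotated region overlaps the true repeat
#' region by at least 50\% of the true region's length; when several
#' non-overlapping annotations share the true n, their intersection lengths
#' with the true region are summed.
#'
#' @param annotations A \code{tr_annotations} data.frame (columns n0, l, r).
#' @param truth A \code{labeled_sequence}.
#' @return TRUE/FALSE.
#' @export
evaluate_detection <- function(annotations, truth) {
  stopifnot(inherits(truth, "labeled_sequence"))
  if (!NROW(annotations)) return(FALSE)
  hits <- annotations[annotations$n0 == truth$n, , drop = FALSE]
  if (!nrow(hits)) return(FALSE)
  true_len <- truth$r0 - truth$l0 + 1L
  ov <- sum(vapply(seq_len(nrow(hits)), function(j)
    span_overlap(hits$l[j], hits$r[j], truth$l0, truth$r0), integer(1)))
  ov >= 0.5 * true_len
}

#' Run the detector over a benchmark set and tabulate detection rates
#'
#' Scans every labeled sequence, filters calls at \code{z0}, scores each
#' with \code{\link{evaluate_detection}} and returns one row per sequence.
#'
#' @param seqs List of \code{labeled_sequence}.
#' @param n_min,n_max Consensus length range to scan.
#' @param set_size,shuffles,seed,del,probe_copies Passed to
#'   \code{\link{scan_sequence}}.
#' @param z0 Significance threshold.
#' @param verbose Print one line per sequence.
#' @return data.frame with columns id, n, k, i, detected.
#' @export
benchmark_detection <- function(seqs, n_min = 2L, n_max = 12L,
                                set_size = 100L, shuffles = 50L, seed = 1L,
                                z0 = 6.0, del = 25.0, probe_copies = 1000L,
                                verbose = FALSE) {
  qsets <- lapply(n_min:n_max, function(n)
    generate_matrix_set(n, count = set_size, seed = seed,
                        probe_copies = probe_copies))
  names(qsets) <- as.character(n_min:n_max)
  rows <- lapply(seqs, function(ls) {
    rseq <- recode_sequence(ls$sequence, id = ls$id)
    spec <- scan_sequence(rseq, n_min = n_min, n_max = n_max,
                          set_size = set_size, shuffles = shuffles,
                          seed = seed, del = del,
                          probe_copies = probe_copies, matrix_sets = qsets)
    ann <- filter_periods(spec, z0 = z0)
    det <- evaluate_detection(ann, ls)
    if (verbose)
      message(sprintf("%s: %d calls, detected=%s", ls$id, nrow(ann), det))
    data.frame(id = ls$id, n = ls$n, k = ls$spec$k,
               i = ls$spec$substitution_pct, detected = det,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
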