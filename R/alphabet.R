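#' Five-group physicochemical alphabet
#'
#' The 20 standard amino acids partitioned into five groups by side-chain
#' polarity: non-polar \code{K} (G, A, V, I, L, P), polar \code{N}
#' (S, T, C, M, Q, N), aromatic \code{I} (F, Y, W), positively charged
#' \code{M} (K, R, H) and negatively charged \code{T} (D, E). Group symbols
#' are fixed integers: K=1, N=2, I=3, M=4, T=5; this numbering is global and
#' is serialized with all results.
#'
#' @return A named integer vector mapping each residue letter to its group
#'   symbol (1..5).
#' @examples
#' residue_groups()[c("G", "S", "F", "K", "D")]
#' @export
residue_groups <- function() {
  c(
    G = 1L, A = 1L, V = 1L, I = 1L, L = 1L, P = 1L,
    S = 2L, T = 2L, C = 2L, M = 2L, Q = 2L, N = 2L,
    F = 3L, Y = 3L, W = 3L,
    K = 4L, R = 4L, H = 4L,
    D = 5L, E = 5L
  )
}

#' @rdname residue_groups
#' @return \code{group_letters()}: the five group letters in symbol order.
#' @export
group_letters <- function() c("K", "N", "I", "M", "T")

#' Re-code a protein sequence into the five-group alphabet
#'
#' Maps each standard residue to its physicochemical group symbol (1..5).
#' Non-standard letters (B, J, O, U, X, Z, '*', and anything else outside the
#' 20-letter alphabet) are either skipped with their positions recorded
#' (default, preserving local periodic phase) or raise an error.
#'
#' @param protein Amino-acid string (case-insensitive).
#' @param id Sequence identifier carried through to results.
#' @param nonstandard Either \code{"skip"} (drop the residue, record its
#'   1-based position) or \code{"error"}.
#' @return An object of class \code{recoded_seq}: list with \code{id},
#'   \code{symbols} (integer vector over 1..5), \code{source} (upper-cased
#'   input), \code{skipped_positions} and \code{positions} (for each symbol,
#'   its 1-based position in \code{source}).
#' @examples
#' r <- recode_sequence("GASDF")
#' r$symbols # 1 1 2 5 3  (K K N T I)
#' @export
recode_sequence <- function(protein, id = "seq",
                            nonstandard = c("skip", "error")) {
  nonstandard <- match.arg(nonstandard)
  if (length(protein) != 1L || !is.character(protein) || !nzchar(protein))
    stop("'protein' must be a non-empty amino-acid string")
  src <- toupper(protein)
  letters20 <- strsplit(src, "", fixed = TRUE)[[1L]]
  sym <- unname(residue_groups()[letters20])
  bad <- which(is.na(sym))
  if (length(bad) && nonstandard == "error")
    stop(sprintf("non-standard residue '%s' at position %d in '%s'",
                 letters20[bad[1L]], bad[1L], id))
  keep <- setdiff(seq_along(sym), bad)
  structure(
    list(
      id = id,
      symbols = as.integer(sym[keep]),
      source = src,
      skipped_positions = as.integer(bad),
      positions = as.integer(keep)
    ),
    class = "recoded_seq"
  )
}

#' @export
print.recoded_seq <- function(x, ...) {
  cat(sprintf("<recoded_seq> %s: %d symbols (%d skipped)\n",
              x$id, length(x$symbols), length(x$skipped_positions)))
  head_n <- min(60L, length(x$symbols))
  cat(" ", paste(group_letters()[x$symbols[seq_len(head_n)]], collapse = ""),
      if (length(x$symbols) > head_n) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Render group symbols as group letters
#'
#' @param symbols Integer vector over 1..5 (NA allowed, rendered as '.').
#' @return Character vector of group letters.
#' @keywords internal
symbols_to_letters <- function(symbols) {
  out <- rep(".", length(symbols))
  ok <- !is.na(symbols)
  out[ok] <- group_letters()[symbols[ok]]
  out
}
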