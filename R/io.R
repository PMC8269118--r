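#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of upper-cased amino-acid strings; names
#'   are the full record descriptions.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  set <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- names(set)
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write repeat annotations to TSV and per-hit JSON
#'
#' Produces \code{<prefix>.tsv} (one row per annotation: id, n0, l, r, Z, S,
#' F_max) and, for each hit, \code{<prefix>_hit<k>.json} holding the
#' M_max weight matrix (bit-identical JSON round-trip), the alignment in
#' five-letter dot notation, and the scalar call fields, with a fixed field
#' order.
#'
#' @param annotations A \code{tr_annotations} data.frame.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_annotations <- function(annotations, prefix) {
  tsv <- paste0(prefix, ".tsv")
  df <- as.data.frame(annotations)[, c("id", "n0", "l", "r", "Z", "S",
                                       "F_max"), drop = FALSE]
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- tsv
  details <- attr(annotations, "details")
  for (k in seq_along(details)) {
    d <- details[[k]]
    jf <- sprintf("%s_hit%d.json", prefix, k)
    jsonlite::write_json(
      list(
        id = df$id[k], n0 = df$n0[k], l = df$l[k], r = df$r[k],
        Z = df$Z[k], S = df$S[k], F_max = df$F_max[k],
        M_max = unclass(d$M_max),
        alignment = render_alignment(d$local)
      ),
      jf, digits = I(17), auto_unbox = TRUE
    )
    files <- c(files, jf)
  }
  invisible(files)
}

#' Read an annotation TSV written by \code{write_annotations}
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
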