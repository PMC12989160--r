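#' Read per-residue score tracks from TSV
#'
#' A track file carries one row per residue position and one column per
#' track (e.g. the 18 conservation scores of an AACon run, or an IUPred-style
#' disorder score), with a `position` column first. Missing scores are
#' encoded explicitly as `NA` (or empty cells), never as silent zeros.
#'
#' @param path Path to a tab-separated file with header
#'   `position <track> <track> ...`.
#' @param protein_id Identifier stored on the tracks; defaults to the file
#'   name without extension.
#' @param sequence Optional `ProteinSequence`; when given, the number of
#'   rows must equal the sequence length.
#' @return A `ResidueTrackSet`: list with `protein_id` and `tracks`, a named
#'   list of numeric vectors (one per track, `NA` = missing).
#' @export
read_tracks <- function(path, protein_id = NULL, sequence = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"position" %in% names(df)) {
    stop("track file '", path, "' has no 'position' column", call. = FALSE)
  }
  if (ncol(df) < 2L) stop("track file '", path, "' has no track columns",
                          call. = FALSE)
  ord <- order(df$position)
  df <- df[ord, , drop = FALSE]
  if (!identical(as.integer(df$position), seq_len(nrow(df)))) {
    stop("track file '", path, "' positions are not 1..n", call. = FALSE)
  }
  if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  if (!is.null(sequence) && nrow(df) != nchar(sequence$residues)) {
    stop(sprintf("track length %d does not match sequence '%s' length %d",
                 nrow(df), sequence$id, nchar(sequence$residues)),
         call. = FALSE)
  }
  tracks <- lapply(df[setdiff(names(df), "position")], as.numeric)
  structure(list(protein_id = protein_id, tracks = tracks),
            class = "ResidueTrackSet")
}

#' Write per-residue score tracks to TSV
#' @param tracks Named list of equal-length numeric vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  n <- unique(vapply(tracks, length, integer(1)))
  if (length(n) != 1L) stop("tracks have differing lengths", call. = FALSE)
  df <- data.frame(position = seq_len(n), tracks, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
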