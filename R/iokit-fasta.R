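#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a list of protein sequences. Record ids are taken
#' from the header line up to the first whitespace; sequences are uppercased
#' and ambiguity / non-standard codes (U, B, Z, J, O) are mapped to `X` with
#' a warning.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return Named list of `ProteinSequence` objects, each a list with elements
#'   `id` and `residues` (a single string over the 20-letter alphabet plus
#'   `X`).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 some description", "ACDE", "FGHI"), fa)
#' seqs <- read_fasta(fa)
#' seqs$p1$residues
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("could not parse FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  residues <- toupper(as.character(set))
  mapped <- FALSE
  for (code in AA_AMBIGUOUS) {
    if (any(grepl(code, residues, fixed = TRUE))) mapped <- TRUE
    residues <- gsub(code, "X", residues, fixed = TRUE)
  }
  if (mapped) {
    warning("non-standard residue codes (U/B/Z/J/O) mapped to X",
            call. = FALSE)
  }
  seqs <- Map(protein_sequence, ids, residues)
  names(seqs) <- ids
  seqs
}

#' Construct a protein sequence object
#'
#' @param id Sequence identifier.
#' @param residues Residue string over `ACDEFGHIKLMNPQRSTVWY` plus `X`.
#' @return A `ProteinSequence` object.
#' @export
protein_sequence <- function(id, residues) {
  residues <- toupper(residues)
  if (nchar(residues) < 1L) stop("empty sequence for id '", id, "'",
                                 call. = FALSE)
  chars <- strsplit(residues, "")[[1]]
  check_residue(chars, what = paste0("residue in sequence '", id, "'"),
                allow_x = TRUE)
  structure(list(id = id, residues = residues,
                 has_x = any(chars == "X")),
            class = "ProteinSequence")
}

#' @export
print.ProteinSequence <- function(x, ...) {
  cat(sprintf("ProteinSequence %s (%d aa)%s\n", x$id, nchar(x$residues),
              if (isTRUE(x$has_x)) " [contains X]" else ""))
  invisible(x)
}

#' @export
length.ProteinSequence <- function(x) nchar(x$residues)

#' Residue letter(s) at 1-based position(s)
#' @param seq A `ProteinSequence` or plain residue string.
#' @param pos Integer position(s), 1-based.
#' @return Character vector of residue letters; `NA` for out-of-range
#'   positions.
#' @export
residue_at <- function(seq, pos) {
  s <- if (inherits(seq, "ProteinSequence")) seq$residues else seq
  n <- nchar(s)
  out <- rep(NA_character_, length(pos))
  ok <- pos >= 1L & pos <= n
  out[ok] <- substring(s, pos[ok], pos[ok])
  out
}

#' Write protein sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: canonical single-line records, so that
#' `write_fasta(read_fasta(f))` reproduces the sequences byte-identically
#' for canonical input.
#'
#' @param seqs List of `ProteinSequence` objects.
#' @param path Output path.
#' @param width Line width for wrapping; `Inf` (default) writes one line per
#'   sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = Inf) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    if (is.finite(width)) {
      n <- nchar(s$residues)
      starts <- seq(1L, n, by = width)
      writeLines(substring(s$residues, starts, pmin(starts + width - 1L, n)),
                 con)
    } else {
      writeLines(s$residues, con)
    }
  }
  invisible(path)
}
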