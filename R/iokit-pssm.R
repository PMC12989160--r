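#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the `-out_ascii_pssm` output dialect: header lines, then one row
#' per sequence position carrying the position index, the query residue
#' letter and two 20-column score blocks. Only the first block (log-odds
#' scores, column order `A R N D C Q E G H I L K M F P S T W Y V`) is read;
#' trailing per-row and per-file statistics are ignored.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence Optional `ProteinSequence` to validate against: the number
#'   of profile rows must equal the sequence length and each row's residue
#'   letter must agree with the sequence.
#' @param protein_id Identifier stored on the profile; defaults to the
#'   attached sequence's id or the file name.
#' @return A `PSSMProfile`: list with `protein_id`, `residues` (per-position
#'   query letters) and `scores`, an `n x 20` integer matrix with columns in
#'   PSI-BLAST order.
#' @export
read_pssm_ascii <- function(path, sequence = NULL, protein_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rows <- grep("^\\s*[0-9]+\\s+[A-Zа-я]\\s+-?[0-9]", lines, value = TRUE)
  if (length(rows) == 0L) {
    stop("no PSSM rows found in '", path, "'", call. = FALSE)
  }
  parsed <- lapply(rows, function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 22L) {
      stop("PSSM row with fewer than 20 scores: '", trimws(ln), "'",
           call. = FALSE)
    }
    scores <- suppressWarnings(as.integer(tok[3:22]))
    if (anyNA(scores)) {
      stop("non-integer score in PSSM row: '", trimws(ln), "'",
           call. = FALSE)
    }
    list(pos = as.integer(tok[1]), aa = toupper(tok[2]), scores = scores)
  })
  scores <- do.call(rbind, lapply(parsed, `[[`, "scores"))
  colnames(scores) <- AA_PSSM_ORDER
  residues <- vapply(parsed, `[[`, character(1), "aa")

  if (is.null(protein_id)) {
    protein_id <- if (!is.null(sequence)) sequence$id else
      sub("\\.[^.]*$", "", basename(path))
  }
  profile <- structure(
    list(protein_id = protein_id, residues = residues, scores = scores),
    class = "PSSMProfile")
  if (!is.null(sequence)) attach_sequence_to_pssm(profile, sequence) else
    profile
}

#' @keywords internal
attach_sequence_to_pssm <- function(profile, sequence) {
  n <- nchar(sequence$residues)
  if (nrow(profile$scores) != n) {
    stop(sprintf(
      "PSSM length %d does not match sequence '%s' length %d",
      nrow(profile$scores), sequence$id, n), call. = FALSE)
  }
  seq_chars <- strsplit(sequence$residues, "")[[1]]
  mismatch <- which(profile$residues != seq_chars & seq_chars != "X")
  if (length(mismatch) > 0L) {
    i <- mismatch[1]
    stop(sprintf(
      "PSSM residue '%s' at position %d disagrees with sequence '%s' ('%s')",
      profile$residues[i], i, sequence$id, seq_chars[i]), call. = FALSE)
  }
  profile$protein_id <- sequence$id
  profile
}

#' @export
print.PSSMProfile <- function(x, ...) {
  cat(sprintf("PSSMProfile %s: %d positions x 20 scores\n",
              x$protein_id, nrow(x$scores)))
  invisible(x)
}

#' Write a PSSM profile in PSI-BLAST ASCII layout
#'
#' Emits a file that [read_pssm_ascii()] parses back to the same profile.
#' Used by the synthetic-fixture generator.
#'
#' @param profile A `PSSMProfile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm_ascii <- function(profile, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", AA_PSSM_ORDER), collapse = ""))),
    con)
  for (i in seq_len(nrow(profile$scores))) {
    writeLines(sprintf("%5d %s %s", i, profile$residues[i],
                       paste(sprintf("%3d", profile$scores[i, ]),
                             collapse = "")), con)
  }
  writeLines("", con)
  invisible(path)
}
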