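#' Read a classic DSSP output file
#'
#' Parses the fixed-column residue section that follows the
#' `"  #  RESIDUE"` header of classic DSSP output. The 8-state DSSP
#' secondary-structure code is collapsed to 3 states using the common
#' convention `{H,G,I} -> H` (helix), `{E,B} -> E` (strand), everything
#' else (`T`, `S`, blank) `-> C` (coil). The `ACC` column is parsed as
#' absolute solvent accessibility in square Angstrom. Chain-break rows
#' (`!` in the residue column) are skipped with a warning.
#'
#' @param path Path to a DSSP output file.
#' @return Data frame with columns `residue_number`, `aa`, `ss` (one of
#'   `H`, `E`, `C`) and `acc`.
#' @export
read_dssp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) {
    stop("not a classic DSSP file (no '  #  RESIDUE' header): ", path,
         call. = FALSE)
  }
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nchar(body) >= 38L]
  if (length(body) == 0L) stop("DSSP file has no residue rows: ", path,
                               call. = FALSE)
  aa <- substr(body, 14L, 14L)
  breaks <- aa == "!"
  if (any(breaks)) {
    warning(sum(breaks), " chain-break row(s) skipped in DSSP file",
            call. = FALSE)
    body <- body[!breaks]
    aa <- aa[!breaks]
  }
  resno <- as.integer(trimws(substr(body, 6L, 10L)))
  ss8 <- substr(body, 17L, 17L)
  acc <- as.numeric(trimws(substr(body, 35L, 38L)))
  data.frame(residue_number = resno, aa = toupper(aa),
             ss = collapse_ss8(ss8), acc = acc,
             stringsAsFactors = FALSE)
}

#' Collapse 8-state DSSP codes to 3 states
#' @param ss8 Character vector of DSSP codes.
#' @return Character vector over `{H, E, C}`.
#' @export
collapse_ss8 <- function(ss8) {
  out <- rep("C", length(ss8))
  out[ss8 %in% c("H", "G", "I")] <- "H"
  out[ss8 %in% c("E", "B")] <- "E"
  out
}

#' Write per-residue annotations in classic DSSP layout
#'
#' Minimal writer used by the synthetic-fixture generator; the output is
#' parseable by [read_dssp()].
#'
#' @param residue_number,aa,ss8,acc Parallel per-residue vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dssp <- function(residue_number, aa, ss8, acc, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"),
    con)
  lines <- sprintf("%5d%5d A %s  %s%17s%4.0f", seq_along(residue_number),
                   residue_number, aa, ss8, "", acc)
  writeLines(lines, con)
  invisible(path)
}
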