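# Amino-acid alphabets, physicochemical classes and per-atom constants
# shared across the feature-extraction modules.

#' @keywords internal
AA_ALPHABETICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# PSI-BLAST PSSM column order
#' @keywords internal
AA_PSSM_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# residues mapped to X on ingestion (selenocysteine, ambiguity codes)
#' @keywords internal
AA_AMBIGUOUS <- c("U", "B", "Z", "J", "O")

#' Six physicochemical side-chain classes
#'
#' Partition of the 20 standard residues into aliphatic, sulfur-containing,
#' aromatic, polar (uncharged), positively charged and negatively charged
#' classes, used for neighbourhood-composition features. The partition covers
#' all 20 residues exactly once.
#'
#' @format Named list of character vectors.
#' @export
AA_SIX_CLASSES <- list(
  aliphatic = c("G", "A", "V", "L", "I", "P"),
  sulfur    = c("C", "M"),
  aromatic  = c("F", "W", "Y"),
  polar     = c("S", "T", "N", "Q"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E")
)

# Theoretical maximum accessible surface areas (A^2) per residue type,
# Tien et al. (2013), used for relative ASA normalisation.
#' @keywords internal
MAX_ASA_TIEN2013 <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

# Three-letter to one-letter residue code map.
#' @keywords internal
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  SEC = "X", PYL = "X", UNK = "X", MSE = "X"
)

#' @keywords internal
AA_ONE_TO_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
  X = "UNK"
)

# Van der Waals radii (A) by element for surface-area quadrature.
#' @keywords internal
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
               P = 1.80, SE = 1.90)

#' @keywords internal
VDW_DEFAULT <- 1.70

#' @keywords internal
vdw_radius <- function(element) {
  element <- toupper(element)
  r <- VDW_RADII[element]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

#' @keywords internal
element_from_atom_name <- function(atom_name) {
  # first alphabetic character of the stripped atom name; two-letter
  # elements (SE) only occur in residues already mapped to X here
  first <- sub("^[0-9' ]*", "", atom_name)
  toupper(substr(first, 1, 1))
}

#' @keywords internal
check_residue <- function(aa, what = "residue", allow_x = FALSE) {
  ok <- AA_ALPHABETICAL
  if (allow_x) ok <- c(ok, "X")
  bad <- !(aa %in% ok)
  if (any(bad)) {
    stop(sprintf("invalid %s letter(s): %s", what,
                 paste(unique(aa[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(aa)
}
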