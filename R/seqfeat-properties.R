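#' Change in amino-acid property upon mutation
#'
#' For a physicochemical property `P` tabulated per residue, the feature is
#' the difference `P(mutant) - P(wild-type)`. Antisymmetric in
#' `(wt, mut)` by construction. Residue `X` (unknown / non-standard) yields
#' a missing value rather than an error, so affected mutations are skipped
#' downstream, not aborted.
#'
#' @param wt,mut One-letter residue codes.
#' @param property_table Named numeric vector over the 20 residues, or an
#'   `index1` `AAindexEntry`.
#' @return `P(mut) - P(wt)`, or `NA` if either residue is not covered.
#' @examples
#' kd <- c(A = 1.8, V = 4.2)  # Kyte-Doolittle hydropathy excerpt
#' delta_property("A", "V", kd)  # 2.4
#' @export
delta_property <- function(wt, mut, property_table) {
  if (inherits(property_table, "AAindexEntry")) {
    stopifnot(property_table$kind == "index1")
    property_table <- property_table$values
  }
  if (!(wt %in% names(property_table)) || !(mut %in% names(property_table))) {
    return(NA_real_)
  }
  unname(property_table[[mut]] - property_table[[wt]])
}

#' Load a set of per-residue property tables
#'
#' Reads AAindex1-format files into a named list of 20-value property
#' tables. The default configuration of the pipeline uses a curated list of
#' physical, chemical, energetic and conformational parameters (152 in the
#' reference configuration); the list is supplied as files, not hard-coded.
#'
#' @param paths Character vector of AAindex1-format file paths.
#' @return A `PropertySet`: named list of numeric 20-vectors.
#' @export
read_property_set <- function(paths) {
  entries <- list()
  for (p in paths) entries <- c(entries, read_aaindex(p, "index1"))
  props <- lapply(entries, `[[`, "values")
  incomplete <- vapply(props, anyNA, logical(1))
  if (any(incomplete)) {
    warning("property table(s) with missing residues: ",
            paste(names(props)[incomplete], collapse = ", "), call. = FALSE)
  }
  structure(props, class = "PropertySet")
}

#' Substitution-matrix feature
#'
#' The `(wt, mut)` cell of an AAindex2 substitution matrix (one feature per
#' configured matrix). Asymmetric matrices distinguish `f(R,Q)` from
#' `f(Q,R)`; symmetric matrices resolve both orders identically.
#'
#' @param wt,mut One-letter residue codes.
#' @param entry An `index2` (or `index3`) `AAindexEntry`.
#' @return Matrix cell value, or `NA` for a missing cell or `X` residue.
#' @export
substitution_matrix_feature <- function(wt, mut, entry) {
  if (wt == "X" || mut == "X") return(NA_real_)
  tryCatch(aaindex_lookup(entry, wt, mut, strict = FALSE),
           error = function(e) NA_real_)
}

#' Neighbour contact-potential differences
#'
#' From an AAindex3 pairwise contact-potential table `CP`, three features
#' describing how the mutation changes the potential of the site's pairing
#' with its sequence neighbours:
#' `delta_N = CP(left, mut) - CP(left, wt)`,
#' `delta_C = CP(right, mut) - CP(right, wt)`,
#' and `delta_LR = CP(left, right)`, the potential of the left and right
#' neighbours themselves. A side missing at a sequence terminus yields a
#' missing value for that component, never a silent zero.
#'
#' @param seq A `ProteinSequence` or residue string.
#' @param pos 1-based mutation position.
#' @param entry An `index3` `AAindexEntry`.
#' @param mut Mutant residue letter.
#' @param wt Wild-type residue letter; defaults to the sequence letter at
#'   `pos`.
#' @return Named numeric vector `c(delta_N, delta_C, delta_LR)` with `NA`
#'   for unavailable components.
#' @export
neighbor_contact_potential_delta <- function(seq, pos, entry, mut,
                                             wt = NULL) {
  s <- if (inherits(seq, "ProteinSequence")) seq$residues else seq
  n <- nchar(s)
  if (pos < 1L || pos > n) stop("position ", pos, " outside sequence",
                                call. = FALSE)
  if (is.null(wt)) wt <- substring(s, pos, pos)
  left <- if (pos > 1L) substring(s, pos - 1L, pos - 1L) else NA_character_
  right <- if (pos < n) substring(s, pos + 1L, pos + 1L) else NA_character_
  cp <- function(a, b) {
    if (is.na(a) || is.na(b) || a == "X" || b == "X") return(NA_real_)
    tryCatch(aaindex_lookup(entry, a, b, strict = FALSE),
             error = function(e) NA_real_)
  }
  delta_side <- function(nb) {
    if (is.na(nb)) return(NA_real_)
    cp(nb, mut) - cp(nb, wt)
  }
  c(delta_N = delta_side(left),
    delta_C = delta_side(right),
    delta_LR = cp(left, right))
}
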