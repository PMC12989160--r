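#' Physicochemical composition of the mutation neighbourhood
#'
#' Counts the residues in a sequence window around the mutation site
#' (default 6 residues on each side, a 13-residue window; the site itself is
#' excluded) in each of the six side-chain classes of [AA_SIX_CLASSES]:
#' aliphatic, sulfur-containing, aromatic, polar, positively charged and
#' negatively charged. Windows are truncated at the sequence termini, so the
#' six counts always sum to the number of in-bounds neighbours,
#' `min(pos - 1, flank) + min(len - pos, flank)`.
#'
#' @param seq A `ProteinSequence` or residue string.
#' @param pos 1-based mutation position.
#' @param flank Residues considered on each side (default 6).
#' @return Named integer vector of six class counts.
#' @export
neighbor_composition <- function(seq, pos, flank = 6L) {
  s <- if (inherits(seq, "ProteinSequence")) seq$residues else seq
  n <- nchar(s)
  if (pos < 1L || pos > n) stop("position ", pos, " outside sequence",
                                call. = FALSE)
  if (flank < 1L) stop("flank must be >= 1", call. = FALSE)
  idx <- setdiff(seq(max(1L, pos - flank), min(n, pos + flank)), pos)
  chars <- substring(s, idx, idx)
  counts <- vapply(AA_SIX_CLASSES, function(cls) sum(chars %in% cls),
                   integer(1))
  counts
}

#' Window positions around a site, truncated at the termini
#' @keywords internal
window_positions <- function(pos, n, flank = 6L, include_site = TRUE) {
  idx <- seq(max(1L, pos - flank), min(n, pos + flank))
  if (!include_site) idx <- setdiff(idx, pos)
  idx
}

#' PSSM profile features at a mutation site
#'
#' Three evolutionary features from a position-specific scoring matrix:
#' the mean profile score over a window around the site (default 13
#' residues, scoring each in-bounds position by its own native residue
#' column), the score difference `score(pos, mut) - score(pos, wt)`, and
#' the site score `score(pos, wt)` itself.
#'
#' @param profile A `PSSMProfile`.
#' @param pos 1-based position.
#' @param wt,mut Wild-type and mutant residue letters.
#' @param flank Window flank (default 6).
#' @return Named numeric vector `c(window_mean, delta, site_score)`.
#' @export
pssm_features <- function(profile, pos, wt, mut, flank = 6L) {
  stopifnot(inherits(profile, "PSSMProfile"))
  n <- nrow(profile$scores)
  if (pos < 1L || pos > n) stop("position ", pos, " outside PSSM profile",
                                call. = FALSE)
  idx <- window_positions(pos, n, flank)
  native <- profile$residues[idx]
  ok <- native %in% AA_PSSM_ORDER
  window_mean <- if (any(ok)) {
    mean(profile$scores[cbind(idx[ok], match(native[ok], AA_PSSM_ORDER))])
  } else NA_real_
  score_of <- function(aa) {
    if (!aa %in% AA_PSSM_ORDER) return(NA_real_)
    unname(profile$scores[pos, aa])
  }
  site <- score_of(wt)
  c(window_mean = window_mean,
    delta = score_of(mut) - site,
    site_score = unname(site))
}

#' Per-residue track features at a mutation site
#'
#' The track value at the mutation site plus the window mean (missing
#' values excluded from the mean). Used for each of the configured
#' conservation tracks and the disorder track.
#'
#' @param track Numeric per-residue vector (`NA` = missing).
#' @param pos 1-based position.
#' @param flank Window flank (default 6).
#' @return Named numeric vector `c(site_value, window_mean)`; both `NA`
#'   when the whole window is missing.
#' @export
track_features <- function(track, pos, flank = 6L) {
  n <- length(track)
  if (pos < 1L || pos > n) stop("position ", pos, " outside track",
                                call. = FALSE)
  idx <- window_positions(pos, n, flank)
  vals <- track[idx]
  window_mean <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  c(site_value = unname(track[pos]), window_mean = window_mean)
}
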