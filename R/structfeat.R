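# Structure-derived per-residue features from predicted models:
# pLDDT, solvent-accessible surface area (Shrake-Rupley quadrature),
# residue depth, secondary-structure one-hot and inter-residue contacts.

#' Per-residue model confidence (pLDDT)
#'
#' AlphaFold-style models store the predicted local distance difference
#' test (pLDDT, 0-100) in the B-factor column of every atom; the
#' per-residue value is the mean over the residue's atoms (identical for
#' genuine AlphaFold files, where all atoms of a residue share the value).
#'
#' @param model A `StructureModel`.
#' @param pos Residue number.
#' @return Mean B-factor, or `NA` if the residue is absent from the model.
#' @export
residue_plddt <- function(model, pos) {
  a <- residue_atoms(model, pos)
  if (nrow(a) == 0L) return(NA_real_)
  mean(a$bfactor)
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-section spiral lattice; deterministic, so the quadrature is
#' seed-independent.
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' @keywords internal
atom_coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA by test-point quadrature: each atom is inflated by the
#' probe radius, sampled with a deterministic spherical point lattice, and
#' points buried inside any neighbouring inflated atom are discarded. Atom
#' radii come from a standard van der Waals table by element.
#'
#' @param model A `StructureModel`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4, a
#'   water molecule).
#' @param n_points Test points per atom (default 960).
#' @param keep_points Also return the retained (solvent-accessible) surface
#'   points, used by [residue_depth()].
#' @return Named numeric vector of per-residue SASA in square Angstrom
#'   (names are residue numbers). With `keep_points = TRUE`, a list with
#'   elements `residue_sasa`, `atom_sasa` and `surface_points` (matrix).
#' @export
sasa <- function(model, probe_radius = 1.4, n_points = 960L,
                 keep_points = FALSE) {
  xyz <- atom_coords(model)
  n_atoms <- nrow(xyz)
  if (n_atoms < 1L) stop("model has no atoms", call. = FALSE)
  radii <- vdw_radius(model$atoms$element) + probe_radius
  pts <- sphere_points(n_points)
  atom_area <- numeric(n_atoms)
  surf <- if (keep_points) vector("list", n_atoms) else NULL
  # neighbour lists via a single distance computation
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n_atoms)) {
    ri <- radii[i]
    nb <- which(d2[i, ] < (ri + radii)^2 & seq_len(n_atoms) != i)
    p <- sweep(pts * ri, 2L, xyz[i, ], `+`)
    keep <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      rj2 <- radii[j]^2
      # points exactly on a neighbour's inflated sphere (coincident equal
      # atoms) are credited to the lower-indexed atom only
      buried <- dj < rj2 * (1 - 1e-9) |
        (abs(dj - rj2) <= rj2 * 1e-9 & j < i)
      keep <- keep & !buried
      if (!any(keep)) break
    }
    atom_area[i] <- 4 * pi * ri^2 * sum(keep) / n_points
    if (keep_points && any(keep)) surf[[i]] <- p[keep, , drop = FALSE]
  }
  res_no <- model$atoms$residue_number
  residue_sasa <- tapply(atom_area, res_no, sum)
  residue_sasa <- setNames(as.numeric(residue_sasa),
                           names(residue_sasa))[as.character(unique(res_no))]
  if (!keep_points) return(residue_sasa)
  list(residue_sasa = residue_sasa, atom_sasa = atom_area,
       surface_points = do.call(rbind, surf))
}

#' Residue depth below the solvent-accessible surface
#'
#' Distance (Angstrom) from the residue's heavy-atom centroid to the
#' nearest solvent-accessible surface point retained by the Shrake-Rupley
#' quadrature of the whole model. Fully exposed residues have depth about
#' one atomic-plus-probe radius; buried residues have larger depth.
#'
#' @param model A `StructureModel`.
#' @param pos Residue number(s); default all residues.
#' @param probe_radius Probe radius (default 1.4).
#' @param n_points Quadrature points per atom (default 960).
#' @param sasa_result Optional precomputed `sasa(..., keep_points = TRUE)`
#'   result, to avoid recomputation.
#' @return Named numeric vector of depths per requested residue (`NA` for
#'   residues absent from the model).
#' @export
residue_depth <- function(model, pos = NULL, probe_radius = 1.4,
                          n_points = 960L, sasa_result = NULL) {
  if (is.null(sasa_result)) {
    sasa_result <- sasa(model, probe_radius, n_points, keep_points = TRUE)
  }
  surf <- sasa_result$surface_points
  if (is.null(surf) || nrow(surf) == 0L) {
    stop("model has no solvent-accessible surface points", call. = FALSE)
  }
  if (is.null(pos)) pos <- model_residues(model)
  out <- setNames(rep(NA_real_, length(pos)), pos)
  for (k in seq_along(pos)) {
    a <- residue_atoms(model, pos[k])
    a <- a[a$element != "H", , drop = FALSE]
    if (nrow(a) == 0L) next
    centroid <- colMeans(a[, c("x", "y", "z")])
    d2 <- (surf[, 1] - centroid[1])^2 + (surf[, 2] - centroid[2])^2 +
          (surf[, 3] - centroid[3])^2
    out[k] <- sqrt(min(d2))
  }
  out
}

#' Relative solvent accessibility
#'
#' Absolute ASA normalised by the theoretical maximum for the residue type
#' (Tien et al. 2013 values), clipped to `[0, 1]`.
#'
#' @param asa Absolute ASA in square Angstrom.
#' @param residue One-letter residue code(s).
#' @return Relative ASA in `[0, 1]` (`NA` for unknown residue types).
#' @export
relative_asa <- function(asa, residue) {
  mx <- MAX_ASA_TIEN2013[residue]
  pmin(pmax(asa / mx, 0), 1)
}

#' One-hot encoding of 3-state secondary structure
#' @param ss One of `"H"` (helix), `"E"` (strand), `"C"` (coil).
#' @return Named 0/1 vector `c(ss_H, ss_E, ss_C)` with exactly one 1.
#' @export
ss3_onehot <- function(ss) {
  if (!ss %in% c("H", "E", "C")) {
    stop("secondary-structure code must be H, E or C (got '", ss, "')",
         call. = FALSE)
  }
  setNames(as.numeric(c("H", "E", "C") == ss), c("ss_H", "ss_E", "ss_C"))
}

#' Number of inter-residue contacts of a residue
#'
#' Counts residues having at least one atom within `cutoff` of any atom of
#' the query residue. Immediate sequence neighbours (residue-number
#' difference of at most 1) are excluded so trivially bonded backbone
#' neighbours do not count as contacts.
#'
#' @param model A `StructureModel`.
#' @param pos Residue number.
#' @param cutoff Atom-atom distance cutoff in Angstrom (default 7).
#' @return Integer contact count (`NA` if the residue is absent).
#' @export
residue_contacts <- function(model, pos, cutoff = 7) {
  a <- residue_atoms(model, pos)
  if (nrow(a) == 0L) return(NA_integer_)
  others <- model$atoms[abs(model$atoms$residue_number - pos) > 1L, ,
                        drop = FALSE]
  if (nrow(others) == 0L) return(0L)
  am <- as.matrix(a[, c("x", "y", "z")])
  om <- as.matrix(others[, c("x", "y", "z")])
  hits <- logical(nrow(om))
  for (i in seq_len(nrow(am))) {
    d2 <- (om[, 1] - am[i, 1])^2 + (om[, 2] - am[i, 2])^2 +
          (om[, 3] - am[i, 3])^2
    hits <- hits | d2 <= cutoff^2
  }
  length(unique(others$residue_number[hits]))
}

#' Average per-residue features across structural models
#'
#' When several structural models are available for one protein, each
#' feature is averaged per residue across the models. Residues present in
#' only some models are averaged over the models containing them and
#' flagged in the `n_models` column.
#'
#' @param feature_maps List of data frames, each with a `residue_number`
#'   column plus numeric feature columns.
#' @return One data frame with the per-residue mean of every feature and an
#'   `n_models` column.
#' @export
average_over_models <- function(feature_maps) {
  stopifnot(length(feature_maps) >= 1L)
  if (length(feature_maps) == 1L) {
    out <- feature_maps[[1]]
    out$n_models <- 1L
    return(out)
  }
  all_res <- sort(unique(unlist(lapply(feature_maps,
                                       `[[`, "residue_number"))))
  cols <- setdiff(names(feature_maps[[1]]), "residue_number")
  out <- data.frame(residue_number = all_res)
  stacked <- do.call(rbind, feature_maps)
  for (cl in cols) {
    out[[cl]] <- as.numeric(tapply(stacked[[cl]], stacked$residue_number,
                                   mean, na.rm = TRUE))[
      match(all_res, sort(unique(stacked$residue_number)))]
  }
  out$n_models <- as.integer(table(stacked$residue_number)[
    as.character(all_res)])
  out
}

#' Per-residue structural annotation table
#'
#' Convenience wrapper computing pLDDT, ASA, relative ASA, residue depth and
#' contact counts for every residue of a model; secondary structure comes
#' from a DSSP table when one is supplied (computed structure assignment is
#' not attempted) and defaults to coil otherwise.
#'
#' @param model A `StructureModel`.
#' @param dssp Optional data frame from [read_dssp()] overriding `ss` and
#'   `acc`.
#' @param probe_radius,n_points Passed to [sasa()].
#' @param contact_cutoff Passed to [residue_contacts()].
#' @return Data frame with one row per residue: `residue_number`,
#'   `residue_name`, `plddt`, `asa`, `rel_asa`, `ss`, `depth`,
#'   `contact_count`.
#' @export
annotate_structure <- function(model, dssp = NULL, probe_radius = 1.4,
                               n_points = 960L, contact_cutoff = 7) {
  res <- model_residues(model)
  sr <- sasa(model, probe_radius, n_points, keep_points = TRUE)
  asa_vals <- sr$residue_sasa[as.character(res)]
  depth_vals <- residue_depth(model, res, sasa_result = sr)
  res_name <- vapply(res, function(r) residue_atoms(model, r)$residue_name[1],
                     character(1))
  ss <- rep("C", length(res))
  if (!is.null(dssp)) {
    m <- match(res, dssp$residue_number)
    ss[!is.na(m)] <- dssp$ss[m[!is.na(m)]]
    asa_vals[!is.na(m)] <- dssp$acc[m[!is.na(m)]]
  }
  data.frame(
    residue_number = res,
    residue_name = res_name,
    plddt = vapply(res, function(r) residue_plddt(model, r), numeric(1)),
    asa = unname(asa_vals),
    rel_asa = unname(relative_asa(asa_vals, res_name)),
    ss = ss,
    depth = unname(depth_vals),
    contact_count = vapply(res, function(r)
      residue_contacts(model, r, contact_cutoff), integer(1)),
    stringsAsFactors = FALSE)
}
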