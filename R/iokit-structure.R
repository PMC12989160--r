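#' Read a predicted protein structure (PDB or mmCIF)
#'
#' Reads `ATOM` records (HETATM entries are ignored) into one
#' `StructureModel` per MODEL block; a file without MODEL records yields a
#' single model. The B-factor column is carried per atom, so that AlphaFold
#' models expose their per-residue pLDDT confidence through it. Parsing is
#' delegated to `bio3d` ([bio3d::read.pdb()] / [bio3d::read.cif()]).
#'
#' Only single-chain models are supported (true for AlphaFold monomer
#' predictions); multi-chain files take the first chain with a warning.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param protein_id Identifier stored on the models; defaults to the file
#'   name without extension.
#' @return List of `StructureModel` objects. Each has `protein_id`,
#'   `model_id` and `atoms`, a data frame with columns `residue_number`,
#'   `residue_name` (one-letter), `resid3`, `atom_name`, `element`, `x`,
#'   `y`, `z` (Angstrom) and `bfactor`.
#' @export
read_structure <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(
      if (is_cif) bio3d::read.cif(path, multi = TRUE)
      else bio3d::read.pdb(path, multi = TRUE, hex = TRUE)
    ),
    error = function(e) stop("could not parse structure file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  keep <- pdb$atom$type == "ATOM"
  if (!any(keep)) {
    stop("no ATOM records in structure file '", path, "'", call. = FALSE)
  }
  atom <- pdb$atom[keep, , drop = FALSE]
  chains <- unique(atom$chain)
  chains <- chains[!is.na(chains)]
  if (length(chains) > 1L) {
    warning("multiple chains in '", path, "'; keeping chain ", chains[1],
            call. = FALSE)
    atom <- atom[atom$chain %in% chains[1] | is.na(atom$chain), ,
                 drop = FALSE]
  }
  resid3 <- toupper(atom$resid)
  res1 <- AA_THREE_TO_ONE[resid3]
  res1[is.na(res1)] <- "X"
  base <- data.frame(
    residue_number = as.integer(atom$resno),
    residue_name = unname(res1),
    resid3 = resid3,
    atom_name = atom$elety,
    element = if (!is.null(atom$elesy) && !all(is.na(atom$elesy)))
      ifelse(is.na(atom$elesy) | atom$elesy == "",
             element_from_atom_name(atom$elety), toupper(atom$elesy))
    else element_from_atom_name(atom$elety),
    bfactor = as.numeric(atom$b),
    stringsAsFactors = FALSE)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  # xyz rows beyond the atom table (e.g. HETATM) are dropped via indices
  idx <- which(keep)
  n_models <- nrow(xyz)
  models <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    coords <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)[idx, , drop = FALSE]
    atoms <- base
    atoms$x <- coords[, 1]; atoms$y <- coords[, 2]; atoms$z <- coords[, 3]
    if (!all(is.finite(coords))) {
      stop("non-finite coordinates in '", path, "' model ", m, call. = FALSE)
    }
    models[[m]] <- structure_model(protein_id, as.character(m), atoms)
  }
  models
}

#' Construct a structure model from an atom table
#' @param protein_id Protein identifier.
#' @param model_id Model identifier within the protein.
#' @param atoms Data frame with columns `residue_number`, `residue_name`,
#'   `atom_name`, `element`, `x`, `y`, `z`, `bfactor` (and optionally
#'   `resid3`).
#' @return A `StructureModel`.
#' @export
structure_model <- function(protein_id, model_id, atoms) {
  stopifnot(all(c("residue_number", "residue_name", "atom_name",
                  "x", "y", "z", "bfactor") %in% names(atoms)))
  if (!"element" %in% names(atoms)) {
    atoms$element <- element_from_atom_name(atoms$atom_name)
  }
  if (!"resid3" %in% names(atoms)) {
    atoms$resid3 <- unname(AA_ONE_TO_THREE[atoms$residue_name])
  }
  rn <- unique(atoms$residue_number)
  if (is.unsorted(rn)) {
    stop("residue numbers are not increasing in model '", model_id,
         "' of '", protein_id, "'", call. = FALSE)
  }
  structure(list(protein_id = protein_id, model_id = model_id,
                 atoms = atoms),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel %s/%s: %d residues, %d atoms\n",
              x$protein_id, x$model_id,
              length(unique(x$atoms$residue_number)), nrow(x$atoms)))
  invisible(x)
}

#' Residue numbers present in a structure model
#' @param model A `StructureModel`.
#' @return Integer vector of residue numbers, in order.
#' @export
model_residues <- function(model) unique(model$atoms$residue_number)

#' @keywords internal
residue_atoms <- function(model, pos) {
  model$atoms[model$atoms$residue_number == pos, , drop = FALSE]
}

#' Write a structure model as PDB text
#'
#' Fixed-column `ATOM` records (coordinates to 0.001 Angstrom, B-factor to
#' 0.01), one `MODEL`/`ENDMDL` block per model when several are given.
#' Output round-trips through [read_structure()] to the printed precision.
#'
#' @param models A `StructureModel` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(models, path) {
  if (inherits(models, "StructureModel")) models <- list(models)
  con <- file(path, "wb")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- models[[m]]$atoms
    lines <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)),
      ifelse(nchar(a$atom_name) < 4L, paste0(" ", a$atom_name), a$atom_name),
      a$resid3, a$residue_number, a$x, a$y, a$z, 1.00, a$bfactor, a$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
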