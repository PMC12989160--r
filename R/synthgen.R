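# Deterministic synthetic-fixture generator. Emits sequences, idealised
# helical structures, PSSM profiles, conservation/disorder tracks and
# mutation tables with planted driver/passenger signal, written in the
# real external file formats so every reader is exercised end to end.

#' Synthetic-corpus configuration
#'
#' @param n_proteins Number of proteins.
#' @param protein_length_range Length range `c(min, max)`.
#' @param n_driver,n_passenger Mutation counts (default 2:1
#'   driver:passenger, inside the band observed in real per-cancer-type
#'   corpora).
#' @param effect_size Planted separation `d` (in SD units) between driver
#'   and passenger sites on the correlated tracks (conservation high / ASA
#'   proxy low at driver sites).
#' @param noise_sd Coordinate jitter SD for structures (Angstrom).
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_proteins = 10L,
                         protein_length_range = c(80L, 120L),
                         n_driver = 200L, n_passenger = 100L,
                         effect_size = 2, noise_sd = 0.1, seed = 1L) {
  stopifnot(effect_size >= 0, n_proteins >= 1L)
  structure(list(n_proteins = as.integer(n_proteins),
                 protein_length_range = as.integer(protein_length_range),
                 n_driver = as.integer(n_driver),
                 n_passenger = as.integer(n_passenger),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate random protein sequences
#'
#' Sequences are drawn from a residue frequency table (uniform over the 20
#' standard residues by default) with lengths uniform in the configured
#' range.
#'
#' @param config A [synth_config()].
#' @param freq Named residue sampling weights (default uniform).
#' @return Named list of `ProteinSequence` objects (`sp1`, `sp2`, ...).
#' @export
gen_sequences <- function(config, freq = NULL) {
  if (is.null(freq)) freq <- setNames(rep(1, 20), AA_ALPHABETICAL)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  rng <- config$protein_length_range
  seqs <- lapply(seq_len(config$n_proteins), function(i) {
    len <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
    protein_sequence(paste0("sp", i),
                     paste(sample(names(freq), len, replace = TRUE,
                                  prob = freq), collapse = ""))
  })
  names(seqs) <- vapply(seqs, `[[`, character(1), "id")
  seqs
}

#' Generate an idealised helical structure for a sequence
#'
#' Places the C-alpha trace on an ideal alpha-helix (rise 1.5 Angstrom and
#' 100 degrees of turn per residue, giving consecutive C-alpha distances
#' of about 3.8 Angstrom), adds backbone and C-beta atoms at fixed local
#' offsets, optional Gaussian coordinate jitter, and fills the B-factor
#' column with a smooth synthetic pLDDT profile. Not a physical fold —
#' just valid, parseable geometry with the right length scales.
#'
#' @param sequence A `ProteinSequence` (length >= 2).
#' @param jitter Gaussian coordinate noise SD in Angstrom (0 =
#'   deterministic, seed-independent coordinates).
#' @param seed Seed for the jitter.
#' @param plddt Optional per-residue pLDDT vector; default a smooth
#'   profile in [60, 95].
#' @return A `StructureModel`.
#' @export
gen_structure <- function(sequence, jitter = 0, seed = 1L, plddt = NULL) {
  n <- nchar(sequence$residues)
  stopifnot(n >= 2L)
  i <- seq_len(n)
  theta <- i * 100 * pi / 180
  r <- 2.3; rise <- 1.5
  ca <- cbind(r * cos(theta), r * sin(theta), rise * i)
  radial <- cbind(cos(theta), sin(theta), 0)
  if (is.null(plddt)) plddt <- 77.5 + 17.5 * sin(i / 7)
  plddt <- pmin(pmax(plddt, 0), 100)
  offs <- list(N = c(-0.8, 0.9, -0.9), C = c(0.7, 1.0, 0.9),
               O = c(1.1, 1.5, 1.6))
  res1 <- strsplit(sequence$residues, "")[[1]]
  rows <- lapply(i, function(k) {
    base <- ca[k, ]
    coords <- rbind(
      N = base + offs$N, CA = base, C = base + offs$C, O = base + offs$O,
      CB = base + 1.5 * radial[k, ])
    nm <- rownames(coords)
    if (res1[k] == "G") { coords <- coords[1:4, , drop = FALSE]
                          nm <- nm[1:4] }
    data.frame(residue_number = k, residue_name = res1[k],
               atom_name = nm,
               element = substr(nm, 1L, 1L),
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               bfactor = plddt[k], stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  if (jitter > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
      matrix(stats::rnorm(3L * nrow(atoms), sd = jitter), ncol = 3L)
  }
  structure_model(sequence$id, "1", atoms)
}

#' Generate a synthetic PSSM profile for a sequence
#'
#' The native residue's column scores high (around +5), all others draw
#' from a low integer range, mimicking a conserved profile.
#'
#' @param sequence A `ProteinSequence`.
#' @param seed Integer seed.
#' @return A `PSSMProfile`.
#' @export
gen_pssm <- function(sequence, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  res <- strsplit(sequence$residues, "")[[1]]
  n <- length(res)
  scores <- matrix(sample(-4:2, n * 20L, replace = TRUE), n, 20L,
                   dimnames = list(NULL, AA_PSSM_ORDER))
  for (k in seq_len(n)) {
    if (res[k] %in% AA_PSSM_ORDER) {
      scores[k, res[k]] <- sample(4:7, 1L)
    }
  }
  structure(list(protein_id = sequence$id,
                 residues = ifelse(res %in% AA_PSSM_ORDER, res, "A"),
                 scores = scores),
            class = "PSSMProfile")
}

#' Generate conservation and disorder tracks for a sequence
#'
#' Builds `n_conservation` correlated conservation tracks plus one
#' disorder track around a latent per-residue conservation profile, which
#' the mutation generator reuses to plant driver/passenger signal.
#'
#' @param sequence A `ProteinSequence`.
#' @param latent Optional latent conservation profile in `[0, 1]`.
#' @param n_conservation Number of conservation tracks (default 18).
#' @param seed Integer seed.
#' @return List with `tracks` (named list of numeric vectors, tracks
#'   `cons01..consNN` and `disorder`) and `latent`.
#' @export
gen_tracks <- function(sequence, latent = NULL, n_conservation = 18L,
                       seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nchar(sequence$residues)
  if (is.null(latent)) latent <- stats::runif(n)
  tracks <- lapply(seq_len(n_conservation), function(j) {
    pmin(pmax(latent + stats::rnorm(n, sd = 0.15), 0), 1)
  })
  names(tracks) <- sprintf("cons%02d", seq_len(n_conservation))
  tracks$disorder <- pmin(pmax(1 - latent + stats::rnorm(n, sd = 0.15),
                               0), 1)
  list(tracks = tracks, latent = latent)
}

#' Generate a full synthetic mutation corpus
#'
#' Driver sites are drawn preferentially at positions with high latent
#' conservation (and correspondingly low disorder), passenger sites from
#' the complement, so the configured effect size separates the classes on
#' the track-derived features. Driver records receive sample counts of at
#' least 3 and passengers at most 2, so recurrence labelling at the
#' default threshold reproduces the intended labels exactly.
#'
#' @param config A [synth_config()].
#' @return List with `sequences`, `structures`, `pssms`, `tracks` (per
#'   protein), `latent` and `records` (a labelled `mutation_table`).
#' @export
gen_mutation_dataset <- function(config) {
  seqs <- gen_sequences(config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  structures <- list(); pssms <- list(); tracks <- list(); latent <- list()
  for (id in names(seqs)) {
    sub_seed <- config$seed + match(id, names(seqs))
    lat <- stats::runif(nchar(seqs[[id]]$residues))
    structures[[id]] <- gen_structure(seqs[[id]], jitter = config$noise_sd,
                                      seed = sub_seed,
                                      plddt = 60 + 35 * lat)
    pssms[[id]] <- gen_pssm(seqs[[id]], seed = sub_seed)
    tr <- gen_tracks(seqs[[id]], latent = lat, seed = sub_seed)
    tracks[[id]] <- tr$tracks
    latent[[id]] <- lat
  }
  # sample mutation sites: drivers biased toward high latent conservation
  d <- config$effect_size
  draw_sites <- function(n_mut, driver) {
    pid <- sample(names(seqs), n_mut, replace = TRUE)
    vapply(seq_len(n_mut), function(i) {
      lat <- latent[[pid[i]]]
      w <- if (d == 0) rep(1, length(lat)) else
        exp((if (driver) d else -d) * 2 * lat)
      sample(length(lat), 1L, prob = w)
    }, integer(1)) -> pos
    list(pid = pid, pos = pos)
  }
  mk_records <- function(sites, driver) {
    n_mut <- length(sites$pid)
    wt <- vapply(seq_len(n_mut), function(i)
      residue_at(seqs[[sites$pid[i]]], sites$pos[i]), character(1))
    mut <- vapply(wt, function(w)
      sample(setdiff(AA_ALPHABETICAL, w), 1L), character(1))
    data.frame(protein_id = sites$pid, position = sites$pos, wt = wt,
               mut = unname(mut), cancer_type = "SYNTH",
               sample_count = if (driver) sample(3:30, n_mut, TRUE)
                              else sample(0:2, n_mut, TRUE),
               label = if (driver) "driver" else "passenger",
               stringsAsFactors = FALSE)
  }
  records <- rbind(mk_records(draw_sites(config$n_driver, TRUE), TRUE),
                   mk_records(draw_sites(config$n_passenger, FALSE),
                              FALSE))
  class(records) <- c("mutation_table", "data.frame")
  list(sequences = seqs, structures = structures, pssms = pssms,
       tracks = tracks, latent = latent, records = records)
}

#' Write a synthetic corpus as a fixture directory tree
#'
#' Emits `fasta/`, `structures/`, `pssm/`, `tracks/`, `mutations.csv` and
#' a `manifest.json` recording the configuration, all in the real external
#' formats, so the corresponding readers are exercised by every
#' end-to-end test.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return The dataset list from [gen_mutation_dataset()], invisibly, with
#'   `$dir` added.
#' @export
write_fixture_tree <- function(config, dir) {
  ds <- gen_mutation_dataset(config)
  for (sub in c("fasta", "structures", "pssm", "tracks")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  write_fasta(ds$sequences, file.path(dir, "fasta", "proteins.fasta"))
  for (id in names(ds$sequences)) {
    write_pdb(ds$structures[[id]],
              file.path(dir, "structures", paste0(id, ".pdb")))
    write_pssm_ascii(ds$pssms[[id]],
                     file.path(dir, "pssm", paste0(id, ".pssm")))
    write_tracks(ds$tracks[[id]],
                 file.path(dir, "tracks", paste0(id, ".tsv")))
  }
  write_mutation_table(ds$records, file.path(dir, "mutations.csv"))
  jsonlite::write_json(
    list(generator = "missdriver::write_fixture_tree",
         seed = config$seed, n_proteins = config$n_proteins,
         n_driver = config$n_driver, n_passenger = config$n_passenger,
         effect_size = config$effect_size, synthetic = TRUE),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  ds$dir <- dir
  invisible(ds)
}

#' Generate a feature matrix with planted signal
#'
#' Direct generator for pipeline-level studies: `n` mutations from
#' `n_proteins` proteins, `p` standard-normal feature columns of which
#' `n_planted` carry a mean shift of `d` standard deviations in the driver
#' class. Labels are drivers and passengers at the configured ratio.
#'
#' @param n Number of rows (default 2000).
#' @param p Number of features (default 40).
#' @param n_planted Number of signal-carrying features (default 5).
#' @param d Effect size in SD units (default 2).
#' @param n_proteins Number of protein groups (default 50).
#' @param driver_frac Driver fraction (default 2/3, the 2:1 ratio).
#' @param seed Integer seed.
#' @return A `feature_matrix`; the planted column names are in
#'   `attr(, "planted")`.
#' @export
gen_feature_matrix <- function(n = 2000L, p = 40L, n_planted = 5L, d = 2,
                               n_proteins = 50L, driver_frac = 2 / 3,
                               seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_pos <- round(driver_frac * n)
  y <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  x <- matrix(stats::rnorm(n * p), n, p)
  planted <- sprintf("planted_%02d", seq_len(n_planted))
  colnames(x) <- c(planted, sprintf("noise_%02d", seq_len(p - n_planted)))
  x[y == 1L, seq_len(n_planted)] <- x[y == 1L, seq_len(n_planted)] + d
  pid <- sample(sprintf("prot%03d", seq_len(n_proteins)), n,
                replace = TRUE)
  ord <- sample(n)
  fm <- feature_matrix(x[ord, , drop = FALSE], y[ord], pid[ord])
  attr(fm, "planted") <- planted
  fm
}
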