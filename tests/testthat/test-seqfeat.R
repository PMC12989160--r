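# Sequence-derived per-mutation features.

kd_entry <- read_aaindex(system.file("extdata", "aaindex1_demo.txt",
                                     package = "missdriver"), "index1")$KYTJ820101

test_that("delta_property is the mutant-minus-wild-type difference", {
  expect_equal(delta_property("A", "V", kd_entry), 4.2 - 1.8)
  expect_equal(delta_property("A", "A", kd_entry), 0)
  expect_true(is.na(delta_property("A", "X", kd_entry)))
})

test_that("delta_property is antisymmetric for every property table", {
  props <- read_property_set(system.file("extdata", "aaindex1_demo.txt",
                                         package = "missdriver"))
  set.seed(5)
  for (k in 1:50) {
    pair <- sample(aa20, 2)
    tb <- props[[sample(length(props), 1)]]
    expect_equal(delta_property(pair[1], pair[2], tb),
                 -delta_property(pair[2], pair[1], tb))
  }
})

test_that("substitution-matrix features resolve both symmetric and asymmetric entries", {
  m <- matrix(0, 20, 20, dimnames = list(aa20, aa20))
  m["R", "Q"] <- 3; m["Q", "R"] <- 7
  asym <- read_aaindex(toy_aaindex_matrix_file(m), "index2")[[1]]
  expect_equal(substitution_matrix_feature("R", "Q", asym), 3)
  expect_equal(substitution_matrix_feature("Q", "R", asym), 7)
  sym <- full_symmetric_entry(2.5)
  expect_equal(substitution_matrix_feature("R", "Q", sym),
               substitution_matrix_feature("Q", "R", sym))
  expect_true(is.na(substitution_matrix_feature("X", "Q", sym)))
})

test_that("neighbour contact-potential deltas follow the stated arithmetic", {
  cp <- toy_cp_entry(data.frame(a = c("A", "A", "C", "C"),
                                b = c("Q", "R", "Q", "R"),
                                v = c(2, 1, 5, 4)))
  v <- neighbor_contact_potential_delta("ARC", 2, cp, mut = "Q", wt = "R")
  expect_equal(v[["delta_N"]], 2 - 1)   # CP(A,Q) - CP(A,R)
  expect_equal(v[["delta_C"]], 5 - 4)   # CP(C,Q) - CP(C,R)
  expect_equal(v[["delta_LR"]], 0)      # CP(A,C) not set -> 0 in table
  # identity mutation on a degenerate all-equal table gives zero deltas
  same <- neighbor_contact_potential_delta("ARC", 2, cp, mut = "R", wt = "R")
  expect_equal(unname(same[c("delta_N", "delta_C")]), c(0, 0))
})

test_that("terminal positions yield missing neighbour deltas, not zeros", {
  cp <- full_symmetric_entry(1)
  left_end <- neighbor_contact_potential_delta("ARC", 1, cp, mut = "Q")
  expect_true(is.na(left_end[["delta_N"]]))
  expect_false(is.na(left_end[["delta_C"]]))
  right_end <- neighbor_contact_potential_delta("ARC", 3, cp, mut = "Q")
  expect_true(is.na(right_end[["delta_C"]]))
})

test_that("neighbourhood composition counts the six classes and conserves totals", {
  v <- neighbor_composition("DDDDDDRDDDDDD", 7, flank = 6)
  expect_equal(v[["negative"]], 12L)
  expect_equal(sum(v), 12L)

  edge <- neighbor_composition("AR", 1, flank = 6)
  expect_equal(sum(edge), 1L)  # only the right neighbour is in bounds

  set.seed(17)
  for (k in 1:25) {
    len <- sample(5:60, 1)
    s <- paste(sample(aa20, len, replace = TRUE), collapse = "")
    pos <- sample(len, 1)
    expect_equal(sum(neighbor_composition(s, pos)),
                 min(pos - 1, 6) + min(len - pos, 6))
  }
})

test_that("motif odds follow the pseudocount formula", {
  # single-family toy corpus: motif "AR" seen 10/100 in drivers, 5/100 in
  # passengers; other sites realise distinct motifs
  seqs <- list()
  recs <- NULL
  mk <- function(prefix, n, motif_first) {
    out <- list()
    for (i in seq_len(n)) {
      id <- paste0(prefix, i)
      body <- if (motif_first(i)) "ARAAA" else
        paste0(c("C", "D", "E", "F", "G")[(i %% 5) + 1], "WAAA")
      out[[id]] <- protein_sequence(id, body)
    }
    out
  }
  d_seqs <- mk("d", 100, function(i) i <= 10)
  p_seqs <- mk("p", 100, function(i) i <= 5)
  seqs <- c(d_seqs, p_seqs)
  recs <- data.frame(
    protein_id = names(seqs), position = 1L, wt = "A", mut = "V",
    cancer_type = "X", sample_count = 1L,
    label = rep(c("driver", "passenger"), each = 100))
  recs$wt <- vapply(seqs, function(s) residue_at(s, 1), character(1))
  tb <- build_motif_odds(recs, seqs, offsets = c(0L, 1L), pseudocount = 0)
  expect_equal(unname(tb$odds[["AR"]]), (10 / 100) / (5 / 100))

  tb2 <- build_motif_odds(recs, seqs, offsets = c(0L, 1L),
                          pseudocount = 0.5)
  # a motif absent from both classes would score (N_P+.5)/(N_D+.5) = 1 here
  expect_equal((0 + 0.5) / (tb2$N_driver + 0.5) /
                 ((0 + 0.5) / (tb2$N_passenger + 0.5)), 1)

  only_d <- recs[recs$label == "driver", ]
  expect_error(build_motif_odds(only_d, seqs, c(0L, 1L)), "passenger")
})

test_that("identical driver and passenger corpora give odds 1 everywhere", {
  ds <- toy_corpus(n_driver = 50, n_passenger = 50, seed = 21)
  rec <- ds$records
  # mirror the driver sites into the passenger class
  mirrored <- rec[rec$label == "driver", ]
  mirrored$label <- "passenger"
  both <- rbind(rec[rec$label == "driver", ], mirrored)
  tb <- build_motif_odds(both, ds$sequences, c(0L, 1L), pseudocount = 0)
  expect_true(all(abs(tb$odds - 1) < 1e-12))
})

test_that("motif features default to neutral odds for unseen and terminal motifs", {
  ds <- toy_corpus(seed = 31)
  tables <- build_all_motif_odds(ds$records, ds$sequences)
  expect_length(tables, 7L)
  s_new <- protein_sequence("new", "WWWWWWWWWWWWW")
  v <- motif_features(s_new, 7, tables)
  # poly-W motifs are absent from the random training corpus
  expect_true(all(v[vapply(tables, function(tb)
    !(motif_at(s_new, 7, tb$offsets) %in% names(tb$odds)),
    logical(1))] == 1))
  # terminal site: left-anchored families fall out of bounds -> neutral
  v1 <- motif_features(ds$sequences[[1]], 1, tables)
  left_anchored <- vapply(tables, function(tb) any(tb$offsets < 0),
                          logical(1))
  expect_true(all(v1[left_anchored] == 1))
})

test_that("label-shuffled corpora give log odds centred at zero", {
  cfg <- synth_config(n_proteins = 20, protein_length_range = c(200L, 200L),
                      n_driver = 5000L, n_passenger = 5000L,
                      effect_size = 0, seed = 91)
  ds <- gen_mutation_dataset(cfg)
  tb <- build_motif_odds(ds$records, ds$sequences, c(0L, 1L))
  w <- tb$n_driver + tb$n_passenger
  mean_log <- sum(log(tb$odds) * w) / sum(w)
  expect_lt(abs(mean_log), 0.1)
})

test_that("PSSM features combine window mean, delta and site score", {
  prof <- structure(list(protein_id = "p",
                         residues = rep("A", 9),
                         scores = matrix(0L, 9, 20,
                                         dimnames = list(NULL, aa_pssm_order))),
                    class = "PSSMProfile")
  expect_equal(unname(pssm_features(prof, 5, "A", "C")), c(0, 0, 0))

  prof$scores[5, "A"] <- 5L
  prof$scores[5, "C"] <- -2L
  v <- pssm_features(prof, 5, "A", "C")
  expect_equal(v[["delta"]], -7)
  expect_equal(v[["site_score"]], 5)
  expect_equal(v[["window_mean"]], 5 / 9)  # only the site row is non-zero
  expect_equal(pssm_features(prof, 5, "A", "A")[["delta"]], 0)
})

test_that("track features handle constants and missing values", {
  expect_equal(unname(track_features(rep(0.5, 13), 7)), c(0.5, 0.5))
  tr <- c(0.2, NA, 0.4)
  v <- track_features(tr, 2, flank = 1)
  expect_true(is.na(v[["site_value"]]))
  expect_equal(v[["window_mean"]], mean(c(0.2, 0.4)))
  expect_true(all(is.na(track_features(rep(NA_real_, 5), 3, flank = 1))))
})

test_that("features are invariant under protein renaming", {
  ds <- toy_corpus(seed = 41)
  tables <- build_all_motif_odds(ds$records, ds$sequences)
  fm1 <- extract_features(ds$records, ds$sequences,
                          motif_tables = tables, pssms = ds$pssms,
                          tracks = ds$tracks)
  renamed <- ds
  map <- setNames(paste0("Z_", names(ds$sequences)), names(ds$sequences))
  names(renamed$sequences) <- map[names(ds$sequences)]
  for (i in seq_along(renamed$sequences)) {
    renamed$sequences[[i]]$id <- names(renamed$sequences)[i]
  }
  names(renamed$pssms) <- map[names(ds$pssms)]
  names(renamed$tracks) <- map[names(ds$tracks)]
  renamed$records$protein_id <- unname(map[ds$records$protein_id])
  tables2 <- build_all_motif_odds(renamed$records, renamed$sequences)
  fm2 <- extract_features(renamed$records, renamed$sequences,
                          motif_tables = tables2, pssms = renamed$pssms,
                          tracks = renamed$tracks)
  expect_equal(fm1$x, fm2$x)
})
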