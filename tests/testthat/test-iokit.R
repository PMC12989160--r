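# Readers/writers for the external formats and the mutation data model.

test_that("FASTA parsing normalises case, folds lines and keeps ids", {
  f <- write_tmp(c(">p1 desc here", "ac", "de", ">p2", "GHIK"), ".fasta")
  seqs <- read_fasta(f)
  expect_named(seqs, c("p1", "p2"))
  expect_equal(seqs$p1$residues, "ACDE")
  expect_equal(seqs$p2$residues, "GHIK")
})

test_that("FASTA rejects duplicates and maps ambiguity codes to X", {
  f <- write_tmp(c(">p1", "ACDE", ">p1", "GHIK"), ".fasta")
  expect_error(read_fasta(f), "duplicate.*p1")
  f2 <- write_tmp(c(">p1", "ACUB"), ".fasta")
  expect_warning(seqs <- read_fasta(f2), "mapped to X")
  expect_equal(seqs$p1$residues, "ACXX")
  expect_error(read_fasta(write_tmp(character(0), ".fasta")))
})

test_that("FASTA round-trips byte-identically for canonical input", {
  f <- write_tmp(c(">p1", "ACDEFGHIKLMNPQRSTVWY", ">p2", "MKV"), ".fasta")
  out <- tempfile(fileext = ".fasta")
  write_fasta(read_fasta(f), out)
  expect_identical(readLines(out), readLines(f))
})

test_that("mutation tables are typed and invalid rows are named", {
  f <- write_tmp(c("protein_id,position,wt,mut,cancer_type,sample_count,label",
                   "p1,5,R,Q,BRCA,7,driver",
                   "p2,1,A,V,LUAD,0,unknown"), ".csv")
  tab <- read_mutation_table(f)
  expect_s3_class(tab, "mutation_table")
  expect_equal(tab$sample_count, c(7L, 0L))
  expect_equal(tab$position, c(5L, 1L))

  bad_pos <- write_tmp(c("protein_id,position,wt,mut,cancer_type,sample_count",
                         "p1,abc,R,Q,BRCA,7"), ".csv")
  expect_error(read_mutation_table(bad_pos), "position.*row 1")
  silent <- write_tmp(c("protein_id,position,wt,mut,cancer_type,sample_count",
                        "p1,5,R,R,BRCA,7"), ".csv")
  expect_error(read_mutation_table(silent), "wild-type equals mutant.*row 1")
  bad_aa <- write_tmp(c("protein_id,position,wt,mut,cancer_type,sample_count",
                        "p1,5,R,Z,BRCA,7"), ".csv")
  expect_error(read_mutation_table(bad_aa), "residue.*row 1")
})

test_that("recurrence labelling promotes at the threshold and never overwrites", {
  rec <- data.frame(protein_id = "p", position = 1:4, wt = "A", mut = "V",
                    cancer_type = "X", sample_count = c(3L, 2L, 10L, 5L),
                    label = c("unknown", "unknown", "passenger", "unknown"))
  out <- label_by_recurrence(rec)
  expect_equal(out$label, c("driver", "unknown", "passenger", "driver"))
})

test_that("PSSM reader takes the first score block and validates length", {
  prof0 <- structure(list(protein_id = "p1", residues = c("A", "C", "D", "E"),
                          scores = matrix(0L, 4, 20,
                                          dimnames = list(NULL, c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")))),
                     class = "PSSMProfile")
  f <- tempfile()
  write_pssm_ascii(prof0, f)
  prof <- read_pssm_ascii(f)
  expect_equal(nrow(prof$scores), 4L)
  expect_true(all(prof$scores == 0L))  # all-zero rows are a valid profile

  seq_ok <- protein_sequence("p1", "ACDE")
  expect_silent(read_pssm_ascii(f, sequence = seq_ok))
  seq_short <- protein_sequence("p1", "ACD")
  expect_error(read_pssm_ascii(f, sequence = seq_short), "length")
  seq_mut <- protein_sequence("p1", "ACDD")
  expect_error(read_pssm_ascii(f, sequence = seq_mut), "disagrees")
})

test_that("structure reader handles single and multi-model PDB files", {
  cfg <- synth_config(n_proteins = 1, protein_length_range = c(12L, 12L),
                      seed = 3)
  s <- gen_sequences(cfg)[[1]]
  m1 <- gen_structure(s, jitter = 0)
  m2 <- gen_structure(s, jitter = 0.2, seed = 9)
  f1 <- tempfile(fileext = ".pdb"); write_pdb(m1, f1)
  back <- read_structure(f1)
  expect_length(back, 1L)
  expect_equal(nrow(back[[1]]$atoms), nrow(m1$atoms))
  # coordinates survive to printed precision (0.001 A)
  expect_lte(max(abs(back[[1]]$atoms$x - m1$atoms$x)), 5e-4 + 1e-12)
  expect_lte(max(abs(back[[1]]$atoms$z - m1$atoms$z)), 5e-4 + 1e-12)
  expect_equal(back[[1]]$atoms$bfactor, m1$atoms$bfactor,
               tolerance = 0.011)

  f2 <- tempfile(fileext = ".pdb"); write_pdb(list(m1, m2), f2)
  models <- read_structure(f2)
  expect_length(models, 2L)
  expect_false(isTRUE(all.equal(models[[1]]$atoms$x, models[[2]]$atoms$x)))

  het <- write_tmp(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00 10.00           O",
    "END"), ".pdb")
  expect_error(read_structure(het), "no ATOM")
})

test_that("DSSP reader collapses 8-state codes and skips chain breaks", {
  acc <- c(55, 10, 20, 30, 40, 5)
  f <- tempfile()
  write_dssp(1:6, c("A", "R", "N", "D", "C", "E"),
             c("H", "B", " ", "G", "T", "E"), acc, f)
  d <- read_dssp(f)
  expect_equal(d$ss, c("H", "E", "C", "H", "C", "E"))
  expect_equal(d$acc, acc)

  # inject a chain-break row
  lines <- readLines(f)
  brk <- sub("^(.{13})R", "\\1!", lines[4])
  writeLines(append(lines, brk, after = 3), f)
  expect_warning(d2 <- read_dssp(f), "chain-break")
  expect_equal(nrow(d2), 6L)
})

test_that("AAindex1 entries resolve per-residue values", {
  kd <- read_aaindex(system.file("extdata", "aaindex1_demo.txt",
                                 package = "missdriver"), "index1")
  expect_true("KYTJ820101" %in% names(kd))
  expect_equal(aaindex_lookup(kd$KYTJ820101, "A"), 1.8)
  expect_equal(aaindex_lookup(kd$KYTJ820101, "V"), 4.2)
  expect_equal(aaindex_lookup(kd$KYTJ820101, "W"), -0.9)
})

test_that("triangular AAindex matrices mirror and NA cells error at lookup", {
  m <- matrix(NA_real_, 20, 20, dimnames = list(aa20, aa20))
  vals <- outer(1:20, 1:20, function(i, j) i + j / 100)
  m[lower.tri(m, diag = TRUE)] <- vals[lower.tri(vals, diag = TRUE)]
  m["W", "W"] <- NA  # missing diagonal cell
  f <- toy_aaindex_matrix_file(m, "TOYT0001", triangular = TRUE)
  e <- read_aaindex(f, "index3")[[1]]
  expect_true(e$symmetric)
  expect_equal(aaindex_lookup(e, "R", "Q"), aaindex_lookup(e, "Q", "R"))
  expect_error(aaindex_lookup(e, "W", "W"), "no value")
  expect_true(is.na(aaindex_lookup(e, "W", "W", strict = FALSE)))
})

test_that("asymmetric AAindex matrices keep direction", {
  m <- matrix(0, 20, 20, dimnames = list(aa20, aa20))
  m["R", "Q"] <- 3; m["Q", "R"] <- -1
  f <- toy_aaindex_matrix_file(m, "TOYA0001")
  e <- read_aaindex(f, "index2")[[1]]
  expect_equal(aaindex_lookup(e, "R", "Q"), 3)
  expect_equal(aaindex_lookup(e, "Q", "R"), -1)
})

test_that("residue tracks round-trip and reject misaligned files", {
  tr <- list(cons = c(0.1, NA, 0.5), disorder = c(1, 0, 0.2))
  f <- tempfile(fileext = ".tsv")
  write_tracks(tr, f)
  back <- read_tracks(f, protein_id = "p1")
  expect_equal(back$tracks$cons, tr$cons)
  expect_equal(back$tracks$disorder, tr$disorder)
  s <- protein_sequence("p1", "ACDE")
  expect_error(read_tracks(f, sequence = s), "length")
})

test_that("mutation validation checks positions against sequences", {
  seqs <- list(p1 = protein_sequence("p1", "ARCDE"))
  ok <- data.frame(protein_id = "p1", position = 2L, wt = "R", mut = "Q",
                   cancer_type = "X", sample_count = 1L, label = "unknown")
  expect_silent(validate_mutations(ok, seqs))
  bad <- ok; bad$wt <- "K"
  expect_error(validate_mutations(bad, seqs), "mismatch")
  far <- ok; far$position <- 99L
  expect_error(validate_mutations(far, seqs), "exceeds")
})
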