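# Mutation-preference statistics.

mk_counts <- function(driver_cells, passenger_cells) {
  rec <- rbind(
    data.frame(protein_id = "p", position = 1L,
               wt = driver_cells$wt, mut = driver_cells$mut,
               cancer_type = "X", sample_count = 5L, label = "driver"),
    data.frame(protein_id = "p", position = 1L,
               wt = passenger_cells$wt, mut = passenger_cells$mut,
               cancer_type = "X", sample_count = 1L, label = "passenger"))
  substitution_counts(rec)
}

test_that("substitution preferences normalise to one", {
  cells_d <- data.frame(wt = rep("E", 10), mut = rep("K", 10))
  cells_p <- data.frame(wt = c(rep("A", 6), rep("P", 4)),
                        mut = c(rep("T", 6), rep("L", 4)))
  sc <- mk_counts(cells_d, cells_p)
  pd <- substitution_preference(sc, "driver")
  expect_equal(pd["E", "K"], 1)
  expect_equal(sum(pd), 1)
  pp <- substitution_preference(sc, "passenger")
  expect_equal(pp["A", "T"], 0.6)
  expect_equal(sum(pp), 1)

  set.seed(3)
  rnd <- data.frame(wt = sample(aa20, 500, TRUE))
  rnd$mut <- vapply(rnd$wt, function(w) sample(setdiff(aa20, w), 1),
                    character(1))
  sc2 <- mk_counts(rnd, rnd)
  expect_equal(sum(substitution_preference(sc2, "driver")), 1)
})

test_that("odds ratios follow the frequency-ratio definition with flags", {
  cells_d <- data.frame(wt = c(rep("E", 10), rep("R", 85), rep("W", 5)),
                        mut = c(rep("K", 10), rep("Q", 85), rep("C", 5)))
  cells_p <- data.frame(wt = c(rep("E", 5), rep("R", 95)),
                        mut = c(rep("K", 5), rep("Q", 95)))
  sc <- mk_counts(cells_d, cells_p)
  o <- odds_ratio(sc, "E", "K")
  expect_equal(o$odds, (10 / 100) / (5 / 100))
  expect_equal(o$flag, "ok")
  # substitution only ever seen in drivers
  expect_equal(odds_ratio(sc, "W", "C")$flag, "driver_unique")
  expect_true(is.na(odds_ratio(sc, "W", "C")$odds))
  # absent substitution
  expect_equal(odds_ratio(sc, "A", "V")$flag, "absent")
  # passenger-only
  sc2 <- mk_counts(cells_d, data.frame(wt = "A", mut = "V"))
  expect_equal(odds_ratio(sc2, "A", "V")$odds, 0)
  expect_equal(odds_ratio(sc2, "A", "V")$flag, "passenger_unique")
})

test_that("class-swapped odds ratios are reciprocals", {
  set.seed(7)
  d <- data.frame(wt = sample(aa20, 300, TRUE))
  d$mut <- vapply(d$wt, function(w) sample(setdiff(aa20, w), 1),
                  character(1))
  p <- data.frame(wt = sample(aa20, 200, TRUE))
  p$mut <- vapply(p$wt, function(w) sample(setdiff(aa20, w), 1),
                  character(1))
  sc <- mk_counts(d, p)
  swapped <- sc
  swapped$counts_driver <- sc$counts_passenger
  swapped$counts_passenger <- sc$counts_driver
  swapped$N_D <- sc$N_P; swapped$N_P <- sc$N_D
  tab <- odds_ratio_table(sc)
  ok <- tab[tab$flag == "ok", ]
  for (i in seq_len(nrow(ok))) {
    rev <- odds_ratio(swapped, ok$wt[i], ok$mut[i])
    expect_equal(rev$odds, 1 / ok$odds[i])
  }
})

test_that("motif preference boundaries are inclusive", {
  expect_equal(classify_motif_preference(c(1.2, 0.8, 1.0, 2, 0.1)),
               c("driver", "passenger", "neither", "driver", "passenger"))
})

test_that("Fisher composition test matches hypergeometric enumeration", {
  # [[10, 0], [0, 10]]
  a <- setNames(c(10, 10), c("R", "other"))
  b <- setNames(c(0, 20), c("R", "other"))
  ca <- c(R = 10, G = 0); cb <- c(R = 0, G = 10)
  res <- composition_fisher(ca, cb, "R")
  expect_equal(res$p_two_sided, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(res$p_two_sided, oracle_fisher_p(10, 0, 0, 10),
               tolerance = 1e-10)
  # perfect homogeneity
  even <- composition_fisher(c(R = 5, G = 5), c(R = 5, G = 5), "R")
  expect_equal(even$p_two_sided, 1)
  # class-swap symmetry
  set.seed(4)
  for (k in 1:10) {
    x <- c(R = sample(1:20, 1), G = sample(1:20, 1))
    y <- c(R = sample(1:20, 1), G = sample(1:20, 1))
    expect_equal(composition_fisher(x, y, "R")$p_two_sided,
                 composition_fisher(y, x, "R")$p_two_sided)
  }
})

test_that("Wilson intervals hit the boundaries and the closed form", {
  expect_equal(wilson_ci(0, 10)[["lo"]], 0)
  expect_equal(wilson_ci(10, 10)[["hi"]], 1)
  z <- qnorm(0.975)
  p <- 0.8; n <- 10
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  ci <- wilson_ci(8, 10)
  expect_equal(ci[["lo"]], centre - half)
  expect_equal(ci[["hi"]], centre + half)
  expect_error(wilson_ci(5, 0), "positive")
  expect_error(wilson_ci(11, 10))
})

test_that("label-shuffled corpora rarely cross the preference cutoffs", {
  set.seed(99)
  n <- 1e5
  wt <- sample(aa20, n, TRUE)
  mut <- vapply(wt, function(w) sample(setdiff(aa20, w), 1), character(1))
  lab <- sample(c("driver", "passenger"), n, TRUE)
  rec <- data.frame(protein_id = "p", position = 1L, wt = wt, mut = mut,
                    cancer_type = "X", sample_count = 1L, label = lab)
  sc <- substitution_counts(rec)
  tab <- odds_ratio_table(sc)
  ok <- tab[tab$flag == "ok", ]
  called <- classify_motif_preference(ok$odds) != "neither"
  frac <- sum((ok$n_driver + ok$n_passenger)[called]) /
    sum(ok$n_driver + ok$n_passenger)
  expect_lt(frac, 0.10)
})
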