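# Mutation-preference statistics: substitution preference tables,
# driver/passenger odds ratios, motif preference calls, composition
# tests and Wilson confidence intervals.

#' Tabulate substitution counts by class
#'
#' Builds 20x20 wild-type-by-mutant substitution count tables for driver
#' and passenger mutations. The diagonal (silent substitutions) is never
#' populated — such records are rejected at ingestion.
#'
#' @param records A labelled `mutation_table`.
#' @return A `SubstitutionCounts`: list with matrices `counts_driver`,
#'   `counts_passenger` and totals `N_D`, `N_P`.
#' @export
substitution_counts <- function(records) {
  make_tab <- function(sub) {
    m <- matrix(0L, 20L, 20L,
                dimnames = list(AA_ALPHABETICAL, AA_ALPHABETICAL))
    if (nrow(sub) > 0L) {
      t0 <- table(factor(sub$wt, AA_ALPHABETICAL),
                  factor(sub$mut, AA_ALPHABETICAL))
      m <- m + unclass(t0)
    }
    storage.mode(m) <- "integer"
    m
  }
  d <- records[records$label == "driver", , drop = FALSE]
  p <- records[records$label == "passenger", , drop = FALSE]
  structure(list(counts_driver = make_tab(d),
                 counts_passenger = make_tab(p),
                 N_D = nrow(d), N_P = nrow(p)),
            class = "SubstitutionCounts")
}

#' Substitution preference table
#'
#' The relative frequency of each substitution within a class:
#' `n_ij / N`, where `n_ij` counts `i -> j` substitutions and `N` is the
#' class total. Entries sum to 1.
#'
#' @param counts A `SubstitutionCounts`.
#' @param class `"driver"` or `"passenger"`.
#' @return 20x20 numeric matrix summing to 1.
#' @export
substitution_preference <- function(counts, class = c("driver",
                                                      "passenger")) {
  class <- match.arg(class)
  n <- if (class == "driver") counts$N_D else counts$N_P
  if (n == 0L) stop("no ", class, " mutations: preference undefined",
                    call. = FALSE)
  m <- if (class == "driver") counts$counts_driver else
    counts$counts_passenger
  m / n
}

#' Driver-vs-passenger odds ratio of one substitution
#'
#' The ratio of the substitution's relative frequency among drivers to
#' that among passengers: `(n_ijD / N_D) / (n_ijP / N_P)`. Values above 1
#' mark driver-preferred substitutions. Zero cells are reported as flags,
#' not numbers: a substitution never seen among passengers is
#' `driver_unique` (odds value `NA`), one never seen among drivers is
#' `passenger_unique` (odds 0), and one absent from both is `absent`.
#' No continuity correction is applied here; pseudocounts are used only
#' where odds become model features (see [build_motif_odds()]).
#'
#' @param counts A `SubstitutionCounts`.
#' @param wt,mut One-letter residue codes.
#' @return List with `odds` (numeric or `NA`) and `flag` (one of `ok`,
#'   `driver_unique`, `passenger_unique`, `absent`).
#' @export
odds_ratio <- function(counts, wt, mut) {
  if (counts$N_D == 0L || counts$N_P == 0L) {
    stop("odds ratio undefined: empty driver or passenger class",
         call. = FALSE)
  }
  n_d <- counts$counts_driver[wt, mut]
  n_p <- counts$counts_passenger[wt, mut]
  if (n_d == 0L && n_p == 0L) {
    return(list(odds = NA_real_, flag = "absent"))
  }
  if (n_p == 0L) return(list(odds = NA_real_, flag = "driver_unique"))
  if (n_d == 0L) return(list(odds = 0, flag = "passenger_unique"))
  list(odds = (n_d / counts$N_D) / (n_p / counts$N_P), flag = "ok")
}

#' Full flagged odds-ratio table
#' @param counts A `SubstitutionCounts`.
#' @return Data frame with one row per observed substitution: `wt`, `mut`,
#'   `n_driver`, `n_passenger`, `odds`, `flag`.
#' @export
odds_ratio_table <- function(counts) {
  seen <- which(counts$counts_driver + counts$counts_passenger > 0L,
                arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(seen)), function(k) {
    wt <- AA_ALPHABETICAL[seen[k, 1]]; mut <- AA_ALPHABETICAL[seen[k, 2]]
    o <- odds_ratio(counts, wt, mut)
    data.frame(wt = wt, mut = mut,
               n_driver = counts$counts_driver[wt, mut],
               n_passenger = counts$counts_passenger[wt, mut],
               odds = o$odds, flag = o$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify a motif (or substitution) by its odds ratio
#'
#' Stringent preference call: odds at or above 1.2 mark driver preference,
#' odds at or below 0.8 mark passenger preference, anything between is
#' neither. Both boundaries are inclusive.
#'
#' @param odds Non-negative odds ratio(s).
#' @param driver_cutoff,passenger_cutoff Inclusive cutoffs (defaults 1.2
#'   and 0.8).
#' @return Character vector over `{driver, passenger, neither}`.
#' @export
classify_motif_preference <- function(odds, driver_cutoff = 1.2,
                                      passenger_cutoff = 0.8) {
  stopifnot(all(odds >= 0, na.rm = TRUE))
  out <- rep("neither", length(odds))
  out[odds >= driver_cutoff] <- "driver"
  out[odds <= passenger_cutoff] <- "passenger"
  out[is.na(odds)] <- NA_character_
  out
}

#' Fisher exact test of residue composition between two classes
#'
#' Forms the 2x2 table (`residue` vs all other residues) x (class a vs
#' class b) and tests homogeneity with Fisher's exact test (two-sided p by
#' summation of hypergeometric probabilities no larger than the observed
#' one). The returned odds is the sample cross-product ratio.
#'
#' @param counts_a,counts_b Named per-residue count vectors for the two
#'   classes.
#' @param residue One-letter residue code.
#' @return List with `odds` (sample odds ratio) and `p_two_sided`.
#' @export
composition_fisher <- function(counts_a, counts_b, residue) {
  a1 <- counts_a[[residue]]; a0 <- sum(counts_a) - a1
  b1 <- counts_b[[residue]]; b0 <- sum(counts_b) - b1
  tab <- matrix(c(a1, b1, a0, b0), 2L)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate margin in 2x2 composition table", call. = FALSE)
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds = (a1 * b0) / (a0 * b1), p_two_sided = ft$p.value)
}

#' Wilson score confidence interval for a proportion
#'
#' Closed-form Wilson interval at the requested confidence, used for
#' per-cancer-type driver-frequency error bars.
#'
#' @param successes Number of successes (`0 <= successes <= n`).
#' @param n Number of trials (`> 0`).
#' @param conf Confidence level (default 0.95).
#' @return Named vector `c(lo, hi)` within `[0, 1]`.
#' @export
wilson_ci <- function(successes, n, conf = 0.95) {
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  if (successes < 0L || successes > n) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}
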