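#!/usr/bin/env Rscript
# Thin command-line wrapper over the missdriver package.
#
#   missdriver synth   --out DIR [--seed N] [--proteins N] [--drivers N] [--passengers N]
#   missdriver stats   --mutations CSV --out TSV
#   missdriver cv      --features TSV --out JSON [--folds K] [--k N] [--seed N]
#
# `synth` writes a synthetic fixture tree (FASTA, PDB, PSSM, tracks,
# mutation CSV); `stats` writes the flagged substitution odds-ratio table;
# `cv` runs stratified cross-validation on a feature TSV produced by
# write_feature_matrix().

suppressMessages({ library(optparse); library(missdriver) })

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) stop("usage: missdriver <synth|stats|cv> [options]")
cmd <- args[1]
rest <- args[-1]

if (cmd == "synth") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--out", type = "character"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--proteins", type = "integer", default = 10L),
    make_option("--drivers", type = "integer", default = 200L),
    make_option("--passengers", type = "integer", default = 100L))),
    args = rest)
  cfg <- synth_config(n_proteins = o$proteins, n_driver = o$drivers,
                      n_passenger = o$passengers, seed = o$seed)
  write_fixture_tree(cfg, o$out)
  cat("fixture tree written to", o$out, "\n")
} else if (cmd == "stats") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--mutations", type = "character"),
    make_option("--out", type = "character"))), args = rest)
  rec <- label_by_recurrence(read_mutation_table(o$mutations))
  tab <- odds_ratio_table(substitution_counts(rec))
  tab$preference <- classify_motif_preference(tab$odds)
  write.table(tab, o$out, sep = "\t", row.names = FALSE, quote = FALSE)
  cat("odds table written to", o$out, "\n")
} else if (cmd == "cv") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--features", type = "character"),
    make_option("--out", type = "character"),
    make_option("--folds", type = "integer", default = 10L),
    make_option("--k", type = "integer", default = NA_integer_),
    make_option("--seed", type = "integer", default = 1L))), args = rest)
  df <- read.delim(o$features, check.names = FALSE)
  fm <- feature_matrix(as.matrix(df[, -(1:2)]), df$label, df$protein_id)
  k <- if (is.na(o$k)) NULL else o$k
  cv <- kfold_cv(fm, mlp_config(seed = o$seed), k_folds = o$folds,
                 seed = o$seed, n_features = k)
  jsonlite::write_json(cv$mean, o$out, auto_unbox = TRUE, digits = NA)
  cat("metrics written to", o$out, "\n")
} else {
  stop("unknown subcommand '", cmd, "'")
}
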