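#' Default gapped di-/tri-peptide motif families
#'
#' Seven pattern families built from the mutation site and neighbouring
#' residues with gaps, expressed as offset vectors relative to the mutation
#' site (offset 0). Di-peptide families pair the site with a neighbour at
#' gap 0, 3 or 4 on either side; tri-peptide families span the two flanking
#' neighbours, adjacent or gapped. The families are configuration, not
#' constants: any list of offset vectors may be supplied to
#' [build_motif_odds()].
#'
#' @return Named list of integer offset vectors.
#' @export
default_motif_families <- function() {
  list(
    di_site_right   = c(0L, 1L),
    di_left_site    = c(-1L, 0L),
    di_site_right_g3 = c(0L, 4L),
    di_left_g3_site = c(-4L, 0L),
    di_site_right_g4 = c(0L, 5L),
    tri_left_site_right = c(-1L, 0L, 1L),
    tri_left_site_right_g3 = c(-1L, 0L, 4L)
  )
}

#' Concrete motif realised at a site
#'
#' The motif string is the concatenation of the wild-type residues at
#' `pos + offsets`. Returns `NA` when any required position is out of
#' bounds (sequence terminus) or is an `X` residue.
#'
#' @param seq A `ProteinSequence` or residue string.
#' @param pos 1-based mutation position.
#' @param offsets Integer offsets relative to the site (0 = site).
#' @return Motif string or `NA`.
#' @export
motif_at <- function(seq, pos, offsets) {
  s <- if (inherits(seq, "ProteinSequence")) seq$residues else seq
  n <- nchar(s)
  idx <- pos + offsets
  if (any(idx < 1L | idx > n)) return(NA_character_)
  chars <- substring(s, idx, idx)
  if (any(chars == "X")) return(NA_character_)
  paste(chars, collapse = "")
}

#' Build a motif odds-ratio table from labelled mutations
#'
#' For one motif family, counts the occurrences of each concrete motif at
#' driver and at passenger mutation sites, and stores the odds ratio
#' `((n_D + c)/(N_D + c)) / ((n_P + c)/(N_P + c))` per motif, where `n` are
#' per-motif counts, `N` the per-class totals of in-bounds sites and `c` a
#' pseudocount (default 0.5, Haldane-Anscombe) protecting against zero
#' counts. Odds above 1 mark driver-enriched motifs.
#'
#' @param records A labelled `mutation_table` (labels `driver`/`passenger`;
#'   other rows ignored).
#' @param sequences Named list of `ProteinSequence` objects.
#' @param offsets Integer offset vector defining the family (see
#'   [default_motif_families()]).
#' @param pseudocount Pseudocount `c >= 0` (default 0.5).
#' @param pattern_class Name recorded on the table.
#' @return A `MotifOddsTable`: list with `pattern_class`, `offsets`,
#'   `pseudocount`, counts `n_driver`/`n_passenger` per motif, totals
#'   `N_driver`/`N_passenger`, and `odds`, a named positive numeric vector.
#' @export
build_motif_odds <- function(records, sequences, offsets,
                             pseudocount = 0.5,
                             pattern_class = paste(offsets, collapse = ",")) {
  lab <- records$label
  motifs <- vapply(seq_len(nrow(records)), function(i) {
    s <- sequences[[records$protein_id[i]]]
    if (is.null(s)) return(NA_character_)
    motif_at(s, records$position[i], offsets)
  }, character(1))
  d_m <- motifs[lab == "driver" & !is.na(motifs)]
  p_m <- motifs[lab == "passenger" & !is.na(motifs)]
  N_D <- length(d_m); N_P <- length(p_m)
  if (N_P == 0L) {
    stop("no passenger sites with an in-bounds motif: odds undefined",
         call. = FALSE)
  }
  if (N_D == 0L) {
    stop("no driver sites with an in-bounds motif: odds undefined",
         call. = FALSE)
  }
  all_motifs <- sort(unique(c(d_m, p_m)))
  n_d <- vapply(all_motifs, function(m) sum(d_m == m), numeric(1))
  n_p <- vapply(all_motifs, function(m) sum(p_m == m), numeric(1))
  c0 <- pseudocount
  if (c0 == 0 && any(n_p == 0)) {
    warning("motifs unseen in passengers give infinite odds at ",
            "pseudocount 0", call. = FALSE)
  }
  odds <- ((n_d + c0) / (N_D + c0)) / ((n_p + c0) / (N_P + c0))
  structure(list(pattern_class = pattern_class, offsets = offsets,
                 pseudocount = pseudocount,
                 n_driver = n_d, n_passenger = n_p,
                 N_driver = N_D, N_passenger = N_P,
                 odds = odds),
            class = "MotifOddsTable")
}

#' @export
print.MotifOddsTable <- function(x, ...) {
  cat(sprintf("MotifOddsTable '%s': %d motifs (N_D=%d, N_P=%d, c=%g)\n",
              x$pattern_class, length(x$odds), x$N_driver, x$N_passenger,
              x$pseudocount))
  invisible(x)
}

#' Build odds tables for every motif family
#' @param records,sequences,pseudocount See [build_motif_odds()].
#' @param families Named list of offset vectors
#'   (default [default_motif_families()]).
#' @return Named list of `MotifOddsTable`s.
#' @export
build_all_motif_odds <- function(records, sequences,
                                 families = default_motif_families(),
                                 pseudocount = 0.5) {
  out <- lapply(names(families), function(nm) {
    build_motif_odds(records, sequences, families[[nm]],
                     pseudocount = pseudocount, pattern_class = nm)
  })
  names(out) <- names(families)
  out
}

#' Motif odds features at a site
#'
#' For each family table, the stored odds of the concrete motif realised at
#' `(seq, pos)`. Motifs unseen during table construction — and sites where
#' the family's offsets fall outside the sequence — score 1.0
#' (odds-neutral).
#'
#' @param seq A `ProteinSequence` or residue string.
#' @param pos 1-based mutation position.
#' @param tables Named list of `MotifOddsTable`s.
#' @return Named numeric vector, one odds value per family.
#' @export
motif_features <- function(seq, pos, tables) {
  vapply(tables, function(tb) {
    m <- motif_at(seq, pos, tb$offsets)
    if (is.na(m) || !(m %in% names(tb$odds))) 1.0 else unname(tb$odds[[m]])
  }, numeric(1))
}

#' Serialise motif odds tables to TSV
#' @param tables Named list of `MotifOddsTable`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_odds <- function(tables, path) {
  rows <- do.call(rbind, lapply(tables, function(tb) {
    data.frame(family = tb$pattern_class, motif = names(tb$odds),
               n_driver = unname(tb$n_driver),
               n_passenger = unname(tb$n_passenger),
               odds = unname(tb$odds), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
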