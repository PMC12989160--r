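# Assembly of the per-mutation feature matrix from all feature families.
# Each family is optional: features from a family are only emitted when
# its inputs are supplied, and mutations at X residues yield missing
# values rather than aborting extraction.

#' Extract the per-mutation feature matrix
#'
#' Assembles all configured feature families for every mutation record:
#' amino-acid property changes (one per property table), AAindex2
#' substitution-matrix values, AAindex3 neighbour contact-potential
#' differences, the six-class neighbourhood composition, gapped-motif odds
#' features, PSSM profile features, per-track conservation/disorder
#' features, structural annotations (pLDDT, ASA, relative ASA, secondary
#' structure one-hot, residue depth, contact count, averaged over models
#' when several are supplied) and contact-network centralities.
#'
#' Column names are stable `"<family>.<detail>"` strings. Missing inputs
#' (e.g. a mutation outside a structure, or an `X` residue) produce `NA`
#' cells, resolved later by the explicit imputation policy.
#'
#' @param records A labelled `mutation_table`.
#' @param sequences Named list of `ProteinSequence` objects.
#' @param properties Optional `PropertySet` (named list of 20-value
#'   tables).
#' @param aaindex2 Optional named list of `index2` `AAindexEntry`s.
#' @param aaindex3 Optional named list of `index3` `AAindexEntry`s.
#' @param motif_tables Optional named list of `MotifOddsTable`s (built on
#'   training data only).
#' @param pssms Optional named list of `PSSMProfile`s per protein.
#' @param tracks Optional named list (per protein) of named lists of
#'   per-residue numeric tracks.
#' @param structures Optional named list (per protein) of a
#'   `StructureModel` or list of models (several models are averaged).
#' @param dssp Optional named list (per protein) of [read_dssp()] tables.
#' @param flank Window flank for windowed features (default 6, a
#'   13-residue window).
#' @param contact_cutoff Distance cutoff for contacts and networks
#'   (default 7 Angstrom).
#' @param sasa_points Quadrature points per atom (default 240 here; the
#'   per-atom default of [sasa()] is finer).
#' @return A `feature_matrix` with one row per record.
#' @export
extract_features <- function(records, sequences, properties = NULL,
                             aaindex2 = NULL, aaindex3 = NULL,
                             motif_tables = NULL, pssms = NULL,
                             tracks = NULL, structures = NULL,
                             dssp = NULL, flank = 6L, contact_cutoff = 7,
                             sasa_points = 240L) {
  struct_ann <- list(); net_cent <- list()
  if (!is.null(structures)) {
    for (id in names(structures)) {
      models <- structures[[id]]
      if (inherits(models, "StructureModel")) models <- list(models)
      anns <- lapply(models, function(m) {
        ann <- annotate_structure(m, dssp = dssp[[id]],
                                  n_points = sasa_points,
                                  contact_cutoff = contact_cutoff)
        ann$ss_H <- as.numeric(ann$ss == "H")
        ann$ss_E <- as.numeric(ann$ss == "E")
        ann$ss_C <- as.numeric(ann$ss == "C")
        ann[, c("residue_number", "plddt", "asa", "rel_asa", "depth",
                "contact_count", "ss_H", "ss_E", "ss_C")]
      })
      struct_ann[[id]] <- average_over_models(anns)
      cents <- lapply(models, function(m) {
        cf <- centrality_features(build_contact_network(m, contact_cutoff))
        cf$residue_number <- as.integer(cf$residue_number)
        cf[, c("residue_number", "closeness", "betweenness",
               "eigenvector", "degree")]
      })
      net_cent[[id]] <- average_over_models(cents)
    }
  }

  rows <- lapply(seq_len(nrow(records)), function(i) {
    pid <- records$protein_id[i]
    pos <- records$position[i]
    wt <- records$wt[i]; mut <- records$mut[i]
    s <- sequences[[pid]]
    if (is.null(s)) stop("no sequence for protein '", pid, "'",
                         call. = FALSE)
    out <- c()
    if (!is.null(properties)) {
      v <- vapply(properties, function(tb) delta_property(wt, mut, tb),
                  numeric(1))
      out <- c(out, setNames(v, paste0("prop.", names(properties))))
    }
    if (!is.null(aaindex2)) {
      v <- vapply(aaindex2, function(e)
        substitution_matrix_feature(wt, mut, e), numeric(1))
      out <- c(out, setNames(v, paste0("mat.", names(aaindex2))))
    }
    if (!is.null(aaindex3)) {
      for (nm in names(aaindex3)) {
        v <- neighbor_contact_potential_delta(s, pos, aaindex3[[nm]],
                                              mut, wt = wt)
        out <- c(out, setNames(v, paste0("cp.", nm, ".", names(v))))
      }
    }
    comp <- neighbor_composition(s, pos, flank)
    out <- c(out, setNames(as.numeric(comp),
                           paste0("comp.", names(comp))))
    if (!is.null(motif_tables)) {
      mf <- motif_features(s, pos, motif_tables)
      out <- c(out, setNames(mf, paste0("motif.", names(motif_tables))))
    }
    if (!is.null(pssms) && !is.null(pssms[[pid]])) {
      pf <- pssm_features(pssms[[pid]], pos, wt, mut, flank)
      out <- c(out, setNames(pf, paste0("pssm.", names(pf))))
    }
    if (!is.null(tracks) && !is.null(tracks[[pid]])) {
      for (tn in names(tracks[[pid]])) {
        tf <- track_features(tracks[[pid]][[tn]], pos, flank)
        out <- c(out, setNames(tf, paste0("track.", tn, ".", names(tf))))
      }
    }
    if (length(struct_ann) > 0L) {
      ann <- struct_ann[[pid]]
      cols <- c("plddt", "asa", "rel_asa", "depth", "contact_count",
                "ss_H", "ss_E", "ss_C")
      v <- setNames(rep(NA_real_, length(cols)), paste0("struct.", cols))
      if (!is.null(ann)) {
        j <- match(pos, ann$residue_number)
        if (!is.na(j)) v[] <- as.numeric(ann[j, cols])
      }
      out <- c(out, v)
    }
    if (length(net_cent) > 0L) {
      cent <- net_cent[[pid]]
      cols <- c("closeness", "betweenness", "eigenvector", "degree")
      v <- setNames(rep(NA_real_, length(cols)), paste0("net.", cols))
      if (!is.null(cent)) {
        j <- match(pos, cent$residue_number)
        if (!is.na(j)) v[] <- as.numeric(cent[j, cols])
      }
      out <- c(out, v)
    }
    out
  })
  x <- do.call(rbind, rows)
  feature_matrix(x, records$label, records$protein_id)
}

#' Write a feature matrix as TSV
#'
#' One row per mutation with the stable feature column names, preceded by
#' `protein_id` and `label` columns.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(protein_id = fm$protein_id,
                   label = ifelse(fm$y == 1L, "driver", "passenger"),
                   fm$x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
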