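#' Read a mutation table from CSV
#'
#' Reads one substitution per row. The canonical column layout is
#' `protein_id, position, wt, mut, cancer_type, sample_count, label`
#' (`label` optional; absent labels become `"unknown"`). Positions are
#' 1-based, matching standard mutation nomenclature such as R175H.
#' Other layouts can be adapted with `col_map`.
#'
#' @param path Path to a CSV file with a header row.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(protein_id = "uniprot", position = "pos")`.
#' @return A `data.frame` of class `mutation_table` with typed columns
#'   `protein_id`, `position` (integer), `wt`, `mut`, `cancer_type`,
#'   `sample_count` (integer) and `label` (one of `driver`, `passenger`,
#'   `unknown`).
#' @export
read_mutation_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  needed <- c("protein_id", "position", "wt", "mut", "cancer_type",
              "sample_count")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canon]]] <- canon
      }
    }
  }
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("mutation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"label" %in% names(raw)) raw$label <- "unknown"
  raw$label[is.na(raw$label) | raw$label == ""] <- "unknown"

  n <- nrow(raw)
  if (n == 0L) stop("mutation table has no data rows", call. = FALSE)
  pos <- suppressWarnings(as.integer(raw$position))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed position '%s' in mutation table row %d",
                 raw$position[bad[1]], bad[1]), call. = FALSE)
  }
  cnt <- suppressWarnings(as.integer(raw$sample_count))
  bad <- which(is.na(cnt) | cnt < 0L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed sample_count '%s' in mutation table row %d",
                 raw$sample_count[bad[1]], bad[1]), call. = FALSE)
  }
  wt <- toupper(raw$wt); mut <- toupper(raw$mut)
  for (col in list(wt = wt, mut = mut)) NULL
  bad <- which(!(wt %in% AA_ALPHABETICAL) | !(mut %in% AA_ALPHABETICAL))
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue letter '%s>%s' in mutation table row %d",
                 wt[bad[1]], mut[bad[1]], bad[1]), call. = FALSE)
  }
  bad <- which(wt == mut)
  if (length(bad) > 0L) {
    stop(sprintf(
      "wild-type equals mutant residue ('%s') in mutation table row %d",
      wt[bad[1]], bad[1]), call. = FALSE)
  }
  bad <- which(!raw$label %in% c("driver", "passenger", "unknown"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown label '%s' in mutation table row %d",
                 raw$label[bad[1]], bad[1]), call. = FALSE)
  }
  out <- data.frame(protein_id = raw$protein_id, position = pos,
                    wt = wt, mut = mut, cancer_type = raw$cancer_type,
                    sample_count = cnt, label = raw$label,
                    stringsAsFactors = FALSE)
  class(out) <- c("mutation_table", "data.frame")
  out
}

#' Write a mutation table to CSV
#' @param records A `mutation_table` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Label mutations as drivers by recurrence
#'
#' Applies the recurrence criterion used to define drivers: a mutation
#' observed in at least `threshold` tumour samples is labelled a driver.
#' Only records currently labelled `unknown` are relabelled; existing
#' `passenger` (or `driver`) labels are never overwritten.
#'
#' @param records A `mutation_table`.
#' @param threshold Minimum sample count for a driver call (default 3).
#' @return The records with updated `label` column.
#' @export
label_by_recurrence <- function(records, threshold = 3L) {
  stopifnot(is.data.frame(records), "sample_count" %in% names(records))
  promote <- records$label == "unknown" & records$sample_count >= threshold
  records$label[promote] <- "driver"
  records
}

#' Check mutation records against their protein sequences
#'
#' Verifies that each record's position lies inside the attached sequence and
#' that the sequence letter at that position equals the record's wild-type
#' residue.
#'
#' @param records A `mutation_table`.
#' @param sequences Named list of `ProteinSequence` objects (names are
#'   protein ids).
#' @return `records`, invisibly, if all checks pass; otherwise an error
#'   naming the first offending row.
#' @export
validate_mutations <- function(records, sequences) {
  for (i in seq_len(nrow(records))) {
    pid <- records$protein_id[i]
    s <- sequences[[pid]]
    if (is.null(s)) stop("no sequence for protein '", pid, "' (row ", i, ")",
                         call. = FALSE)
    if (records$position[i] > nchar(s$residues)) {
      stop(sprintf("position %d exceeds length of '%s' (row %d)",
                   records$position[i], pid, i), call. = FALSE)
    }
    obs <- residue_at(s, records$position[i])
    if (obs != records$wt[i]) {
      stop(sprintf(
        "wild-type mismatch at %s position %d: table says %s, sequence has %s (row %d)",
        pid, records$position[i], records$wt[i], obs, i), call. = FALSE)
    }
  }
  invisible(records)
}
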