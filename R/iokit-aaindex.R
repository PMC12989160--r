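#' Read AAindex flat files
#'
#' Parses the AAindex flat-file format (blocks of tagged lines terminated by
#' `//`). `index1` entries carry 20 per-residue values on an `I` line pair;
#' `index2` (substitution matrices) and `index3` (pairwise contact
#' potentials) entries carry an `M rows = ..., cols = ...` table, either
#' full or lower-triangular. Lower-triangular tables are mirrored to a full
#' symmetric 20x20 lookup. `NA` cells are preserved as missing: parsing
#' succeeds, and the error is raised at lookup time (see
#' [aaindex_lookup()]).
#'
#' @param path Path to an AAindex-format file (one or more entries).
#' @param kind One of `"index1"`, `"index2"`, `"index3"`.
#' @return Named list of `AAindexEntry` objects (names are accessions).
#'   `index1` entries hold `values` as a named vector over the 20 residues;
#'   `index2`/`index3` entries hold a 20x20 matrix (row = wild-type,
#'   column = mutant for asymmetric matrices).
#' @export
read_aaindex <- function(path, kind = c("index1", "index2", "index3")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  term <- grep("^//", lines)
  if (length(term) == 0L) stop("no '//' entry terminator in '", path, "'",
                               call. = FALSE)
  starts <- c(1L, head(term, -1L) + 1L)
  entries <- list()
  for (b in seq_along(term)) {
    block <- lines[starts[b]:(term[b] - 1L)]
    block <- block[nchar(trimws(block)) > 0L]
    if (length(block) == 0L) next
    entry <- if (kind == "index1") parse_aaindex1_block(block)
             else parse_aaindex_matrix_block(block, kind)
    entries[[entry$accession]] <- entry
  }
  if (length(entries) == 0L) stop("no AAindex entries in '", path, "'",
                                  call. = FALSE)
  entries
}

#' @keywords internal
aaindex_tokens <- function(block, after_line) {
  n <- length(block)
  if (after_line >= n) return(character(0))
  cont <- block[(after_line + 1L):n]
  # data continuation lines start with whitespace; a new tag starts a
  # capital letter in column 1
  stop_at <- which(grepl("^[A-Z]", cont))
  if (length(stop_at) > 0L) cont <- cont[seq_len(stop_at[1] - 1L)]
  unlist(strsplit(trimws(cont), "\\s+"))
}

#' @keywords internal
parse_aaindex1_block <- function(block) {
  acc_line <- grep("^H ", block, value = TRUE)
  if (length(acc_line) == 0L) stop("AAindex entry without H accession line",
                                   call. = FALSE)
  accession <- trimws(sub("^H ", "", acc_line[1]))
  i_line <- grep("^I ", block)
  if (length(i_line) == 0L) {
    stop("AAindex1 entry '", accession, "' has no I line", call. = FALSE)
  }
  # order on the I line: A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V
  pairs <- strsplit(trimws(sub("^I ", "", block[i_line[1]])), "\\s+")[[1]]
  top <- vapply(strsplit(pairs, "/"), `[`, character(1), 1L)
  bottom <- vapply(strsplit(pairs, "/"), `[`, character(1), 2L)
  tok <- aaindex_tokens(block, i_line[1])
  if (length(tok) != 20L) {
    stop("AAindex1 entry '", accession, "' has ", length(tok),
         " values (expected 20)", call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(tok))
  vals[tok %in% c("NA", "-")] <- NA_real_
  values <- setNames(vals, c(top, bottom))[AA_ALPHABETICAL]
  structure(list(accession = accession, kind = "index1", values = values),
            class = "AAindexEntry")
}

#' @keywords internal
parse_aaindex_matrix_block <- function(block, kind) {
  acc_line <- grep("^H ", block, value = TRUE)
  if (length(acc_line) == 0L) stop("AAindex entry without H accession line",
                                   call. = FALSE)
  accession <- trimws(sub("^H ", "", acc_line[1]))
  m_line_i <- grep("^M ", block)
  if (length(m_line_i) == 0L) {
    stop("AAindex entry '", accession, "' has no M line", call. = FALSE)
  }
  m_line <- block[m_line_i[1]]
  rows <- sub(".*rows\\s*=\\s*([A-Z]+).*", "\\1", m_line)
  cols <- sub(".*cols\\s*=\\s*([A-Z]+).*", "\\1", m_line)
  row_aa <- strsplit(rows, "")[[1]]
  col_aa <- strsplit(cols, "")[[1]]
  nr <- length(row_aa); nc <- length(col_aa)
  tok <- aaindex_tokens(block, m_line_i[1])
  vals <- suppressWarnings(as.numeric(tok))
  vals[tok %in% c("NA", "-")] <- NA_real_
  mat <- matrix(NA_real_, nr, nc, dimnames = list(row_aa, col_aa))
  n_tri <- nr * (nr + 1L) / 2L
  symmetric <- FALSE
  if (identical(row_aa, col_aa) && length(vals) == n_tri) {
    k <- 1L
    for (i in seq_len(nr)) {
      for (j in seq_len(i)) {
        mat[i, j] <- vals[k]
        mat[j, i] <- vals[k]
        k <- k + 1L
      }
    }
    symmetric <- TRUE
  } else if (length(vals) == nr * nc) {
    mat <- matrix(vals, nr, nc, byrow = TRUE,
                  dimnames = list(row_aa, col_aa))
  } else {
    stop("AAindex entry '", accession, "' has ", length(vals),
         " values; expected ", n_tri, " (triangular) or ", nr * nc,
         " (full)", call. = FALSE)
  }
  structure(list(accession = accession, kind = kind, values = mat,
                 symmetric = symmetric),
            class = "AAindexEntry")
}

#' Look up an AAindex entry value
#'
#' For `index1` entries, `mut` is ignored and the per-residue value of `wt`
#' is returned. For `index2`/`index3` entries, the `(wt, mut)` cell is
#' returned (symmetric entries resolve both orders identically). A missing
#' (`NA`) cell raises an error when `strict = TRUE` (the default) and
#' returns `NA` otherwise.
#'
#' @param entry An `AAindexEntry`.
#' @param wt,mut One-letter residue codes.
#' @param strict Error on missing cells?
#' @return Numeric scalar.
#' @export
aaindex_lookup <- function(entry, wt, mut = NULL, strict = TRUE) {
  stopifnot(inherits(entry, "AAindexEntry"))
  if (entry$kind == "index1") {
    v <- entry$values[[wt]]
  } else {
    if (is.null(mut)) stop("mut residue required for ", entry$kind,
                           " lookup", call. = FALSE)
    if (!(wt %in% rownames(entry$values)) ||
        !(mut %in% colnames(entry$values))) {
      stop(sprintf("residue pair (%s, %s) not covered by AAindex entry %s",
                   wt, mut, entry$accession), call. = FALSE)
    }
    v <- entry$values[wt, mut]
  }
  if (is.na(v) && strict) {
    stop(sprintf("AAindex entry %s has no value for (%s%s)",
                 entry$accession, wt,
                 if (is.null(mut)) "" else paste0(", ", mut)),
         call. = FALSE)
  }
  unname(v)
}

#' @export
print.AAindexEntry <- function(x, ...) {
  cat(sprintf("AAindexEntry %s (%s)\n", x$accession, x$kind))
  invisible(x)
}
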