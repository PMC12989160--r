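# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code; oracles never call the code paths
# they check.

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# --- AAindex fixture writers -------------------------------------------

toy_aaindex1_file <- function(values, accession = "TOY00001") {
  # values: named over the 20 residues
  order1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  order2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  write_tmp(c(
    paste("H", accession),
    "D toy per-residue property",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    paste0("   ", paste(sprintf("%7.3f", values[order1]), collapse = " ")),
    paste0("   ", paste(sprintf("%7.3f", values[order2]), collapse = " ")),
    "//"))
}

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

aa_pssm_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

toy_aaindex_matrix_file <- function(mat, accession = "TOYM0001",
                                    triangular = FALSE) {
  rows_aa <- paste(rownames(mat), collapse = "")
  cols_aa <- paste(colnames(mat), collapse = "")
  fmt <- function(v) {
    paste(ifelse(is.na(v), "NA", sprintf("%.2f", v)), collapse = " ")
  }
  body <- if (triangular) {
    vapply(seq_len(nrow(mat)), function(i)
      paste0("    ", fmt(mat[i, seq_len(i)])), character(1))
  } else {
    vapply(seq_len(nrow(mat)), function(i)
      paste0("    ", fmt(mat[i, ])), character(1))
  }
  write_tmp(c(
    paste("H", accession),
    "D toy matrix",
    sprintf("M rows = %s, cols = %s", rows_aa, cols_aa),
    body, "//"))
}

full_symmetric_entry <- function(fill = 1, accession = "TOYS0001") {
  m <- matrix(fill, 20, 20, dimnames = list(aa20, aa20))
  read_aaindex(toy_aaindex_matrix_file(m, accession), "index3")[[1]]
}

# toy contact-potential entry over a few residues, values settable
toy_cp_entry <- function(cells) {
  # cells: data.frame(a, b, v); symmetric fill, default 0
  m <- matrix(0, 20, 20, dimnames = list(aa20, aa20))
  for (i in seq_len(nrow(cells))) {
    m[cells$a[i], cells$b[i]] <- cells$v[i]
    m[cells$b[i], cells$a[i]] <- cells$v[i]
  }
  f <- toy_aaindex_matrix_file(m, "TOYCP001", triangular = FALSE)
  read_aaindex(f, "index3")[[1]]
}

# --- structure fixtures ------------------------------------------------

# residues as single atoms at given coordinates
point_model <- function(xyz, residue_numbers = seq_len(nrow(xyz)),
                        element = "C", bfactor = 50) {
  structure_model("toy", "1", data.frame(
    residue_number = as.integer(residue_numbers),
    residue_name = "A", atom_name = "CA", element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], bfactor = bfactor,
    stringsAsFactors = FALSE))
}

golden_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# a single carbon atom at the origin enclosed by a tight shell of atoms
caged_model <- function(n_shell = 100, shell_radius = 3.0) {
  shell <- golden_sphere(n_shell) * shell_radius
  xyz <- rbind(c(0, 0, 0), shell)
  point_model(xyz, residue_numbers = c(1L, rep(2L, n_shell)))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2+b^2-c^2-d^2, 2*(b*c-a*d),     2*(b*d+a*c),
           2*(b*c+a*d),     a^2-b^2+c^2-d^2, 2*(c*d-a*b),
           2*(b*d-a*c),     2*(c*d+a*b),     a^2-b^2-c^2+d^2),
         3, 3, byrow = TRUE)
}

rotate_model <- function(model, R) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  a <- model$atoms
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  structure_model(model$protein_id, model$model_id, a)
}

# --- graph oracles -----------------------------------------------------

# all-pairs shortest path matrix by Floyd-Warshall (unit edge lengths)
oracle_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# enumerate every shortest path between s and t; returns list of paths
enum_shortest_paths <- function(adj, d, s, t) {
  if (!is.finite(d[s, t])) return(list())
  if (s == t) return(list(s))
  nbrs <- which(adj[s, ] > 0 & d[, t] == d[s, t] - 1)
  out <- list()
  for (u in nbrs) {
    for (p in enum_shortest_paths(adj, d, u, t)) {
      out[[length(out) + 1L]] <- c(s, p)
    }
  }
  out
}

oracle_centralities <- function(adj) {
  n <- nrow(adj)
  d <- oracle_dist(adj)
  clo <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (length(reach) == 0L) return(0)
    # reciprocal of mean shortest-path length to reachable vertices
    length(reach) / sum(d[v, reach])
  }, numeric(1))
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(d[s, t])) next
    paths <- enum_shortest_paths(adj, d, s, t)
    if (length(paths) == 0L) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      thr <- sum(vapply(paths, function(p) v %in% p[-c(1, length(p))],
                        logical(1)))
      btw[v] <- btw[v] + thr / length(paths)
    }
  }
  if (n > 2L) btw <- btw / ((n - 1) * (n - 2) / 2)
  ev <- eigen(adj, symmetric = TRUE)
  v1 <- abs(ev$vectors[, which.max(ev$values)])
  ev_cent <- if (max(v1) > 0) v1 / max(v1) else v1
  list(closeness = clo, betweenness = btw, eigenvector = ev_cent,
       degree = rowSums(adj))
}

random_connected_adj <- function(n, seed) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  # random spanning tree, then extra random edges, integer weights
  for (v in 2:n) {
    u <- sample(v - 1L, 1L)
    w <- sample(1:5, 1L)
    adj[u, v] <- adj[v, u] <- w
  }
  extra <- which(upper.tri(adj) & adj == 0)
  if (length(extra) > 0L) {
    add <- extra[runif(length(extra)) < 0.3]
    for (e in add) {
      ij <- arrayInd(e, dim(adj))
      w <- sample(1:5, 1L)
      adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- w
    }
  }
  adj
}

adj_to_network <- function(adj) {
  n <- nrow(adj)
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  contact_network(as.character(seq_len(n)),
                  cbind(as.character(idx[, 1]), as.character(idx[, 2])),
                  weights = adj[idx])
}

# --- classification oracles --------------------------------------------

# exhaustive pairwise Mann-Whitney AUC with half-credit ties
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# two-sided Fisher p by full hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small labelled corpus over synthetic sequences, for motif/odds tests
toy_corpus <- function(n_driver = 60, n_passenger = 60, seed = 11,
                       n_proteins = 4, len = c(60, 60)) {
  cfg <- synth_config(n_proteins = n_proteins,
                      protein_length_range = len,
                      n_driver = n_driver, n_passenger = n_passenger,
                      effect_size = 0, seed = seed)
  gen_mutation_dataset(cfg)
}
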