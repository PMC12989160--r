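# Weighted amino-acid contact networks and residue centrality features.
# Nodes are residues; an edge joins two residues with at least one
# atom-atom pair within the distance cutoff, weighted by the number of
# such atom pairs.

#' Build a weighted amino-acid contact network
#'
#' Residues become nodes; residues `i != j` are joined iff at least one
#' atom of `i` lies within `cutoff` Angstrom of an atom of `j`; the edge
#' weight is the number of such atom pairs. The network is undirected with
#' no self-edges.
#'
#' @param model A `StructureModel`.
#' @param cutoff Atom-atom distance cutoff in Angstrom (default 7).
#' @return A `ContactNetwork`: list with an `igraph` `graph` (vertex names
#'   are residue numbers, edge attribute `weight`) and the `cutoff`.
#' @export
build_contact_network <- function(model, cutoff = 7) {
  res <- model_residues(model)
  if (length(res) < 2L) stop("model needs at least 2 residues",
                             call. = FALSE)
  xyz <- atom_coords(model)
  res_of_atom <- model$atoms$residue_number
  d <- as.matrix(stats::dist(xyz))
  within <- d <= cutoff
  diag(within) <- FALSE
  edges <- list(); weights <- integer(0)
  for (a in seq_along(res)) {
    ia <- which(res_of_atom == res[a])
    for (b in seq_along(res)) {
      if (b <= a) next
      ib <- which(res_of_atom == res[b])
      w <- sum(within[ia, ib, drop = FALSE])
      if (w > 0L) {
        edges[[length(edges) + 1L]] <- c(a, b)
        weights <- c(weights, w)
      }
    }
  }
  g <- igraph::make_empty_graph(n = length(res), directed = FALSE)
  igraph::V(g)$name <- as.character(res)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
    igraph::E(g)$weight <- weights
  }
  structure(list(graph = g, cutoff = cutoff), class = "ContactNetwork")
}

#' Construct a contact network from an explicit edge list
#' @param nodes Vector of node names.
#' @param edges Two-column matrix/data frame of node names.
#' @param weights Positive integer edge weights (default 1).
#' @param cutoff Cutoff recorded on the network.
#' @return A `ContactNetwork`.
#' @export
contact_network <- function(nodes, edges, weights = NULL, cutoff = NA_real_) {
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- as.character(nodes)
  if (NROW(edges) > 0L) {
    em <- rbind(match(as.character(edges[, 1]), as.character(nodes)),
                match(as.character(edges[, 2]), as.character(nodes)))
    g <- igraph::add_edges(g, em)
    igraph::E(g)$weight <- if (is.null(weights)) rep(1, NROW(edges))
                           else weights
  }
  structure(list(graph = g, cutoff = cutoff), class = "ContactNetwork")
}

#' @export
print.ContactNetwork <- function(x, ...) {
  cat(sprintf("ContactNetwork: %d residues, %d edges (cutoff %.1f A)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$cutoff))
  invisible(x)
}

#' Eigenvector centrality by power iteration
#'
#' Dominant eigenvector of the weighted adjacency matrix, computed by
#' power iteration from an all-ones start vector and scaled to maximum 1.
#' Deterministic by construction.
#'
#' @param adj Square non-negative adjacency matrix.
#' @param tol Convergence tolerance (default 1e-9).
#' @param max_iter Iteration cap (default 1e4).
#' @return Numeric vector with `max` 1 (all zeros for an empty graph).
#' @export
eigen_centrality_power <- function(adj, tol = 1e-9, max_iter = 10000L) {
  n <- nrow(adj)
  if (sum(adj) == 0) return(rep(0, n))
  # shift by sigma*I so the dominant eigenvalue is strictly largest in
  # magnitude (bipartite graphs have lambda_min = -lambda_max, on which
  # unshifted power iteration oscillates); the eigenvectors are unchanged
  sigma <- max(rowSums(adj))
  shifted <- adj + diag(sigma, n)
  v <- rep(1, n)
  for (it in seq_len(max_iter)) {
    w <- as.numeric(shifted %*% v)
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) return(rep(0, n))
    w <- w / nrm
    if (max(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  v / max(v)
}

#' Residue centrality features
#'
#' Four centralities of a residue in the contact network: normalised
#' closeness (reciprocal of the mean shortest-path length to reachable
#' residues, unit edge lengths), betweenness normalised by
#' `(n-1)(n-2)/2`, eigenvector centrality of the weighted adjacency
#' (power iteration, maximum scaled to 1), and weighted degree (sum of
#' incident edge weights). A node with no edges has closeness and
#' betweenness 0. Shortest paths use unit edge lengths by default; set
#' `weighted_paths = TRUE` to use reciprocal-weight edge lengths instead.
#'
#' @param network A `ContactNetwork`.
#' @param pos Residue number (node name); `NULL` returns all residues.
#' @param weighted_paths Use edge weights in path lengths? Default `FALSE`.
#' @return A data frame with columns `residue_number`, `closeness`,
#'   `betweenness`, `eigenvector`, `degree` (one row when `pos` given).
#' @export
centrality_features <- function(network, pos = NULL,
                                weighted_paths = FALSE) {
  g <- network$graph
  nm <- igraph::V(g)$name
  if (!is.null(pos) && !as.character(pos) %in% nm) {
    stop("residue ", pos, " is not a node of the network", call. = FALSE)
  }
  n <- igraph::vcount(g)
  pw <- if (weighted_paths) 1 / igraph::E(g)$weight else NA
  clo <- suppressWarnings(
    igraph::closeness(g, weights = pw, normalized = TRUE, mode = "all"))
  clo[!is.finite(clo)] <- 0
  btw <- if (n > 2L) {
    igraph::betweenness(g, weights = pw, directed = FALSE,
                        normalized = TRUE)
  } else rep(0, n)
  adj <- igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g) > 0L)
    "weight" else NULL, sparse = FALSE)
  eig <- eigen_centrality_power(adj)
  deg <- igraph::strength(g)
  out <- data.frame(residue_number = nm, closeness = as.numeric(clo),
                    betweenness = as.numeric(btw),
                    eigenvector = as.numeric(eig),
                    degree = as.numeric(deg), stringsAsFactors = FALSE)
  if (!is.null(pos)) out <- out[out$residue_number == as.character(pos), ,
                                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a contact network as an edge-list TSV
#' @param network A `ContactNetwork`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_network <- function(network, path) {
  el <- igraph::as_edgelist(network$graph)
  w <- if (igraph::ecount(network$graph) > 0L)
    igraph::E(network$graph)$weight else numeric(0)
  df <- data.frame(i = el[, 1], j = el[, 2], weight = w,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
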