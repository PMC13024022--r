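# Sparsity-thresholded binary graph topology. Weighted matrices are
# proportionally thresholded (keep the strongest fraction of edges),
# binarized, and summarized by global efficiency (Eg), local efficiency
# (Eloc), characteristic path length (Lp), clustering coefficient (Cp),
# degree centrality (Dc) and betweenness centrality (Bc); metric curves
# over a sparsity grid are reduced to a threshold-independent AUC.

#' Proportional threshold of a connectivity matrix
#'
#' Keeps the `ceiling(s * n_pairs)` strongest upper-triangle edges and
#' binarizes. Ties are broken deterministically by lexicographic (i, j)
#' order of the node indices, so equal-weight edges are retained in a
#' fixed, documented order.
#'
#' @param m A `conn_matrix` or symmetric numeric matrix.
#' @param s Sparsity fraction in (0, 1) — fraction of possible edges kept.
#' @return A `thresholded_graph`: list with `adjacency` (binary symmetric,
#'   zero diagonal), `sparsity`, `n_edges`, `band`.
#' @export
threshold_by_sparsity <- function(m, s) {
  if (!(is.numeric(s) && length(s) == 1L && s > 0 && s < 1)) {
    stop("sparsity must lie strictly between 0 and 1", call. = FALSE)
  }
  band <- if (inherits(m, "conn_matrix")) m$band else NA_character_
  w <- if (inherits(m, "conn_matrix")) m$weights else m
  n <- nrow(w)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(-w[idx], idx[, 1], idx[, 2])
  k <- ceiling(s * nrow(idx))
  keep <- idx[ord[seq_len(k)], , drop = FALSE]
  adj <- matrix(0L, n, n, dimnames = dimnames(w))
  adj[keep] <- 1L
  adj <- adj + t(adj)
  structure(list(adjacency = adj, sparsity = s, n_edges = k, band = band),
            class = "thresholded_graph")
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)
}

# Global efficiency of a binary adjacency matrix: mean over ordered node
# pairs of 1/d_ij, disconnected pairs contributing 0.
global_efficiency_adj <- function(adj) {
  n <- nrow(adj)
  if (n < 2L || sum(adj) == 0) return(0)
  d <- igraph::distances(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  )
  inv <- 1 / d[upper.tri(d)]
  mean(ifelse(is.finite(inv), inv, 0))
}

#' Global graph metrics
#'
#' * `Eg` — global efficiency, mean of 1/d over node pairs (disconnected
#'   pairs contribute 0);
#' * `Eloc` — local efficiency, mean over nodes of the global efficiency
#'   of each node's neighborhood subgraph (nodes with fewer than two
#'   neighbors contribute 0);
#' * `Lp` — characteristic path length, mean shortest path over
#'   *connected* pairs (NA when no pair is connected);
#' * `Cp` — mean local clustering coefficient (degree < 2 contributes 0).
#'
#' @param g A `thresholded_graph`.
#' @param lp_scope `"connected-pairs"` (default) or `"largest-component"`
#'   for the Lp average.
#' @return Named numeric vector `c(Eg, Eloc, Lp, Cp)`.
#' @export
global_metrics <- function(g, lp_scope = c("connected-pairs",
                                           "largest-component")) {
  stopifnot(inherits(g, "thresholded_graph"))
  lp_scope <- match.arg(lp_scope)
  adj <- g$adjacency
  n <- nrow(adj)
  if (sum(adj) == 0) {
    return(c(Eg = 0, Eloc = 0, Lp = NA_real_, Cp = 0))
  }
  ig <- as_igraph(g)
  d <- igraph::distances(ig)
  ut <- d[upper.tri(d)]
  eg <- mean(ifelse(is.finite(1 / ut), 1 / ut, 0))
  lp <- if (lp_scope == "connected-pairs") {
    fin <- ut[is.finite(ut)]
    if (length(fin)) mean(fin) else NA_real_
  } else {
    comp <- igraph::components(ig)
    giant <- which(comp$membership == which.max(comp$csize))
    if (length(giant) < 2L) NA_real_ else {
      dg <- d[giant, giant]
      mean(dg[upper.tri(dg)])
    }
  }
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  eloc <- mean(vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency_adj(adj[nb, nb, drop = FALSE])
  }, numeric(1)))
  c(Eg = eg, Eloc = eloc, Lp = lp, Cp = mean(cc))
}

#' Nodal graph metrics
#'
#' Degree centrality (number of incident edges) and betweenness centrality
#' (number of shortest paths passing through the node, with even splitting
#' across tied geodesics).
#'
#' @param g A `thresholded_graph`.
#' @return List with numeric vectors `Dc` and `Bc`, named by node label.
#' @export
nodal_metrics <- function(g) {
  stopifnot(inherits(g, "thresholded_graph"))
  ig <- as_igraph(g)
  dc <- igraph::degree(ig)
  bc <- igraph::betweenness(ig, directed = FALSE)
  labels <- rownames(g$adjacency)
  if (!is.null(labels)) names(dc) <- names(bc) <- labels
  list(Dc = dc, Bc = bc)
}

#' Canonical sparsity grid
#'
#' @return Numeric vector 0.2 to 0.6 in steps of 0.05 (9 thresholds).
#' @export
sparsity_grid <- function() seq(0.2, 0.6, by = 0.05)

#' Area under a metric-vs-sparsity curve
#'
#' Trapezoidal integral of a metric over the sparsity grid; the standard
#' threshold-independent summary of a thresholded-network analysis.
#'
#' @param values Metric values at each grid point (NA allowed nowhere).
#' @param grid Sparsity grid, default [sparsity_grid()].
#' @return Single number.
#' @export
auc_over_sparsity <- function(values, grid = sparsity_grid()) {
  if (length(values) != length(grid) || length(grid) < 2L) {
    stop("values must match the sparsity grid (>= 2 points)", call. = FALSE)
  }
  pracma::trapz(grid, values)
}

#' Metric curves and AUCs over the sparsity grid
#'
#' Thresholds the matrix at every sparsity in `grid`, computes the global
#' and nodal metrics at each, and integrates each metric curve to an AUC.
#'
#' @param m A `conn_matrix` or symmetric matrix.
#' @param grid Sparsity grid, default [sparsity_grid()].
#' @return A `graph_metric_set`: list with `grid`, `global` (grid x metric
#'   matrix), `global_auc` (named vector), `Dc`/`Bc` (grid x node
#'   matrices), `Dc_auc`/`Bc_auc` (per-node vectors). Lp AUC is NA if any
#'   grid point had no connected pair.
#' @export
graph_metric_set <- function(m, grid = sparsity_grid()) {
  globals <- matrix(NA_real_, length(grid), 4,
                    dimnames = list(NULL, c("Eg", "Eloc", "Lp", "Cp")))
  dc <- bc <- NULL
  for (i in seq_along(grid)) {
    g <- threshold_by_sparsity(m, grid[i])
    globals[i, ] <- global_metrics(g)
    nm <- nodal_metrics(g)
    if (is.null(dc)) {
      dc <- matrix(NA_real_, length(grid), length(nm$Dc),
                   dimnames = list(NULL, names(nm$Dc)))
      bc <- dc
    }
    dc[i, ] <- nm$Dc
    bc[i, ] <- nm$Bc
  }
  auc1 <- function(v) if (anyNA(v)) NA_real_ else auc_over_sparsity(v, grid)
  structure(
    list(grid = grid, global = globals,
         global_auc = apply(globals, 2L, auc1),
         Dc = dc, Bc = bc,
         Dc_auc = apply(dc, 2L, auc1), Bc_auc = apply(bc, 2L, auc1)),
    class = "graph_metric_set"
  )
}
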