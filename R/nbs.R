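# Network-based statistic for paired connectivity contrasts.
#
# Edge-wise paired t-tests on post-minus-pre matrices; edges below the
# primary (cluster-forming) threshold are linked into connected
# components; the component statistic is its edge count; the family-wise
# error null distribution is built by sign-flipping each subject's delta
# matrix (the paired-design exchangeability operation) and recording the
# maximal component size per permutation.

# upper-triangle index pairs of an n x n matrix, fixed (i < j) order
ut_pairs <- function(n) which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)

# edge-wise paired t values given delta matrix rows = subjects
edge_t <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  m / sqrt(v / n)
}

# max connected-component edge count among supra-threshold edges
max_component_size <- function(supra, pairs, n_nodes) {
  if (!any(supra)) return(0L)
  e <- pairs[supra, , drop = FALSE]
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_nodes - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  max(tabulate(memb[e[, 1]]))
}

#' Network-based statistic for a paired pre/post contrast
#'
#' @param pre_mats,post_mats Lists of `conn_matrix` objects (or plain
#'   symmetric matrices), one per subject, in matching order; >= 5
#'   subjects.
#' @param primary_alpha Cluster-forming edge-wise threshold (two-sided
#'   paired-t p-value; default 0.01).
#' @param n_perm Number of sign-flip permutations (default 5000; fewer
#'   than 100 triggers a warning).
#' @param seed RNG seed for the permutations.
#' @param alternative `"two.sided"` (default) or `"greater"` (post > pre
#'   enhancement only).
#' @return An `nbs_result`: list with `components` (list of data.frames
#'   region_i/region_j/t per component, largest first), `component_sizes`,
#'   `fwe_p` (per component, `(1 + #\{perm max >= size\})/(n_perm + 1)`),
#'   `edge_t`/`edge_p` matrices, `primary_alpha`, `n_perm`, `seed`.
#' @export
nbs_paired <- function(pre_mats, post_mats, primary_alpha = 0.01,
                       n_perm = 5000, seed = 1L,
                       alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(pre_mats)
  if (n < 5L || length(post_mats) != n) {
    stop("need matched pre/post matrices for at least 5 subjects",
         call. = FALSE)
  }
  if (n_perm < 100) warning("fewer than 100 permutations: FWE p-values are coarse")
  get_w <- function(m) if (inherits(m, "conn_matrix")) m$weights else m
  w1 <- get_w(pre_mats[[1]])
  n_nodes <- nrow(w1)
  labels <- rownames(w1) %||% as.character(seq_len(n_nodes))
  pairs <- ut_pairs(n_nodes)
  D <- t(vapply(seq_len(n), function(i) {
    d <- get_w(post_mats[[i]]) - get_w(pre_mats[[i]])
    d[upper.tri(d)]
  }, numeric(nrow(pairs))))

  df <- n - 1
  tcrit <- if (alternative == "two.sided") {
    stats::qt(1 - primary_alpha / 2, df)
  } else {
    stats::qt(1 - primary_alpha, df)
  }
  tobs <- edge_t(D)
  tobs[!is.finite(tobs)] <- 0
  pobs <- if (alternative == "two.sided") {
    2 * stats::pt(-abs(tobs), df)
  } else {
    stats::pt(tobs, df, lower.tail = FALSE)
  }
  stat_obs <- if (alternative == "two.sided") abs(tobs) else tobs
  supra <- stat_obs > tcrit

  # observed components
  components <- list()
  sizes <- integer(0)
  if (any(supra)) {
    e <- pairs[supra, , drop = FALSE]
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n_nodes - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
    comp_of_edge <- memb[e[, 1]]
    for (cid in unique(comp_of_edge)) {
      sel <- comp_of_edge == cid
      components[[length(components) + 1L]] <- data.frame(
        region_i = labels[e[sel, 1]], region_j = labels[e[sel, 2]],
        t = tobs[supra][sel], stringsAsFactors = FALSE)
      sizes <- c(sizes, sum(sel))
    }
    ord <- order(-sizes)
    components <- components[ord]
    sizes <- sizes[ord]
  }

  perm_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      tp <- edge_t(s * D)
      tp[!is.finite(tp)] <- 0
      sp <- if (alternative == "two.sided") abs(tp) > tcrit else tp > tcrit
      max_component_size(sp, pairs, n_nodes)
    }, integer(1))
  })
  fwe_p <- vapply(sizes, function(sz) {
    (1 + sum(perm_max >= sz)) / (n_perm + 1)
  }, numeric(1))

  tmat <- pmat <- matrix(0, n_nodes, n_nodes, dimnames = list(labels, labels))
  tmat[upper.tri(tmat)] <- tobs
  tmat <- tmat + t(tmat)
  pmat[upper.tri(pmat)] <- pobs
  pmat <- pmat + t(pmat)
  diag(pmat) <- 1

  structure(
    list(components = components, component_sizes = sizes, fwe_p = fwe_p,
         edge_t = tmat, edge_p = pmat, primary_alpha = primary_alpha,
         n_perm = n_perm, seed = seed, alternative = alternative,
         n_subjects = n),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %d subjects, alpha = %g, %d permutations\n",
              x$n_subjects, x$primary_alpha, x$n_perm))
  if (length(x$component_sizes) == 0) {
    cat("  no supra-threshold components\n")
  } else {
    for (i in seq_along(x$component_sizes)) {
      cat(sprintf("  component %d: %d edges, FWE p = %.4f\n", i,
                  x$component_sizes[i], x$fwe_p[i]))
    }
  }
  invisible(x)
}
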