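# Markov Clustering (MCL), implemented from first principles on a dense
# column-stochastic flow matrix. The loop alternates expansion (matrix power),
# inflation (elementwise power + column renormalization), and pruning of small
# entries, until the flow matrix stops changing; clusters are read from the
# attractor structure of the limit matrix.

#' Markov Clustering of a weighted undirected graph
#'
#' @param edges Either a tibble of undirected edges with columns `from`, `to`
#'   and optionally `weight` (default 1), or a symmetric non-negative square
#'   matrix with dimnames.
#' @param inflation Elementwise-power inflation parameter (> 1); larger values
#'   give more, smaller clusters.
#' @param expansion Matrix-power expansion parameter (integer >= 2).
#' @param prune_threshold Entries below this are zeroed after each inflation.
#' @param convergence_tolerance Iteration stops when the largest entrywise
#'   change falls below this.
#' @param max_iterations Iteration cap; hitting it raises a warning and the
#'   current matrix is interpreted as-is (`converged = FALSE`).
#' @param self_loop_weight Weight of the self-loop added to every node before
#'   normalization.
#' @param nodes Optional character vector of node names; nodes without edges
#'   become singleton clusters.
#' @return An object of class `vv_mcl` with elements `membership` (named
#'   integer vector), `clusters` (list of character vectors, ordered by
#'   decreasing size), `n_iterations`, `converged`, and the parameters.
#'   [tidy()] gives a node/cluster tibble, [glance()] a one-row summary, and
#'   [autoplot()] a cluster-size bar chart.
#' @examples
#' g <- tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "a"))
#' mcl(g)$clusters
#' @export
mcl <- function(edges, inflation = 2, expansion = 2L, prune_threshold = 1e-5,
                convergence_tolerance = 1e-6, max_iterations = 100L,
                self_loop_weight = 1, nodes = NULL) {
  stopifnot(inflation > 1, expansion >= 2, prune_threshold > 0,
            max_iterations >= 1)
  if (is.matrix(edges)) {
    A <- edges
    stopifnot(nrow(A) == ncol(A), !is.null(rownames(A)))
    nodes <- union(rownames(A), nodes %||% character(0))
    A <- A[nodes, nodes, drop = FALSE]
  } else {
    edges <- as_tibble(edges)
    stopifnot(all(c("from", "to") %in% names(edges)))
    w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
    if (any(w < 0)) abort("edge weights must be non-negative")
    nodes <- sort(union(union(edges$from, edges$to), nodes %||% character(0)))
    A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(edges))) {
      A[edges$from[i], edges$to[i]] <- max(A[edges$from[i], edges$to[i]], w[i])
      A[edges$to[i], edges$from[i]] <- A[edges$from[i], edges$to[i]]
    }
  }
  if (any(A < 0)) abort("edge weights must be non-negative")
  n <- nrow(A)
  if (n == 0) {
    return(structure(list(membership = integer(0), clusters = list(),
                          n_iterations = 0L, converged = TRUE,
                          params = list(inflation = inflation)),
                     class = "vv_mcl"))
  }
  diag(A) <- diag(A) + self_loop_weight
  normalize_cols <- function(M) {
    cs <- colSums(M)
    zero <- cs == 0
    if (any(zero)) {            # re-seed fully pruned columns on the node itself
      M[cbind(which(zero), which(zero))] <- 1
      cs[zero] <- 1
    }
    sweep(M, 2, cs, "/")
  }
  M <- normalize_cols(A)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- normalize_cols(Mexp^inflation)
    Minf[Minf < prune_threshold] <- 0
    Minf <- normalize_cols(Minf)
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < convergence_tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("MCL did not converge in %d iterations; interpreting current matrix",
                 max_iterations))
  }
  membership <- interpret_mcl(M, nodes)
  clusters <- split(names(membership), membership)
  clusters <- clusters[order(-lengths(clusters),
                             vapply(clusters, min, character(1)))]
  membership <- setNames(rep(seq_along(clusters), lengths(clusters)),
                         unlist(clusters))[nodes]
  structure(list(membership = membership,
                 clusters = unname(lapply(clusters, sort)),
                 n_iterations = iter, converged = converged,
                 params = list(inflation = inflation, expansion = expansion,
                               prune_threshold = prune_threshold,
                               convergence_tolerance = convergence_tolerance,
                               max_iterations = max_iterations,
                               self_loop_weight = self_loop_weight)),
            class = "vv_mcl")
}

# Read a partition off the limit matrix: rows with positive diagonal are
# attractors; attractors seeing each other form one attractor system; a node
# belongs to the systems whose attractors give it positive flow. A node caught
# by several systems joins the one holding the lexicographically smallest
# attractor; a node caught by none (fully pruned) follows its strongest row.
interpret_mcl <- function(M, nodes) {
  n <- length(nodes)
  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0) attractors <- seq_len(n)
  sys_id <- seq_along(attractors)
  for (ai in seq_along(attractors)) {
    for (bi in seq_along(attractors)) {
      if (ai < bi && (M[attractors[ai], attractors[bi]] > 0 ||
                      M[attractors[bi], attractors[ai]] > 0)) {
        old <- sys_id[bi]
        sys_id[sys_id == old] <- sys_id[ai]
      }
    }
  }
  systems <- split(attractors, sys_id)
  # order systems by their smallest attractor label for deterministic tie-breaks
  systems <- systems[order(vapply(systems, function(s) min(nodes[s]), character(1)))]
  membership <- integer(n)
  for (si in seq_along(systems)) {
    support <- which(colSums(M[systems[[si]], , drop = FALSE]) > 0)
    take <- support[membership[support] == 0]
    membership[take] <- si
  }
  if (any(membership == 0)) {
    for (j in which(membership == 0)) {
      best <- which.max(M[, j])
      membership[j] <- if (membership[best] > 0) membership[best] else {
        length(systems) + j   # isolated leftover: own cluster
      }
    }
  }
  setNames(membership, nodes)
}

#' @method tidy vv_mcl
#' @export
tidy.vv_mcl <- function(x, ...) {
  tibble(node = names(x$membership), cluster = unname(x$membership))
}

#' @method glance vv_mcl
#' @export
glance.vv_mcl <- function(x, ...) {
  sizes <- lengths(x$clusters)
  tibble(n_nodes = length(x$membership),
         n_clusters = length(x$clusters),
         n_singletons = sum(sizes == 1),
         largest_cluster = if (length(sizes)) max(sizes) else 0L,
         n_iterations = x$n_iterations,
         converged = x$converged)
}

#' @method autoplot vv_mcl
#' @export
autoplot.vv_mcl <- function(object, ...) {
  df <- tibble(cluster = factor(seq_along(object$clusters)),
               size = lengths(object$clusters))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cluster", y = "members",
                  title = sprintf("MCL clusters (inflation %.2g)",
                                  object$params$inflation)) +
    ggplot2::theme_minimal()
}

#' @export
print.vv_mcl <- function(x, ...) {
  cat(sprintf("MCL clustering: %d nodes, %d clusters (%d singletons), %d iterations%s\n",
              length(x$membership), length(x$clusters),
              sum(lengths(x$clusters) == 1), x$n_iterations,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}
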