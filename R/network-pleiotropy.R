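#' Random walk with restart (personalized PageRank) over an interactome
#'
#' Solves the stationary propagation `s = restart * e + (1 - restart) * W s`
#' by power iteration, where `W` is the column-stochastic adjacency of the
#' undirected gene network and `e` the seed distribution: the seed genes'
#' evidence scores (`-log` adjusted p-values) normalized to sum 1.
#' Scores conserve mass (sum 1) for any restart in (0, 1]; isolated nodes
#' keep their own mass (self-restart) so conservation holds on disconnected
#' graphs. With `restart = 1` the seed vector is returned unchanged.
#'
#' @param network an igraph (undirected, simple).
#' @param seeds either a data.frame with `gene_id` and `p_adj` columns or a
#'   named numeric vector of non-negative evidence scores.
#' @param restart restart probability in (0, 1].
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter iteration cap.
#' @return named score vector over all nodes, summing to 1.
#' @export
rwr <- function(network, seeds, restart = 0.5, tol = 1e-10,
                max_iter = 10000) {
  if (!(restart > 0 && restart <= 1)) stopf("restart must be in (0, 1]")
  e <- seed_vector(network, seeds)
  W <- transition_matrix(network)
  s <- e
  for (it in seq_len(max_iter)) {
    s_new <- restart * e + (1 - restart) * as.vector(W %*% s)
    if (sum(abs(s_new - s)) < tol) {
      s <- s_new
      break
    }
    s <- s_new
  }
  setNames(s, igraph::V(network)$name)
}

seed_vector <- function(network, seeds) {
  nodes <- igraph::V(network)$name
  if (is.data.frame(seeds)) {
    ev <- setNames(-log(seeds$p_adj), seeds$gene_id)
  } else {
    ev <- seeds
  }
  ev <- ev[names(ev) %in% nodes]
  ev <- ev[ev > 0]
  if (length(ev) == 0) stopf("no seed genes present in the network")
  e <- setNames(numeric(length(nodes)), nodes)
  e[names(ev)] <- ev / sum(ev)
  e
}

# column-stochastic transition matrix; isolated nodes get a self-loop
transition_matrix <- function(network) {
  A <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  A <- (A > 0) * 1
  diag(A) <- 0
  deg <- colSums(A)
  iso <- deg == 0
  if (any(iso)) {
    diag(A)[iso] <- 1
    deg[iso] <- 1
  }
  sweep(A, 2, deg, "/")
}

#' Knee point of a descending score curve (Kneedle)
#'
#' Normalizes the curve to the unit square and locates the index
#' maximizing the difference between the descending chord and the curve.
#' A knee is reported only when that maximum exceeds
#' `sensitivity / (n - 1)` (the mean x-spacing scaled by the sensitivity);
#' a straight line therefore yields no knee.
#'
#' @param sorted_scores numeric vector sorted in non-increasing order.
#' @param sensitivity positive sensitivity parameter (default 1).
#' @return the knee index, or `NA_integer_` when the curve has no knee
#'   (callers should fall back to a configured quantile).
#' @export
kneedle_cutoff <- function(sorted_scores, sensitivity = 1) {
  n <- length(sorted_scores)
  if (n < 3) stopf("need at least 3 points")
  if (is.unsorted(rev(sorted_scores))) {
    if (any(diff(sorted_scores) > 1e-12))
      stopf("scores must be sorted in non-increasing order")
  }
  rng <- max(sorted_scores) - min(sorted_scores)
  if (rng == 0) return(NA_integer_)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (sorted_scores - min(sorted_scores)) / rng
  d <- (1 - x) - y
  if (max(d) <= sensitivity / (n - 1)) return(NA_integer_)
  which.max(d)
}

#' Top genes of a propagated score ranking
#'
#' Sorts scores, applies [kneedle_cutoff()] and returns the genes up to the
#' knee; when no knee exists, falls back to the top `fallback_quantile`
#' fraction.
#'
#' @param scores named score vector (e.g. from [rwr()]).
#' @param sensitivity Kneedle sensitivity.
#' @param fallback_quantile fraction kept when the curve has no knee.
#' @export
select_top_genes <- function(scores, sensitivity = 1,
                             fallback_quantile = 0.1) {
  ord <- order(scores, decreasing = TRUE)
  knee <- kneedle_cutoff(scores[ord], sensitivity)
  ntop <- if (is.na(knee)) max(1L, ceiling(fallback_quantile *
                                             length(scores))) else knee
  names(scores)[ord[seq_len(ntop)]]
}

#' Nonoverlapping interactome modules by spectral clustering
#'
#' Normalized-Laplacian spectral embedding (with unit self-loop
#' regularization so isolated nodes are well-defined) followed by k-means
#' on the row-normalized eigenvector matrix. When `n_modules` is NULL it is
#' chosen by the largest eigengap, capped at the square root of the number
#' of nodes.
#'
#' @param subgraph an igraph restricted to the genes of interest.
#' @param n_modules number of modules, or NULL for the eigengap choice.
#' @param seed seed for the embedding k-means.
#' @return a list of character vectors (disjoint gene sets covering the
#'   subgraph), with attributes `membership` and `eigenvalues`.
#' @export
spectral_modules <- function(subgraph, n_modules = NULL, seed = 1) {
  n <- igraph::vcount(subgraph)
  if (n == 0) stopf("empty subgraph")
  if (!is.null(n_modules) && n_modules > n)
    stopf("n_modules cannot exceed the number of nodes")
  nodes <- igraph::V(subgraph)$name
  A <- igraph::as_adjacency_matrix(subgraph, sparse = FALSE)
  A <- (A > 0) * 1
  diag(A) <- 1  # regularization keeps D positive on isolated nodes
  dh <- 1 / sqrt(rowSums(A))
  L <- diag(n) - t(A * dh) * dh
  ev <- eigen(L, symmetric = TRUE)
  lambda <- rev(ev$values)  # ascending
  if (is.null(n_modules)) {
    cap <- max(1L, min(n - 1L, ceiling(sqrt(n))))
    gaps <- diff(lambda)[seq_len(cap)]
    n_modules <- which.max(gaps)
  }
  if (n_modules == 1) {
    membership <- setNames(rep(1L, n), nodes)
  } else {
    U <- ev$vectors[, n:(n - n_modules + 1), drop = FALSE]
    nr <- sqrt(rowSums(U^2))
    nr[nr == 0] <- 1
    U <- U / nr
    km <- with_seed(seed,
                    suppressWarnings(stats::kmeans(U, centers = n_modules,
                                                   nstart = 20,
                                                   iter.max = 100)))
    membership <- setNames(km$cluster, nodes)
  }
  mods <- split(nodes, membership)
  names(mods) <- paste0("module", seq_along(mods))
  structure(mods, membership = membership, eigenvalues = lambda)
}

#' Module-level pleiotropy test against a degree-aware permutation null
#'
#' The statistic of a module is the sum of the propagated target evidence
#' (RWR scores seeded from the target gene scores) over the module's
#' genes. The null redistributes the seed genes' evidence to random nodes
#' within logarithmic (factor-2) degree bins, preserving hubness, and the
#' permutation p-value is `(1 + #(null >= observed)) / (B + 1)`. Because
#' propagation is linear in the seed distribution, the statistic is
#' evaluated through one adjoint propagation per module, so permutations
#' cost one inner product each.
#'
#' @param modules list of gene sets (e.g. from [spectral_modules()]).
#' @param network the full interactome igraph.
#' @param target_seeds target-disease gene scores (data.frame with
#'   `gene_id`, `p_adj`, or a named evidence vector).
#' @param restart restart probability.
#' @param B number of permutations (>= 1).
#' @param seed integer seed.
#' @param tol,max_iter power-iteration controls.
#' @return data.frame (class `module_result`): `module`, `n_genes`,
#'   `statistic`, `p_value`, `n_permutations`.
#' @export
module_pleiotropy_test <- function(modules, network, target_seeds,
                                   restart = 0.5, B = 999, seed = 1,
                                   tol = 1e-12, max_iter = 10000) {
  if (B < 1) stopf("B must be at least 1")
  nodes <- igraph::V(network)$name
  e_obs <- seed_vector(network, target_seeds)
  W <- transition_matrix(network)
  Wt <- t(W)
  deg <- colSums((igraph::as_adjacency_matrix(network, sparse = FALSE) > 0))
  bins <- ifelse(deg == 0, -1L, floor(log2(deg)))
  seed_idx <- which(e_obs > 0)
  ev <- e_obs[seed_idx]

  perms <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      idx <- integer(length(seed_idx))
      for (bn in unique(bins[seed_idx])) {
        mine <- which(bins[seed_idx] == bn)
        pool <- which(bins == bn)
        idx[mine] <- if (length(pool) == 1) pool else
          sample(pool, length(mine))
      }
      idx
    })
  })

  rows <- lapply(seq_along(modules), function(mi) {
    u <- as.numeric(nodes %in% modules[[mi]])
    v <- u
    for (it in seq_len(max_iter)) {
      v_new <- u + (1 - restart) * as.vector(Wt %*% v)
      if (sum(abs(v_new - v)) < tol) {
        v <- v_new
        break
      }
      v <- v_new
    }
    obs <- restart * sum(v * e_obs)
    nulls <- vapply(perms, function(idx) restart * sum(v[idx] * ev),
                    numeric(1))
    data.frame(module = names(modules)[mi] %||% paste0("module", mi),
               n_genes = length(modules[[mi]]),
               statistic = obs,
               p_value = (1 + sum(nulls >= obs)) / (B + 1),
               n_permutations = B)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("module_result", "data.frame")
  out
}
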