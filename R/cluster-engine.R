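#' Aggregate per-cohort relevance tables into cross-cohort scores
#'
#' Weighted mean of the cohort-specific strong-relevance posteriors per
#' (disease, interval) cell, restricted to diseases available in every
#' cohort. Uniform weights by default.
#'
#' @param per_cohort list of [relevance_table()] objects sharing the same
#'   interval grid.
#' @param weights probability vector over cohorts (sums to 1).
#' @return a [relevance_table()] with provenance `"cross-cohort"`.
#' @export
cross_cohort_scores <- function(per_cohort,
                                weights = rep(1 / length(per_cohort),
                                              length(per_cohort))) {
  stopifnot(length(per_cohort) >= 1)
  if (abs(sum(weights) - 1) > 1e-9) stopf("weights must sum to 1")
  ints <- lapply(per_cohort, colnames)
  if (!all(vapply(ints, identical, logical(1), ints[[1]])))
    stopf("cohorts have mismatched interval grids")
  shared <- sort(Reduce(intersect, lapply(per_cohort, rownames)))
  acc <- matrix(0, length(shared), length(ints[[1]]),
                dimnames = list(shared, ints[[1]]))
  for (i in seq_along(per_cohort))
    acc <- acc + weights[i] * unclass(per_cohort[[i]])[shared, , drop = FALSE]
  relevance_table(acc, provenance = "cross-cohort")
}

#' Select diseases strongly relevant in at least one cohort and interval
#'
#' A disease is selected when its posterior strong-relevance probability
#' strictly exceeds `cutoff` in at least one time interval of at least one
#' cohort, restricted to diseases available in every cohort.
#'
#' @param tables list of per-cohort [relevance_table()] objects.
#' @param cutoff selection threshold in (0, 1); the conventional rule is
#'   0.5.
#' @return sorted character vector of selected disease codes.
#' @export
select_diseases <- function(tables, cutoff = 0.5) {
  if (!(cutoff > 0 && cutoff < 1)) stopf("cutoff must be in (0,1)")
  shared <- Reduce(intersect, lapply(tables, rownames))
  hits <- unique(unlist(lapply(tables, function(tb) {
    rownames(tb)[apply(unclass(tb) > cutoff, 1, any)]
  })))
  sort(intersect(hits, shared))
}

#' Weighted multimorbidity scores per participant and interval
#'
#' The trajectory coordinates of every participant: the sum over diseases
#' of the cumulative onset indicator times the disease's per-interval
#' relevance score. Entries are missing (NA) for intervals the participant
#' was not observed through.
#'
#' @param panel an [interval_panel] whose diseases are all present in
#'   `relevance`.
#' @param relevance a [relevance_table()].
#' @return numeric matrix (participants x interval ends) with attribute
#'   `interval_ends`.
#' @export
multimorbidity_scores <- function(panel, relevance) {
  stopifnot(inherits(panel, "interval_panel"))
  missing_d <- setdiff(panel$diseases, rownames(relevance))
  if (length(missing_d) > 0)
    stopf("disease(s) missing from relevance table: %s",
          paste(missing_d, collapse = ", "))
  ends <- panel$grid$interval_ends
  if (!identical(as.numeric(colnames(relevance)), as.numeric(ends)))
    stopf("relevance table intervals do not match the panel grid")
  n <- length(panel$participants)
  S <- matrix(NA_real_, n, length(ends),
              dimnames = list(panel$participants, ends))
  rel <- unclass(relevance)[panel$diseases, , drop = FALSE]
  for (t in seq_along(ends)) {
    M <- panel$indicators[, , t, drop = FALSE]
    dim(M) <- dim(M)[1:2]
    S[, t] <- as.vector(M %*% rel[, t])
  }
  S[!panel$included] <- NA_real_
  attr(S, "interval_ends") <- ends
  S
}

# k-means++ seeding (optionally weighted)
kmeanspp_init <- function(X, k, w = NULL) {
  n <- nrow(X)
  w <- w %||% rep(1, n)
  centres <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1, prob = w)
  centres[1, ] <- X[i, ]
  if (k > 1) {
    d2 <- colSums((t(X) - centres[1, ])^2)
    for (j in 2:k) {
      p <- d2 * w
      if (sum(p) <= 0) p <- w
      i <- sample.int(n, 1, prob = p)
      centres[j, ] <- X[i, ]
      d2 <- pmin(d2, colSums((t(X) - centres[j, ])^2))
    }
  }
  centres
}

# simplified silhouette on (a subsample of) the clustered rows
silhouette_score <- function(X, labels, max_n = 1000) {
  if (length(unique(labels)) < 2) return(NA_real_)
  n <- nrow(X)
  idx <- if (n > max_n) sample.int(n, max_n) else seq_len(n)
  D <- as.matrix(stats::dist(X[idx, , drop = FALSE]))
  lab <- labels[idx]
  s <- vapply(seq_along(idx), function(i) {
    own <- lab == lab[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(D[i, own]) else 0
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(cl) mean(D[i, lab == cl]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Fit the trajectory cluster model
#'
#' k-means over participants with completely observed multimorbidity-score
#' trajectories (observed through the last interval). Initialization is
#' k-means++ with `n_init` restarts; the restart with the lowest total
#' within-cluster sum of squares wins. A simplified mean silhouette score
#' is reported as a fit diagnostic.
#'
#' @param scores matrix from [multimorbidity_scores()].
#' @param k number of clusters (default 7).
#' @param seed integer seed (determines initialization).
#' @param n_init number of k-means++ restarts.
#' @return an object of class `traj_clusters` with `centres` (k x T),
#'   `inertia`, `silhouette`, `n_complete` and a `degenerate` flag (set
#'   when fewer than `k` distinct complete rows exist, in which case the
#'   centres repeat the distinct points).
#' @seealso [assign_clusters()], [predict.traj_clusters()]
#' @export
fit_clusters <- function(scores, k = 7, seed = 1, n_init = 50) {
  X <- scores[stats::complete.cases(scores), , drop = FALSE]
  if (nrow(X) < k)
    stopf("need at least k = %d complete-score participants (got %d)",
          k, nrow(X))
  uni <- unique(X)
  degenerate <- nrow(uni) < k
  if (degenerate) {
    centres <- uni[rep(seq_len(nrow(uni)), length.out = k), , drop = FALSE]
    labels <- apply(X, 1, function(r)
      which.min(colSums((t(centres) - r)^2)))
    inertia <- sum((X - centres[labels, , drop = FALSE])^2)
    sil <- NA_real_
  } else {
    res <- with_seed(seed, {
      best <- NULL
      for (rep_i in seq_len(n_init)) {
        init <- kmeanspp_init(X, k)
        km <- suppressWarnings(
          stats::kmeans(X, centers = init, iter.max = 100))
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      list(best = best, sil = silhouette_score(X, best$cluster))
    })
    centres <- res$best$centers
    inertia <- res$best$tot.withinss
    labels <- res$best$cluster
    sil <- res$sil
  }
  dimnames(centres) <- list(paste0("cluster", seq_len(k)),
                            colnames(scores))
  structure(list(centres = centres, k = as.integer(k), inertia = inertia,
                 silhouette = sil, n_complete = nrow(X),
                 degenerate = degenerate, federated = FALSE,
                 seed = as.integer(seed), call = match.call()),
            class = "traj_clusters")
}

#' @export
print.traj_clusters <- function(x, ...) {
  cat(sprintf("Trajectory cluster model: k = %d over %d intervals%s\n",
              x$k, ncol(x$centres),
              if (x$federated) " (federated fit)" else ""))
  cat(sprintf("fitted on %d complete trajectories; inertia %.4g",
              x$n_complete, x$inertia))
  if (!is.na(x$silhouette))
    cat(sprintf("; mean silhouette %.3f", x$silhouette))
  cat("\n")
  if (x$degenerate) cat("NOTE: degenerate fit (fewer distinct points than k)\n")
  invisible(x)
}

#' @export
summary.traj_clusters <- function(object, ...) {
  print(object)
  cat("\nCluster centres (multimorbidity score by interval end):\n")
  print(round(object$centres, 4))
  invisible(object)
}

#' @export
coef.traj_clusters <- function(object, ...) object$centres

#' @export
plot.traj_clusters <- function(x, ...) {
  ends <- as.numeric(colnames(x$centres))
  graphics::matplot(ends, t(x$centres), type = "b", pch = 19, lty = 1,
                    xlab = "interval end (age, years)",
                    ylab = "multimorbidity score",
                    main = "Cluster centre trajectories", ...)
  graphics::legend("topleft", legend = rownames(x$centres),
                   col = seq_len(x$k), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Soft cluster membership for every participant
#'
#' Distances to the cluster centres give the membership likelihood
#' `exp(-d)`, the posterior (softmax of negative distances) and the
#' posterior log-odds `ln(P / (1 - P))`. Participants with partially
#' observed trajectories are handled with Euclidean distance on the
#' observed coordinates only (no rescaling); the hard label is the
#' posterior argmax with ties broken toward the lowest cluster index.
#'
#' @param scores matrix from [multimorbidity_scores()]; rows may contain
#'   NA for unobserved intervals but not be entirely missing.
#' @param model a fitted `traj_clusters` object.
#' @return a `membership_table` data.frame: `participant_id`,
#'   `likelihood_*`, `posterior_*`, `logodds_*`, `hard_label`, `complete`,
#'   `included` (all TRUE until a confidence filter is applied).
#' @export
assign_clusters <- function(scores, model) {
  stopifnot(inherits(model, "traj_clusters"))
  X <- as.matrix(scores)
  k <- model$k
  n <- nrow(X)
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0))
    stopf("participant(s) with zero observed score coordinates: %s",
          paste(head(rownames(X)[rowSums(obs) == 0], 5), collapse = ", "))
  D <- matrix(0, n, k)
  for (j in seq_len(k)) {
    R2 <- (X - matrix(model$centres[j, ], n, ncol(X), byrow = TRUE))^2
    D[, j] <- sqrt(rowSums(R2, na.rm = TRUE))
  }
  S <- -D
  M <- apply(S, 1, max)
  lse <- M + log(rowSums(exp(S - M)))
  logP <- S - lse
  post <- exp(logP)
  if (k > 1) {
    log1mP <- vapply(seq_len(k), function(j) {
      apply(S[, -j, drop = FALSE], 1, logsumexp) - lse
    }, numeric(n))
    if (n == 1) log1mP <- matrix(log1mP, 1, k)
    logodds <- logP - log1mP
  } else {
    logodds <- matrix(Inf, n, 1)
  }
  hard <- max.col(post, ties.method = "first")
  out <- data.frame(participant_id = rownames(X) %||%
                      as.character(seq_len(n)),
                    stringsAsFactors = FALSE)
  lik <- exp(-D)
  colnames(lik) <- paste0("likelihood_", seq_len(k))
  colnames(post) <- paste0("posterior_", seq_len(k))
  colnames(logodds) <- paste0("logodds_", seq_len(k))
  out <- cbind(out, lik, post, logodds)
  out$hard_label <- hard
  out$complete <- rowSums(obs) == ncol(X)
  out$included <- TRUE
  class(out) <- c("membership_table", "data.frame")
  out
}

#' @rdname assign_clusters
#' @param object,newdata standard predict arguments (`newdata` is a score
#'   matrix).
#' @param ... unused.
#' @export
predict.traj_clusters <- function(object, newdata, ...) {
  assign_clusters(newdata, object)
}

# convenience accessors on membership tables
posterior_matrix <- function(memberships) {
  as.matrix(memberships[, grep("^posterior_", names(memberships)),
                        drop = FALSE])
}

logodds_matrix <- function(memberships) {
  as.matrix(memberships[, grep("^logodds_", names(memberships)),
                        drop = FALSE])
}

#' Confidence filter on uncertain young trajectories
#'
#' Excludes participants who are both under `age_cut` years of age and
#' whose maximum posterior membership probability does not exceed
#' `posterior_cut` for any cluster.
#'
#' @param memberships a `membership_table`.
#' @param ages numeric vector of ages, aligned with the rows.
#' @param age_cut,posterior_cut thresholds (defaults 60 years, 0.25).
#' @return logical inclusion mask (TRUE = retained).
#' @export
confidence_filter <- function(memberships, ages, age_cut = 60,
                              posterior_cut = 0.25) {
  if (length(ages) != nrow(memberships))
    stopf("ages must align with the membership rows")
  maxp <- apply(posterior_matrix(memberships), 1, max)
  !(ages < age_cut & maxp <= posterior_cut)
}

#' Privacy-preserving federated cluster fit from binned score counts
#'
#' Each site reduces its complete score trajectories to counts on a shared
#' quantization lattice (hypercube bins of side `bin_width`); the counts
#' are pooled and a count-weighted k-means (k-means++ seeding, Lloyd
#' iterations) is fitted on the bin midpoints. No individual-level rows
#' cross sites, and sites whose pooled counts match a centralized cohort
#' yield the identical model.
#'
#' @param site_scores list of score matrices, one per site, sharing the
#'   interval grid.
#' @param bin_width lattice resolution in score units.
#' @param k,seed,n_init as in [fit_clusters()].
#' @return a `traj_clusters` object with `federated = TRUE`.
#' @export
federated_fit <- function(site_scores, bin_width, k = 7, seed = 1,
                          n_init = 50) {
  stopifnot(length(site_scores) >= 1, bin_width > 0)
  ends <- lapply(site_scores, function(s)
    attr(s, "interval_ends") %||% colnames(s))
  if (!all(vapply(ends, identical, logical(1), ends[[1]])))
    stopf("sites have incompatible interval grids")
  counts <- new.env(parent = emptyenv())
  for (s in site_scores) {
    X <- s[stats::complete.cases(s), , drop = FALSE]
    if (nrow(X) == 0) next
    idx <- floor(X / bin_width)
    keys <- apply(idx, 1, paste, collapse = ",")
    tab <- table(keys)
    for (kk in names(tab)) {
      counts[[kk]] <- (counts[[kk]] %||% 0) + as.numeric(tab[[kk]])
    }
  }
  keys <- sort(ls(counts))
  if (length(keys) < 1) stopf("no complete trajectories at any site")
  mids <- t(vapply(strsplit(keys, ","), function(v)
    (as.numeric(v) + 0.5) * bin_width, numeric(ncol(site_scores[[1]]))))
  w <- vapply(keys, function(kk) counts[[kk]], numeric(1))
  if (sum(w) < k) stopf("fewer pooled observations than clusters")
  fit <- with_seed(seed, weighted_kmeans(mids, w, k, n_init))
  centres <- fit$centres
  dimnames(centres) <- list(paste0("cluster", seq_len(k)),
                            colnames(site_scores[[1]]))
  structure(list(centres = centres, k = as.integer(k),
                 inertia = fit$inertia, silhouette = NA_real_,
                 n_complete = sum(w), degenerate = fit$degenerate,
                 federated = TRUE, bin_width = bin_width,
                 seed = as.integer(seed), call = match.call()),
            class = "traj_clusters")
}

weighted_kmeans <- function(X, w, k, n_init = 50, max_iter = 100) {
  uni <- unique(X)
  if (nrow(uni) < k) {
    centres <- uni[rep(seq_len(nrow(uni)), length.out = k), , drop = FALSE]
    lab <- apply(X, 1, function(r) which.min(colSums((t(centres) - r)^2)))
    return(list(centres = centres,
                inertia = sum(w * rowSums((X - centres[lab, , drop = FALSE])^2)),
                degenerate = TRUE))
  }
  best <- NULL
  for (rep_i in seq_len(n_init)) {
    centres <- kmeanspp_init(X, k, w)
    lab_old <- rep(0L, nrow(X))
    for (it in seq_len(max_iter)) {
      D <- vapply(seq_len(k), function(j)
        rowSums((X - matrix(centres[j, ], nrow(X), ncol(X),
                            byrow = TRUE))^2), numeric(nrow(X)))
      if (nrow(X) == 1) D <- matrix(D, 1, k)
      lab <- max.col(-D, ties.method = "first")
      if (identical(lab, lab_old)) break
      lab_old <- lab
      for (j in seq_len(k)) {
        sel <- lab == j
        if (any(sel)) {
          centres[j, ] <- colSums(X[sel, , drop = FALSE] * w[sel]) /
            sum(w[sel])
        }
      }
    }
    inertia <- sum(w * D[cbind(seq_len(nrow(X)), lab)])
    if (is.null(best) || inertia < best$inertia)
      best <- list(centres = centres, inertia = inertia, degenerate = FALSE)
  }
  best
}

#' Write a membership table and cluster model to disk
#' @param memberships a `membership_table`; `model` a `traj_clusters`.
#' @param model,path output targets.
#' @export
write_membership_table <- function(memberships, path) {
  write.table(as.data.frame(memberships), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_membership_table
#' @export
write_cluster_model <- function(model, path) {
  jsonlite::write_json(list(k = model$k, centres = model$centres,
                            seed = model$seed,
                            interval_ends = colnames(model$centres)),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
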