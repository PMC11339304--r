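#' BDeu family score (log Dirichlet-multinomial marginal)
#'
#' Log marginal likelihood contribution of one node given its parent set,
#' under the Bayesian Dirichlet equivalent uniform prior with equivalent
#' sample size `ess`: hyperparameters `ess / (q r)` per (parent
#' configuration, child state) cell, where `q` is the number of parent
#' configurations and `r` the child's arity.
#'
#' @param x integer vector of child values coded `0..r-1`.
#' @param parents integer matrix of parent columns (or NULL).
#' @param ess equivalent sample size (> 0).
#' @param arity optional arity vector `c(child, parents...)`; inferred as
#'   `max(value) + 1` (at least 2) when omitted.
#' @return log marginal likelihood (0 for zero data rows).
#' @keywords internal
bdeu_family_score <- function(x, parents = NULL, ess = 1, arity = NULL) {
  if (ess <= 0) stopf("ess must be positive")
  n <- length(x)
  if (n == 0) return(0)  # empty-product marginal: all structures tie
  np <- if (is.null(parents)) 0L else ncol(parents)
  if (is.null(arity)) {
    arity <- c(max(2L, if (n) max(x) + 1L else 2L),
               if (np > 0) pmax(2L, apply(parents, 2, max) + 1L))
  }
  r <- arity[1]
  q <- if (np > 0) prod(arity[-1]) else 1
  idx <- rep(0L, n)
  if (np > 0) {
    for (j in seq_len(np)) idx <- idx * arity[j + 1] + parents[, j]
  }
  cnt <- tabulate(idx * r + x + 1L, nbins = q * r)
  aj <- ess / q
  ajk <- ess / (q * r)
  nj <- colSums(matrix(cnt, nrow = r))
  keep <- nj > 0
  # unobserved parent configurations and cells contribute nothing
  sum(lgamma(aj) - lgamma(aj + nj[keep])) +
    sum(lgamma(ajk + cnt[cnt > 0]) - lgamma(ajk))
}

#' Directed acyclic graph structure
#'
#' @param nodes character vector of variable names.
#' @param parents named list mapping each node to its parent nodes; nodes
#'   omitted from the list have no parents.
#' @param max_parents parent-set size limit.
#' @export
dag_structure <- function(nodes, parents = list(), max_parents = 8) {
  bad <- setdiff(c(names(parents), unlist(parents)), nodes)
  if (length(bad) > 0)
    stopf("unknown nodes in parent sets: %s", paste(bad, collapse = ", "))
  pa <- setNames(vector("list", length(nodes)), nodes)
  for (v in names(parents)) pa[[v]] <- parents[[v]]
  if (any(lengths(pa) > max_parents))
    stopf("a node has more than max_parents = %d parents", max_parents)
  # Kahn's algorithm for acyclicity
  indeg <- lengths(pa)
  remaining <- nodes
  while (length(remaining) > 0) {
    src <- remaining[vapply(remaining, function(v)
      length(intersect(pa[[v]], remaining)) == 0, logical(1))]
    if (length(src) == 0) stopf("parent sets describe a cyclic graph")
    remaining <- setdiff(remaining, src)
  }
  structure(list(nodes = nodes, parents = pa, max_parents = max_parents),
            class = "dag_structure")
}

#' Score a DAG structure against discrete data
#'
#' Sum of BDeu family scores over the nodes; decomposable, so editing one
#' parent set changes exactly one term. Rows with missing values on any
#' node are dropped (complete cases only).
#'
#' @param graph a [dag_structure()].
#' @param data matrix or data.frame with one column per node, integer coded
#'   from 0.
#' @param ess equivalent sample size of the BDeu prior.
#' @return log marginal likelihood of the structure.
#' @export
score_structure <- function(graph, data, ess = 1) {
  stopifnot(inherits(graph, "dag_structure"))
  data <- as.matrix(data)
  if (!all(graph$nodes %in% colnames(data)))
    stopf("data must have a column for every node")
  data <- data[stats::complete.cases(data[, graph$nodes, drop = FALSE]), ,
               drop = FALSE]
  storage.mode(data) <- "integer"
  sum(vapply(graph$nodes, function(v) {
    pa <- graph$parents[[v]]
    bdeu_family_score(data[, v],
                      if (length(pa)) data[, pa, drop = FALSE] else NULL,
                      ess = ess)
  }, numeric(1)))
}

#' Settings for the Metropolis-coupled structure sampler
#'
#' Defaults are sized for production cohorts: a burn-in of 2e6 steps and 1e7
#' collected structure samples, with at most 8 parents per node. The
#' temperature ladder is geometric (ratio 1.5) and always starts at 1 (the
#' cold chain); adjacent chains attempt a state swap every `swap_every`
#' steps. Every `thin`-th cold-chain sample is recorded.
#'
#' @param burn_in,n_samples chain lengths (steps).
#' @param max_parents parent-set size limit (default 8).
#' @param n_chains number of tempered chains.
#' @param temperature_ladder positive temperatures; must include 1.
#' @param ess BDeu equivalent sample size.
#' @param thin record every `thin`-th cold-chain sample.
#' @param swap_every steps between adjacent-chain swap proposals.
#' @param seed integer seed; fully determines the trace.
#' @export
mcmc_settings <- function(burn_in = 2e6, n_samples = 1e7, max_parents = 8,
                          n_chains = 4, temperature_ladder = NULL, ess = 1,
                          thin = 10, swap_every = 100, seed = 1) {
  if (burn_in < 0) stopf("burn_in must be non-negative")
  if (n_samples < 1) stopf("n_samples must be at least 1")
  if (max_parents < 1) stopf("max_parents must be at least 1")
  if (thin < 1) stopf("thin must be at least 1")
  temperature_ladder <- temperature_ladder %||% 1.5^(seq_len(n_chains) - 1)
  if (!any(abs(temperature_ladder - 1) < 1e-12))
    stopf("temperature_ladder must include 1.0")
  if (any(temperature_ladder <= 0)) stopf("temperatures must be positive")
  temperature_ladder <- sort(temperature_ladder)
  structure(list(burn_in = burn_in, n_samples = n_samples,
                 max_parents = as.integer(max_parents),
                 n_chains = length(temperature_ladder),
                 temperature_ladder = temperature_ladder,
                 ess = ess, thin = as.integer(thin),
                 swap_every = as.integer(swap_every),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

# Assemble the per-interval data matrix of the inhomogeneous dynamic BN:
# current-slice disease indicators (target possibly an OR-composite of
# several codes), previous-slice indicators as parent-only nodes, and
# covariates as current-slice nodes. Only participants observed through
# the interval enter.
build_interval_data <- function(panel, target, interval, covariates = NULL) {
  stopifnot(inherits(panel, "interval_panel"))
  T_ <- length(panel$grid$interval_ends)
  if (interval < 1 || interval > T_) stopf("interval out of range")
  if (!all(target %in% panel$diseases))
    stopf("target codes missing from panel: %s",
          paste(setdiff(target, panel$diseases), collapse = ", "))
  rows <- which(panel$included[, interval])
  tname <- paste(target, collapse = "|")
  tcol <- as.integer(
    rowSums(panel$indicators[rows, target, interval, drop = FALSE]) > 0)
  others <- setdiff(panel$diseases, target)
  cur <- panel$indicators[rows, others, interval, drop = FALSE]
  dim(cur) <- dim(cur)[1:2]
  colnames(cur) <- others
  X <- cbind(tcol, cur)
  colnames(X)[1] <- tname
  slice <- rep("current", ncol(X))
  if (!is.null(covariates)) {
    cv <- covariates[match(panel$participants[rows],
                           covariates$participant_id), , drop = FALSE]
    for (v in setdiff(names(cv), "participant_id")) {
      X <- cbind(X, as.integer(factor(cv[[v]])) - 1L)
      colnames(X)[ncol(X)] <- v
      slice <- c(slice, "current")
    }
  }
  if (interval > 1) {
    prevt <- as.integer(rowSums(
      panel$indicators[rows, target, interval - 1, drop = FALSE]) > 0)
    prev <- panel$indicators[rows, others, interval - 1, drop = FALSE]
    dim(prev) <- dim(prev)[1:2]
    prev <- cbind(prevt, prev)
    colnames(prev) <- paste0(c(tname, others), ".prev")
    X <- cbind(X, prev)
    slice <- c(slice, rep("prev", ncol(prev)))
  }
  storage.mode(X) <- "integer"
  list(data = X, slice = slice, target = tname)
}

drop_constant <- function(built, target) {
  keep <- rep(TRUE, ncol(built$data))
  for (j in seq_len(ncol(built$data))) {
    nm <- colnames(built$data)[j]
    if (nm == built$target) next
    if (nrow(built$data) > 0 &&
        length(unique(built$data[, j])) < 2) keep[j] <- FALSE
  }
  dropped <- colnames(built$data)[!keep]
  if (length(dropped) > 0) {
    warning("excluding constant candidate variable(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    built$data <- built$data[, keep, drop = FALSE]
    built$slice <- built$slice[keep]
  }
  built$dropped <- dropped
  built
}

#' Sample structures of the dynamic Bayesian network around a target
#'
#' Runs Metropolis-coupled structure MCMC over the interval's binary
#' disease indicators (plus covariates and the previous interval's
#' indicators as parent-only nodes) and records, for every retained
#' cold-chain structure, the strong-relevance indicator of each candidate
#' variable with respect to the target: a direct edge in either direction
#' or a common child. Only participants with complete onset information
#' through the interval contribute.
#'
#' @param panel an [interval_panel].
#' @param target disease code(s); several codes form a single OR-composite
#'   target variable.
#' @param interval index into the time grid.
#' @param covariates optional data.frame (`participant_id` plus variables)
#'   entering as current-slice nodes.
#' @param settings an [mcmc_settings()] object.
#' @return object of class `structure_trace` with elements `indicators`
#'   (samples x candidates binary matrix), `log_score`, `accept_rate`,
#'   `swap_rate`, `variables` and `dropped`.
#' @export
mcmc_sample <- function(panel, target, interval, covariates = NULL,
                        settings = mcmc_settings()) {
  stopifnot(inherits(settings, "mcmc_settings"))
  built <- drop_constant(build_interval_data(panel, target, interval,
                                             covariates), target)
  X <- built$data
  if (ncol(X) > 32) stopf("at most 32 variables are supported (got %d)",
                          ncol(X))
  ty <- match(built$target, colnames(X))
  arity <- pmax(2L, apply(X, 2, function(v) if (length(v)) max(v) + 1L else 2L))
  if (nrow(X) == 0) arity <- rep(2L, ncol(X))
  res <- mc3_structure_sample(
    X, as.integer(arity), ty - 1L, built$slice == "prev",
    settings$ess, settings$max_parents, settings$temperature_ladder,
    settings$burn_in, settings$n_samples, settings$thin,
    settings$swap_every, settings$seed)
  ind <- res$indicators
  colnames(ind) <- colnames(X)[res$candidates]
  structure(list(indicators = ind,
                 log_score = res$log_score,
                 accept_rate = res$accept_rate,
                 swap_rate = res$swap_rate,
                 variables = data.frame(name = colnames(X),
                                        slice = built$slice,
                                        stringsAsFactors = FALSE),
                 target = built$target, interval = interval,
                 dropped = built$dropped,
                 settings = settings),
            class = "structure_trace")
}

#' @export
print.structure_trace <- function(x, ...) {
  cat(sprintf(
    "Structure trace: %d samples x %d candidates (target %s, interval %d)\n",
    nrow(x$indicators), ncol(x$indicators), x$target, x$interval))
  cat(sprintf("acceptance %.3f, swap acceptance %.3f\n",
              x$accept_rate, x$swap_rate))
  invisible(x)
}

#' Posterior probability of strong relevance from a structure trace
#'
#' Mean of the per-sample Markov-boundary indicator over the cold chain.
#'
#' @param trace a `structure_trace`.
#' @return named numeric vector in `[0, 1]`, one entry per candidate.
#' @export
strong_relevance_posterior <- function(trace) {
  stopifnot(inherits(trace, "structure_trace"))
  if (nrow(trace$indicators) == 0) stopf("empty trace")
  colMeans(trace$indicators)
}

#' Geweke convergence diagnostic of the relevance indicators
#'
#' Compares the indicator mean over the first `first_frac` of the trace
#' with the mean over the last `last_frac`, standardized by
#' spectral-density estimates of the asymptotic variance (AR-model estimate
#' at frequency zero). A candidate is flagged converged when |z| <= 2; a
#' completely constant trace is defined as z = 0 (converged).
#'
#' @param trace a `structure_trace`.
#' @param first_frac,last_frac segment fractions (Geweke's 0.1 and 0.5).
#' @return named z-score vector with attribute `converged`.
#' @export
geweke_diagnostic <- function(trace, first_frac = 0.1, last_frac = 0.5) {
  stopifnot(inherits(trace, "structure_trace"))
  N <- nrow(trace$indicators)
  if (N < 100) stopf("trace must have at least 100 samples")
  z <- apply(trace$indicators, 2, function(x) {
    a <- x[seq_len(floor(first_frac * N))]
    b <- x[(N - floor(last_frac * N) + 1):N]
    if (var(x) == 0) return(0)
    s2 <- spectrum0(a) / length(a) + spectrum0(b) / length(b)
    dm <- mean(a) - mean(b)
    if (s2 == 0) return(ifelse(dm == 0, 0, sign(dm) * Inf))
    dm / sqrt(s2)
  })
  z <- setNames(as.numeric(z), colnames(trace$indicators))
  attr(z, "converged") <- abs(z) <= 2
  z
}

# AR-based spectral density estimate at frequency zero
spectrum0 <- function(x) {
  v <- var(x)
  if (!is.finite(v) || v == 0) return(0)
  ord <- max(1, min(floor(10 * log10(length(x))), length(x) - 1))
  fit <- try(ar(x, aic = TRUE, order.max = ord), silent = TRUE)
  if (inherits(fit, "try-error")) return(v)
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Exact strong-relevance posterior by DAG enumeration
#'
#' Brute-force oracle for small instances: enumerates every DAG over the
#' current-slice variables (at most 5, including the target), sums over
#' previous-slice parent subsets analytically per family, and weights the
#' strong-relevance indicator by the normalized exponentiated BDeu score
#' under a uniform structure prior -- the same score, prior and constraints
#' as the sampler.
#'
#' @inheritParams mcmc_sample
#' @param ess BDeu equivalent sample size.
#' @param max_parents parent-set size limit.
#' @return named posterior vector over the candidate variables.
#' @export
exact_relevance_posterior <- function(panel, target, interval,
                                      covariates = NULL, ess = 1,
                                      max_parents = 8) {
  built <- build_interval_data(panel, target, interval, covariates)
  X <- built$data
  cur <- which(built$slice == "current")
  prev <- which(built$slice == "prev")
  m <- length(cur)
  P <- length(prev)
  if (m > 5)
    stopf("exact enumeration supports at most 5 current-slice variables (got %d)", m)
  if (P > 5)
    stopf("exact enumeration supports at most 5 previous-slice variables (got %d)", P)
  arity <- pmax(2L, apply(X, 2, function(v) if (length(v)) max(v) + 1L else 2L))
  if (nrow(X) == 0) arity <- rep(2L, ncol(X))
  ty <- match(built$target, colnames(X))  # position within cur (first col)
  tpos <- match(ty, cur)

  fam <- function(child_col, parent_cols) {
    bdeu_family_score(X[, child_col],
                      if (length(parent_cols)) X[, parent_cols, drop = FALSE]
                      else NULL,
                      ess = ess, arity = c(arity[child_col],
                                           arity[parent_cols]))
  }

  n_sub_prev <- 2^P
  prev_masks <- 0:(n_sub_prev - 1)
  prev_size <- vapply(prev_masks, function(s) {
    cnt <- 0L
    while (s > 0) {
      cnt <- cnt + s %% 2L
      s <- s %/% 2L
    }
    cnt
  }, integer(1))
  # per current node v and current-parent mask pc: log-marginals summed over
  # admissible prev subsets, and the same excluding each prev variable
  n_mask_cur <- 2^m
  Tlse <- vector("list", m)
  Texcl <- vector("list", m)
  for (vi in seq_len(m)) {
    Tlse[[vi]] <- rep(NA_real_, n_mask_cur)
    Texcl[[vi]] <- matrix(NA_real_, n_mask_cur, max(P, 1))
    for (pc in 0:(n_mask_cur - 1)) {
      if (bitwAnd(pc, bitwShiftL(1L, vi - 1L)) > 0) next
      pc_idx <- cur[which(bitwAnd(pc, 2^(seq_len(m) - 1)) > 0)]
      if (length(pc_idx) > max_parents) next
      ok <- which(length(pc_idx) + prev_size <= max_parents)
      vals <- vapply(prev_masks[ok], function(s) {
        s_idx <- prev[which(bitwAnd(s, 2^(seq_len(max(P, 1)) - 1)) > 0)]
        fam(cur[vi], c(pc_idx, s_idx))
      }, numeric(1))
      Tlse[[vi]][pc + 1] <- logsumexp(vals)
      if (P > 0) {
        for (x in seq_len(P)) {
          sel <- bitwAnd(prev_masks[ok], bitwShiftL(1L, x - 1L)) == 0
          Texcl[[vi]][pc + 1, x] <- logsumexp(vals[sel])
        }
      }
    }
  }

  # enumerate DAGs over the current slice
  pairs <- if (m >= 2) utils::combn(m, 2) else matrix(0, 2, 0)
  npair <- ncol(pairs)
  n_states <- 3^npair
  cand_cur <- setdiff(seq_len(m), tpos)
  logw <- numeric(0)
  ind_cur <- NULL
  lognot_prev <- NULL
  logw_list <- vector("list", 0)
  acc_ind <- list()
  acc_not <- list()
  for (st in 0:(n_states - 1)) {
    A <- matrix(FALSE, m, m)
    s <- st
    ok <- TRUE
    for (pr in seq_len(npair)) {
      dg <- s %% 3
      s <- s %/% 3
      if (dg == 1) A[pairs[1, pr], pairs[2, pr]] <- TRUE
      if (dg == 2) A[pairs[2, pr], pairs[1, pr]] <- TRUE
    }
    # acyclicity via Kahn elimination
    Ak <- A
    alive <- rep(TRUE, m)
    repeat {
      srcs <- which(alive & colSums(Ak[alive, , drop = FALSE]) == 0)
      srcs <- srcs[alive[srcs]]
      if (length(srcs) == 0) break
      alive[srcs] <- FALSE
      Ak[srcs, ] <- FALSE
    }
    if (any(alive)) next
    pa_mask <- vapply(seq_len(m), function(v)
      sum(2^(which(A[, v]) - 1)), numeric(1))
    if (any(vapply(seq_len(m), function(v) sum(A[, v]), numeric(1)) >
            max_parents)) next
    lw <- sum(vapply(seq_len(m), function(v) Tlse[[v]][pa_mask[v] + 1],
                     numeric(1)))
    if (!is.finite(lw)) next
    # indicator per current candidate
    ic <- vapply(cand_cur, function(x)
      A[x, tpos] || A[tpos, x] || any(A[x, ] & A[tpos, ]), logical(1))
    # log P(not strongly relevant | DAG) per prev candidate
    ln <- if (P > 0) {
      fams <- c(tpos, which(A[tpos, ]))
      vapply(seq_len(P), function(x)
        sum(vapply(fams, function(v)
          Texcl[[v]][pa_mask[v] + 1, x] - Tlse[[v]][pa_mask[v] + 1],
          numeric(1))), numeric(1))
    } else numeric(0)
    logw <- c(logw, lw)
    acc_ind[[length(acc_ind) + 1]] <- ic
    acc_not[[length(acc_not) + 1]] <- ln
  }
  lz <- logsumexp(logw)
  w <- exp(logw - lz)
  ind_mat <- do.call(rbind, acc_ind)
  post_cur <- if (length(cand_cur))
    colSums(w * ind_mat) else numeric(0)
  post_prev <- if (P > 0) {
    notmat <- exp(do.call(rbind, acc_not))
    1 - colSums(w * notmat)
  } else numeric(0)
  out <- c(setNames(post_cur, colnames(X)[cur[cand_cur]]),
           setNames(post_prev, colnames(X)[prev]))
  out
}

#' Relevance table: per-disease, per-interval strong-relevance posteriors
#'
#' @param mat numeric matrix, diseases x intervals, entries in `[0, 1]`.
#' @param provenance cohort label or `"cross-cohort"`.
#' @export
relevance_table <- function(mat, provenance = "cohort") {
  mat <- as.matrix(mat)
  if (any(mat < 0 | mat > 1, na.rm = TRUE))
    stopf("relevance scores must lie in [0, 1]")
  structure(mat, provenance = provenance,
            class = c("relevance_table", class(mat)))
}

#' @export
print.relevance_table <- function(x, ...) {
  cat(sprintf("Relevance table (%s): %d diseases x %d intervals\n",
              attr(x, "provenance"), nrow(x), ncol(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Estimate strong-relevance scores across all intervals
#'
#' Convenience driver: one MCMC run per cumulative interval, collecting the
#' posterior strong-relevance probability of every current-slice disease
#' with respect to the target.
#'
#' @inheritParams mcmc_sample
#' @param provenance cohort label stored on the result.
#' @return a [relevance_table()] (diseases x interval ends) with attributes
#'   `geweke` (z-score matrix) and `accept_rate`.
#' @export
relevance_scores <- function(panel, target, covariates = NULL,
                             settings = mcmc_settings(),
                             provenance = "cohort") {
  ends <- panel$grid$interval_ends
  others <- setdiff(panel$diseases, target)
  mat <- matrix(NA_real_, length(others), length(ends),
                dimnames = list(others, ends))
  gw <- matrix(NA_real_, length(others), length(ends),
               dimnames = list(others, ends))
  acc <- numeric(length(ends))
  for (t in seq_along(ends)) {
    tr <- mcmc_sample(panel, target, t, covariates, settings)
    post <- strong_relevance_posterior(tr)
    z <- geweke_diagnostic(tr)
    hit <- intersect(others, names(post))
    mat[hit, t] <- post[hit]
    gw[hit, t] <- z[hit]
    acc[t] <- tr$accept_rate
  }
  mat[is.na(mat)] <- 0  # constant (never-onset) diseases carry no relevance
  out <- relevance_table(mat, provenance = provenance)
  attr(out, "geweke") <- gw
  attr(out, "accept_rate") <- acc
  out
}

#' Write a relevance table as long-format TSV
#' @param x a [relevance_table()].
#' @param path output file.
#' @export
write_relevance_table <- function(x, path) {
  long <- data.frame(
    disease = rep(rownames(x), times = ncol(x)),
    interval_end = rep(colnames(x), each = nrow(x)),
    posterior = as.vector(unclass(x)),
    cohort = attr(x, "provenance") %||% "cohort",
    stringsAsFactors = FALSE)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
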