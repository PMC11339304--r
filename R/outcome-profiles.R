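#' Posterior-weighted Cox model of disease risk in a cluster
#'
#' The duplicated-row design: every participant enters twice, once with the
#' cluster-membership dummy set to 1 and case weight equal to the posterior
#' membership probability, once with the dummy 0 and weight one minus that
#' probability (the two weights sum to 1). The time axis is age; a
#' participant is right-censored at the censoring age when the disease was
#' not diagnosed. Ties use the Efron approximation; confidence intervals
#' are Wald on the log-hazard scale (optionally with robust standard
#' errors).
#'
#' @param memberships a `membership_table` aligned by `participant_id`.
#' @param cohort a [cohort_table()].
#' @param disease target disease code.
#' @param cluster cluster index whose posterior supplies the weights.
#' @param covariates covariate column names from the cohort's covariate
#'   table; `birth_year` is standardized to a `norm_birth_year` term.
#' @param robust use robust (sandwich) standard errors?
#' @return one-row data.frame (class `hazard_result`): `cluster`,
#'   `disease`, `hr`, `ci_lower`, `ci_upper`, `p_value`, `p_adjusted`
#'   (NA until [adjust_bh()]), `n_effective`, `n_events`.
#' @export
weighted_cox <- function(memberships, cohort, disease, cluster,
                         covariates = c("sex", "income", "birth_year"),
                         robust = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  keep <- memberships$included
  ids <- memberships$participant_id[keep]
  p <- posterior_matrix(memberships)[keep, cluster]
  if (any(!is.finite(p))) stopf("non-finite membership weights")
  cov <- cohort$covariates[match(ids, cohort$covariates$participant_id), ,
                           drop = FALSE]
  on <- cohort$onsets[cohort$onsets$icd10_code == disease, , drop = FALSE]
  age <- on$onset_age[match(ids, on$participant_id)]
  status <- as.integer(!is.na(age))
  time <- ifelse(status == 1, age, cov$censor_age)
  if (sum(status) == 0) stopf("no events for disease %s", disease)

  base <- data.frame(time = time, status = status)
  for (v in covariates) {
    if (!v %in% names(cov)) stopf("covariate %s missing from cohort", v)
    x <- cov[[v]]
    if (v == "birth_year") {
      base$norm_birth_year <- as.numeric(scale(x))
    } else if (is.numeric(x)) {
      base[[v]] <- x
    } else {
      base[[v]] <- factor(x)
    }
  }
  dup <- rbind(cbind(base, dummy = 1, w = p),
               cbind(base, dummy = 0, w = 1 - p))
  dup <- dup[dup$w > 1e-12, , drop = FALSE]
  rhs <- paste(c("dummy", setdiff(names(base), c("time", "status"))),
               collapse = " + ")
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(time, status) ~", rhs)),
    data = dup, weights = dup$w, ties = "efron", robust = robust)
  est <- coef(fit)["dummy"]
  se <- sqrt(diag(fit$var))[1]  # dummy is the first model term
  z <- est / se
  res <- data.frame(cluster = cluster, disease = disease,
                    hr = exp(est),
                    ci_lower = exp(est - 1.959964 * se),
                    ci_upper = exp(est + 1.959964 * se),
                    p_value = 2 * stats::pnorm(-abs(z)),
                    p_adjusted = NA_real_,
                    n_effective = sum(p),
                    n_events = sum(status),
                    row.names = NULL)
  class(res) <- c("hazard_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment within cohorts
#'
#' Step-up false-discovery-rate adjustment of the hazard-model p-values,
#' applied separately within each level of `grouping` (typically the
#' cohort); with no grouping column all rows form one family.
#'
#' @param results data.frame with a `p_value` column (e.g. stacked
#'   [weighted_cox()] rows).
#' @param grouping optional column name defining adjustment families.
#' @return `results` with `p_adjusted` filled in.
#' @export
adjust_bh <- function(results, grouping = NULL) {
  stopifnot(is.data.frame(results), "p_value" %in% names(results))
  if (any(results$p_value < 0 | results$p_value > 1))
    stopf("p-values must lie in [0, 1]")
  if (is.null(grouping) || !grouping %in% names(results)) {
    results$p_adjusted <- p.adjust(results$p_value, method = "BH")
  } else {
    results$p_adjusted <- ave(results$p_value, results[[grouping]],
                              FUN = function(p) p.adjust(p, method = "BH"))
  }
  results
}

#' Posterior-weighted Kaplan-Meier curve of disease-free survival
#'
#' Product-limit estimator in which every participant's contribution to
#' the risk set and event count is weighted by the posterior probability
#' of belonging to the cluster. Invariant to a uniform rescaling of the
#' weights.
#'
#' @inheritParams weighted_cox
#' @return data.frame with `age` and `surv`, starting at `S(0) = 1`.
#' @export
weighted_km <- function(memberships, cohort, disease, cluster) {
  stopifnot(inherits(cohort, "cohort_table"))
  keep <- memberships$included
  ids <- memberships$participant_id[keep]
  w <- posterior_matrix(memberships)[keep, cluster]
  if (sum(w) <= 0) stopf("total weight is zero")
  cov <- cohort$covariates[match(ids, cohort$covariates$participant_id), ,
                           drop = FALSE]
  on <- cohort$onsets[cohort$onsets$icd10_code == disease, , drop = FALSE]
  age <- on$onset_age[match(ids, on$participant_id)]
  status <- as.integer(!is.na(age))
  time <- ifelse(status == 1, age, cov$censor_age)
  sel <- w > 1e-12  # negligible weights leave the risk set entirely
  fit <- survival::survfit(survival::Surv(time, status) ~ 1,
                           data = data.frame(time = time,
                                             status = status)[sel, ],
                           weights = w[sel])
  data.frame(age = c(0, fit$time), surv = c(1, fit$surv))
}

# standardized-Euclidean k-nearest-neighbour imputation on numeric columns
knn_impute <- function(X, k = 5) {
  X <- as.matrix(X)
  mu <- colMeans(X, na.rm = TRUE)
  sdv <- apply(X, 2, sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  out <- Z
  miss <- which(is.na(Z), arr.ind = TRUE)
  for (r in unique(miss[, 1])) {
    obs_j <- which(!is.na(Z[r, ]))
    d <- rowMeans((Z[, obs_j, drop = FALSE] -
                     matrix(Z[r, obs_j], nrow(Z), length(obs_j),
                            byrow = TRUE))^2, na.rm = TRUE)
    d[r] <- Inf
    for (j in which(is.na(Z[r, ]))) {
      cand <- which(!is.na(Z[, j]) & is.finite(d))
      if (length(cand) == 0) {
        out[r, j] <- 0  # column standardized mean
      } else {
        nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
        out[r, j] <- mean(Z[nb, j])
      }
    }
  }
  sweep(sweep(out, 2, sdv, "*"), 2, mu, "+")
}

#' Risk-factor regressions on posterior log-odds of cluster membership
#'
#' For every cluster, the standardized posterior log-odds is regressed on
#' behavioural and physiological factors. `mode = "simple"` fits one factor
#' at a time with a nonlinear age term (cubic B-spline with knots at 40
#' and 60 years, falling back to the knots inside the observed age span)
#' and sex as covariates, on complete cases for that factor.
#' `mode = "complex"` fits all factors jointly after k-nearest-neighbour
#' imputation of missing factor values. Continuous predictors and the
#' outcome are standardized; significance is by two-sided t-tests with
#' Bonferroni correction over all factor-by-cluster tests of the call.
#'
#' @param memberships a `membership_table`.
#' @param factors data.frame with `participant_id`, `age`, `sex` and one
#'   column per risk factor.
#' @param mode `"simple"` or `"complex"`.
#' @param knots interior spline knots for the age term (years).
#' @param k_impute neighbours for the complex-mode imputation.
#' @param clusters cluster indices to profile (default all).
#' @return data.frame (class `riskfactor_result`): `cluster`, `factor`,
#'   `estimate`, `se`, `p_value`, `p_adjusted`, `model`.
#' @export
riskfactor_regression <- function(memberships, factors,
                                  mode = c("simple", "complex"),
                                  knots = c(40, 60), k_impute = 5,
                                  clusters = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("participant_id", "age", "sex") %in% names(factors)))
  lo <- logodds_matrix(memberships)
  k <- ncol(lo)
  clusters <- clusters %||% seq_len(k)
  fac <- factors[match(memberships$participant_id,
                       factors$participant_id), , drop = FALSE]
  fnames <- setdiff(names(fac), c("participant_id", "age", "sex"))
  age <- fac$age
  sex <- fac$sex
  usable_knots <- knots[knots > min(age, na.rm = TRUE) &
                          knots < max(age, na.rm = TRUE)]
  spl <- if (length(usable_knots) > 0)
    splines::bs(age, knots = usable_knots, degree = 3)
  else splines::bs(age, degree = 3)

  std <- function(x) {
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(NULL)
    (x - mean(x, na.rm = TRUE)) / s
  }
  Xf <- list()
  skipped <- character(0)
  for (f in fnames) {
    z <- std(fac[[f]])
    if (is.null(z)) {
      skipped <- c(skipped, f)
    } else {
      Xf[[f]] <- z
    }
  }
  if (length(skipped) > 0)
    warning("skipping zero-variance factor(s): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  fnames <- names(Xf)
  if (length(fnames) == 0) stopf("no usable risk factors")

  rows <- list()
  if (mode == "simple") {
    for (j in clusters) {
      y <- std(lo[, j])
      for (f in fnames) {
        x <- Xf[[f]]
        cc <- complete.cases(y, x, age, sex)
        fit <- lm(y[cc] ~ x[cc] + spl[cc, , drop = FALSE] + sex[cc])
        sm <- summary(fit)$coefficients
        rows[[length(rows) + 1]] <- data.frame(
          cluster = j, factor = f, estimate = sm["x[cc]", 1],
          se = sm["x[cc]", 2], p_value = sm["x[cc]", 4], model = "simple")
      }
    }
  } else {
    Xmat <- do.call(cbind, Xf)
    Xmat <- knn_impute(Xmat, k = k_impute)
    colnames(Xmat) <- fnames
    for (j in clusters) {
      y <- std(lo[, j])
      cc <- complete.cases(y, age, sex)
      Z <- cbind(Xmat[cc, , drop = FALSE], spl[cc, , drop = FALSE],
                 sexcov = sex[cc])
      fit <- lm(y[cc] ~ Z)
      sm <- summary(fit)$coefficients
      for (f in fnames) {
        rn <- paste0("Z", f)
        rows[[length(rows) + 1]] <- data.frame(
          cluster = j, factor = f, estimate = sm[rn, 1],
          se = sm[rn, 2], p_value = sm[rn, 4], model = "complex")
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  class(out) <- c("riskfactor_result", "data.frame")
  out
}
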