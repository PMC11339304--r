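# two-cluster cohort with a planted hazard-ratio contrast for one disease
cox_fixture <- function(n = 2000, hr = 2, seed = 1, soft = FALSE) {
  dset <- list(codes = "D06",
               baseline = matrix(0.004, 1, 5, dimnames = list("D06", NULL)),
               multiplier = matrix(c(hr, 1), 1, 2,
                                   dimnames = list("D06", NULL)))
  cfg <- synthetic_config(n, n_clusters = 2, diseases = dset,
                          direct_parents = "D06",
                          mediated_diseases = character(0),
                          mediator = "D06", effect_direct = 0,
                          cluster_mixture = c(0.5, 0.5),
                          covariate_effects = c(sex = 0, income_medium = 0,
                                                income_high = 0),
                          seed = seed)
  g <- generate_cohort(cfg)
  p1 <- as.numeric(g$truth$cluster == 1)
  if (soft) p1 <- pmin(pmax(p1, 0.5), 0.5)
  mem <- fake_memberships(cbind(p1, 1 - p1),
                          ids = g$cohort$covariates$participant_id)
  list(g = g, mem = mem)
}

test_that("degenerate 0/1 posteriors reproduce the hard-label Cox fit", {
  fx <- cox_fixture(n = 2000, hr = 2, seed = 5)
  res <- weighted_cox(fx$mem, fx$g$cohort, "D06", cluster = 1,
                      covariates = character(0))
  # reference: plain unweighted Cox on the hard split
  cov <- fx$g$cohort$covariates
  on <- fx$g$cohort$onsets[fx$g$cohort$onsets$icd10_code == "D06", ]
  age <- on$onset_age[match(cov$participant_id, on$participant_id)]
  d <- data.frame(time = ifelse(is.na(age), cov$censor_age, age),
                  status = as.integer(!is.na(age)),
                  grp = as.numeric(fx$g$truth$cluster == 1))
  ref <- survival::coxph(survival::Surv(time, status) ~ grp, data = d,
                         ties = "efron")
  expect_equal(log(res$hr), unname(coef(ref)), tolerance = 1e-8)
  expect_true(res$ci_lower < res$hr && res$hr < res$ci_upper)
  expect_gt(res$n_events, 0)
})

test_that("uninformative 0.5 posteriors give HR = 1", {
  fx <- cox_fixture(n = 800, hr = 2, seed = 6, soft = TRUE)
  res <- weighted_cox(fx$mem, fx$g$cohort, "D06", cluster = 1,
                      covariates = character(0))
  expect_equal(log(res$hr), 0, tolerance = 1e-8)
})

test_that("weighted Cox validates its inputs", {
  fx <- cox_fixture(n = 200, hr = 1, seed = 7)
  expect_error(weighted_cox(fx$mem, fx$g$cohort, "NOPE", 1,
                            covariates = character(0)), "no events")
})

test_that("BH adjustment follows the step-up arithmetic within groups", {
  res <- data.frame(p_value = c(0.01, 0.02, 0.03))
  adj <- adjust_bh(res)
  expect_equal(adj$p_adjusted, c(0.03, 0.03, 0.03))

  one <- adjust_bh(data.frame(p_value = 0.04))
  expect_equal(one$p_adjusted, 0.04)

  set.seed(1)
  p <- runif(20)
  a1 <- adjust_bh(data.frame(p_value = p))$p_adjusted
  ord <- sample(20)
  a2 <- adjust_bh(data.frame(p_value = p[ord]))$p_adjusted
  expect_equal(a2, a1[ord])  # permutation invariance

  grp <- data.frame(p_value = c(0.01, 0.04, 0.01, 0.04),
                    cohort = c("u", "u", "v", "v"))
  ag <- adjust_bh(grp, grouping = "cohort")
  expect_equal(ag$p_adjusted, c(0.02, 0.04, 0.02, 0.04))
  expect_true(all(ag$p_adjusted >= ag$p_value))
})

test_that("weighted Kaplan-Meier matches the hand product-limit", {
  onsets <- data.frame(participant_id = c("a", "b", "c", "d"),
                       icd10_code = "F32",
                       onset_age = c(50, 60, 70, 80))
  cov <- data.frame(participant_id = c("a", "b", "c", "d"),
                    censor_age = rep(85, 4))
  ct <- cohort_table(onsets, cov)
  mem <- fake_memberships(cbind(rep(1, 4), rep(0, 4)),
                          ids = c("a", "b", "c", "d"))
  km <- weighted_km(mem, ct, "F32", cluster = 1)
  expect_equal(km$surv[km$age == 0], 1)
  expect_equal(km$surv[km$age == 50], 0.75)
  expect_equal(km$surv[km$age == 60], 0.50)
  expect_equal(km$surv[km$age == 70], 0.25)
  expect_true(all(diff(km$surv) <= 0))

  # uniform rescaling of the weights leaves the curve unchanged
  mem_half <- fake_memberships(cbind(rep(0.5, 4), rep(0.5, 4)),
                               ids = c("a", "b", "c", "d"))
  km2 <- weighted_km(mem_half, ct, "F32", cluster = 1)
  expect_equal(km2$surv, km$surv)

  mem0 <- fake_memberships(cbind(rep(0, 4), rep(1, 4)),
                           ids = c("a", "b", "c", "d"))
  mem0$posterior_1 <- 0
  expect_error(weighted_km(mem0, ct, "F32", 1), "zero")
})

test_that("weighted KM agrees with the standard estimator at unit weights", {
  fx <- cox_fixture(n = 300, hr = 2, seed = 8)
  km <- weighted_km(fx$mem, fx$g$cohort, "D06", cluster = 1)
  cov <- fx$g$cohort$covariates
  sel <- fx$g$truth$cluster == 1
  on <- fx$g$cohort$onsets[fx$g$cohort$onsets$icd10_code == "D06", ]
  age <- on$onset_age[match(cov$participant_id, on$participant_id)]
  d <- data.frame(time = ifelse(is.na(age), cov$censor_age, age),
                  status = as.integer(!is.na(age)))[sel, ]
  ref <- survival::survfit(survival::Surv(time, status) ~ 1, data = d)
  expect_equal(km$surv[-1], ref$surv, tolerance = 1e-12)
})

riskfactor_fixture <- function(n = 400, seed = 1) {
  with_seed(seed, {
    age <- runif(n, 30, 80)
    sex <- rbinom(n, 1, 0.5)
    z <- rnorm(n)
    spl <- splines::bs(age, knots = c(40, 60), degree = 3)
    zperp <- resid(lm(z ~ spl + sex))
    list(age = age, sex = sex, zperp = zperp)
  })
}

test_that("a factor equal to the standardized log-odds has coefficient 1", {
  fxr <- riskfactor_fixture()
  n <- length(fxr$zperp)
  lo <- fxr$zperp
  mem <- fake_memberships(cbind(1 / (1 + exp(-lo)),
                                1 - 1 / (1 + exp(-lo))))
  # overwrite the log-odds column with the orthogonalized outcome
  mem$logodds_1 <- lo
  factors <- data.frame(participant_id = mem$participant_id,
                        age = fxr$age, sex = fxr$sex,
                        f = lo / sd(lo))
  res <- suppressWarnings(  # the fit is exact by construction
    riskfactor_regression(mem, factors, mode = "simple", clusters = 1))
  expect_equal(res$estimate, 1, tolerance = 1e-6)
})

test_that("risk-factor p-values are calibrated under the null", {
  fxr <- riskfactor_fixture(n = 200, seed = 2)
  lo <- fxr$zperp
  mem <- fake_memberships(matrix(0.5, length(lo), 2))
  mem$logodds_1 <- lo
  base <- data.frame(participant_id = mem$participant_id,
                     age = fxr$age, sex = fxr$sex)
  set.seed(99)
  pvals <- vapply(seq_len(1000), function(i) {
    factors <- base
    factors$f <- rnorm(nrow(base))
    riskfactor_regression(mem, factors, mode = "simple",
                          clusters = 1)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("a planted standardized effect is recovered with nominal coverage", {
  covered <- vapply(1:50, function(s) with_seed(1000 + s, {
    n <- 2000
    age <- runif(n, 30, 80)
    sex <- rbinom(n, 1, 0.5)
    x <- rnorm(n)
    y <- 0.3 * x + rnorm(n, sd = sqrt(1 - 0.09))
    mem <- fake_memberships(matrix(0.5, n, 2))
    mem$logodds_1 <- y
    factors <- data.frame(participant_id = mem$participant_id,
                          age = age, sex = sex, f = x)
    res <- riskfactor_regression(mem, factors, mode = "simple",
                                 clusters = 1)
    # true standardized coefficient is 0.3 up to the sample scaling
    beta <- 0.3 * sd(x) / sd(y)
    abs(res$estimate - beta) <= 1.959964 * res$se
  }), logical(1))
  expect_gte(sum(covered), 45)
})

test_that("complex mode imputes and fits all factors jointly", {
  with_seed(7, {
    n <- 300
    age <- runif(n, 30, 80)
    sex <- rbinom(n, 1, 0.5)
    f1 <- rnorm(n)
    f2 <- 0.8 * f1 + rnorm(n, sd = 0.6)
    f2[sample(n, 30)] <- NA  # missing at random, imputable from f1
    lo <- 0.5 * f1 + rnorm(n)
    mem <- fake_memberships(matrix(0.5, n, 2))
    mem$logodds_1 <- lo
    factors <- data.frame(participant_id = mem$participant_id,
                          age = age, sex = sex, f1 = f1, f2 = f2,
                          flat = 1)
    expect_warning(
      res <- riskfactor_regression(mem, factors, mode = "complex",
                                   clusters = 1),
      "zero-variance")
    expect_setequal(res$factor, c("f1", "f2"))
    expect_true(all(res$p_adjusted >= res$p_value))
    expect_true(all(res$p_adjusted <= 1))
    # the planted factor dominates
    expect_lt(res$p_value[res$factor == "f1"], 0.001)
  })
})
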