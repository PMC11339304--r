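rel_tab <- function(vals, diseases, ends = c(20, 40, 60, 70), prov = "c") {
  relevance_table(matrix(vals, length(diseases), length(ends),
                         dimnames = list(diseases, ends)), prov)
}

test_that("cross-cohort aggregation averages and intersects availability", {
  t1 <- rel_tab(0.4, c("A", "B"))
  t2 <- rel_tab(0.8, c("A", "C"))
  cc <- cross_cohort_scores(list(t1, t2))
  expect_equal(unname(cc["A", 1]), 0.6)
  expect_equal(rownames(cc), "A")  # availability intersection
  expect_equal(attr(cc, "provenance"), "cross-cohort")

  expect_equal(unclass(cross_cohort_scores(list(t1)))[, ],
               unclass(t1)[, ])  # single cohort is the identity

  t3 <- relevance_table(matrix(0.5, 2, 3,
                               dimnames = list(c("A", "B"), c(20, 40, 60))))
  expect_error(cross_cohort_scores(list(t1, t3)), "mismatched")
  expect_error(cross_cohort_scores(list(t1, t2), weights = c(0.9, 0.3)),
               "sum to 1")
})

test_that("disease selection uses a strict cutoff across cohorts", {
  t1 <- rel_tab(0.2, c("A", "B", "C"))
  t1["A", 2] <- 0.5    # exactly at the cutoff: dropped
  t1["B", 3] <- 0.51   # just above: kept
  t2 <- rel_tab(0.1, c("A", "B", "D"))
  t2["D", 1] <- 0.9    # relevant but unavailable in cohort 1
  expect_equal(select_diseases(list(t1, t2), cutoff = 0.5), "B")
})

test_that("multimorbidity scores evaluate the weighted indicator sum", {
  # one participant, onsets at 30 and 65 with interval-specific relevance
  ages <- cbind(P = c(30), Q = c(65))
  p <- panel_from_ages(ages, censor = 80)
  rel <- relevance_table(rbind(P = c(0.2, 0.5, 0.5, 0.4),
                               Q = c(0.1, 0.1, 0.1, 0.3)))
  colnames(rel) <- c(20, 40, 60, 70)
  S <- multimorbidity_scores(p, rel)
  expect_equal(as.vector(S), c(0, 0.5, 0.5, 0.7))

  # no onsets: zero in observed intervals; early onset with constant weight
  ages2 <- cbind(P = c(NA, 10), Q = c(NA, NA))
  p2 <- panel_from_ages(ages2, censor = c(70, 50))
  rel2 <- rel_tab(0.6, c("P", "Q"))
  S2 <- multimorbidity_scores(p2, rel2)
  expect_equal(as.vector(S2[1, ]), c(0, 0, 0, 0))
  expect_equal(as.vector(S2[2, ]), c(0.6, 0.6, NA, NA))

  expect_error(multimorbidity_scores(p2, rel_tab(0.6, "P")),
               "missing from relevance")
})

test_that("well-separated planted clusters are recovered", {
  skip_if_not_installed("mclust")
  ss <- sim_scores(n = 700, sep = 6, seed = 3)
  fit <- fit_clusters(ss$X, k = 7, seed = 1, n_init = 30)
  mem <- assign_clusters(ss$X, fit)
  expect_gte(mclust::adjustedRandIndex(mem$hard_label, ss$lab), 0.9)
  expect_false(fit$degenerate)
  expect_true(is.finite(fit$silhouette))

  fit2 <- fit_clusters(ss$X, k = 7, seed = 1, n_init = 30)
  expect_identical(fit$centres, fit2$centres)  # determinism
})

test_that("degenerate and undersized inputs are handled", {
  X <- matrix(1, 10, 4, dimnames = list(NULL, c(20, 40, 60, 70)))
  fit <- fit_clusters(X, k = 3, seed = 1)
  expect_true(fit$degenerate)
  expect_equal(fit$inertia, 0)
  expect_true(all(fit$centres == 1))

  expect_error(fit_clusters(X[1:2, ], k = 3), "at least k")
})

test_that("membership equations match their closed forms", {
  # k = 2, participant at centre 1, centre 2 at distance ln 3
  model <- structure(list(
    centres = rbind(cluster1 = c(0, 0), cluster2 = c(log(3), 0)),
    k = 2L, inertia = 0, silhouette = NA_real_, n_complete = 2L,
    degenerate = FALSE, federated = FALSE, seed = 1L, call = NULL),
    class = "traj_clusters")
  mem <- assign_clusters(matrix(0, 1, 2), model)
  expect_equal(mem$posterior_1, 0.75, tolerance = 1e-9)
  expect_equal(mem$posterior_2, 0.25, tolerance = 1e-9)
  expect_equal(mem$logodds_1, log(3), tolerance = 1e-9)
  expect_equal(mem$logodds_2, -log(3), tolerance = 1e-9)
  expect_equal(mem$likelihood_1, 1, tolerance = 1e-12)
  expect_equal(mem$likelihood_2, 1 / 3, tolerance = 1e-9)
  expect_posteriors_valid(mem)

  # all centres equidistant: posterior 1/k, log-odds -ln(k - 1)
  k <- 5
  model5 <- structure(list(
    centres = matrix(rnorm(k * 2), k, 2,
                     dimnames = list(paste0("cluster", 1:k), NULL)),
    k = as.integer(k), inertia = 0, silhouette = NA_real_,
    n_complete = k, degenerate = FALSE, federated = FALSE,
    seed = 1L, call = NULL), class = "traj_clusters")
  model5$centres <- 2 * model5$centres /
    sqrt(rowSums(model5$centres^2))  # all at distance 2 from the origin
  mem5 <- assign_clusters(matrix(0, 1, 2), model5)
  expect_equal(unname(unlist(mem5[grep("^posterior_", names(mem5))])),
               rep(1 / k, k), tolerance = 1e-9)
  expect_equal(unname(unlist(mem5[grep("^logodds_", names(mem5))])),
               rep(-log(k - 1), k), tolerance = 1e-9)
})

test_that("partial rows use observed-coordinate distances", {
  ss <- sim_scores(n = 50, sep = 6, seed = 9)
  fit <- fit_clusters(ss$X, k = 7, seed = 2, n_init = 10)
  # a row observed on dims 1-2 only, matching centre 3 there
  x <- rep(NA_real_, 4)
  x[1:2] <- fit$centres[3, 1:2]
  mem <- assign_clusters(matrix(x, 1, 4), fit)
  d_brute <- apply(fit$centres, 1, function(cc)
    sqrt(sum((x[1:2] - cc[1:2])^2)))
  expect_equal(mem$hard_label, unname(which.min(d_brute)))

  expect_error(assign_clusters(matrix(NA_real_, 1, 4), fit),
               "zero observed")
})

test_that("posterior likelihood increases when moving toward a centre", {
  ss <- sim_scores(n = 60, sep = 4, seed = 11)
  fit <- fit_clusters(ss$X, k = 7, seed = 1, n_init = 10)
  x_far <- fit$centres[2, ] + c(2, 2, 2, 2)
  x_near <- fit$centres[2, ] + c(1, 1, 1, 1)
  m <- assign_clusters(rbind(x_far, x_near), fit)
  expect_gt(m$posterior_2[2], m$posterior_2[1])
})

test_that("confidence filter applies the age and posterior thresholds", {
  P <- rbind(c(0.10, 0.9, 0, 0) / 1.0,
             c(0.25, 0.25, 0.25, 0.25),
             c(0.26, 0.26, 0.24, 0.24) / 1.0)
  P <- P / rowSums(P)
  P[1, ] <- c(0.10, 0.10, 0.10, 0.70)  # max 0.70
  P[2, ] <- 0.25                       # max exactly 0.25
  P[3, ] <- c(0.26, 0.26, 0.24, 0.24)  # max 0.26
  mem <- fake_memberships(P)
  keep <- confidence_filter(mem, ages = c(65, 45, 45))
  expect_equal(keep, c(TRUE, FALSE, TRUE))
  keep2 <- confidence_filter(fake_memberships(P[2, , drop = FALSE]),
                             ages = 65)
  expect_true(keep2)  # old enough, low confidence is fine
})

test_that("federated fitting matches pooled counts and the central fit", {
  ss <- sim_scores(n = 600, sep = 6, seed = 13)
  X <- ss$X
  s1 <- X[1:300, , drop = FALSE]
  s2 <- X[301:600, , drop = FALSE]
  attr(s1, "interval_ends") <- attr(X, "interval_ends")
  attr(s2, "interval_ends") <- attr(X, "interval_ends")
  bw <- 0.5
  f_two <- federated_fit(list(s1, s2), bin_width = bw, k = 7, seed = 4)
  f_one <- federated_fit(list(X), bin_width = bw, k = 7, seed = 4)
  expect_identical(f_two$centres, f_one$centres)  # count additivity

  # single site approximates the centralized fit within the quantization
  # bound per centre
  cen <- fit_clusters(X, k = 7, seed = 4, n_init = 30)
  match_d <- apply(f_one$centres, 1, function(cc)
    min(sqrt(colSums((t(cen$centres) - cc)^2))))
  expect_true(all(match_d <= bw * sqrt(4)))

  # refinement: smaller bins converge to the centralized centres
  d_for <- function(bw) {
    f <- federated_fit(list(X), bin_width = bw, k = 7, seed = 4)
    max(apply(f$centres, 1, function(cc)
      min(sqrt(colSums((t(cen$centres) - cc)^2)))))
  }
  expect_lt(d_for(0.05), d_for(1.5))
  expect_lt(d_for(0.05), 0.15)

  s_bad <- s2[, 1:3]
  expect_error(federated_fit(list(s1, s_bad), bin_width = 0.5, k = 2),
               "incompatible")
})

test_that("membership tables and models serialize to text", {
  ss <- sim_scores(n = 80, sep = 6, seed = 15)
  fit <- fit_clusters(ss$X, k = 7, seed = 1, n_init = 5)
  mem <- assign_clusters(ss$X, fit)
  tf <- tempfile(fileext = ".tsv")
  write_membership_table(mem, tf)
  expect_equal(nrow(read.delim(tf)), 80)
  tj <- tempfile(fileext = ".json")
  write_cluster_model(fit, tj)
  mj <- jsonlite::read_json(tj, simplifyVector = TRUE)
  expect_equal(mj$k, 7)
})
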