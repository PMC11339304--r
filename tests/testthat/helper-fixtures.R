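# shared fixtures, built once per test run
.fx_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- builder()
  .fx_env[[name]]
}

# mid-sized default cohort with panel
fx_cohort <- function() fx("cohort", function() {
  g <- generate_cohort(synthetic_config(n_participants = 3000, seed = 42))
  g$panel <- discretize(g$cohort, time_grid())
  g
})

# hand-built four-participant cohort for exact-arithmetic checks
fx_tiny_cohort <- function() {
  onsets <- data.frame(
    participant_id = c("a", "a", "b", "c"),
    icd10_code = c("F32", "K21", "K21", "F32"),
    onset_age = c(25, 65, 30, 50))
  covariates <- data.frame(
    participant_id = c("a", "b", "c", "d"),
    sex = c(0, 1, 0, 1),
    birth_year = c(1950, 1955, 1960, 1965),
    income = c("low", "medium", "high", "low"),
    censor_age = c(80, 75, 70, 72))
  cohort_table(onsets, covariates)
}

# membership table with hand-set posteriors (likelihood/log-odds consistent)
fake_memberships <- function(P, ids = NULL) {
  P <- as.matrix(P)
  k <- ncol(P)
  eps <- 1e-12
  P <- pmin(pmax(P, eps), 1 - eps)
  out <- data.frame(participant_id = ids %||%
                      sprintf("P%06d", seq_len(nrow(P))),
                    stringsAsFactors = FALSE)
  lik <- P
  colnames(lik) <- paste0("likelihood_", seq_len(k))
  post <- P
  colnames(post) <- paste0("posterior_", seq_len(k))
  lo <- log(P) - log(1 - P)
  colnames(lo) <- paste0("logodds_", seq_len(k))
  out <- cbind(out, lik, post, lo)
  out$hard_label <- max.col(P, ties.method = "first")
  out$complete <- TRUE
  out$included <- TRUE
  class(out) <- c("membership_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap an indicator matrix as a structure_trace
fake_trace <- function(ind) {
  structure(list(indicators = as.matrix(ind),
                 log_score = numeric(nrow(as.matrix(ind))),
                 accept_rate = NA_real_, swap_rate = NA_real_,
                 variables = NULL, target = "Y", interval = 1L,
                 dropped = character(0), settings = NULL),
            class = "structure_trace")
}

# build an interval panel directly from an onset-age matrix (NA = no onset)
panel_from_ages <- function(ages, censor, ends = c(20, 40, 60, 70)) {
  n <- nrow(ages)
  pid <- sprintf("P%06d", seq_len(n))
  rows <- which(!is.na(ages), arr.ind = TRUE)
  onsets <- data.frame(participant_id = pid[rows[, 1]],
                       icd10_code = colnames(ages)[rows[, 2]],
                       onset_age = ages[rows])
  covariates <- data.frame(participant_id = pid, sex = 0L,
                           birth_year = 1950L, income = "low",
                           censor_age = censor)
  discretize(cohort_table(onsets, covariates), time_grid(ends),
             diseases = colnames(ages))
}

expect_posteriors_valid <- function(mem) {
  P <- as.matrix(mem[, grep("^posterior_", names(mem))])
  L <- as.matrix(mem[, grep("^logodds_", names(mem))])
  expect_true(all(P > 0 & P < 1))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  expect_lt(max(abs(1 / (1 + exp(-L)) - P)), 1e-9)
}

sim_scores <- function(n = 700, k = 7, sep = 6, seed = 1) {
  # 7 distinct monotone centre trajectories, within-cluster SD 1, centre
  # separation sep * SD along the distinguishing coordinates
  centres <- sep * rbind(c(0, 0, 0, 0), c(0, 0, 0, 1), c(0, 0, 1, 1),
                         c(0, 1, 1, 1), c(1, 1, 1, 1), c(0, 1, 1, 2),
                         c(1, 1, 2, 2))[seq_len(k), , drop = FALSE]
  with_seed(seed, {
    lab <- sample.int(k, n, replace = TRUE)
    X <- centres[lab, ] + matrix(rnorm(n * 4), n, 4)
    rownames(X) <- sprintf("P%06d", seq_len(n))
    colnames(X) <- c(20, 40, 60, 70)
    attr(X, "interval_ends") <- c(20, 40, 60, 70)
    list(X = X, lab = lab, centres = centres)
  })
}


# shared clustered cohort with a 10-disease scoring pool
subset_fixture <- function() fx("subset_fixture", function() {
  g <- generate_cohort(synthetic_config(2500, censor_age_range = c(60, 90),
                                        seed = 77))
  panel <- discretize(g$cohort, time_grid())
  pool <- c("D01", "D02", "D03", "D04", "D06",
            "T01", "T02", "T05", "T09", "T13")
  rel <- relevance_table(matrix(1, length(pool), 4,
                                dimnames = list(pool, c(20, 40, 60, 70))))
  scores <- multimorbidity_scores(subset_panel(panel, pool), rel)
  model <- fit_clusters(scores, k = 7, seed = 3, n_init = 20)
  reference <- assign_clusters(scores, model)
  list(g = g, panel = panel, pool = pool, rel = rel, model = model,
       reference = reference)
})

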