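#' Cohort table of first disease onsets and participant covariates
#'
#' The universal input of the pipeline: a long-format onset table
#' (`participant_id`, `icd10_code`, `onset_age` in years) together with a
#' covariate table (`participant_id`, `sex`, `birth_year`, `income`,
#' `censor_age`, optional risk factors). Duplicate (participant, disease)
#' onset rows are collapsed to the earliest onset (first onsets only).
#' Validation enforces that every onset participant appears in the covariate
#' table and that no onset exceeds its participant's censoring age.
#'
#' @param onsets data.frame with columns `participant_id`, `icd10_code`,
#'   `onset_age`.
#' @param covariates data.frame with at least `participant_id` and
#'   `censor_age`.
#' @return an object of class `cohort_table`.
#' @export
cohort_table <- function(onsets, covariates) {
  need_on <- c("participant_id", "icd10_code", "onset_age")
  if (!all(need_on %in% names(onsets)))
    stopf("onset table must have columns %s", paste(need_on, collapse = ", "))
  if (!all(c("participant_id", "censor_age") %in% names(covariates)))
    stopf("covariate table must have participant_id and censor_age")
  if (anyDuplicated(covariates$participant_id))
    stopf("duplicated participant_id in covariate table")
  onsets <- onsets[order(onsets$participant_id, onsets$icd10_code,
                         onsets$onset_age), , drop = FALSE]
  dup <- duplicated(onsets[c("participant_id", "icd10_code")])
  onsets <- onsets[!dup, , drop = FALSE]
  rownames(onsets) <- NULL

  unknown <- setdiff(onsets$participant_id, covariates$participant_id)
  if (length(unknown) > 0)
    stopf("onset rows reference participants absent from covariates: %s",
          paste(head(unknown, 5), collapse = ", "))
  if (any(onsets$onset_age < 0)) stopf("onset_age must be non-negative")
  cens <- covariates$censor_age[match(onsets$participant_id,
                                      covariates$participant_id)]
  bad <- which(onsets$onset_age > cens)
  if (length(bad) > 0)
    stopf("onset after censoring age in row %d (participant %s, %s at %.1f > censor %.1f)",
          bad[1], onsets$participant_id[bad[1]], onsets$icd10_code[bad[1]],
          onsets$onset_age[bad[1]], cens[bad[1]])
  structure(list(onsets = onsets, covariates = covariates),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort:", nrow(x$covariates), "participants,",
      nrow(x$onsets), "first onsets of",
      length(unique(x$onsets$icd10_code)), "diseases\n")
  invisible(x)
}

#' Read a cohort from onset and covariate TSV files
#'
#' @param onset_path TSV with `participant_id`, `icd10_code`, `onset_age`.
#' @param covariate_path TSV with `participant_id`, `censor_age`, ...
#' @return a validated [cohort_table()].
#' @export
read_cohort <- function(onset_path, covariate_path) {
  if (!file.exists(onset_path)) stopf("onset file not found: %s", onset_path)
  if (!file.exists(covariate_path))
    stopf("covariate file not found: %s", covariate_path)
  onsets <- read.delim(onset_path, stringsAsFactors = FALSE)
  covariates <- read.delim(covariate_path, stringsAsFactors = FALSE)
  cohort_table(onsets, covariates)
}

#' Cumulative time grid
#'
#' Ordered interval ends defining the cumulative age intervals
#' `[0, e1], ..., [0, eT]` used to discretize trajectories. An onset exactly
#' at an interval end counts as inside that interval (closed right end).
#'
#' @param interval_ends strictly increasing positive ages (years).
#' @export
time_grid <- function(interval_ends = c(20, 40, 60, 70)) {
  if (length(interval_ends) < 1 || any(interval_ends <= 0) ||
      any(diff(interval_ends) <= 0))
    stopf("interval_ends must be strictly increasing and positive")
  structure(list(interval_ends = as.numeric(interval_ends)),
            class = "time_grid")
}

#' Discretize a cohort into a censoring-aware interval panel
#'
#' Builds the binary data matrix of the dynamic Bayesian network:
#' `indicators[i, d, t]` is 1 iff the first onset of disease `d` for
#' participant `i` occurred at or before `interval_ends[t]`, and
#' `included[i, t]` is TRUE iff the participant has complete onset
#' information through the end of interval `t`
#' (`censor_age >= interval_ends[t]`). Indicators are non-decreasing along
#' the interval axis and inclusion is monotone decreasing.
#'
#' @param cohort a [cohort_table()].
#' @param grid a [time_grid()].
#' @param diseases optional character vector fixing the disease axis; by
#'   default the sorted set of codes present in the onset table.
#' @return object of class `interval_panel`.
#' @export
discretize <- function(cohort, grid = time_grid(), diseases = NULL) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(grid, "time_grid"))
  ends <- grid$interval_ends
  pid <- cohort$covariates$participant_id
  diseases <- diseases %||% sort(unique(cohort$onsets$icd10_code))
  n <- length(pid)
  d <- length(diseases)
  T_ <- length(ends)
  ind <- array(0L, dim = c(n, d, T_),
               dimnames = list(pid, diseases, ends))
  on <- cohort$onsets[cohort$onsets$icd10_code %in% diseases, , drop = FALSE]
  if (nrow(on) > 0) {
    i <- match(on$participant_id, pid)
    j <- match(on$icd10_code, diseases)
    for (t in seq_len(T_)) {
      hit <- which(on$onset_age <= ends[t])
      if (length(hit) > 0)
        ind[cbind(i[hit], j[hit], rep(t, length(hit)))] <- 1L
    }
  }
  included <- outer(cohort$covariates$censor_age, ends, `>=`)
  dimnames(included) <- list(pid, ends)
  structure(list(indicators = ind, included = included,
                 diseases = diseases, participants = pid, grid = grid),
            class = "interval_panel")
}

#' @export
print.interval_panel <- function(x, ...) {
  cat("Interval panel:", length(x$participants), "participants x",
      length(x$diseases), "diseases x",
      length(x$grid$interval_ends), "cumulative intervals",
      sprintf("([0-%s])\n",
              paste(x$grid$interval_ends, collapse = "], [0-")))
  invisible(x)
}

#' Restrict an interval panel to a subset of diseases
#' @param panel an [interval_panel].
#' @param diseases codes to keep (order preserved as given).
#' @export
subset_panel <- function(panel, diseases) {
  stopifnot(inherits(panel, "interval_panel"))
  missing_d <- setdiff(diseases, panel$diseases)
  if (length(missing_d) > 0)
    stopf("diseases not in panel: %s", paste(missing_d, collapse = ", "))
  panel$indicators <- panel$indicators[, diseases, , drop = FALSE]
  panel$diseases <- diseases
  panel
}

#' Prevalence pre-filter for candidate diseases
#'
#' Keeps diseases whose prevalence exceeds `threshold` either in the whole
#' cohort or in the subset of participants with any onset of a target code;
#' target codes themselves are always retained. Used to exclude rare
#' disorders before relevance estimation.
#'
#' @param cohort a [cohort_table()].
#' @param threshold proportion in (0, 1); the conventional cut is 0.01.
#' @param target_codes disease codes defining the target subset (e.g. F32
#'   and F33).
#' @return character vector of retained disease codes.
#' @export
prevalence_filter <- function(cohort, threshold = 0.01, target_codes) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!(threshold > 0 && threshold < 1)) stopf("threshold must be in (0,1)")
  if (missing(target_codes) || length(target_codes) == 0)
    stopf("target_codes must be non-empty")
  n <- nrow(cohort$covariates)
  if (n == 0) stopf("empty cohort")
  on <- cohort$onsets
  carriers <- unique(on$participant_id[on$icd10_code %in% target_codes])
  n_t <- length(carriers)
  codes <- sort(unique(on$icd10_code))
  keep <- vapply(codes, function(d) {
    who <- on$participant_id[on$icd10_code == d]
    (length(who) / n > threshold) ||
      (n_t > 0 && sum(who %in% carriers) / n_t > threshold)
  }, logical(1))
  sort(union(codes[keep], intersect(target_codes, codes)))
}
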