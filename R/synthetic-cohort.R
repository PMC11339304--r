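#' Configuration for the synthetic cohort generator
#'
#' Defines a generative model for disease-onset trajectories with a planted
#' cluster structure and a planted Markov boundary around a target disease
#' (an analogue of major depressive disorder, MDD). Onset times follow
#' piecewise-constant hazards over the age bands induced by the cumulative
#' time grid, with per-cluster hazard multipliers. The target's hazard is
#' multiplied by `exp(effect_direct)` from the moment any direct-parent
#' disease has its onset; mediated diseases act on the mediator's hazard
#' only (multiplier `exp(effect_mediated)` from their first onset), never
#' on the target directly, so mediated diseases are conditionally
#' independent of the target given the mediator's exact onset history.
#' Covariate effects apply to the target hazard.
#'
#' @param n_participants number of participants to simulate.
#' @param n_clusters number of latent trajectory clusters (default 7).
#' @param diseases disease specification as returned by
#'   [default_disease_set()]: a list with `codes`, a `baseline` hazard matrix
#'   (disease x age band, in events per person-year) and a `multiplier`
#'   matrix (disease x cluster).
#' @param target_code code of the target disease.
#' @param target_baseline per-band baseline hazard of the target.
#' @param direct_parents codes whose onset multiplies the target hazard.
#' @param mediated_diseases codes influencing the target only through
#'   `mediator`.
#' @param mediator a member of `direct_parents` that carries the mediated
#'   effect.
#' @param effect_direct,effect_mediated log hazard-rate increments.
#' @param censor_age_range uniform range (years) of right-censoring ages.
#' @param cluster_mixture mixing probabilities; must sum to 1.
#' @param covariate_effects named vector of log-hazard effects on the target
#'   (`sex`, `income_medium`, `income_high`).
#' @param birth_year_range uniform range of birth years.
#' @param interval_ends cumulative interval ends defining the age bands.
#' @param seed integer seed; fully determines the generated cohort.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants,
                             n_clusters = 7,
                             diseases = default_disease_set(n_clusters, interval_ends),
                             target_code = "F32",
                             target_baseline = c(0.002, 0.003, 0.004, 0.004, 0.004),
                             direct_parents = c("D01", "D02", "D03"),
                             mediated_diseases = c("D04", "D05"),
                             mediator = "D01",
                             effect_direct = log(3),
                             effect_mediated = log(3),
                             censor_age_range = c(40, 90),
                             cluster_mixture = rep(1 / n_clusters, n_clusters),
                             covariate_effects = c(sex = 0.4, income_medium = 0,
                                                   income_high = 0),
                             birth_year_range = c(1930, 1970),
                             interval_ends = c(20, 40, 60, 70),
                             seed = 1) {
  if (n_participants < 0) stopf("n_participants must be non-negative")
  if (abs(sum(cluster_mixture) - 1) > 1e-12)
    stopf("cluster_mixture must sum to 1 (got %.15f)", sum(cluster_mixture))
  if (any(cluster_mixture < 0)) stopf("cluster_mixture must be non-negative")
  if (length(cluster_mixture) != n_clusters)
    stopf("cluster_mixture must have length n_clusters")
  if (any(diseases$baseline < 0) || any(diseases$multiplier < 0) ||
      any(target_baseline < 0))
    stopf("all hazards and multipliers must be non-negative")
  if (length(intersect(direct_parents, mediated_diseases)) > 0)
    stopf("direct_parents and mediated_diseases must be disjoint")
  if (!mediator %in% direct_parents)
    stopf("mediator must be one of the direct parents")
  missing_codes <- setdiff(c(direct_parents, mediated_diseases),
                           diseases$codes)
  if (length(missing_codes) > 0)
    stopf("unknown disease codes: %s", paste(missing_codes, collapse = ", "))
  n_bands <- length(interval_ends) + 1L
  if (ncol(diseases$baseline) != n_bands ||
      length(target_baseline) != n_bands)
    stopf("baseline hazards must have one column per age band (%d)", n_bands)

  structure(list(
    n_participants = as.integer(n_participants),
    n_clusters = as.integer(n_clusters),
    diseases = diseases,
    target_code = target_code,
    target_baseline = target_baseline,
    direct_parents = direct_parents,
    mediated_diseases = mediated_diseases,
    mediator = mediator,
    effect_direct = effect_direct,
    effect_mediated = effect_mediated,
    censor_age_range = censor_age_range,
    cluster_mixture = cluster_mixture,
    covariate_effects = covariate_effects,
    birth_year_range = birth_year_range,
    interval_ends = interval_ends,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default disease set with planted relevance and cluster structure
#'
#' Builds three direct parents of the target (`D01`-`D03`, with `D01` the
#' default mediator), two mediated diseases (`D04`, `D05`), two irrelevant
#' background diseases (`D06`, `D07`) and, when `markers = TRUE`, twelve
#' trajectory-marker diseases (`T01`-`T12`) arranged in four groups of three.
#' Each marker group has a high onset hazard inside one age band; clusters
#' differ in which marker groups are active, producing seven well-separated
#' mean multimorbidity-score trajectories. Direct parents, mediated and
#' background diseases are cluster-invariant so that the planted Markov
#' boundary of the target is exactly `{D01, D02, D03}` plus the covariates.
#'
#' @param n_clusters number of clusters the multiplier matrix must cover.
#' @param interval_ends cumulative interval ends (defines the age bands).
#' @param markers include the trajectory-marker diseases?
#' @param n_per_group markers per age-band group.
#' @param marker_hazard in-band hazard of an active marker (per year).
#' @param marker_background multiplier applied to markers in inactive
#'   clusters.
#' @return a list with `codes`, `baseline` and `multiplier`.
#' @export
default_disease_set <- function(n_clusters = 7,
                                interval_ends = c(20, 40, 60, 70),
                                markers = TRUE,
                                n_per_group = 4,
                                marker_hazard = 0.25,
                                marker_background = 0.004) {
  n_bands <- length(interval_ends) + 1L
  codes <- sprintf("D%02d", 1:7)
  baseline <- matrix(0.004, nrow = 7, ncol = n_bands,
                     dimnames = list(codes, NULL))
  multiplier <- matrix(1, nrow = 7, ncol = n_clusters,
                       dimnames = list(codes, NULL))
  if (markers) {
    n_groups <- min(4L, n_bands - 1L)
    mcodes <- sprintf("T%02d", seq_len(n_per_group * n_groups))
    mbase <- matrix(5e-4, nrow = length(mcodes), ncol = n_bands,
                    dimnames = list(mcodes, NULL))
    grp <- function(g) (n_per_group * (g - 1L) + 1L):(n_per_group * g)
    for (g in seq_len(n_groups)) mbase[grp(g), g] <- marker_hazard
    # cluster "active band" design: rows = clusters, entries = marker groups
    active <- list(integer(0), 4L, 3L, 2L, 1L, c(2L, 4L), c(1L, 3L))
    mmult <- matrix(marker_background, nrow = length(mcodes),
                    ncol = n_clusters, dimnames = list(mcodes, NULL))
    for (cl in seq_len(min(n_clusters, length(active)))) {
      for (g in active[[cl]]) {
        if (g <= n_groups) mmult[grp(g), cl] <- 1
      }
    }
    codes <- c(codes, mcodes)
    baseline <- rbind(baseline, mbase)
    multiplier <- rbind(multiplier, mmult)
  }
  list(codes = codes, baseline = baseline, multiplier = multiplier)
}

#' Ground-truth relevance weighting of a synthetic cohort
#'
#' Builds the relevance table a perfectly informed analyst would use for
#' the clustering stages: weight 1 for every disease that shapes the
#' planted structure (direct parents of the target plus all
#' cluster-informative diseases, i.e. those with cluster-varying hazard
#' multipliers), restricted to exactly those diseases. Mediated and
#' background diseases are excluded.
#'
#' @param truth a `truth_record` from [generate_cohort()].
#' @param interval_ends interval ends labelling the columns.
#' @return a [relevance_table()] with provenance `"planted-truth"`.
#' @export
planted_relevance <- function(truth, interval_ends = c(20, 40, 60, 70)) {
  mult <- truth$hazard_multipliers
  varying <- apply(mult, 1, function(r) max(r) - min(r) > 0)
  keep <- rownames(mult)[(varying |
                            truth$disease_roles[rownames(mult)] == "direct") &
                           truth$disease_roles[rownames(mult)] != "mediated"]
  relevance_table(matrix(1, length(keep), length(interval_ends),
                         dimnames = list(keep, interval_ends)),
                  provenance = "planted-truth")
}

# inverse cumulative hazard under piecewise-constant per-participant rates.
# rates: n x B matrix (per-year); edges: band edges c(0, ends..., Inf).
# returns the age at which the cumulative hazard reaches E (NA if never).
invhaz_pc <- function(E, rates, edges) {
  n <- nrow(rates)
  B <- ncol(rates)
  if (n == 0) return(numeric(0))
  widths <- diff(edges)
  H <- rates * rep(widths, each = n)
  H[rates == 0] <- 0  # 0 * Inf in the open-ended last band
  cum <- H
  if (B > 1) for (b in 2:B) cum[, b] <- cum[, b - 1] + H[, b]
  crossed <- cum >= E
  any_cross <- rowSums(crossed) > 0
  bidx <- max.col(crossed, ties.method = "first")
  age <- rep(NA_real_, n)
  if (any(any_cross)) {
    i <- which(any_cross)
    b <- bidx[i]
    prev <- ifelse(b > 1, cum[cbind(i, pmax(b - 1, 1))], 0)
    age[i] <- edges[b] + (E[i] - prev) / rates[cbind(i, b)]
  }
  age
}

sample_onset_pc <- function(rates, edges) invhaz_pc(rexp(nrow(rates)), rates, edges)

# cumulative baseline hazard evaluated at per-participant ages (NA -> Inf,
# i.e. "no trigger": the whole lifespan stays on the baseline hazard)
cumhaz_pc <- function(age, rates, edges) {
  age2 <- ifelse(is.na(age), Inf, age)
  H <- numeric(length(age2))
  for (b in seq_len(ncol(rates))) {
    dur <- pmax(0, pmin(age2, edges[b + 1]) - edges[b])
    contrib <- rates[, b] * dur
    contrib[rates[, b] == 0] <- 0
    H <- H + contrib
  }
  H
}

# first-passage time when the hazard is multiplied by exp(log_effect) from
# the trigger age onward (inversion through the baseline cumulative hazard)
sample_triggered_onset <- function(rates, edges, trigger_age, log_effect) {
  E <- rexp(nrow(rates))
  Ht <- cumhaz_pc(trigger_age, rates, edges)
  E2 <- ifelse(E <= Ht, E, Ht + (E - Ht) / exp(log_effect))
  invhaz_pc(E2, rates, edges)
}

# age band containing an onset age: band b covers (end[b-1], end[b]]
band_of <- function(age, interval_ends) {
  1L + rowSums(outer(age, interval_ends, ">"))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' @param config a [synthetic_config()] object.
#' @return a list with `cohort` (a [cohort_table()]) and `truth` (class
#'   `truth_record`: per-participant cluster labels, per-disease
#'   direct/mediated/irrelevant flags and the planted multiplier matrix).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_participants
  ends <- config$interval_ends
  edges <- c(0, ends, Inf)
  n_bands <- length(ends) + 1L
  codes <- config$diseases$codes
  base <- config$diseases$baseline
  mult <- config$diseases$multiplier

  pid <- sprintf("P%06d", seq_len(n))
  cl <- if (n > 0)
    sample.int(config$n_clusters, n, replace = TRUE,
               prob = config$cluster_mixture) else integer(0)
  censor <- runif(n, config$censor_age_range[1], config$censor_age_range[2])
  sex <- rbinom(n, 1, 0.5)
  income <- sample(c("low", "medium", "high"), size = n, replace = TRUE)
  birth_year <- round(runif(n, config$birth_year_range[1],
                            config$birth_year_range[2]))

  roles <- setNames(rep("irrelevant", length(codes)), codes)
  roles[config$direct_parents] <- "direct"
  roles[config$mediated_diseases] <- "mediated"

  onset_age <- matrix(NA_real_, nrow = n, ncol = length(codes),
                      dimnames = list(NULL, codes))
  if (n > 0) {
    plain <- setdiff(codes, config$mediator)
    for (d in plain) {
      rates <- matrix(base[d, ], n, n_bands, byrow = TRUE) * mult[d, cl]
      onset_age[, d] <- sample_onset_pc(rates, edges)
    }
    # mediator: hazard multiplied from the first mediated onset onward
    med_first <- if (length(config$mediated_diseases) == 0) {
      rep(NA_real_, n)
    } else {
      suppressWarnings(
        do.call(pmin, c(lapply(config$mediated_diseases,
                               function(d) onset_age[, d]), na.rm = TRUE)))
    }
    dmed <- config$mediator
    rates <- matrix(base[dmed, ], n, n_bands, byrow = TRUE) * mult[dmed, cl]
    onset_age[, dmed] <- sample_triggered_onset(rates, edges, med_first,
                                                config$effect_mediated)
    # target: covariate effects plus the direct-parent trigger
    par_first <- suppressWarnings(
      do.call(pmin, c(lapply(config$direct_parents,
                             function(d) onset_age[, d]), na.rm = TRUE)))
    covlog <- config$covariate_effects["sex"] * sex +
      config$covariate_effects["income_medium"] * (income == "medium") +
      config$covariate_effects["income_high"] * (income == "high")
    rates <- matrix(config$target_baseline, n, n_bands, byrow = TRUE) *
      exp(covlog)
    target_age <- sample_triggered_onset(rates, edges, par_first,
                                         config$effect_direct)
    onset_age <- cbind(onset_age, target_age)
    colnames(onset_age) <- c(codes, config$target_code)
  }

  all_codes <- c(codes, config$target_code)
  rows <- which(!is.na(onset_age) & onset_age <= censor, arr.ind = TRUE)
  onsets <- data.frame(
    participant_id = pid[rows[, 1]],
    icd10_code = all_codes[rows[, 2]],
    onset_age = onset_age[rows],
    stringsAsFactors = FALSE
  )
  onsets <- onsets[order(onsets$participant_id, onsets$icd10_code), ,
                   drop = FALSE]
  rownames(onsets) <- NULL
  covariates <- data.frame(
    participant_id = pid,
    sex = sex,
    birth_year = birth_year,
    income = income,
    censor_age = censor,
    stringsAsFactors = FALSE
  )
  truth <- structure(list(
    cluster = cl,
    disease_roles = roles,
    hazard_multipliers = mult,
    effect_direct = config$effect_direct,
    effect_mediated = config$effect_mediated
  ), class = "truth_record")
  list(cohort = cohort_table(onsets, covariates), truth = truth)
}

#' Generate gene-level association scores with planted signal genes
#'
#' Stand-in for gene-level GWAS results: adjusted p-values are uniform on
#' (0, 1) for null genes, while signal genes receive `u^(1 + effect)` draws
#' floored at `p_floor`, hence stochastically smaller p-values.
#'
#' @param n_genes size of the gene universe (`g00001`, ...).
#' @param signal_genes subset of the universe carrying signal.
#' @param effect positive signal strength; `Inf`-like values drive signal
#'   p-values to `p_floor`.
#' @param seed integer seed.
#' @param p_floor smallest reportable adjusted p-value.
#' @return data.frame with `gene_id` and `p_adj`.
#' @export
generate_gene_scores <- function(n_genes, signal_genes = character(),
                                 effect = 1, seed = 1, p_floor = 1e-12) {
  if (effect <= 0) stopf("effect must be positive")
  genes <- sprintf("g%05d", seq_len(n_genes))
  if (!all(signal_genes %in% genes))
    stopf("signal_genes must be a subset of the gene universe")
  with_seed(seed, {
    u <- runif(n_genes)
    p <- u
    idx <- match(signal_genes, genes)
    if (length(idx) > 0)
      p[idx] <- pmax(p_floor, u[idx]^(1 + effect))
    data.frame(gene_id = genes, p_adj = p, stringsAsFactors = FALSE)
  })
}

#' Generate a planted-partition interactome
#'
#' Undirected simple graph over `n_nodes` genes partitioned into
#' `n_modules` blocks; within-block edges occur with probability `intra_p`,
#' between-block edges with `inter_p`.
#'
#' @param n_nodes,n_modules graph and partition sizes.
#' @param intra_p,inter_p edge probabilities, `0 <= inter_p < intra_p <= 1`.
#' @param seed integer seed.
#' @return an igraph with vertex attribute `module` (the planted block) and
#'   graph attribute `largest_component` (size of the largest connected
#'   component).
#' @export
generate_interactome <- function(n_nodes, n_modules, intra_p, inter_p,
                                 seed = 1) {
  if (n_modules > n_nodes) stopf("n_modules cannot exceed n_nodes")
  if (!(inter_p >= 0 && inter_p < intra_p && intra_p <= 1))
    stopf("need 0 <= inter_p < intra_p <= 1")
  with_seed(seed, {
    membership <- sort(rep_len(seq_len(n_modules), n_nodes))
    g <- if (n_nodes >= 2) {
      pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
      same <- membership[pairs[, 1]] == membership[pairs[, 2]]
      keep <- runif(nrow(pairs)) < ifelse(same, intra_p, inter_p)
      el <- pairs[keep, , drop = FALSE]
      igraph::graph_from_data_frame(
        data.frame(from = sprintf("g%05d", el[, 1]),
                   to = sprintf("g%05d", el[, 2])),
        directed = FALSE,
        vertices = data.frame(name = sprintf("g%05d", seq_len(n_nodes))))
    } else {
      igraph::make_empty_graph(n = n_nodes, directed = FALSE)
    }
    if (n_nodes == 1) igraph::V(g)$name <- "g00001"
    igraph::V(g)$module <- membership
    g <- igraph::set_graph_attr(g, "largest_component",
                                max(igraph::components(g)$csize))
    g
  })
}

#' @export
print.truth_record <- function(x, ...) {
  cat("Planted ground truth:", length(x$cluster), "participants,",
      ncol(x$hazard_multipliers), "clusters\n")
  cat("Disease roles:\n")
  print(table(x$disease_roles))
  invisible(x)
}

#' Write synthetic outputs to plain-text files
#'
#' `write_cohort()` writes `onsets.tsv` and `covariates.tsv`;
#' `write_truth()` writes the ground truth as JSON; `write_gene_scores()`
#' and `write_interactome()` write a TSV and a two-column edge list.
#'
#' @param cohort,truth,scores,graph objects to serialize.
#' @param dir,path output locations.
#' @return the paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  po <- file.path(dir, "onsets.tsv")
  pc <- file.path(dir, "covariates.tsv")
  write.table(cohort$onsets, po, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$covariates, pc, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(po, pc))
}

#' @rdname write_cohort
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(cluster = truth$cluster,
         disease_roles = as.list(truth$disease_roles),
         hazard_multipliers = truth$hazard_multipliers),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_gene_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_interactome <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
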