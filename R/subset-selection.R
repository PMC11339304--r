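#' Clustering fidelity under a reduced disease set
#'
#' Recomputes the multimorbidity scores from a disease subset only,
#' reassigns every participant with the ORIGINAL cluster centres and
#' compares the result with the full-set reference memberships: accuracy
#' and balanced accuracy of the hard labels, and the mean absolute / mean
#' squared error of the posterior membership probabilities. Metrics are
#' averaged over `n_repeats` random draws of `sample_size` participants.
#'
#' @param subset disease codes to keep (must be present in `relevance`);
#'   an empty subset is only allowed with `allow_empty = TRUE` (null
#'   baselines).
#' @param reference a `membership_table` computed on the full disease set
#'   with the same model.
#' @param panel the full [interval_panel].
#' @param relevance the [relevance_table()] used for the reference scores.
#' @param model the fitted `traj_clusters` model (frozen centres).
#' @param sample_size participants per evaluation draw.
#' @param n_repeats number of draws.
#' @param seed integer seed.
#' @param allow_empty permit the empty subset.
#' @return one-row data.frame (class `subset_performance`).
#' @export
evaluate_subset <- function(subset, reference, panel, relevance, model,
                            sample_size = 10000, n_repeats = 100, seed = 1,
                            allow_empty = FALSE) {
  if (length(subset) == 0 && !allow_empty)
    stopf("empty subset is only allowed for null baselines")
  bad <- setdiff(subset, rownames(relevance))
  if (length(bad) > 0)
    stopf("subset diseases missing from relevance: %s",
          paste(bad, collapse = ", "))
  subset <- panel$diseases[panel$diseases %in% subset]  # panel order
  scores <- if (length(subset) > 0) {
    multimorbidity_scores(subset_panel(panel, subset),
                          relevance_table(
                            unclass(relevance)[subset, , drop = FALSE],
                            attr(relevance, "provenance") %||% "cohort"))
  } else {
    ends <- panel$grid$interval_ends
    S <- matrix(0, length(panel$participants), length(ends),
                dimnames = list(panel$participants, ends))
    S[!panel$included] <- NA_real_
    attr(S, "interval_ends") <- ends
    S
  }
  pred <- assign_clusters(scores, model)
  compare_memberships(pred, reference, sample_size, n_repeats, seed,
                      n_diseases = length(subset))
}

compare_memberships <- function(pred, reference, sample_size, n_repeats,
                                seed, n_diseases = NA_integer_) {
  stopifnot(nrow(pred) == nrow(reference))
  P1 <- posterior_matrix(pred)
  P0 <- posterior_matrix(reference)
  h1 <- pred$hard_label
  h0 <- reference$hard_label
  n <- nrow(P0)
  with_seed(seed, {
    m <- vapply(seq_len(n_repeats), function(rep_i) {
      idx <- sample.int(n, min(sample_size, n),
                        replace = sample_size > n)
      acc <- mean(h1[idx] == h0[idx])
      recalls <- vapply(unique(h0[idx]), function(cl) {
        sel <- h0[idx] == cl
        mean(h1[idx][sel] == cl)
      }, numeric(1))
      c(acc = acc, bacc = mean(recalls),
        mae = mean(abs(P1[idx, ] - P0[idx, ])),
        mse = mean((P1[idx, ] - P0[idx, ])^2))
    }, numeric(4))
    out <- data.frame(n_diseases = n_diseases,
                      accuracy = mean(m["acc", ]),
                      balanced_accuracy = mean(m["bacc", ]),
                      mae = mean(m["mae", ]),
                      mse = mean(m["mse", ]),
                      n_evaluated = min(sample_size, n),
                      n_repeats = n_repeats)
    class(out) <- c("subset_performance", "data.frame")
    out
  })
}

#' Greedy forward selection of a disease subset
#'
#' Step 1 picks the single disease with the highest reassignment accuracy
#' against the full-set reference; every subsequent step adds the disease
#' with the highest accuracy gain. Ties are broken by disease-code order.
#' Greedy expansion may be suboptimal for a given subset size.
#'
#' @inheritParams evaluate_subset
#' @param diseases candidate pool (defaults to all relevance diseases in
#'   the panel).
#' @param budget number of greedy steps (>= 1).
#' @return list with `order` (codes in selection order) and `curve` (a
#'   `subset_performance` row per step).
#' @export
greedy_select <- function(diseases, reference, panel, relevance, model,
                          budget, sample_size = 10000, n_repeats = 100,
                          seed = 1) {
  if (budget < 1) stopf("budget must be at least 1")
  if (budget > length(diseases)) stopf("budget exceeds the candidate pool")
  diseases <- sort(diseases)
  chosen <- character(0)
  curve <- list()
  for (step in seq_len(budget)) {
    remaining <- setdiff(diseases, chosen)
    perf <- lapply(remaining, function(d)
      evaluate_subset(c(chosen, d), reference, panel, relevance, model,
                      sample_size, n_repeats, seed))
    accs <- vapply(perf, function(p) p$accuracy, numeric(1))
    best <- which.max(accs)  # remaining is sorted: ties -> code order
    chosen <- c(chosen, remaining[best])
    row <- perf[[best]]
    row$step <- step
    row$disease_added <- remaining[best]
    curve[[step]] <- row
  }
  curve <- do.call(rbind, curve)
  class(curve) <- c("subset_performance", "data.frame")
  list(order = chosen, curve = curve)
}

#' Null models for clustering fidelity
#'
#' `kind = "random"` draws membership probability vectors uniformly from
#' the probability simplex (symmetric Dirichlet(1)) and hard-assigns by
#' argmax, so accuracy converges to `1/k` regardless of the reference
#' label distribution. `kind = "uniform"` sets every posterior to `1/k`
#' and breaks the hard-label tie uniformly at random.
#'
#' @inheritParams evaluate_subset
#' @param kind `"random"` or `"uniform"`.
#' @return one-row `subset_performance` data.frame.
#' @export
null_performance <- function(model, reference, kind = c("random", "uniform"),
                             sample_size = 10000, n_repeats = 100,
                             seed = 1) {
  kind <- match.arg(kind)
  k <- model$k
  n <- nrow(reference)
  P0 <- posterior_matrix(reference)
  h0 <- reference$hard_label
  with_seed(seed, {
    m <- vapply(seq_len(n_repeats), function(rep_i) {
      idx <- sample.int(n, min(sample_size, n),
                        replace = sample_size > n)
      nn <- length(idx)
      if (kind == "random") {
        G <- matrix(rexp(nn * k), nn, k)
        P1 <- G / rowSums(G)
        h1 <- max.col(P1, ties.method = "first")
      } else {
        P1 <- matrix(1 / k, nn, k)
        h1 <- sample.int(k, nn, replace = TRUE)
      }
      acc <- mean(h1 == h0[idx])
      recalls <- vapply(unique(h0[idx]), function(cl) {
        sel <- h0[idx] == cl
        mean(h1[sel] == cl)
      }, numeric(1))
      c(acc = acc, bacc = mean(recalls),
        mae = mean(abs(P1 - P0[idx, , drop = FALSE])),
        mse = mean((P1 - P0[idx, , drop = FALSE])^2))
    }, numeric(4))
    out <- data.frame(n_diseases = NA_integer_,
                      accuracy = mean(m["acc", ]),
                      balanced_accuracy = mean(m["bacc", ]),
                      mae = mean(m["mae", ]),
                      mse = mean(m["mse", ]),
                      n_evaluated = min(sample_size, n),
                      n_repeats = n_repeats,
                      kind = kind)
    class(out) <- c("subset_performance", "data.frame")
    out
  })
}
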