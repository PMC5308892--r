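#' Type-I-error calibration of the MI permutation test
#'
#' Simulates neurons whose trial firing rates are drawn independently of
#' condition (Poisson counts at `rate_hz` over a `window_s` trace
#' interval, trials split evenly across two conditions) and runs the
#' mutual-information permutation test on each. Under this null the
#' fraction declared significant at the upper-tail criterion estimates
#' the test's actual size.
#'
#' @param n_neurons simulated neurons.
#' @param n_trials trials per neuron (even; split across two conditions).
#' @param rate_hz Poisson firing rate.
#' @param window_s analysis-window duration (s).
#' @param n_perm label permutations per neuron.
#' @param alpha nominal level of the upper-tail criterion.
#' @param n_bins rate bins for MI.
#' @return list: `rejection_rate`, `p_values`.
#' @export
calibrate_mi_test <- function(n_neurons = 1000, n_trials = 40, rate_hz = 5,
                              window_s = 0.5, n_perm = 1000, alpha = 0.05,
                              n_bins = 10) {
  labels <- factor(rep(c("A", "B"), each = n_trials / 2))
  p <- vapply(seq_len(n_neurons), function(i) {
    rates <- stats::rpois(n_trials, rate_hz * window_s) / window_s
    mi_permutation_test(rates, labels, n_bins = n_bins, n_perm = n_perm)$p
  }, numeric(1))
  list(rejection_rate = mean(p <= alpha), p_values = p)
}

#' Type-I-error calibration of the decoding pipeline
#'
#' Generates datasets whose rate features are statistically independent
#' of their condition labels (standard normal features, four balanced
#' conditions), runs the full decoding procedure and its label-shuffled
#' chance calibration on each, and reports how often raw accuracy exceeds
#' the 5% upper-tail chance cutoff — the pipeline's realized
#' false-positive rate.
#'
#' @param n_datasets independent null datasets.
#' @param n_units feature dimensions (units).
#' @param n_per_condition trials per condition.
#' @param grid SVM hyperparameter grid (a reduced grid keeps the study
#'   tractable; the procedure is otherwise unchanged).
#' @param n_shuffles chance-calibration repetitions per dataset.
#' @param k_folds cross-validation folds.
#' @return list: `rejection_rate`, `per_dataset` (data.frame with raw
#'   accuracy and chance cutoff).
#' @export
calibrate_decoding_null <- function(n_datasets = 100, n_units = 150,
                                    n_per_condition = 20,
                                    grid = svm_grid_reduced(),
                                    n_shuffles = 50, k_folds = 5) {
  labels <- factor(rep(c("ACS_ALONE", "ACS_US", "VCS_ALONE", "VCS_US"),
                       each = n_per_condition))
  res <- lapply(seq_len(n_datasets), function(d) {
    x <- matrix(stats::rnorm(length(labels) * n_units),
                length(labels), n_units)
    run <- decode_once(x, labels, grid = grid, k_folds = k_folds)
    ch <- chance_calibration(x, labels, grid = grid, k_folds = k_folds,
                             n_shuffles = n_shuffles)
    data.frame(dataset = d, raw = run$accuracy, cutoff = ch$cutoff,
               significant = run$accuracy > ch$cutoff)
  })
  per_dataset <- do.call(rbind, res)
  list(rejection_rate = mean(per_dataset$significant),
       per_dataset = per_dataset)
}

#' Type-I-error calibration of the similarity-difference permutation test
#'
#' Builds null ensembles whose binned rates are independent of condition
#' (independent standard normal entries per unit, trial, and bin, on the
#' usual 20/80 trial schedule), applies the population-vector
#' r-difference permutation test in every bin, and reports the rejection
#' rate at `alpha`.
#'
#' @param n_datasets independent null ensembles.
#' @param n_units units per ensemble.
#' @param n_bins time bins per ensemble.
#' @param n_perm permutations per test.
#' @param alpha two-sided level per bin.
#' @return list: `rejection_rate`, `n_tests`, `p_values`.
#' @export
calibrate_similarity_null <- function(n_datasets = 200, n_units = 30,
                                      n_bins = 10, n_perm = 199,
                                      alpha = 0.05) {
  cond <- rep(c("ACS_ALONE", "ACS_US", "VCS_ALONE", "VCS_US"),
              c(20, 80, 20, 80))
  trials <- data.frame(session_id = 1, epoch = 1,
                       trial_index = seq_along(cond), condition = cond,
                       cs_onset_s = seq_along(cond), box_id = 1L)
  ps <- unlist(lapply(seq_len(n_datasets), function(d) {
    tens <- structure(
      array(stats::rnorm(n_units * length(cond) * n_bins),
            dim = c(n_units, length(cond), n_bins)),
      class = c("rate_tensor", "array"),
      window = c(0, n_bins * 50), bin_width = 50,
      normalization = "RAW", trials = trials)
    similarity_difference_permtest(tens, bins = seq_len(n_bins),
                                   n_perm = n_perm, alpha = alpha)$p
  }))
  list(rejection_rate = mean(ps <= alpha), n_tests = length(ps),
       p_values = ps)
}
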