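#' Hyperparameter grid for the RBF-kernel SVM
#'
#' The default is the standard libsvm practice grid, cost 2^(-5..15) and
#' gamma 2^(-15..3) in steps of 2 in the exponent. Rows are ordered by
#' (cost, gamma) ascending; grid search keeps the first row attaining the
#' maximal cross-validated accuracy, so ties break toward the smallest
#' cost, then the smallest gamma.
#'
#' @param cost_exp,gamma_exp exponents of 2.
#' @return data.frame with columns `cost`, `gamma`.
#' @export
svm_grid <- function(cost_exp = seq(-5, 15, 2), gamma_exp = seq(-15, 3, 2)) {
  g <- expand.grid(gamma = 2^gamma_exp, cost = 2^cost_exp)[, c("cost", "gamma")]
  g[order(g$cost, g$gamma), , drop = FALSE]
}

#' A small grid for calibration studies
#'
#' @return data.frame with columns `cost`, `gamma`.
#' @export
svm_grid_reduced <- function() svm_grid(cost_exp = c(0, 5), gamma_exp = -7)

## stratified fold assignment: balanced within class
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

## grid search by k-fold CV; returns best row of the grid
grid_search_cv <- function(x, y, grid, k = 5) {
  fold <- stratified_folds(y, k)
  best <- NULL; best_acc <- -1
  for (i in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = grid$cost[i], gamma = grid$gamma[i],
                      scale = FALSE)
      correct <- correct +
        sum(stats::predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }
    acc <- correct / length(y)
    if (acc > best_acc) { best_acc <- acc; best <- grid[i, ] }
  }
  list(cost = best$cost, gamma = best$gamma, cv_accuracy = best_acc)
}

#' One population-decoding run
#'
#' Implements the full single-run decoding procedure: sample
#' `n_train + n_test` trials per condition without replacement, divide
#' each unit's rates by its maximum across the sampled trials (a unit
#' silent in all sampled trials contributes zeros), split the sample into
#' per-condition train/test halves, select RBF-SVM hyperparameters by
#' grid search with `k`-fold cross-validation on the training half, refit
#' on the training half, and score the held-out half.
#'
#' @param features trials x units matrix of rate features (e.g. the mean
#'   rate over the first 200 ms after CS offset).
#' @param labels condition label per trial (coerced to factor).
#' @param n_train,n_test trials per condition in the train and test
#'   halves.
#' @param grid hyperparameter grid, see [svm_grid()].
#' @param k_folds cross-validation folds for grid search.
#' @return object of class `decoding_run`: `accuracy`, `confusion`
#'   (rows = true condition, counts), `cost`, `gamma`, `sampled`
#'   (trial ids), `norm_constants`, `predicted`, `truth`.
#' @export
decode_once <- function(features, labels, n_train = 10, n_test = 10,
                        grid = svm_grid(), k_folds = 5) {
  labels <- factor(labels)
  need <- n_train + n_test
  for (cl in levels(labels))
    if (sum(labels == cl) < need)
      ec_input_error("condition %s has %d trials; %d required",
                     cl, sum(labels == cl), need)
  sampled <- unlist(lapply(levels(labels), function(cl)
    sample(which(labels == cl), need)))
  x <- features[sampled, , drop = FALSE]
  y <- droplevels(labels[sampled])
  # per-unit max normalization over the sampled trials
  mx <- apply(abs(x), 2, max)
  x <- sweep(x, 2, ifelse(mx == 0, 1, mx), "/")
  # per-condition disjoint train/test split
  train <- unlist(lapply(levels(y), function(cl)
    sample(which(y == cl), n_train)))
  test <- setdiff(seq_along(y), train)
  gs <- grid_search_cv(x[train, , drop = FALSE], y[train], grid, k_folds)
  model <- e1071::svm(x[train, , drop = FALSE], y[train], kernel = "radial",
                      cost = gs$cost, gamma = gs$gamma, scale = FALSE)
  pred <- stats::predict(model, x[test, , drop = FALSE])
  truth <- y[test]
  confusion <- table(truth = truth, predicted = pred)
  structure(list(accuracy = mean(pred == truth),
                 confusion = confusion,
                 cost = gs$cost, gamma = gs$gamma,
                 cv_accuracy = gs$cv_accuracy,
                 sampled = sampled, norm_constants = mx,
                 predicted = pred, truth = truth),
            class = "decoding_run")
}

#' @export
print.decoding_run <- function(x, ...) {
  cat(sprintf("decoding run: accuracy %.3f (cost %g, gamma %g)\n",
              x$accuracy, x$cost, x$gamma))
  print(x$confusion)
  invisible(x)
}

#' Chance-performance distribution of the decoder
#'
#' Repeats the complete decoding procedure (including trial sampling,
#' normalization, and grid search) `n_shuffles` times with condition
#' labels randomly re-assigned to trials; each repetition scores its
#' held-out readouts, yielding the chance accuracy distribution against
#' which raw accuracy is judged at the 5% upper tail.
#'
#' Two cutoff constructions are emitted: `"per_repetition"` (default) is
#' the 95th percentile of the `n_shuffles` repetition accuracies;
#' `"pooled"` treats all pooled held-out readouts as Bernoulli draws and
#' takes the 95th percentile of the implied binomial accuracy
#' distribution.
#'
#' @inheritParams decode_once
#' @param n_shuffles label-shuffled repetitions.
#' @param prob upper-tail mass for the cutoff.
#' @return object of class `chance_distribution`: `accuracies`,
#'   `n_readouts`, `cutoff` (the default construction),
#'   `cutoff_per_repetition`, `cutoff_pooled`.
#' @export
chance_calibration <- function(features, labels, n_train = 10, n_test = 10,
                               grid = svm_grid(), k_folds = 5,
                               n_shuffles = 50, prob = 0.95) {
  labels <- factor(labels)
  acc <- numeric(n_shuffles)
  hits <- 0L
  n_readout <- n_test * nlevels(labels)
  for (i in seq_len(n_shuffles)) {
    shuffled <- sample(labels)
    run <- decode_once(features, shuffled, n_train, n_test, grid, k_folds)
    acc[i] <- run$accuracy
    hits <- hits + sum(run$predicted == run$truth)
  }
  k_idx <- max(1L, ceiling(prob * n_shuffles))
  cutoff_rep <- sort(acc)[k_idx]
  phat <- hits / (n_shuffles * n_readout)
  cutoff_pooled <- stats::qbinom(prob, n_readout, phat) / n_readout
  structure(list(accuracies = acc, n_readouts = n_shuffles * n_readout,
                 cutoff = cutoff_rep,
                 cutoff_per_repetition = cutoff_rep,
                 cutoff_pooled = cutoff_pooled,
                 prob = prob),
            class = "chance_distribution")
}

## collapse labels for a binary decoding dimension; "fourway" is identity
apply_labeling <- function(labels, labeling) {
  switch(labeling,
         fourway = factor(labels),
         relational_binary = collapse_labels(labels, "relational"),
         physical_binary = collapse_labels(labels, "physical"),
         box_binary = collapse_labels(labels, "box"),
         ec_config_error("unknown labeling '%s'", labeling))
}

#' Stage-wise relative decoding accuracy over neuron sets
#'
#' For each of `n_sets` random samples of `n_neurons` units, assembles a
#' pseudo-population (trial order re-drawn uniformly at random within each
#' condition, independently per unit, since units come from different
#' sessions and noise correlations are ignored), runs [decode_once()] and
#' [chance_calibration()], and reports the relative accuracy (raw minus
#' the chance cutoff). Trials are always sampled per original (four-way)
#' condition, then collapsed onto the requested labeling, preserving
#' balance across modalities.
#'
#' @param rates units x trials matrix of rate features.
#' @param labels four-way condition label per trial.
#' @param labeling `"fourway"`, `"relational_binary"`, `"physical_binary"`,
#'   or `"box_binary"`.
#' @param n_sets number of neuron sets.
#' @param n_neurons units per set; if the pool is smaller, all units are
#'   used with a warning.
#' @inheritParams chance_calibration
#' @return object of class `decoding_result`: `per_set` data.frame
#'   (set, raw, chance_cutoff, relative), `mean_confusion` (proportions),
#'   `labeling`, `n_neurons`, `mean_relative`, `sem_relative`.
#' @export
decode_stage <- function(rates, labels, labeling = "fourway",
                         n_sets = 20, n_neurons = 150,
                         n_train = 10, n_test = 10,
                         grid = svm_grid(), k_folds = 5,
                         n_shuffles = 50) {
  labels <- factor(labels)
  pool <- nrow(rates)
  if (pool < n_neurons) {
    ec_warn("ec_small_pool",
            "unit pool (%d) smaller than n_neurons (%d); using all units",
            pool, n_neurons)
    n_neurons <- pool
  }
  conds <- levels(labels)
  per_set <- vector("list", n_sets)
  conf_sum <- NULL
  for (s in seq_len(n_sets)) {
    units <- sample.int(pool, n_neurons)
    # pseudo-population: re-pair trials within condition per unit
    feat <- matrix(0, length(labels), n_neurons)
    for (j in seq_along(units)) {
      for (cl in conds) {
        idx <- which(labels == cl)
        feat[idx, j] <- rates[units[j], sample(idx)]
      }
    }
    y <- apply_labeling(labels, labeling)
    # sample per original (four-way) condition so binary collapses stay
    # balanced across modalities, then decode on the collapsed labels
    sampled <- unlist(lapply(conds, function(cl)
      sample(which(labels == cl), n_train + n_test)))
    ys <- droplevels(y[sampled])
    ntr <- n_train * length(conds) / nlevels(ys)
    nte <- n_test * length(conds) / nlevels(ys)
    run <- decode_once(feat[sampled, , drop = FALSE], ys,
                       n_train = ntr, n_test = nte,
                       grid = grid, k_folds = k_folds)
    chance <- chance_calibration(feat[sampled, , drop = FALSE], ys,
                                 n_train = ntr, n_test = nte,
                                 grid = grid, k_folds = k_folds,
                                 n_shuffles = n_shuffles)
    per_set[[s]] <- data.frame(set = s, raw = run$accuracy,
                               chance_cutoff = chance$cutoff,
                               relative = run$accuracy - chance$cutoff)
    cp <- prop.table(run$confusion, 1)
    conf_sum <- if (is.null(conf_sum)) cp else conf_sum + cp
  }
  per_set <- do.call(rbind, per_set)
  structure(list(per_set = per_set,
                 mean_confusion = conf_sum / n_sets,
                 labeling = labeling, n_neurons = n_neurons,
                 n_sets = n_sets,
                 mean_relative = mean(per_set$relative),
                 sem_relative = stats::sd(per_set$relative) / sqrt(n_sets)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "decoding (%s, %d neurons x %d sets): relative accuracy %.3f +/- %.3f\n",
    x$labeling, x$n_neurons, x$n_sets, x$mean_relative, x$sem_relative))
  invisible(x)
}

#' Decoding-accuracy sweeps over bin size, window position, and ensemble size
#'
#' Re-runs [decode_once()] while varying the feature construction: the
#' temporal bin (size and position of the rate window relative to CS
#' onset) and the number of units included. Chance cutoffs come from
#' [chance_calibration()] with the same settings.
#'
#' @param spikes a `spike_train_set`.
#' @param trial_table its trial table (single session or stage pool).
#' @param windows list of c(start, end) ms windows to evaluate.
#' @param n_neurons_seq ensemble sizes to evaluate (at the first window).
#' @param n_repeats decoding repeats per setting.
#' @inheritParams chance_calibration
#' @return data.frame: `sweep` ("window" or "n_neurons"), `win_start`,
#'   `win_end`, `n_neurons`, `accuracy` (mean over repeats), `sd`,
#'   `chance_cutoff`.
#' @export
sweep_parameters <- function(spikes, trial_table,
                             windows = list(c(100, 300)),
                             n_neurons_seq = NULL,
                             n_repeats = 5,
                             n_train = 10, n_test = 10,
                             grid = svm_grid_reduced(), k_folds = 5,
                             n_shuffles = 20) {
  labels <- factor(trial_table$condition)
  rows <- list()
  for (w in windows) {
    rates <- t(trial_window_rates(spikes, trial_table, window = w))
    acc <- vapply(seq_len(n_repeats), function(i)
      decode_once(rates, labels, n_train, n_test, grid, k_folds)$accuracy,
      numeric(1))
    chance <- chance_calibration(rates, labels, n_train, n_test, grid,
                                 k_folds, n_shuffles = n_shuffles)
    rows[[length(rows) + 1]] <- data.frame(
      sweep = "window", win_start = w[1], win_end = w[2],
      n_neurons = ncol(rates), accuracy = mean(acc), sd = stats::sd(acc),
      chance_cutoff = chance$cutoff)
  }
  if (!is.null(n_neurons_seq)) {
    w <- windows[[1]]
    rates_all <- t(trial_window_rates(spikes, trial_table, window = w))
    for (nn in n_neurons_seq) {
      nn <- min(nn, ncol(rates_all))
      acc <- vapply(seq_len(n_repeats), function(i) {
        u <- sample.int(ncol(rates_all), nn)
        decode_once(rates_all[, u, drop = FALSE], labels,
                    n_train, n_test, grid, k_folds)$accuracy
      }, numeric(1))
      u <- sample.int(ncol(rates_all), nn)
      chance <- chance_calibration(rates_all[, u, drop = FALSE], labels,
                                   n_train, n_test, grid, k_folds,
                                   n_shuffles = n_shuffles)
      rows[[length(rows) + 1]] <- data.frame(
        sweep = "n_neurons", win_start = w[1], win_end = w[2],
        n_neurons = nn, accuracy = mean(acc), sd = stats::sd(acc),
        chance_cutoff = chance$cutoff)
    }
  }
  do.call(rbind, rows)
}
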