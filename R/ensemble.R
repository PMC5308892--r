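#' Pearson similarity between two population vectors
#'
#' @param a,b numeric vectors over the same units, length >= 3.
#' @return Pearson r, or NA (with a warning) if either vector has zero
#'   variance.
#' @export
pv_similarity <- function(a, b) {
  if (length(a) != length(b))
    ec_input_error("population vectors differ in length")
  if (length(a) < 3)
    ec_input_error("population vectors need >= 3 units")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    ec_warn("ec_degenerate_r", "zero variance population vector; r undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Per-condition mean population matrices
#'
#' Averages a rate tensor over trials within each condition and sorts
#' units by their mean trace-interval rate in the reference condition,
#' descending (the display order of the population matrices).
#'
#' @param tensor a `rate_tensor`.
#' @param sort_condition condition whose trace-window response defines the
#'   unit order (NULL keeps the tensor order).
#' @param trace_window window (ms) used for sorting.
#' @return named list of unit x bin matrices, identical unit order across
#'   conditions; attribute `unit_order`.
#' @export
population_matrices <- function(tensor, sort_condition = "ACS_US",
                                trace_window = c(100, 600)) {
  trials <- attr(tensor, "trials")
  conds <- unique(trials$condition)
  n_bins <- dim(tensor)[3]
  mats <- lapply(conds, function(cc) {
    idx <- which(trials$condition == cc)
    m <- apply(tensor[, idx, , drop = FALSE], c(1, 3), mean)
    dimnames(m) <- list(dimnames(tensor)[[1]], NULL)
    m
  })
  names(mats) <- conds
  ord <- seq_len(dim(tensor)[1])
  if (!is.null(sort_condition)) {
    if (!sort_condition %in% conds)
      ec_config_error("sort condition %s absent from trials", sort_condition)
    w <- attr(tensor, "window")
    bw <- attr(tensor, "bin_width")
    bins <- which(seq(w[1], w[2] - bw, by = bw) >= trace_window[1] &
                    seq(w[1], w[2] - bw, by = bw) < trace_window[2])
    ord <- order(rowMeans(mats[[sort_condition]][, bins, drop = FALSE]),
                 decreasing = TRUE)
    mats <- lapply(mats, function(m) m[ord, , drop = FALSE])
  }
  attr(mats, "unit_order") <- ord
  mats
}

## column-wise Pearson r between two matrices of matched columns
colwise_cor <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2) * colSums(B^2))
  ifelse(den == 0, NA_real_, num / den)
}

## bin indices of the tensor covering [lo, hi) ms
tensor_bins <- function(tensor, lo, hi) {
  w <- attr(tensor, "window"); bw <- attr(tensor, "bin_width")
  starts <- seq(w[1], w[2] - bw, by = bw)
  which(starts >= lo & starts < hi)
}

#' Permutation test for a difference in population-vector similarity
#'
#' For each time bin, computes the Pearson r between condition-mean
#' population vectors of `pair1` (by default the relational pair, ACS-US
#' vs VCS-US) and of `pair2` (the physical pair, ACS-US vs ACS-alone), and
#' tests their difference against a null built by randomly re-assigning
#' the pooled trials of all involved conditions to conditions (relative
#' trial counts held constant) in a single shared re-labeling, then
#' recomputing both r values and their difference, `n_perm` times. The
#' shared re-labeling preserves the dependence between the two pair
#' similarities through their common condition, which the observed
#' difference also carries; shuffling the pairs independently would
#' inflate the null variance and make the test conservative. The
#' difference is judged at `alpha` split equally across the two tails,
#' with the `(b + 1) / (n_perm + 1)` p-value convention. The default
#' `alpha = 0.05 / 10` Bonferroni-adjusts for the ten 50 ms bins covering
#' 0-500 ms after CS onset.
#'
#' @param tensor a normalized `rate_tensor` (normalization constants are
#'   held fixed under permutation).
#' @param pair1,pair2 character(2) of condition labels.
#' @param bins tensor bin indices to test; default the bins covering
#'   \[0, 500) ms.
#' @param n_perm number of permutations (>= 100; coarser resolution cannot
#'   resolve the Bonferroni-adjusted tails).
#' @param alpha total two-sided significance level per bin.
#' @return data.frame per bin: `bin`, `time_ms` (bin start),
#'   `r_pair1`, `r_pair2`, `delta` (r1 - r2), `p` (two-sided permutation),
#'   `significant`.
#' @export
similarity_difference_permtest <- function(tensor,
                                           pair1 = c("ACS_US", "VCS_US"),
                                           pair2 = c("ACS_US", "ACS_ALONE"),
                                           bins = NULL,
                                           n_perm = 1000,
                                           alpha = 0.05 / 10) {
  if (n_perm < 100)
    ec_config_error("n_perm = %d too coarse for tail resolution; use >= 100",
                    n_perm)
  trials <- attr(tensor, "trials")
  if (is.null(bins)) bins <- tensor_bins(tensor, 0, 500)
  w <- attr(tensor, "window"); bw <- attr(tensor, "bin_width")

  conds <- unique(c(pair1, pair2))
  pool <- which(trials$condition %in% conds)
  lab <- trials$condition[pool]
  n_c <- table(factor(lab, levels = conds))
  if (any(n_c == 0))
    ec_config_error("condition(s) without trials: %s",
                    paste(conds[n_c == 0], collapse = ", "))
  npool <- length(pool)

  # one shared re-labeling per permutation: weight matrix per condition
  # (pool x n_perm) averaging the trials assigned to that condition
  W <- lapply(conds, function(cc) matrix(0, npool, n_perm))
  names(W) <- conds
  bounds <- cumsum(c(0, n_c))
  for (k in seq_len(n_perm)) {
    perm <- sample.int(npool)
    for (ci in seq_along(conds)) {
      rows <- perm[(bounds[ci] + 1):bounds[ci + 1]]
      W[[ci]][rows, k] <- 1 / n_c[ci]
    }
  }

  out <- lapply(bins, function(b) {
    X <- tensor[, pool, b, drop = TRUE]
    m_obs <- lapply(conds, function(cc)
      rowMeans(X[, lab == cc, drop = FALSE]))
    names(m_obs) <- conds
    r1 <- pv_similarity(m_obs[[pair1[1]]], m_obs[[pair1[2]]])
    r2 <- pv_similarity(m_obs[[pair2[1]]], m_obs[[pair2[2]]])
    delta <- r1 - r2
    M <- lapply(conds, function(cc) X %*% W[[cc]])
    names(M) <- conds
    null1 <- colwise_cor(M[[pair1[1]]], M[[pair1[2]]])
    null2 <- colwise_cor(M[[pair2[1]]], M[[pair2[2]]])
    null <- null1 - null2
    null <- null[is.finite(null)]
    if (is.na(delta) || length(null) < 100) {
      p <- NA_real_
    } else {
      p_up <- (sum(null >= delta) + 1) / (length(null) + 1)
      p_lo <- (sum(null <= delta) + 1) / (length(null) + 1)
      p <- min(1, 2 * min(p_up, p_lo))
    }
    data.frame(bin = b, time_ms = w[1] + (b - 1) * bw,
               r_pair1 = r1, r_pair2 = r2, delta = delta, p = p,
               significant = !is.na(p) & p <= alpha)
  })
  out <- do.call(rbind, out)
  attr(out, "pair1") <- pair1
  attr(out, "pair2") <- pair2
  attr(out, "alpha") <- alpha
  out
}

#' Trial-by-trial correlation with a template population vector
#'
#' Builds per-trial population vectors (mean rate of every unit over the
#' trace interval), defines a template as the average vector over the
#' 10th-80th trials of the template condition, and correlates every
#' trial's vector with the template. Template-member trials are included
#' in the comparison (set `leave_one_out = TRUE` to exclude each template
#' trial from its own template).
#'
#' @param rates units x trials matrix (e.g. [trial_window_rates()] over
#'   \[100, 600) ms).
#' @param conditions condition label per trial.
#' @param template_condition condition defining the template.
#' @param template_range within-condition trial range averaged into the
#'   template.
#' @param ci `"fisher"` (Fisher z interval over units) or `"bootstrap"`
#'   (unit resampling).
#' @param conf confidence level.
#' @param n_boot bootstrap replicates.
#' @param leave_one_out exclude each template trial from its own template.
#' @return data.frame: `trial`, `condition`, `r`, `ci_lo`, `ci_hi`;
#'   attribute `ci_method`.
#' @export
template_correlation <- function(rates, conditions,
                                 template_condition = "ACS_US",
                                 template_range = c(10, 80),
                                 ci = c("fisher", "bootstrap"),
                                 conf = 0.95, n_boot = 200,
                                 leave_one_out = FALSE) {
  ci <- match.arg(ci)
  n_units <- nrow(rates); n_tr <- ncol(rates)
  if (length(conditions) != n_tr)
    ec_input_error("conditions length must match trial count")
  cond_idx <- which(conditions == template_condition)
  if (length(cond_idx) < template_range[2])
    ec_config_error("only %d %s trials; template needs trials %d-%d",
                    length(cond_idx), template_condition,
                    template_range[1], template_range[2])
  tmpl_trials <- cond_idx[template_range[1]:template_range[2]]
  tmpl <- rowMeans(rates[, tmpl_trials, drop = FALSE])
  z_half <- stats::qnorm(1 - (1 - conf) / 2)
  res <- lapply(seq_len(n_tr), function(t) {
    tm <- tmpl
    if (leave_one_out && t %in% tmpl_trials)
      tm <- rowMeans(rates[, setdiff(tmpl_trials, t), drop = FALSE])
    r <- if (stats::sd(tm) == 0 || stats::sd(rates[, t]) == 0) {
      ec_warn("ec_degenerate_r", "zero variance in trial %d; r undefined", t)
      NA_real_
    } else stats::cor(tm, rates[, t])
    if (is.na(r)) {
      lo <- hi <- NA_real_
    } else if (ci == "fisher") {
      z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
      se <- 1 / sqrt(n_units - 3)
      lo <- tanh(z - z_half * se); hi <- tanh(z + z_half * se)
    } else {
      rb <- vapply(seq_len(n_boot), function(b) {
        u <- sample.int(n_units, replace = TRUE)
        if (stats::sd(tm[u]) == 0 || stats::sd(rates[u, t]) == 0) NA_real_
        else stats::cor(tm[u], rates[u, t])
      }, numeric(1))
      qs <- stats::quantile(rb, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                            na.rm = TRUE, names = FALSE)
      lo <- qs[1]; hi <- qs[2]
    }
    data.frame(trial = t, condition = conditions[t], r = r,
               ci_lo = lo, ci_hi = hi)
  })
  out <- do.call(rbind, res)
  attr(out, "ci_method") <- ci
  attr(out, "template_trials") <- tmpl_trials
  out
}
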