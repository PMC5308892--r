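#' Differentiation index between two mean firing rates
#'
#' `(Fr1 - Fr2) / (Fr1 + Fr2)`: the normalized contrast of mean
#' trace-interval rates between two condition groups, the magnitude
#' measure of single-neuron selectivity. For the relational contrast,
#' Fr1 is the mean rate on CS-alone trials and Fr2 on CS-US paired
#' trials; for the physical contrast, Fr1 is the auditory-CS and Fr2 the
#' visual-CS mean rate. Downstream comparisons use `abs()` of the index.
#'
#' @param fr1,fr2 mean rates (Hz), >= 0; vectorized.
#' @return signed index in \[-1, 1\]; NA (with a warning) where both
#'   rates are zero.
#' @export
differentiation_index <- function(fr1, fr2) {
  if (any(fr1 < 0 | fr2 < 0)) ec_input_error("firing rates must be >= 0")
  both_zero <- fr1 + fr2 == 0
  if (any(both_zero))
    ec_warn("ec_undefined_index",
            "differentiation index undefined where both rates are 0")
  ifelse(both_zero, NA_real_, (fr1 - fr2) / (fr1 + fr2))
}

## Discretize trial rates into n_bins equal-width bins over the observed
## range (last bin right-closed). A constant rate occupies a single bin.
rate_bins <- function(rates, n_bins = 10) {
  rng <- range(rates)
  if (rng[1] == rng[2]) return(rep(1L, length(rates)))
  b <- floor((rates - rng[1]) / diff(rng) * n_bins) + 1L
  pmin(b, n_bins)
}

## plug-in MI (bits) from a contingency table of counts
mi_from_table <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  pi_ <- rowSums(p); pj <- colSums(p)
  terms <- p * log2(p / outer(pi_, pj))
  sum(terms[p > 0])
}

#' Mutual information between condition and discretized firing rate
#'
#' The plug-in estimate of `sum_ij P(i,j) log2(P(i,j) / (P(i) P(j)))`,
#' with trial firing rates discretized into `n_bins` equal-width bins
#' over the neuron's observed rate range. Quantifies the consistency of
#' differential firing; reported in bits (the base cancels from
#' normalized values and permutation p-values).
#'
#' @param rates trial firing rates (Hz) of one neuron.
#' @param labels condition label per trial (>= 2 conditions).
#' @param n_bins number of rate bins.
#' @return MI in bits (0 when the rate is constant).
#' @export
mutual_information <- function(rates, labels, n_bins = 10) {
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    ec_input_error("mutual information needs >= 2 conditions")
  if (any(table(labels) < 2))
    ec_input_error("each condition needs >= 2 trials")
  bins <- rate_bins(rates, n_bins)
  mi_from_table(table(labels, bins))
}

#' Permutation significance of a selectivity statistic
#'
#' Builds the chance distribution of `statistic(rates, labels)` by
#' recomputing it under `n_perm` random re-assignments of condition
#' labels to trials. The upper-tail p-value uses the
#' `(b + 1) / (n_perm + 1)` convention (never exactly zero), and the
#' statistic is additionally normalized against the null as
#' `(observed - mean(null)) / sd(null)`.
#'
#' @param rates trial rates of one neuron.
#' @param labels condition label per trial.
#' @param statistic function(rates, labels) returning a scalar; default
#'   [mutual_information()].
#' @param n_perm permutations.
#' @param tail `"upper"` (selectivity statistics are one-sided).
#' @return list: `observed`, `p`, `normalized` (NA, flagged via warning,
#'   when the null SD is zero), `null` (the permutation values).
#' @export
permutation_selectivity_test <- function(rates, labels,
                                         statistic = mutual_information,
                                         n_perm = 1000,
                                         tail = "upper") {
  stopifnot(identical(tail, "upper"))
  labels <- factor(labels)
  obs <- statistic(rates, labels)
  null <- vapply(seq_len(n_perm),
                 function(i) statistic(rates, sample(labels)),
                 numeric(1))
  p <- (sum(null >= obs) + 1) / (n_perm + 1)
  s <- stats::sd(null)
  norm <- if (is.na(s) || s == 0) {
    ec_warn("ec_zero_null_sd", "null SD is zero; normalized value undefined")
    NA_real_
  } else (obs - mean(null)) / s
  list(observed = obs, p = p, normalized = norm, null = null)
}

#' Fast mutual-information permutation test
#'
#' Identical inference to [permutation_selectivity_test()] with
#' `statistic = mutual_information`, vectorized over permutations: rate
#' bins are fixed under label shuffling, so the null MI values reduce to
#' per-condition bin-count matrices obtained by matrix products with a
#' permutation indicator matrix.
#'
#' @inheritParams mutual_information
#' @param n_perm permutations.
#' @return list: `observed`, `p`, `normalized`, `null`.
#' @export
mi_permutation_test <- function(rates, labels, n_bins = 10, n_perm = 1000) {
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    ec_input_error("mutual information needs >= 2 conditions")
  n <- length(rates)
  bins <- rate_bins(rates, n_bins)
  B <- matrix(0, n, n_bins)
  B[cbind(seq_len(n), bins)] <- 1
  obs <- mi_from_table(table(labels, factor(bins, levels = seq_len(n_bins))))
  pj <- colSums(B) / n                       # bin marginal, shuffle-invariant
  n_per <- table(labels)
  pi_ <- as.numeric(n_per) / n               # condition marginal, invariant
  # permuted label matrix: each row of P is a permutation of labels
  P <- t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  mi_null <- numeric(n_perm)
  lab_int <- as.integer(labels)
  for (ci in seq_len(nlevels(labels))) {
    member <- matrix(as.numeric(lab_int[as.vector(P)] == ci),
                     n_perm, n)            # n_perm x trials indicator
    counts <- member %*% B                 # n_perm x bins
    pij <- counts / n
    denom <- pi_[ci] * matrix(pj, n_perm, n_bins, byrow = TRUE)
    term <- pij * log2(pij / denom)
    term[pij == 0] <- 0
    mi_null <- mi_null + rowSums(term)
  }
  p <- (sum(mi_null >= obs) + 1) / (n_perm + 1)
  s <- stats::sd(mi_null)
  norm <- if (is.na(s) || s == 0) {
    ec_warn("ec_zero_null_sd", "null SD is zero; normalized value undefined")
    NA_real_
  } else (obs - mean(mi_null)) / s
  list(observed = obs, p = p, normalized = norm, null = mi_null)
}

#' Fast permutation test for a two-group mean-rate difference
#'
#' Upper-tail permutation test on `|mean(group1) - mean(group2)|`,
#' vectorized over permutations; used for condition contrasts and
#' responsiveness.
#'
#' @param rates trial rates.
#' @param group1 logical vector marking group-1 trials.
#' @param n_perm permutations.
#' @return list: `observed`, `p`, `normalized`, `null`.
#' @export
rate_diff_perm_test <- function(rates, group1, n_perm = 1000) {
  n <- length(rates); n1 <- sum(group1); n2 <- n - n1
  if (n1 == 0 || n2 == 0) ec_input_error("both groups need trials")
  obs <- abs(mean(rates[group1]) - mean(rates[!group1]))
  tot <- sum(rates)
  s1 <- vapply(seq_len(n_perm),
               function(i) sum(rates[sample.int(n, n1)]), numeric(1))
  null <- abs(s1 / n1 - (tot - s1) / n2)
  p <- (sum(null >= obs) + 1) / (n_perm + 1)
  s <- stats::sd(null)
  norm <- if (is.na(s) || s == 0) NA_real_ else (obs - mean(null)) / s
  list(observed = obs, p = p, normalized = norm, null = null)
}

#' Task-responsiveness of one unit
#'
#' Tests, per condition, whether the unit's firing rate over the CS +
#' trace window differs from equal-duration inter-trial-interval windows
#' placed 6 s before each CS onset (at least 5 s from any stimulus), via
#' [rate_diff_perm_test()] at `alpha` per condition. A unit is responsive
#' when at least one condition rejects.
#'
#' @param unit_ts spike timestamps (s).
#' @param trial_table single-session trial table.
#' @param window CS-relative analysis window (ms).
#' @param iti_offset_s seconds before CS onset where the matched ITI
#'   window starts.
#' @param n_perm permutations.
#' @param alpha per-condition level.
#' @return list: `responsive`, `p_by_condition` (named vector).
#' @export
responsiveness_test <- function(unit_ts, trial_table, window = c(0, 600),
                                iti_offset_s = 6, n_perm = 1000,
                                alpha = 0.05) {
  win_s <- window / 1000
  dur <- diff(win_s)
  rate_in <- function(onsets) {
    vapply(onsets, function(t0)
      sum(unit_ts >= t0 & unit_ts < t0 + dur) / dur, numeric(1))
  }
  conds <- unique(trial_table$condition)
  p <- vapply(conds, function(cc) {
    tt <- trial_table[trial_table$condition == cc, ]
    stim <- rate_in(tt$cs_onset_s + win_s[1])
    iti <- rate_in(tt$cs_onset_s - iti_offset_s)
    rate_diff_perm_test(c(stim, iti),
                        rep(c(TRUE, FALSE), each = nrow(tt)),
                        n_perm = n_perm)$p
  }, numeric(1))
  names(p) <- conds
  list(responsive = any(p <= alpha), p_by_condition = p)
}

#' Categorize a neuron from its contrast significances
#'
#' RELATIONAL when only the relational contrast (CS-alone vs CS-US,
#' regardless of modality) is significant; PHYSICAL when only the
#' modality contrast is; CONJUNCTIVE when both are (default rule) or,
#' under `rule = "one_vs_rest"`, when a single condition differs from
#' the other three; NONSELECTIVE otherwise. Only responsive neurons are
#' categorized (NA for unresponsive ones).
#'
#' @param p_relational,p_physical permutation p-values of the two
#'   contrasts.
#' @param responsive logical.
#' @param alpha significance level.
#' @param rule conjunction rule, `"both"` or `"one_vs_rest"`.
#' @param p_one_vs_rest smallest one-vs-rest contrast p-value (only used
#'   by `rule = "one_vs_rest"`).
#' @return factor level among RELATIONAL, PHYSICAL, CONJUNCTIVE,
#'   NONSELECTIVE, or NA if not responsive.
#' @export
classify_neuron <- function(p_relational, p_physical, responsive,
                            alpha = 0.05, rule = c("both", "one_vs_rest"),
                            p_one_vs_rest = NULL) {
  rule <- match.arg(rule)
  if (is.na(p_relational) || is.na(p_physical))
    ec_input_error("both contrast p-values are required")
  lv <- c("RELATIONAL", "PHYSICAL", "CONJUNCTIVE", "NONSELECTIVE")
  if (!isTRUE(responsive)) return(factor(NA, levels = lv))
  rel <- p_relational <= alpha
  phy <- p_physical <= alpha
  conj <- if (rule == "both") rel && phy
  else !is.null(p_one_vs_rest) && p_one_vs_rest <= alpha && !(xor(rel, phy))
  out <- if (conj) "CONJUNCTIVE"
  else if (rel && phy) "CONJUNCTIVE"
  else if (rel) "RELATIONAL"
  else if (phy) "PHYSICAL"
  else "NONSELECTIVE"
  factor(out, levels = lv)
}

#' Full selectivity profile of every unit
#'
#' Computes, per unit: mean trace-interval rates of the contrasted
#' condition groups, signed and absolute differentiation indices for the
#' relational and physical contrasts, mutual information (raw,
#' null-normalized, and permutation p) for both contrasts, mean-rate
#' contrast p-values, responsiveness, and category.
#'
#' @param spikes a `spike_train_set` (typically QC-filtered).
#' @param trial_table trial table of the units' sessions.
#' @param window trace-interval window (ms, CS-relative) for rates.
#' @param n_perm permutations for every test.
#' @param alpha significance level for contrasts and responsiveness.
#' @param n_bins rate bins for mutual information.
#' @return data.frame, one row per unit.
#' @export
selectivity_profiles <- function(spikes, trial_table, window = c(100, 600),
                                 n_perm = 1000, alpha = 0.05, n_bins = 10) {
  stopifnot(inherits(spikes, "spike_train_set"))
  rates <- trial_window_rates(spikes, trial_table, window = window)
  out <- lapply(seq_len(nrow(rates)), function(u) {
    uid <- rownames(rates)[u]
    sess <- spikes$manifest$session_id[spikes$manifest$unit_id == uid][1]
    tt_rows <- which(trial_table$session_id == sess)
    r <- rates[u, tt_rows]
    cond <- trial_table$condition[tt_rows]
    alone <- !is_paired_label(cond)
    aud <- substr(cond, 1, 1) == "A"
    fr_alone <- mean(r[alone]); fr_paired <- mean(r[!alone])
    fr_aud <- mean(r[aud]); fr_vis <- mean(r[!aud])
    idx_rel <- differentiation_index(fr_alone, fr_paired)
    idx_phys <- differentiation_index(fr_aud, fr_vis)
    rel_lab <- factor(ifelse(alone, "ALONE", "PAIRED"))
    phys_lab <- factor(ifelse(aud, "ACS", "VCS"))
    mi_rel <- mi_permutation_test(r, rel_lab, n_bins, n_perm)
    mi_phys <- mi_permutation_test(r, phys_lab, n_bins, n_perm)
    d_rel <- rate_diff_perm_test(r, alone, n_perm)
    d_phys <- rate_diff_perm_test(r, aud, n_perm)
    resp <- responsiveness_test(spikes$units[[uid]],
                                trial_table[tt_rows, ],
                                window = c(0, window[2]),
                                n_perm = n_perm, alpha = alpha)
    data.frame(unit_id = uid, session_id = sess,
               fr_alone = fr_alone, fr_paired = fr_paired,
               fr_acs = fr_aud, fr_vcs = fr_vis,
               idx_rel = idx_rel, idx_phys = idx_phys,
               abs_idx_rel = abs(idx_rel), abs_idx_phys = abs(idx_phys),
               mi_rel = mi_rel$observed, mi_phys = mi_phys$observed,
               mi_rel_norm = mi_rel$normalized,
               mi_phys_norm = mi_phys$normalized,
               mi_rel_p = mi_rel$p, mi_phys_p = mi_phys$p,
               p_rel = d_rel$p, p_phys = d_phys$p,
               responsive = resp$responsive,
               category = as.character(
                 classify_neuron(d_rel$p, d_phys$p, resp$responsive,
                                 alpha = alpha)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
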