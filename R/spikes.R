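#' Unit quality control
#'
#' A unit passes when fewer than 1% of its inter-spike intervals fall
#' within a 2 ms refractory period and it fired more than 1500 spikes over
#' the recording (strictly more; too few waveforms to judge isolation
#' otherwise).
#'
#' @param timestamps sorted spike times (s) of one unit.
#' @param refractory_ms refractory period (ms).
#' @param min_spikes spike-count criterion (strict `>`).
#' @param max_violation maximal tolerated ISI-violation fraction.
#' @return list: `n_spikes`, `isi_violation_fraction` (NA when fewer than
#'   two spikes), `passed`.
#' @export
unit_qc <- function(timestamps, refractory_ms = 2, min_spikes = 1500,
                    max_violation = 0.01) {
  if (is.unsorted(timestamps))
    ec_input_error("spike timestamps must be sorted increasingly")
  n <- length(timestamps)
  if (n < 2)
    return(list(n_spikes = n, isi_violation_fraction = NA_real_,
                passed = FALSE))
  isi <- diff(timestamps)
  viol <- mean(isi < refractory_ms / 1000)
  list(n_spikes = n, isi_violation_fraction = viol,
       passed = viol < max_violation && n > min_spikes)
}

#' Apply quality control to a spike-train set
#'
#' @param spikes a `spike_train_set`.
#' @param ... passed to [unit_qc()].
#' @return list: `spikes` (the filtered set), `report` (data.frame of
#'   per-unit QC fields).
#' @export
qc_filter <- function(spikes, ...) {
  stopifnot(inherits(spikes, "spike_train_set"))
  rep <- do.call(rbind, lapply(names(spikes$units), function(uid) {
    q <- unit_qc(spikes$units[[uid]], ...)
    data.frame(unit_id = uid, n_spikes = q$n_spikes,
               isi_violation_fraction = q$isi_violation_fraction,
               passed = q$passed)
  }))
  keep <- rep$unit_id[rep$passed]
  out <- structure(list(units = spikes$units[keep],
                        manifest = spikes$manifest[
                          spikes$manifest$unit_id %in% keep, , drop = FALSE]),
                   class = "spike_train_set")
  list(spikes = out, report = rep)
}

#' Binned, normalized firing-rate tensor aligned to CS onset
#'
#' Bins each unit's spikes around every trial's CS onset into a
#' units x trials x bins array of firing rates (Hz). Bins are half-open
#' `[a, b)` in CS-relative milliseconds and must tile the window exactly.
#' Normalization modes:
#' \describe{
#'   \item{RAW}{spike count / bin width, Hz.}
#'   \item{MAX}{each unit divided by its maximum across the per-condition
#'     mean rate matrices (a unit with zero rate everywhere is emitted
#'     all-zero with a warning).}
#'   \item{ZSCORE_BASELINE}{standard scores against the mean and SD of the
#'     unit's binned rates over the 1 s pre-CS baseline, pooled across
#'     trials (zero-SD units are emitted as all-zero with a warning).}
#' }
#'
#' @param spikes a `spike_train_set`; every unit must belong to the
#'   sessions present in `trial_table`.
#' @param trial_table trial table; rows define the trial axis (per unit,
#'   only trials of the unit's own session are populated — pass a
#'   single-session table unless you know what you are doing).
#' @param window c(start, end) ms relative to CS onset.
#' @param bin_width bin width, ms.
#' @param normalization `"RAW"`, `"MAX"`, or `"ZSCORE_BASELINE"`.
#' @param baseline_window window (ms) for the z-score baseline.
#' @return 3-D array of class `rate_tensor` `[unit, trial, bin]` with
#'   attributes `window`, `bin_width`, `normalization`, `trials` (the trial
#'   table), `norm_constants`.
#' @export
bin_rates <- function(spikes, trial_table,
                      window = c(-400, 600), bin_width = 50,
                      normalization = c("RAW", "MAX", "ZSCORE_BASELINE"),
                      baseline_window = c(-1000, 0)) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(spikes, "spike_train_set"))
  span <- diff(window)
  if (span <= 0 || abs(span / bin_width - round(span / bin_width)) > 1e-9)
    ec_config_error("bin width %g ms does not tile window [%g, %g) ms",
                    bin_width, window[1], window[2])
  n_bins <- as.integer(round(span / bin_width))
  uids <- names(spikes$units)
  n_tr <- nrow(trial_table)
  tens <- array(0, dim = c(length(uids), n_tr, n_bins),
                dimnames = list(uids, NULL, NULL))
  sess_of <- stats::setNames(spikes$manifest$session_id,
                             spikes$manifest$unit_id)
  count_bins <- function(ts, onsets, w0, w1, nb, bw) {
    # counts matrix trials x bins for one unit, half-open bins
    out <- matrix(0L, length(onsets), nb)
    for (i in seq_along(onsets)) {
      rel <- ts - onsets[i]
      rel <- rel[rel >= w0 / 1000 & rel < w1 / 1000]
      if (length(rel))
        out[i, ] <- tabulate(floor((rel * 1000 - w0) / bw) + 1L, nb)
    }
    out
  }
  for (u in seq_along(uids)) {
    tt_rows <- which(trial_table$session_id == sess_of[[uids[u]]])
    if (!length(tt_rows)) next
    cnt <- count_bins(spikes$units[[uids[u]]],
                      trial_table$cs_onset_s[tt_rows],
                      window[1], window[2], n_bins, bin_width)
    tens[u, tt_rows, ] <- cnt / (bin_width / 1000)
  }
  norm_constants <- NULL
  if (normalization == "MAX") {
    cond <- trial_table$condition
    norm_constants <- numeric(length(uids))
    for (u in seq_along(uids)) {
      mu <- matrix(tens[u, , ], n_tr, n_bins)
      cond_means <- vapply(unique(cond), function(cc)
        colMeans(mu[cond == cc, , drop = FALSE]), numeric(n_bins))
      mx <- max(cond_means)
      norm_constants[u] <- mx
      if (mx == 0) {
        ec_warn("ec_zero_max", "unit %s has zero rate everywhere; %s",
                uids[u], "emitted as all-zero under MAX normalization")
      } else tens[u, , ] <- tens[u, , ] / mx
    }
    names(norm_constants) <- uids
  } else if (normalization == "ZSCORE_BASELINE") {
    nb_base <- as.integer(round(diff(baseline_window) / bin_width))
    norm_constants <- matrix(NA_real_, length(uids), 2,
                             dimnames = list(uids, c("mean", "sd")))
    for (u in seq_along(uids)) {
      tt_rows <- which(trial_table$session_id == sess_of[[uids[u]]])
      if (!length(tt_rows)) next
      base <- count_bins(spikes$units[[uids[u]]],
                         trial_table$cs_onset_s[tt_rows],
                         baseline_window[1], baseline_window[2],
                         nb_base, bin_width) / (bin_width / 1000)
      m <- mean(base); s <- stats::sd(as.vector(base))
      norm_constants[u, ] <- c(m, s)
      if (is.na(s) || s == 0) {
        tens[u, , ] <- 0
        ec_warn("ec_zero_sd", "unit %s has zero baseline SD; %s",
                uids[u], "z-scores emitted as 0")
      } else tens[u, , ] <- (tens[u, , ] - m) / s
    }
  }
  structure(tens,
            class = c("rate_tensor", "array"),
            window = window, bin_width = bin_width,
            normalization = normalization,
            trials = trial_table,
            norm_constants = norm_constants)
}

#' Mean firing rate per unit and trial over a CS-relative window
#'
#' The workhorse feature extractor for decoding and single-neuron
#' selectivity: mean rate (Hz) of each unit in `[window[1], window[2])` ms
#' around each trial's CS onset.
#'
#' @inheritParams bin_rates
#' @param window c(start, end) ms relative to CS onset.
#' @return matrix units x trials (Hz).
#' @export
trial_window_rates <- function(spikes, trial_table, window = c(100, 600)) {
  stopifnot(inherits(spikes, "spike_train_set"))
  tens <- bin_rates(spikes, trial_table, window = window,
                    bin_width = diff(window), normalization = "RAW")
  matrix(tens[, , 1], dim(tens)[1], dim(tens)[2],
         dimnames = list(dimnames(tens)[[1]], NULL))
}
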