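# Shared fixtures, all generated in code at test time.

# A short session: 3 CS-alone + 9 paired trials per epoch, two epochs.
small_config <- function(...) {
  generator_config(n_sessions = 1, n_cs_alone = 3, n_paired = 9,
                   iti_range = c(2000, 4000), seed = 11, ...)
}

# Deterministic four-condition trial table without RNG: n trials per
# condition, alone blocks before paired blocks within each epoch.
toy_trials <- function(n_alone = 5, n_paired = 20, iti = 10) {
  cond <- c(rep("ACS_ALONE", n_alone), rep("ACS_US", n_paired),
            rep("VCS_ALONE", n_alone), rep("VCS_US", n_paired))
  n <- length(cond)
  data.frame(session_id = 1,
             epoch = rep(1:2, each = n / 2),
             trial_index = rep(seq_len(n / 2), 2),
             condition = cond,
             cs_onset_s = 30 + (seq_len(n) - 1) * iti,
             box_id = 1L)
}

# Spike set with one unit whose spikes are given relative to each trial's
# CS onset (recycled across trials).
toy_spike_set <- function(trials, rel_spikes_s, unit_id = "u1") {
  ts <- sort(as.vector(outer(rel_spikes_s, trials$cs_onset_s, "+")))
  structure(list(
    units = stats::setNames(list(ts), unit_id),
    manifest = data.frame(unit_id = unit_id, session_id = 1, neuron_id = 1,
                          class = "NONSELECTIVE", tetrode = 1, rat = 1,
                          stage = "LEARNING")),
    class = "spike_train_set")
}

# Poisson rate tensor-ready spike set: one unit per requested rate, firing
# homogeneously at that rate across the whole session span.
poisson_spike_set <- function(trials, rates_hz, t_pad = 30) {
  t_stop <- max(trials$cs_onset_s) + t_pad
  units <- lapply(seq_along(rates_hz), function(i)
    sort(stats::runif(stats::rpois(1, rates_hz[i] * t_stop), 0, t_stop)))
  ids <- sprintf("u%03d", seq_along(rates_hz))
  names(units) <- ids
  structure(list(
    units = units,
    manifest = data.frame(unit_id = ids, session_id = 1,
                          neuron_id = seq_along(rates_hz),
                          class = "NONSELECTIVE", tetrode = 1, rat = 1,
                          stage = "LEARNING")),
    class = "spike_train_set")
}

# A peri-trial EMG trace built by hand: noise plus optional bursts, for
# detector tests with known ground truth. `bursts` is a list of
# c(start_s, end_s, amplitude) relative to CS onset.
constructed_emg <- function(trials, config, bursts_by_trial = NULL,
                            noise_sd = 1) {
  fs <- config$emg_rate
  us_off <- (config$cs_duration + config$trace_interval) / 1000
  seg_pre <- 1.2
  seg_post <- us_off + config$us_duration / 1000 + 0.1
  n_seg <- round((seg_pre + seg_post) * fs)
  t_rel <- (seq_len(n_seg) - 1) / fs - seg_pre
  samples <- lapply(seq_len(nrow(trials)), function(i) {
    x <- stats::rnorm(n_seg, 0, noise_sd)
    for (b in bursts_by_trial[[i]] %||% list()) {
      idx <- t_rel >= b[1] & t_rel < b[2]
      x[idx] <- x[idx] + b[3] * sin(2 * pi * 150 * t_rel[idx])
    }
    x
  })
  structure(list(session_id = trials$session_id[1], sample_rate = fs,
                 segments = data.frame(epoch = trials$epoch,
                                       trial_index = trials$trial_index,
                                       condition = trials$condition,
                                       t0 = trials$cs_onset_s - seg_pre,
                                       n = n_seg,
                                       cr_true = NA, hyper_true = NA),
                 samples = samples), class = "emg_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent MI oracle: entropy decomposition H(C) + H(R) - H(C, R) on
# the full contingency table.
mi_entropy_oracle <- function(tab) {
  n <- sum(tab)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h(rowSums(tab) / n) + h(colSums(tab) / n) - h(as.vector(tab) / n)
}
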