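#' Configuration for the synthetic conditioning-session generator
#'
#' Bundles the trial-schedule, EMG, and learning-trajectory parameters of the
#' simulated trace eyeblink conditioning experiment. Defaults reproduce the
#' paradigm the analysis assumes: daily sessions of two 100-trial epochs (20
#' CS-alone trials followed by 80 CS-US paired trials per epoch), a 100 ms CS,
#' a 500 ms stimulus-free trace interval, a 100 ms US, inter-trial intervals
#' drawn uniformly from 20-40 s, and eyelid EMG sampled at 6108 Hz.
#'
#' @param n_sessions number of daily sessions to simulate.
#' @param epochs_per_session epochs per session; each epoch uses one CS
#'   modality.
#' @param n_cs_alone,n_paired CS-alone and CS-US paired trials per epoch.
#' @param cs_duration,trace_interval,us_duration stimulus timings (ms).
#' @param iti_range inter-trial interval range (ms), CS onset to CS onset.
#' @param emg_rate EMG sampling rate (Hz).
#' @param emg_noise_sd baseline EMG noise standard deviation (arbitrary
#'   amplitude units; all EMG amplitudes are relative to this floor).
#' @param baseline_jitter_sd log-scale SD of the per-trial multiplicative
#'   jitter on the baseline noise amplitude (tonic muscle activity varies
#'   from trial to trial; the session CR threshold absorbs this spread).
#' @param cr_burst_amp,hyperactive_amp,us_artifact_amp amplitudes of the
#'   conditioned-response burst, pre-CS "hyperactive" burst, and US artifact,
#'   in units of `emg_noise_sd`.
#' @param learning_midpoint,learning_slope parameters of the sigmoid
#'   conditioned-response learning trajectory across sessions: the CR
#'   probability on paired trials in session s is
#'   `plogis(learning_slope * (s - learning_midpoint))`.
#' @param cr_prob_alone flat CR probability on CS-alone trials (expression on
#'   unpaired trials stays near the false-positive floor throughout training).
#' @param hyperactive_prob per-trial probability of a pre-CS hyperactive
#'   burst (grooming, teeth grinding, climbing).
#' @param seed integer seed used by [generate_dataset()].
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_sessions = 1L,
                             epochs_per_session = 2L,
                             n_cs_alone = 20L,
                             n_paired = 80L,
                             cs_duration = 100,
                             trace_interval = 500,
                             us_duration = 100,
                             iti_range = c(20000, 40000),
                             emg_rate = 6108,
                             emg_noise_sd = 1,
                             baseline_jitter_sd = 0.15,
                             cr_burst_amp = 8,
                             hyperactive_amp = 10,
                             us_artifact_amp = 50,
                             learning_midpoint = 6,
                             learning_slope = 1,
                             cr_prob_alone = 0.05,
                             hyperactive_prob = 0.05,
                             seed = 1L) {
  counts <- c(n_sessions = n_sessions, epochs_per_session = epochs_per_session,
              n_cs_alone = n_cs_alone, n_paired = n_paired)
  for (nm in names(counts))
    if (!is.numeric(counts[[nm]]) || counts[[nm]] < 1 ||
        counts[[nm]] != round(counts[[nm]]))
      ec_config_error("'%s' must be a positive integer, got %s", nm,
                      format(counts[[nm]]))
  for (nm in c("cs_duration", "trace_interval", "us_duration", "emg_rate",
               "emg_noise_sd"))
    if (get(nm) <= 0)
      ec_config_error("'%s' must be positive", nm)
  if (length(iti_range) != 2L || iti_range[1] > iti_range[2] ||
      iti_range[1] <= 0)
    ec_config_error("'iti_range' must be (low, high) with 0 < low <= high")
  for (nm in c("hyperactive_prob", "cr_prob_alone"))
    if (get(nm) < 0 || get(nm) > 1)
      ec_config_error("'%s' must be a probability in [0, 1]", nm)
  structure(list(
    n_sessions = as.integer(n_sessions),
    epochs_per_session = as.integer(epochs_per_session),
    n_cs_alone = as.integer(n_cs_alone),
    n_paired = as.integer(n_paired),
    cs_duration = cs_duration,
    trace_interval = trace_interval,
    us_duration = us_duration,
    iti_range = iti_range,
    emg_rate = emg_rate,
    emg_noise_sd = emg_noise_sd,
    baseline_jitter_sd = baseline_jitter_sd,
    cr_burst_amp = cr_burst_amp,
    hyperactive_amp = hyperactive_amp,
    us_artifact_amp = us_artifact_amp,
    learning_midpoint = learning_midpoint,
    learning_slope = learning_slope,
    cr_prob_alone = cr_prob_alone,
    hyperactive_prob = hyperactive_prob,
    seed = as.integer(seed)
  ), class = "generator_config")
}

## CS-onset-to-US-onset offset in seconds.
us_offset_s <- function(config) (config$cs_duration + config$trace_interval) / 1000

#' Sigmoid conditioned-response learning trajectory
#'
#' CR probability on paired trials per session, following the logistic
#' trajectory parameterized in [generator_config()].
#'
#' @param config a `generator_config`.
#' @param sessions session indices (default all configured sessions).
#' @return numeric vector of probabilities.
#' @export
learning_trajectory <- function(config, sessions = seq_len(config$n_sessions)) {
  stats::plogis(config$learning_slope * (sessions - config$learning_midpoint))
}

#' Simulate the trial-event schedule
#'
#' Builds the trial table for all sessions: per session,
#' `epochs_per_session` epochs of `n_cs_alone` CS-alone trials followed by
#' `n_paired` CS-US paired trials. The CS modality of epoch 1 (auditory vs
#' visual) is pseudorandomized per session; the other modality is used in
#' epoch 2. Times are absolute seconds within the session.
#'
#' @param config a `generator_config`. Uses the current RNG state (seed it or
#'   use [generate_dataset()] for reproducibility).
#' @return data.frame with columns `session_id`, `epoch`, `trial_index`
#'   (within epoch), `condition`, `cs_onset_s`, `box_id`.
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  per_epoch <- config$n_cs_alone + config$n_paired
  rows <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    modalities <- sample(c("A", "V"))
    if (config$epochs_per_session > 2L)
      modalities <- rep_len(modalities, config$epochs_per_session)
    t_cursor <- 30  # head-room before the first trial
    epoch_rows <- vector("list", config$epochs_per_session)
    for (e in seq_len(config$epochs_per_session)) {
      mod <- modalities[e]
      pairing <- rep(c("ALONE", "US"), c(config$n_cs_alone, config$n_paired))
      itis <- stats::runif(per_epoch - 1L,
                           config$iti_range[1], config$iti_range[2]) / 1000
      onsets <- t_cursor + c(0, cumsum(itis))
      epoch_rows[[e]] <- data.frame(
        session_id = s,
        epoch = e,
        trial_index = seq_len(per_epoch),
        condition = paste0(mod, "CS_", pairing),
        cs_onset_s = onsets,
        box_id = 1L,
        stringsAsFactors = FALSE)
      # 10 min rest between epochs
      t_cursor <- onsets[per_epoch] + us_offset_s(config) + 600
    }
    rows[[s]] <- do.call(rbind, epoch_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Specification of one synthetic neuron
#'
#' Encodes a neuron's coding class and its condition-dependent evoked gains
#' over the CS + trace window. Classes mirror the selectivity taxonomy the
#' analyses test for:
#' \describe{
#'   \item{RELATIONAL}{gain depends only on pairing (CS-alone vs CS-US),
#'     identical across CS modalities.}
#'   \item{PHYSICAL}{gain depends only on CS modality, identical across
#'     pairing.}
#'   \item{CONJUNCTIVE}{one condition's gain differs from the rest.}
#'   \item{NONSELECTIVE}{equal evoked gain in all conditions (responsive but
#'     not selective).}
#'   \item{UNRESPONSIVE}{gain 1 everywhere.}
#' }
#' Per-trial rate noise is multiplicative log-normal with mean 1, so the
#' consistency of differential firing can be degraded (via
#' `stage_consistency`) without changing mean rates, while
#' `stage_magnitude` scales the evoked gain contrast `(gain - 1)` to move
#' the magnitude of differential firing independently of its consistency.
#'
#' @param neuron_id identifier.
#' @param class coding class, see Details.
#' @param baseline_rate baseline firing rate (Hz).
#' @param effect_size evoked gain of the preferred condition group
#'   (dimensionless multiplier on baseline rate).
#' @param trial_noise_sd log-scale SD of the multiplicative per-trial rate
#'   noise.
#' @param stage_magnitude,stage_consistency named multipliers per learning
#'   stage applied to the gain contrast and to `trial_noise_sd`.
#' @param gains optional named vector of per-condition gains overriding the
#'   class default; names must cover the condition label set.
#' @param labels condition label set.
#' @return an object of class `neuron_spec`.
#' @export
neuron_spec <- function(neuron_id,
                        class = c("RELATIONAL", "PHYSICAL", "CONJUNCTIVE",
                                  "NONSELECTIVE", "UNRESPONSIVE"),
                        baseline_rate = 5,
                        effect_size = 2,
                        trial_noise_sd = 0.3,
                        stage_magnitude = NULL,
                        stage_consistency = NULL,
                        gains = NULL,
                        labels = c("ACS_ALONE", "ACS_US",
                                   "VCS_ALONE", "VCS_US")) {
  class <- match.arg(class)
  if (baseline_rate < 0) ec_config_error("'baseline_rate' must be >= 0")
  if (effect_size < 0) ec_config_error("'effect_size' must be >= 0")
  stages <- c("BEFORE", "LEARNING", "POST_1W", "POST_2W", "POST_3W")
  if (is.null(stage_magnitude))
    stage_magnitude <- stats::setNames(rep(1, length(stages)), stages)
  if (is.null(stage_consistency))
    stage_consistency <- stats::setNames(rep(1, length(stages)), stages)
  if (is.null(gains)) {
    gains <- stats::setNames(rep(1, length(labels)), labels)
    gains[] <- switch(class,
      RELATIONAL   = ifelse(is_paired_label(labels), effect_size, 1),
      PHYSICAL     = ifelse(startsWith(labels, "A"), effect_size, 1),
      CONJUNCTIVE  = ifelse(labels == labels[is_paired_label(labels)][1],
                            effect_size, 1),
      NONSELECTIVE = effect_size,
      UNRESPONSIVE = 1)
  }
  if (!all(labels %in% names(gains)))
    ec_config_error("'gains' must name every condition label")
  if (any(gains < 0)) ec_config_error("gains must be >= 0")
  gains <- gains[labels]
  # class contracts on custom gains
  paired <- is_paired_label(labels)
  if (class == "RELATIONAL") {
    if (length(unique(gains[paired])) != 1L ||
        length(unique(gains[!paired])) != 1L)
      ec_config_error("RELATIONAL gains must be equal across CS modalities")
  }
  if (class == "PHYSICAL") {
    aud <- startsWith(labels, "A")
    if (length(unique(gains[aud])) != 1L ||
        length(unique(gains[!aud])) != 1L)
      ec_config_error("PHYSICAL gains must be equal across pairing")
  }
  structure(list(neuron_id = neuron_id, class = class,
                 baseline_rate = baseline_rate,
                 trial_noise_sd = trial_noise_sd,
                 stage_magnitude = stage_magnitude,
                 stage_consistency = stage_consistency,
                 gains = gains, labels = labels),
            class = "neuron_spec")
}

#' Specification of a synthetic neuron ensemble
#'
#' Generates `n_neurons` neuron specs from a mixture over coding classes.
#' Default mixture proportions follow the reported composition of the
#' recorded population: 65.1% of neurons task-responsive, and of those,
#' 10.5% relational, 13.7% physical, and 17.6% conjunctive, the remainder
#' responsive but non-selective.
#'
#' @param n_neurons ensemble size.
#' @param proportions named class mixture, summing to 1.
#' @param baseline_rates function(n) drawing baseline rates (Hz); default
#'   log-normal with median 4 Hz.
#' @param ... passed to [neuron_spec()] (e.g. `effect_size`,
#'   `stage_magnitude`).
#' @return an object of class `ensemble_spec` (list of `neuron_spec`).
#' @export
ensemble_spec <- function(n_neurons,
                          proportions = c(RELATIONAL = 0.651 * 0.105,
                                          PHYSICAL = 0.651 * 0.137,
                                          CONJUNCTIVE = 0.651 * 0.176,
                                          NONSELECTIVE = 0.651 * 0.582,
                                          UNRESPONSIVE = 0.349),
                          baseline_rates = function(n) stats::rlnorm(n, log(4), 0.5),
                          ...) {
  if (n_neurons < 1) ec_config_error("'n_neurons' must be >= 1")
  if (abs(sum(proportions) - 1) > 1e-9)
    ec_config_error("class mixture proportions must sum to 1 (got %.6f)",
                    sum(proportions))
  if (any(proportions < 0)) ec_config_error("proportions must be >= 0")
  # largest-remainder apportionment of counts
  raw <- proportions * n_neurons
  counts <- floor(raw)
  rem <- n_neurons - sum(counts)
  if (rem > 0) {
    add <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  classes <- rep(names(counts), counts)
  rates <- baseline_rates(n_neurons)
  neurons <- lapply(seq_len(n_neurons), function(i)
    neuron_spec(neuron_id = i, class = classes[i],
                baseline_rate = rates[i], ...))
  structure(list(neurons = neurons, proportions = proportions,
                 n_neurons = as.integer(n_neurons)),
            class = "ensemble_spec")
}

#' Simulate eyelid EMG around every trial
#'
#' Synthesizes one EMG trace per session as peri-trial segments covering
#' \[-1.2 s, US offset + 0.1 s\] around each CS onset (the scoring windows
#' plus head-room; continuous inter-trial EMG carries no analysis content
#' and is not synthesized). Each segment is zero-mean Gaussian noise, with:
#' a conditioned-response burst (150 Hz sinusoid, amplitude
#' `cr_burst_amp` noise SDs) occupying the 200 ms immediately before US
#' onset on CR trials; a pre-CS hyperactive burst in part of the 300 ms
#' pre-CS window with probability `hyperactive_prob`; and a saturated
#' square-wave US artifact over the 100 ms US on paired trials.
#'
#' @param trial_table a trial table from [simulate_trials()].
#' @param cr_probability CR probability per trial: a scalar, or a
#'   data.frame with columns `session_id`, `condition`, `p`. Default is the
#'   config's sigmoid trajectory on paired trials and `cr_prob_alone` on
#'   CS-alone trials.
#' @param config a `generator_config`.
#' @return list of `emg_trace` objects, one per session. Each carries the
#'   simulated ground-truth flags (`cr_true`, `hyper_true`) per trial for
#'   calibration studies.
#' @export
simulate_emg <- function(trial_table, cr_probability = NULL, config) {
  stopifnot(inherits(config, "generator_config"))
  fs <- config$emg_rate
  us_off <- us_offset_s(config)
  seg_pre <- 1.2
  seg_post <- us_off + config$us_duration / 1000 + 0.1
  n_seg <- round((seg_pre + seg_post) * fs)
  t_rel <- (seq_len(n_seg) - 1) / fs - seg_pre  # time of each sample rel. CS

  p_of <- function(session, condition) {
    if (is.null(cr_probability)) {
      if (is_paired_label(condition))
        learning_trajectory(config, session)
      else config$cr_prob_alone
    } else if (is.data.frame(cr_probability)) {
      hit <- cr_probability$session_id == session &
        cr_probability$condition == condition
      if (!any(hit)) ec_config_error(
        "cr_probability has no row for session %s condition %s",
        session, condition)
      cr_probability$p[which(hit)[1]]
    } else cr_probability
  }

  lapply(split(trial_table, trial_table$session_id), function(tt) {
    n_tr <- nrow(tt)
    if (any(tt$cs_onset_s < seg_pre))
      ec_schedule_error("trial window extends before session start")
    samples <- vector("list", n_tr)
    cr_true <- logical(n_tr)
    hyper_true <- logical(n_tr)
    for (i in seq_len(n_tr)) {
      trial_sd <- config$emg_noise_sd *
        exp(stats::rnorm(1, 0, config$baseline_jitter_sd))
      x <- stats::rnorm(n_seg, 0, trial_sd)
      p <- p_of(tt$session_id[i], tt$condition[i])
      if (p < 0 || p > 1)
        ec_config_error("cr_probability %.3f outside [0, 1]", p)
      if (stats::runif(1) < p) {
        cr_true[i] <- TRUE
        idx <- in_window(t_rel, us_off - 0.2, us_off)
        amp <- config$cr_burst_amp * config$emg_noise_sd *
          stats::runif(1, 0.8, 1.2)
        x[idx] <- x[idx] + amp * sin(2 * pi * 150 * t_rel[idx])
      }
      if (stats::runif(1) < config$hyperactive_prob) {
        hyper_true[i] <- TRUE
        idx <- in_window(t_rel, -0.28, -0.05)
        amp <- config$hyperactive_amp * config$emg_noise_sd *
          stats::runif(1, 0.8, 1.2)
        x[idx] <- x[idx] + amp * sin(2 * pi * 120 * t_rel[idx])
      }
      if (is_paired_label(tt$condition[i])) {
        idx <- which(in_window(t_rel, us_off, us_off + config$us_duration / 1000))
        amp <- config$us_artifact_amp * config$emg_noise_sd
        # railed 150 Hz artifact with 10 ms raised-cosine edges: band-limited
        # so the stimulation transient does not bleed into the adjacent
        # CR-scoring window through the analytic-signal envelope
        n_ramp <- min(round(0.01 * fs), length(idx) %/% 2)
        taper <- rep(1, length(idx))
        ramp <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp))
        taper[seq_len(n_ramp)] <- ramp
        taper[length(idx) + 1 - seq_len(n_ramp)] <- ramp
        x[idx] <- x[idx] + taper * amp * sin(2 * pi * 150 * t_rel[idx])
      }
      samples[[i]] <- x
    }
    structure(list(
      session_id = tt$session_id[1],
      sample_rate = fs,
      segments = data.frame(epoch = tt$epoch, trial_index = tt$trial_index,
                            condition = tt$condition,
                            t0 = tt$cs_onset_s - seg_pre,
                            n = n_seg,
                            cr_true = cr_true, hyper_true = hyper_true),
      samples = samples), class = "emg_trace")
  })
}

#' Simulate spike trains for an ensemble over the trial schedule
#'
#' Draws each unit's spikes from an inhomogeneous Poisson process: the
#' baseline rate everywhere except the CS + trace window \[0, 600) ms of
#' each trial, where the rate is
#' `baseline * (1 + (gain(condition) - 1) * stage_magnitude(stage)) * noise`,
#' with `noise` a per-trial log-normal factor of mean 1 and log-SD
#' `trial_noise_sd * stage_consistency(stage)`. Inter-trial spiking is
#' simulated throughout, so responsiveness tests have a baseline.
#'
#' Each session instantiates its own units from the shared ensemble spec
#' (cross-day unit identity enters only as this re-sampling overlap).
#'
#' @param trial_table a trial table from [simulate_trials()].
#' @param ensemble an `ensemble_spec`.
#' @param stage_schedule named character vector mapping session id to a
#'   learning-stage label; defaults to `"LEARNING"` for every session.
#' @param config a `generator_config`.
#' @return an object of class `spike_train_set`: `units` (named list of
#'   sorted spike-time vectors, seconds) and `manifest` (data.frame of
#'   unit_id, session_id, neuron_id, class, tetrode, rat, stage).
#' @export
simulate_spike_trains <- function(trial_table, ensemble, stage_schedule = NULL,
                                  config) {
  stopifnot(inherits(ensemble, "ensemble_spec"),
            inherits(config, "generator_config"))
  sessions <- unique(trial_table$session_id)
  if (is.null(stage_schedule))
    stage_schedule <- stats::setNames(rep("LEARNING", length(sessions)),
                                      sessions)
  win_len <- us_offset_s(config)  # CS + trace, seconds
  units <- list()
  manifest <- list()
  for (s in sessions) {
    tt <- trial_table[trial_table$session_id == s, ]
    stage <- stage_schedule[[as.character(s)]]
    t_stop <- max(tt$cs_onset_s) + win_len + 30
    for (spec in ensemble$neurons) {
      if (!all(tt$condition %in% names(spec$gains)))
        ec_config_error("neuron %s has no gain for condition(s): %s",
                        spec$neuron_id,
                        paste(setdiff(tt$condition, names(spec$gains)),
                              collapse = ", "))
      mag <- spec$stage_magnitude[[stage]]
      sigma <- spec$trial_noise_sd * spec$stage_consistency[[stage]]
      base <- spec$baseline_rate
      # baseline process over the whole session, stimulus windows carved out
      n_base <- stats::rpois(1, base * t_stop)
      ts <- stats::runif(n_base, 0, t_stop)
      win_idx <- findInterval(ts, tt$cs_onset_s)
      in_win <- win_idx > 0 &
        ts < tt$cs_onset_s[pmax(win_idx, 1)] + win_len
      ts <- ts[!in_win]
      # evoked windows at the modulated rate
      gain <- spec$gains[tt$condition]
      eff <- 1 + (gain - 1) * mag
      noise <- if (sigma > 0)
        exp(stats::rnorm(nrow(tt), -sigma^2 / 2, sigma)) else rep(1, nrow(tt))
      lambda <- pmax(base * eff * noise, 0)
      n_ev <- stats::rpois(nrow(tt), lambda * win_len)
      ev <- rep(tt$cs_onset_s, n_ev) + stats::runif(sum(n_ev), 0, win_len)
      uid <- sprintf("s%02d_u%03d", s, spec$neuron_id)
      all_ts <- sort(c(ts, ev))
      # enforce a 2 ms refractory dead-time so simulated units behave like
      # well-isolated neurons under the ISI quality criterion
      if (length(all_ts) > 1)
        all_ts <- all_ts[c(TRUE, diff(all_ts) >= 0.002)]
      units[[uid]] <- all_ts
      manifest[[uid]] <- data.frame(
        unit_id = uid, session_id = s, neuron_id = spec$neuron_id,
        class = spec$class,
        tetrode = ((spec$neuron_id - 1L) %% 14L) + 1L,
        rat = 1L, stage = stage, stringsAsFactors = FALSE)
    }
  }
  structure(list(units = units,
                 manifest = do.call(rbind, c(manifest,
                                             make.row.names = FALSE))),
            class = "spike_train_set")
}

#' Generate a complete synthetic dataset
#'
#' Composes [simulate_trials()], [simulate_emg()], and
#' [simulate_spike_trains()] under the config's seed; re-running with the
#' same configuration reproduces the outputs exactly.
#'
#' @inheritParams simulate_emg
#' @inheritParams simulate_spike_trains
#' @param ensemble an `ensemble_spec`.
#' @return list of class `ec_dataset` with elements `trials`, `emg`,
#'   `spikes`, `config`.
#' @export
generate_dataset <- function(config, ensemble, cr_probability = NULL,
                             stage_schedule = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  trials <- simulate_trials(config)
  emg <- simulate_emg(trials, cr_probability, config)
  spikes <- simulate_spike_trains(trials, ensemble, stage_schedule, config)
  structure(list(trials = trials, emg = emg, spikes = spikes,
                 config = config),
            class = "ec_dataset")
}

#' Write / read a trial table as CSV
#'
#' @param trial_table,path data.frame and file path.
#' @return `read_trial_table` returns the data.frame.
#' @export
write_trial_table <- function(trial_table, path) {
  utils::write.csv(trial_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read spike trains as per-unit CSVs plus a manifest
#'
#' One `timestamp_s` CSV per unit and a `units.csv` manifest, the columnar
#' plain-text layout the pipeline consumes.
#'
#' @param spikes a `spike_train_set`.
#' @param dir directory to write into (created if needed).
#' @return `read_spike_trains` returns a `spike_train_set`.
#' @export
write_spike_trains <- function(spikes, dir) {
  stopifnot(inherits(spikes, "spike_train_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(spikes$manifest, file.path(dir, "units.csv"),
                   row.names = FALSE)
  for (uid in names(spikes$units))
    utils::write.csv(data.frame(timestamp_s = spikes$units[[uid]]),
                     file.path(dir, paste0(uid, ".csv")), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "units.csv"),
                              stringsAsFactors = FALSE)
  units <- lapply(manifest$unit_id, function(uid)
    utils::read.csv(file.path(dir, paste0(uid, ".csv")))$timestamp_s)
  names(units) <- manifest$unit_id
  structure(list(units = units, manifest = manifest),
            class = "spike_train_set")
}

#' Write / read a generator configuration as YAML
#'
#' @param config a `generator_config`.
#' @param path file path.
#' @return `read_generator_config` returns a validated `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  do.call(generator_config, yaml::read_yaml(path))
}
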