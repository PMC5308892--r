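test_that("default schedule has 200 trials/session with one modality per epoch", {
  set.seed(1)
  cfg <- generator_config(n_sessions = 2)
  tt <- simulate_trials(cfg)
  expect_equal(nrow(tt), 2 * 200)
  for (s in 1:2) {
    for (e in 1:2) {
      ep <- tt[tt$session_id == s & tt$epoch == e, ]
      expect_equal(nrow(ep), 100)
      mods <- unique(substr(ep$condition, 1, 1))
      expect_length(mods, 1)
      # alone trials strictly precede paired trials
      expect_equal(ep$condition[1:20], rep(paste0(mods, "CS_ALONE"), 20))
      expect_equal(ep$condition[21:100], rep(paste0(mods, "CS_US"), 80))
      expect_true(all(diff(ep$cs_onset_s) > 0))
      itis <- diff(ep$cs_onset_s)
      expect_true(all(itis >= 20 & itis <= 40))
    }
    # the two epochs use the two different modalities
    expect_setequal(
      unique(substr(tt$condition[tt$session_id == s], 1, 1)), c("A", "V"))
  }
})

test_that("custom trial counts are honored, unpaired rows first", {
  set.seed(2)
  cfg <- generator_config(n_cs_alone = 2, n_paired = 3)
  tt <- simulate_trials(cfg)
  expect_equal(nrow(tt), 10)
  for (e in 1:2)
    expect_true(all(grepl("ALONE", tt$condition[tt$epoch == e][1:2])))
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- small_config()
  ens <- ensemble_spec(6)
  d1 <- generate_dataset(cfg, ens)
  d2 <- generate_dataset(cfg, ens)
  expect_identical(d1$trials, d2$trials)
  expect_identical(d1$spikes$units, d2$spikes$units)
  expect_identical(d1$emg[[1]]$samples, d2$emg[[1]]$samples)
})

test_that("configuration errors name the offending field", {
  expect_error(generator_config(n_paired = 0), "n_paired",
               class = "ec_config_error")
  expect_error(generator_config(cs_duration = -5), "cs_duration",
               class = "ec_config_error")
  expect_error(generator_config(iti_range = c(40, 20)), "iti_range",
               class = "ec_config_error")
  expect_error(generator_config(hyperactive_prob = 1.4), "hyperactive_prob",
               class = "ec_config_error")
  expect_error(ensemble_spec(10, proportions = c(RELATIONAL = 0.6,
                                                 PHYSICAL = 0.6)),
               "sum to 1", class = "ec_config_error")
})

test_that("ensemble mixture counts follow the requested proportions", {
  set.seed(3)
  ens <- ensemble_spec(200)
  cls <- table(vapply(ens$neurons, function(n) n$class, character(1)))
  expect_equal(sum(cls), 200)
  # default mixture: responsive fraction ~65%, relational ~6.8% overall
  expect_equal(unname(cls[["UNRESPONSIVE"]]), round(0.349 * 200), tolerance = 1)
  expect_equal(unname(cls[["RELATIONAL"]]), round(0.651 * 0.105 * 200),
               tolerance = 1)
})

test_that("neuron class gain contracts hold", {
  rel <- neuron_spec(1, "RELATIONAL", effect_size = 3)
  expect_equal(unname(rel$gains["ACS_US"]), unname(rel$gains["VCS_US"]))
  expect_equal(unname(rel$gains["ACS_ALONE"]), unname(rel$gains["VCS_ALONE"]))
  phy <- neuron_spec(2, "PHYSICAL", effect_size = 3)
  expect_equal(unname(phy$gains["ACS_US"]), unname(phy$gains["ACS_ALONE"]))
  expect_error(neuron_spec(3, "RELATIONAL",
                           gains = c(ACS_ALONE = 1, ACS_US = 2,
                                     VCS_ALONE = 1, VCS_US = 3)),
               class = "ec_config_error")
})

test_that("evoked rate ratios and Poisson counts match the generating spec", {
  set.seed(4)
  # many trials: 5 sessions x (20 alone + 80 paired) x 2 epochs
  cfg <- generator_config(n_sessions = 5, iti_range = c(2000, 3000), seed = 4)
  tt <- simulate_trials(cfg)
  ens <- structure(list(
    neurons = list(neuron_spec(1, "RELATIONAL", baseline_rate = 10,
                               effect_size = 3, trial_noise_sd = 0)),
    proportions = c(RELATIONAL = 1), n_neurons = 1L),
    class = "ensemble_spec")
  sp <- simulate_spike_trains(tt, ens, config = cfg)
  rates <- do.call(cbind, lapply(1:5, function(s) {
    ss <- structure(list(units = sp$units[s],
                         manifest = sp$manifest[s, , drop = FALSE]),
                    class = "spike_train_set")
    trial_window_rates(ss, tt[tt$session_id == s, ], window = c(100, 600))
  }))
  cond <- tt$condition
  paired_rate <- mean(rates[cond %in% c("ACS_US", "VCS_US")])
  alone_rate <- mean(rates[cond %in% c("ACS_ALONE", "VCS_ALONE")])
  # paired/alone ratio ~ effect_size = 3, corrected for the 2 ms
  # dead-time thinning (factor exp(-lambda * tau) at each rate)
  n_p <- sum(grepl("US$", cond)); n_a <- sum(grepl("ALONE", cond))
  ratio_exp <- 3 * exp(-0.002 * 30) / exp(-0.002 * 10)
  se_ratio <- 3 * sqrt(1 / (30 * 0.5 * n_p) + 1 / (10 * 0.5 * n_a))
  expect_lt(abs(paired_rate / alone_rate - ratio_exp), 3.5 * se_ratio)
  # Poisson sanity on the alone trials: mean count within 3.5 SE of the
  # thinned 10 Hz x 0.5 s expectation
  counts <- rates[cond %in% c("ACS_ALONE", "VCS_ALONE")] * 0.5
  mu <- 5 * exp(-0.002 * 10)
  expect_lt(abs(mean(counts) - mu), 3.5 * sqrt(mu / n_a))
})

test_that("RELATIONAL specs carry no physical contrast and vice versa", {
  set.seed(5)
  cfg <- generator_config(n_sessions = 4, iti_range = c(2000, 3000), seed = 5)
  tt <- simulate_trials(cfg)
  mk <- function(class) structure(list(
    neurons = list(neuron_spec(1, class, baseline_rate = 8, effect_size = 3,
                               trial_noise_sd = 0)),
    proportions = stats::setNames(1, class), n_neurons = 1L),
    class = "ensemble_spec")
  for (cl in c("RELATIONAL", "PHYSICAL")) {
    sp <- simulate_spike_trains(tt, mk(cl), config = cfg)
    rates <- unlist(lapply(1:4, function(s) {
      ss <- structure(list(units = sp$units[s],
                           manifest = sp$manifest[s, , drop = FALSE]),
                      class = "spike_train_set")
      trial_window_rates(ss, tt[tt$session_id == s, ], window = c(100, 600))
    }))
    cond <- tt$condition
    if (cl == "RELATIONAL") {
      idx <- differentiation_index(mean(rates[substr(cond, 1, 1) == "A"]),
                                   mean(rates[substr(cond, 1, 1) == "V"]))
    } else {
      idx <- differentiation_index(mean(rates[grepl("ALONE", cond)]),
                                   mean(rates[!grepl("ALONE", cond)]))
    }
    expect_lt(abs(idx), 0.05)
  }
})

test_that("simulated EMG carries CR bursts, hyperactive bursts and artifacts", {
  cfg <- generator_config(n_sessions = 1, hyperactive_prob = 0, seed = 6,
                          n_cs_alone = 2, n_paired = 10,
                          iti_range = c(2000, 3000))
  set.seed(6)
  tt <- simulate_trials(cfg)
  emg <- simulate_emg(tt, cr_probability = 1, cfg)[[1]]
  expect_true(all(emg$segments$cr_true))
  expect_false(any(emg$segments$hyper_true))
  # paired trials end with a saturated US artifact
  fs <- emg$sample_rate
  i <- which(emg$segments$condition == "ACS_US")[1]
  t_rel <- (seq_len(emg$segments$n[i]) - 1) / fs - 1.2
  seg <- emg$samples[[i]]
  expect_gt(max(abs(seg[t_rel >= 0.62 & t_rel < 0.68])), 30)
  expect_lt(max(abs(seg[t_rel >= -1.1 & t_rel < -0.9])), 8)
})

test_that("spike train CSV round-trip preserves the set", {
  cfg <- small_config()
  ens <- ensemble_spec(3)
  ds <- generate_dataset(cfg, ens)
  dir <- withr::local_tempdir()
  write_spike_trains(ds$spikes, dir)
  back <- read_spike_trains(dir)
  expect_equal(names(back$units), names(ds$spikes$units))
  expect_equal(back$units[[1]], ds$spikes$units[[1]], tolerance = 1e-12)
  write_trial_table(ds$trials, file.path(dir, "trials.csv"))
  tt <- read_trial_table(file.path(dir, "trials.csv"))
  expect_equal(tt$condition, ds$trials$condition)
})

test_that("generator configs round-trip through YAML", {
  cfg <- generator_config(n_sessions = 3, learning_slope = 1.5, seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back, cfg)
})
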