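test_that("differentiation index matches its closed form", {
  expect_equal(differentiation_index(5, 5), 0)
  expect_equal(differentiation_index(3, 1), 0.5)
  expect_equal(differentiation_index(4, 0), 1)
  expect_equal(differentiation_index(0, 4), -1)
  expect_warning(di <- differentiation_index(0, 0),
                 class = "ec_undefined_index")
  expect_true(is.na(di))
  expect_error(differentiation_index(-1, 2), class = "ec_input_error")
  # invariant to common rescaling of rates
  expect_equal(abs(differentiation_index(6, 2)),
               abs(differentiation_index(6 * 13, 2 * 13)))
  # vectorized
  expect_equal(differentiation_index(c(3, 5), c(1, 5)), c(0.5, 0))
})

test_that("mutual information hits the deterministic benchmarks", {
  # two equiprobable conditions, rates in disjoint bins: 1 bit
  expect_equal(mutual_information(c(rep(0, 10), rep(50, 10)),
                                  rep(c("a", "b"), each = 10)), 1)
  # four equiprobable conditions, disjoint bins: 2 bits
  expect_equal(mutual_information(rep(c(0, 10, 30, 50), each = 5),
                                  rep(letters[1:4], each = 5)), 2)
  # constant rate: single occupied bin, MI = 0
  expect_equal(mutual_information(rep(7, 20), rep(c("a", "b"), 10)), 0)
  expect_error(mutual_information(1:10, rep("a", 10)),
               class = "ec_input_error")
})

test_that("plug-in MI equals the entropy-decomposition oracle to 1e-12", {
  set.seed(50)
  for (i in 1:20) {
    n_cond <- sample(2:4, 1)
    n_bins <- sample(2:4, 1)
    labels <- factor(sample(letters[1:n_cond], 60, replace = TRUE,
                            prob = runif(n_cond)))
    while (any(table(labels) < 2))
      labels <- factor(sample(letters[1:n_cond], 60, replace = TRUE))
    rates <- runif(60)
    mi <- mutual_information(rates, labels, n_bins = n_bins)
    bins <- floor(rates * n_bins) + 1  # equal-width over [0, 1) near enough
    # oracle on the same discretization the implementation used:
    rng <- range(rates)
    bins <- pmin(floor((rates - rng[1]) / diff(rng) * n_bins) + 1, n_bins)
    tab <- table(labels, bins)
    expect_equal(mi, mi_entropy_oracle(tab), tolerance = 1e-12)
  }
  # MI nonnegative, and zero iff the empirical joint factorizes
  tab_ind <- outer(c(10, 20), c(5, 15, 10))  # product table
  expect_equal(mi_entropy_oracle(tab_ind), 0, tolerance = 1e-12)
})

test_that("MI of condition-independent rates shrinks with sample size", {
  set.seed(51)
  mis <- sapply(c(40, 400), function(n) {
    mean(replicate(30, mutual_information(rpois(n, 5),
                                          rep(c("a", "b"), n / 2))))
  })
  expect_lt(mis[2], mis[1])  # positive plug-in bias decays with n
  expect_gt(mis[1], 0)
})

test_that("generic and vectorized MI permutation tests agree", {
  set.seed(52)
  rates <- rpois(40, 6)
  labels <- rep(c("a", "b"), each = 20)
  g <- permutation_selectivity_test(rates, labels, n_perm = 300)
  f <- mi_permutation_test(rates, labels, n_perm = 300)
  expect_equal(g$observed, f$observed, tolerance = 1e-12)
  # the two draws of the same null distribution agree in their moments
  # up to permutation sampling noise
  expect_lt(abs(mean(g$null) - mean(f$null)), 0.03)
  expect_lt(abs(stats::sd(g$null) - stats::sd(f$null)), 0.03)
  expect_lt(abs(g$p - f$p), 0.15)
})

test_that("extreme selectivity reaches the minimal attainable p", {
  set.seed(53)
  rates <- c(rnorm(20, 1, 0.05), rnorm(20, 40, 0.05))
  labels <- rep(c("a", "b"), each = 20)
  f <- mi_permutation_test(rates, labels, n_perm = 500)
  expect_equal(f$p, 1 / 501)
  expect_gt(f$normalized, 3)
  d <- rate_diff_perm_test(rates, labels == "a", n_perm = 500)
  expect_equal(d$p, 1 / 501)
})

test_that("a statistic equal to every null value yields p near 1", {
  rates <- rep(c(0, 50), 20)  # perfectly balanced two-bin rates
  labels <- rep(c("a", "b"), each = 20)
  expect_warning(
    r <- permutation_selectivity_test(rates, labels,
                                      statistic = function(r, l) 1,
                                      n_perm = 100),
    class = "ec_zero_null_sd")
  expect_equal(r$observed, 1)
  expect_equal(r$p, 1)
  expect_true(is.na(r$normalized))
})

test_that("null permutation p-values are superuniform across neurons", {
  set.seed(54)
  ps <- replicate(400, {
    r <- rpois(40, 4)
    mi_permutation_test(r, rep(c("a", "b"), each = 20), n_perm = 200)$p
  })
  # superuniformity: P(p <= alpha) <= alpha, up to binomial noise, at
  # every probed level
  for (alpha in c(0.01, 0.05, 0.2, 0.5)) {
    upper <- qbinom(0.995, 400, alpha) / 400
    expect_lte(mean(ps <= alpha), upper)
  }
  # but not wildly conservative either
  expect_gt(mean(ps <= 0.5), 0.3)
})

test_that("neuron categorization follows the two-contrast rule", {
  lv <- c("RELATIONAL", "PHYSICAL", "CONJUNCTIVE", "NONSELECTIVE")
  expect_equal(as.character(classify_neuron(0.01, 0.8, TRUE)), "RELATIONAL")
  expect_equal(as.character(classify_neuron(0.8, 0.01, TRUE)), "PHYSICAL")
  expect_equal(as.character(classify_neuron(0.01, 0.04, TRUE)), "CONJUNCTIVE")
  expect_equal(as.character(classify_neuron(0.5, 0.6, TRUE)), "NONSELECTIVE")
  expect_true(is.na(classify_neuron(0.01, 0.5, FALSE)))
  expect_error(classify_neuron(NA, 0.5, TRUE), class = "ec_input_error")
  expect_equal(levels(classify_neuron(0.5, 0.5, TRUE)), lv)
})

test_that("responsiveness test rejects unresponsive units at about alpha", {
  set.seed(55)
  trials <- toy_trials(n_alone = 10, n_paired = 10, iti = 15)
  hits <- replicate(60, {
    sp <- poisson_spike_set(trials, rates_hz = 5)
    responsiveness_test(sp$units[[1]], trials, n_perm = 199,
                        alpha = 0.05)$responsive
  })
  # 4 conditions at alpha = 0.05 each: family-wise rate <= ~0.19
  expect_lt(mean(hits), 0.35)
  # and a strongly evoked unit always rejects
  sp <- toy_spike_set(trials, seq(0.0, 0.59, by = 0.01))
  base <- sort(c(sp$units[[1]], runif(2000, 0, max(trials$cs_onset_s))))
  expect_true(responsiveness_test(base, trials, n_perm = 199)$responsive)
})

test_that("selectivity profiles recover generator classes on strong effects", {
  cfg <- generator_config(n_sessions = 1, iti_range = c(2000, 3000),
                          seed = 56)
  set.seed(56)
  tt <- simulate_trials(cfg)
  neurons <- list(
    neuron_spec(1, "RELATIONAL", baseline_rate = 8, effect_size = 4,
                trial_noise_sd = 0.05),
    neuron_spec(2, "PHYSICAL", baseline_rate = 8, effect_size = 4,
                trial_noise_sd = 0.05),
    neuron_spec(3, "NONSELECTIVE", baseline_rate = 8, effect_size = 3,
                trial_noise_sd = 0.05))
  ens <- structure(list(neurons = neurons, proportions = c(x = 1),
                        n_neurons = 3L), class = "ensemble_spec")
  sp <- simulate_spike_trains(tt, ens, config = cfg)
  prof <- selectivity_profiles(sp, tt, n_perm = 300)
  expect_equal(prof$category, c("RELATIONAL", "PHYSICAL", "NONSELECTIVE"))
  expect_true(all(prof$responsive))
  expect_gt(prof$abs_idx_rel[1], 0.3)
  expect_lt(prof$abs_idx_phys[1], 0.15)
  expect_gt(prof$mi_phys_norm[2], prof$mi_phys_norm[1])
})
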