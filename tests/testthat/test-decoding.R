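test_that("grid search order breaks ties toward small cost then gamma", {
  g <- svm_grid(cost_exp = c(3, -1), gamma_exp = c(1, -3))
  expect_equal(g$cost[1], 2^-1)
  expect_equal(g$gamma[1], 2^-3)
  expect_true(!is.unsorted(g$cost))
})

test_that("linearly separable features decode perfectly; constant features at chance", {
  set.seed(40)
  labs <- factor(rep(c("ACS_ALONE", "ACS_US", "VCS_ALONE", "VCS_US"),
                     each = 25))
  mu <- diag(4)[as.integer(labs), ]
  x <- cbind(mu, mu, mu, mu, mu) * 10 +
    matrix(rnorm(100 * 20, 0, 0.05), 100, 20)
  run <- decode_once(x, labs, grid = svm_grid_reduced())
  expect_equal(run$accuracy, 1)
  # confusion marginals: each row sums to the held-out count
  expect_true(all(rowSums(run$confusion) == 10))
  xc <- matrix(1, 100, 20)
  runc <- decode_once(xc, labs, grid = svm_grid_reduced())
  expect_equal(runc$accuracy, 0.25)
})

test_that("null features decode at chance on average", {
  set.seed(41)
  labs <- factor(rep(c("a", "b", "c", "d"), each = 20))
  accs <- replicate(30, decode_once(matrix(rnorm(80 * 30), 80, 30), labs,
                                    grid = svm_grid_reduced())$accuracy)
  se <- sqrt(0.25 * 0.75 / (30 * 40))
  expect_lt(abs(mean(accs) - 0.25), 3 * se)
})

test_that("decoding runs are reproducible from the RNG state", {
  labs <- factor(rep(c("a", "b", "c", "d"), each = 20))
  x <- matrix(rnorm(80 * 15), 80, 15)
  set.seed(42); r1 <- decode_once(x, labs, grid = svm_grid_reduced())
  set.seed(42); r2 <- decode_once(x, labs, grid = svm_grid_reduced())
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$sampled, r2$sampled)
  expect_identical(unname(r1$predicted), unname(r2$predicted))
})

test_that("insufficient trials are reported with the condition name", {
  labs <- factor(c(rep("a", 20), rep("b", 12)))
  x <- matrix(rnorm(32 * 5), 32, 5)
  expect_error(decode_once(x, labs, grid = svm_grid_reduced()),
               "b", class = "ec_input_error")
})

test_that("chance distributions center at 1/k and ignore informative features", {
  set.seed(43)
  labs4 <- factor(rep(c("a", "b", "c", "d"), each = 20))
  x <- matrix(rnorm(80 * 20), 80, 20)
  ch4 <- chance_calibration(x, labs4, grid = svm_grid_reduced(),
                            n_shuffles = 30)
  expect_lt(abs(mean(ch4$accuracies) - 0.25), 0.05)
  expect_gte(ch4$cutoff, mean(ch4$accuracies))
  labs2 <- factor(rep(c("a", "b"), each = 40))
  ch2 <- chance_calibration(x, labs2, n_train = 20, n_test = 20,
                            grid = svm_grid_reduced(), n_shuffles = 30)
  expect_lt(abs(mean(ch2$accuracies) - 0.5), 0.06)
  # informative features do not move the shuffled-label chance level
  mu <- diag(4)[as.integer(labs4), ] * 8
  xi <- cbind(x[, 1:10], mu)
  chi <- chance_calibration(xi, labs4, grid = svm_grid_reduced(),
                            n_shuffles = 30)
  expect_lt(abs(mean(chi$accuracies) - mean(ch4$accuracies)), 0.08)
})

test_that("stage decoding emits relative accuracy and honors labelings", {
  set.seed(44)
  n_units <- 25
  labs <- factor(rep(c("ACS_ALONE", "ACS_US", "VCS_ALONE", "VCS_US"),
                     each = 20))
  # relational-coded population: paired conditions share an offset
  base <- matrix(rpois(n_units * 80, 4), n_units, 80)
  base[, grepl("US$", labs)] <- base[, grepl("US$", labs)] + 6
  res <- decode_stage(base, labs, labeling = "relational_binary",
                      n_sets = 2, n_neurons = 10,
                      grid = svm_grid_reduced(), n_shuffles = 10)
  expect_equal(nrow(res$per_set), 2)
  expect_true(all(res$per_set$relative <= res$per_set$raw))
  expect_gt(res$mean_relative, 0.2)
  resp <- decode_stage(base, labs, labeling = "physical_binary",
                       n_sets = 2, n_neurons = 10,
                       grid = svm_grid_reduced(), n_shuffles = 10)
  expect_lt(resp$mean_relative, res$mean_relative)
  expect_error(decode_stage(base, labs, labeling = "bogus", n_sets = 1,
                            n_neurons = 5, grid = svm_grid_reduced(),
                            n_shuffles = 10),
               class = "ec_config_error")
  expect_warning(decode_stage(base, labs, labeling = "fourway", n_sets = 1,
                              n_neurons = 500, grid = svm_grid_reduced(),
                              n_shuffles = 5),
                 class = "ec_small_pool")
})

test_that("label collapses preserve four-way information", {
  labs <- c("ACS_ALONE", "ACS_US", "VCS_ALONE", "VCS_US")
  expect_equal(as.character(collapse_labels(labs, "relational")),
               c("ALONE", "PAIRED", "ALONE", "PAIRED"))
  expect_equal(as.character(collapse_labels(labs, "physical")),
               c("ACS", "ACS", "VCS", "VCS"))
  expect_equal(as.character(collapse_labels(
    c("ACS_ALONE_B1", "ACS_US_B2"), "box")), c("B1", "B2"))
  # collapsing the predictions of a 4-way decoder can only help accuracy
  set.seed(45)
  truth <- factor(sample(labs, 200, replace = TRUE))
  pred <- factor(ifelse(runif(200) < 0.6, as.character(truth),
                        sample(labs, 200, replace = TRUE)), levels = labs)
  acc4 <- mean(pred == truth)
  acc2 <- mean(collapse_labels(pred, "relational") ==
                 collapse_labels(truth, "relational"))
  expect_gte(acc2, acc4)
})

test_that("parameter sweeps favor informative windows and larger ensembles", {
  cfg <- generator_config(n_sessions = 1, n_cs_alone = 20, n_paired = 30,
                          iti_range = c(2000, 3000), seed = 46)
  set.seed(46)
  tt <- simulate_trials(cfg)
  neurons <- lapply(1:30, function(i)
    neuron_spec(i, sample(c("RELATIONAL", "PHYSICAL", "CONJUNCTIVE"), 1),
                baseline_rate = runif(1, 4, 12), effect_size = 4,
                trial_noise_sd = 0.1))
  ens <- structure(list(neurons = neurons, proportions = c(RELATIONAL = 1),
                        n_neurons = 30L), class = "ensemble_spec")
  sp <- simulate_spike_trains(tt, ens, config = cfg)
  sw <- sweep_parameters(sp, tt,
                         windows = list(c(100, 300), c(-300, -100)),
                         n_neurons_seq = c(5, 30),
                         n_repeats = 3, n_shuffles = 10)
  post <- sw$accuracy[sw$sweep == "window" & sw$win_start == 100]
  pre <- sw$accuracy[sw$sweep == "window" & sw$win_start == -300]
  # stimulus-locked coding: pre-CS window is at chance, post-CS far above
  expect_gt(post, pre + 0.2)
  expect_lt(abs(pre - 0.25), 0.2)
  nn <- sw[sw$sweep == "n_neurons", ]
  expect_gte(nn$accuracy[nn$n_neurons == 30],
             nn$accuracy[nn$n_neurons == 5] - 0.05)
})
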