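#' Configuration of a full pipeline run
#'
#' Collects everything [run_pipeline()] needs: either a synthetic-data
#' recipe (`generator` + `ensemble`) or paths to on-disk inputs, plus the
#' analysis parameters. Stage criteria default to the behavioral
#' segmentation constants (30% / 60% CR, 2-day run, 7-day weeks).
#'
#' @param generator a `generator_config` (for synthetic input), or NULL.
#' @param ensemble an `ensemble_spec`, or NULL.
#' @param trials_path,spikes_dir optional on-disk inputs (CSV trial table,
#'   per-unit CSV directory) used when `generator` is NULL.
#' @param outdir optional output directory; when given, all tables are
#'   written as CSV plus a JSON summary.
#' @param trace_window trace-interval analysis window (ms).
#' @param decode_window decoding feature window (ms, first 200 ms after
#'   CS offset).
#' @param bin_width similarity-analysis bin width (ms).
#' @param n_perm permutations for similarity and selectivity tests.
#' @param n_sets,n_neurons,n_shuffles decoding parameters.
#' @param n_train,n_test decoding trials per four-way condition in the
#'   train and test halves.
#' @param k_folds cross-validation folds for the SVM grid search.
#' @param grid SVM hyperparameter grid.
#' @param before_criterion,asymptote_criterion,run_length,week_length
#'   stage-segmentation constants (CR%, days).
#' @param seed global seed, recorded in all outputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(generator = NULL, ensemble = NULL,
                       trials_path = NULL, spikes_dir = NULL,
                       outdir = NULL,
                       trace_window = c(100, 600),
                       decode_window = c(100, 300),
                       bin_width = 50,
                       n_perm = 1000,
                       n_sets = 20, n_neurons = 150, n_shuffles = 50,
                       n_train = 10, n_test = 10, k_folds = 5,
                       grid = svm_grid_reduced(),
                       before_criterion = 30, asymptote_criterion = 60,
                       run_length = 2L, week_length = 7L,
                       seed = 1L) {
  if (is.null(generator)) {
    if (is.null(trials_path) || is.null(spikes_dir))
      ec_config_error(
        "either a generator config or input paths must be supplied")
    for (p in c(trials_path, spikes_dir))
      if (!file.exists(p)) ec_config_error("input path does not exist: %s", p)
  } else if (is.null(ensemble)) {
    ec_config_error("a generator config requires an ensemble spec")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data generation (or loading), EMG
#' conditioned-response scoring and stage segmentation, unit quality
#' control, population-vector similarity with permutation inference,
#' stage-wise relative decoding accuracy for the relational and physical
#' dimensions, and single-neuron selectivity profiles. Idempotent for a
#' fixed config and seed.
#'
#' @param config a `run_config`.
#' @return list of class `pipeline_result` with elements `behavior`,
#'   `sessions`, `stages`, `qc`, `similarity`, `decoding`, `selectivity`,
#'   `summary` (the JSON-serializable digest, including the seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stage_fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  ## --- data -----------------------------------------------------------
  if (!is.null(config$generator)) {
    gen <- config$generator
    # draw per-session stages later from behavior; simulate with a
    # provisional schedule following the configured learning trajectory
    provisional <- stats::setNames(
      rep("LEARNING", gen$n_sessions), seq_len(gen$n_sessions))
    p_cr <- learning_trajectory(gen)
    guess <- assign_stages_from_prob(p_cr, config)
    provisional[!is.na(guess)] <- as.character(guess[!is.na(guess)])
    dataset <- generate_dataset(gen, config$ensemble,
                                stage_schedule = provisional)
    trials <- dataset$trials
    emg <- dataset$emg
    spikes <- dataset$spikes
  } else {
    trials <- read_trial_table(config$trials_path)
    spikes <- read_spike_trains(config$spikes_dir)
    emg <- NULL
  }

  ## --- behavior -------------------------------------------------------
  behavior <- sessions <- stages <- NULL
  if (!is.null(emg)) {
    gen <- config$generator
    behavior <- tryCatch(
      do.call(rbind, lapply(emg, score_session, config = gen)),
      error = function(e) stage_fail("behavior", e))
    sessions <- compute_cr_percent(behavior)
    daily <- daily_paired_cr(sessions)
    stages <- withCallingHandlers(
      assign_stages(daily,
                    before_criterion = config$before_criterion,
                    asymptote_criterion = config$asymptote_criterion,
                    run_length = config$run_length,
                    week_length = config$week_length),
      ec_no_asymptote = function(w) invokeRestart("muffleWarning"))
  }

  ## --- spike QC -------------------------------------------------------
  qc <- tryCatch(qc_filter(spikes), error = function(e) stage_fail("qc", e))
  spikes <- qc$spikes

  stage_of_session <- if (!is.null(stages))
    stats::setNames(as.character(stages), names(daily_paired_cr(sessions)))
  else stats::setNames(spikes$manifest$stage, spikes$manifest$session_id)

  ## --- per-stage analyses --------------------------------------------
  stage_levels <- c("BEFORE", "LEARNING", "POST_1W", "POST_2W", "POST_3W")
  similarity <- list(); decoding <- list(); selectivity <- list()
  for (st in stage_levels) {
    sess_ids <- as.numeric(names(stage_of_session))[
      !is.na(stage_of_session) & stage_of_session == st]
    if (!length(sess_ids)) next
    # one representative session per stage keeps trial counts canonical
    # across stages; remaining sessions contribute via the unit pool
    tt_all <- trials[trials$session_id %in% sess_ids, ]
    sp <- structure(list(
      units = spikes$units[spikes$manifest$session_id %in% sess_ids],
      manifest = spikes$manifest[
        spikes$manifest$session_id %in% sess_ids, , drop = FALSE]),
      class = "spike_train_set")
    if (!length(sp$units)) next
    # pseudo-population rate matrix: units from every session of this
    # stage, aligned by within-condition trial order
    feats <- pseudo_population_rates(sp, tt_all, config$decode_window)
    labels <- feats$labels
    similarity[[st]] <- tryCatch({
      s0 <- sess_ids[1]
      tens <- bin_rates(
        structure(list(
          units = sp$units[sp$manifest$session_id == s0],
          manifest = sp$manifest[sp$manifest$session_id == s0, ,
                                 drop = FALSE]),
          class = "spike_train_set"),
        trials[trials$session_id == s0, ],
        bin_width = config$bin_width, normalization = "MAX")
      similarity_difference_permtest(tens, n_perm = config$n_perm)
    }, error = function(e) stage_fail(paste0("ensemble/", st), e))
    decoding[[st]] <- tryCatch(lapply(
      c(relational = "relational_binary", physical = "physical_binary"),
      function(lb) decode_stage(feats$rates, labels, labeling = lb,
                                n_sets = config$n_sets,
                                n_neurons = config$n_neurons,
                                n_train = config$n_train,
                                n_test = config$n_test,
                                grid = config$grid,
                                k_folds = config$k_folds,
                                n_shuffles = config$n_shuffles)),
      error = function(e) stage_fail(paste0("decoding/", st), e))
    selectivity[[st]] <- tryCatch(
      cbind(stage = st,
            selectivity_profiles(sp, tt_all, window = config$trace_window,
                                 n_perm = config$n_perm)),
      error = function(e) stage_fail(paste0("selectivity/", st), e))
  }
  selectivity <- do.call(rbind, selectivity)

  summary <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ensemblecode")),
    n_units_passed = length(spikes$units),
    stages = if (!is.null(stages)) as.character(stages) else NULL,
    relative_accuracy = lapply(decoding, function(d)
      lapply(d, function(r) r$mean_relative)),
    category_proportions = if (!is.null(selectivity))
      lapply(split(selectivity$category, selectivity$stage), function(x)
        as.list(prop.table(table(factor(x, levels = c(
          "RELATIONAL", "PHYSICAL", "CONJUNCTIVE", "NONSELECTIVE"))))))
    else NULL)

  out <- structure(list(behavior = behavior, sessions = sessions,
                        stages = stages, qc = qc$report,
                        similarity = similarity, decoding = decoding,
                        selectivity = selectivity, summary = summary),
                   class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_outputs(out, config$outdir)
  out
}

## crude stage guess from the configured CR trajectory, used only to give
## the generator a stage schedule before behavior is scored
assign_stages_from_prob <- function(p_cr, config) {
  assign_stages(100 * p_cr,
                before_criterion = config$before_criterion,
                asymptote_criterion = config$asymptote_criterion,
                run_length = config$run_length,
                week_length = config$week_length)
}

#' Assemble pseudo-population rate features across sessions
#'
#' Concatenates units recorded in different sessions into one
#' units x trials matrix by matching trials of the same condition by
#' within-condition order (trial counts per condition must agree across
#' sessions). Units never recorded together this way contribute no
#' correlated noise, which the decoding analyses deliberately ignore.
#'
#' @param spikes a `spike_train_set` spanning one or more sessions.
#' @param trial_table trial table covering those sessions.
#' @param window rate window (ms, CS-relative).
#' @return list: `rates` (units x trials of the first session's schedule),
#'   `labels` (condition per trial column).
#' @export
pseudo_population_rates <- function(spikes, trial_table,
                                    window = c(100, 300)) {
  sess <- unique(spikes$manifest$session_id)
  ref_tt <- trial_table[trial_table$session_id == sess[1], ]
  ref_cond <- ref_tt$condition
  rows <- lapply(sess, function(s) {
    ss <- structure(list(
      units = spikes$units[spikes$manifest$session_id == s],
      manifest = spikes$manifest[spikes$manifest$session_id == s, ,
                                 drop = FALSE]),
      class = "spike_train_set")
    tt <- trial_table[trial_table$session_id == s, ]
    r <- trial_window_rates(ss, tt, window = window)
    # align columns to the reference schedule by within-condition order
    ord <- unlist(lapply(unique(ref_cond), function(cc) {
      mine <- which(tt$condition == cc)
      ref <- which(ref_cond == cc)
      if (length(mine) < length(ref))
        ec_input_error("session %s has %d %s trials; reference has %d",
                       s, length(mine), cc, length(ref))
      mine[seq_along(ref)]
    }))
    ref_ord <- unlist(lapply(unique(ref_cond), function(cc)
      which(ref_cond == cc)))
    out <- matrix(0, nrow(r), length(ref_cond),
                  dimnames = list(rownames(r), NULL))
    out[, ref_ord] <- r[, ord, drop = FALSE]
    out
  })
  list(rates = do.call(rbind, rows), labels = factor(ref_cond))
}

#' Write pipeline tables and summary to disk
#'
#' @param result a `pipeline_result`.
#' @param outdir directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) if (!is.null(x))
    utils::write.csv(x, file.path(outdir, name), row.names = FALSE)
  wr(result$behavior, "behavior.csv")
  wr(result$sessions, "sessions.csv")
  if (!is.null(result$stages))
    wr(data.frame(session = seq_along(result$stages),
                  stage = as.character(result$stages)), "stages.csv")
  wr(result$qc, "qc.csv")
  for (st in names(result$similarity))
    wr(result$similarity[[st]], sprintf("similarity_%s.csv", st))
  for (st in names(result$decoding))
    for (lb in names(result$decoding[[st]]))
      wr(result$decoding[[st]][[lb]]$per_set,
         sprintf("decoding_%s_%s.csv", st, lb))
  wr(result$selectivity, "selectivity.csv")
  jsonlite::write_json(result$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
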