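#' Instantaneous EMG amplitude via the analytic signal
#'
#' Computes the envelope of a signal as the magnitude of its analytic
#' signal (the FFT construction of the Hilbert transform: negative
#' frequencies zeroed, positive doubled).
#'
#' @param x numeric vector of samples.
#' @return numeric vector of the same length, all values >= 0.
#' @export
emg_envelope <- function(x) {
  if (any(!is.finite(x)))
    ec_input_error("EMG samples contain non-finite values")
  n <- length(x)
  if (n < 2) return(abs(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

## Mean envelope amplitude over [t0, t1) (seconds relative to CS onset)
## within one peri-trial segment whose first sample sits at time `seg_t0`
## relative to CS onset.
window_mean_env <- function(env, fs, seg_t0, t0, t1) {
  i0 <- floor((t0 - seg_t0) * fs) + 1
  i1 <- ceiling((t1 - seg_t0) * fs)
  if (i0 < 1 || i1 > length(env))
    ec_schedule_error("scoring window [%0.2f, %0.2f) s not covered by EMG",
                      t0, t1)
  mean(env[i0:min(i1, length(env))])
}

#' Score one trial's EMG for a conditioned response
#'
#' Computes the three scoring amplitudes from the EMG envelope and applies
#' the CR rule. The Pre-Value is the mean envelope over the 300 ms
#' immediately before CS onset; the CR-Value is the mean over the 200 ms
#' immediately before US onset; a pre-CS-phase control value is taken over
#' \[-1000, -800) ms. A trial contains a CR iff the CR-Value exceeds both
#' the Pre-Value and the session threshold; a trial whose Pre-Value exceeds
#' the threshold is flagged hyperactive (and is discarded from CR%
#' denominators downstream).
#'
#' @param env envelope samples of the peri-trial segment (from
#'   [emg_envelope()]).
#' @param fs sampling rate (Hz).
#' @param seg_t0 time of the first envelope sample relative to CS onset (s,
#'   negative).
#' @param us_onset US onset relative to CS onset (s).
#' @param threshold session-level amplitude threshold (see
#'   [session_threshold()]).
#' @return one-row data.frame: `pre_value`, `cr_value_post`,
#'   `cr_value_pre_phase`, `threshold`, `is_cr`, `is_hyperactive`.
#' @export
detect_cr <- function(env, fs, seg_t0, us_onset, threshold) {
  pre <- window_mean_env(env, fs, seg_t0, -0.3, 0)
  post <- window_mean_env(env, fs, seg_t0, us_onset - 0.2, us_onset)
  pre_phase <- window_mean_env(env, fs, seg_t0, -1.0, -0.8)
  data.frame(pre_value = pre,
             cr_value_post = post,
             cr_value_pre_phase = pre_phase,
             threshold = threshold,
             is_cr = post > pre & post > threshold,
             is_hyperactive = pre > threshold)
}

#' Session-level CR threshold
#'
#' The mean Pre-Value across trials plus two standard deviations, computed
#' in a single pass over all trials of the session (both epochs).
#'
#' @param pre_values numeric vector of per-trial Pre-Values.
#' @return scalar threshold.
#' @export
session_threshold <- function(pre_values) {
  mean(pre_values) + 2 * stats::sd(pre_values)
}

#' Score every trial of a session's EMG trace
#'
#' Computes per-trial envelope amplitudes, derives the session threshold
#' from all trials' Pre-Values, and applies the CR / hyperactive rules.
#'
#' @param emg an `emg_trace` (see [simulate_emg()]).
#' @param config a `generator_config` supplying stimulus timings.
#' @param threshold optional externally supplied threshold; default is
#'   computed from this session's Pre-Values via [session_threshold()].
#' @return data.frame with one row per trial: session, epoch, trial index,
#'   condition, and the [detect_cr()] fields.
#' @export
score_session <- function(emg, config, threshold = NULL) {
  stopifnot(inherits(emg, "emg_trace"))
  us_onset <- us_offset_s(config)
  fs <- emg$sample_rate
  seg <- emg$segments
  envs <- lapply(emg$samples, emg_envelope)
  # segments start 1.2 s before CS onset by construction
  pre <- vapply(seq_along(envs), function(i)
    window_mean_env(envs[[i]], fs, -1.2, -0.3, 0), numeric(1))
  if (is.null(threshold)) threshold <- session_threshold(pre)
  res <- do.call(rbind, lapply(seq_along(envs), function(i)
    detect_cr(envs[[i]], fs, -1.2, us_onset, threshold)))
  cbind(data.frame(session_id = emg$session_id, epoch = seg$epoch,
                   trial_index = seg$trial_index, condition = seg$condition),
        res)
}

#' Per-condition conditioned-response percentage
#'
#' CR% is 100 times the number of CR trials over the number of valid
#' (non-hyperactive) trials, per condition.
#'
#' @param cr_results data.frame of scored trials (from [score_session()]).
#' @return data.frame with `session_id`, `condition`, `n_valid`, `n_cr`,
#'   `cr_percent` (NA, with a warning, for conditions with no valid
#'   trial), and `hyperactive_fraction`.
#' @export
compute_cr_percent <- function(cr_results) {
  split_by <- interaction(cr_results$session_id, cr_results$condition,
                          drop = TRUE)
  out <- do.call(rbind, lapply(split(cr_results, split_by), function(d) {
    valid <- !d$is_hyperactive
    n_valid <- sum(valid)
    cr_pct <- if (n_valid == 0) {
      ec_warn("ec_undefined_cr",
              "no valid trials for condition %s in session %s; CR%% undefined",
              d$condition[1], d$session_id[1])
      NA_real_
    } else 100 * sum(d$is_cr[valid]) / n_valid
    data.frame(session_id = d$session_id[1], condition = d$condition[1],
               n_valid = n_valid, n_cr = sum(d$is_cr[valid]),
               cr_percent = cr_pct,
               hyperactive_fraction = mean(d$is_hyperactive))
  }))
  rownames(out) <- NULL
  out
}

#' Segment daily sessions into learning stages
#'
#' Assigns each session (one per day, in chronological order) to one of the
#' five learning stages from its daily CR% on CS-US paired trials:
#' \describe{
#'   \item{BEFORE}{all days prior to the first day with CR% at or above
#'     `before_criterion` (default 30%).}
#'   \item{LEARNING}{from that day up to and including the first run of
#'     `run_length` (default 2) consecutive days with CR% at or above
#'     `asymptote_criterion` (default 60%).}
#'   \item{POST_1W / POST_2W / POST_3W}{successive 7-day blocks after the
#'     asymptote trigger.}
#' }
#' Days beyond the third post-learning week are returned as `NA` (excluded)
#' and counted in the `n_excluded` attribute. If the asymptote criterion is
#' never met, all non-BEFORE days are labeled LEARNING and a warning is
#' raised.
#'
#' @param daily_cr numeric vector of daily CR% values (paired conditions),
#'   one per day in chronological order.
#' @param before_criterion,asymptote_criterion CR% criteria (percent).
#' @param run_length consecutive days required at the asymptote criterion.
#' @param week_length days per post-learning block.
#' @param n_weeks number of post-learning blocks retained.
#' @return factor of stage labels (levels BEFORE, LEARNING, POST_1W,
#'   POST_2W, POST_3W) with attributes `asymptote_day` (last LEARNING day,
#'   NA if never reached) and `n_excluded`.
#' @export
assign_stages <- function(daily_cr,
                          before_criterion = 30,
                          asymptote_criterion = 60,
                          run_length = 2L,
                          week_length = 7L,
                          n_weeks = 3L) {
  if (any(!is.finite(daily_cr)))
    ec_input_error("daily CR%% sequence contains non-finite values")
  n <- length(daily_cr)
  levels <- c("BEFORE", "LEARNING",
              paste0("POST_", seq_len(n_weeks), "W"))
  stage <- rep(NA_character_, n)
  first_reach <- which(daily_cr >= before_criterion)[1]
  if (is.na(first_reach)) {
    out <- factor(rep("BEFORE", n), levels = levels)
    attr(out, "asymptote_day") <- NA_integer_
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  if (first_reach > 1) stage[seq_len(first_reach - 1)] <- "BEFORE"
  # first run of `run_length` consecutive days at the asymptote criterion
  hit <- daily_cr >= asymptote_criterion
  runs <- which(vapply(seq_len(n - run_length + 1L), function(i)
    all(hit[i:(i + run_length - 1L)]), logical(1)))
  runs <- runs[runs >= first_reach]
  if (length(runs) == 0) {
    stage[first_reach:n] <- "LEARNING"
    ec_warn("ec_no_asymptote",
            "asymptote criterion (%g%% on %d consecutive days) never met; %s",
            asymptote_criterion, run_length,
            "all non-BEFORE days labeled LEARNING")
    asymptote_day <- NA_integer_
    n_excluded <- 0L
  } else {
    asymptote_day <- runs[1] + run_length - 1L  # trigger days are LEARNING
    stage[first_reach:asymptote_day] <- "LEARNING"
    post <- seq(asymptote_day + 1L, length.out = n - asymptote_day)
    if (length(post) > 0) {
      week <- (post - asymptote_day - 1L) %/% week_length + 1L
      keep <- week <= n_weeks
      stage[post[keep]] <- paste0("POST_", week[keep], "W")
    }
    n_excluded <- sum(is.na(stage))
  }
  out <- factor(stage, levels = levels)
  attr(out, "asymptote_day") <- asymptote_day
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Daily CR% on paired trials from per-condition session summaries
#'
#' Convenience wrapper: averages `cr_percent` over the CS-US paired
#' conditions of each session, the quantity [assign_stages()] consumes.
#'
#' @param session_behavior data.frame from [compute_cr_percent()] rows
#'   (possibly several sessions).
#' @return named numeric vector, one value per session in order.
#' @export
daily_paired_cr <- function(session_behavior) {
  paired <- session_behavior[is_paired_label(session_behavior$condition), ]
  out <- tapply(paired$cr_percent, paired$session_id,
                function(x) mean(x, na.rm = TRUE))
  out <- stats::setNames(as.numeric(out), names(out))
  out[order(as.numeric(names(out)))]
}
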