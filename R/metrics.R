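# Peri-event summary metrics on z-scored activity: AUC, time to peak,
# maximum z, and early/late trial splits.

# Trial-averaged z trace of one neuron within a window around the alignment
# event. Returns the averaged samples and their times (s, relative to the
# alignment event). Uses the per-trial alignment offsets stored in the
# zscored_tensor, so windows are event-relative even for head-entry
# alignment.
.zwindow_average <- function(z, neuron_id, window_s, trial_subset = NULL) {
  stopifnot(inherits(z, "zscored_tensor"))
  if (!.is_window(window_s)) .stopf("window_s must be numeric [start, end) with start < end")
  i <- match(neuron_id, z$neuron_ids)
  if (is.na(i)) .stopf("neuron '%s' not present", neuron_id)
  trials <- seq_len(dim(z$values)[2])
  if (!is.null(trial_subset)) {
    if (length(trial_subset) == 0L) .stopf("trial subset is empty")
    if (!all(trial_subset %in% trials)) .stopf("trial subset out of range")
    trials <- trial_subset
  }
  if (all(z$flagged[i, trials])) {
    .stopf("metric undefined: all selected trials of neuron '%s' have zero-variance baselines",
           neuron_id)
  }
  rate <- z$sampling_rate
  origin <- z$trial_time_origin
  n_time <- dim(z$values)[3]
  n_samples <- .window_n_samples(window_s, rate)
  acc <- matrix(NA_real_, length(trials), n_samples)
  for (k in seq_along(trials)) {
    idx <- .window_index(window_s + z$alignment_offsets_s[trials[k]], rate, origin)
    if (idx[1] < 1L || idx[2] > n_time) {
      .stopf("window [%g, %g) falls outside the recorded span on trial %d",
             window_s[1], window_s[2], trials[k])
    }
    acc[k, ] <- z$values[i, trials[k], idx[1]:idx[2]]
  }
  list(trace = colMeans(acc),
       times = window_s[1] + (seq_len(n_samples) - 1) / rate,
       n_trials_used = length(trials))
}

#' Area under the trial-averaged z-scored trace
#'
#' Trapezoidal integral (in z-score x seconds) of the trial-averaged z trace
#' over the half-open window `[start, end)`. The window contributes the
#' samples at `start, start + 1/rate, ..., end - 1/rate`; trapezoids of width
#' `1/rate` connect consecutive included samples, so a window of length L at
#' rate r integrates over `L - 1/r` seconds (e.g. a constant z = 1 over
#' `[0, 5)` at 10 Hz gives exactly 4.9). Adjacent windows therefore omit the
#' bridging trapezoid across their shared boundary; see the package vignette.
#'
#' @param z A `zscored_tensor` from [zscore_session()].
#' @param neuron_id Neuron to evaluate.
#' @param window_s `[start, end)` in seconds relative to the alignment event.
#' @param trial_subset Optional integer trial indices (e.g. from
#'   [split_trials()]).
#' @return A single number in z·s.
#' @export
auc <- function(z, neuron_id, window_s, trial_subset = NULL) {
  avg <- .zwindow_average(z, neuron_id, window_s, trial_subset)
  y <- avg$trace
  if (length(y) < 2L) return(0)
  dt <- 1 / z$sampling_rate
  sum((y[-1] + y[-length(y)]) / 2) * dt
}

#' Time of peak trial-averaged activity
#'
#' Time (seconds, relative to the alignment event) of the maximum of the
#' trial-averaged z trace within the window; ties resolve to the earliest
#' sample.
#'
#' @inheritParams auc
#' @return Seconds from the alignment event.
#' @export
time_to_peak <- function(z, neuron_id, window_s, trial_subset = NULL) {
  avg <- .zwindow_average(z, neuron_id, window_s, trial_subset)
  avg$times[which.max(avg$trace)]
}

#' Maximum trial-averaged z-score within a window
#'
#' @inheritParams auc
#' @return The maximum z value.
#' @export
peak_z <- function(z, neuron_id, window_s, trial_subset = NULL) {
  avg <- .zwindow_average(z, neuron_id, window_s, trial_subset)
  max(avg$trace)
}

#' Split trials into early and late subsets
#'
#' @param n_trials Trial count, or a [session_recording()].
#' @param scheme `"half"` (first ceiling(n/2) vs the rest) or
#'   `"first_k_last_k"` (trials `1..k` vs `n-k+1..n`).
#' @param k Subset size for `"first_k_last_k"`; must satisfy `k <= n/2`.
#' @return A list with integer vectors `early` and `late`.
#' @export
split_trials <- function(n_trials, scheme = c("half", "first_k_last_k"), k = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(n_trials, "session_recording")) n_trials <- dim(n_trials$traces)[2]
  n <- as.integer(n_trials)
  if (n < 1L) .stopf("need at least one trial")
  if (scheme == "half") {
    h <- ceiling(n / 2)
    early <- seq_len(h)
    late <- if (h < n) (h + 1L):n else integer(0)
    if (length(late) == 0L) .warnf("only %d trial(s): late subset is empty", n)
  } else {
    if (is.null(k) || k < 1L || k > n / 2) {
      .stopf("k must satisfy 1 <= k <= n_trials/2")
    }
    early <- seq_len(k)
    late <- (n - k + 1L):n
  }
  list(early = early, late = as.integer(late))
}

#' Per-neuron metric report
#'
#' Computes AUC, time to peak and maximum z for every neuron over a stated
#' window, optionally on a trial subset.
#'
#' @inheritParams auc
#' @param stimulus Label recorded in the output (free text).
#' @param trial_subset_name Label for the trial subset column
#'   (default `"all"`).
#' @return A data.frame keyed by (`neuron_id`, `stimulus`, `trial_subset`)
#'   with columns `auc`, `time_to_peak_s`, `peak_z`, `n_trials_used`.
#'   Neurons whose every selected trial is zero-variance-flagged get `NA`
#'   metrics.
#' @export
metric_report <- function(z, window_s, stimulus = "stimulus",
                          trial_subset = NULL, trial_subset_name = "all") {
  stopifnot(inherits(z, "zscored_tensor"))
  ids <- z$neuron_ids
  n_used <- if (is.null(trial_subset)) dim(z$values)[2] else length(trial_subset)
  out <- data.frame(neuron_id = ids, stimulus = stimulus,
                    trial_subset = trial_subset_name,
                    auc = NA_real_, time_to_peak_s = NA_real_,
                    peak_z = NA_real_, n_trials_used = n_used,
                    stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    ok <- tryCatch({
      out$auc[k] <- auc(z, ids[k], window_s, trial_subset)
      out$time_to_peak_s[k] <- time_to_peak(z, ids[k], window_s, trial_subset)
      out$peak_z[k] <- peak_z(z, ids[k], window_s, trial_subset)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) out$n_trials_used[k] <- 0L
  }
  out
}
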