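#' Event schedule for a trial-structured conditioning session
#'
#' Times are in seconds relative to CS (conditioned stimulus) onset. The
#' default schedule is a 10 s CS with the unconditioned stimulus (food pellet
#' or foot shock) delivered 3 s after CS offset, i.e. 13 s after CS onset.
#'
#' @param cs_onset_s CS onset time (0 by convention).
#' @param cs_offset_s CS offset time.
#' @param us_onset_s Unconditioned-stimulus delivery time.
#' @param head_entry_s Optional numeric vector, one value per trial, giving
#'   the first head entry into the food receptacle after US delivery
#'   (appetitive sessions only); `NA` marks trials without a head entry.
#' @return An object of class `event_schedule`.
#' @export
event_schedule <- function(cs_onset_s = 0, cs_offset_s = 10, us_onset_s = 13,
                           head_entry_s = NULL) {
  if (!(cs_onset_s < cs_offset_s && cs_offset_s < us_onset_s)) {
    .stopf("event schedule must satisfy cs_onset_s < cs_offset_s < us_onset_s")
  }
  structure(
    list(cs_onset_s = cs_onset_s, cs_offset_s = cs_offset_s,
         us_onset_s = us_onset_s, head_entry_s = head_entry_s),
    class = "event_schedule")
}

#' Trial-aligned calcium recording for one session
#'
#' Container for a session's peri-CS calcium traces: a numeric tensor of
#' dimension neurons x trials x timepoints, sampled at `sampling_rate` Hz,
#' with trial time measured relative to CS onset. By default each trial trace
#' spans -30 s to +30 s around CS onset (`trial_time_origin = 30`, 600 samples
#' at 10 Hz).
#'
#' @param traces Numeric array `[n_neurons, n_trials, n_timepoints]`.
#' @param neuron_ids Character vector of unique neuron identifiers.
#' @param paradigm One of `"appetitive"`, `"fear"`, `"baseline"`, `"post_test"`.
#' @param session_id Free-text session identifier.
#' @param sampling_rate Sampling rate in Hz.
#' @param trial_time_origin Seconds from trial-trace start to CS onset.
#' @param events An [event_schedule()]. If it carries head-entry times their
#'   length must equal the trial count.
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(traces, neuron_ids, paradigm, session_id = paradigm,
                              sampling_rate = 10, trial_time_origin = 30,
                              events = event_schedule()) {
  paradigm <- match.arg(paradigm, c("appetitive", "fear", "baseline", "post_test"))
  if (!is.array(traces) || length(dim(traces)) != 3L) {
    .stopf("traces must be a 3-d array [n_neurons x n_trials x n_timepoints]")
  }
  if (!is.numeric(traces)) .stopf("traces must be numeric")
  storage.mode(traces) <- "double"
  neuron_ids <- as.character(neuron_ids)
  if (anyDuplicated(neuron_ids)) .stopf("neuron_ids must be unique")
  if (dim(traces)[1] != length(neuron_ids)) {
    .stopf("traces first dimension (%d) must equal length(neuron_ids) (%d)",
           dim(traces)[1], length(neuron_ids))
  }
  if (!inherits(events, "event_schedule")) .stopf("events must be an event_schedule")
  n_trials <- dim(traces)[2]
  n_time <- dim(traces)[3]
  span <- n_time / sampling_rate
  t_min <- -trial_time_origin
  t_max <- span - trial_time_origin
  ev_times <- c(events$cs_onset_s, events$cs_offset_s, events$us_onset_s)
  if (!is.null(events$head_entry_s)) {
    if (length(events$head_entry_s) != n_trials) {
      .stopf("head_entry_s must have one entry per trial (%d), got %d",
             n_trials, length(events$head_entry_s))
    }
    ev_times <- c(ev_times, events$head_entry_s[!is.na(events$head_entry_s)])
  }
  if (n_time > 0 && length(ev_times) &&
      (min(ev_times) < t_min - .grid_eps || max(ev_times) > t_max + .grid_eps)) {
    .stopf("event times must lie within the recorded trial span [%g, %g)",
           t_min, t_max)
  }
  dimnames(traces) <- list(neuron_ids, NULL, NULL)
  structure(
    list(session_id = as.character(session_id), paradigm = paradigm,
         traces = traces, sampling_rate = sampling_rate,
         trial_time_origin = trial_time_origin, neuron_ids = neuron_ids,
         events = events),
    class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  d <- dim(x$traces)
  cat(sprintf("<session_recording> %s (%s): %d neurons x %d trials x %d timepoints @ %g Hz\n",
              x$session_id, x$paradigm, d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  trial time span: [%g, %g) s around CS onset; US at %g s\n",
              -x$trial_time_origin,
              d[3] / x$sampling_rate - x$trial_time_origin,
              x$events$us_onset_s))
  invisible(x)
}

#' @export
dim.session_recording <- function(x) dim(x$traces)

#' Pre/post analysis windows for one stimulus test
#'
#' Defines the three second-denominated windows of the responsiveness test,
#' all relative to CS onset: the isolation window (the stretch of trace the
#' circular shift operates on), and the disjoint pre- and post-stimulus
#' windows within it that the rank-sum statistic compares.
#'
#' Defaults follow the conditioning design (10 s CS; US at 13 s):
#' \describe{
#'   \item{cs}{isolation `[-30, 10)`, pre `[-20, 0)`, post `[0, 10)`}
#'   \item{food}{isolation `[-30, 30)`, pre `[-5, 13)`, post `[13, 30)`}
#'   \item{shock}{isolation `[-30, 30)`, pre `[-5, 13)`, post `[13, 18)`}
#'   \item{head_entry}{isolation `[-30, 30)`, pre `[-5, 0)`, post `[0, 5)`,
#'     a package default for head-entry-aligned summaries}
#' }
#'
#' @param stimulus One of `"cs"`, `"food"`, `"shock"`, `"head_entry"`.
#' @param isolation_window_s,pre_window_s,post_window_s Optional `[start, end)`
#'   overrides in seconds relative to CS onset.
#' @return An object of class `analysis_windows`.
#' @export
analysis_windows <- function(stimulus = c("cs", "food", "shock", "head_entry"),
                             isolation_window_s = NULL, pre_window_s = NULL,
                             post_window_s = NULL) {
  stimulus <- match.arg(stimulus)
  defaults <- list(
    cs         = list(iso = c(-30, 10), pre = c(-20, 0), post = c(0, 10)),
    food       = list(iso = c(-30, 30), pre = c(-5, 13), post = c(13, 30)),
    shock      = list(iso = c(-30, 30), pre = c(-5, 13), post = c(13, 18)),
    head_entry = list(iso = c(-30, 30), pre = c(-5, 0),  post = c(0, 5)))[[stimulus]]
  iso <- if (is.null(isolation_window_s)) defaults$iso else isolation_window_s
  pre <- if (is.null(pre_window_s)) defaults$pre else pre_window_s
  post <- if (is.null(post_window_s)) defaults$post else post_window_s
  for (w in list(iso, pre, post)) {
    if (!.is_window(w)) .stopf("windows must be numeric [start, end) with start < end")
  }
  if (pre[1] < iso[1] || pre[2] > iso[2] || post[1] < iso[1] || post[2] > iso[2]) {
    .stopf("pre and post windows must lie inside the isolation window")
  }
  if (max(pre[1], post[1]) < min(pre[2], post[2])) {
    .stopf("pre and post windows must be disjoint")
  }
  structure(list(stimulus = stimulus, isolation_window_s = iso,
                 pre_window_s = pre, post_window_s = post),
            class = "analysis_windows")
}

#' @export
print.analysis_windows <- function(x, ...) {
  cat(sprintf("<analysis_windows> %s: isolation [%g, %g), pre [%g, %g), post [%g, %g) s\n",
              x$stimulus, x$isolation_window_s[1], x$isolation_window_s[2],
              x$pre_window_s[1], x$pre_window_s[2],
              x$post_window_s[1], x$post_window_s[2]))
  invisible(x)
}

# Per-trial alignment offsets in seconds relative to CS onset.
# head_entry returns NA for trials without a head entry.
.alignment_offsets <- function(session, alignment) {
  n_trials <- dim(session$traces)[2]
  switch(alignment,
    cs_onset = rep(session$events$cs_onset_s, n_trials),
    us_onset = rep(session$events$us_onset_s, n_trials),
    head_entry = {
      he <- session$events$head_entry_s
      if (is.null(he)) {
        .stopf("head_entry alignment requires head-entry events in the session")
      }
      he
    },
    .stopf("unknown alignment '%s'", alignment))
}

#' Extract a time window from every trial of a session
#'
#' Selects the samples of the half-open window `[start, end)` seconds around a
#' per-trial alignment event. Seconds map to sample indices by
#' `floor(t * rate)` relative to trial-trace start, so a window of length L at
#' rate r always yields `round(L * r)` samples.
#'
#' @param session A [session_recording()].
#' @param alignment `"cs_onset"`, `"us_onset"` or `"head_entry"`.
#' @param window_s Numeric `[start, end)` in seconds relative to the alignment
#'   event.
#' @param allow_missing For `head_entry` alignment: drop trials lacking a head
#'   entry (with a message) instead of erroring.
#' @return Numeric array `[n_neurons, n_trials_used, n_samples]` with an
#'   attribute `trials_used` giving the original trial indices retained.
#' @export
extract_window <- function(session, alignment = c("cs_onset", "us_onset", "head_entry"),
                           window_s, allow_missing = FALSE) {
  stopifnot(inherits(session, "session_recording"))
  alignment <- match.arg(alignment)
  if (!.is_window(window_s)) .stopf("window_s must be numeric [start, end) with start < end")
  offs <- .alignment_offsets(session, alignment)
  trials <- seq_along(offs)
  if (anyNA(offs)) {
    missing <- trials[is.na(offs)]
    if (!allow_missing) {
      .stopf("trial(s) %s lack a head-entry event (pass allow_missing = TRUE to drop them)",
             paste(missing, collapse = ", "))
    }
    message(sprintf("dropping %d trial(s) without a head entry: %s",
                    length(missing), paste(missing, collapse = ", ")))
    trials <- trials[!is.na(offs)]
    offs <- offs[trials]
  }
  rate <- session$sampling_rate
  origin <- session$trial_time_origin
  n_time <- dim(session$traces)[3]
  n_samples <- .window_n_samples(window_s, rate)
  out <- array(NA_real_, dim = c(dim(session$traces)[1], length(trials), n_samples))
  for (k in seq_along(trials)) {
    idx <- .window_index(window_s + offs[k], rate, origin)
    if (idx[1] < 1L || idx[2] > n_time) {
      .stopf("window [%g, %g) around the alignment event falls outside the recorded span on trial %d",
             window_s[1], window_s[2], trials[k])
    }
    out[, k, ] <- session$traces[, trials[k], idx[1]:idx[2], drop = FALSE]
  }
  dimnames(out) <- list(session$neuron_ids, NULL, NULL)
  attr(out, "trials_used") <- trials
  out
}

#' Peri-event z-scoring of a session
#'
#' Standardizes every neuron x trial trace against its own baseline: samples
#' in `baseline_window_s` around the alignment event define the mean and
#' standard deviation, and the whole trial trace is transformed to
#' `z = (x - mean) / sd`. Trials whose baseline has zero variance are flagged
#' and filled with zeros (with a warning) so population summaries can proceed.
#'
#' @param session A [session_recording()].
#' @param alignment Alignment event for the baseline window (default CS onset).
#' @param baseline_window_s Baseline window `[start, end)` in seconds relative
#'   to the alignment event; default `[-10, 0)`.
#' @param allow_missing Passed to [extract_window()] for head-entry alignment.
#' @return An object of class `zscored_tensor`: a list with `values` (array of
#'   the same shape as the traces of the retained trials), `flagged` (logical
#'   neurons x trials matrix of zero-variance baselines), `alignment_event`,
#'   `baseline_window_s`, `sampling_rate`, `trial_time_origin`, `neuron_ids`,
#'   `trials_used`.
#' @export
zscore_session <- function(session, alignment = c("cs_onset", "us_onset", "head_entry"),
                           baseline_window_s = c(-10, 0), allow_missing = FALSE) {
  stopifnot(inherits(session, "session_recording"))
  alignment <- match.arg(alignment)
  base <- extract_window(session, alignment, baseline_window_s,
                         allow_missing = allow_missing)
  trials <- attr(base, "trials_used")
  vals <- session$traces[, trials, , drop = FALSE]
  n_neurons <- dim(vals)[1]
  flagged <- matrix(FALSE, n_neurons, length(trials),
                    dimnames = list(session$neuron_ids, NULL))
  for (i in seq_len(n_neurons)) {
    for (k in seq_along(trials)) {
      b <- base[i, k, ]
      s <- stats::sd(b)
      if (!is.finite(s) || s < .Machine$double.eps * 100) {
        flagged[i, k] <- TRUE
        vals[i, k, ] <- 0
      } else {
        vals[i, k, ] <- (vals[i, k, ] - mean(b)) / s
      }
    }
  }
  if (any(flagged)) {
    .warnf("%d neuron x trial baseline(s) had zero variance; filled with zeros",
           sum(flagged))
  }
  offs <- .alignment_offsets(session, alignment)[trials]
  structure(
    list(values = vals, flagged = flagged, alignment_event = alignment,
         baseline_window_s = baseline_window_s,
         alignment_offsets_s = offs,
         sampling_rate = session$sampling_rate,
         trial_time_origin = session$trial_time_origin,
         neuron_ids = session$neuron_ids, trials_used = trials),
    class = "zscored_tensor")
}
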