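#' GCaMP-like transient model for the simulator
#'
#' Synthetic traces are built as Poisson-like calcium events convolved with a
#' peak-normalized difference-of-exponentials kernel
#' `k(t) = exp(-t / tau_decay) - exp(-t / tau_rise)`, on top of Gaussian
#' noise and a slow sinusoidal drift. Defaults emulate GCaMP6m dynamics
#' (fast rise, ~1.5 s decay). Traces are \eqn{\Delta F/F}-like (unconstrained
#' sign); the mode is recorded in the simulation metadata.
#'
#' @param baseline_event_rate Baseline calcium-event rate, Hz.
#' @param kernel_rise_s,kernel_decay_s Kernel time constants, seconds
#'   (rise < decay).
#' @param noise_sd Gaussian noise standard deviation, fluorescence units.
#' @param drift_amplitude Amplitude of the slow sinusoidal drift.
#' @param drift_period_s Drift period, seconds.
#' @param event_amplitude_mean Mean of the exponential amplitudes of baseline
#'   events.
#' @return An object of class `transient_model`.
#' @export
transient_model <- function(baseline_event_rate = 0.5, kernel_rise_s = 0.2,
                            kernel_decay_s = 1.5, noise_sd = 0.2,
                            drift_amplitude = 0.1, drift_period_s = 40,
                            event_amplitude_mean = 1) {
  vals <- c(baseline_event_rate, kernel_rise_s, kernel_decay_s, noise_sd,
            drift_amplitude, drift_period_s, event_amplitude_mean)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    .stopf("transient model parameters must be finite and non-negative")
  }
  if (kernel_rise_s >= kernel_decay_s) .stopf("kernel rise must be shorter than decay")
  structure(list(baseline_event_rate = baseline_event_rate,
                 kernel_rise_s = kernel_rise_s, kernel_decay_s = kernel_decay_s,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 event_amplitude_mean = event_amplitude_mean),
            class = "transient_model")
}

#' Fig-like default joint response distribution
#'
#' The default 3 x 3 joint probability table of (food, shock) response
#' categories used by [population_spec()]: rows are the food label, columns
#' the shock label, in order excited / inhibited / not_significant.
#' @return A 3 x 3 numeric matrix summing to 1.
#' @export
default_joint_probabilities <- function() {
  m <- matrix(c(36, 16, 60,
                25, 10, 50,
                34, 13, 59) / 303,
              nrow = 3, byrow = TRUE,
              dimnames = list(food = .response_levels, shock = .response_levels))
  m
}

#' Population specification for paired-session simulation
#'
#' Describes the simulated population of cross-session-registered neurons:
#' how many there are, the joint distribution of their true (food, shock)
#' response categories, how likely US-responsive neurons are to also carry a
#' direction-matched CS response, and the shape of injected responses.
#'
#' @param n_registered Number of registered neurons (present in both
#'   sessions).
#' @param joint_category_probabilities 3 x 3 matrix (rows = food label,
#'   columns = shock label, order excited / inhibited / not_significant)
#'   summing to 1 within 1e-9. Default:
#'   [default_joint_probabilities()].
#' @param cs_response_given_us Probability that a neuron with a given US
#'   response also responds to the corresponding CS in the same direction.
#' @param effect_size Peak amplitude of injected excitatory events, in units
#'   of the noise standard deviation.
#' @param response_latency_s Named vector with elements `cs`, `food` and
#'   `shock`: response onset latency after stimulus onset, seconds.
#' @param response_duration_s Named vector with elements `cs`, `food` and
#'   `shock`: response duration, seconds. Defaults reflect a sustained
#'   consummatory response to food, a brief response to shock, and a
#'   CS response spanning most of the 10 s tone.
#' @param latency_jitter_s Upper bound of the uniform per-trial latency
#'   jitter, seconds.
#' @param stim_event_rate Rate of added calcium events inside the response
#'   window of excited neurons, Hz.
#' @param suppression Fraction of baseline events removed inside the response
#'   window of inhibited neurons (1 = complete suppression).
#' @param head_entry_meanlog,head_entry_sdlog Lognormal parameters of the
#'   head-entry latency after food delivery, seconds (a stand-in; the
#'   source data give no latency distribution).
#' @param seed Master integer seed. Each neuron consumes an independent
#'   substream derived from it, so enlarging the population does not perturb
#'   existing neurons.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_registered = 303,
                            joint_category_probabilities = default_joint_probabilities(),
                            cs_response_given_us = 0.25,
                            effect_size = 6,
                            response_latency_s = c(cs = 0.1, food = 0.1, shock = 0.1),
                            response_duration_s = c(cs = 8, food = 15, shock = 4),
                            latency_jitter_s = 0.3,
                            stim_event_rate = 1.5,
                            suppression = 1,
                            head_entry_meanlog = log(1.5),
                            head_entry_sdlog = 0.4,
                            seed = 1L) {
  p <- as.matrix(joint_category_probabilities)
  if (!all(dim(p) == c(3L, 3L))) .stopf("joint_category_probabilities must be 3 x 3")
  if (any(p < 0) || any(p > 1)) .stopf("probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9) {
    .stopf("joint_category_probabilities must sum to 1 (got %.12f)", sum(p))
  }
  if (cs_response_given_us < 0 || cs_response_given_us > 1) {
    .stopf("cs_response_given_us must lie in [0, 1]")
  }
  if (effect_size < 0) .stopf("effect_size must be >= 0")
  for (nm in c("cs", "food", "shock")) {
    if (is.na(response_latency_s[nm]) || is.na(response_duration_s[nm])) {
      .stopf("response_latency_s and response_duration_s need elements 'cs', 'food', 'shock'")
    }
  }
  dimnames(p) <- list(food = .response_levels, shock = .response_levels)
  structure(list(n_registered = as.integer(n_registered),
                 joint_category_probabilities = p,
                 cs_response_given_us = cs_response_given_us,
                 effect_size = effect_size,
                 response_latency_s = response_latency_s,
                 response_duration_s = response_duration_s,
                 latency_jitter_s = latency_jitter_s,
                 stim_event_rate = stim_event_rate,
                 suppression = suppression,
                 head_entry_meanlog = head_entry_meanlog,
                 head_entry_sdlog = head_entry_sdlog,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# Draw true labels for one neuron from its own RNG stream (already seeded).
.draw_truth_one <- function(spec) {
  p <- as.vector(t(spec$joint_category_probabilities))  # food-major
  cell <- sample.int(9L, 1L, prob = p)
  food <- .response_levels[((cell - 1L) %/% 3L) + 1L]
  shock <- .response_levels[((cell - 1L) %% 3L) + 1L]
  cs_food <- if (food != "not_significant" &&
                 stats::runif(1) < spec$cs_response_given_us) food else "not_significant"
  cs_shock <- if (shock != "not_significant" &&
                  stats::runif(1) < spec$cs_response_given_us) shock else "not_significant"
  list(food = food, shock = shock, cs_food = cs_food, cs_shock = cs_shock)
}

# Simulate the trials of one neuron in one session. Assumes the per-neuron
# RNG stream is positioned; consumes a fixed draw order (drift phase, then
# per trial: jitters, baseline events, amplitudes, added events, noise).
.simulate_neuron_session <- function(cs_label, us_label, us_name, n_trials,
                                     us_onset_s, spec, tm, rate = 10,
                                     origin = 30, span_s = 60) {
  dt <- 1 / rate
  warm <- 10                                  # seconds of kernel warm-up
  n_ext <- as.integer(round((span_s + warm) * rate))
  t_ext <- -origin - warm + (seq_len(n_ext) - 1) * dt  # relative to CS onset
  n_keep <- as.integer(round(span_s * rate))
  keep <- (n_ext - n_keep + 1L):n_ext
  kt <- seq(0, 6 * tm$kernel_decay_s, by = dt)
  k <- exp(-kt / tm$kernel_decay_s) - exp(-kt / tm$kernel_rise_s)
  k <- k / max(k)
  amp_eff <- spec$effect_size * tm$noise_sd
  out <- matrix(NA_real_, n_trials, n_keep)
  stim <- list(
    list(label = cs_label, onset = 0,
         lat = spec$response_latency_s[["cs"]],
         dur = spec$response_duration_s[["cs"]]),
    list(label = us_label, onset = us_onset_s,
         lat = spec$response_latency_s[[us_name]],
         dur = spec$response_duration_s[[us_name]]))
  for (j in seq_len(n_trials)) {
    # trials fall at arbitrary times relative to slow drift (variable ITIs),
    # so the drift phase is incoherent across trials
    phase <- stats::runif(1, 0, 2 * pi)
    jit <- stats::runif(2, 0, spec$latency_jitter_s)
    amps <- stats::rbinom(n_ext, 1L, min(1, tm$baseline_event_rate * dt)) *
      stats::rexp(n_ext, rate = 1 / tm$event_amplitude_mean)
    add <- numeric(n_ext)
    for (q in 1:2) {
      st <- stim[[q]]
      if (st$label == "not_significant") next
      w0 <- st$onset + st$lat + jit[q]
      in_win <- t_ext >= w0 & t_ext < w0 + st$dur
      if (st$label == "inhibited") {
        drop <- stats::runif(n_ext) < spec$suppression
        amps[in_win & drop] <- 0
      } else {
        add_ev <- stats::rbinom(n_ext, 1L, min(1, spec$stim_event_rate * dt))
        add[in_win & add_ev == 1L] <- amp_eff
      }
    }
    train <- amps + add
    sig <- stats::filter(train, k, method = "convolution", sides = 1)
    sig[is.na(sig)] <- 0
    x <- as.numeric(sig) +
      stats::rnorm(n_ext, 0, tm$noise_sd) +
      tm$drift_amplitude * sin(2 * pi * t_ext / tm$drift_period_s + phase)
    out[j, ] <- x[keep]
  }
  out
}

# Shared engine: simulate one session for a set of neurons with given labels.
.simulate_session <- function(labels_cs, labels_us, us_name, neuron_ids,
                              paradigm, n_trials, spec, tm, master_seed, salt,
                              head_entry = FALSE) {
  rate <- 10; origin <- 30; span_s <- 60
  n_time <- as.integer(round(span_s * rate))
  n <- length(neuron_ids)
  traces <- array(NA_real_, dim = c(n, n_trials, n_time))
  ev <- event_schedule()
  for (i in seq_len(n)) {
    set.seed(.substream_seed(master_seed, i, salt))
    traces[i, , ] <- .simulate_neuron_session(labels_cs[i], labels_us[i],
                                              us_name, n_trials, ev$us_onset_s,
                                              spec, tm, rate, origin, span_s)
  }
  he <- NULL
  if (head_entry && n_trials > 0L) {
    set.seed(.substream_seed(master_seed, 0, salt + 50L))
    he <- ev$us_onset_s + pmin(stats::rlnorm(n_trials, spec$head_entry_meanlog,
                                             spec$head_entry_sdlog), 10)
  }
  session_recording(traces, neuron_ids, paradigm,
                    session_id = paste0("sim_", paradigm),
                    sampling_rate = rate, trial_time_origin = origin,
                    events = event_schedule(head_entry_s = he))
}

#' Simulate paired appetitive and fear sessions with known ground truth
#'
#' Generates a population of registered neurons whose true (food, shock,
#' CS food, CS shock) response categories are drawn from
#' `spec$joint_category_probabilities` and `spec$cs_response_given_us`, then
#' simulates an appetitive session (20 trials) and a fear session (10
#' trials), both spanning -30 s to +30 s around CS onset at 10 Hz, with a 10
#' s CS and the US delivered 13 s after CS onset. Excited neurons gain extra
#' calcium events inside the response window (with per-trial latency
#' jitter); inhibited neurons have their baseline events multiplicatively
#' suppressed there (rates cannot go negative). Head-entry times in the
#' appetitive session are drawn as US onset plus a lognormal latency.
#'
#' Each neuron consumes its own RNG substream derived from `spec$seed`, and
#' truth labels are drawn inside that substream, so growing `n_registered`
#' leaves existing neurons bit-identical.
#'
#' @param spec A [population_spec()].
#' @param transient A [transient_model()].
#' @param truth Optional data.frame overriding the random truth draw; must
#'   have columns `label_food`, `label_shock`, `label_cs_food`,
#'   `label_cs_shock` with `spec$n_registered` rows (used e.g. for
#'   stratified fixtures).
#' @return A list with elements `appetitive` and `fear`
#'   ([session_recording()]s), `registration` (a [registration_map()]), and
#'   `ground_truth` (data.frame of true labels and derived encoding
#'   categories).
#' @export
simulate_paired_sessions <- function(spec, transient = transient_model(),
                                     truth = NULL) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(transient, "transient_model"))
  n <- spec$n_registered
  ids <- sprintf("cell%04d", seq_len(n))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (is.null(truth)) {
    lab <- data.frame(label_food = character(n), label_shock = character(n),
                      label_cs_food = character(n), label_cs_shock = character(n),
                      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      set.seed(.substream_seed(spec$seed, i, 0L))
      d <- .draw_truth_one(spec)
      lab$label_food[i] <- d$food
      lab$label_shock[i] <- d$shock
      lab$label_cs_food[i] <- d$cs_food
      lab$label_cs_shock[i] <- d$cs_shock
    }
  } else {
    need <- c("label_food", "label_shock", "label_cs_food", "label_cs_shock")
    if (!all(need %in% names(truth)) || nrow(truth) != n) {
      .stopf("truth override must have %d rows and columns %s", n,
             paste(need, collapse = ", "))
    }
    lab <- truth[, need]
    for (col in need) .check_label(lab[[col]], col)
  }
  app <- .simulate_session(lab$label_cs_food, lab$label_food, "food", ids,
                           "appetitive", 20L, spec, transient, spec$seed, 1L,
                           head_entry = TRUE)
  fear <- .simulate_session(lab$label_cs_shock, lab$label_shock, "shock", ids,
                            "fear", 10L, spec, transient, spec$seed, 2L)
  us_cls <- classify_encoding(lab$label_food, lab$label_shock)
  cs_cls <- classify_encoding(lab$label_cs_food, lab$label_cs_shock)
  gt <- data.frame(neuron_id = ids, lab,
                   us_category = us_cls$category, us_subtype = us_cls$subtype,
                   cs_category = cs_cls$category, cs_subtype = cs_cls$subtype,
                   stringsAsFactors = FALSE)
  list(appetitive = app, fear = fear,
       registration = registration_map(ids, ids),
       ground_truth = gt)
}

#' Simulate a stimulus-independent (null) session
#'
#' Every neuron is generated with no event-locked modulation: pure baseline
#' events, noise and drift. Used for type-I-error calibration of the
#' responsiveness test.
#'
#' @param n_neurons,n_trials Session dimensions.
#' @param transient A [transient_model()].
#' @param seed Master integer seed (per-neuron substreams as in
#'   [simulate_paired_sessions()]).
#' @param paradigm Paradigm tag for the returned session.
#' @return A [session_recording()].
#' @export
simulate_null_session <- function(n_neurons, n_trials = 20,
                                  transient = transient_model(), seed = 1L,
                                  paradigm = "baseline") {
  spec <- population_spec(n_registered = max(n_neurons, 1L), seed = seed)
  ids <- if (n_neurons > 0) sprintf("cell%04d", seq_len(n_neurons)) else character(0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (n_neurons == 0L) {
    traces <- array(numeric(0), dim = c(0L, n_trials, 600L))
    return(session_recording(traces, character(0), paradigm,
                             session_id = "sim_null", sampling_rate = 10,
                             trial_time_origin = 30))
  }
  .simulate_session(rep("not_significant", n_neurons),
                    rep("not_significant", n_neurons), "food",
                    ids, paradigm, as.integer(n_trials), spec, transient,
                    seed, 3L)
}
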