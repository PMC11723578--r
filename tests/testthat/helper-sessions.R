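# Builders for small deterministic sessions used across tests.

# A compact session: short trial span so window math stays readable.
# span [-origin, span - origin) seconds around CS onset.
make_session <- function(traces, rate = 10, origin = 5,
                         events = event_schedule(0, 1, 2),
                         paradigm = "baseline", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("n%02d", seq_len(dim(traces)[1]))
  session_recording(traces, ids, paradigm, session_id = "toy",
                    sampling_rate = rate, trial_time_origin = origin,
                    events = events)
}

# n x t x time array filled from a function of (neuron, trial, sample index)
make_traces <- function(n_neurons, n_trials, n_time, f = function(i, j, k) 0) {
  arr <- array(0, dim = c(n_neurons, n_trials, n_time))
  for (i in seq_len(n_neurons))
    for (j in seq_len(n_trials))
      arr[i, j, ] <- f(i, j, seq_len(n_time))
  arr
}

# Full-size (default-span) session of pure N(0,1) noise.
make_noise_session <- function(n_neurons = 3, n_trials = 4, seed = 1,
                               paradigm = "baseline") {
  set.seed(seed)
  arr <- array(rnorm(n_neurons * n_trials * 600),
               dim = c(n_neurons, n_trials, 600))
  session_recording(arr, sprintf("n%02d", seq_len(n_neurons)), paradigm,
                    session_id = "noise", sampling_rate = 10,
                    trial_time_origin = 30)
}

# Independent naive midrank: rank by counting, no calls to rank().
naive_midrank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# Independent rank-sum of post samples via naive ranking.
naive_wrst <- function(pre, post) {
  r <- naive_midrank(c(pre, post))
  sum(r[seq_along(post) + length(pre)])
}

# Independent circular shift via modular index arithmetic.
naive_shift <- function(x, s) {
  n <- length(x)
  x[((seq_len(n) - 1 + s) %% n) + 1]
}

compact_windows <- function() {
  analysis_windows("cs", isolation_window_s = c(-5, 5),
                   pre_window_s = c(-2, 0), post_window_s = c(0, 2))
}
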