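# Internal helpers shared across modules.

# data.table is used via :: but with [] query syntax
.datatable.aware <- TRUE

# Tolerance used when snapping second-denominated times to the sample grid,
# so that e.g. 0.1 * 10 = 0.9999999 does not fall off a bin boundary.
.grid_eps <- 1e-9

# First 1-based sample index of a half-open window [start, end) in seconds,
# relative to an absolute time axis that starts at -origin seconds.
# floor(t * rate) indexing per the package's half-open convention.
.window_index <- function(window_s, rate, origin) {
  i0 <- floor((window_s[1] + origin) * rate + .grid_eps) + 1L
  i1 <- floor((window_s[2] + origin) * rate - .grid_eps) + 1L
  c(as.integer(i0), as.integer(i1))
}

.window_n_samples <- function(window_s, rate) {
  as.integer(round((window_s[2] - window_s[1]) * rate))
}

.is_window <- function(w) {
  is.numeric(w) && length(w) == 2L && is.finite(w[1]) && is.finite(w[2]) &&
    w[1] < w[2]
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Derive a per-unit RNG seed from a master seed so that substreams are stable:
# adding neurons never perturbs the streams of existing ones. Kept below 2^31.
.substream_seed <- function(master_seed, index, salt = 0L) {
  (as.numeric(master_seed) + 7919 * as.numeric(index) + 104729 * as.numeric(salt)) %%
    2147483629
}

.response_levels <- c("excited", "inhibited", "not_significant")

.check_label <- function(x, arg = "label") {
  if (!all(x %in% .response_levels)) {
    .stopf("%s must be one of %s", arg, paste(.response_levels, collapse = ", "))
  }
  x
}
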