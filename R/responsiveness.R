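#' Circularly shift a trace
#'
#' Rotates a time series: the output is the concatenation of elements
#' `s+1 .. N` followed by elements `1 .. s` (1-based). This preserves the
#' shape and autocorrelation of calcium transients while destroying their
#' alignment to task events, which is what makes it a valid permutation
#' scheme for dependent samples. `s = N` is the identity.
#'
#' @param trace Numeric vector of length N.
#' @param s Integer shift in `[1, N]`.
#' @return Numeric vector of length N.
#' @export
circular_shift <- function(trace, s) {
  n <- length(trace)
  if (n < 1L) .stopf("trace must be non-empty")
  if (length(s) != 1L || is.na(s) || s != round(s) || s < 1 || s > n) {
    .stopf("shift s must be a single integer in [1, %d]", n)
  }
  if (s == n) return(trace)
  c(trace[(s + 1):n], trace[1:s])
}

#' Wilcoxon rank-sum statistic (rank-sum form)
#'
#' Pools the pre- and post-stimulus samples, assigns midranks (ties share the
#' average of the ranks they span), and returns the sum of the ranks of the
#' post samples. Larger values indicate post > pre. No normal approximation
#' or continuity correction is applied: the statistic is compared against an
#' empirical permutation null, so only its ordering matters.
#'
#' @param pre,post Non-empty numeric vectors.
#' @return The post-sample rank sum (a single number).
#' @export
wrst_statistic <- function(pre, post) {
  n_pre <- length(pre)
  n_post <- length(post)
  if (n_pre < 1L || n_post < 1L) .stopf("pre and post samples must be non-empty")
  r <- rank(c(pre, post))
  sum(r[(n_pre + 1):(n_pre + n_post)])
}

# Positions of the pre and post windows inside the isolated window, plus the
# isolation extraction itself, shared by observed and null computations.
.isolation_layout <- function(session, windows) {
  rate <- session$sampling_rate
  origin <- session$trial_time_origin
  iso_idx <- .window_index(windows$isolation_window_s, rate, origin)
  n_time <- dim(session$traces)[3]
  if (iso_idx[1] < 1L || iso_idx[2] > n_time) {
    .stopf("isolation window [%g, %g) falls outside the recorded trial span",
           windows$isolation_window_s[1], windows$isolation_window_s[2])
  }
  pre_idx <- .window_index(windows$pre_window_s, rate, origin)
  post_idx <- .window_index(windows$post_window_s, rate, origin)
  list(iso = iso_idx[1]:iso_idx[2],
       pre = (pre_idx[1]:pre_idx[2]) - iso_idx[1] + 1L,
       post = (post_idx[1]:post_idx[2]) - iso_idx[1] + 1L,
       n = iso_idx[2] - iso_idx[1] + 1L)
}

#' Observed trial-summed rank-sum statistic for one neuron
#'
#' For each trial the trace is restricted to the isolation window and the
#' rank-sum statistic of post- versus pre-stimulus samples is computed; the
#' per-trial statistics are summed across trials.
#'
#' @param session A [session_recording()].
#' @param neuron_id A neuron present in the session.
#' @param windows An [analysis_windows()].
#' @return The summed statistic (a single number).
#' @export
observed_statistic <- function(session, neuron_id, windows) {
  stopifnot(inherits(session, "session_recording"),
            inherits(windows, "analysis_windows"))
  i <- match(neuron_id, session$neuron_ids)
  if (is.na(i)) .stopf("neuron '%s' not present in session", neuron_id)
  lay <- .isolation_layout(session, windows)
  n_trials <- dim(session$traces)[2]
  w <- 0
  for (j in seq_len(n_trials)) {
    y <- session$traces[i, j, lay$iso]
    w <- w + wrst_statistic(y[lay$pre], y[lay$post])
  }
  w
}

#' Build the population-pooled permutation null
#'
#' Repeats B times: draw one neuron uniformly at random (with replacement
#' across repetitions) from the session's full pool; for each of its trials,
#' restrict the trace to the isolation window, draw an independent uniform
#' shift `s` in `[1, N]`, circularly shift, and compute the pre/post rank-sum
#' statistic; sum across trials. The resulting B summed statistics form the
#' null distribution shared by every neuron of the session for this window
#' set. Pooling across the whole recorded population lets the null capture
#' the heterogeneity of transient shapes.
#'
#' The RNG stream is consumed in a fixed documented order (repetition-major,
#' trial-minor: one neuron draw, then one shift per trial) so repositories
#' are exactly reproducible from `seed`.
#'
#' @param session A [session_recording()].
#' @param windows An [analysis_windows()].
#' @param B Number of null draws (default 500).
#' @param seed Integer seed for the draw stream.
#' @return An object of class `null_repository` with elements `stats`
#'   (length-B numeric), `B`, `windows`, `session_id`, `rng_seed`.
#' @export
build_null_repository <- function(session, windows, B = 500, seed = 1L) {
  stopifnot(inherits(session, "session_recording"),
            inherits(windows, "analysis_windows"))
  n_neurons <- dim(session$traces)[1]
  n_trials <- dim(session$traces)[2]
  if (n_neurons < 1L || n_trials < 1L) .stopf("session must contain neurons and trials")
  if (B < 1L) .stopf("B must be >= 1")
  lay <- .isolation_layout(session, windows)
  stats <- numeric(B)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(B)) {
    i <- sample.int(n_neurons, 1L)
    w <- 0
    for (j in seq_len(n_trials)) {
      s <- sample.int(lay$n, 1L)
      y <- circular_shift(session$traces[i, j, lay$iso], s)
      w <- w + wrst_statistic(y[lay$pre], y[lay$post])
    }
    stats[b] <- w
  }
  structure(list(stats = stats, B = B, windows = windows,
                 session_id = session$session_id, rng_seed = seed),
            class = "null_repository")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Construct a null repository from precomputed statistics
#'
#' Wraps a vector of summed null statistics (e.g. from an external run, or a
#' stated worked example) in the container [empirical_pvalue()] expects.
#' [build_null_repository()] is the usual way to obtain one.
#'
#' @param stats Numeric vector of B summed rank-sum statistics.
#' @param windows Optional [analysis_windows()] the statistics refer to.
#' @param session_id Optional session tag.
#' @param rng_seed Optional seed record.
#' @return An object of class `null_repository`.
#' @export
null_repository <- function(stats, windows = NULL, session_id = "",
                            rng_seed = NA_integer_) {
  if (!is.numeric(stats) || length(stats) < 1L) {
    .stopf("stats must be a non-empty numeric vector")
  }
  structure(list(stats = as.numeric(stats), B = length(stats),
                 windows = windows, session_id = session_id,
                 rng_seed = rng_seed),
            class = "null_repository")
}

#' Empirical permutation p-values for an observed statistic
#'
#' Add-one empirical p-values against a null repository of B summed
#' statistics: `p_plus = (#\{W* >= W_obs\} + 1) / (B + 1)` (right tail,
#' excitation), `p_minus = (#\{W* <= W_obs\} + 1) / (B + 1)` (left tail,
#' inhibition), and the two-sided p-value is `min(1, 2 * min(p_plus,
#' p_minus))`. The direction is `"excited"` when `p_plus < p_minus`,
#' `"inhibited"` when `p_minus < p_plus`, `"none"` on an exact tie.
#'
#' @param W_obs Observed summed rank-sum statistic.
#' @param repo A `null_repository` from [build_null_repository()].
#' @return A list with `p_plus`, `p_minus`, `p_two_sided`, `direction`.
#' @export
empirical_pvalue <- function(W_obs, repo) {
  stopifnot(inherits(repo, "null_repository"))
  B <- repo$B
  if (B < 1L) .stopf("null repository is empty")
  p_plus <- (sum(repo$stats >= W_obs) + 1) / (B + 1)
  p_minus <- (sum(repo$stats <= W_obs) + 1) / (B + 1)
  p_two <- min(1, 2 * min(p_plus, p_minus))
  direction <- if (p_plus < p_minus) "excited" else
    if (p_minus < p_plus) "inhibited" else "none"
  list(p_plus = p_plus, p_minus = p_minus, p_two_sided = p_two,
       direction = direction)
}

#' Circular-shift responsiveness test for every neuron of a session
#'
#' Builds one population-pooled null repository for the session and window
#' set, computes each neuron's observed trial-summed rank-sum statistic, and
#' labels each neuron `excited` (two-sided p below `alpha` with the right
#' tail smaller), `inhibited` (left tail smaller) or `not_significant`.
#' P-values are raw per-neuron values (no multiplicity correction, matching
#' the method's standard use); set `adjust = "BH"` to add a
#' Benjamini-Hochberg adjusted column and label from it instead.
#'
#' @param session A [session_recording()].
#' @param windows An [analysis_windows()].
#' @param B Number of null draws (default 500).
#' @param alpha Significance level (default 0.05).
#' @param seed Seed for the null repository draws.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data.frame with one row per neuron: `neuron_id`, `stimulus`,
#'   `W_obs`, `p_plus`, `p_minus`, `p_two_sided`, `label`, `alpha`, `B`,
#'   `seed` (and `p_adjusted` when `adjust = "BH"`). The null repository is
#'   attached as attribute `"null_repository"`.
#' @export
test_population <- function(session, windows, B = 500, alpha = 0.05, seed = 1L,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!(alpha > 0 && alpha < 1)) .stopf("alpha must be in (0, 1)")
  repo <- build_null_repository(session, windows, B = B, seed = seed)
  ids <- session$neuron_ids
  res <- data.frame(neuron_id = ids, stimulus = windows$stimulus,
                    W_obs = NA_real_, p_plus = NA_real_, p_minus = NA_real_,
                    p_two_sided = NA_real_, label = NA_character_,
                    alpha = alpha, B = B, seed = seed,
                    stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    W <- observed_statistic(session, ids[k], windows)
    p <- empirical_pvalue(W, repo)
    res$W_obs[k] <- W
    res$p_plus[k] <- p$p_plus
    res$p_minus[k] <- p$p_minus
    res$p_two_sided[k] <- p$p_two_sided
    res$label[k] <- if (p$p_two_sided < alpha && p$direction != "none") {
      p$direction
    } else "not_significant"
  }
  if (adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_two_sided, method = "BH")
    sig <- res$p_adjusted < alpha & res$p_plus != res$p_minus
    res$label <- ifelse(sig, ifelse(res$p_plus < res$p_minus, "excited",
                                    "inhibited"), "not_significant")
  }
  attr(res, "null_repository") <- repo
  res
}

#' Per-trial sign-rank responsiveness test
#'
#' A conventional alternative to the circular-shift test: for every trial, a
#' one-sample Wilcoxon signed-rank test compares the post-stimulus samples
#' against the median of that trial's pre-stimulus samples, one-sided in each
#' direction at `per_trial_alpha / 2`. A neuron is labelled excited
#' (inhibited) when the number of trials individually significant in that
#' direction reaches `trial_count_cutoff`; the default cutoff is the smallest
#' k whose upper binomial tail `P(Binom(n_trials, per_trial_alpha/2) >= k)`
#' is at most 0.05, i.e. a count that would itself be surprising under the
#' per-trial null. If both directions reach the cutoff the neuron is labelled
#' `not_significant`.
#'
#' @param session A [session_recording()].
#' @param windows An [analysis_windows()].
#' @param per_trial_alpha Per-trial two-sided significance budget
#'   (default 0.05; each direction is tested at half of it).
#' @param trial_count_cutoff Optional integer override of the binomial-tail
#'   cutoff.
#' @return A data.frame with one row per neuron: `neuron_id`, `stimulus`,
#'   `n_sig_up`, `n_sig_down`, `cutoff`, `label`.
#' @export
signrank_responsiveness <- function(session, windows, per_trial_alpha = 0.05,
                                    trial_count_cutoff = NULL) {
  stopifnot(inherits(session, "session_recording"),
            inherits(windows, "analysis_windows"))
  lay <- .isolation_layout(session, windows)
  n_trials <- dim(session$traces)[2]
  n_neurons <- dim(session$traces)[1]
  if (is.null(trial_count_cutoff)) {
    trial_count_cutoff <- stats::qbinom(0.95, n_trials, per_trial_alpha / 2) + 1L
  }
  res <- data.frame(neuron_id = session$neuron_ids,
                    stimulus = windows$stimulus,
                    n_sig_up = 0L, n_sig_down = 0L,
                    cutoff = as.integer(trial_count_cutoff),
                    label = "not_significant", stringsAsFactors = FALSE)
  for (i in seq_len(n_neurons)) {
    k_up <- 0L; k_dn <- 0L
    for (j in seq_len(n_trials)) {
      y <- session$traces[i, j, lay$iso]
      pre <- y[lay$pre]; post <- y[lay$post]
      med <- stats::median(pre)
      d <- post - med
      if (all(d == 0)) next  # degenerate: no information in this trial
      p_up <- suppressWarnings(
        stats::wilcox.test(post, mu = med, alternative = "greater",
                           exact = FALSE, correct = TRUE)$p.value)
      p_dn <- suppressWarnings(
        stats::wilcox.test(post, mu = med, alternative = "less",
                           exact = FALSE, correct = TRUE)$p.value)
      if (!is.na(p_up) && p_up < per_trial_alpha / 2) k_up <- k_up + 1L
      if (!is.na(p_dn) && p_dn < per_trial_alpha / 2) k_dn <- k_dn + 1L
    }
    res$n_sig_up[i] <- k_up
    res$n_sig_down[i] <- k_dn
    up <- k_up >= trial_count_cutoff
    dn <- k_dn >= trial_count_cutoff
    res$label[i] <- if (up && !dn) "excited" else if (dn && !up) "inhibited" else
      "not_significant"
  }
  res
}
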