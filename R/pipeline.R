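#' End-to-end analysis pipeline
#'
#' Orchestrates a full run: obtain a paired appetitive/fear dataset (either
#' by simulation or by loading files written with [write_session()]), test
#' every neuron's responsiveness to the US and the CS in both sessions,
#' classify registered neurons into salience / valence / not-significant
#' categories for the US and the CS pair, compare the two category
#' distributions with a Pearson chi-square, compute peri-event z-scored
#' metrics, and write all tables plus a JSON report to `out_dir`.
#'
#' The configuration is a named list (or a YAML file path) with elements:
#' \describe{
#'   \item{mode}{`"simulate"` (default) or `"load"`.}
#'   \item{spec, transient}{For simulate mode: a [population_spec()] /
#'     [transient_model()], or named lists of their arguments.}
#'   \item{paths}{For load mode: list with `appetitive`, `fear`,
#'     `registration`, and `format` (`"csv_long"` or `"hdf5"`).}
#'   \item{B, alpha}{Permutation draws (default 500) and significance level
#'     (default 0.05).}
#'   \item{method}{`"circular_shift"` (default), `"sign_rank"`, or
#'     `"both"`.}
#'   \item{seed}{Master seed; all stages derive their streams from it.}
#'   \item{out_dir}{Output directory (created if needed); omit to skip
#'     writing files.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with the responsiveness tables, encoding
#'   tables, contingency results, metric reports and run metadata.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  mode <- if (is.null(config$mode)) "simulate" else config$mode
  B <- if (is.null(config$B)) 500L else as.integer(config$B)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  method <- if (is.null(config$method)) "circular_shift" else config$method
  method <- match.arg(method, c("circular_shift", "sign_rank", "both"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (B < 1L) .stopf("config error: B must be >= 1")
  if (!(alpha > 0 && alpha < 1)) .stopf("config error: alpha must be in (0, 1)")

  if (mode == "simulate") {
    spec <- config$spec
    if (is.null(spec)) spec <- population_spec(seed = seed)
    if (!inherits(spec, "population_spec")) {
      spec <- do.call(population_spec, c(spec, if (is.null(spec$seed)) list(seed = seed)))
    }
    tm <- config$transient
    if (is.null(tm)) tm <- transient_model()
    if (!inherits(tm, "transient_model")) tm <- do.call(transient_model, tm)
    sim <- simulate_paired_sessions(spec, tm)
    app <- sim$appetitive; fear <- sim$fear
    registration <- sim$registration
    ground_truth <- sim$ground_truth
  } else if (mode == "load") {
    p <- config$paths
    if (is.null(p$appetitive) || is.null(p$fear) || is.null(p$registration)) {
      .stopf("config error: load mode needs paths$appetitive, paths$fear, paths$registration")
    }
    fmt <- if (is.null(p$format)) "csv_long" else p$format
    app <- read_session(p$appetitive, fmt)
    fear <- read_session(p$fear, fmt)
    registration <- read_registration(p$registration)
    ground_truth <- NULL
  } else .stopf("config error: mode must be 'simulate' or 'load'")

  run_method <- function(session, windows, salt) {
    if (method == "sign_rank") {
      signrank_responsiveness(session, windows)
    } else {
      test_population(session, windows, B = B, alpha = alpha,
                      seed = .substream_seed(seed, salt))
    }
  }
  res <- list(
    food = run_method(app, analysis_windows("food"), 11L),
    cs_food = run_method(app, analysis_windows("cs"), 12L),
    shock = run_method(fear, analysis_windows("shock"), 13L),
    cs_shock = run_method(fear, analysis_windows("cs"), 14L))

  enc_us <- build_encoding_table(res$food, res$shock, registration)
  enc_cs <- build_encoding_table(res$cs_food, res$cs_shock, registration)
  counts_us <- category_counts(enc_us)
  counts_cs <- category_counts(enc_cs)
  cs_vs_us <- chi_square_independence(rbind(cs = counts_cs[1, ],
                                            us = counts_us[1, ]))

  agreement <- NULL
  if (method == "both") {
    alt <- list(
      food = signrank_responsiveness(app, analysis_windows("food")),
      cs_food = signrank_responsiveness(app, analysis_windows("cs")),
      shock = signrank_responsiveness(fear, analysis_windows("shock")),
      cs_shock = signrank_responsiveness(fear, analysis_windows("cs")))
    agreement <- lapply(names(res), function(nm) {
      base::table(circular_shift = factor(res[[nm]]$label, .response_levels),
                  sign_rank = factor(alt[[nm]]$label, .response_levels))
    })
    names(agreement) <- names(res)
  }

  z_app <- zscore_session(app)
  z_fear <- zscore_session(fear)
  metrics <- rbind(
    metric_report(z_app, c(13, 23), stimulus = "food"),
    metric_report(z_app, c(0, 10), stimulus = "cs_food"),
    metric_report(z_fear, c(13, 23), stimulus = "shock"),
    metric_report(z_fear, c(0, 10), stimulus = "cs_shock"))

  report <- list(
    responsiveness = res, encoding_us = enc_us, encoding_cs = enc_cs,
    counts_us = counts_us, counts_cs = counts_cs,
    cs_vs_us_chi_square = cs_vs_us, agreement = agreement,
    metrics = metrics, ground_truth = ground_truth,
    meta = list(mode = mode, method = method, B = B, alpha = alpha,
                seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
                package_version = as.character(utils::packageVersion("perishift")),
                windows = list(cs = unclass(analysis_windows("cs")),
                               food = unclass(analysis_windows("food")),
                               shock = unclass(analysis_windows("shock")))))

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res)) {
      utils::write.csv(res[[nm]], file.path(out_dir, paste0("responsiveness_", nm, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(enc_us, file.path(out_dir, "encoding_us.csv"), row.names = FALSE)
    utils::write.csv(enc_cs, file.path(out_dir, "encoding_cs.csv"), row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    if (!is.null(ground_truth)) {
      utils::write.csv(ground_truth, file.path(out_dir, "ground_truth.csv"),
                       row.names = FALSE)
    }
    contingency <- list(
      counts_us = as.list(counts_us[1, ]), percent_us = as.list(attr(counts_us, "percent")[1, ]),
      counts_cs = as.list(counts_cs[1, ]), percent_cs = as.list(attr(counts_cs, "percent")[1, ]),
      cs_vs_us_chi_square = cs_vs_us, meta = report$meta)
    jsonlite::write_json(contingency, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Write a small deterministic fixture dataset
#'
#' Generates a paired appetitive/fear dataset whose truth is stratified so
#' that each of the nine (food, shock) response subtypes occurs at least
#' once, writes both sessions (csv_long), the registration map and the
#' ground-truth table to `output_dir`. Regeneration with the same seed is
#' bit-identical.
#'
#' @param output_dir Destination directory (created if needed).
#' @param seed Integer seed.
#' @param n_registered Number of neurons (>= 9; default 30).
#' @return Invisibly, the list returned by [simulate_paired_sessions()].
#' @export
make_fixtures <- function(output_dir, seed = 42L, n_registered = 30L) {
  if (n_registered < 9L) .stopf("need at least 9 neurons to cover all subtypes")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- population_spec(n_registered = n_registered, seed = seed)
  # first nine neurons cover the 9 subtypes deterministically; the rest are
  # drawn from the joint distribution in per-neuron substreams
  grid <- expand.grid(shock = .response_levels, food = .response_levels,
                      stringsAsFactors = FALSE)
  lab <- data.frame(label_food = character(n_registered),
                    label_shock = character(n_registered),
                    label_cs_food = character(n_registered),
                    label_cs_shock = character(n_registered),
                    stringsAsFactors = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (i in seq_len(n_registered)) {
    set.seed(.substream_seed(seed, i, 0L))
    if (i <= 9L) {
      d <- list(food = grid$food[i], shock = grid$shock[i])
      d$cs_food <- if (d$food != "not_significant" &&
                       stats::runif(1) < spec$cs_response_given_us) d$food else "not_significant"
      d$cs_shock <- if (d$shock != "not_significant" &&
                        stats::runif(1) < spec$cs_response_given_us) d$shock else "not_significant"
    } else {
      d <- .draw_truth_one(spec)
    }
    lab$label_food[i] <- d$food; lab$label_shock[i] <- d$shock
    lab$label_cs_food[i] <- d$cs_food; lab$label_cs_shock[i] <- d$cs_shock
  }
  sim <- simulate_paired_sessions(spec, transient_model(), truth = lab)
  write_session(sim$appetitive, file.path(output_dir, "appetitive.csv"), "csv_long")
  write_session(sim$fear, file.path(output_dir, "fear.csv"), "csv_long")
  write_registration(sim$registration, file.path(output_dir, "registration.csv"))
  utils::write.csv(sim$ground_truth, file.path(output_dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(sim)
}
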