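#' Write a session recording to disk
#'
#' Two on-disk schemata are supported.
#'
#' `csv_long`: one row per (neuron, trial, timepoint) with columns
#' `session_id, paradigm, neuron_id, trial, time_s, value` (`time_s` relative
#' to trial-trace start), plus a JSON sidecar `<path>.json` holding
#' `sampling_rate`, `trial_time_origin` and the event schedule including
#' per-trial head-entry times.
#'
#' `hdf5`: datasets `/traces` (float64, neurons x trials x time),
#' `/neuron_ids`; root attributes `session_id`, `paradigm`, `sampling_rate`,
#' `trial_time_origin`; group `/events` with `cs_onset_s`, `cs_offset_s`,
#' `us_onset_s` and `head_entry_s` (one value per trial, `NaN` for absent).
#'
#' @param session A [session_recording()].
#' @param path Output file path.
#' @param format `"csv_long"` or `"hdf5"`.
#' @return Invisibly, `path`.
#' @export
write_session <- function(session, path, format = c("csv_long", "hdf5")) {
  stopifnot(inherits(session, "session_recording"))
  format <- match.arg(format)
  if (format == "csv_long") .write_session_csv(session, path) else
    .write_session_h5(session, path)
  invisible(path)
}

#' Read a session recording written by [write_session()]
#'
#' @param path Input file path (for `csv_long`, the JSON sidecar `<path>.json`
#'   must sit next to it).
#' @param format `"csv_long"` or `"hdf5"`.
#' @return A validated [session_recording()].
#' @export
read_session <- function(path, format = c("csv_long", "hdf5")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "csv_long") .read_session_csv(path) else .read_session_h5(path)
}

.sidecar_path <- function(path) paste0(path, ".json")

.write_session_csv <- function(session, path) {
  d <- dim(session$traces)
  rate <- session$sampling_rate
  if (d[1] == 0L || d[2] == 0L || d[3] == 0L) {
    dt <- data.table::data.table(session_id = character(), paradigm = character(),
                                 neuron_id = character(), trial = integer(),
                                 time_s = numeric(), value = numeric())
  } else {
    dt <- data.table::data.table(
      session_id = session$session_id,
      paradigm = session$paradigm,
      neuron_id = rep(session$neuron_ids, times = d[2] * d[3]),
      trial = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      time_s = rep((seq_len(d[3]) - 1) / rate, each = d[1] * d[2]),
      value = as.vector(session$traces))
    dt[, `:=`(.nidx = match(neuron_id, session$neuron_ids))]
    data.table::setorder(dt, .nidx, trial, time_s)
    dt[, .nidx := NULL]
  }
  data.table::fwrite(dt, path)
  meta <- list(
    session_id = session$session_id, paradigm = session$paradigm,
    sampling_rate = session$sampling_rate,
    trial_time_origin = session$trial_time_origin,
    n_trials = d[2], n_timepoints = d[3],
    events = list(cs_onset_s = session$events$cs_onset_s,
                  cs_offset_s = session$events$cs_offset_s,
                  us_onset_s = session$events$us_onset_s,
                  head_entry_s = session$events$head_entry_s))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
}

.read_session_csv <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(side)) .stopf("schema error: missing JSON sidecar %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (field in c("sampling_rate", "trial_time_origin", "paradigm", "events")) {
    if (is.null(meta[[field]])) .stopf("schema error: sidecar lacks field '%s'", field)
  }
  for (field in c("cs_onset_s", "cs_offset_s", "us_onset_s")) {
    if (is.null(meta$events[[field]])) {
      .stopf("schema error: sidecar events lack field '%s'", field)
    }
  }
  dt <- data.table::fread(path, colClasses = list(character = "neuron_id"))
  required <- c("session_id", "paradigm", "neuron_id", "trial", "time_s", "value")
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    .stopf("schema error: csv lacks column(s) %s", paste(missing, collapse = ", "))
  }
  he <- meta$events$head_entry_s
  if (!is.null(he)) he <- as.numeric(he)
  ev <- event_schedule(meta$events$cs_onset_s, meta$events$cs_offset_s,
                       meta$events$us_onset_s, head_entry_s = he)
  if (nrow(dt) == 0L) {
    n_trials <- if (!is.null(meta$n_trials)) meta$n_trials else 0L
    n_time <- if (!is.null(meta$n_timepoints)) meta$n_timepoints else 0L
    traces <- array(numeric(0), dim = c(0L, n_trials, n_time))
    return(session_recording(traces, character(0), meta$paradigm,
                             session_id = meta$session_id,
                             sampling_rate = meta$sampling_rate,
                             trial_time_origin = meta$trial_time_origin,
                             events = ev))
  }
  neuron_ids <- unique(dt$neuron_id)
  trials <- sort(unique(dt$trial))
  counts <- dt[, .N, by = c("neuron_id", "trial")]
  if (length(unique(counts$N)) != 1L) {
    .stopf("shape error: ragged trial lengths across neuron x trial blocks")
  }
  n_time <- counts$N[1]
  if (nrow(counts) != length(neuron_ids) * length(trials)) {
    .stopf("shape error: not every neuron x trial combination is present")
  }
  dt[, `:=`(.nidx = match(neuron_id, neuron_ids))]
  data.table::setorder(dt, .nidx, trial, time_s)
  # rows are now neuron-major, then trial, then time
  arr <- array(dt$value, dim = c(n_time, length(trials), length(neuron_ids)))
  traces <- aperm(arr, c(3, 2, 1))
  session_recording(traces, neuron_ids, meta$paradigm,
                    session_id = meta$session_id,
                    sampling_rate = meta$sampling_rate,
                    trial_time_origin = meta$trial_time_origin,
                    events = ev)
}

.write_session_h5 <- function(session, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(session$traces, path, "traces")
  rhdf5::h5write(session$neuron_ids, path, "neuron_ids")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(session$session_id, fid, "session_id")
  rhdf5::h5writeAttribute(session$paradigm, fid, "paradigm")
  rhdf5::h5writeAttribute(session$sampling_rate, fid, "sampling_rate")
  rhdf5::h5writeAttribute(session$trial_time_origin, fid, "trial_time_origin")
  rhdf5::h5createGroup(fid, "events")
  rhdf5::h5write(session$events$cs_onset_s, fid, "events/cs_onset_s")
  rhdf5::h5write(session$events$cs_offset_s, fid, "events/cs_offset_s")
  rhdf5::h5write(session$events$us_onset_s, fid, "events/us_onset_s")
  he <- session$events$head_entry_s
  if (is.null(he)) he <- rep(NaN, dim(session$traces)[2])
  he[is.na(he)] <- NaN
  rhdf5::h5write(he, fid, "events/head_entry_s")
}

.read_session_h5 <- function(path) {
  contents <- rhdf5::h5ls(path)
  need <- c("traces", "neuron_ids")
  have <- contents$name[contents$group == "/"]
  missing <- setdiff(need, have)
  if (length(missing)) {
    .stopf("schema error: hdf5 file lacks dataset(s) %s", paste(missing, collapse = ", "))
  }
  attrs <- rhdf5::h5readAttributes(path, "/")
  for (field in c("sampling_rate", "trial_time_origin", "paradigm", "session_id")) {
    if (is.null(attrs[[field]])) .stopf("schema error: hdf5 file lacks attribute '%s'", field)
  }
  ev_names <- contents$name[contents$group == "/events"]
  for (field in c("cs_onset_s", "cs_offset_s", "us_onset_s", "head_entry_s")) {
    if (!(field %in% ev_names)) {
      .stopf("schema error: hdf5 /events group lacks '%s'", field)
    }
  }
  traces <- rhdf5::h5read(path, "traces")
  neuron_ids <- as.character(rhdf5::h5read(path, "neuron_ids"))
  he <- as.numeric(rhdf5::h5read(path, "events/head_entry_s"))
  he[is.nan(he)] <- NA_real_
  if (all(is.na(he))) he <- NULL
  ev <- event_schedule(as.numeric(rhdf5::h5read(path, "events/cs_onset_s")),
                       as.numeric(rhdf5::h5read(path, "events/cs_offset_s")),
                       as.numeric(rhdf5::h5read(path, "events/us_onset_s")),
                       head_entry_s = he)
  session_recording(traces, neuron_ids, as.character(attrs$paradigm),
                    session_id = as.character(attrs$session_id),
                    sampling_rate = as.numeric(attrs$sampling_rate),
                    trial_time_origin = as.numeric(attrs$trial_time_origin),
                    events = ev)
}

#' Read or write a cross-session neuron registration map
#'
#' A registration map asserts which neuron in session A is the same physical
#' cell as which neuron in session B (one-to-one partial matching). On disk it
#' is a two-column CSV `neuron_id_session_a, neuron_id_session_b`.
#'
#' @param path CSV file path.
#' @return For `read_registration`, a data.frame with columns
#'   `neuron_id_session_a` and `neuron_id_session_b`.
#' @export
read_registration <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  dt <- data.table::fread(path, colClasses = "character")
  need <- c("neuron_id_session_a", "neuron_id_session_b")
  missing <- setdiff(need, names(dt))
  if (length(missing)) {
    .stopf("schema error: registration csv lacks column(s) %s",
           paste(missing, collapse = ", "))
  }
  registration_map(dt$neuron_id_session_a, dt$neuron_id_session_b)
}

#' @param registration A registration data.frame as returned by
#'   [registration_map()].
#' @rdname read_registration
#' @export
write_registration <- function(registration, path) {
  stopifnot(is.data.frame(registration))
  data.table::fwrite(registration[, c("neuron_id_session_a", "neuron_id_session_b")],
                     path)
  invisible(path)
}

#' Construct a validated registration map
#'
#' @param ids_a,ids_b Character vectors of equal length pairing neuron IDs in
#'   session A with neuron IDs in session B. Each ID may appear at most once
#'   per side.
#' @return A data.frame with columns `neuron_id_session_a`,
#'   `neuron_id_session_b`.
#' @export
registration_map <- function(ids_a, ids_b) {
  ids_a <- as.character(ids_a); ids_b <- as.character(ids_b)
  if (length(ids_a) != length(ids_b)) .stopf("registration sides must have equal length")
  if (anyDuplicated(ids_a) || anyDuplicated(ids_b)) {
    .stopf("registration must be one-to-one: duplicated neuron ID on one side")
  }
  data.frame(neuron_id_session_a = ids_a, neuron_id_session_b = ids_b,
             stringsAsFactors = FALSE)
}
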