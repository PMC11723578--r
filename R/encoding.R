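#' Classify a joint response pattern as salience or valence encoding
#'
#' Salience-encoding neurons respond significantly to both the appetitive and
#' the aversive stimulus in the same direction (both excited or both
#' inhibited); valence-encoding neurons respond in opposite directions, or
#' significantly to exactly one of the two; neurons significant to neither
#' are not significant. The subtype records the ordered pair of labels (role
#' A is the appetitive stimulus, role B the aversive one), so
#' "food-excited-only" and "shock-excited-only" are distinct cells.
#'
#' @param label_a,label_b Response labels in
#'   `c("excited", "inhibited", "not_significant")`; A is the appetitive
#'   stimulus, B the aversive one. Vectorized.
#' @return A data.frame with columns `category`
#'   (`salience`/`valence`/`not_significant`) and `subtype`
#'   (`"<label_a>:<label_b>"`).
#' @export
classify_encoding <- function(label_a, label_b) {
  .check_label(label_a, "label_a")
  .check_label(label_b, "label_b")
  if (length(label_a) != length(label_b)) .stopf("labels must have equal length")
  ns <- "not_significant"
  category <- ifelse(label_a == ns & label_b == ns, "not_significant",
              ifelse(label_a == label_b, "salience", "valence"))
  data.frame(category = category,
             subtype = paste(label_a, label_b, sep = ":"),
             stringsAsFactors = FALSE)
}

#' The nine ordered response subtypes
#'
#' Ordered cells of the excited/inhibited/not_significant cross for the
#' (appetitive, aversive) stimulus pair, appetitive label varying slowest.
#' @return Character vector of length 9.
#' @export
encoding_subtypes <- function() {
  as.vector(outer(.response_levels, .response_levels,
                  function(a, b) paste(a, b, sep = ":")))
}

#' Join responsiveness results across registered neurons
#'
#' Combines the per-neuron labels of two sessions over a cross-session
#' registration map and derives each registered neuron's encoding category
#' and subtype.
#'
#' @param results_a Responsiveness table for the appetitive-session stimulus
#'   (from [test_population()] or [signrank_responsiveness()]).
#' @param results_b Responsiveness table for the aversive-session stimulus.
#' @param registration A [registration_map()] pairing neuron IDs of session A
#'   (appetitive) with session B (aversive).
#' @return An `encoding_table` data.frame with one row per registered pair:
#'   `neuron_id_a`, `neuron_id_b`, `label_a`, `label_b`, `category`,
#'   `subtype`.
#' @export
build_encoding_table <- function(results_a, results_b, registration) {
  stopifnot(is.data.frame(results_a), is.data.frame(results_b),
            is.data.frame(registration))
  ia <- match(registration$neuron_id_session_a, results_a$neuron_id)
  ib <- match(registration$neuron_id_session_b, results_b$neuron_id)
  if (anyNA(ia)) {
    .stopf("registration pair(s) unresolved in session A results: %s",
           paste(registration$neuron_id_session_a[is.na(ia)], collapse = ", "))
  }
  if (anyNA(ib)) {
    .stopf("registration pair(s) unresolved in session B results: %s",
           paste(registration$neuron_id_session_b[is.na(ib)], collapse = ", "))
  }
  label_a <- results_a$label[ia]
  label_b <- results_b$label[ib]
  cls <- classify_encoding(label_a, label_b)
  out <- data.frame(neuron_id_a = registration$neuron_id_session_a,
                    neuron_id_b = registration$neuron_id_session_b,
                    label_a = label_a, label_b = label_b,
                    category = cls$category, subtype = cls$subtype,
                    stringsAsFactors = FALSE)
  class(out) <- c("encoding_table", "data.frame")
  out
}

#' Category or subtype counts of an encoding table
#'
#' Collapses an encoding table to a 1 x 3 (salience / valence /
#' not_significant) or 1 x 9 (ordered subtype) contingency row, with integer
#' percentages (round half away from zero) as an attribute. Counts are the
#' normative output; percentages are a display convenience.
#'
#' @param table An `encoding_table` from [build_encoding_table()].
#' @param by `"category"` or `"subtype"`.
#' @return An integer matrix with one row; attribute `"percent"` holds the
#'   rounded percentages.
#' @export
category_counts <- function(table, by = c("category", "subtype")) {
  by <- match.arg(by)
  if (nrow(table) == 0L) .stopf("encoding table is empty")
  levels <- if (by == "category") {
    c("salience", "valence", "not_significant")
  } else encoding_subtypes()
  counts <- base::table(factor(table[[by]], levels = levels))
  m <- matrix(as.integer(counts), nrow = 1,
              dimnames = list("count", levels))
  pct <- floor(100 * m / sum(m) + 0.5)  # round half away from zero (counts >= 0)
  attr(m, "percent") <- pct
  m
}

#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic on an r x c table of counts,
#' `sum((O - E)^2 / E)` with expectations from the row/column margins,
#' `df = (r-1)(c-1)`, upper-tail asymptotic p-value, no continuity
#' correction.
#'
#' @param table Integer matrix of counts with at least 2 rows and 2 columns
#'   and strictly positive row and column sums.
#' @return A list with `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    .stopf("contingency table must be at least 2 x 2")
  }
  if (any(table < 0)) .stopf("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    .stopf("all row and column sums must be positive")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Compare encoding-category proportions between conditioning-order groups
#'
#' Splits the registered neurons by which valence conditioning the animal
#' experienced first, tabulates encoding categories per group into a 2 x 3
#' contingency table, and tests independence with the Pearson chi-square.
#'
#' @param table An `encoding_table`.
#' @param group_assignment Character/factor vector, one of
#'   `"appetitive_first"`, `"fear_first"` per row of `table`.
#' @return A list with `table` (2 x 3 counts, groups x categories) and
#'   `chi_square` (result of [chi_square_independence()]).
#' @export
compare_order_groups <- function(table, group_assignment) {
  stopifnot(is.data.frame(table))
  if (length(group_assignment) != nrow(table)) {
    .stopf("group_assignment must have one entry per registered neuron")
  }
  groups <- c("appetitive_first", "fear_first")
  if (!all(group_assignment %in% groups)) {
    .stopf("group_assignment values must be in {%s}", paste(groups, collapse = ", "))
  }
  cats <- c("salience", "valence", "not_significant")
  tab <- base::table(factor(group_assignment, levels = groups),
                     factor(table$category, levels = cats))
  m <- matrix(as.integer(tab), nrow = 2, dimnames = list(groups, cats))
  list(table = m, chi_square = chi_square_independence(m))
}
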