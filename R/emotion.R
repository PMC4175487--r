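#' Z-score one behavioral measure against a comparison group
#'
#' `z = direction * (X - mu) / sigma` where `mu` and `sigma` (sample SD,
#' n - 1 denominator) come from the comparison group only and `direction`
#' is +1 when a larger raw value means more anxiety-like emotionality and
#' -1 otherwise (e.g. time in the open arms). Comparison-group members are
#' scored as well, so their per-measure mean is 0 by construction.
#'
#' @param values Numeric raw measure values.
#' @param in_comparison Logical, same length: membership in the comparison
#'   group.
#' @param direction `+1` or `-1`.
#' @param measure Name used in error messages.
#' @return Numeric vector of z-scores.
#' @export
zscore_measure <- function(values, in_comparison, direction, measure = "measure") {
  stopifnot(length(values) == length(in_comparison), direction %in% c(-1, 1))
  comp <- values[in_comparison & !is.na(values)]
  if (length(comp) < 2) {
    abort(paste0("comparison group for '", measure, "' has fewer than 2 values"),
      class = "fcg_degenerate_scale"
    )
  }
  s <- sd(comp)
  if (!is.finite(s) || s <= 0) {
    abort(paste0("comparison-group SD is zero for measure '", measure, "'"),
      class = "fcg_degenerate_scale"
    )
  }
  direction * (values - mean(comp)) / s
}

#' Per-animal behavioral emotionality Z-scores
#'
#' Three-level composite: each measure is standardized against the
#' comparison group (default XX mice with blank capsules) with its anxiety
#' direction applied; per-test scores average that test's measure z-scores;
#' the overall emotionality score averages the per-test scores. Averaging is
#' unweighted at both levels, so tests contribute equally regardless of how
#' many measures they carry.
#'
#' @param behavior Long tibble `sample_id`, `test`, `measure`, `value`.
#' @param design Design tibble with `sample_id` and the factor columns.
#' @param directions Tibble `measure`, `direction` (or named vector) marking
#'   whether a larger raw value means more (+1) or less (-1) anxiety.
#' @param comparison Named list of design-column values defining the
#'   comparison group; default `list(sex_chromosome = "XX", hormone =
#'   "blank")`.
#' @return Tibble: `sample_id`, one `z_<test>` column per test, `z_overall`;
#'   per-measure z-scores attached as attribute `"measure_z"`.
#' @export
#' @examples
#' sim <- simulate_study(simulation_config(n_per_group = 3), seed = 1)
#' scores <- emotionality_scores(sim$behavior, sim$design, sim$directions)
#' head(scores)
emotionality_scores <- function(behavior, design, directions,
                                comparison = list(
                                  sex_chromosome = "XX",
                                  hormone = "blank"
                                )) {
  stopifnot(all(c("sample_id", "test", "measure", "value") %in% names(behavior)))
  directions <- as_direction_table(directions)
  missing_dir <- setdiff(unique(behavior$measure), directions$measure)
  if (length(missing_dir) > 0) {
    abort(
      paste0(
        "no direction given for measure(s): ",
        paste(missing_dir, collapse = ", ")
      ),
      class = "fcg_invalid_input"
    )
  }
  comp_ids <- comparison_group_ids(design, comparison)
  if (length(comp_ids) < 2) {
    abort("comparison group has fewer than 2 samples",
      class = "fcg_invalid_input"
    )
  }

  measure_z <- behavior |>
    inner_join(directions, by = "measure") |>
    group_by(.data$test, .data$measure) |>
    mutate(
      z = zscore_measure(
        .data$value,
        .data$sample_id %in% comp_ids,
        .data$direction[1],
        measure = .data$measure[1]
      )
    ) |>
    ungroup()

  n_missing <- sum(is.na(measure_z$z))
  if (n_missing > 0) {
    inform(paste0(n_missing, " missing measure value(s) excluded from test means"))
  }

  test_z <- measure_z |>
    group_by(.data$sample_id, .data$test) |>
    summarise(z_test = mean(.data$z, na.rm = TRUE), .groups = "drop") |>
    mutate(z_test = ifelse(is.nan(.data$z_test), NA_real_, .data$z_test))

  overall <- test_z |>
    group_by(.data$sample_id) |>
    summarise(
      z_overall = mean(.data$z_test, na.rm = TRUE),
      n_tests = sum(!is.na(.data$z_test)),
      .groups = "drop"
    )
  if (any(overall$n_tests == 0)) {
    abort(
      paste0(
        "sample(s) with no scored behavior test: ",
        paste(overall$sample_id[overall$n_tests == 0], collapse = ", ")
      ),
      class = "fcg_invalid_input"
    )
  }

  out <- test_z |>
    pivot_wider(
      names_from = "test", values_from = "z_test",
      names_prefix = "z_"
    ) |>
    inner_join(select(overall, "sample_id", "z_overall"), by = "sample_id")
  attr(out, "measure_z") <- select(
    measure_z, "sample_id", "test", "measure", "z"
  )
  attr(out, "comparison_ids") <- comp_ids
  out
}

comparison_group_ids <- function(design, comparison) {
  keep <- rep(TRUE, nrow(design))
  for (col in names(comparison)) {
    if (!col %in% names(design)) {
      abort(paste0("comparison column '", col, "' not in design"),
        class = "fcg_invalid_input"
      )
    }
    keep <- keep & design[[col]] %in% comparison[[col]]
  }
  design$sample_id[keep]
}

as_direction_table <- function(directions) {
  if (is.numeric(directions) && !is.null(names(directions))) {
    directions <- tibble(
      measure = names(directions),
      direction = as.numeric(directions)
    )
  }
  directions <- as_tibble(directions)
  stopifnot(all(c("measure", "direction") %in% names(directions)))
  if (!all(directions$direction %in% c(-1, 1))) {
    abort("directions must be +1 or -1", class = "fcg_invalid_input")
  }
  distinct(directions, .data$measure, .keep_all = TRUE)
}
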