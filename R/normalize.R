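#' Normalise raw time series to percent of baseline
#'
#' Rescales each animal x variable series so that the baseline phase maps to
#' 100%. The baseline aggregate is the mean of all non-missing values inside
#' the baseline window (by convention, all negative times; the intervention
#' happens at time 0). Values above 100% are retained — clipping in the
#' severity direction happens later, in [severity_delta()]. Variables flagged
#' `already_normalized` in the specification pass through unchanged.
#'
#' @param data Long-format tibble with columns `animal_id`, `time`,
#'   `variable`, `value` (and optionally `group`). Missing values allowed.
#' @param specs Variable specification from [variable_spec()].
#' @param baseline_window Numeric vector of times making up the baseline
#'   phase, or `NULL` (default) for all negative times.
#'
#' @return A tibble in the same long layout with `value` on the
#'   percent-of-baseline scale (baseline = 100). Missing raw values stay
#'   missing.
#' @examples
#' specs <- variable_spec("bwc", "decrease")
#' d <- tibble::tibble(
#'   animal_id = "m1", time = c(-1, 0, 1), variable = "bwc",
#'   value = c(20, 18, 19)
#' )
#' normalize_to_baseline(d, specs)
#' @export
normalize_to_baseline <- function(data, specs, baseline_window = NULL) {
  specs <- as_variable_spec(specs)
  data <- as_long_series(data)
  check_no_duplicates(data)
  check_variables_known(data, specs)

  window <- resolve_baseline_window(data$time, baseline_window)
  if (length(window) == 0L) {
    abort("empty baseline window: no negative times found and none supplied.")
  }

  base <- data %>%
    filter(.data$time %in% window) %>%
    group_by(.data$animal_id, .data$variable) %>%
    summarise(.baseline = mean(.data$value, na.rm = TRUE), .groups = "drop")

  out <- data %>%
    left_join(base, by = c("animal_id", "variable")) %>%
    left_join(specs, by = "variable")

  needs_base <- out %>%
    filter(!.data$already_normalized) %>%
    distinct(.data$animal_id, .data$variable, .data$.baseline)
  bad <- needs_base %>%
    filter(!is.finite(.data$.baseline) | .data$.baseline <= 0)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "baseline mean is missing, zero or negative for: %s",
      paste(sprintf("%s/%s", bad$animal_id, bad$variable), collapse = ", ")
    ))
  }

  out %>%
    mutate(value = ifelse(.data$already_normalized,
      .data$value, 100 * .data$value / .data$.baseline
    )) %>%
    select("animal_id", "group", "time", "variable", "value")
}

#' Directional deviation from baseline, in percent points
#'
#' The severity-bearing deviation of a percent-of-baseline value: for
#' `"decrease"`-type variables the shortfall below 100, for `"increase"`-type
#' variables the excess above 100. Deviations in the non-severity direction
#' contribute zero — values at or above baseline contribute nothing for a
#' decrease-type variable, and symmetrically for increase-type variables.
#' Missing values stay missing.
#'
#' @param norm_value Numeric vector on the percent-of-baseline scale.
#' @param direction `"decrease"` or `"increase"` (recycled).
#' @return Non-negative numeric vector of deviations in percent points.
#' @examples
#' severity_delta(90, "decrease") # 10
#' severity_delta(110, "decrease") # 0
#' severity_delta(120, "increase") # 20
#' @export
severity_delta <- function(norm_value, direction) {
  direction <- rep_len(as.character(direction), length(norm_value))
  bad <- setdiff(unique(direction), c("decrease", "increase"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown direction: %s", paste(bad, collapse = ", ")))
  }
  delta <- ifelse(direction == "decrease", 100 - norm_value, norm_value - 100)
  pmax(delta, 0)
}
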