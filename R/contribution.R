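#' Time-resolved variable contributions (radar profiles)
#'
#' The composite score hides which variables drive it; the contribution
#' profile exposes them. For each requested time point the per-variable
#' weights (averaged over animals for a group-level profile) are returned in
#' a fixed variable order together with a radar polygon area fraction: the
#' area of the polygon whose vertices sit at equal angles with radius equal
#' to each weight (missing treated as 0), divided by the area of the same
#' polygon with all radii 1. The fraction depends on the variable order — it
#' is an advisory summary of how broadly severity is distributed across
#' variables, not an invariant statistic. With fewer than three variables the
#' polygon degenerates and the fraction is `NA` (the weight vectors are still
#' returned).
#'
#' @param result A `relsa_result` from [relsa()].
#' @param at_times Times to profile; `NULL` (default) for all scored times.
#' @param var_order Variable ordering around the radar; `NULL` for the order
#'   of the reference specification.
#' @param animal_id Profile a single animal instead of the group mean.
#'
#' @return An object of class `relsa_contribution`:
#'   \describe{
#'     \item{profile}{tibble `(time, variable, weight)` with `variable`
#'       an ordered factor in `var_order`}
#'     \item{area}{tibble `(time, n_variables, area_fraction)`}
#'   }
#' @examples
#' spec <- sim_spec(n_animals = 4, seed = 7)
#' cohort <- simulate_cohort(spec)
#' ref <- build_reference_set(
#'   normalize_to_baseline(cohort, spec$variables), spec$variables
#' )
#' cp <- contribution_profile(relsa(cohort, ref), at_times = c(0, 2, 7))
#' cp$area
#' @export
contribution_profile <- function(result, at_times = NULL, var_order = NULL,
                                 animal_id = NULL) {
  if (!inherits(result, "relsa_result")) {
    abort("`result` must come from relsa().")
  }
  w <- result$weights
  if (!is.null(animal_id)) {
    if (!animal_id %in% w$animal_id) {
      abort(sprintf("animal '%s' is not in the result.", animal_id))
    }
    w <- w %>% filter(.data$animal_id %in% !!animal_id)
  }

  vars <- unique(w$variable)
  if (is.null(var_order)) {
    var_order <- intersect(result$ref$specs$variable, vars)
  }
  if (!setequal(var_order, vars) || anyDuplicated(var_order)) {
    abort("`var_order` must be a permutation of the result's variables.")
  }

  times <- sort(unique(w$time))
  if (is.null(at_times)) at_times <- times
  missing_t <- setdiff(at_times, times)
  if (length(missing_t) > 0L) {
    abort(sprintf(
      "requested time%s not in the result: %s",
      if (length(missing_t) > 1L) "s" else "",
      paste(missing_t, collapse = ", ")
    ))
  }

  profile <- w %>%
    filter(.data$time %in% at_times) %>%
    group_by(.data$time, .data$variable) %>%
    summarise(weight = mean(.data$weight, na.rm = TRUE), .groups = "drop") %>%
    mutate(
      weight = ifelse(is.nan(.data$weight), NA_real_, .data$weight),
      variable = factor(.data$variable, levels = var_order)
    ) %>%
    tidyr::complete(
      time = at_times,
      variable = factor(var_order, levels = var_order)
    ) %>%
    arrange(.data$time, .data$variable)

  area <- profile %>%
    group_by(.data$time) %>%
    summarise(
      n_variables = dplyr::n(),
      area_fraction = radar_area_fraction(.data$weight),
      .groups = "drop"
    )

  structure(list(profile = profile, area = area), class = "relsa_contribution")
}

# Fraction of the unit radar polygon covered by radii `r` at equal angles:
# polygon area = sin(2*pi/n)/2 * sum(r_i * r_{i+1}) cyclically, so the unit
# polygon cancels to sum(r_i * r_{i+1}) / n. Missing radii count as 0.
radar_area_fraction <- function(r) {
  n <- length(r)
  if (n < 3L) return(NA_real_)
  r <- ifelse(is.na(r), 0, r)
  sum(r * r[c(2:n, 1L)]) / n
}

#' @export
print.relsa_contribution <- function(x, ...) {
  cat(sprintf(
    "<relsa_contribution> %d time points x %d variables\n",
    nrow(x$area), dplyr::n_distinct(x$profile$variable)
  ))
  print(x$area)
  invisible(x)
}

#' @describeIn contribution_profile Weight profile joined with the area
#'   fraction, one row per time x variable.
#' @param x A `relsa_contribution` object.
#' @param ... Unused.
#' @method tidy relsa_contribution
#' @export
tidy.relsa_contribution <- function(x, ...) {
  x$profile %>% left_join(x$area, by = "time")
}
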