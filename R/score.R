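#' Per-variable severity weight
#'
#' The severity weight of one variable at one time point is its directional
#' deviation from baseline divided by the maximal deviation of that variable
#' in the reference set — a within-animal effect size on the reference scale.
#' Weights are non-negative and unbounded above: test animals may exceed the
#' reference maxima. Missing values stay missing.
#'
#' @param norm_value Numeric vector on the percent-of-baseline scale.
#' @param direction `"decrease"` or `"increase"` (recycled).
#' @param max_delta Positive reference maximum deviation in percent points
#'   (recycled).
#' @return Numeric vector of weights.
#' @examples
#' relsa_weight(75, "decrease", 30) # 25/30
#' relsa_weight(100, "decrease", 30) # 0
#' relsa_weight(55, "decrease", 30) # 1.5 — beyond the reference ceiling
#' @export
relsa_weight <- function(norm_value, direction, max_delta) {
  max_delta <- rep_len(as.numeric(max_delta), length(norm_value))
  if (any(!is.finite(max_delta) | max_delta <= 0)) {
    abort("`max_delta` must be positive and finite (invalid reference).")
  }
  severity_delta(norm_value, direction) / max_delta
}

#' Composite severity score from per-variable weights
#'
#' The composite score at one time point is the root mean square of the
#' available weights: missing variables do not contribute (they are excluded
#' from both the sum and the divisor), whereas variables present at or beyond
#' baseline in the non-severity direction contribute a weight of zero and do
#' count toward the divisor. With no available weight the score is undefined
#' (`NA`).
#'
#' @param weights Numeric vector of per-variable weights, `NA` for missing.
#' @return A single score, or `NA` if every weight is missing.
#' @examples
#' relsa_score(c(1, 1, 1)) # 1 — the reference ceiling
#' relsa_score(c(0.6, 0.8)) # sqrt((0.36 + 0.64) / 2)
#' relsa_score(c(1, NA, 0)) # sqrt((1 + 0) / 2): the missing entry drops out
#' @export
relsa_score <- function(weights) {
  weights <- as.numeric(weights)
  n <- sum(!is.na(weights))
  if (n == 0L) return(NA_real_)
  sqrt(sum(weights^2, na.rm = TRUE) / n)
}

#' Score an animal cohort against a reference set
#'
#' Runs the full per-time scoring: normalises each series to its baseline
#' (unless `normalized = TRUE`), computes per-variable severity weights
#' against the reference maxima, and combines them per time point into the
#' composite score by [relsa_score()]. Any non-empty subset of the reference
#' variables may be present in the test data; times at which every variable
#' is missing carry an undefined score and are ignored by the per-animal
#' maximum.
#'
#' @param data Long-format tibble with columns `animal_id`, `time`,
#'   `variable`, `value` (optionally `group`).
#' @param ref A `relsa_ref` from [build_reference_set()].
#' @param baseline_window Baseline times for normalisation; `NULL` (default)
#'   means all negative times.
#' @param normalized Set `TRUE` if `data` is already percent-of-baseline.
#'
#' @return An object of class `relsa_result` with components
#'   \describe{
#'     \item{weights}{tibble `(animal_id, group, time, variable, weight)`}
#'     \item{scores}{tibble `(animal_id, group, time, n_contributing, relsa)`}
#'     \item{summary}{tibble `(animal_id, group, relsa_max, time_of_max)`}
#'   }
#'   Use [tidy()] / [glance()] / [autoplot()] to inspect it.
#' @examples
#' spec <- sim_spec(n_animals = 4, seed = 42)
#' cohort <- simulate_cohort(spec)
#' ref <- build_reference_set(
#'   normalize_to_baseline(cohort, spec$variables), spec$variables
#' )
#' fit <- relsa(cohort, ref)
#' tidy(fit)
#' relsa_max(fit)
#' @export
relsa <- function(data, ref, baseline_window = NULL, normalized = FALSE) {
  ref <- as_relsa_ref(ref)
  data <- as_long_series(data)
  check_no_duplicates(data)

  shared <- intersect(unique(data$variable), ref$specs$variable)
  if (length(shared) == 0L) {
    abort("no variable in the data matches the reference set.")
  }
  check_variables_known(data, ref$specs)

  if (!normalized) {
    data <- normalize_to_baseline(data, ref$specs, baseline_window)
  }

  weights <- data %>%
    inner_join(ref$specs, by = "variable") %>%
    mutate(weight = relsa_weight(.data$value, .data$direction, .data$max_delta)) %>%
    select("animal_id", "group", "time", "variable", "weight")

  scores <- weights %>%
    group_by(.data$animal_id, .data$group, .data$time) %>%
    summarise(
      n_contributing = sum(!is.na(.data$weight)),
      relsa = relsa_score(.data$weight),
      .groups = "drop"
    )

  summary <- scores %>%
    filter(!is.na(.data$relsa)) %>%
    group_by(.data$animal_id, .data$group) %>%
    summarise(
      relsa_max = max(.data$relsa),
      time_of_max = .data$time[which.max(.data$relsa)],
      .groups = "drop"
    )

  structure(
    list(weights = weights, scores = scores, summary = summary, ref = ref),
    class = "relsa_result"
  )
}

#' Per-animal maximum severity
#'
#' The maximum composite score an animal attains over its observation period
#' — the unit of between-animal and between-model comparison.
#'
#' @param result A `relsa_result` from [relsa()].
#' @return Tibble `(animal_id, group, relsa_max, time_of_max)`.
#' @export
relsa_max <- function(result) {
  if (!inherits(result, "relsa_result")) {
    abort("`result` must come from relsa().")
  }
  result$summary
}

#' @export
print.relsa_result <- function(x, ...) {
  cat(sprintf(
    "<relsa_result> %d animals x %d variables, %d scored time points\n",
    dplyr::n_distinct(x$scores$animal_id),
    dplyr::n_distinct(x$weights$variable),
    nrow(x$scores)
  ))
  print(x$summary)
  invisible(x)
}

#' Tidiers for scored cohorts
#'
#' `tidy()` returns the per-time table (`"scores"`, the default), the
#' per-variable weight table (`"weights"`), or the per-animal maxima
#' (`"max"`). `glance()` returns a one-row cohort summary.
#'
#' @param x A `relsa_result`.
#' @param type One of `"scores"`, `"weights"`, `"max"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy relsa_result
#' @export
tidy.relsa_result <- function(x, type = c("scores", "weights", "max"), ...) {
  switch(match.arg(type),
    scores = x$scores,
    weights = x$weights,
    max = x$summary
  )
}

#' @rdname tidy.relsa_result
#' @method glance relsa_result
#' @export
glance.relsa_result <- function(x, ...) {
  tibble(
    n_animals = dplyr::n_distinct(x$scores$animal_id),
    n_variables = dplyr::n_distinct(x$weights$variable),
    n_times = dplyr::n_distinct(x$scores$time),
    mean_relsa_max = mean(x$summary$relsa_max),
    max_relsa_max = max(x$summary$relsa_max)
  )
}
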