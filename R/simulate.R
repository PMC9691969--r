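# Synthetic cohort generator: the structural assumptions of the severity
# score made explicit — baseline plateau, intervention-time deflection with
# direction, exponential (half-life) recovery, additive noise on the percent
# scale, per-variable sampling periods, optional missingness and a humane
# endpoint rule.

#' Specify a synthetic welfare-monitoring cohort
#'
#' Each variable follows `baseline * (1 +/- deflection * 2^(-t / half_life) / 100)`
#' after the intervention at time 0 (sign set by the severity direction),
#' stays at baseline before it, and receives additive Gaussian noise
#' expressed in percent points of baseline. The defaults mimic a
#' transmitter-implantation cohort qualitatively: a ~11% body-weight drop,
#' burrowing collapsing by ~74%, a transient heart-rate rise, an activity
#' drop, and slowly recovering heart-rate variability, observed daily over
#' two weeks with one baseline day.
#'
#' @param n_animals Number of animals.
#' @param variables Tibble with one row per variable: `variable`,
#'   `direction`, `already_normalized`, `baseline` (raw-scale baseline
#'   level), `deflection` (% of baseline at time 0, >= 0), `half_life`
#'   (recovery half-life in time units, > 0), `noise_sd` (% points, >= 0),
#'   `period` (sampling period in time units). `NULL` for the default
#'   five-variable panel.
#' @param study_length Last observation time (time units; intervention at 0).
#' @param n_baseline Number of baseline observations per variable, placed at
#'   negative multiples of the sampling period.
#' @param missing_rate Probability that a post-baseline observation is
#'   missing, i.i.d. (baseline observations are never removed, so every
#'   series keeps a usable baseline).
#' @param endpoint Optional humane-endpoint rule, a list
#'   `list(variable =, threshold =)`: when that variable's noiseless percent
#'   of baseline drops to or below `threshold` (e.g. 80 for a 20% body-weight
#'   loss), the animal's whole series is truncated after that time.
#' @param seed Default RNG seed used by [simulate_cohort()].
#'
#' @return A validated list of class `sim_spec`.
#' @examples
#' sim_spec(n_animals = 6, missing_rate = 0.05, seed = 3)
#' @export
sim_spec <- function(n_animals = 10,
                     variables = NULL,
                     study_length = 14,
                     n_baseline = 1,
                     missing_rate = 0,
                     endpoint = NULL,
                     seed = NULL) {
  if (is.null(variables)) {
    variables <- tibble(
      variable = c("bwc", "burON", "hr", "hrv", "act"),
      direction = c("decrease", "decrease", "increase", "decrease", "decrease"),
      already_normalized = c(FALSE, TRUE, FALSE, FALSE, FALSE),
      baseline = c(25, 100, 550, 10, 40),
      deflection = c(11, 74, 18, 25, 35),
      half_life = c(3, 1, 2, 5, 3),
      noise_sd = c(1.5, 8, 2, 4, 5),
      period = c(1, 1, 1, 1, 1)
    )
  }
  variables <- as_tibble(variables)
  assert_columns(
    variables,
    c("variable", "direction", "deflection", "half_life"),
    "`variables`"
  )
  if (!"already_normalized" %in% names(variables)) variables$already_normalized <- FALSE
  if (!"baseline" %in% names(variables)) variables$baseline <- 100
  if (!"noise_sd" %in% names(variables)) variables$noise_sd <- 0
  if (!"period" %in% names(variables)) variables$period <- 1
  as_variable_spec(variables[c("variable", "direction", "already_normalized")])
  if (any(variables$deflection < 0)) abort("`deflection` must be >= 0.")
  if (any(variables$half_life <= 0)) abort("`half_life` must be > 0.")
  if (any(variables$noise_sd < 0)) abort("`noise_sd` must be >= 0.")
  if (any(variables$period <= 0)) abort("`period` must be > 0.")
  if (any(variables$baseline <= 0)) abort("`baseline` must be > 0.")
  if (n_animals < 1L) abort("`n_animals` must be >= 1.")
  if (study_length <= 0) abort("`study_length` must be > 0.")
  if (n_baseline < 1L) abort("at least one baseline observation is required.")
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  if (!is.null(endpoint)) {
    if (!is.list(endpoint) || !all(c("variable", "threshold") %in% names(endpoint))) {
      abort("`endpoint` must be list(variable =, threshold =).")
    }
    if (!endpoint$variable %in% variables$variable) {
      abort(sprintf("endpoint variable '%s' is not simulated.", endpoint$variable))
    }
  }

  structure(
    list(
      n_animals = as.integer(n_animals),
      variables = variables,
      study_length = study_length,
      n_baseline = as.integer(n_baseline),
      missing_rate = missing_rate,
      endpoint = endpoint,
      seed = seed
    ),
    class = "sim_spec"
  )
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(
    "<sim_spec> %d animals, length %g, missing rate %g\n",
    x$n_animals, x$study_length, x$missing_rate
  ))
  print(x$variables)
  invisible(x)
}

# noiseless percent-of-baseline trajectory
sim_percent <- function(t, direction, deflection, half_life) {
  sgn <- ifelse(direction == "decrease", -1, 1)
  ifelse(t < 0, 100, 100 + sgn * deflection * 2^(-t / half_life))
}

#' Simulate a welfare-monitoring cohort
#'
#' Draws the cohort declared by a [sim_spec()]: per-variable sampling grids,
#' the deterministic deflection-and-recovery trajectory, additive percent-
#' scale noise, i.i.d. missingness on post-baseline observations, and
#' optional humane-endpoint truncation. Identical seeds give identical
#' cohorts.
#'
#' @param spec A `sim_spec`.
#' @param seed RNG seed; overrides `spec$seed` when given.
#' @param group Group label attached to every animal.
#' @param id_prefix Prefix for animal identifiers.
#' @return A long-format tibble `(animal_id, group, time, variable, value)`
#'   on the raw scale, ready for [normalize_to_baseline()] or [relsa()].
#' @examples
#' head(simulate_cohort(sim_spec(n_animals = 2, seed = 11)))
#' @export
simulate_cohort <- function(spec, seed = NULL, group = "sim",
                            id_prefix = "animal") {
  if (!inherits(spec, "sim_spec")) abort("`spec` must come from sim_spec().")
  seed <- seed %||% spec$seed

  with_seed(seed, {
    animals <- sprintf(
      "%s%0*d", id_prefix, nchar(as.character(spec$n_animals)),
      seq_len(spec$n_animals)
    )
    grid <- tidyr::crossing(animal_id = animals, spec$variables) %>%
      mutate(times = purrr::map(.data$period, function(p) {
        c(-p * rev(seq_len(spec$n_baseline)), seq(0, spec$study_length, by = p))
      })) %>%
      tidyr::unnest("times") %>%
      rename(time = "times")

    out <- grid %>%
      mutate(
        percent = sim_percent(
          .data$time, .data$direction, .data$deflection, .data$half_life
        ),
        percent_obs = .data$percent + rnorm(dplyr::n(), 0, .data$noise_sd),
        value = ifelse(.data$already_normalized,
          .data$percent_obs,
          .data$baseline * .data$percent_obs / 100
        )
      )

    if (spec$missing_rate > 0) {
      drop <- stats::runif(nrow(out)) < spec$missing_rate & out$time >= 0
      out$value[drop] <- NA_real_
    }

    if (!is.null(spec$endpoint)) {
      ep <- spec$endpoint
      hit <- out %>%
        filter(.data$variable == ep$variable, .data$percent <= ep$threshold)
      if (nrow(hit) > 0L) {
        cutoff <- hit %>%
          group_by(.data$animal_id) %>%
          summarise(end_time = min(.data$time), .groups = "drop")
        out <- out %>%
          left_join(cutoff, by = "animal_id") %>%
          filter(is.na(.data$end_time) | .data$time <= .data$end_time)
      }
    }

    out %>%
      mutate(group = group) %>%
      select("animal_id", "group", "time", "variable", "value") %>%
      arrange(.data$animal_id, .data$variable, .data$time)
  })
}

#' Engineer an animal with a prescribed severity profile
#'
#' Constructs a noise-free series whose per-variable weights all equal the
#' target score at every requested time (the root mean square of equal
#' weights is that weight), so scoring it against `ref` recovers the target
#' profile to numerical precision. Useful as an analytic ground truth: a
#' target of 1 reproduces the reference ceiling exactly.
#'
#' @param ref A `relsa_ref` the animal will be scored against.
#' @param target_profile Named numeric vector or two-column data frame
#'   (`time`, `relsa`) of intended scores per time (all >= 0).
#' @param variables Subset of reference variables to use (default: all).
#' @param animal_id,group Identifiers for the generated series.
#' @return Long-format tibble including a baseline row (time -1, value 100)
#'   per variable; values are on the percent scale with baseline 100, so raw
#'   and normalised coincide.
#' @examples
#' spec <- sim_spec(n_animals = 3, seed = 5)
#' ref <- build_reference_set(
#'   normalize_to_baseline(simulate_cohort(spec), spec$variables),
#'   spec$variables
#' )
#' probe <- engineer_known_severity(ref, c(`0` = 1, `1` = 0.5))
#' tidy(relsa(probe, ref))
#' @export
engineer_known_severity <- function(ref, target_profile, variables = NULL,
                                    animal_id = "engineered", group = "probe") {
  ref <- as_relsa_ref(ref)
  if (is.data.frame(target_profile)) {
    assert_columns(target_profile, c("time", "relsa"), "`target_profile`")
    times <- as.numeric(target_profile$time)
    targets <- as.numeric(target_profile$relsa)
  } else {
    if (is.null(names(target_profile))) {
      abort("`target_profile` must be named by time or be a (time, relsa) data frame.")
    }
    times <- as.numeric(names(target_profile))
    targets <- as.numeric(target_profile)
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    abort("target times must be finite and >= 0 (baseline is added at time -1).")
  }
  if (any(!is.finite(targets)) || any(targets < 0)) {
    abort("unreachable target: severity scores cannot be negative.")
  }

  specs <- ref$specs
  if (!is.null(variables)) {
    unknown <- setdiff(variables, specs$variable)
    if (length(unknown) > 0L) {
      abort(sprintf(
        "variable%s not in the reference set: %s",
        if (length(unknown) > 1L) "s" else "", paste(unknown, collapse = ", ")
      ))
    }
    specs <- specs %>% filter(.data$variable %in% !!variables)
  }

  tidyr::crossing(tibble(time = times, target = targets), specs) %>%
    mutate(
      delta = .data$target * .data$max_delta,
      value = ifelse(.data$direction == "decrease",
        100 - .data$delta, 100 + .data$delta
      )
    ) %>%
    select("time", "variable", "value") %>%
    bind_rows(tibble(
      time = -1, variable = specs$variable, value = 100
    )) %>%
    mutate(animal_id = animal_id, group = group) %>%
    select("animal_id", "group", "time", "variable", "value") %>%
    arrange(.data$variable, .data$time)
}
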