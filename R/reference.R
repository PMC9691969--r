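#' Build a reference set of maximal baseline deviations
#'
#' The severity scale is anchored to a reference cohort of known qualitative
#' severity (e.g. a transmitter-implantation cohort graded "moderate" under
#' the EU directive). For every variable, the reference set records the
#' largest directional deviation from baseline observed anywhere in the
#' cohort after the baseline phase — pooled over all reference animals and
#' all post-baseline times. These maxima are the denominators of the severity
#' weights: a test animal matching them everywhere scores exactly 1.
#'
#' @param data Long-format tibble of the reference cohort, already on the
#'   percent-of-baseline scale (see [normalize_to_baseline()]).
#' @param specs Variable specification from [variable_spec()]. The variable
#'   set of the reference is fixed at construction; every spec variable must
#'   show a positive post-baseline deviation in at least one animal.
#' @param label Free-text severity context of the reference cohort
#'   (e.g. `"moderate"`).
#' @param baseline_window Times making up the baseline phase, excluded from
#'   the maxima; `NULL` (default) means all negative times.
#'
#' @return An object of class `relsa_ref`: the per-variable maxima
#'   (`$specs$max_delta`, percent points) plus provenance (`$provenance`).
#'   A variable with zero maximal deviation is a hard error — it could never
#'   contribute and would silently distort the contributing-variable count.
#' @examples
#' specs <- variable_spec(c("bwc", "hr"), c("decrease", "increase"))
#' cohort <- simulate_cohort(sim_spec(n_animals = 4, seed = 1))
#' ref <- build_reference_set(
#'   normalize_to_baseline(cohort, sim_spec()$variables),
#'   sim_spec()$variables,
#'   label = "moderate"
#' )
#' ref
#' @export
build_reference_set <- function(data, specs, label = "reference",
                                baseline_window = NULL) {
  specs <- as_variable_spec(specs)
  data <- as_long_series(data)
  check_variables_known(data, specs)
  if (nrow(data) == 0L) abort("reference cohort is empty.")

  window <- resolve_baseline_window(data$time, baseline_window)
  post <- data %>% filter(!.data$time %in% window)

  maxima <- post %>%
    inner_join(specs, by = "variable") %>%
    mutate(delta = severity_delta(.data$value, .data$direction)) %>%
    group_by(.data$variable) %>%
    summarise(
      max_delta = if (all(is.na(.data$delta))) NA_real_ else max(.data$delta, na.rm = TRUE),
      .groups = "drop"
    )

  specs <- specs %>% left_join(maxima, by = "variable")
  unusable <- specs$variable[is.na(specs$max_delta) | specs$max_delta <= 0]
  if (length(unusable) > 0L) {
    abort(sprintf(
      "reference build failed: no positive post-baseline deviation for variable%s %s.",
      if (length(unusable) > 1L) "s" else "", paste(unusable, collapse = ", ")
    ))
  }

  structure(
    list(
      specs = specs,
      provenance = list(
        label = label,
        n_animals = dplyr::n_distinct(data$animal_id),
        groups = sort(unique(data$group)),
        time_range = range(data$time),
        baseline_window = window
      )
    ),
    class = "relsa_ref"
  )
}

#' @export
print.relsa_ref <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<relsa_ref> severity context \"%s\" — %d animals, times [%g, %g]\n",
    p$label, p$n_animals, p$time_range[1], p$time_range[2]
  ))
  print(x$specs)
  invisible(x)
}

#' @describeIn build_reference_set Per-variable maxima as a tibble.
#' @param x A `relsa_ref` object.
#' @param ... Unused.
#' @method tidy relsa_ref
#' @export
tidy.relsa_ref <- function(x, ...) x$specs

as_relsa_ref <- function(ref) {
  if (!inherits(ref, "relsa_ref")) {
    abort("`ref` must be a reference set built by build_reference_set().")
  }
  ref
}

#' Serialise / restore a reference set
#'
#' A reference set, once built, anchors every later study; these helpers
#' round-trip it through JSON so it can be stored alongside results.
#'
#' @param ref A `relsa_ref` object.
#' @param path File path for the JSON representation.
#' @return `write_reference_set()` returns `path` invisibly;
#'   `read_reference_set()` returns the restored `relsa_ref`.
#' @export
write_reference_set <- function(ref, path) {
  ref <- as_relsa_ref(ref)
  jsonlite::write_json(
    list(specs = ref$specs, provenance = ref$provenance),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      specs = as_tibble(raw$specs),
      provenance = raw$provenance
    ),
    class = "relsa_ref"
  )
}
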