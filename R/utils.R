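# internal helpers

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1L) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Coerce the input table to the canonical long layout: animal_id, group,
# time, variable, value. A missing group column becomes a single group.
as_long_series <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  data <- as_tibble(data)
  if (!"group" %in% names(data)) data$group <- "all"
  assert_columns(data, c("animal_id", "group", "time", "variable", "value"))
  data %>%
    mutate(
      animal_id = as.character(.data$animal_id),
      group = as.character(.data$group),
      time = as.numeric(.data$time),
      variable = as.character(.data$variable),
      value = as.numeric(.data$value)
    ) %>%
    select("animal_id", "group", "time", "variable", "value") %>%
    arrange(.data$animal_id, .data$variable, .data$time)
}

check_no_duplicates <- function(data, what = "data") {
  dup <- data %>%
    count(.data$animal_id, .data$time, .data$variable) %>%
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    ex <- dup[1L, ]
    abort(sprintf(
      "%s contains %d duplicated (animal_id, time, variable) key%s, e.g. animal '%s', time %g, variable '%s'.",
      what, nrow(dup), if (nrow(dup) > 1L) "s" else "",
      ex$animal_id, ex$time, ex$variable
    ))
  }
  invisible(data)
}

# Baseline times: an explicit numeric vector, or by convention all negative
# times (intervention at time 0).
resolve_baseline_window <- function(times, baseline_window = NULL) {
  if (is.null(baseline_window)) {
    sort(unique(times[times < 0]))
  } else {
    sort(unique(as.numeric(baseline_window)))
  }
}
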