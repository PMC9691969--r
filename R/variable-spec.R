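#' Declare outcome variables and their severity directions
#'
#' Every outcome measure used in a severity analysis must declare the
#' direction in which severity unfolds: impairment lowers body weight,
#' burrowing, activity and heart rate variability (`"decrease"`), but raises
#' heart rate (`"increase"`). Variables already expressed as a percentage of
#' baseline (e.g. overnight burrowing performance) are flagged
#' `already_normalized` and pass through baseline normalisation unchanged.
#'
#' @param variable Character vector of unique variable names.
#' @param direction Character vector (recycled): `"decrease"` or `"increase"`,
#'   the direction of unfolding severity relative to baseline.
#' @param already_normalized Logical vector (recycled): is the variable
#'   already a percent-of-baseline measure?
#'
#' @return A tibble with columns `variable`, `direction`,
#'   `already_normalized` — the variable specification used throughout the
#'   package.
#' @examples
#' variable_spec(
#'   c("bwc", "burON", "hr", "hrv", "temp", "act"),
#'   c("decrease", "decrease", "increase", "decrease", "decrease", "decrease"),
#'   already_normalized = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
#' )
#' @export
variable_spec <- function(variable, direction, already_normalized = FALSE) {
  variable <- as.character(variable)
  if (anyDuplicated(variable)) {
    abort("variable names must be unique within a specification.")
  }
  if (length(variable) == 0L) abort("at least one variable is required.")
  direction <- rep_len(as.character(direction), length(variable))
  bad <- setdiff(unique(direction), c("decrease", "increase"))
  if (length(bad) > 0L) {
    abort(sprintf(
      "`direction` must be \"decrease\" or \"increase\" (got: %s).",
      paste(bad, collapse = ", ")
    ))
  }
  already_normalized <- rep_len(as.logical(already_normalized), length(variable))
  if (anyNA(already_normalized)) abort("`already_normalized` must be TRUE or FALSE.")
  tibble(
    variable = variable,
    direction = direction,
    already_normalized = already_normalized
  )
}

as_variable_spec <- function(specs) {
  if (!is.data.frame(specs)) abort("`specs` must be a data frame (see variable_spec()).")
  assert_columns(specs, c("variable", "direction"), "`specs`")
  if (!"already_normalized" %in% names(specs)) specs$already_normalized <- FALSE
  variable_spec(specs$variable, specs$direction, specs$already_normalized)
}

check_variables_known <- function(data, specs) {
  unknown <- setdiff(unique(data$variable), specs$variable)
  if (length(unknown) > 0L) {
    abort(sprintf(
      "data contains variable%s absent from the specification: %s",
      if (length(unknown) > 1L) "s" else "", paste(unknown, collapse = ", ")
    ))
  }
  invisible(data)
}
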