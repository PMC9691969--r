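# Delimited-text readers/writers for animal time-series tables and study
# configurations. Delimiters are auto-detected between comma and tab;
# decimals use points.

#' Read an animal time-series table
#'
#' Reads a delimited text file in long layout (columns `animal_id`, `time`,
#' `variable`, `value`, optional `group`) or wide layout (`animal_id`,
#' `time`, optional `group`, one column per variable) and returns the
#' canonical long tibble used by the rest of the package. Empty cells and
#' `"NA"` become missing values. Duplicated `(animal_id, time, variable)`
#' keys are an error with the offending key named.
#'
#' @param path Path to a CSV or TSV file.
#' @param layout `"auto"` (default), `"long"` or `"wide"`.
#' @param delim Field delimiter; `NULL` auto-detects comma vs tab.
#' @return Long-format tibble `(animal_id, group, time, variable, value)`.
#' @export
read_animal_data <- function(path, layout = c("auto", "long", "wide"),
                             delim = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(
    path,
    delim = delim, na = c("", "NA"),
    show_col_types = FALSE, progress = FALSE
  )
  if (layout == "auto") {
    layout <- if (all(c("variable", "value") %in% names(raw))) "long" else "wide"
  }

  if (layout == "long") {
    assert_columns(raw, c("animal_id", "time", "variable", "value"), path)
  } else {
    assert_columns(raw, c("animal_id", "time"), path)
    id_cols <- intersect(c("animal_id", "group", "time"), names(raw))
    var_cols <- setdiff(names(raw), id_cols)
    if (length(var_cols) == 0L) {
      abort(sprintf("%s: wide layout needs at least one variable column.", path))
    }
    raw <- raw %>%
      tidyr::pivot_longer(
        dplyr::all_of(var_cols),
        names_to = "variable", values_to = "value",
        values_transform = as.numeric
      )
  }

  bad_time <- which(!is.na(raw$time) & is.na(suppressWarnings(as.numeric(raw$time))))
  if (length(bad_time) > 0L) {
    abort(sprintf(
      "%s: unparseable time value in data row %d.", path, bad_time[1L]
    ))
  }

  out <- as_long_series(raw)
  check_no_duplicates(out, path)
  out
}

#' Write a long-format animal table
#'
#' @param data Long-format tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_animal_data <- function(data, path) {
  readr::write_csv(as_long_series(data), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write a study configuration
#'
#' A study configuration collects everything needed to run the pipeline:
#' the input table (or a simulation block), the variable specification with
#' severity directions, the baseline window, which group anchors the
#' reference set, clustering and bootstrap options, and the master seed.
#' YAML and JSON are supported and round-trip losslessly.
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`).
#' @return `read_study_config()`: a validated list of class `study_config`;
#'   `write_study_config()`: `path`, invisibly.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_study_config(raw)
}

#' @rdname read_study_config
#' @param config A `study_config` (or plain list with the same fields).
#' @export
write_study_config <- function(config, path) {
  config <- as_study_config(config)
  plain <- unclass(config)
  plain$variables <- purrr::transpose(as.list(as_tibble(plain$variables)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  } else {
    yaml::write_yaml(plain, path)
  }
  invisible(path)
}

as_study_config <- function(raw) {
  if (inherits(raw, "study_config")) return(raw)
  if (!is.list(raw)) abort("configuration must be a list.")
  if (is.null(raw$variables)) abort("configuration needs a `variables` block.")
  vars <- if (is.data.frame(raw$variables)) {
    as_tibble(raw$variables)
  } else {
    dplyr::bind_rows(lapply(raw$variables, as_tibble))
  }
  vars <- as_variable_spec(vars)

  defaults <- list(
    input = NULL, # path to a data table; NULL when `simulate` is given
    layout = "auto",
    simulate = NULL, # optional simulation block replacing `input`
    baseline_window = NULL, # NULL = all negative times
    reference_group = NULL, # NULL = whole input is the reference cohort
    reference_label = "reference",
    levels = list(k = "auto", method = "dp", threshold_mode = "max", restarts = 25),
    bootstrap = list(B = 10000, level = 0.95),
    seed = 1
  )
  cfg <- modifyList(defaults, raw[setdiff(names(raw), "variables")])
  cfg$variables <- vars
  if (is.null(cfg$input) && is.null(cfg$simulate)) {
    abort("configuration needs either `input` (a file) or a `simulate` block.")
  }
  structure(cfg, class = "study_config")
}
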