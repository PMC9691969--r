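#' BCa bootstrap confidence interval for a statistic
#'
#' Nonparametric bootstrap with bias-corrected and accelerated (BCa) 95%
#' intervals: the data are resampled with replacement `B` times, the bias
#' correction `z0` comes from the share of replicate statistics below the
#' point estimate, and the acceleration `a` from the skewness of the
#' jackknife (leave-one-out) distribution. When the jackknife variance is
#' degenerate (all leave-one-out values equal) the BCa adjustment is
#' undefined and the function falls back to the plain percentile interval
#' with a warning. With no resampling variability at all the interval
#' collapses to the point estimate.
#'
#' @param x Numeric vector of observations (length >= 2).
#' @param statistic Function of a numeric vector returning one number
#'   (default `mean`).
#' @param B Number of bootstrap replicates (default 10000).
#' @param seed RNG seed; identical seed, `B` and data give bit-identical
#'   intervals.
#' @param level Coverage probability (default 0.95).
#' @param label Statistic label recorded in the output.
#'
#' @return A one-row tibble: `statistic`, `estimate`, `conf_low`,
#'   `conf_high`, `level`, `B`, `z0`, `acceleration`, `method`
#'   (`"bca"` or `"percentile"`), `seed`, `n`.
#' @examples
#' bootstrap_bca(rnorm(30, 1), B = 999, seed = 1)
#' @export
bootstrap_bca <- function(x, statistic = mean, B = 10000, seed = NULL,
                          level = 0.95, label = "mean") {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) abort("at least 2 observations are required for the BCa bootstrap.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  B <- as.integer(B)
  if (B < 2L) abort("`B` must be at least 2.")

  theta_hat <- statistic(x)
  if (!is.numeric(theta_hat) || length(theta_hat) != 1L || !is.finite(theta_hat)) {
    abort("`statistic` must return a single finite number.")
  }

  theta_star <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    vapply(seq_len(B), function(b) statistic(x[idx[, b]]), numeric(1))
  })

  alpha <- c((1 - level) / 2, 1 - (1 - level) / 2)

  if (max(theta_star) - min(theta_star) == 0) {
    # no resampling variability: interval is the point estimate
    return(bca_row(
      label, theta_hat, rep(theta_star[1L], 2L), level, B,
      z0 = 0, a = 0, method = "bca", seed = seed, n = n
    ))
  }

  # bias correction from the replicate distribution
  prop_below <- mean(theta_star < theta_hat)
  # jackknife acceleration
  theta_jack <- vapply(seq_len(n), function(i) statistic(x[-i]), numeric(1))
  jack_dev <- mean(theta_jack) - theta_jack
  denom <- sum(jack_dev^2)^1.5

  degenerate <- prop_below <= 0 || prop_below >= 1 || denom == 0
  if (degenerate) {
    warn(paste(
      "BCa adjustment degenerate (jackknife variance or bias correction",
      "undefined); falling back to the percentile interval."
    ))
    ci <- as.numeric(quantile(theta_star, alpha, type = 7, names = FALSE))
    return(bca_row(
      label, theta_hat, ci, level, B,
      z0 = NA_real_, a = NA_real_, method = "percentile", seed = seed, n = n
    ))
  }

  z0 <- qnorm(prop_below)
  a <- sum(jack_dev^3) / (6 * denom)
  z_alpha <- qnorm(alpha)
  adj <- pnorm(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha)))
  ci <- as.numeric(quantile(theta_star, adj, type = 7, names = FALSE))

  if (ci[1L] > theta_hat || ci[2L] < theta_hat) {
    warn("BCa interval does not contain the point estimate (heavily skewed resamples).")
  }

  bca_row(label, theta_hat, ci, level, B,
    z0 = z0, a = a, method = "bca", seed = seed, n = n
  )
}

bca_row <- function(label, estimate, ci, level, B, z0, a, method, seed, n) {
  tibble(
    statistic = label,
    estimate = estimate,
    conf_low = ci[1L],
    conf_high = ci[2L],
    level = level,
    B = B,
    z0 = z0,
    acceleration = a,
    method = method,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    n = n
  )
}

#' Bootstrap group means of per-animal severity maxima
#'
#' Applies [bootstrap_bca()] to each group's values, giving the group mean
#' score maximum with its BCa confidence interval — the standard
#' between-group comparison of maximal experienced severity.
#'
#' @param data Data frame with a value column and a grouping column.
#' @param value_col,group_col Column names (strings).
#' @inheritParams bootstrap_bca
#' @return Tibble, one row per group, with a `group` column ahead of the
#'   [bootstrap_bca()] fields. Each group uses a seed derived
#'   deterministically from `seed`.
#' @export
bootstrap_group_means <- function(data, value_col = "relsa_max",
                                  group_col = "group", B = 10000,
                                  seed = NULL, level = 0.95) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  assert_columns(data, c(value_col, group_col))
  groups <- sort(unique(as.character(data[[group_col]])))
  purrr::imap_dfr(setNames(groups, groups), function(g, nm) {
    vals <- data[[value_col]][data[[group_col]] == g]
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, match(g, groups))
    res <- bootstrap_bca(vals,
      statistic = mean, B = B, seed = sub_seed,
      level = level, label = "group_mean"
    )
    dplyr::bind_cols(tibble(group = g), res)
  })
}

#' Bootstrap cluster centroids of severity levels
#'
#' Resamples the score maxima within each identified severity cluster
#' (cluster membership held fixed) and recomputes the cluster mean, yielding
#' a BCa confidence interval per centroid — a stability check on the level
#' positions.
#'
#' @param levels A `severity_levels` object from [cluster_relsa_max()].
#' @inheritParams bootstrap_bca
#' @return Tibble, one row per level with centroid estimate and interval.
#'   Singleton clusters cannot be bootstrapped and carry `NA` bounds.
#' @export
bootstrap_centroids <- function(levels, B = 10000, seed = NULL, level = 0.95) {
  if (!inherits(levels, "severity_levels")) {
    abort("`levels` must come from cluster_relsa_max().")
  }
  purrr::map_dfr(seq_len(levels$k), function(j) {
    vals <- levels$values[levels$assignments == j]
    lab <- paste0("L", j)
    if (length(vals) < 2L) {
      return(tibble(
        statistic = paste0("centroid_", lab), estimate = mean(vals),
        conf_low = NA_real_, conf_high = NA_real_, level = level,
        B = as.integer(B), z0 = NA_real_, acceleration = NA_real_,
        method = "singleton",
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        n = length(vals)
      ))
    }
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, j)
    bootstrap_bca(vals,
      statistic = mean, B = B, seed = sub_seed,
      level = level, label = paste0("centroid_", lab)
    )
  })
}

# stable per-task sub-seed below 2^31
derive_seed <- function(seed, index) {
  (as.integer(seed) * 1009L + as.integer(index) * 9176L) %% 2147483629L
}
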