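# Severity levels from per-animal maxima: univariate k-means with a
# deterministic elbow rule, an exact dynamic-programming mode, and grading.

#' Choose the number of severity levels from a scree curve
#'
#' Computes the within-cluster sum of squares (WSS) of the optimal univariate
#' clustering for each candidate number of clusters and picks the elbow as
#' the k with the maximum second difference of the WSS curve — a
#' deterministic, reproducible surrogate for the visual scree heuristic. The
#' choice can always be overridden by passing an explicit `k` downstream.
#'
#' @param values Numeric vector of per-animal score maxima (finite, >= 0).
#' @param k_range Candidate cluster counts (default `1:8`).
#' @return An object of class `relsa_scree`: `$k` (selected), `$wss`
#'   (tibble `k`, `wss`).
#' @examples
#' x <- c(rnorm(20, 0.1, 0.01), rnorm(20, 0.9, 0.01))
#' scree_select_k(x)$k # 2
#' @export
scree_select_k <- function(values, k_range = 1:8) {
  values <- check_level_values(values)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L)) abort("`k_range` must be positive.")
  n_distinct <- length(unique(values))
  if (max(k_range) > n_distinct) {
    abort(sprintf(
      "`k_range` reaches %d clusters but only %d distinct values exist.",
      max(k_range), n_distinct
    ))
  }
  if (length(values) < 2L * max(k_range)) {
    warn(sprintf(
      "only %d observations for up to %d clusters; the scree curve may be unstable.",
      length(values), max(k_range)
    ))
  }

  wss <- vapply(k_range, function(k) kmeans_1d_dp(values, k)$wss, numeric(1))
  if (all(wss == 0)) {
    abort("all within-cluster sums of squares are zero; no elbow exists (values too homogeneous).")
  }

  # elbow = interior k maximising the discrete second difference of log-WSS.
  # The log scale makes the rule scale-free: a raw-WSS second difference is
  # dominated by the first split whenever the curve decays geometrically,
  # whereas the log curve kinks exactly where the clusters stop being real.
  if (length(k_range) < 3L) {
    k_sel <- k_range[which.min(wss)]
  } else {
    floor_wss <- max(wss[wss > 0]) * 1e-12
    d2 <- diff(log(pmax(wss, floor_wss)), differences = 2)
    k_sel <- k_range[which.max(d2) + 1L]
  }

  structure(
    list(k = k_sel, wss = tibble(k = k_range, wss = wss)),
    class = "relsa_scree"
  )
}

#' @export
print.relsa_scree <- function(x, ...) {
  cat(sprintf("<relsa_scree> selected k = %d\n", x$k))
  print(x$wss)
  invisible(x)
}

#' Derive ordered severity levels by univariate clustering
#'
#' Clusters per-animal score maxima on the severity axis and turns the
#' clusters into ordered severity levels L1 < L2 < ... < Lk with one upper
#' threshold per level. Two modes are available: `"dp"` (default) solves the
#' 1-D clustering exactly by dynamic programming over contiguous partitions
#' of the sorted values; `"lloyd"` runs standard k-means with random restarts
#' and keeps the lowest-WSS solution. Thresholds are, by default, the largest
#' observed value inside each sorted cluster (so "level j" reads "score at or
#' below threshold j"); `threshold_mode = "midpoint"` places each boundary
#' halfway between adjacent clusters instead (the top threshold is always the
#' overall maximum).
#'
#' @param values Numeric vector of score maxima (finite, >= 0).
#' @param k Number of levels, or `"auto"` to select via [scree_select_k()].
#' @param method `"dp"` (exact) or `"lloyd"` (k-means with restarts).
#' @param seed RNG seed for the Lloyd restarts (ignored for `"dp"`).
#' @param restarts Number of random initialisations in Lloyd mode.
#' @param threshold_mode `"max"` (within-cluster maxima) or `"midpoint"`.
#' @param k_range Candidate range handed to [scree_select_k()] when
#'   `k = "auto"`.
#'
#' @return An object of class `severity_levels`: `$k`, `$centroids` (ordered),
#'   `$thresholds` (ordered upper bounds), `$assignments` (per-observation
#'   level index, in input order), `$wss`, `$method`, `$seed`.
#' @examples
#' x <- c(0.10, 0.12, 0.50, 0.52, 0.90, 0.92)
#' cluster_relsa_max(x, k = 3)$thresholds # 0.12 0.52 0.92
#' @export
cluster_relsa_max <- function(values, k = "auto", method = c("dp", "lloyd"),
                              seed = NULL, restarts = 25,
                              threshold_mode = c("max", "midpoint"),
                              k_range = 1:8) {
  values <- check_level_values(values)
  method <- match.arg(method)
  threshold_mode <- match.arg(threshold_mode)

  if (identical(k, "auto")) {
    k <- scree_select_k(values, k_range)$k
  }
  k <- as.integer(k)
  if (k < 2L) abort("`k` must be at least 2.")
  if (k > length(unique(values))) {
    abort(sprintf(
      "cannot form %d clusters from %d distinct values.",
      k, length(unique(values))
    ))
  }

  if (method == "dp") {
    fit <- kmeans_1d_dp(values, k)
    assignments <- fit$assignments
    centroids <- fit$centroids
    wss <- fit$wss
  } else {
    fit <- with_seed(seed, lloyd_restarts(values, k, restarts))
    ord <- order(fit$centers[, 1L])
    relabel <- match(seq_len(k), ord)
    assignments <- relabel[fit$cluster]
    centroids <- sort(as.numeric(fit$centers[, 1L]))
    wss <- fit$tot.withinss
  }

  cluster_max <- vapply(
    seq_len(k), function(j) max(values[assignments == j]), numeric(1)
  )
  cluster_min <- vapply(
    seq_len(k), function(j) min(values[assignments == j]), numeric(1)
  )
  thresholds <- if (threshold_mode == "max") {
    cluster_max
  } else {
    c((cluster_max[-k] + cluster_min[-1L]) / 2, cluster_max[k])
  }

  structure(
    list(
      k = k, centroids = centroids, thresholds = thresholds,
      assignments = assignments, values = values, wss = wss,
      method = method, threshold_mode = threshold_mode,
      seed = seed, restarts = if (method == "lloyd") restarts else NA_integer_
    ),
    class = "severity_levels"
  )
}

#' @export
print.severity_levels <- function(x, ...) {
  cat(sprintf(
    "<severity_levels> k = %d (%s, thresholds = within-cluster %s)\n",
    x$k, x$method, x$threshold_mode
  ))
  print(tidy(x))
  invisible(x)
}

#' Tidiers for severity levels
#'
#' `tidy()` gives one row per level (centroid, threshold, size); `glance()`
#' a one-row summary; `augment()` the input values with their level
#' assignments.
#'
#' @param x A `severity_levels` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy severity_levels
#' @export
tidy.severity_levels <- function(x, ...) {
  tibble(
    level = paste0("L", seq_len(x$k)),
    centroid = x$centroids,
    threshold = x$thresholds,
    n = as.integer(table(factor(x$assignments, levels = seq_len(x$k))))
  )
}

#' @rdname tidy.severity_levels
#' @method glance severity_levels
#' @export
glance.severity_levels <- function(x, ...) {
  tibble(
    k = x$k, wss = x$wss, method = x$method,
    threshold_mode = x$threshold_mode,
    n = length(x$assignments)
  )
}

#' @rdname tidy.severity_levels
#' @method augment severity_levels
#' @export
augment.severity_levels <- function(x, ...) {
  tibble(
    value = x$values,
    level = x$assignments,
    level_label = paste0("L", x$assignments)
  )
}

#' Grade severity values against level thresholds
#'
#' Maps each score maximum to the smallest level whose upper threshold
#' contains it (ties grade into the lower level, so "Lj < x" reads: values
#' strictly below x belong to level j or lower). Values above the top
#' threshold still grade into the top level but are flagged as beyond the
#' reference range.
#'
#' @param values Numeric vector of score maxima (finite).
#' @param levels A `severity_levels` object or a strictly increasing numeric
#'   vector of upper thresholds.
#' @return Tibble `(value, level, level_label, beyond_range)`.
#' @examples
#' grade_severity(c(0, 0.30, 4.0), levels = c(0.27, 0.59, 0.79, 3.45))
#' @export
grade_severity <- function(values, levels) {
  thresholds <- if (inherits(levels, "severity_levels")) {
    levels$thresholds
  } else {
    as.numeric(levels)
  }
  if (length(thresholds) < 1L || any(diff(thresholds) <= 0)) {
    abort("`levels` must supply strictly increasing thresholds.")
  }
  values <- as.numeric(values)
  if (any(!is.finite(values))) abort("`values` must be finite.")

  k <- length(thresholds)
  idx <- vapply(values, function(v) {
    j <- which(v <= thresholds)
    if (length(j) == 0L) k else j[1L]
  }, integer(1))

  tibble(
    value = values,
    level = idx,
    level_label = paste0("L", idx),
    beyond_range = values > thresholds[k]
  )
}

check_level_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) abort("`values` is empty.")
  if (any(!is.finite(values))) abort("`values` must be finite.")
  if (any(values < 0)) abort("`values` must be non-negative severity maxima.")
  values
}

# Lloyd's k-means with `restarts` random initialisations (k-means++
# distance-weighted seeding over the distinct observed values), keeping the
# lowest-WSS run. Runs that collapse to an empty cluster are discarded and
# redrawn.
lloyd_restarts <- function(values, k, restarts) {
  distinct_vals <- unique(values)
  seed_pp <- function() {
    centers <- sample(distinct_vals, 1L)
    while (length(centers) < k) {
      d2 <- vapply(distinct_vals, function(v) min((v - centers)^2), numeric(1))
      if (sum(d2) == 0) {
        rest <- setdiff(distinct_vals, centers)
        centers <- c(centers, rest[sample.int(length(rest), 1L)])
      } else {
        centers <- c(centers, sample(distinct_vals, 1L, prob = d2))
      }
    }
    centers
  }
  best <- NULL
  done <- 0L
  guard <- 0L
  while (done < restarts && guard < 50L * restarts) {
    guard <- guard + 1L
    init <- seed_pp()
    fit <- tryCatch(
      suppressWarnings(
        kmeans(values, centers = init, iter.max = 100L, algorithm = "Lloyd")
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    done <- done + 1L
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) abort("k-means failed for every restart.")
  best
}

# Exact 1-D k-means by dynamic programming. Optimal clusters of ordered
# scalars are contiguous, so minimising WSS reduces to an optimal
# segmentation of the sorted values: cost(i, j) is the sum of squared
# deviations of values i..j from their mean (computed from prefix sums),
# D[k][j] = min over split points of D[k-1][s-1] + cost(s, j).
# O(k n^2), ample for cohort-sized inputs.
kmeans_1d_dp <- function(values, k) {
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  k <- as.integer(k)

  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  seg_cost <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }

  D <- matrix(Inf, nrow = k, ncol = n)
  B <- matrix(NA_integer_, nrow = k, ncol = n)
  for (j in seq_len(n)) {
    D[1L, j] <- seg_cost(1L, j)
    B[1L, j] <- 1L
  }
  if (k > 1L) {
    for (q in 2:k) {
      for (j in q:n) {
        best <- Inf
        arg <- NA_integer_
        for (s in q:j) {
          cand <- D[q - 1L, s - 1L] + seg_cost(s, j)
          if (cand < best) {
            best <- cand
            arg <- s
          }
        }
        D[q, j] <- best
        B[q, j] <- arg
      }
    }
  }

  # backtrack segment starts
  starts <- integer(k)
  j <- n
  for (q in k:1) {
    starts[q] <- B[q, j]
    j <- starts[q] - 1L
  }
  ends <- c(starts[-1L] - 1L, n)

  assign_sorted <- rep.int(seq_len(k), ends - starts + 1L)
  assignments <- integer(n)
  assignments[ord] <- assign_sorted
  centroids <- vapply(
    seq_len(k), function(q) mean(x[starts[q]:ends[q]]), numeric(1)
  )

  list(
    assignments = assignments,
    centroids = centroids,
    wss = max(D[k, n], 0)
  )
}
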