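# Independent oracles, written with plain base-R loops so they share no code
# path with the package implementation.

# Brute-force severity scoring of raw long-format data frames.
# ref_df and test_df: data.frames with animal_id, time, variable, value.
# specs_df: variable, direction, already_normalized.
# Returns list(max_delta, scores, relsa_max) computed by explicit loops.
oracle_relsa <- function(test_df, ref_df, specs_df, baseline_times = NULL) {
  norm_one <- function(df) {
    out <- df
    out$norm <- NA_real_
    for (a in unique(df$animal_id)) {
      for (v in unique(df$variable[df$animal_id == a])) {
        rows <- which(df$animal_id == a & df$variable == v)
        times <- df$time[rows]
        bt <- if (is.null(baseline_times)) times[times < 0] else baseline_times
        already <- specs_df$already_normalized[specs_df$variable == v]
        if (already) {
          out$norm[rows] <- df$value[rows]
        } else {
          b <- mean(df$value[rows][times %in% bt], na.rm = TRUE)
          out$norm[rows] <- 100 * df$value[rows] / b
        }
      }
    }
    out
  }
  delta_of <- function(norm, dir) {
    if (is.na(norm)) return(NA_real_)
    d <- if (dir == "decrease") 100 - norm else norm - 100
    max(d, 0)
  }

  refn <- norm_one(ref_df)
  max_delta <- c()
  for (v in specs_df$variable) {
    dir <- specs_df$direction[specs_df$variable == v]
    rows <- which(refn$variable == v & refn$time >= 0)
    deltas <- vapply(refn$norm[rows], delta_of, numeric(1), dir = dir)
    max_delta[v] <- suppressWarnings(max(deltas, na.rm = TRUE))
  }

  testn <- norm_one(test_df)
  scores <- data.frame()
  for (a in unique(testn$animal_id)) {
    for (t in sort(unique(testn$time[testn$animal_id == a]))) {
      ws <- c()
      for (v in unique(testn$variable[testn$animal_id == a])) {
        row <- which(testn$animal_id == a & testn$time == t & testn$variable == v)
        if (length(row) == 0) next
        dir <- specs_df$direction[specs_df$variable == v]
        ws <- c(ws, delta_of(testn$norm[row], dir) / max_delta[v])
      }
      n_ok <- sum(!is.na(ws))
      s <- if (n_ok == 0) NA_real_ else sqrt(sum(ws^2, na.rm = TRUE) / n_ok)
      scores <- rbind(scores, data.frame(animal_id = a, time = t, relsa = s))
    }
  }
  rmax <- sapply(split(scores$relsa, scores$animal_id), function(s) {
    if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
  })
  list(max_delta = max_delta, scores = scores, relsa_max = rmax)
}

# Exhaustive optimal 1-D clustering: tries every contiguous partition of the
# sorted values into k segments and keeps the minimal within-cluster SS.
oracle_cluster_1d <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  wss_of <- function(bounds) {
    starts <- c(1, bounds + 1)
    ends <- c(bounds, n)
    sum(vapply(seq_along(starts), function(i) {
      seg <- x[starts[i]:ends[i]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
  }
  cuts <- utils::combn(n - 1, k - 1)
  all_wss <- apply(cuts, 2, wss_of)
  best_wss <- min(all_wss)
  best <- cuts[, which.min(all_wss)]
  starts <- c(1, best + 1)
  ends <- c(best, n)
  list(
    wss = best_wss,
    centroids = vapply(seq_len(k), function(i) mean(x[starts[i]:ends[i]]), numeric(1)),
    cluster_max = vapply(seq_len(k), function(i) x[ends[i]], numeric(1)),
    n_optima = sum(all_wss <= best_wss + 1e-12)
  )
}

# Shoelace area of the radar polygon with radii r at equal angles.
oracle_radar_fraction <- function(r) {
  r[is.na(r)] <- 0
  n <- length(r)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  poly_area <- function(rad) {
    x <- rad * cos(theta)
    y <- rad * sin(theta)
    xs <- c(x, x[1])
    ys <- c(y, y[1])
    abs(sum(xs[-(n + 1)] * ys[-1] - xs[-1] * ys[-(n + 1)])) / 2
  }
  poly_area(r) / poly_area(rep(1, n))
}

radar_fraction_for_test <- function(r) relsev:::radar_area_fraction(r)

as_study_config_for_test <- function(x) relsev:::as_study_config(x)

# Random small raw cohort for oracle-equivalence checks.
random_cohort <- function(n_animals, variables, n_times, missing_rate = 0,
                          prefix = "a") {
  specs <- variable_spec(
    variables,
    sample(c("decrease", "increase"), length(variables), replace = TRUE)
  )
  rows <- expand.grid(
    animal_id = paste0(prefix, seq_len(n_animals)),
    variable = variables,
    time = c(-2, -1, seq(0, n_times - 1)),
    stringsAsFactors = FALSE
  )
  rows$value <- runif(nrow(rows), 50, 150)
  # keep baselines positive and intact
  drop <- runif(nrow(rows)) < missing_rate & rows$time >= 0
  rows$value[drop] <- NA_real_
  list(data = rows, specs = specs)
}

default_ref <- function(seed = 99, n_animals = 6) {
  spec <- sim_spec(n_animals = n_animals, seed = seed)
  cohort <- simulate_cohort(spec)
  norm <- normalize_to_baseline(cohort, spec$variables)
  list(
    spec = spec, cohort = cohort, norm = norm,
    ref = build_reference_set(norm, spec$variables, label = "moderate")
  )
}
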