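test_that("noise-free trajectories follow the closed-form recovery curve", {
  vars <- tibble::tibble(
    variable = c("bwc", "hr"), direction = c("decrease", "increase"),
    already_normalized = FALSE, baseline = c(20, 500),
    deflection = c(10, 20), half_life = c(2, 2), noise_sd = 0, period = 1
  )
  spec <- sim_spec(n_animals = 1, variables = vars, study_length = 4)
  cohort <- simulate_cohort(spec, seed = 1)
  norm <- normalize_to_baseline(cohort, vars)
  get <- function(v, t) norm$value[norm$variable == v & norm$time == t]
  expect_equal(get("bwc", 0), 90)
  expect_equal(get("bwc", 2), 95) # one half-life later
  expect_equal(get("bwc", 4), 97.5)
  expect_equal(get("hr", 0), 120)
  expect_equal(get("hr", 2), 110)
  expect_equal(get("bwc", -1), 100)
})

test_that("zero deflection everywhere gives zero severity", {
  vars <- sim_spec()$variables %>% dplyr::mutate(deflection = 0, noise_sd = 0)
  spec <- sim_spec(n_animals = 3, variables = vars)
  cohort <- simulate_cohort(spec, seed = 4)
  # a degenerate reference cannot be built from it; score against a real one
  base <- default_ref(seed = 4)
  fit <- relsa(cohort, base$ref)
  expect_equal(max(fit$scores$relsa), 0)
})

test_that("the same seed reproduces the cohort exactly", {
  spec <- sim_spec(n_animals = 4, missing_rate = 0.1)
  a <- simulate_cohort(spec, seed = 8)
  b <- simulate_cohort(spec, seed = 8)
  expect_identical(a, b)
  c <- simulate_cohort(spec, seed = 9)
  expect_false(identical(a, c))
})

test_that("missingness hits post-baseline rows only, near the nominal rate", {
  spec <- sim_spec(n_animals = 30, missing_rate = 0.2)
  cohort <- simulate_cohort(spec, seed = 15)
  pre <- cohort %>% dplyr::filter(time < 0)
  post <- cohort %>% dplyr::filter(time >= 0)
  expect_false(anyNA(pre$value))
  expect_lt(abs(mean(is.na(post$value)) - 0.2), 0.03)
})

test_that("the humane endpoint truncates series at the trigger time", {
  vars <- tibble::tibble(
    variable = c("bwc", "act"), direction = "decrease",
    already_normalized = FALSE, baseline = c(20, 40),
    deflection = c(30, 10), half_life = c(5, 2), noise_sd = 0, period = 1
  )
  # bwc percent bottoms out at 70 on day 0, so an 80% cut-off triggers there
  spec <- sim_spec(
    n_animals = 2, variables = vars, study_length = 10,
    endpoint = list(variable = "bwc", threshold = 80)
  )
  cohort <- simulate_cohort(spec, seed = 2)
  expect_equal(max(cohort$time), 0) # nothing observed after the trigger
  expect_true(all(c(-1, 0) %in% cohort$time))
  # a cut-off below the deepest excursion never triggers
  spec2 <- sim_spec(
    n_animals = 2, variables = vars, study_length = 10,
    endpoint = list(variable = "bwc", threshold = 60)
  )
  expect_equal(max(simulate_cohort(spec2, seed = 2)$time), 10)
})

test_that("engineered profiles are recovered exactly by the scorer", {
  base <- default_ref(seed = 19, n_animals = 5)
  prof <- c(`0` = 1, `1` = 0.62, `2` = 0.31, `3` = 0)
  probe <- engineer_known_severity(base$ref, prof)
  got <- tidy(relsa(probe, base$ref)) %>% dplyr::filter(time >= 0)
  expect_equal(got$relsa, unname(prof), tolerance = 1e-9)

  sub <- engineer_known_severity(base$ref, c(`0` = 0.5),
    variables = c("bwc", "hr")
  )
  got2 <- tidy(relsa(sub, base$ref))
  expect_equal(got2$relsa[got2$time == 0], 0.5, tolerance = 1e-9)
  expect_equal(got2$n_contributing[got2$time == 0], 2L)

  expect_error(engineer_known_severity(base$ref, c(`0` = -0.2)), "unreachable")
  expect_error(
    engineer_known_severity(base$ref, c(`0` = 1), variables = "nope"),
    "nope"
  )
})

test_that("pipeline severity maxima equal the generator's analytic values without noise", {
  vars <- sim_spec()$variables %>% dplyr::mutate(noise_sd = 0)
  spec <- sim_spec(n_animals = 6, variables = vars)
  cohort <- simulate_cohort(spec, seed = 23)
  ref <- build_reference_set(
    normalize_to_baseline(cohort, vars), vars
  )
  fit <- relsa(cohort, ref)
  # identical animals all attain every reference maximum at t = 0
  expect_equal(relsa_max(fit)$relsa_max, rep(1, 6), tolerance = 1e-9)
  # and the analytic per-time score follows the common recovery profile
  w_t <- function(t, v) {
    2^(-t / v$half_life) # weight = deflection*2^(-t/hl) / deflection
  }
  t_grid <- 0:14
  analytic <- vapply(t_grid, function(t) {
    sqrt(mean(w_t(t, vars)^2))
  }, numeric(1))
  one <- fit$scores %>%
    dplyr::filter(animal_id == "animal1", time >= 0) %>%
    dplyr::arrange(time)
  expect_equal(one$relsa, analytic, tolerance = 1e-9)
})

test_that("day-0 score spread shrinks with the noise level", {
  spreads <- vapply(c(6, 3, 0.5), function(sigma) {
    vars <- sim_spec()$variables %>% dplyr::mutate(noise_sd = sigma)
    spec <- sim_spec(n_animals = 60, variables = vars, study_length = 4)
    cohort <- simulate_cohort(spec, seed = 31)
    base <- default_ref(seed = 31, n_animals = 8)
    day0 <- relsa(cohort, base$ref)$scores %>% dplyr::filter(time == 0)
    stats::sd(day0$relsa)
  }, numeric(1))
  expect_true(all(diff(spreads) < 0))
})
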