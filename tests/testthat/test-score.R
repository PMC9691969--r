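test_that("severity weights follow the reference-scaled deviation", {
  expect_equal(relsa_weight(75, "decrease", 30), 25 / 30)
  expect_equal(relsa_weight(100, "decrease", 30), 0)
  expect_equal(relsa_weight(100, "increase", 12), 0)
  expect_equal(relsa_weight(55, "decrease", 30), 1.5) # beyond the ceiling
  expect_true(is.na(relsa_weight(NA, "decrease", 30)))
  expect_error(relsa_weight(90, "decrease", 0), "reference")
  expect_error(relsa_weight(90, "decrease", -3), "reference")
})

test_that("the composite score is the RMS over available weights", {
  expect_equal(relsa_score(c(1, 1, 1)), 1)
  expect_equal(relsa_score(c(0, 0)), 0)
  expect_equal(relsa_score(c(0.6, 0.8)), sqrt((0.36 + 0.64) / 2))
  expect_equal(relsa_score(c(1, NA, 0)), sqrt(1 / 2))
  expect_true(is.na(relsa_score(c(NA, NA))))
  expect_true(is.na(relsa_score(numeric(0))))
  # present zeros dilute the score, missing entries do not
  expect_lt(relsa_score(c(1, 0)), relsa_score(c(1, NA)))
})

test_that("removing a weight equal to the RMS of the rest leaves the score unchanged", {
  # algebraic identity behind missing-variable neutrality
  others <- c(0.3, 0.5, 0.9)
  rms <- sqrt(mean(others^2))
  expect_equal(relsa_score(c(others, rms)), relsa_score(others))
  expect_equal(relsa_score(c(others, NA)), relsa_score(others))
})

test_that("scores are non-negative, zero iff no severity-direction deviation", {
  set.seed(31)
  for (i in 1:20) {
    w <- runif(5, 0, 2)
    w[sample(5, sample(0:3, 1))] <- NA
    s <- relsa_score(w)
    if (!is.na(s)) {
      expect_gte(s, 0)
      expect_equal(s == 0, all(w[!is.na(w)] == 0))
    }
  }
})

test_that("increasing one variable's deviation never decreases the score", {
  set.seed(77)
  for (i in 1:50) {
    w <- runif(6, 0, 1.5)
    j <- sample(6, 1)
    w2 <- w
    w2[j] <- w[j] + runif(1, 0, 1)
    expect_gte(relsa_score(w2), relsa_score(w))
  }
})

test_that("the timecourse matches the brute-force oracle on random cohorts", {
  set.seed(123)
  for (i in 1:20) {
    vars <- paste0("v", seq_len(sample(2:6, 1)))
    ref_c <- random_cohort(sample(2:5, 1), vars, sample(3:10, 1), prefix = "r")
    test_c <- random_cohort(sample(1:5, 1), vars, sample(3:10, 1),
      missing_rate = 0.15, prefix = "t"
    )
    test_c$specs <- ref_c$specs

    orc <- oracle_relsa(test_c$data, ref_c$data, ref_c$specs)
    ref <- build_reference_set(
      normalize_to_baseline(ref_c$data, ref_c$specs), ref_c$specs
    )
    expect_equal(
      setNames(ref$specs$max_delta, ref$specs$variable),
      orc$max_delta[ref$specs$variable],
      tolerance = 1e-12
    )
    fit <- relsa(test_c$data, ref)
    got <- fit$scores %>% dplyr::arrange(animal_id, time)
    exp <- orc$scores[order(orc$scores$animal_id, orc$scores$time), ]
    expect_equal(got$relsa, exp$relsa, tolerance = 1e-12)
    mx <- relsa_max(fit)
    expect_equal(
      mx$relsa_max,
      unname(orc$relsa_max[mx$animal_id]),
      tolerance = 1e-12
    )
  }
})

test_that("reference animals scored against their own reference stay at or below 1", {
  base <- default_ref(seed = 11, n_animals = 8)
  fit <- relsa(base$cohort, base$ref)
  expect_true(all(fit$weights$weight <= 1 + 1e-9, na.rm = TRUE))
  # every variable's ceiling is attained by some animal at some time
  top <- fit$weights %>%
    dplyr::group_by(variable) %>%
    dplyr::summarise(peak = max(weight, na.rm = TRUE))
  expect_equal(top$peak, rep(1, nrow(top)), tolerance = 1e-9)
})

test_that("subset-variable animals are scored; disjoint ones are rejected", {
  base <- default_ref(seed = 21, n_animals = 4)
  one_var <- tibble::tibble(
    animal_id = "solo", time = c(-1, 0), variable = "bwc",
    value = c(100, 85)
  )
  md <- base$ref$specs$max_delta[base$ref$specs$variable == "bwc"]
  fit <- relsa(one_var, base$ref)
  expect_equal(relsa_max(fit)$relsa_max, 15 / md, tolerance = 1e-12)

  alien <- tibble::tibble(
    animal_id = "x", time = c(-1, 0), variable = "unseen", value = c(1, 2)
  )
  expect_error(relsa(alien, base$ref), "no variable")
})

test_that("flat-at-baseline animals score zero everywhere", {
  base <- default_ref(seed = 3, n_animals = 3)
  flat <- tidyr::crossing(
    animal_id = "flat", time = c(-1, 0, 1, 2),
    variable = base$ref$specs$variable
  ) %>% dplyr::mutate(value = 100)
  fit <- relsa(flat, base$ref)
  expect_equal(relsa_max(fit)$relsa_max, 0)
  expect_equal(fit$scores$relsa, rep(0, nrow(fit$scores)))
})

test_that("all-missing time points carry NA scores and are ignored by the maximum", {
  base <- default_ref(seed = 13, n_animals = 3)
  d <- tibble::tibble(
    animal_id = "gap", time = c(-1, 0, 1), variable = "bwc",
    value = c(100, 90, NA)
  )
  fit <- relsa(d, base$ref)
  expect_true(is.na(fit$scores$relsa[fit$scores$time == 1]))
  expect_equal(fit$scores$n_contributing[fit$scores$time == 1], 0L)
  expect_false(is.na(relsa_max(fit)$relsa_max))
})

test_that("duplicate (animal, time, variable) rows are rejected", {
  base <- default_ref(seed = 2, n_animals = 3)
  dup <- tibble::tibble(
    animal_id = "d", time = c(-1, 0, 0), variable = "bwc",
    value = c(100, 90, 91)
  )
  expect_error(relsa(dup, base$ref), "duplicated")
})
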