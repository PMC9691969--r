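test_that("the exact DP clustering matches exhaustive search on random instances", {
  set.seed(55)
  for (i in 1:15) {
    n <- sample(6:20, 1)
    x <- round(runif(n, 0, 3), 3)
    k <- sample(2:4, 1)
    if (length(unique(x)) < k) next
    dp <- relsev:::kmeans_1d_dp(x, k)
    orc <- oracle_cluster_1d(x, k)
    expect_equal(dp$wss, orc$wss, tolerance = 1e-9)
    expect_equal(sort(dp$centroids), orc$centroids, tolerance = 1e-9)
  }
})

test_that("well-separated clumps produce the expected thresholds", {
  lv <- cluster_relsa_max(c(0.10, 0.12, 0.50, 0.52, 0.90, 0.92), k = 3)
  expect_equal(lv$thresholds, c(0.12, 0.52, 0.92))
  expect_equal(lv$centroids, c(0.11, 0.51, 0.91))
  expect_equal(lv$assignments, c(1, 1, 2, 2, 3, 3))

  lv2 <- cluster_relsa_max(c(0, 1), k = 2)
  expect_equal(lv2$centroids, c(0, 1))
  expect_equal(lv2$thresholds, c(0, 1))

  mid <- cluster_relsa_max(c(0.10, 0.12, 0.50, 0.52, 0.90, 0.92),
    k = 3, threshold_mode = "midpoint"
  )
  expect_equal(mid$thresholds, c(0.31, 0.71, 0.92))
})

test_that("Lloyd mode with restarts reproduces the DP partition", {
  set.seed(66)
  for (i in 1:8) {
    n <- sample(10:50, 1)
    centers <- sort(runif(sample(2:4, 1), 0, 3))
    k <- length(centers)
    x <- unlist(lapply(centers, function(c) rnorm(ceiling(n / k), c, 0.03)))
    dp <- cluster_relsa_max(x, k = k, method = "dp")
    ll <- cluster_relsa_max(x, k = k, method = "lloyd", seed = 100 + i, restarts = 25)
    expect_equal(ll$assignments, dp$assignments)
    expect_equal(ll$thresholds, dp$thresholds)
    expect_equal(ll$centroids, dp$centroids, tolerance = 1e-9)
  }
})

test_that("the scree elbow finds clear clump counts", {
  set.seed(44)
  four <- unlist(lapply(c(0.1, 0.5, 1.2, 2.4), function(c) rnorm(10, c, 0.02)))
  sel <- scree_select_k(four)
  expect_equal(sel$k, 4)
  expect_equal(nrow(sel$wss), 8)
  expect_true(all(diff(sel$wss$wss) <= 1e-12)) # WSS non-increasing in k

  two <- c(rnorm(20, 0.1, 0.01), rnorm(20, 1, 0.01))
  expect_equal(scree_select_k(two)$k, 2)

  expect_error(scree_select_k(rep(0.5, 30)), "distinct")
  expect_error(
    scree_select_k(c(rep(0.5, 15), rep(0.7, 15)), k_range = 1:3),
    "elbow|distinct"
  )
})

test_that("permuting the input changes neither centroids nor thresholds", {
  set.seed(10)
  x <- c(rnorm(10, 0.2, 0.05), rnorm(10, 0.7, 0.05), rnorm(10, 1.6, 0.05))
  a <- cluster_relsa_max(x, k = 3)
  perm <- sample(length(x))
  b <- cluster_relsa_max(x[perm], k = 3)
  expect_equal(a$centroids, b$centroids)
  expect_equal(a$thresholds, b$thresholds)
  expect_equal(a$assignments[perm], b$assignments)
})

test_that("severity levels satisfy their ordering invariants", {
  set.seed(12)
  x <- runif(40, 0, 3)
  lv <- cluster_relsa_max(x, k = 4)
  expect_true(all(diff(lv$centroids) > 0))
  expect_true(all(diff(lv$thresholds) > 0))
  expect_true(all(lv$thresholds >= lv$centroids))
  # each value at or below its level threshold, above the one beneath
  for (i in seq_along(x)) {
    j <- lv$assignments[i]
    expect_lte(x[i], lv$thresholds[j])
    if (j > 1) expect_gt(x[i], lv$thresholds[j - 1])
  }
})

test_that("grading maps values into ordered levels with an overflow flag", {
  th <- c(0.27, 0.59, 0.79, 3.45)
  g <- grade_severity(c(0, 0.30, 0.27, 0.60, 4.0), th)
  expect_equal(g$level, c(1, 2, 1, 3, 4)) # ties grade into the lower level
  expect_equal(g$beyond_range, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  # monotone in the graded value
  set.seed(8)
  v <- sort(runif(30, 0, 5))
  expect_true(all(diff(grade_severity(v, th)$level) >= 0))

  expect_error(grade_severity(NA, th), "finite")
  expect_error(grade_severity(1, c(0.5, 0.4)), "increasing")
})

test_that("tidy/glance/augment expose the level structure", {
  x <- c(0.10, 0.12, 0.50, 0.52, 0.90, 0.92)
  lv <- cluster_relsa_max(x, k = 3)
  td <- tidy(lv)
  expect_equal(td$level, c("L1", "L2", "L3"))
  expect_equal(td$n, c(2L, 2L, 2L))
  expect_equal(glance(lv)$k, 3)
  au <- augment(lv)
  expect_equal(nrow(au), 6)
  expect_equal(au$value, x)
})
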