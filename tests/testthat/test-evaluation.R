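test_that("residual metrics match hand computation", {
  obs <- c(10, 20)
  draws <- rbind(rep(12, 10), rep(18, 10))  # posterior means (12, 18)
  m <- residual_metrics(obs, draws)
  expect_equal(m$bias, 0)
  expect_equal(m$imprecision, 2 * sqrt(2))  # sd of (-2, 2) with n-1
  expect_equal(m$inaccuracy, 2)
  expect_equal(m$mae, 2)
  expect_equal(m$rmse, 2)
  expect_equal(m$mae, m$inaccuracy)  # identical by definition
  # scaled versions divide by the posterior means
  expect_equal(m$bias_scaled, mean(c(-2 / 12, 2 / 18)))
})

test_that("a perfect fit yields zero errors, unit R2 and full coverage", {
  obs <- c(5, 9, 14)
  draws <- cbind(obs, obs, obs)
  m <- residual_metrics(obs, draws)
  expect_equal(m$bias, 0)
  expect_equal(m$inaccuracy, 0)
  expect_equal(m$rmse, 0)
  expect_equal(m$r2, 1)
  expect_equal(m$coverage_pct, 100)
})

test_that("rmse^2 = bias^2 + ((n-1)/n) imprecision^2 exactly, and rmse >= |bias|", {
  set.seed(9)
  for (r in 1:20) {
    n <- sample(5:60, 1)
    obs <- rpois(n, 50)
    draws <- matrix(rpois(n * 30, 45), n, 30)
    m <- residual_metrics(obs, draws)
    expect_equal(m$rmse^2, m$bias^2 + (n - 1) / n * m$imprecision^2,
                 tolerance = 1e-12)
    expect_gte(m$rmse, abs(m$bias))
  }
})

test_that("R2 is invariant to affine rescaling of the predictions", {
  set.seed(10)
  obs <- rpois(30, 40)
  draws <- matrix(rpois(30 * 20, 40), 30, 20)
  m1 <- residual_metrics(obs, draws)
  m2 <- residual_metrics(obs, 3 * draws + 7)
  expect_equal(m1$r2, m2$r2, tolerance = 1e-12)
})

test_that("zero-posterior-mean units are excluded from scaled metrics with a warning", {
  obs <- c(0, 10, 20)
  draws <- rbind(rep(0, 10), rep(12, 10), rep(18, 10))
  expect_warning(m <- residual_metrics(obs, draws), "zero posterior mean")
  expect_equal(m$bias_scaled, mean(c(-2 / 12, 2 / 18)))
  expect_equal(m$bias, mean(c(0, -2, 2)))  # raw metrics keep all units
})

test_that("coverage counts observations inside their predictive intervals", {
  set.seed(11)
  draws <- matrix(rpois(4 * 200, 50), 4, 200)
  obs_in <- round(rowMeans(draws))
  expect_equal(residual_metrics(obs_in, draws)$coverage_pct, 100)
  obs_out <- c(5000, 5000, 5000, 5000)
  expect_equal(residual_metrics(obs_out, draws)$coverage_pct, 0)
})

test_that("the formatted metrics table shows raw (scaled) rows", {
  obs <- c(10, 20)
  draws <- rbind(rep(12, 10), rep(18, 10))
  tab <- format_metrics_table(residual_metrics(obs, draws))
  expect_equal(tab$metric[1], "Bias")
  expect_match(tab$value[1], "^0.00 \\(")
  expect_equal(nrow(tab), 7)
})

test_that("stratified splits follow the per-class rounding rule", {
  cl <- simulate_microcensus(default_truth("cluster"), n_clusters = 213,
                             seed = 12, class_shares = c(1, 1, 1) / 3)
  sp <- stratified_split(cl, 0.8, seed = 1)
  # per-class test counts: max(1, round(0.2 * n_class)), enumerated
  expected <- sum(vapply(1:3, function(s)
    max(1, round(0.2 * sum(cl$class == s))), numeric(1)))
  expect_equal(length(sp$test), expected)
  expect_true(expected %in% c(42, 43))
  expect_equal(sort(c(sp$train, sp$test)), 1:213)
  # every class represented in both halves
  expect_setequal(unique(cl$class[sp$test]), 1:3)
  # same seed, same split
  expect_identical(sp, stratified_split(cl, 0.8, seed = 1))
  # singleton class forced into training
  cl2 <- cl[c(which(cl$class == 1)[1], which(cl$class != 1)), ]
  expect_warning(sp2 <- stratified_split(cl2, 0.8, seed = 2), "single cluster")
  expect_false(which(cl2$class == 1) %in% sp2$test)
})

test_that("checkerboard residuals on a rook band give global I of -1", {
  m <- morans_i(c(1, -1, -1, 1), cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)),
                breaks = c(0, 1), n_perm = 99, seed = 1)
  expect_equal(m$bands[[1]]$global_i, -1)
  expect_true(m$bands[[1]]$computable)
  expect_equal(nrow(m$bands[[1]]$local), 4)
  expect_true(all(m$bands[[1]]$local$p_adj >= m$bands[[1]]$local$p_value - 1e-12))
})

test_that("clustered residuals are detected as positive autocorrelation", {
  set.seed(13)
  xy <- expand.grid(x = 1:10, y = 1:10)
  r <- as.numeric(xy$x <= 5) + rnorm(100, 0, 0.2)  # east-west split
  m <- morans_i(r, as.matrix(xy), breaks = c(0, 1.5), n_perm = 199, seed = 13)
  expect_gt(m$bands[[1]]$global_i, 0.5)
  expect_lte(m$bands[[1]]$p_value, 0.01)
})

test_that("degenerate and empty-band cases are flagged, not crashes", {
  expect_warning(m <- morans_i(rep(2, 5), cbind(1:5, 1:5), breaks = c(0, 1),
                               n_perm = 99), "zero variance")
  expect_false(m$bands[[1]]$computable)
  # a band with no neighbour pairs
  m2 <- morans_i(c(1, 2, 3, 4.5), cbind(c(0, 10, 20, 30), rep(0, 4)),
                 breaks = c(0, 1), n_perm = 99, seed = 1)
  expect_false(m2$bands[[1]]$computable)
  expect_error(morans_i(1:3, cbind(1:3, 1:3), breaks = c(0, 1)), "4 units")
  expect_error(morans_i(1:5, cbind(1:5, 1:5), breaks = c(1, 1)), "increasing")
})

test_that("global Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(14)
  n <- 40
  xy <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  r <- rnorm(n) + 0.3 * xy[, 1]
  wb <- as.matrix(dist(xy))
  w <- (wb > 0 & wb <= 3) * 1
  rs <- rowSums(w)
  w_std <- w / ifelse(rs > 0, rs, 1)
  ours <- morans_i(r, xy, breaks = c(0, 3), n_perm = 99, seed = 2,
                   local = FALSE)
  theirs <- ape::Moran.I(r, w_std, scaled = FALSE)
  expect_equal(ours$bands[[1]]$global_i, theirs$observed, tolerance = 1e-10)
})
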