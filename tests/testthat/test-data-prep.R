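test_that("zonal summaries follow the mode / weighted-sum / mean rules", {
  # mode: majority class wins
  zones <- data.frame(zone = "z1", cell = 1:3)
  expect_equal(unname(zonal_summary(c(3, 3, 1), zones, "mode")), 3)
  # mode tie resolves to the more urban (lower) class
  expect_equal(unname(zonal_summary(c(1, 3), data.frame(zone = "z", cell = 1:2),
                                    "mode")), 1)
  # weighted sum: single fully-covered pixel is the identity
  expect_equal(unname(zonal_summary(7, data.frame(zone = "z", cell = 1,
                                                  fraction = 1),
                                    "weighted_sum")), 7)
  # weighted sum with fractional intersection: 10*1 + 20*0.5
  z <- data.frame(zone = "z", cell = 1:2, fraction = c(1, 0.5))
  expect_equal(unname(zonal_summary(c(10, 20), z, "weighted_sum")), 20)
  # mean is unweighted
  expect_equal(unname(zonal_summary(c(10, 20), z, "mean")), 15)
})

test_that("zones without intersecting pixels are flagged missing, not zero", {
  zones <- data.frame(zone = c("a", "b"), cell = c(1, NA))
  out <- zonal_summary(c(5), zones, "mean")
  expect_equal(unname(out["a"]), 5)
  expect_true(is.na(out["b"]))
  expect_equal(attr(out, "missing_zones"), "b")
})

test_that("zonal means over a partition reconstruct the grid mean", {
  set.seed(4)
  v <- rnorm(100)
  zone <- sample(letters[1:5], 100, TRUE)
  zs <- zonal_summary(v, data.frame(zone = zone, cell = 1:100), "mean")
  n_z <- table(zone)[names(zs)]
  expect_equal(sum(zs * n_z) / 100, mean(v))
})

test_that("standardization uses the sample sd and round-trips exactly", {
  const <- standardization_constants(data.frame(a = c(1, 2, 3)))
  expect_equal(const["a", "sd"], 1)  # sample (n-1) sd
  z <- standardize(c(1, 2, 3), const["a", ])
  expect_equal(z, c(-1, 0, 1))
  expect_equal(standardize(const["a", "mean"], const["a", ]), 0)
  # grid constants applied to a cluster summary
  expect_equal(standardize(5, list(mean = 3, sd = 2)), 1)
  # round trip
  set.seed(1)
  x <- rnorm(50)
  cc <- standardization_constants(data.frame(v = x))
  expect_lt(max(abs(unstandardize(standardize(x, cc["v", ]), cc["v", ]) - x)),
            1e-12)
  expect_error(standardization_constants(data.frame(flat = rep(2, 5))), "flat")
})

test_that("covariate screening keeps signal, drops duplicates, reports tests", {
  set.seed(8)
  n <- 213
  B <- rpois(n, 80)
  P <- rpois(n, 4 * B)
  sig <- log(B) + rnorm(n, 0, 0.1)       # near-perfect correlate of log B
  noise <- rnorm(n)
  cand <- data.frame(sig = sig, dup = sig + rnorm(n, 0, 1e-3), noise = noise)
  out <- screen_covariates(cand, B, P, alpha = 0.05)
  expect_true("sig" %in% out$selected)
  # the duplicated candidate is collinear with the retained one
  expect_false(all(c("sig", "dup") %in% out$selected))
  expect_true("dup" %in% out$dropped_collinear || !("dup" %in% out$selected))
  expect_true(all(c("cor_logB", "p_logB", "cor_logD", "p_logD") %in%
                    names(out$tests)))
  expect_lt(out$tests$p_logB[out$tests$candidate == "sig"], 1e-10)
  # deterministic given inputs
  expect_identical(out$selected, screen_covariates(cand, B, P, 0.05)$selected)
  expect_error(screen_covariates(cand[1:2, ], B[1:2], P[1:2]), "3 clusters")
})

test_that("null-candidate selection rate matches the significance level", {
  # single-outcome p-value calibration: P(p_logB < alpha) ~ alpha
  set.seed(15)
  n <- 213
  reps <- 400
  hits_B <- 0
  hits_any <- 0
  for (r in seq_len(reps)) {
    B <- rpois(n, 80)
    P <- rpois(n, 4 * B)
    out <- screen_covariates(data.frame(x = rnorm(n)), B, P, alpha = 0.05)
    hits_B <- hits_B + (out$tests$p_logB[1] < 0.05)
    hits_any <- hits_any + (length(out$selected) == 1)
  }
  ci <- qbinom(c(0.0025, 0.9975), reps, 0.05) / reps
  expect_gte(hits_B / reps, ci[1])
  expect_lte(hits_B / reps, ci[2])
  # union over the two outcomes sits near 1 - (1 - alpha)^2 ~ 0.0975;
  # allow 3 binomial SEs around that
  p_union <- 1 - (1 - 0.05)^2
  slack <- 3 * sqrt(p_union * (1 - p_union) / reps)
  expect_lte(hits_any / reps, p_union + slack)
  expect_gte(hits_any / reps, p_union - slack)
})

test_that("building covariate log transform validates the settled mask", {
  expect_equal(log_building_covariate(c(1, exp(2))), c(0, 2))
  expect_error(log_building_covariate(c(3, 0, 2)), "settled cells")
  expect_equal(log_building_covariate(c(0, 1), method = "log1p"),
               log1p(c(0, 1)))
})

test_that("refusal imputation uses the cluster mean and rounds half-up", {
  hh <- data.frame(cluster_id = c(1, 1, 1), residents = c(4, 6, NA),
                   refused = c(FALSE, FALSE, TRUE))
  out <- impute_refusals(hh)
  expect_equal(out$P_obs, 15L)
  expect_equal(out$imputed_value, 5)
  # no refusals: total unchanged
  hh2 <- data.frame(cluster_id = 1, residents = c(3, 4), refused = FALSE)
  expect_equal(impute_refusals(hh2)$P_obs, 7L)
  # two refusals at mean 3.5 each: 7 + 7 = 14
  hh3 <- data.frame(cluster_id = 1, residents = c(3, 4, NA, NA),
                    refused = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(impute_refusals(hh3)$P_obs, 14L)
  # half-up rounding: responders (3, 4), one refusal -> 10.5 -> 11
  hh4 <- data.frame(cluster_id = 1, residents = c(3, 4, NA),
                    refused = c(FALSE, FALSE, TRUE))
  expect_equal(impute_refusals(hh4)$P_obs, 11L)
  expect_error(impute_refusals(data.frame(cluster_id = 1, residents = NA,
                                          refused = TRUE)),
               "imputation impossible")
})
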