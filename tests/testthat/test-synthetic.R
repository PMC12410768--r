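test_that("degenerate simplex puts every cell in the single class", {
  g <- generate_grid(3, class_proportions = c(1, 0, 0), seed = 1)
  expect_true(all(g$class == 1L))
  expect_error(generate_grid(10, c(0.5, 0.2, 0.2)), "simplex")
  expect_error(generate_grid(2, c(1, 0, 0)), "at least 3")
})

test_that("class frequencies follow the requested proportions", {
  g <- generate_grid(10000, c(0.1, 0.2, 0.7), seed = 1)
  freq <- tabulate(g$class, 3) / nrow(g)
  expect_true(all(abs(freq - c(0.1, 0.2, 0.7)) <= 0.02))
})

test_that("grid generation is deterministic given the seed", {
  g1 <- generate_grid(500, seed = 7)
  g2 <- generate_grid(500, seed = 7)
  expect_identical(g1, g2)
  g3 <- generate_grid(500, seed = 8)
  expect_false(identical(g1$x_B, g3$x_B))
})

test_that("standardized grid covariates have mean 0 and sd 1", {
  g <- generate_grid(2000, seed = 3)
  for (v in c("x_B", paste0("xD", 1:4))) {
    expect_lt(abs(mean(g[[v]])), 1e-9)
    expect_lt(abs(sd(g[[v]]) - 1), 1e-9)
  }
})

test_that("near-zero sigma collapses the latent rates onto exp(mu)", {
  g <- generate_grid(200, seed = 2)
  tr <- synthetic_truth(alpha_B = c(1, 1, 1), beta_B = c(0.5, 0.5, 0.5),
                        sigma_B = rep(1e-12, 3), alpha_D = c(1, 1, 1),
                        beta_D = rep(0.1, 4), sigma_D = rep(1e-12, 3))
  sim <- simulate_truth(g, tr, seed = 2)
  mu_B <- 1 + 0.5 * g$x_B
  expect_true(all(abs(sim$grid$lambda_B / exp(mu_B) - 1) < 1e-6))
})

test_that("simulated latent means match the log-normal closed form", {
  # mu = 0, sigma = 1: E[lambda] = exp(1/2); compare within 3 MC SEs
  g <- generate_grid(1e5, seed = 11)
  g$x_B <- 0 * g$x_B  # kill covariate contribution
  tr <- synthetic_truth(alpha_B = c(0, 0, 0), beta_B = c(0, 0, 0),
                        sigma_B = c(1, 1, 1), alpha_D = c(0, 0, 0),
                        beta_D = rep(0, 4), sigma_D = rep(1e-6, 3))
  for (k in 1:4) g[[paste0("xD", k)]] <- 0
  sim <- simulate_truth(g, tr, seed = 12)
  se <- sd(sim$grid$lambda_B) / sqrt(nrow(g))
  expect_lt(abs(mean(sim$grid$lambda_B) - exp(0.5)), 3 * se)
  # empirical variance vs closed form (exp(1)-1)exp(1), within MC error
  v <- (exp(1) - 1) * exp(1)
  expect_lt(abs(var(sim$grid$lambda_B) - v) / v, 0.1)
})

test_that("fixed rates give Poisson counts with the product mean", {
  # lambda_B = 10, lambda_D = 4 -> E[P] = 40
  g <- generate_grid(1e5, seed = 13)
  g$x_B <- 0 * g$x_B
  for (k in 1:4) g[[paste0("xD", k)]] <- 0
  tr <- synthetic_truth(alpha_B = rep(log(10), 3), beta_B = c(0, 0, 0),
                        sigma_B = rep(1e-12, 3), alpha_D = rep(log(4), 3),
                        beta_D = rep(0, 4), sigma_D = rep(1e-12, 3))
  sim <- simulate_truth(g, tr, seed = 14)
  se <- sd(sim$grid$P) / sqrt(nrow(g))
  expect_lt(abs(mean(sim$grid$P) - 40), 3 * se)
})

test_that("invalid sigma is rejected", {
  expect_error(synthetic_truth(c(0, 0, 0), c(0, 0, 0), c(1, 0, 1),
                               c(0, 0, 0), rep(0, 4), c(1, 1, 1)),
               "positive")
})

test_that("a single-cell grid yields a singleton cluster equal to the cell", {
  g <- generate_grid(3, c(1, 0, 0), seed = 5)
  sim <- simulate_truth(g, default_truth("cell"), seed = 5)
  one <- sim$grid[1, , drop = FALSE]
  attr(one, "constants") <- attr(sim$grid, "constants")
  attr(one, "transform") <- list(x_origin = 0, y_origin = 0, cell_size = 1,
                                 nrow = 1, ncol = 1)
  one$row <- 1L; one$col <- 1L
  cl <- sample_clusters(one, 1, seed = 6)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$B_obs, one$B)
  expect_equal(cl$P_obs, one$P)
  expect_equal(cl$n_cells, 1L)
})

test_that("cluster counts conserve member-cell counts and sizes stay in bounds", {
  g <- generate_grid(3000, c(0.2, 0.3, 0.5), seed = 9)
  sim <- simulate_truth(g, default_truth("cell"), seed = 9)
  cl <- sample_clusters(sim$grid, 40, target_buildings = 80, max_cells = 600,
                        seed = 10)
  expect_equal(nrow(cl), 40)
  # exact conservation per cluster
  for (i in seq_len(nrow(cl))) {
    cells <- match(cl$cells[[i]], sim$grid$cell_id)
    expect_identical(cl$B_obs[i], sum(sim$grid$B[cells]))
    expect_identical(cl$P_obs[i], sum(sim$grid$P[cells]))
  }
  expect_true(all(cl$n_cells >= 1 & cl$n_cells <= 600))
  # disjoint membership
  all_cells <- unlist(cl$cells)
  expect_equal(anyDuplicated(all_cells), 0)
  # clusters are single-class and stratification covers all classes
  expect_setequal(unique(cl$class), 1:3)
  # summing clusters that partition a set of cells reproduces cell totals
  expect_equal(sum(cl$B_obs), sum(sim$grid$B[match(all_cells, sim$grid$cell_id)]))
})

test_that("cluster-level generator reproduces the assumed count structure", {
  tr <- default_truth("cluster")
  cl <- simulate_microcensus(tr, n_clusters = 213, seed = 21)
  expect_equal(nrow(cl), 213)
  expect_setequal(unique(cl$class), 1:3)
  # ~80 buildings per cluster by design of the defaults
  expect_gt(median(cl$B_obs), 40)
  expect_lt(median(cl$B_obs), 160)
  # urban clusters are denser than rural on average (people per building)
  dens <- cl$P_obs / pmax(cl$B_obs, 1)
  expect_gt(mean(dens[cl$class == 1]), mean(dens[cl$class == 3]))
  expect_identical(cl, simulate_microcensus(tr, n_clusters = 213, seed = 21))
})
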