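# Shared fixtures, built in code at test time.

# one-row cluster table with all-zero covariates
one_cluster <- function(class = 1L, B = 0L, P = 0L) {
  tibble::tibble(cluster_id = 1L, class = class, B_obs = B, P_obs = P,
                 x_B = 0, xD1 = 0, xD2 = 0, xD3 = 0, xD4 = 0,
                 n_cells = 1L, cx = 0, cy = 0)
}

# treat grid-cell rows as single-cell survey units
cells_as_clusters <- function(grid, rows = seq_len(nrow(grid))) {
  g <- grid[rows, , drop = FALSE]
  cl <- tibble::tibble(cluster_id = seq_along(rows), class = g$class,
                       B_obs = g$B, P_obs = g$P, x_B = g$x_B)
  for (k in 1:4) cl[[paste0("xD", k)]] <- g[[paste0("xD", k)]]
  cl$n_cells <- 1L
  cl$cx <- g$x
  cl$cy <- g$y
  cl
}

# independent textbook-density oracle for the joint model log density
oracle_log_density <- function(params, clusters, include_prior = TRUE) {
  lpois <- function(k, lam) -lam + k * log(lam) - lgamma(k + 1)
  llnorm <- function(x, mu, sig)
    -log(x * sig * sqrt(2 * pi)) - (log(x) - mu)^2 / (2 * sig^2)
  total <- 0
  for (i in seq_len(nrow(clusters))) {
    s <- clusters$class[i]
    muB <- params$alpha_B[s] + params$beta_B[s] * clusters$x_B[i]
    muD <- params$alpha_D[s] +
      sum(unlist(clusters[i, paste0("xD", 1:4)]) * params$beta_D)
    total <- total + lpois(clusters$B_obs[i], params$lambda_B[i]) +
      lpois(clusters$P_obs[i], params$lambda_B[i] * params$lambda_D[i]) +
      llnorm(params$lambda_B[i], muB, params$sigma_B[s]) +
      llnorm(params$lambda_D[i], muD, params$sigma_D[s])
  }
  if (include_prior) {
    ldnorm <- function(x, sd) -log(sd * sqrt(2 * pi)) - x^2 / (2 * sd^2)
    total <- total +
      sum(ldnorm(c(params$alpha_B, params$alpha_D), 10)) +
      sum(ldnorm(c(params$sigma_B, params$sigma_D), 10) + log(2))
  }
  total
}

# small shared fit, computed once per test run
shared_fit_env <- new.env(parent = emptyenv())
get_shared_fit <- function() {
  if (is.null(shared_fit_env$fit)) {
    cl <- simulate_microcensus(default_truth("cluster"), n_clusters = 120,
                               seed = 42)
    shared_fit_env$clusters <- cl
    shared_fit_env$fit <- fit_microcensus(cl, chains = 2, iterations = 800,
                                          warmup = 200, adapt = 300,
                                          seed = 42, quiet = TRUE)
  }
  shared_fit_env
}

# hand-constructed prediction object (bypasses MCMC) for summary tests
fake_prediction <- function(P, grid) {
  qs <- t(apply(P, 1, posterior_quantile))
  structure(list(P = P, lambda_B = NULL, lambda_D = NULL,
                 summary = tibble::tibble(cell_id = grid$cell_id,
                                          mean = rowMeans(P),
                                          ci_low = qs[, 1], ci_high = qs[, 2]),
                 cell_id = grid$cell_id, n_draws = ncol(P),
                 draw_index = seq_len(ncol(P)), chain = rep(1L, ncol(P)),
                 seed = 0L, fit_seed = 0L, grid = grid),
            class = "bupop_prediction")
}

# fit object with externally fixed parameter draws (all sigmas tiny unless given)
fake_fit <- function(draws, clusters, chains = 1L) {
  structure(list(draws = draws, chain = rep(seq_len(chains),
                                            each = nrow(draws) / chains),
                 clusters = clusters,
                 config = list(chains = chains, iterations = nrow(draws) / chains,
                               warmup = 0, adapt = 0, seed = 0,
                               intercept_sd = 10, sigma_sd = 10,
                               slope_sd = 1000),
                 sampler = list(backend = "fixed", divergences = NA_integer_,
                                treedepth_saturations = NA_integer_,
                                energy = NULL)),
            class = "bupop_fit")
}

# parameter-draw matrix where every draw is the same point
constant_draws <- function(n, alpha_B, beta_B = c(0, 0, 0), sigma_B = rep(1e-8, 3),
                           alpha_D = c(0, 0, 0), beta_D = rep(0, 4),
                           sigma_D = rep(1e-8, 3)) {
  v <- c(alpha_B, beta_B, sigma_B, alpha_D, beta_D, sigma_D)
  m <- matrix(rep(v, each = n), nrow = n)
  colnames(m) <- c(sprintf("alpha_B[%d]", 1:3), sprintf("beta_B[%d]", 1:3),
                   sprintf("sigma_B[%d]", 1:3), sprintf("alpha_D[%d]", 1:3),
                   sprintf("beta_D[%d]", 1:4), sprintf("sigma_D[%d]", 1:3))
  m
}
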