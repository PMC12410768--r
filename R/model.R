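#' Construct a full parameter point for the joint model
#'
#' Bundles the population-level parameters with the per-cluster latent
#' rates, for use with [log_density()].
#'
#' @inheritParams synthetic_truth
#' @param lambda_B,lambda_D per-cluster latent building-count and density
#'   rates (strictly positive).
#' @return object of class `bupop_params`.
#' @export
model_parameters <- function(alpha_B, beta_B, sigma_B, alpha_D, beta_D,
                             sigma_D, lambda_B, lambda_D) {
  p <- synthetic_truth(alpha_B, beta_B, sigma_B, alpha_D, beta_D, sigma_D)
  p$lambda_B <- as.numeric(lambda_B)
  p$lambda_D <- as.numeric(lambda_D)
  class(p) <- c("bupop_params", class(p))
  p
}

#' Joint log posterior density of the micro-census model
#'
#' Evaluates, by direct summation of the textbook densities, the log of the
#' (unnormalized) posterior: for each cluster i with settlement class s,
#' `Poisson(B_i | lambda_B_i) + Poisson(P_i | lambda_B_i * lambda_D_i) +
#' logNormal(lambda_B_i | mu_B_i, sigma_B_s) + logNormal(lambda_D_i |
#' mu_D_i, sigma_D_s)` with `mu_B_i = alpha_B_s + beta_B_s * x_B_i` and
#' `mu_D_i = alpha_D_s + xD_i . beta_D`, plus the priors: Normal(0, sd 10)
#' on the intercepts, half-Normal(sd 10) on the sigmas and flat (zero
#' contribution) on the slopes.
#'
#' Any non-positive latent rate returns `-Inf` by contract.
#'
#' @param params a `bupop_params` from [model_parameters()] (or any
#'   `bupop_truth` with `lambda_B`/`lambda_D` filled).
#' @param clusters micro-census cluster table (needs `class`, `B_obs`,
#'   `P_obs`, `x_B`, `xD1..4`).
#' @param include_prior include the log-prior terms (default TRUE).
#' @param intercept_sd,sigma_sd prior standard deviations.
#' @return a single real, the log density.
#' @export
log_density <- function(params, clusters, include_prior = TRUE,
                        intercept_sd = 10, sigma_sd = 10) {
  stopifnot(inherits(params, "bupop_truth"))
  n <- nrow(clusters)
  lam_B <- params$lambda_B
  lam_D <- params$lambda_D
  stop_if(length(lam_B) != n || length(lam_D) != n,
          "latent rates must match the number of clusters")
  if (any(lam_B <= 0) || any(lam_D <= 0)) return(-Inf)
  xD <- as.matrix(clusters[, paste0("xD", 1:4)])
  stop_if(any(!is.finite(clusters$x_B)) || any(!is.finite(xD)),
          "non-finite covariates")
  s <- clusters$class
  mu_B <- params$alpha_B[s] + params$beta_B[s] * clusters$x_B
  mu_D <- params$alpha_D[s] + as.numeric(xD %*% params$beta_D)
  ll <- sum(stats::dpois(clusters$B_obs, lam_B, log = TRUE)) +
    sum(stats::dpois(clusters$P_obs, lam_B * lam_D, log = TRUE)) +
    sum(stats::dlnorm(lam_B, mu_B, params$sigma_B[s], log = TRUE)) +
    sum(stats::dlnorm(lam_D, mu_D, params$sigma_D[s], log = TRUE))
  if (include_prior) {
    lp <- sum(stats::dnorm(c(params$alpha_B, params$alpha_D), 0, intercept_sd,
                           log = TRUE)) +
      sum(stats::dnorm(c(params$sigma_B, params$sigma_D), 0, sigma_sd,
                       log = TRUE) + log(2))  # half-normal on sigma > 0
    ll <- ll + lp  # flat prior on slopes contributes zero
  }
  ll
}

jags_model_string <- function(intercept_sd, sigma_sd, slope_sd) {
  # JAGS parameterizes normals by precision; dlnorm by log-scale precision.
  # Latent rates kept centred: each lambda is strongly identified by its
  # own count, which makes the centred form the well-mixing one for Gibbs.
  sprintf("
model {
  for (i in 1:N) {
    B[i] ~ dpois(lamB[i])
    P[i] ~ dpois(lamB[i] * lamD[i])
    lamB[i] ~ dlnorm(muB[i], tauB[s[i]])
    muB[i] <- aB[s[i]] + bB[s[i]] * xB[i]
    lamD[i] ~ dlnorm(muD[i], tauD[s[i]])
    muD[i] <- aD[s[i]] + inprod(xD[i, ], bD)
  }
  for (k in 1:3) {
    aB[k] ~ dnorm(0, %.8g)
    bB[k] ~ dnorm(0, %.8g)
    sigB[k] ~ dnorm(0, %.8g) T(0,)
    tauB[k] <- pow(sigB[k], -2)
    aD[k] ~ dnorm(0, %.8g)
    sigD[k] ~ dnorm(0, %.8g) T(0,)
    tauD[k] <- pow(sigD[k], -2)
  }
  for (k in 1:4) { bD[k] ~ dnorm(0, %.8g) }
}", intercept_sd^-2, slope_sd^-2, sigma_sd^-2,
     intercept_sd^-2, sigma_sd^-2, slope_sd^-2)
}

canonical_par_names <- function(n_clusters, latent = TRUE) {
  nm <- c(sprintf("alpha_B[%d]", 1:3), sprintf("beta_B[%d]", 1:3),
          sprintf("sigma_B[%d]", 1:3), sprintf("alpha_D[%d]", 1:3),
          sprintf("beta_D[%d]", 1:4), sprintf("sigma_D[%d]", 1:3))
  if (latent)
    nm <- c(nm, sprintf("lambda_B[%d]", seq_len(n_clusters)),
            sprintf("lambda_D[%d]", seq_len(n_clusters)))
  nm
}

#' Fit the joint micro-census model by MCMC
#'
#' Samples the posterior of the hierarchical Poisson-lognormal model with
#' JAGS (Gibbs sampling), using the priors Normal(0, sd 10) on intercepts,
#' half-Normal(sd 10) on the log-scale sds, and a wide Normal(0, sd 1000)
#' on the slopes standing in for the improper flat prior. Defaults follow
#' the study configuration: 3 chains, 5000 iterations per chain of which
#' 500 warm-up are discarded, giving 13,500 retained draws.
#'
#' The run is deterministic given `seed` (per-chain RNG streams are derived
#' from it).
#'
#' @param clusters micro-census cluster table.
#' @param chains number of MCMC chains.
#' @param iterations post-adaptation iterations per chain (warm-up
#'   included).
#' @param warmup warm-up iterations discarded per chain.
#' @param adapt JAGS adaptation iterations (sampler tuning, additional to
#'   `iterations`). Short chains need generous adaptation: tuning quality,
#'   not retained-draw count, dominated effective sample sizes in our
#'   profiling, so err on the high side when `iterations` is small.
#' @param seed integer seed.
#' @param intercept_sd,sigma_sd,slope_sd prior scales.
#' @param monitor_latent also retain the per-cluster latent rates (needed
#'   for in-sample posterior predictions; default TRUE).
#' @param quiet suppress JAGS progress output.
#' @return object of class `bupop_fit`: list with `draws` (matrix, retained
#'   draws x named parameters in canonical order), `chain` (chain label per
#'   draw row), `clusters`, `config`, and `sampler` (backend bookkeeping;
#'   divergence/treedepth/energy fields are NA for the Gibbs backend, which
#'   has no such concepts).
#' @export
fit_microcensus <- function(clusters, chains = 3, iterations = 5000,
                            warmup = 500, adapt = 1000, seed = 1L,
                            intercept_sd = 10, sigma_sd = 10, slope_sd = 1000,
                            monitor_latent = TRUE, quiet = TRUE) {
  stop_if(nrow(clusters) < 3, "need at least 3 clusters")
  stop_if(warmup >= iterations, "warmup must be smaller than iterations")
  present <- sort(unique(clusters$class))
  under <- present[tabulate(clusters$class, 3)[present] < 2]
  if (length(under) > 0)
    warning("settlement class(es) ", paste(under, collapse = ", "),
            " have fewer than 2 clusters; their parameters are weakly identified")
  dat <- list(N = nrow(clusters), B = clusters$B_obs, P = clusters$P_obs,
              s = clusters$class, xB = clusters$x_B,
              xD = as.matrix(clusters[, paste0("xD", 1:4)]))
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((as.numeric(seed) * 104729 + ch) %% 2147483629),
         lamB = pmax(clusters$B_obs, 0.5),
         lamD = pmax(clusters$P_obs, 0.5) / pmax(clusters$B_obs, 0.5)))
  model_txt <- jags_model_string(intercept_sd, sigma_sd, slope_sd)
  jm <- rjags::jags.model(textConnection(model_txt), data = dat, inits = inits,
                          n.chains = chains, n.adapt = adapt, quiet = quiet)
  if (warmup > 0) update(jm, warmup, progress.bar = "none")
  monitors <- c("aB", "bB", "sigB", "aD", "bD", "sigD")
  if (monitor_latent) monitors <- c(monitors, "lamB", "lamD")
  samp <- rjags::coda.samples(jm, monitors, n.iter = iterations - warmup,
                              progress.bar = "none")
  rename <- function(x) {
    x <- sub("^aB", "alpha_B", x); x <- sub("^bB", "beta_B", x)
    x <- sub("^sigB", "sigma_B", x); x <- sub("^aD", "alpha_D", x)
    x <- sub("^bD", "beta_D", x); x <- sub("^sigD", "sigma_D", x)
    x <- sub("^lamB", "lambda_B", x); sub("^lamD", "lambda_D", x)
  }
  mats <- lapply(samp, function(m) {
    m <- as.matrix(m)
    colnames(m) <- rename(colnames(m))
    m[, canonical_par_names(nrow(clusters), latent = monitor_latent),
      drop = FALSE]
  })
  draws <- do.call(rbind, mats)
  chain <- rep(seq_len(chains), each = nrow(mats[[1]]))
  structure(list(draws = draws, chain = chain, clusters = clusters,
                 config = list(chains = chains, iterations = iterations,
                               warmup = warmup, adapt = adapt, seed = seed,
                               intercept_sd = intercept_sd,
                               sigma_sd = sigma_sd, slope_sd = slope_sd),
                 sampler = list(backend = "jags",
                                divergences = NA_integer_,
                                treedepth_saturations = NA_integer_,
                                energy = NULL)),
            class = "bupop_fit")
}

#' @export
print.bupop_fit <- function(x, ...) {
  cat("Joint micro-census model fit (", x$config$chains, " chains x ",
      x$config$iterations - x$config$warmup, " retained iterations = ",
      nrow(x$draws), " draws; ", nrow(x$clusters), " clusters)\n", sep = "")
  invisible(x)
}

#' Population-level parameter columns of a fit
#'
#' @param fit a `bupop_fit`.
#' @param latent include per-cluster latent rate columns.
#' @return draws matrix.
#' @export
draws_matrix <- function(fit, latent = FALSE) {
  keep <- if (latent) colnames(fit$draws) else
    grep("^lambda", colnames(fit$draws), invert = TRUE, value = TRUE)
  fit$draws[, keep, drop = FALSE]
}
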