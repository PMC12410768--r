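# Rank-normalized split-chain diagnostics (bulk ESS, Rhat) implemented from
# the standard definitions: pool-rank the draws, map ranks through the
# normal quantile function with the (r - 3/8)/(S + 1/4) offset, split each
# chain in half, then combine within- and between-chain variances with
# Geyer's initial monotone positive sequence for the autocorrelation sum.

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

split_chain_matrix <- function(x) {
  # x: iterations x chains -> floor(n/2) x (2*chains)
  n <- nrow(x)
  h <- n %/% 2
  do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(h), j], x[(n - h + 1):n, j])))
}

ess_base <- function(x) {
  # x: iterations x chains, already transformed as desired
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) return(NA_real_)
  chain_var <- apply(x, 2, stats::var)
  if (any(!is.finite(chain_var)) || all(chain_var == 0)) return(NA_real_)
  w <- mean(chain_var)
  var_plus <- w * (n - 1) / n
  if (m > 1) var_plus <- var_plus + stats::var(colMeans(x))
  if (var_plus == 0) return(NA_real_)
  # per-chain autocovariance via acf
  acov <- vapply(seq_len(m), function(j)
    as.numeric(stats::acf(x[, j], lag.max = n - 1, type = "covariance",
                          plot = FALSE, demean = TRUE)$acf),
    numeric(n))
  rho <- 1 - (w - rowMeans(acov)) / var_plus  # rho[1] is lag 0
  # Geyer initial monotone positive sequence over paired sums
  # P_k = rho(2k) + rho(2k+1); stop at the first non-positive pair
  pair_sums <- numeric(0)
  k <- 1
  while (k + 1 <= length(rho)) {
    ps <- rho[k] + rho[k + 1]
    if (ps <= 0) break
    pair_sums <- c(pair_sums, ps)
    k <- k + 2
  }
  if (length(pair_sums) > 1) pair_sums <- cummin(pair_sums)
  tau <- max(-1 + 2 * sum(pair_sums), 1 / log10(n * m + 10))
  min(n * m / tau, n * m * log10(n * m))
}

#' Rank-normalized bulk effective sample size
#'
#' @param x draws: a matrix (iterations x chains) or a vector (one chain;
#'   computed with a warning since between-chain information is missing).
#' @return scalar ESS; `NA` for constant draws.
#' @export
ess_bulk <- function(x) {
  if (is.null(dim(x))) {
    warning("single chain: ESS computed without between-chain information")
    x <- matrix(x, ncol = 1)
  }
  if (length(unique(as.numeric(x))) == 1) return(NA_real_)
  z <- matrix(rank_normalize(as.numeric(x)), nrow = nrow(x))
  ess_base(split_chain_matrix(z))
}

#' Rank-normalized split-chain Rhat
#'
#' @inheritParams ess_bulk
#' @return scalar potential scale reduction factor; `NA` for constant draws.
#' @export
rhat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (length(unique(as.numeric(x))) == 1) return(NA_real_)
  z <- split_chain_matrix(matrix(rank_normalize(as.numeric(x)), nrow = nrow(x)))
  n <- nrow(z)
  w <- mean(apply(z, 2, stats::var))
  b_over_n <- stats::var(colMeans(z))
  sqrt((w * (n - 1) / n + b_over_n) / w)
}

#' Estimated Bayesian fraction of missing information per chain
#'
#' Defined from a sampler energy trace as the mean squared energy increment
#' divided by the energy variance; values below 0.2 indicate poor energy
#' exploration. Only meaningful for Hamiltonian-type backends that expose
#' an energy; the Gibbs backend used by [fit_microcensus()] does not.
#'
#' @param energy numeric matrix (iterations x chains) of sampler energies.
#' @return numeric vector, one EBFMI per chain.
#' @export
ebfmi <- function(energy) {
  if (is.null(dim(energy))) energy <- matrix(energy, ncol = 1)
  apply(energy, 2, function(e) mean(diff(e)^2) / stats::var(e))
}

#' Convergence and sampler diagnostics for a fit
#'
#' Reports per-parameter rank-normalized bulk ESS and split-Rhat for the
#' population-level parameters, plus backend bookkeeping: divergent
#' transitions, treedepth saturations and per-chain EBFMI where the backend
#' records them (`NA` under the Gibbs backend, which has no such notions).
#' Parameters with ESS below `ess_flag` are flagged, as are chains with
#' EBFMI below 0.2.
#'
#' @param fit a `bupop_fit`.
#' @param ess_flag flag threshold for bulk ESS (default 400).
#' @return list with `parameters` (tibble: parameter, ess_bulk, rhat,
#'   flagged), `min_ess_bulk`, `divergences`, `treedepth_saturations`,
#'   `ebfmi`, `flagged_ebfmi`, and `trace` (draws + chain labels for trace
#'   plotting).
#' @export
fit_diagnostics <- function(fit, ess_flag = 400) {
  stopifnot(inherits(fit, "bupop_fit"))
  dm <- draws_matrix(fit, latent = FALSE)
  chains <- fit$config$chains
  n_iter <- nrow(dm) / chains
  if (chains < 2)
    warning("fewer than 2 chains: rank-normalized diagnostics are weaker")
  per_par <- lapply(colnames(dm), function(p) {
    m <- matrix(dm[, p], nrow = n_iter, ncol = chains)
    tibble::tibble(parameter = p, ess_bulk = ess_bulk(m), rhat = rhat(m))
  })
  pars <- do.call(rbind, per_par)
  pars$flagged <- is.na(pars$ess_bulk) | pars$ess_bulk < ess_flag
  energy <- fit$sampler$energy
  eb <- if (is.null(energy)) rep(NA_real_, chains) else ebfmi(energy)
  list(parameters = pars,
       min_ess_bulk = suppressWarnings(min(pars$ess_bulk, na.rm = TRUE)),
       divergences = fit$sampler$divergences,
       treedepth_saturations = fit$sampler$treedepth_saturations,
       ebfmi = eb,
       flagged_ebfmi = which(!is.na(eb) & eb < 0.2),
       trace = list(draws = dm, chain = fit$chain))
}
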