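#' Residual metrics for posterior predictions of counts
#'
#' Residuals are observed minus posterior-mean predicted counts. Reported
#' metrics: bias (mean residual), imprecision (sd of residuals, n-1
#' denominator), inaccuracy (mean absolute residual, identical to MAE), R2
#' (squared Pearson correlation between observed values and posterior
#' means), RMSE, MAE, and the percentage of observations falling inside
#' their 95\% posterior predictive interval (2.5-97.5 percentiles of the
#' count draws, interval bounds inclusive). Scaled versions of bias /
#' imprecision / inaccuracy divide each residual by the unit's posterior
#' mean; units with zero posterior mean are excluded from the scaled
#' metrics with a warning.
#'
#' @param observed observed counts per unit.
#' @param pred_draws posterior predictive count draws, units x draws.
#' @return object of class `bupop_metrics` (a one-row tibble).
#' @export
residual_metrics <- function(observed, pred_draws) {
  n <- length(observed)
  stop_if(n < 2, "need at least 2 units")
  stop_if(nrow(pred_draws) != n, "one draw row per observation required")
  stop_if(ncol(pred_draws) < 2, "need at least 2 draws per unit")
  post_mean <- rowMeans(pred_draws)
  r <- observed - post_mean
  qs <- t(apply(pred_draws, 1, posterior_quantile))
  inside <- observed >= qs[, 1] & observed <= qs[, 2]
  ok <- post_mean != 0
  if (!all(ok))
    warning(sum(!ok), " unit(s) with zero posterior mean excluded from scaled metrics")
  rs <- r[ok] / post_mean[ok]
  r2 <- if (stats::sd(post_mean) == 0 || stats::sd(observed) == 0) {
    if (all(r == 0)) 1 else NA_real_
  } else stats::cor(observed, post_mean)^2
  if (all(r == 0)) r2 <- 1
  out <- tibble::tibble(
    bias = mean(r), imprecision = stats::sd(r), inaccuracy = mean(abs(r)),
    bias_scaled = mean(rs), imprecision_scaled = stats::sd(rs),
    inaccuracy_scaled = mean(abs(rs)),
    r2 = r2, rmse = sqrt(mean(r^2)), mae = mean(abs(r)),
    coverage_pct = mean(inside) * 100, n = n)
  class(out) <- c("bupop_metrics", class(out))
  out
}

#' Format residual metrics in the raw (scaled) table layout
#'
#' @param metrics a `bupop_metrics` row.
#' @return data.frame with rows Bias, Imprecision, Inaccuracy, R2, RMSE,
#'   MAE, Observed within 95\% CIs; raw values with scaled values in
#'   parentheses where defined.
#' @export
format_metrics_table <- function(metrics) {
  f <- function(x) formatC(x, digits = 2, format = "f")
  data.frame(
    metric = c("Bias", "Imprecision", "Inaccuracy", "R2", "RMSE", "MAE",
               "Observed within 95% CIs"),
    value = c(sprintf("%s (%s)", f(metrics$bias), f(metrics$bias_scaled)),
              sprintf("%s (%s)", f(metrics$imprecision), f(metrics$imprecision_scaled)),
              sprintf("%s (%s)", f(metrics$inaccuracy), f(metrics$inaccuracy_scaled)),
              f(metrics$r2), f(metrics$rmse), f(metrics$mae),
              sprintf("%s%%", f(metrics$coverage_pct))))
}

#' Stratified train/test split of clusters
#'
#' Per settlement class, the test count is the class size times the test
#' fraction rounded to nearest with a minimum of 1; classes with a single
#' cluster are forced into training with a warning.
#'
#' @param clusters cluster table.
#' @param train_fraction fraction of clusters per class used for training
#'   (study design: 0.8).
#' @param seed integer seed.
#' @return list with integer row indices `train` and `test`.
#' @export
stratified_split <- function(clusters, train_fraction = 0.8, seed = 1L) {
  stop_if(train_fraction <= 0 || train_fraction >= 1,
          "train_fraction must be in (0,1)")
  set.seed(seed)
  test <- integer(0)
  for (s in sort(unique(clusters$class))) {
    rows <- which(clusters$class == s)
    if (length(rows) < 2) {
      warning("settlement class ", s,
              " has a single cluster; forced into training")
      next
    }
    n_test <- max(1L, round((1 - train_fraction) * length(rows)))
    n_test <- min(n_test, length(rows) - 1L)
    test <- c(test, sort(sample(rows, n_test)))
  }
  list(train = setdiff(seq_len(nrow(clusters)), test), test = test)
}

#' Stratified leave-p-out cross-validation of the joint model
#'
#' Repeatedly splits the clusters 80-20 within each settlement class,
#' refits the model on the training clusters, and evaluates residual
#' metrics in-sample (training clusters) and out-of-sample (held-out
#' clusters). Both use the prediction path — latent rates redrawn from the
#' class parameters and covariates — so the two samples are compared like
#' for like and the gap isolates overfitting.
#'
#' @param clusters cluster table.
#' @param train_fraction per-class training fraction.
#' @param repeats number of random splits.
#' @param seed root seed; each repeat derives its own split/fit/predict
#'   seeds.
#' @param chains,iterations,warmup,adapt MCMC settings passed to
#'   [fit_microcensus()] (defaults reduced relative to the full fit).
#' @param ... further arguments to [fit_microcensus()].
#' @return tibble with one row per repeat and outcome (building /
#'   population) and sample (in / out), carrying all residual metrics.
#' @export
cross_validate <- function(clusters, train_fraction = 0.8, repeats = 1,
                           seed = 1L, chains = 3, iterations = 1000,
                           warmup = 200, adapt = 300, ...) {
  out <- list()
  for (r in seq_len(repeats)) {
    sp <- stratified_split(clusters, train_fraction,
                           seed = stage_seed(seed + r, "evaluate"))
    train <- clusters[sp$train, , drop = FALSE]
    test <- clusters[sp$test, , drop = FALSE]
    fit <- fit_microcensus(train, chains = chains, iterations = iterations,
                           warmup = warmup, adapt = adapt,
                           seed = stage_seed(seed + r, "fit"),
                           monitor_latent = FALSE, ...)
    pin <- predict_clusters(fit, train, newdata = TRUE,
                            seed = stage_seed(seed + r, "predict"))
    pout <- predict_clusters(fit, test, newdata = TRUE,
                             seed = stage_seed(seed + r, "predict") + 1L)
    rows <- list(
      cbind(repeat_ = r, sample = "in", outcome = "building",
            residual_metrics(train$B_obs, pin$B_rep)),
      cbind(repeat_ = r, sample = "in", outcome = "population",
            residual_metrics(train$P_obs, pin$P_rep)),
      cbind(repeat_ = r, sample = "out", outcome = "building",
            residual_metrics(test$B_obs, pout$B_rep)),
      cbind(repeat_ = r, sample = "out", outcome = "population",
            residual_metrics(test$P_obs, pout$P_rep)))
    out <- c(out, rows)
  }
  do.call(rbind, out)
}

distance_band_weights <- function(coords, lower, upper) {
  d <- as.matrix(stats::dist(coords))
  w <- (d > lower & d <= upper) * 1
  diag(w) <- 0
  rs <- rowSums(w)
  w[rs > 0, ] <- w[rs > 0, ] / rs[rs > 0]
  list(w = w, n_pairs = sum(w > 0))
}

global_moran_stat <- function(z, w) {
  n <- length(z)
  s0 <- sum(w)
  (n / s0) * sum(z * (w %*% z)) / sum(z^2)
}

#' Global and local Moran's I on residuals, by distance band
#'
#' For each distance class `(breaks[k], breaks[k+1]]` a binary spatial
#' weights matrix is built (1 if the pair distance falls in the band) and
#' row-standardized. The global statistic is `I = (n/S0) * sum_kl w_kl z_k
#' z_l / sum_k z_k^2` with `z` the centred residuals; significance comes
#' from random permutations of the residuals (two-sided, centred on the
#' permutation mean). Local Moran `I_k = z_k / m2 * sum_l w_kl z_l` uses
#' conditional permutations (unit k held fixed); local p-values are
#' reported raw and Benjamini-Hochberg adjusted.
#'
#' @param residuals per-unit residuals.
#' @param coords units x 2 matrix of planar centroid coordinates.
#' @param breaks strictly increasing distance-class breaks; bands are
#'   consecutive pairs. A length-2 vector gives a single band.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param local also compute local Moran statistics (slower; default TRUE).
#' @return object of class `bupop_moran`: list of per-band results, each
#'   with `global_i`, `p_value`, `n_pairs`, `computable`, and a `local`
#'   tibble (`local_i`, `p_value`, `p_adj`). Zero-variance residuals give a
#'   result flagged `degenerate` with every band non-computable.
#' @export
morans_i <- function(residuals, coords, breaks, n_perm = 999, seed = 1L,
                     local = TRUE) {
  n <- length(residuals)
  stop_if(n < 4, "need at least 4 units")
  stop_if(any(diff(breaks) <= 0), "breaks must be strictly increasing")
  if (stats::sd(residuals) == 0) {
    warning("residuals have zero variance: Moran's I undefined")
    bands <- lapply(seq_len(length(breaks) - 1), function(k)
      list(band = c(breaks[k], breaks[k + 1]), computable = FALSE,
           global_i = NA_real_, p_value = NA_real_, n_pairs = NA_integer_,
           local = NULL))
    return(structure(list(bands = bands, breaks = breaks, n_perm = n_perm,
                          degenerate = TRUE), class = "bupop_moran"))
  }
  coords <- as.matrix(coords)
  set.seed(seed)
  z <- residuals - mean(residuals)
  bands <- lapply(seq_len(length(breaks) - 1), function(k) {
    wb <- distance_band_weights(coords, breaks[k], breaks[k + 1])
    w <- wb$w
    if (sum(w) == 0)
      return(list(band = c(breaks[k], breaks[k + 1]), computable = FALSE,
                  global_i = NA_real_, p_value = NA_real_, n_pairs = 0,
                  local = NULL))
    i_obs <- global_moran_stat(z, w)
    # batched permutations: columns are permuted residual vectors
    perm_z <- vapply(seq_len(n_perm), function(p) z[sample.int(n)],
                     numeric(n))
    perm_i <- (n / sum(w)) * colSums(perm_z * (w %*% perm_z)) / sum(z^2)
    centre <- mean(perm_i)
    p_global <- (1 + sum(abs(perm_i - centre) >= abs(i_obs - centre))) /
      (n_perm + 1)
    if (!local)
      return(list(band = c(breaks[k], breaks[k + 1]), computable = TRUE,
                  global_i = i_obs, p_value = p_global, n_pairs = wb$n_pairs,
                  local = NULL))
    # local Moran with conditional permutations
    m2 <- sum(z^2) / n
    lag <- as.numeric(w %*% z)
    local_i <- z / m2 * lag
    p_local <- vapply(seq_len(n), function(k) {
      wk <- w[k, -k]
      nz <- sum(wk > 0)
      if (nz == 0) return(NA_real_)
      others <- z[-k]
      perm <- vapply(seq_len(n_perm), function(p)
        z[k] / m2 * sum(wk * others[sample.int(n - 1)]), numeric(1))
      centre_k <- mean(perm)
      (1 + sum(abs(perm - centre_k) >= abs(local_i[k] - centre_k))) /
        (n_perm + 1)
    }, numeric(1))
    list(band = c(breaks[k], breaks[k + 1]), computable = TRUE,
         global_i = i_obs, p_value = p_global, n_pairs = wb$n_pairs,
         local = tibble::tibble(unit = seq_len(n), local_i = local_i,
                                p_value = p_local,
                                p_adj = stats::p.adjust(p_local, "BH")))
  })
  structure(list(bands = bands, breaks = breaks, n_perm = n_perm),
            class = "bupop_moran")
}

#' @export
print.bupop_moran <- function(x, ...) {
  for (b in x$bands)
    cat(sprintf("band (%g, %g]: %s\n", b$band[1], b$band[2],
                if (!b$computable) "no neighbour pairs" else
                  sprintf("global I = %.4f, p = %.4f (%d weighted pairs)",
                          b$global_i, b$p_value, b$n_pairs)))
  invisible(x)
}
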