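#' Posterior predictive draws of population per settled grid cell
#'
#' Propagates each retained posterior parameter draw through the prediction
#' equations: per cell j with settlement class s, compute `mu_B = alpha_B_s
#' + beta_B_s * x_B_j` and `mu_D = alpha_D_s + xD_j . beta_D` from that
#' draw's parameters, then redraw fresh noise `lambda_B ~ logNormal(mu_B,
#' sigma_B_s)`, `lambda_D ~ logNormal(mu_D, sigma_D_s)` and finally
#' `P ~ Poisson(lambda_B * lambda_D)`. Latent rates are redrawn per cell
#' per draw (posterior predictive), never plugged in at posterior means.
#'
#' Cells are processed in blocks with bounded working memory; per-cell
#' summaries (mean and 95% interval) are accumulated in the same pass.
#'
#' @param fit a `bupop_fit`.
#' @param grid grid-cell table with standardized covariates (the SAME
#'   standardization constants as at fit time) and `class`.
#' @param seed prediction seed (independent of the fit seed).
#' @param thin keep every `thin`-th draw within each chain (default 1: all
#'   retained draws, the study kept all 13,500).
#' @param block_size number of cells per processing block.
#' @param keep_lambda also store the per-draw latent rate matrices
#'   (memory: cells x draws doubles twice; default FALSE).
#' @return object of class `bupop_prediction`: list with `P` (integer
#'   matrix cells x draws), `summary` (tibble: cell_id, mean, ci_low,
#'   ci_high), `cell_id`, `n_draws`, `draw_index`/`chain` provenance, and
#'   optionally `lambda_B`, `lambda_D`.
#' @export
predict_cells <- function(fit, grid, seed = 1L, thin = 1L,
                          block_size = 10000L, keep_lambda = FALSE) {
  stopifnot(inherits(fit, "bupop_fit"))
  xD <- as.matrix(grid[, paste0("xD", 1:4)])
  cls <- grid$class
  stop_if(!all(cls %in% unique(fit$clusters$class)),
          "grid contains settlement classes absent from the fitted data")
  # standardization check over settled cells (tolerant at small n)
  if (nrow(grid) >= 50) {
    ok <- abs(mean(grid$x_B)) < 0.2 && abs(stats::sd(grid$x_B) - 1) < 0.2
    stop_if(!ok, "grid covariates do not look standardized; ",
            "standardize with the fit-time grid constants first")
  }
  n_iter <- nrow(fit$draws) / fit$config$chains
  keep <- as.vector(vapply(seq_len(fit$config$chains), function(ch)
    (ch - 1) * n_iter + seq(thin, n_iter, by = thin), numeric(n_iter %/% thin)))
  dm <- draws_matrix(fit)[keep, , drop = FALSE]
  nd <- nrow(dm)
  n <- nrow(grid)
  aB <- dm[, sprintf("alpha_B[%d]", 1:3)]; bB <- dm[, sprintf("beta_B[%d]", 1:3)]
  sB <- dm[, sprintf("sigma_B[%d]", 1:3)]; aD <- dm[, sprintf("alpha_D[%d]", 1:3)]
  sD <- dm[, sprintf("sigma_D[%d]", 1:3)]; bD <- dm[, sprintf("beta_D[%d]", 1:4)]

  set.seed(seed)
  P <- matrix(NA_integer_, n, nd)
  lamB_keep <- if (keep_lambda) matrix(NA_real_, n, nd)
  lamD_keep <- if (keep_lambda) matrix(NA_real_, n, nd)
  for (start in seq(1, n, by = block_size)) {
    jj <- start:min(start + block_size - 1, n)
    s <- cls[jj]
    xb <- grid$x_B[jj]
    xd <- xD[jj, , drop = FALSE]
    for (d in seq_len(nd)) {
      mu_B <- aB[d, s] + bB[d, s] * xb
      mu_D <- aD[d, s] + as.numeric(xd %*% bD[d, ])
      lam_B <- stats::rlnorm(length(jj), mu_B, sB[d, s])
      lam_D <- stats::rlnorm(length(jj), mu_D, sD[d, s])
      P[jj, d] <- stats::rpois(length(jj), lam_B * lam_D)
      if (keep_lambda) {
        lamB_keep[jj, d] <- lam_B
        lamD_keep[jj, d] <- lam_D
      }
    }
  }
  qs <- t(apply(P, 1, posterior_quantile))
  summary <- tibble::tibble(cell_id = grid$cell_id,
                            mean = rowMeans(P),
                            ci_low = qs[, 1], ci_high = qs[, 2])
  structure(list(P = P, lambda_B = lamB_keep, lambda_D = lamD_keep,
                 summary = summary, cell_id = grid$cell_id, n_draws = nd,
                 draw_index = keep, chain = fit$chain[keep],
                 seed = seed, fit_seed = fit$config$seed, grid = grid),
            class = "bupop_prediction")
}

#' @export
print.bupop_prediction <- function(x, ...) {
  cat("Gridded posterior prediction: ", length(x$cell_id), " cells x ",
      x$n_draws, " draws\n", sep = "")
  invisible(x)
}

#' Summarize cell predictions onto raster layers
#'
#' Returns the per-cell posterior mean and 2.5/97.5 percentile surfaces as
#' matrices on the grid's lattice georeference; unsettled lattice positions
#' are NA (no-data).
#'
#' @param pred a `bupop_prediction`.
#' @return list of matrices `mean`, `ci_low`, `ci_high` plus the affine
#'   `transform` of the grid.
#' @export
summarize_cells <- function(pred) {
  stopifnot(inherits(pred, "bupop_prediction"))
  stop_if(pred$n_draws < 2, "need at least 2 draws to summarize")
  grid <- pred$grid
  tr <- attr(grid, "transform")
  lay <- function(v) {
    m <- matrix(NA_real_, tr$nrow, tr$ncol)
    m[cbind(grid$row, grid$col)] <- v
    m
  }
  list(mean = lay(pred$summary$mean),
       ci_low = lay(pred$summary$ci_low),
       ci_high = lay(pred$summary$ci_high),
       transform = tr)
}

#' Posterior predictive count draws for micro-census clusters
#'
#' Two prediction modes. With `newdata = TRUE` (the mode behind all
#' reported goodness-of-fit metrics, in- or out-of-sample) the latent rates
#' are redrawn from the class parameters and covariates exactly as in
#' [predict_cells()], so a cluster is predicted from what the model learned
#' about its class and covariates, not from its own counts. With
#' `newdata = FALSE`, predictions condition on each fitted cluster's own
#' latent rates (`B_rep ~ Poisson(lambda_B_i)`, `P_rep ~ Poisson(lambda_B_i
#' * lambda_D_i)` draw by draw) — a posterior-predictive check of the count
#' likelihood given the latents, which by construction tracks the
#' observations closely.
#'
#' @param fit a `bupop_fit` (latent rates monitored for in-sample mode).
#' @param clusters cluster table; for in-sample mode must be the fitted
#'   clusters (row order defines the latent index).
#' @param newdata redraw latent rates from covariates instead of using the
#'   fitted latents.
#' @param seed seed for the predictive noise.
#' @return list with matrices `B_rep`, `P_rep` (clusters x draws).
#' @export
predict_clusters <- function(fit, clusters = fit$clusters, newdata = FALSE,
                             seed = 1L) {
  stopifnot(inherits(fit, "bupop_fit"))
  n <- nrow(clusters)
  nd <- nrow(fit$draws)
  set.seed(seed)
  if (!newdata) {
    lamB <- fit$draws[, sprintf("lambda_B[%d]", seq_len(n)), drop = FALSE]
    stop_if(ncol(lamB) != n, "fit does not carry latent rates for in-sample prediction")
    lamD <- fit$draws[, sprintf("lambda_D[%d]", seq_len(n)), drop = FALSE]
    # lamB/lamD are draws x clusters; rpois recycles column-major
    B_rep <- matrix(stats::rpois(n * nd, lamB), nrow = nd)
    P_rep <- matrix(stats::rpois(n * nd, lamB * lamD), nrow = nd)
    return(list(B_rep = t(B_rep), P_rep = t(P_rep)))
  }
  dm <- draws_matrix(fit)
  s <- clusters$class
  xD <- as.matrix(clusters[, paste0("xD", 1:4)])
  aB <- dm[, sprintf("alpha_B[%d]", 1:3)]; bB <- dm[, sprintf("beta_B[%d]", 1:3)]
  sB <- dm[, sprintf("sigma_B[%d]", 1:3)]; aD <- dm[, sprintf("alpha_D[%d]", 1:3)]
  sD <- dm[, sprintf("sigma_D[%d]", 1:3)]; bD <- dm[, sprintf("beta_D[%d]", 1:4)]
  B_rep <- matrix(NA_integer_, n, nd)
  P_rep <- matrix(NA_integer_, n, nd)
  for (d in seq_len(nd)) {
    mu_B <- aB[d, s] + bB[d, s] * clusters$x_B
    mu_D <- aD[d, s] + as.numeric(xD %*% bD[d, ])
    lam_B <- stats::rlnorm(n, mu_B, sB[d, s])
    lam_D <- stats::rlnorm(n, mu_D, sD[d, s])
    B_rep[, d] <- stats::rpois(n, lam_B)
    P_rep[, d] <- stats::rpois(n, lam_B * lam_D)
  }
  list(B_rep = B_rep, P_rep = P_rep)
}
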