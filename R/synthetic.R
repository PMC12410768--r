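#' Ground-truth parameter set for synthetic data
#'
#' Bundles the class-specific intercepts, slopes and log-scale standard
#' deviations of the joint building-count / population-density model into a
#' validated object used by the generative simulators.
#'
#' Vectors indexed by settlement class are ordered urban, peri-urban, rural
#' (see [settlement_classes()]). `beta_D` holds the four global density
#' covariate effects.
#'
#' @param alpha_B,beta_B,sigma_B length-3 numeric: building-count component.
#' @param alpha_D,sigma_D length-3 numeric: density component intercepts and
#'   log-scale sd.
#' @param beta_D length-4 numeric: global density covariate effects.
#' @param seed integer stored for provenance.
#' @return an object of class `bupop_truth`.
#' @export
synthetic_truth <- function(alpha_B, beta_B, sigma_B,
                            alpha_D, beta_D, sigma_D, seed = NA_integer_) {
  stop_if(length(alpha_B) != 3 || length(beta_B) != 3 || length(sigma_B) != 3,
          "building-count parameters must have one entry per settlement class")
  stop_if(length(alpha_D) != 3 || length(sigma_D) != 3,
          "density intercepts/sds must have one entry per settlement class")
  stop_if(length(beta_D) != 4, "beta_D must hold 4 covariate effects")
  vals <- c(alpha_B, beta_B, sigma_B, alpha_D, beta_D, sigma_D)
  stop_if(any(!is.finite(vals)), "truth parameters must be finite")
  stop_if(any(sigma_B <= 0) || any(sigma_D <= 0),
          "all sigma must be strictly positive")
  structure(list(alpha_B = as.numeric(alpha_B), beta_B = as.numeric(beta_B),
                 sigma_B = as.numeric(sigma_B), alpha_D = as.numeric(alpha_D),
                 beta_D = as.numeric(beta_D), sigma_D = as.numeric(sigma_D),
                 lambda_B = NULL, lambda_D = NULL, seed = seed),
            class = "bupop_truth")
}

#' Default ground-truth parameters
#'
#' Shipped defaults mirror the qualitative structure of the study system:
#' urban mean population density (people per building) above peri-urban
#' above rural; a weaker building-count covariate effect and a larger
#' residual variance in rural settlements; density covariates dominated by a
#' negative distance-to-roads effect. Two scales are provided because the
#' same model applies at two unit sizes: `"cluster"` places the
#' building-count intercept near log(80) (micro-census clusters hold roughly
#' 80 buildings), `"cell"` near log of a few buildings per ~1 ha settled
#' cell.
#'
#' @param scale `"cluster"` for micro-census-cluster units, `"cell"` for
#'   grid-cell units.
#' @return a `bupop_truth` object.
#' @export
default_truth <- function(scale = c("cluster", "cell")) {
  scale <- match.arg(scale)
  if (scale == "cluster") {
    synthetic_truth(alpha_B = c(4.45, 4.40, 4.25),
                    beta_B  = c(0.95, 0.85, 0.60),
                    sigma_B = c(0.15, 0.25, 0.45),
                    alpha_D = c(1.70, 1.50, 1.30),
                    beta_D  = c(-0.30, 0.00, -0.10, -0.05),
                    sigma_D = c(0.30, 0.32, 0.34))
  } else {
    synthetic_truth(alpha_B = c(1.80, 1.20, 0.70),
                    beta_B  = c(0.50, 0.45, 0.35),
                    sigma_B = c(0.30, 0.35, 0.45),
                    alpha_D = c(1.70, 1.50, 1.30),
                    beta_D  = c(-0.30, 0.00, -0.10, -0.05),
                    sigma_D = c(0.30, 0.32, 0.34))
  }
}

#' Default per-class covariate specification for the synthetic landscape
#'
#' One building-count covariate (generated on its natural positive scale and
#' later log-transformed) and four density covariates. Rows are settlement
#' classes (urban, peri-urban, rural); the building-count covariate mean
#' decreases from urban to rural.
#'
#' @return list with `mean` and `sd` 3 x 5 matrices (columns: bldg,
#'   dcov1..dcov4) where the bldg column is on the log scale.
#' @export
default_covariate_spec <- function() {
  mean <- rbind(urban        = c(1.6, -0.5, 0.0, 0.3, -0.2),
                `peri-urban` = c(1.0,  0.0, 0.0, 0.0,  0.0),
                rural        = c(0.4,  0.6, 0.0, -0.2, 0.3))
  sd <- matrix(c(rep(0.5, 3), rep(1, 12)), nrow = 3)
  dimnames(mean) <- dimnames(sd) <-
    list(settlement_classes()$label, c("bldg", paste0("dcov", 1:4)))
  list(mean = mean, sd = sd)
}

gaussian_blur <- function(mat, sigma) {
  # separable kernel convolution with edge renormalization
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  smooth1 <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    wt <- matrix(0, nrow(m), ncol(m))
    for (o in -half:half) {
      rows <- seq_len(nrow(m)) + o
      ok <- rows >= 1 & rows <= nrow(m)
      out[ok, ] <- out[ok, ] + k[o + half + 1] * m[rows[ok], ]
      wt[ok, ] <- wt[ok, ] + k[o + half + 1]
    }
    out / wt
  }
  t(smooth1(t(smooth1(mat))))
}

#' Generate a synthetic settled-cell landscape
#'
#' Lays `n_cells` settled grid cells on a regular unit lattice, assigns each
#' a settlement class, and draws one building-count covariate plus four
#' density covariates with class-dependent means. Classes are carved out of
#' a smoothed Gaussian random field by its empirical quantiles, so class
#' patches are spatially contiguous and class frequencies match the
#' requested proportions up to lattice rounding. Covariates are drawn
#' independently per cell (optionally blurred for spatial smoothness) and
#' standardized over settled cells; the raw columns and the standardization
#' constants are kept so cluster-level zonal summaries can reuse the same
#' grid-level constants.
#'
#' @param n_cells number of settled cells (>= 3).
#' @param class_proportions length-3 simplex of urban / peri-urban / rural
#'   shares.
#' @param covariate_spec per-class mean/sd matrices, see
#'   [default_covariate_spec()].
#' @param seed integer seed; identical seeds give identical tables.
#' @param blur_sigma optional Gaussian-blur sd (in cell units) applied to
#'   the covariate fields to induce spatial autocorrelation; `NULL` leaves
#'   covariates independent across cells.
#' @return a tibble with one row per settled cell: `cell_id`, lattice
#'   `row`/`col`, centre coordinates `x`/`y`, `class`, `settled`, raw
#'   covariates (`bldg`, `dcov1..4`) and standardized covariates
#'   (`x_B`, `xD1..4`). The standardization constants are attached as
#'   attribute `constants`; the affine transform (origin and cell size) as
#'   attribute `transform`.
#' @export
generate_grid <- function(n_cells, class_proportions = c(0.15, 0.25, 0.60),
                          covariate_spec = default_covariate_spec(),
                          seed = 1L, blur_sigma = NULL) {
  stop_if(n_cells < 3, "need at least 3 cells")
  stop_if(length(class_proportions) != 3 ||
            abs(sum(class_proportions) - 1) > 1e-9 ||
            any(class_proportions < 0),
          "class_proportions must be a length-3 simplex summing to 1")
  set.seed(seed)
  nc <- ceiling(sqrt(n_cells))
  nr <- ceiling(n_cells / nc)
  idx <- seq_len(n_cells)
  row <- (idx - 1L) %/% nc + 1L
  col <- (idx - 1L) %% nc + 1L

  # contiguous class patches: quantile-slice a smoothed random field
  field <- matrix(stats::rnorm(nr * nc), nr, nc)
  field <- gaussian_blur(field, sigma = max(2, sqrt(n_cells) / 12))
  f <- field[cbind(row, col)]
  cls <- integer(n_cells)
  ord <- order(f)
  cuts <- round(cumsum(class_proportions) * n_cells)
  cuts[3] <- n_cells
  cls[ord[seq_len(cuts[1])]] <- 1L
  if (cuts[2] > cuts[1]) cls[ord[(cuts[1] + 1):cuts[2]]] <- 2L
  if (cuts[3] > cuts[2]) cls[ord[(cuts[2] + 1):cuts[3]]] <- 3L

  draw_cov <- function(jcol) {
    z <- stats::rnorm(n_cells)
    if (!is.null(blur_sigma)) {
      zm <- matrix(0, nr, nc)
      zm[cbind(row, col)] <- z
      z <- gaussian_blur(zm, blur_sigma)[cbind(row, col)]
      z <- (z - mean(z)) / stats::sd(z)
    }
    covariate_spec$mean[cls, jcol] + covariate_spec$sd[cls, jcol] * z
  }
  bldg <- exp(draw_cov(1))           # natural positive scale
  dcov <- vapply(2:5, draw_cov, numeric(n_cells))
  colnames(dcov) <- paste0("dcov", 1:4)

  grid <- tibble::tibble(cell_id = idx, row = row, col = col,
                         x = col - 0.5, y = row - 0.5,
                         class = cls, settled = TRUE,
                         bldg = bldg)
  for (k in 1:4) grid[[paste0("dcov", k)]] <- dcov[, k]

  const <- standardization_constants(
    data.frame(log_bldg = log_building_covariate(bldg), dcov))
  grid$x_B <- standardize(log_building_covariate(grid$bldg),
                          const["log_bldg", ])
  for (k in 1:4)
    grid[[paste0("xD", k)]] <-
      standardize(grid[[paste0("dcov", k)]], const[paste0("dcov", k), ])

  attr(grid, "constants") <- const
  attr(grid, "transform") <- list(x_origin = 0, y_origin = 0, cell_size = 1,
                                  nrow = nr, ncol = nc)
  attr(grid, "seed") <- seed
  grid
}

#' Simulate ground-truth counts on a grid
#'
#' Applies the generative model cell by cell: the expected log building
#' count is `alpha_B[class] + beta_B[class] * x_B`, the expected log density
#' `alpha_D[class] + xD %*% beta_D`; latent rates are drawn log-normally
#' around these with class-specific log-scale sd; building counts are
#' Poisson with rate `lambda_B` and population counts Poisson with rate
#' `lambda_B * lambda_D`.
#'
#' @param grid a grid from [generate_grid()] (standardized covariates).
#' @param truth a `bupop_truth`.
#' @param seed integer seed (defaults to the truth's stored seed, else 1).
#' @return list with `grid` (the input plus `lambda_B`, `lambda_D`, `B`,
#'   `P` columns) and `truth` (with per-cell latent rates filled in).
#' @export
simulate_truth <- function(grid, truth, seed = NULL) {
  stopifnot(inherits(truth, "bupop_truth"))
  stop_if(any(truth$sigma_B <= 0) || any(truth$sigma_D <= 0),
          "all sigma must be strictly positive")
  xD <- as.matrix(grid[, paste0("xD", 1:4)])
  stop_if(any(!is.finite(grid$x_B)) || any(!is.finite(xD)),
          "grid covariates must be finite")
  seed <- seed %||% (if (is.na(truth$seed)) 1L else truth$seed)
  set.seed(seed)
  s <- grid$class
  mu_B <- truth$alpha_B[s] + truth$beta_B[s] * grid$x_B
  mu_D <- truth$alpha_D[s] + as.numeric(xD %*% truth$beta_D)
  lam_B <- stats::rlnorm(nrow(grid), mu_B, truth$sigma_B[s])
  lam_D <- stats::rlnorm(nrow(grid), mu_D, truth$sigma_D[s])
  grid$lambda_B <- lam_B
  grid$lambda_D <- lam_D
  grid$B <- stats::rpois(nrow(grid), lam_B)
  grid$P <- stats::rpois(nrow(grid), lam_B * lam_D)
  truth$lambda_B <- lam_B
  truth$lambda_D <- lam_D
  truth$seed <- seed
  list(grid = grid, truth = truth)
}

#' Simulate micro-census clusters directly from the cluster-level model
#'
#' Draws cluster covariates as standardized normals and generates observed
#' building and population counts exactly from the hierarchical model at
#' the cluster scale. This is the generator used for parameter-recovery and
#' cross-validation checks, where the fitted model must be well specified.
#'
#' @param truth a `bupop_truth` at cluster scale.
#' @param n_clusters number of clusters (the study surveyed 213).
#' @param class_shares length-3 allocation shares across settlement classes
#'   (each non-empty class receives at least one cluster).
#' @param seed integer seed.
#' @return a tibble of micro-census clusters: `cluster_id`, `class`,
#'   `B_obs`, `P_obs`, `x_B`, `xD1..4`, `n_cells`, centroid `cx`/`cy`, and
#'   the latent `lambda_B`/`lambda_D` used (kept for oracle tests).
#' @export
simulate_microcensus <- function(truth, n_clusters = 213,
                                 class_shares = c(1, 1, 1) / 3, seed = 1L) {
  stopifnot(inherits(truth, "bupop_truth"))
  stop_if(n_clusters < 3, "need at least one cluster per settlement class")
  set.seed(seed)
  n_c <- pmax(1L, round(class_shares / sum(class_shares) * n_clusters))
  while (sum(n_c) != n_clusters) {
    k <- if (sum(n_c) > n_clusters) which.max(n_c) else which.min(n_c)
    n_c[k] <- n_c[k] + sign(n_clusters - sum(n_c))
  }
  s <- rep(1:3, n_c)
  n <- length(s)
  x_B <- stats::rnorm(n)
  xD <- matrix(stats::rnorm(n * 4), n, 4)
  mu_B <- truth$alpha_B[s] + truth$beta_B[s] * x_B
  mu_D <- truth$alpha_D[s] + as.numeric(xD %*% truth$beta_D)
  lam_B <- stats::rlnorm(n, mu_B, truth$sigma_B[s])
  lam_D <- stats::rlnorm(n, mu_D, truth$sigma_D[s])
  cl <- tibble::tibble(cluster_id = seq_len(n), class = s,
                       B_obs = stats::rpois(n, lam_B),
                       P_obs = stats::rpois(n, lam_B * lam_D),
                       x_B = x_B)
  for (k in 1:4) cl[[paste0("xD", k)]] <- xD[, k]
  cl$n_cells <- 1L
  cl$cx <- stats::runif(n, 0, 100)
  cl$cy <- stats::runif(n, 0, 100)
  cl$lambda_B <- lam_B
  cl$lambda_D <- lam_D
  attr(cl, "truth") <- truth
  cl
}

#' Sample micro-census clusters from a simulated grid
#'
#' Emulates the survey's stratified cluster design at the contract level:
#' clusters are disjoint groups of contiguous (rook-adjacent) settled cells
#' of one settlement class, grown from random seed cells until the
#' cumulative true building count reaches `target_buildings` or `max_cells`
#' cells are used. Clusters are allocated to classes proportionally to
#' settled-cell counts, with at least one per non-empty class. Cluster
#' counts are exact sums of member-cell counts; cluster covariates are the
#' zonal summaries of member cells (building-count covariate: weighted sum
#' then log then grid-constant standardization; density covariates: mean
#' then grid-constant standardization).
#'
#' @param grid a grid carrying true `B` and `P` (see [simulate_truth()]).
#' @param n_clusters number of clusters to draw.
#' @param target_buildings growth stops once the cluster's true building
#'   count reaches this (survey design: ~80 buildings).
#' @param max_cells hard cap on cells per cluster (survey design envelope:
#'   clusters spanned up to hundreds of cells; default 600).
#' @param seed integer seed.
#' @return a tibble of clusters as in [simulate_microcensus()] (without
#'   latent rates), plus a `cells` list-column of member cell ids.
#' @export
sample_clusters <- function(grid, n_clusters, target_buildings = 80,
                            max_cells = 600, seed = 1L) {
  stop_if(nrow(grid) == 0, "empty grid")
  stop_if(!all(c("B", "P") %in% names(grid)),
          "grid must carry true B and P; run simulate_truth() first")
  set.seed(seed)
  const <- attr(grid, "constants")
  tr <- attr(grid, "transform")
  nr <- tr$nrow; nc <- tr$ncol
  cell_at <- matrix(0L, nr, nc)
  cell_at[cbind(grid$row, grid$col)] <- grid$cell_id

  n_class <- tabulate(grid$class, 3)
  avail <- n_class > 0
  alloc <- integer(3)
  alloc[avail] <- pmax(1L, round(n_class[avail] / sum(n_class) * n_clusters))
  while (sum(alloc) != n_clusters) {
    k <- if (sum(alloc) > n_clusters) which.max(alloc) else
      which(avail)[which.max(n_class[avail] / pmax(alloc[avail], 1))]
    if (sum(alloc) > n_clusters && alloc[k] <= 1) k <- which.max(alloc)
    alloc[k] <- alloc[k] + sign(n_clusters - sum(alloc))
  }

  used <- logical(nrow(grid))
  out <- vector("list", n_clusters)
  ci <- 0L
  for (s in which(alloc > 0)) {
    for (r in seq_len(alloc[s])) {
      free <- which(grid$class == s & !used)
      stop_if(length(free) == 0,
              "not enough unused cells to build the requested clusters")
      seed_cell <- if (length(free) == 1) free else sample(free, 1)
      members <- integer(0)
      frontier <- seed_cell
      b_sum <- 0
      while (length(frontier) > 0 && b_sum < target_buildings &&
             length(members) < max_cells) {
        j <- frontier[1]
        frontier <- frontier[-1]
        if (used[j]) next
        used[j] <- TRUE
        members <- c(members, j)
        b_sum <- b_sum + grid$B[j]
        rw <- grid$row[j]; cl <- grid$col[j]
        nb <- c(if (rw > 1) cell_at[rw - 1, cl], if (rw < nr) cell_at[rw + 1, cl],
                if (cl > 1) cell_at[rw, cl - 1], if (cl < nc) cell_at[rw, cl + 1])
        nb <- nb[nb > 0]
        nb <- nb[!used[nb] & grid$class[nb] == s]
        frontier <- c(frontier, nb)
      }
      ci <- ci + 1L
      bldg_sum <- sum(grid$bldg[members])
      row <- tibble::tibble(
        cluster_id = ci, class = s,
        B_obs = sum(grid$B[members]), P_obs = sum(grid$P[members]),
        x_B = standardize(log_building_covariate(bldg_sum),
                          const["log_bldg", ]))
      for (k in 1:4)
        row[[paste0("xD", k)]] <-
          standardize(mean(grid[[paste0("dcov", k)]][members]),
                      const[paste0("dcov", k), ])
      row$n_cells <- length(members)
      row$cx <- mean(grid$x[members])
      row$cy <- mean(grid$y[members])
      row$cells <- list(grid$cell_id[members])
      out[[ci]] <- row
    }
  }
  do.call(rbind, out)
}
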