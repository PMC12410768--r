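#' Grid-level standardization constants
#'
#' Computes, for each covariate column, the mean and the empirical (sample,
#' n-1 denominator) standard deviation over settled grid cells. The same
#' constants are applied both to grid cells and to cluster-level zonal
#' summaries, so cluster covariates live on the grid-derived scale.
#'
#' @param values data.frame/matrix of covariate columns over settled cells.
#' @return data.frame with rownames = covariate names and columns `mean`,
#'   `sd`. Errors if any covariate has zero sd.
#' @export
standardization_constants <- function(values) {
  values <- as.data.frame(values)
  m <- vapply(values, mean, numeric(1))
  s <- vapply(values, stats::sd, numeric(1))
  bad <- names(values)[s <= 0 | !is.finite(s)]
  stop_if(length(bad) > 0,
          "zero or undefined standard deviation for covariate(s): ",
          paste(bad, collapse = ", "))
  data.frame(mean = m, sd = s, row.names = names(values))
}

#' Centre and scale values with given constants
#'
#' @param values numeric vector (grid cells or cluster summaries).
#' @param constants one row of [standardization_constants()] output (or any
#'   list with `mean` and `sd`).
#' @return `(values - mean) / sd`.
#' @export
standardize <- function(values, constants) {
  stop_if(is.null(constants$mean) || is.null(constants$sd),
          "constants must carry mean and sd")
  stop_if(constants$sd <= 0, "zero standard deviation: cannot standardize")
  (values - constants$mean) / constants$sd
}

#' Invert [standardize()]
#' @inheritParams standardize
#' @return values on the original scale.
#' @export
unstandardize <- function(values, constants) {
  values * constants$sd + constants$mean
}

#' Zonal summary of gridded values
#'
#' Summarises per-cell values within zones, with the three summary rules
#' used for covariate preparation: `mode` (for the settlement class; ties
#' resolve to the most urban, i.e. lowest, class index), `weighted_sum`
#' (pixel values weighted by their areal intersection fraction, for
#' building count/area layers) and `mean` (unweighted over intersecting
#' pixels, for everything else).
#'
#' @param values numeric vector of per-cell values, indexed by cell id.
#' @param zones data.frame with columns `zone`, `cell` and (for
#'   `weighted_sum`) optional `fraction` (defaults to 1, i.e. fully covered
#'   pixels).
#' @param method one of `"mode"`, `"weighted_sum"`, `"mean"`.
#' @return named numeric vector, one entry per zone (in first-appearance
#'   order). Zones listed in `levels(zones$zone)` but with no intersecting
#'   cells are returned as `NA` and named in attribute `missing_zones`.
#' @export
zonal_summary <- function(values, zones, method = c("mean", "weighted_sum", "mode")) {
  method <- match.arg(method)
  stop_if(!all(c("zone", "cell") %in% names(zones)),
          "zones must have columns zone and cell")
  ids <- unique(zones$zone)
  frac <- zones$fraction %||% rep(1, nrow(zones))
  out <- vapply(ids, function(z) {
    sel <- zones$zone == z
    v <- values[zones$cell[sel]]
    if (length(v) == 0 || all(is.na(v))) return(NA_real_)
    switch(method,
           mean = mean(v),
           weighted_sum = sum(v * frac[sel]),
           mode = {
             tab <- table(v)
             top <- names(tab)[tab == max(tab)]
             min(as.numeric(top))  # tie -> most urban (lowest index)
           })
  }, numeric(1))
  names(out) <- ids
  if (anyNA(out)) attr(out, "missing_zones") <- names(out)[is.na(out)]
  out
}

#' Screen candidate covariates against the model outcomes
#'
#' Reproduces the exploratory covariate selection: a candidate is eligible
#' if its Pearson correlation with log building counts or with log
#' population densities (people per building) is significant at `alpha`.
#' Eligible candidates are then processed in decreasing order of their best
#' absolute outcome correlation and retained unless their correlation with
#' an already-retained candidate is itself significant at `alpha` (a
#' multicollinearity screen). Clusters with zero counts are excluded from
#' the log transforms.
#'
#' @param candidates data.frame of per-cluster covariate summaries.
#' @param B_obs,P_obs observed building and population counts per cluster.
#' @param alpha significance level for both screens (study used 0.05).
#' @return list with `selected` (names), `tests` (per-candidate correlation
#'   and p-value against each outcome) and `dropped_collinear`.
#' @export
screen_covariates <- function(candidates, B_obs, P_obs, alpha = 0.05) {
  stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0,1)")
  candidates <- as.data.frame(candidates)
  n <- nrow(candidates)
  stop_if(n < 3, "need at least 3 clusters for correlation screening")
  ok <- B_obs > 0 & P_obs > 0
  log_B <- log(B_obs[ok])
  log_D <- log(P_obs[ok] / B_obs[ok])
  tests <- do.call(rbind, lapply(names(candidates), function(nm) {
    x <- candidates[[nm]][ok]
    tb <- stats::cor.test(x, log_B)
    td <- stats::cor.test(x, log_D)
    data.frame(candidate = nm,
               cor_logB = unname(tb$estimate), p_logB = tb$p.value,
               cor_logD = unname(td$estimate), p_logD = td$p.value)
  }))
  tests$best_abs_cor <- pmax(abs(tests$cor_logB), abs(tests$cor_logD))
  eligible <- tests$candidate[tests$p_logB < alpha | tests$p_logD < alpha]
  ord <- eligible[order(-tests$best_abs_cor[match(eligible, tests$candidate)])]
  selected <- character(0)
  dropped <- character(0)
  for (nm in ord) {
    collinear <- any(vapply(selected, function(sl) {
      stats::cor.test(candidates[[nm]][ok], candidates[[sl]][ok])$p.value < alpha
    }, logical(1)))
    if (collinear) dropped <- c(dropped, nm) else selected <- c(selected, nm)
  }
  list(selected = selected, tests = tests, dropped_collinear = dropped)
}

#' Log-transform the building-count covariate
#'
#' The building-count covariate enters the model on the log scale. Under
#' the default `"log"` rule, non-positive values are invalid: the
#' settlement layer defines settled cells as containing buildings, so a
#' zero signals a mask inconsistency and errors (listing the offending
#' cells) rather than propagating -Inf. The `"log1p"` fallback admits
#' zeros.
#'
#' @param values raw building-count covariate values.
#' @param method `"log"` (default) or `"log1p"`.
#' @return transformed values.
#' @export
log_building_covariate <- function(values, method = c("log", "log1p")) {
  method <- match.arg(method)
  if (method == "log1p") return(log1p(values))
  bad <- which(values <= 0)
  stop_if(length(bad) > 0,
          "non-positive building-count covariate at cell(s) ",
          paste(utils::head(bad, 5), collapse = ", "),
          if (length(bad) > 5) ", ..." else "",
          "; settled cells must contain buildings (or use method = \"log1p\")")
  log(values)
}

#' Impute refused households and complete cluster population counts
#'
#' Households whose respondent refused the interview are assigned the mean
#' number of residents among responding households of the same cluster; the
#' cluster population count is the rounded (half-up) sum, so Poisson
#' likelihoods stay well defined.
#'
#' @param households data.frame with columns `cluster_id`, `residents`
#'   (NA or arbitrary for refusals) and logical `refused`.
#' @return tibble with `cluster_id`, completed `P_obs`, `n_households`,
#'   `n_refused`, `imputed_value`.
#' @export
impute_refusals <- function(households) {
  stop_if(!all(c("cluster_id", "residents", "refused") %in% names(households)),
          "households needs cluster_id, residents, refused")
  ids <- unique(households$cluster_id)
  rows <- lapply(ids, function(id) {
    h <- households[households$cluster_id == id, ]
    resp <- h$residents[!h$refused]
    stop_if(length(resp) == 0,
            "all households refused in cluster ", id, ": imputation impossible")
    imp <- mean(resp)
    total <- sum(resp) + sum(h$refused) * imp
    tibble::tibble(cluster_id = id,
                   P_obs = as.integer(floor(total + 0.5)),  # round half-up
                   n_households = nrow(h),
                   n_refused = sum(h$refused),
                   imputed_value = if (any(h$refused)) imp else NA_real_)
  })
  do.call(rbind, rows)
}
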