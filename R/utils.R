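#' Shared posterior quantile rule
#'
#' All credible intervals in the package use the linear-interpolation
#' quantile definition (type 7), fixed once here so that cell summaries,
#' cluster intervals and area aggregates cannot drift apart.
#'
#' @param x numeric vector of draws.
#' @param probs probabilities, defaults to the 95\% interval bounds.
#' @return numeric vector of quantiles.
#' @export
posterior_quantile <- function(x, probs = c(0.025, 0.975)) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

#' Derive a named per-stage seed from a root seed
#'
#' All randomness flows from a single root seed expanded into fixed,
#' documented per-stage offsets, so stages are independently reproducible.
#' Offsets keep the result within the 32-bit integer range.
#'
#' @param seed root integer seed.
#' @param stage stage name.
#' @return integer seed for the stage.
#' @export
stage_seed <- function(seed, stage = c("simulate", "clusters", "fit", "predict",
                                       "aggregate", "evaluate")) {
  stage <- match.arg(stage)
  offset <- c(simulate = 11L, clusters = 23L, fit = 37L, predict = 53L,
              aggregate = 71L, evaluate = 89L)[[stage]]
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# settlement classes are fixed: urban = 1, peri-urban = 2, rural = 3

#' Settlement class labels and indices
#'
#' The three settlement strata used throughout: urban (1), peri-urban (2),
#' rural (3). The index mapping is fixed; class-specific model parameters
#' are always ordered this way.
#'
#' @return a data.frame with columns `index` and `label`.
#' @export
settlement_classes <- function() {
  data.frame(index = 1:3,
             label = c("urban", "peri-urban", "rural"),
             stringsAsFactors = FALSE)
}
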