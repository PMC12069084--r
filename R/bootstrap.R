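# Standard and stratified non-parametric resampling, bootstrap
# replication, and percentile-method confidence intervals.

#' A resampling plan
#'
#' @param mode `"standard"` (uniform resampling with replacement) or
#'   `"stratified"` (resampling with replacement within each stratum,
#'   keeping every stratum at its observed size).
#' @param strata for stratified mode, a vector of stratum labels, one per
#'   observation.
#' @return An object of class `resample_plan`.
#' @export
resample_plan <- function(mode = c("standard", "stratified"), strata = NULL) {
  mode <- match.arg(mode)
  if (mode == "stratified" && is.null(strata)) {
    stop("stratified resampling requires stratum labels")
  }
  structure(list(mode = mode, strata = strata), class = "resample_plan")
}

#' Draw one set of bootstrap indices
#'
#' Standard mode draws `n` indices uniformly with replacement. Stratified
#' mode draws, within each stratum, as many indices with replacement as
#' the stratum originally holds, so stratum sample sizes are controlled
#' exactly; indices are returned grouped by stratum.
#'
#' @param n number of observations.
#' @param plan a [resample_plan()].
#' @return Integer vector of length `n`.
#' @export
resample_indices <- function(n, plan = resample_plan()) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (plan$mode == "standard") {
    return(sample.int(n, n, replace = TRUE))
  }
  s <- plan$strata
  if (length(s) != n) {
    stop("strata must label every observation exactly once (length ",
         length(s), " != n = ", n, ")")
  }
  idx_by <- split(seq_len(n), s)
  if (any(lengths(idx_by) == 0L)) {
    stop("empty stratum: ", paste(names(idx_by)[lengths(idx_by) == 0L],
                                  collapse = ", "))
  }
  unlist(lapply(idx_by, function(i) i[sample.int(length(i), length(i),
                                                 replace = TRUE)]),
         use.names = FALSE)
}

#' Bootstrap a statistic
#'
#' @param data numeric vector or data.frame of observations.
#' @param stat function mapping a resampled `data` to a scalar.
#' @param B number of bootstrap replicates.
#' @param plan a [resample_plan()].
#' @param seed optional integer; if given, the RNG is seeded so the
#'   replicate vector is reproducible.
#' @param statistic_label free-text label stored with the result.
#' @return An object of class `bootstrap_distribution` with elements
#'   `values` (length-`B` numeric), `B`, `statistic_label`, `seed`.
#' @export
bootstrap_statistic <- function(data, stat, B = 1000,
                                plan = resample_plan(), seed = NULL,
                                statistic_label = NULL) {
  if (!is.numeric(B) || B < 1) stop("B must be >= 1")
  B <- as.integer(B)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (!is.null(seed)) set.seed(seed)
  values <- numeric(B)
  for (b in seq_len(B)) {
    idx <- resample_indices(n, plan)
    sub <- if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
    v <- tryCatch(stat(sub), error = function(e) {
      stop("statistic failed on replicate ", b, ": ", conditionMessage(e),
           call. = FALSE)
    })
    values[b] <- v
  }
  structure(
    list(values = values, B = B,
         statistic_label = statistic_label %||%
           paste(deparse(substitute(stat)), collapse = "")[1L],
         seed = seed),
    class = "bootstrap_distribution"
  )
}

#' @export
print.bootstrap_distribution <- function(x, ...) {
  cat("<bootstrap_distribution> ", x$statistic_label, ", B = ", x$B,
      "; mean = ", format(mean(x$values), digits = 4),
      ", sd = ", format(stats::sd(x$values), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Percentile-method confidence interval
#'
#' The (1-level)/2 and 1-(1-level)/2 empirical quantiles of the bootstrap
#' replicates, using linear interpolation between order statistics
#' (quantile type 7, the package-wide convention).
#'
#' @param dist a `bootstrap_distribution`, or a numeric vector of
#'   replicates.
#' @param level confidence level in (0, 1).
#' @return Named numeric `c(lower, upper)` in the units of the statistic.
#' @export
percentile_ci <- function(dist, level = 0.95) {
  values <- if (inherits(dist, "bootstrap_distribution")) dist$values
            else as.numeric(dist)
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    stop("level must be a single number strictly between 0 and 1")
  }
  if (length(values) < 2L) stop("need at least 2 bootstrap replicates")
  q <- stats::quantile(values, probs = c((1 - level) / 2,
                                         1 - (1 - level) / 2),
                       type = 7, names = FALSE)
  c(lower = q[1L], upper = q[2L])
}
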