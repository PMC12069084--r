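# Left-censored occurrence handling: LOD substitution scenarios and
# censored maximum-likelihood distribution fitting with AIC selection.

.cens_families <- c("normal", "lognormal", "gamma", "weibull")

# fitdistrplus distribution codes and (density, cdf) pairs per family
.family_info <- list(
  normal    = list(dist = "norm",    d = stats::dnorm,    p = stats::pnorm),
  lognormal = list(dist = "lnorm",   d = stats::dlnorm,   p = stats::plnorm),
  gamma     = list(dist = "gamma",   d = stats::dgamma,   p = stats::pgamma),
  weibull   = list(dist = "weibull", d = stats::dweibull, p = stats::pweibull)
)

#' A scenario for substituting left-censored values
#'
#' Values below the limit of detection (LOD) are replaced by 0
#' (lower bound), LOD/2 (middle bound) or LOD (upper bound). The middle
#' bound is the default throughout the package.
#'
#' @param kind one of `"middle_bound"`, `"lower_bound"`, `"upper_bound"`.
#' @return An object of class `lod_scenario` with the substitution factor
#'   (multiple of the LOD).
#' @export
lod_scenario <- function(kind = c("middle_bound", "lower_bound",
                                  "upper_bound")) {
  kind <- match.arg(kind)
  factor <- switch(kind, lower_bound = 0, middle_bound = 0.5, upper_bound = 1)
  structure(list(kind = kind, factor = factor), class = "lod_scenario")
}

#' Substitute censored occurrence values under an LOD scenario
#'
#' Censored records get `factor * LOD` as their working value and are
#' flagged `substituted`; uncensored records are untouched. Distribution
#' fitting ([fit_censored()]) does not use substituted values -- it works
#' on the censored likelihood directly; substitution feeds the exposure
#' computation.
#'
#' @param table an [occurrence_table].
#' @param scenario an [lod_scenario()]; middle bound by default.
#' @return The table with substituted values.
#' @export
apply_lod_scenario <- function(table, scenario = lod_scenario()) {
  stopifnot(inherits(table, "occurrence_table"),
            inherits(scenario, "lod_scenario"))
  cz <- table$censored
  table$value[cz] <- table$lod[cz] * scenario$factor
  table$substituted[cz] <- TRUE
  attr(table, "lod_scenario") <- scenario$kind
  table
}

#' Censored log-likelihood
#'
#' Sum of log densities over uncensored points plus log CDF at the LOD
#' over censored points. With no censored points this reduces to the
#' ordinary log-likelihood.
#'
#' @param values concentrations (ug/g); for censored entries the raw value
#'   is ignored.
#' @param censored logical flags.
#' @param lods LODs (ug/g), required where `censored` is `TRUE`.
#' @param family one of `"normal"`, `"lognormal"`, `"gamma"`, `"weibull"`.
#' @param params named parameter vector in the family's native
#'   parameterization (`mean`/`sd`, `meanlog`/`sdlog`, `shape`/`rate`,
#'   `shape`/`scale`).
#' @return The log-likelihood (scalar).
#' @export
censored_loglik <- function(values, censored, lods, family, params) {
  family <- match.arg(family, .cens_families)
  fi <- .family_info[[family]]
  censored <- as.logical(censored)
  args <- as.list(unname(params))
  ll <- 0
  if (any(!censored)) {
    ll <- ll + sum(do.call(fi$d, c(list(values[!censored]), args,
                                   list(log = TRUE))))
  }
  if (any(censored)) {
    ll <- ll + sum(do.call(fi$p, c(list(lods[censored]), args,
                                   list(log.p = TRUE))))
  }
  ll
}

# moment-based starting values on the uncensored observations
.start_values <- function(x, family) {
  m <- mean(x); v <- stats::var(x)
  switch(family,
    normal    = list(mean = m, sd = sqrt(v)),
    lognormal = list(meanlog = mean(log(x)), sdlog = stats::sd(log(x))),
    gamma     = list(shape = m^2 / v, rate = m / v),
    weibull   = {
      cv <- sqrt(v) / m
      shape <- max(0.1, cv^-1.086)  # Justus approximation
      list(shape = shape, scale = m / gamma(1 + 1 / shape))
    }
  )
}

#' Fit a censored parametric distribution
#'
#' Maximizes the censored likelihood: density contributions for
#' uncensored values, cumulative probability at the LOD for censored
#' ones. Fitting is delegated to [fitdistrplus::fitdistcens()]; on
#' failure with default starts, a moment-based start and up to three
#' jittered restarts are attempted.
#'
#' @inheritParams censored_loglik
#' @return An object of class `censored_fit` with elements `family`,
#'   `params` (named estimates), `se`, `loglik`, `aic` (always equal to
#'   `2k - 2 loglik` with `k = 2` free parameters), `n`, `n_censored`.
#' @export
fit_censored <- function(values, censored = rep(FALSE, length(values)),
                         lods = NULL, family = "lognormal") {
  if (length(family) != 1L || !family %in% .cens_families) {
    stop("unsupported family '", paste(family, collapse = ","),
         "'; use one of: ", paste(.cens_families, collapse = ", "))
  }
  censored <- as.logical(censored)
  stopifnot(length(censored) == length(values))
  if (sum(!censored) < 3L) {
    stop("insufficient uncensored data: need at least 3 uncensored values (",
         sum(!censored), " available)")
  }
  if (any(censored)) {
    if (is.null(lods)) stop("lods required when any value is censored")
    if (any(!is.finite(lods[censored]) | lods[censored] <= 0)) {
      stop("censored records need a finite positive LOD")
    }
  }
  cdat <- data.frame(left = ifelse(censored, NA_real_, values),
                     right = ifelse(censored, lods, values))
  dist <- .family_info[[family]]$dist

  try_fit <- function(start) {
    tryCatch(
      suppressWarnings(
        if (is.null(start)) fitdistrplus::fitdistcens(cdat, dist)
        else fitdistrplus::fitdistcens(cdat, dist, start = start)
      ),
      error = function(e) e
    )
  }
  fit <- try_fit(NULL)
  if (inherits(fit, "error")) {
    start <- .start_values(values[!censored], family)
    fit <- try_fit(start)
    tries <- 0L
    while (inherits(fit, "error") && tries < 3L) {
      tries <- tries + 1L
      jit <- lapply(start, function(p) p * stats::runif(1, 0.7, 1.3))
      fit <- try_fit(jit)
    }
  }
  if (inherits(fit, "error")) {
    stop("censored ", family, " fit failed to converge: ",
         conditionMessage(fit))
  }
  k <- length(fit$estimate)
  structure(
    list(family = family,
         params = fit$estimate,
         se = fit$sd,
         loglik = fit$loglik,
         aic = 2 * k - 2 * fit$loglik,
         n = length(values),
         n_censored = sum(censored)),
    class = "censored_fit"
  )
}

#' @export
print.censored_fit <- function(x, ...) {
  cat("<censored_fit> ", x$family, " (n = ", x$n, ", censored = ",
      x$n_censored, ")\n  ", sep = "")
  cat(paste(names(x$params), format(x$params, digits = 4),
            sep = " = ", collapse = ", "),
      "\n  loglik = ", format(x$loglik, digits = 6),
      ", AIC = ", format(x$aic, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Select the best fit by AIC
#'
#' Given fits of several families to the same data, returns the one with
#' the lowest AIC. Exact ties are broken by the canonical family order
#' (normal, lognormal, gamma, weibull) with a warning.
#'
#' @param fits list of `censored_fit` objects over identical data.
#' @return The winning `censored_fit`.
#' @export
select_best_fit <- function(fits) {
  if (length(fits) == 0L) stop("no fits supplied")
  stopifnot(all(vapply(fits, inherits, logical(1), "censored_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  ncs <- vapply(fits, `[[`, numeric(1), "n_censored")
  if (length(unique(ns)) > 1L || length(unique(ncs)) > 1L) {
    stop("fits were computed on different data (n or n_censored differ)")
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- which(aics == min(aics))
  if (length(best) > 1L) {
    fam_rank <- match(vapply(fits[best], `[[`, character(1), "family"),
                      .cens_families)
    best <- best[order(fam_rank)]
    warning("AIC tie between families; keeping '",
            fits[[best[1L]]]$family, "' by canonical order")
  }
  fits[[best[1L]]]
}

#' Fit all supported families and pick the best
#'
#' Convenience wrapper: fits the censored normal, lognormal, gamma and
#' Weibull distributions and selects the lowest-AIC fit.
#'
#' @inheritParams censored_loglik
#' @param families families to fit (default all four).
#' @return List with `fits` (all attempted fits; failures dropped with a
#'   warning) and `best` (the selected `censored_fit`).
#' @export
fit_occurrence_distributions <- function(values, censored =
                                           rep(FALSE, length(values)),
                                         lods = NULL,
                                         families = .cens_families) {
  fits <- list()
  for (f in families) {
    fit <- tryCatch(fit_censored(values, censored, lods, f),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("fit of censored ", f, " failed: ", conditionMessage(fit))
    } else {
      fits[[f]] <- fit
    }
  }
  if (length(fits) == 0L) stop("every family failed to fit")
  list(fits = fits, best = select_best_fit(fits))
}
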