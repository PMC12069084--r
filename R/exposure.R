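# Deterministic and probabilistic chronic exposure estimation under the
# OIM, sOIM and wsOIM methodologies.
#
# Exposure of individual i is
#   E_i = sum_c  consumption_i(c) [g/day] * mean_occ(c) [ug/g] / bw_i [kg]
# in ug/kg bw/day. OIM/sOIM use the arithmetic category mean occurrence;
# wsOIM uses a weighted mean of subcategory means.

.prob_names <- function(probs) paste0("p", probs * 100)

#' Specify an exposure estimation method
#'
#' @param name `"OIM"`, `"sOIM"` or `"wsOIM"`. OIM uses the standard
#'   bootstrap on occurrence data; sOIM and wsOIM use the stratified
#'   bootstrap (resampling within subcategory at observed stratum sizes).
#' @param weights a [weight_scheme()]; required for wsOIM (the weighted
#'   mean occurrence), disallowed otherwise.
#' @return An object of class `method_spec` with the derived
#'   `resample_mode`.
#' @export
method_spec <- function(name = c("OIM", "sOIM", "wsOIM"), weights = NULL) {
  name <- match.arg(name)
  if (name == "wsOIM") {
    if (is.null(weights)) stop("wsOIM requires a weight_scheme")
    stopifnot(inherits(weights, "weight_scheme"))
  } else if (!is.null(weights)) {
    stop(name, " does not take a weight scheme")
  }
  structure(
    list(name = name, weights = weights,
         resample_mode = if (name == "OIM") "standard" else "stratified"),
    class = "method_spec"
  )
}

#' @export
print.method_spec <- function(x, ...) {
  cat("<method_spec> ", x$name,
      if (!is.null(x$weights)) paste0(" [", x$weights$label, "]"),
      " (", x$resample_mode, " occurrence bootstrap)\n", sep = "")
  invisible(x)
}

# weighted mean of stratum means for one category's values;
# validates that the weight keys match the strata present
.weighted_mean_occ <- function(values, strata, scheme) {
  means <- tapply(values, strata, mean)
  w <- scheme$weights
  if (!setequal(names(w), names(means))) {
    stop("weight scheme '", scheme$label, "' keys {",
         paste(sort(names(w)), collapse = ", "),
         "} do not match occurrence strata {",
         paste(sort(names(means)), collapse = ", "), "}")
  }
  sum(w[names(means)] * as.numeric(means))
}

#' Category-specific mean occurrence
#'
#' OIM and sOIM use the pooled arithmetic mean of all sample values in
#' the category; wsOIM uses `sum_s w_s * mean_s` over subcategory means.
#'
#' @param table an [occurrence_table].
#' @param method a [method_spec()].
#' @return Named numeric vector, one mean occurrence (ug/g) per category.
#' @export
mean_occurrence <- function(table, method = method_spec("OIM")) {
  stopifnot(inherits(table, "occurrence_table"),
            inherits(method, "method_spec"))
  if (nrow(table) == 0L) stop("empty occurrence table")
  cats <- unique(table$category)
  out <- stats::setNames(numeric(length(cats)), cats)
  for (ct in cats) {
    sel <- table$category == ct
    if (method$name == "wsOIM") {
      sub <- table$subcategory[sel]
      if (anyNA(sub)) {
        stop("strata unavailable: occurrence records in category '", ct,
             "' lack subcategory labels")
      }
      out[ct] <- .weighted_mean_occ(table$value[sel], sub, method$weights)
    } else {
      out[ct] <- mean(table$value[sel])
    }
  }
  out
}

#' Consumption-aware weights for wsOIM*
#'
#' The weight of subcategory s is its share of the total mean daily
#' consumption of the category, summed over all subjects.
#'
#' @param consumers a [consumer_table].
#' @param category category label.
#' @param label label for the resulting scheme (default `"w*"`).
#' @return A [weight_scheme()].
#' @export
consumption_aware_weights <- function(consumers, category, label = "w*") {
  stopifnot(inherits(consumers, "consumer_table"))
  it <- consumers$intake
  it <- it[it$category == category & it$amount > 0, , drop = FALSE]
  if (nrow(it) == 0L || sum(it$amount) <= 0) {
    stop("degenerate weights: zero total consumption for category '",
         category, "'")
  }
  if (anyNA(it$subcategory)) {
    stop("strata unavailable: consumption records for category '", category,
         "' lack subcategory labels")
  }
  tot <- tapply(it$amount, it$subcategory, sum)
  w <- stats::setNames(as.numeric(tot) / sum(tot), names(tot))
  weight_scheme(w, label = label)
}

# intake matrix: subjects x categories, mean daily consumption (g/day)
.intake_matrix <- function(consumers, categories) {
  M <- vapply(categories, function(ct) category_consumption(consumers, ct),
              numeric(n_subjects(consumers)))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L,
                                   dimnames = list(
                                     consumers$subjects$subject_id,
                                     categories))
  M
}

#' Individual chronic exposure
#'
#' Combines each subject's category consumption with the category mean
#' occurrence: `sum_c consumption(c) * mean_occ[c] / body_weight`.
#'
#' @param consumers a [consumer_table].
#' @param mean_occ named numeric vector of mean occurrences (ug/g) per
#'   category, e.g. from [mean_occurrence()].
#' @return Named numeric vector of exposures (ug/kg bw/day), one per
#'   subject.
#' @export
individual_exposure <- function(consumers, mean_occ) {
  stopifnot(inherits(consumers, "consumer_table"))
  consumed <- unique(consumers$intake$category[consumers$intake$amount > 0])
  missing <- setdiff(consumed, names(mean_occ))
  if (length(missing) > 0L) {
    stop("missing mean occurrence for consumed categor",
         if (length(missing) == 1L) "y: " else "ies: ",
         paste(missing, collapse = ", "))
  }
  cats <- names(mean_occ)
  M <- .intake_matrix(consumers, cats)
  ex <- as.numeric(M %*% mean_occ[cats]) / consumers$subjects$body_weight
  stats::setNames(ex, consumers$subjects$subject_id)
}

new_exposure_estimate <- function(method, probs, de, ci = NULL,
                                  level = NA_real_, ecdf = NULL,
                                  B = NA_integer_, seeds = NULL,
                                  mean_occ = NULL, replicates = NULL,
                                  occ_replicates = NULL) {
  structure(
    list(method = method, probs = probs, de = de, ci = ci, level = level,
         ecdf = ecdf, B = B, seeds = seeds, mean_occ = mean_occ,
         replicates = replicates, occ_replicates = occ_replicates),
    class = "exposure_estimate"
  )
}

#' @export
print.exposure_estimate <- function(x, ...) {
  cat("<exposure_estimate> ", x$method$name,
      if (!is.null(x$method$weights)) paste0(" [", x$method$weights$label, "]"),
      if (!is.null(x$ci)) paste0(", B = ", x$B, ", ", 100 * x$level, "% CI"),
      " (ug/kg bw/day)\n", sep = "")
  tab <- data.frame(probability = x$probs, DE = unname(x$de))
  if (!is.null(x$ci)) {
    tab$ci_lower <- unname(x$ci[, "lower"])
    tab$ci_upper <- unname(x$ci[, "upper"])
  }
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

# shared validation for the estimate entry points
.check_match <- function(consumers, occurrence) {
  consumed <- unique(consumers$intake$category[consumers$intake$amount > 0])
  occ_cats <- unique(occurrence$category)
  if (length(intersect(consumed, occ_cats)) == 0L &&
      length(consumed) > 0L) {
    stop("no food category is shared between consumption and occurrence ",
         "data; OIM requires the classifications to match")
  }
}

#' Deterministic exposure estimate (DE)
#'
#' Point estimate from the original data: the category mean occurrence
#' (per method), each subject's exposure, and the requested percentiles
#' of the exposure distribution, together with its eCDF.
#'
#' @param consumers a [consumer_table].
#' @param occurrence an [occurrence_table] (censored values should already
#'   be substituted, see [apply_lod_scenario()]).
#' @param method a [method_spec()].
#' @param probs percentile probabilities; the default includes the upper
#'   tail percentile used for risk characterization (0.95).
#' @param keep_ecdf attach the full eCDF grid.
#' @return An `exposure_estimate` with `de` filled and no CIs.
#' @export
deterministic_estimate <- function(consumers, occurrence,
                                   method = method_spec("OIM"),
                                   probs = c(0.5, 0.95), keep_ecdf = TRUE) {
  stopifnot(inherits(consumers, "consumer_table"),
            inherits(occurrence, "occurrence_table"),
            all(probs > 0 & probs < 1))
  .check_match(consumers, occurrence)
  mo <- mean_occurrence(occurrence, method)
  ex <- individual_exposure(consumers, mo)
  de <- stats::quantile(ex, probs = probs, type = 7, names = FALSE)
  grid <- NULL
  if (keep_ecdf) {
    xs <- sort(ex)
    grid <- data.frame(exposure = xs,
                       probability = seq_along(xs) / length(xs))
  }
  new_exposure_estimate(method, probs,
                        de = stats::setNames(de, .prob_names(probs)),
                        ecdf = grid, mean_occ = mo)
}

#' Probabilistic exposure estimate (PE)
#'
#' The OIM bootstrap: consumers are resampled with replacement (B
#' replicates, one RNG stream) and, independently, occurrence data are
#' resampled (standard bootstrap for OIM; stratified within subcategory
#' for sOIM/wsOIM; second RNG stream). Replicate b pairs consumer
#' resample b with the category mean occurrence of occurrence resample b
#' and records the requested exposure percentiles; percentile-method CIs
#' are attached to each percentile. The DE is computed on the original
#' data.
#'
#' @inheritParams deterministic_estimate
#' @param B number of bootstrap replicates.
#' @param level confidence level for the percentile-method CIs.
#' @param seeds integer pair: seed of the consumer stream and seed of the
#'   occurrence stream.
#' @return An `exposure_estimate` with `de`, `ci`, the percentile
#'   replicates (`replicates`, a `B x length(probs)` matrix) and the mean
#'   occurrence replicates (`occ_replicates`, `B x n_categories`).
#' @export
probabilistic_estimate <- function(consumers, occurrence,
                                   method = method_spec("OIM"),
                                   B = 1000, level = 0.95,
                                   probs = c(0.5, 0.95),
                                   seeds = c(20260101L, 20260102L)) {
  stopifnot(inherits(consumers, "consumer_table"),
            inherits(occurrence, "occurrence_table"))
  if (!is.numeric(B) || B < 2) stop("B must be >= 2")
  B <- as.integer(B)
  stopifnot(length(seeds) == 2L)
  de_est <- deterministic_estimate(consumers, occurrence, method, probs)

  cats <- names(de_est$mean_occ)
  n_sub <- n_subjects(consumers)
  M <- .intake_matrix(consumers, cats)
  bw <- consumers$subjects$body_weight

  # per-category occurrence resampling setup
  occ_setup <- lapply(cats, function(ct) {
    sel <- which(occurrence$category == ct)
    vals <- occurrence$value[sel]
    strata <- occurrence$subcategory[sel]
    if (method$resample_mode == "stratified" && anyNA(strata)) {
      stop("strata unavailable: occurrence records in category '", ct,
           "' lack subcategory labels")
    }
    plan <- if (method$resample_mode == "stratified") {
      resample_plan("stratified", strata = strata)
    } else {
      resample_plan("standard")
    }
    list(values = vals, strata = strata, plan = plan, n = length(sel))
  })
  names(occ_setup) <- cats

  # stream 1: consumer resamples
  set.seed(seeds[1L])
  cons_idx <- lapply(seq_len(B), function(b)
    sample.int(n_sub, n_sub, replace = TRUE))

  # stream 2: occurrence resamples -> mean occurrence replicates
  set.seed(seeds[2L])
  occ_rep <- matrix(NA_real_, nrow = B, ncol = length(cats),
                    dimnames = list(NULL, cats))
  for (b in seq_len(B)) {
    for (ct in cats) {
      os <- occ_setup[[ct]]
      idx <- resample_indices(os$n, os$plan)
      occ_rep[b, ct] <- if (method$name == "wsOIM") {
        .weighted_mean_occ(os$values[idx], os$strata[idx], method$weights)
      } else {
        mean(os$values[idx])
      }
    }
  }

  # combine: replicate b = percentiles of exposure of consumer resample b
  # under mean occurrence replicate b
  reps <- matrix(NA_real_, nrow = B, ncol = length(probs),
                 dimnames = list(NULL, .prob_names(probs)))
  for (b in seq_len(B)) {
    idx <- cons_idx[[b]]
    expo <- as.numeric(M[idx, , drop = FALSE] %*% occ_rep[b, ]) / bw[idx]
    reps[b, ] <- stats::quantile(expo, probs = probs, type = 7,
                                 names = FALSE)
  }
  ci <- t(vapply(seq_along(probs),
                 function(j) percentile_ci(reps[, j], level = level),
                 numeric(2)))
  dimnames(ci) <- list(.prob_names(probs), c("lower", "upper"))

  new_exposure_estimate(method, probs, de = de_est$de, ci = ci,
                        level = level, ecdf = de_est$ecdf, B = B,
                        seeds = as.integer(seeds),
                        mean_occ = de_est$mean_occ,
                        replicates = reps, occ_replicates = occ_rep)
}

#' Heuristic difference verdict between two estimates
#'
#' Two estimates are declared different at the CI level if each point
#' estimate lies outside the other's confidence interval (mutual
#' CI-exclusion). This is a screening heuristic, not a formal test.
#'
#' @param a,b `exposure_estimate`s carrying CIs.
#' @param prob which percentile to compare (default the 95th).
#' @return Logical: `TRUE` if the estimates are heuristically different.
#' @export
estimates_differ <- function(a, b, prob = 0.95) {
  stopifnot(inherits(a, "exposure_estimate"), inherits(b, "exposure_estimate"))
  ja <- match(prob, a$probs); jb <- match(prob, b$probs)
  if (is.na(ja) || is.na(jb) || is.null(a$ci) || is.null(b$ci)) {
    stop("both estimates need a CI for probability ", prob)
  }
  a_out <- a$de[ja] < b$ci[jb, "lower"] || a$de[ja] > b$ci[jb, "upper"]
  b_out <- b$de[jb] < a$ci[ja, "lower"] || b$de[jb] > a$ci[ja, "upper"]
  unname(a_out && b_out)
}
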