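# Orchestration of the full simulation study: the method x weight-scheme
# grid, risk characterization against the TDI, and the tipping-point
# style robustness assessment.

.verdict_levels <- c("below_tdi", "not_different", "above_tdi")

#' Run the method comparison study
#'
#' For each cell of the grid {OIM, sOIM, wsOIM* and the three wsOIM
#' sensitivity scenarios}, computes the probabilistic estimate over
#' simulated occurrence datasets: replicate b draws a fresh occurrence
#' dataset from the study design, takes one bootstrap resample of it
#' (standard for OIM, stratified for the others), computes the cell's
#' mean occurrence, and pairs it with consumer bootstrap resample b.
#' All cells share the same consumer resamples, the same simulated
#' datasets and -- across the stratified cells -- the same stratified
#' resamples, so that between-method contrasts are not blurred by
#' independent resampling noise. The DE of every cell is computed on a
#' common reference dataset drawn once from the same design.
#'
#' @param config a [simulation_config()].
#' @param consumers a [consumer_table] whose category matches
#'   `config$category`.
#' @param scale reduction factor in (0, 1] applied to `B` and
#'   `n_datasets`; scaled counts below 10 are rejected.
#' @param seed integer master seed (defaults to `config$seed`); every
#'   stream is derived from it.
#' @param probs exposure percentiles to track (must include 0.95 for risk
#'   characterization).
#' @param level confidence level of the percentile-method CIs.
#' @return An object of class `study_result`: `cells` (named list of
#'   `exposure_estimate`s), `occ_distributions` (per-cell
#'   `bootstrap_distribution` of mean occurrence), `comparisons`
#'   (pairwise heuristic difference verdicts on the UTP), `config`,
#'   `scale`, `B`, `seed`.
#' @export
run_study <- function(config, consumers, scale = 1,
                      seed = NULL, probs = c(0.5, 0.95), level = 0.95) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(consumers, "consumer_table"),
            is.numeric(scale), scale > 0, scale <= 1)
  seed <- as.integer(seed %||% config$seed)
  B <- as.integer(round(config$B * scale))
  nd <- as.integer(round(config$n_datasets * scale))
  if (B < 10L || nd < 10L) {
    stop("scaled replicate counts must be at least 10 (got B = ", B,
         ", datasets = ", nd, ")")
  }
  n_rep <- min(B, nd)

  ws <- config$weight_schemes
  cells <- c(
    list(OIM = method_spec("OIM"), sOIM = method_spec("sOIM")),
    stats::setNames(
      lapply(ws, function(w) method_spec("wsOIM", w)),
      vapply(ws, function(w)
        if (identical(w$label, "w*")) "wsOIM*"
        else paste0("wsOIM(", w$label, ")"), character(1))
    )
  )

  set.seed(seed)
  s_ref <- sample.int(.Machine$integer.max, 1L)
  s_cons <- sample.int(.Machine$integer.max, 1L)
  seed_mat <- matrix(sample.int(.Machine$integer.max, 3L * n_rep),
                     ncol = 3L)  # dataset, standard resample, stratified

  ref_table <- simulate_occurrence(config, rng_seed = s_ref)
  ct <- config$category
  de_list <- lapply(cells, function(m)
    deterministic_estimate(consumers, ref_table, m, probs = probs))

  # consumer stream (shared across cells)
  n_sub <- n_subjects(consumers)
  ratio <- category_consumption(consumers, ct) /
    consumers$subjects$body_weight
  set.seed(s_cons)
  cons_q <- matrix(NA_real_, nrow = n_rep, ncol = length(probs))
  for (b in seq_len(n_rep)) {
    idx <- sample.int(n_sub, n_sub, replace = TRUE)
    cons_q[b, ] <- stats::quantile(ratio[idx], probs = probs, type = 7,
                                   names = FALSE)
  }

  # occurrence stream: fresh dataset + one resample per replicate
  occ_rep <- matrix(NA_real_, nrow = n_rep, ncol = length(cells),
                    dimnames = list(NULL, names(cells)))
  for (b in seq_len(n_rep)) {
    tab <- simulate_occurrence(config, rng_seed = seed_mat[b, 1L])
    vals <- tab$value
    strata <- tab$subcategory
    set.seed(seed_mat[b, 2L])
    idx_std <- sample.int(length(vals), length(vals), replace = TRUE)
    set.seed(seed_mat[b, 3L])
    idx_str <- resample_indices(length(vals),
                                resample_plan("stratified", strata))
    str_means <- tapply(vals[idx_str], strata[idx_str], mean)
    for (nm in names(cells)) {
      m <- cells[[nm]]
      occ_rep[b, nm] <- switch(
        m$name,
        OIM = mean(vals[idx_std]),
        sOIM = mean(vals[idx_str]),
        wsOIM = sum(m$weights$weights[names(str_means)] *
                      as.numeric(str_means))
      )
    }
  }

  # combine: exposure percentile replicate = mean occ * consumer quantile
  # (exposure is linear in mean occurrence for a single category)
  estimates <- list()
  occ_dists <- list()
  for (nm in names(cells)) {
    reps <- occ_rep[, nm] * cons_q
    colnames(reps) <- .prob_names(probs)
    ci <- t(vapply(seq_along(probs),
                   function(j) percentile_ci(reps[, j], level = level),
                   numeric(2)))
    dimnames(ci) <- list(.prob_names(probs), c("lower", "upper"))
    de <- de_list[[nm]]
    estimates[[nm]] <- new_exposure_estimate(
      cells[[nm]], probs, de = de$de, ci = ci, level = level,
      ecdf = de$ecdf, B = n_rep, seeds = seed, mean_occ = de$mean_occ,
      replicates = reps, occ_replicates = occ_rep[, nm, drop = FALSE]
    )
    occ_dists[[nm]] <- structure(
      list(values = occ_rep[, nm], B = n_rep,
           statistic_label = paste0("mean occurrence [", nm, "]"),
           seed = seed),
      class = "bootstrap_distribution"
    )
  }

  nms <- names(cells)
  comparisons <- NULL
  if (length(nms) > 1L) {
    pairs <- utils::combn(nms, 2L)
    comparisons <- data.frame(
      a = pairs[1L, ], b = pairs[2L, ],
      different = apply(pairs, 2L, function(p)
        estimates_differ(estimates[[p[1L]]], estimates[[p[2L]]],
                         prob = 0.95)),
      stringsAsFactors = FALSE
    )
  }

  structure(
    list(cells = estimates, occ_distributions = occ_dists,
         comparisons = comparisons, config = config, scale = scale,
         B = n_rep, seed = seed),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result> ", length(x$cells), " cells, B = ", x$B,
      " (scale ", x$scale, "), seed ", x$seed, "\n", sep = "")
  j <- match(0.95, x$cells[[1L]]$probs)
  tab <- do.call(rbind, lapply(names(x$cells), function(nm) {
    e <- x$cells[[nm]]
    data.frame(cell = nm, utp_de = unname(e$de[j]),
               ci_lower = unname(e$ci[j, "lower"]),
               ci_upper = unname(e$ci[j, "upper"]))
  }))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Construct a risk verdict from a UTP confidence interval
#'
#' Compares the 95% CI of the upper tail percentile (UTP) of exposure to
#' the tolerable daily intake: `below_tdi` if the upper bound is below
#' the TDI, `above_tdi` if the lower bound exceeds it, `not_different`
#' if the TDI lies inside the interval (CI-inclusion reading of "not
#' statistically different at the 0.05 level").
#'
#' @param utp UTP point estimate (ug/kg bw/day).
#' @param lower,upper CI bounds (ug/kg bw/day).
#' @param tdi tolerable daily intake (ug/kg bw/day).
#' @return An object of class `risk_verdict`.
#' @export
risk_verdict <- function(utp, lower, upper, tdi = 2) {
  utp <- unname(utp); lower <- unname(lower); upper <- unname(upper)
  stopifnot(is.finite(lower), is.finite(upper), lower <= upper, tdi > 0)
  verdict <- if (upper < tdi) "below_tdi"
             else if (lower > tdi) "above_tdi"
             else "not_different"
  structure(
    list(utp = utp, ci = c(lower = lower, upper = upper), tdi = tdi,
         verdict = verdict, robust = NA, tipping_schemes = character()),
    class = "risk_verdict"
  )
}

#' @export
print.risk_verdict <- function(x, ...) {
  cat("<risk_verdict> UTP = ", format(x$utp, digits = 4),
      " (", format(x$ci["lower"], digits = 4), ", ",
      format(x$ci["upper"], digits = 4), ") vs TDI = ", x$tdi,
      " ug/kg bw/day -> ", x$verdict, "\n", sep = "")
  if (!is.na(x$robust)) {
    cat("  robust: ", x$robust,
        if (length(x$tipping_schemes) > 0L)
          paste0(" (tipping: ", paste(x$tipping_schemes, collapse = ", "),
                 ")"),
        "\n", sep = "")
  }
  invisible(x)
}

#' Risk characterization of an exposure estimate
#'
#' @param estimate an `exposure_estimate` carrying a 95% CI for the 95th
#'   percentile.
#' @param tdi tolerable daily intake (ug/kg bw/day).
#' @return A [risk_verdict()].
#' @export
risk_characterization <- function(estimate, tdi = 2) {
  stopifnot(inherits(estimate, "exposure_estimate"))
  j <- match(0.95, estimate$probs)
  if (is.na(j) || is.null(estimate$ci)) {
    stop("estimate must carry a CI for the 0.95 percentile")
  }
  if (!isTRUE(all.equal(estimate$level, 0.95))) {
    stop("risk characterization requires a 95% CI (estimate has level ",
         estimate$level, ")")
  }
  risk_verdict(unname(estimate$de[j]), estimate$ci[j, "lower"],
               estimate$ci[j, "upper"], tdi = tdi)
}

#' Robustness of a risk conclusion across sensitivity scenarios
#'
#' The primary conclusion is robust if no sensitivity scenario points to
#' strictly higher risk, under the ordering
#' `below_tdi < not_different < above_tdi`. Scenarios that do point
#' higher are listed as tipping schemes.
#'
#' @param primary the primary [risk_verdict()].
#' @param scenarios named list of [risk_verdict()]s from sensitivity
#'   weighting schemes (wsOIM degree scenarios).
#' @return `primary` with `robust` and `tipping_schemes` filled in.
#' @export
robustness_assessment <- function(primary, scenarios) {
  stopifnot(inherits(primary, "risk_verdict"), length(scenarios) > 0L,
            all(vapply(scenarios, inherits, logical(1), "risk_verdict")))
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    stop("scenarios must be named by weighting scheme")
  }
  rank_of <- function(v) match(v$verdict, .verdict_levels)
  higher <- vapply(scenarios, function(s) rank_of(s) > rank_of(primary),
                   logical(1))
  primary$robust <- !any(higher)
  primary$tipping_schemes <- names(scenarios)[higher]
  primary
}
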