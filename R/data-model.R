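# Core data containers: consumer tables (variability axis) and occurrence
# tables (uncertainty axis), plus the CSV schemas used for interchange.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a consumer table
#'
#' A consumer table couples per-subject body weights with per-(category,
#' subcategory) mean daily consumption, the variability axis of a chronic
#' exposure assessment.
#'
#' @param subjects data.frame with columns `subject_id`, `body_weight`
#'   (kg) and `age` (years), one row per individual.
#' @param intake data.frame with columns `subject_id`, `category`,
#'   `subcategory` and `amount` (mean daily consumption, g/day). Subjects
#'   absent from `intake` are retained as non-consumers (zero exposure).
#'   `subcategory` may be `NA`: plain OIM does not need it, and operations
#'   that do (stratified resampling, weighting) raise a specific error.
#' @param survey_days number of survey days the daily means were averaged
#'   over (informational; a single integer or a per-subject named vector).
#'
#' @return An object of class `consumer_table`.
#' @export
consumer_table <- function(subjects, intake, survey_days = NULL) {
  stopifnot(is.data.frame(subjects), is.data.frame(intake))
  need_s <- c("subject_id", "body_weight", "age")
  if (length(miss <- setdiff(need_s, names(subjects))) > 0L) {
    stop("subjects is missing column(s): ", paste(miss, collapse = ", "))
  }
  need_i <- c("subject_id", "category", "subcategory", "amount")
  if (length(miss <- setdiff(need_i, names(intake))) > 0L) {
    stop("intake is missing column(s): ", paste(miss, collapse = ", "))
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  intake$subject_id <- as.character(intake$subject_id)
  if (nrow(subjects) == 0L) {
    stop("empty consumer table: no subjects remain")
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop("subject_ids must be unique")
  }
  if (any(!is.finite(subjects$body_weight) | subjects$body_weight <= 0)) {
    stop("all subjects must have a positive body weight; ",
         "filter before constructing the table")
  }
  if (any(!is.finite(intake$amount) | intake$amount < 0)) {
    stop("consumption amounts must be finite and non-negative")
  }
  if (!all(intake$subject_id %in% subjects$subject_id)) {
    stop("intake refers to subject_ids absent from subjects")
  }
  structure(
    list(subjects = subjects[need_s],
         intake = intake[need_i],
         survey_days = survey_days),
    class = "consumer_table"
  )
}

#' @export
print.consumer_table <- function(x, ...) {
  cats <- unique(x$intake$category)
  cat("<consumer_table> ", nrow(x$subjects), " subjects, ",
      length(cats), " food categor", if (length(cats) == 1L) "y" else "ies",
      " (", paste(utils::head(cats, 3), collapse = ", "),
      if (length(cats) > 3) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Number of subjects in a consumer table
#' @param x a `consumer_table`.
#' @export
n_subjects <- function(x) {
  stopifnot(inherits(x, "consumer_table"))
  nrow(x$subjects)
}

# coerce a column to numeric, naming the first malformed row
.as_num <- function(col, name, rows = seq_along(col)) {
  if (is.numeric(col)) return(col)
  out <- suppressWarnings(as.numeric(col))
  bad <- which(is.na(out) & !is.na(col) & trimws(as.character(col)) != "" &
                 !toupper(trimws(as.character(col))) %in% "NA")
  if (length(bad) > 0L) {
    stop("malformed value in column '", name, "' at row ", rows[bad[1L]],
         ": '", col[bad[1L]], "'")
  }
  out
}

#' Read a consumption survey CSV into a consumer table
#'
#' Expects one row per individual x survey day x food item with columns
#' `subject_id`, `body_weight_kg`, `age_y`, `category`, `subcategory`,
#' `amount_g`, `day`. Chronic consumption is the per-subject arithmetic
#' mean of daily totals over the surveyed days; days on which a subject
#' consumed nothing from a category count as 0 g/day, so the per-subject
#' divisor is the number of survey days, not the number of rows.
#'
#' Subjects with missing or non-positive body weight are dropped with a
#' logged count; with `adult_only = TRUE` subjects younger than 18 are
#' dropped as well. Subjects left without any consumption rows (e.g. after
#' `category_filter`) are retained as non-consumers.
#'
#' @param path CSV file path (comma-separated, UTF-8, header row, "."
#'   decimal separator).
#' @param category_filter optional character vector: keep only these
#'   `category` values.
#' @param adult_only drop subjects with age < 18 years.
#' @param survey_days number of survey days per subject; default is the
#'   number of distinct `day` values observed in the whole file.
#' @param quiet suppress the dropped-subject messages.
#'
#' @return A [consumer_table].
#' @export
read_consumption <- function(path, category_filter = NULL, adult_only = FALSE,
                             survey_days = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "body_weight_kg", "age_y", "category",
            "subcategory", "amount_g", "day")
  if (length(miss <- setdiff(need, names(raw))) > 0L) {
    stop("consumption file is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop("empty consumer table: file has no records")
  raw$body_weight_kg <- .as_num(raw$body_weight_kg, "body_weight_kg")
  raw$age_y <- .as_num(raw$age_y, "age_y")
  raw$amount_g <- .as_num(raw$amount_g, "amount_g")
  if (any(bad <- !is.finite(raw$amount_g))) {
    stop("malformed value in column 'amount_g' at row ", which(bad)[1L])
  }
  if (any(raw$amount_g < 0)) {
    stop("negative amount_g at row ", which(raw$amount_g < 0)[1L])
  }

  first <- !duplicated(raw$subject_id)
  subjects <- data.frame(subject_id = as.character(raw$subject_id[first]),
                         body_weight = raw$body_weight_kg[first],
                         age = raw$age_y[first],
                         stringsAsFactors = FALSE)
  drop_bw <- !is.finite(subjects$body_weight) | subjects$body_weight <= 0
  if (any(drop_bw) && !quiet) {
    message("Dropped ", sum(drop_bw),
            " subject(s) with missing or non-positive body weight")
  }
  subjects <- subjects[!drop_bw, , drop = FALSE]
  if (adult_only) {
    minor <- is.na(subjects$age) | subjects$age < 18
    if (any(minor) && !quiet) {
      message("Dropped ", sum(minor), " subject(s) younger than 18 years")
    }
    subjects <- subjects[!minor, , drop = FALSE]
  }
  if (nrow(subjects) == 0L) {
    stop("empty consumer table: all subjects were dropped")
  }

  if (is.null(survey_days)) survey_days <- length(unique(raw$day))
  stopifnot(all(survey_days >= 1))
  days_of <- function(id) {
    if (length(survey_days) == 1L && is.null(names(survey_days))) {
      survey_days
    } else {
      survey_days[[id]]
    }
  }

  rows <- raw[raw$subject_id %in% subjects$subject_id, , drop = FALSE]
  if (!is.null(category_filter)) {
    rows <- rows[rows$category %in% category_filter, , drop = FALSE]
  }
  if (nrow(rows) > 0L) {
    agg <- stats::aggregate(
      amount_g ~ subject_id + category + subcategory, data = rows,
      FUN = sum, na.action = stats::na.pass
    )
    agg$amount <- agg$amount_g /
      vapply(as.character(agg$subject_id), days_of, numeric(1))
    intake <- data.frame(subject_id = as.character(agg$subject_id),
                         category = agg$category,
                         subcategory = agg$subcategory,
                         amount = agg$amount,
                         stringsAsFactors = FALSE)
  } else {
    intake <- data.frame(subject_id = character(), category = character(),
                         subcategory = character(), amount = numeric(),
                         stringsAsFactors = FALSE)
  }
  consumer_table(subjects, intake, survey_days = survey_days)
}

#' Total mean daily consumption of a category, per subject
#'
#' The per-subject category total is the sum of its subcategory means; the
#' result has one entry per subject (zero for non-consumers).
#'
#' @param consumers a [consumer_table].
#' @param category category label.
#' @return Named numeric vector (g/day), names are subject ids.
#' @export
category_consumption <- function(consumers, category) {
  stopifnot(inherits(consumers, "consumer_table"))
  out <- stats::setNames(numeric(n_subjects(consumers)),
                         consumers$subjects$subject_id)
  it <- consumers$intake
  it <- it[it$category == category, , drop = FALSE]
  if (nrow(it) > 0L) {
    tot <- tapply(it$amount, it$subject_id, sum)
    out[names(tot)] <- as.numeric(tot)
  }
  out
}

#' Construct an occurrence table
#'
#' One row per analysed food sample with its contaminant concentration,
#' limit of detection (LOD) and censoring flag. Subcategory labels define
#' the strata used by the stratified bootstrap; an optional mapping
#' collapses fine labels (e.g. individual seed-oil types) into strata.
#'
#' @param df data.frame with columns `sample_id`, `category`,
#'   `subcategory`, `value` (concentration, ug/g), `lod` (ug/g) and
#'   `censored` (logical). Extra columns are carried along.
#' @param stratum_map optional data.frame with columns `raw_label`,
#'   `stratum`; subcategory labels found in `raw_label` are replaced by
#'   the corresponding `stratum` (the original label is kept in a
#'   `raw_label` column).
#'
#' @return A data.frame of class `occurrence_table`. Censored values are
#'   left as read; substitution under an LOD scenario is an explicit step
#'   ([apply_lod_scenario()]).
#' @export
occurrence_table <- function(df, stratum_map = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("sample_id", "category", "subcategory", "value", "lod", "censored")
  if (length(miss <- setdiff(need, names(df))) > 0L) {
    stop("occurrence data is missing column(s): ", paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$censored <- as.logical(df$censored)
  if (anyNA(df$censored)) stop("censored flags must be TRUE/FALSE")
  if (any(bad <- !is.finite(df$value) | df$value < 0)) {
    stop("invalid concentration for sample_id ", df$sample_id[which(bad)[1L]],
         ": values must be finite and >= 0")
  }
  if (any(bad <- !is.finite(df$lod) | df$lod <= 0)) {
    stop("invalid LOD for sample_id ", df$sample_id[which(bad)[1L]],
         ": LOD must be finite and > 0")
  }
  if (!is.null(stratum_map)) {
    stopifnot(is.data.frame(stratum_map),
              all(c("raw_label", "stratum") %in% names(stratum_map)))
    df$raw_label <- df$subcategory
    m <- match(df$subcategory, stratum_map$raw_label)
    df$subcategory[!is.na(m)] <- stratum_map$stratum[m[!is.na(m)]]
  }
  if (is.null(df$substituted)) df$substituted <- FALSE
  rownames(df) <- NULL
  class(df) <- c("occurrence_table", "data.frame")
  df
}

#' @export
print.occurrence_table <- function(x, ...) {
  tab <- table(x$subcategory)
  cat("<occurrence_table> ", nrow(x), " samples in ", length(tab),
      " strata (", paste(names(tab), tab, sep = ":", collapse = ", "),
      "); ", sum(x$censored), " censored\n", sep = "")
  invisible(x)
}

#' Stratum index of an occurrence table
#'
#' @param table an `occurrence_table`.
#' @param category optional category label to restrict to.
#' @return Named list mapping each subcategory to the row indices of its
#'   samples (indices into the full table).
#' @export
occurrence_strata <- function(table, category = NULL) {
  stopifnot(inherits(table, "occurrence_table"))
  keep <- if (is.null(category)) seq_len(nrow(table)) else
    which(table$category == category)
  split(keep, table$subcategory[keep])
}

#' Read an occurrence CSV
#'
#' Columns: `sample_id`, `category`, `subcategory`, `value_ug_g`,
#' `lod_ug_g`, `censored`.
#'
#' @inheritParams occurrence_table
#' @param path CSV file path.
#' @return An [occurrence_table].
#' @export
read_occurrence <- function(path, stratum_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "category", "subcategory", "value_ug_g",
            "lod_ug_g", "censored")
  if (length(miss <- setdiff(need, names(raw))) > 0L) {
    stop("occurrence file is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- data.frame(sample_id = raw$sample_id,
                   category = raw$category,
                   subcategory = raw$subcategory,
                   value = .as_num(raw$value_ug_g, "value_ug_g"),
                   lod = .as_num(raw$lod_ug_g, "lod_ug_g"),
                   censored = raw$censored,
                   stringsAsFactors = FALSE)
  occurrence_table(df, stratum_map = stratum_map)
}

#' Write an occurrence table to CSV
#' @param table an [occurrence_table].
#' @param path output path.
#' @param overwrite allow replacing an existing file.
#' @export
write_occurrence <- function(table, path, overwrite = FALSE) {
  stopifnot(inherits(table, "occurrence_table"))
  if (file.exists(path) && !overwrite) {
    stop("refusing to overwrite existing file: ", path,
         " (set overwrite = TRUE)")
  }
  out <- data.frame(sample_id = table$sample_id,
                    category = table$category,
                    subcategory = table$subcategory,
                    # %.17g keeps the round trip bit-exact
                    value_ug_g = sprintf("%.17g", table$value),
                    lod_ug_g = sprintf("%.17g", table$lod),
                    censored = table$censored)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' A weighting scheme over occurrence strata
#'
#' Non-negative weights over subcategories, summing to one; the engine of
#' the weighted-mean (wsOIM) estimators.
#'
#' @param weights named numeric vector; names are subcategory labels.
#' @param label free-text tag (e.g. `"w_SO"`, `"w*"`).
#' @return An object of class `weight_scheme`.
#' @export
weight_scheme <- function(weights, label = "w") {
  if (is.null(names(weights)) || any(names(weights) == "")) {
    stop("weights must be a fully named numeric vector")
  }
  if (anyDuplicated(names(weights))) stop("duplicate subcategory in weights")
  if (any(!is.finite(weights) | weights < 0)) {
    stop("weights must be finite and >= 0")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1 (got ", format(sum(weights)), ")")
  }
  structure(list(weights = weights, label = label), class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("<weight_scheme> ", x$label, ": ",
      paste(names(x$weights), format(x$weights, digits = 3),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write an exposure estimate to JSON
#'
#' Serializes the deterministic percentiles, any bootstrap confidence
#' intervals, and the method/seed/B provenance as flat JSON. Numeric
#' fields are written at full precision so that a read/write round trip
#' is bit-exact. A DE-only estimate (no bootstrap run) omits the CI
#' fields.
#'
#' @param result an `exposure_estimate` (see [deterministic_estimate()],
#'   [probabilistic_estimate()]).
#' @param path output path (`.json`).
#' @param overwrite allow replacing an existing file.
#' @export
write_estimates <- function(result, path, overwrite = FALSE) {
  stopifnot(inherits(result, "exposure_estimate"))
  if (file.exists(path) && !overwrite) {
    stop("refusing to overwrite existing file: ", path,
         " (set overwrite = TRUE)")
  }
  tab <- data.frame(probability = result$probs,
                    de_ug_per_kg_bw_day = unname(result$de))
  if (!is.null(result$ci)) {
    tab$ci_lower_ug_per_kg_bw_day <- unname(result$ci[, "lower"])
    tab$ci_upper_ug_per_kg_bw_day <- unname(result$ci[, "upper"])
  }
  obj <- list(
    method = result$method$name,
    weight_label = if (!is.null(result$method$weights))
      result$method$weights$label else NULL,
    weights = if (!is.null(result$method$weights))
      as.list(result$method$weights$weights) else NULL,
    B = result$B,
    seeds = result$seeds,
    level = result$level,
    units = "ug/kg bw/day",
    percentiles = tab
  )
  # I(17) significant digits: doubles survive a write/read round trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' Read an exposure estimate written by [write_estimates()]
#' @param path JSON file path.
#' @return An `exposure_estimate` (percentiles, CIs and provenance; the
#'   bootstrap replicates themselves are not serialized).
#' @export
read_estimates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- if (!is.null(obj$weights))
    weight_scheme(unlist(obj$weights), label = obj$weight_label %||% "w")
  method <- method_spec(obj$method, weights = w)
  tab <- obj$percentiles
  ci <- NULL
  if (!is.null(tab$ci_lower_ug_per_kg_bw_day)) {
    ci <- cbind(lower = tab$ci_lower_ug_per_kg_bw_day,
                upper = tab$ci_upper_ug_per_kg_bw_day)
  }
  new_exposure_estimate(
    method = method, probs = tab$probability,
    de = stats::setNames(tab$de_ug_per_kg_bw_day,
                         .prob_names(tab$probability)),
    ci = ci,
    level = if (is.null(obj$level) || length(obj$level) == 0L) NA_real_
            else obj$level,
    B = if (is.null(obj$B) || length(obj$B) == 0L) NA_integer_ else obj$B,
    seeds = if (length(obj$seeds)) unlist(obj$seeds) else NULL
  )
}
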