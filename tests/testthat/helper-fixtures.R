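# In-code fixtures shared across the suite.

# write a day-level consumption survey CSV and return its path
write_survey_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE)
  path
}

survey_row <- function(subject_id, bw, age, subcategory, amount, day,
                       category = "Vegetable Oil") {
  data.frame(subject_id = subject_id, body_weight_kg = bw, age_y = age,
             category = category, subcategory = subcategory,
             amount_g = amount, day = day, stringsAsFactors = FALSE)
}

# a small two-stratum occurrence fixture with well-separated means
toy_occurrence <- function(values_a = c(0.1, 0.2, 0.3),
                           values_b = c(1.5, 1.7, 1.9),
                           category = "Vegetable Oil") {
  n <- length(values_a) + length(values_b)
  occurrence_table(data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    category = category,
    subcategory = rep(c("A", "B"), c(length(values_a), length(values_b))),
    value = c(values_a, values_b),
    lod = 0.035,
    censored = FALSE,
    stringsAsFactors = FALSE
  ))
}

# a deterministic consumer table built directly from vectors
toy_consumers <- function(bw, amount, subcategory = NULL,
                          category = "Vegetable Oil") {
  n <- length(bw)
  subjects <- data.frame(subject_id = sprintf("c%02d", seq_len(n)),
                         body_weight = bw, age = 40,
                         stringsAsFactors = FALSE)
  if (is.null(subcategory)) subcategory <- rep(NA_character_, n)
  intake <- data.frame(subject_id = subjects$subject_id,
                       category = category, subcategory = subcategory,
                       amount = amount, stringsAsFactors = FALSE)
  consumer_table(subjects, intake)
}
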