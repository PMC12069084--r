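test_that("day averaging yields mean daily consumption over survey days", {
  rows <- rbind(survey_row("A", 70, 40, "OO", 10, 1),
                survey_row("A", 70, 40, "OO", 30, 2))
  ct <- read_consumption(write_survey_csv(rows), quiet = TRUE)
  expect_equal(ct$intake$amount, 20)
  expect_equal(unname(category_consumption(ct, "Vegetable Oil")["A"]), 20)

  # zero-consumption days count as 0 g/day: a single consumption day in a
  # two-day survey halves the mean
  rows2 <- rbind(survey_row("A", 70, 40, "OO", 10, 1),
                 survey_row("B", 60, 30, "OO", 8, 2))
  ct2 <- read_consumption(write_survey_csv(rows2), quiet = TRUE)
  amt <- setNames(ct2$intake$amount, ct2$intake$subject_id)
  expect_equal(unname(amt["A"]), 5)
  expect_equal(unname(amt["B"]), 4)
})

test_that("day averaging is invariant to row order within subject", {
  rows <- rbind(survey_row("A", 70, 40, "OO", 10, 1),
                survey_row("A", 70, 40, "SO", 4, 1),
                survey_row("A", 70, 40, "OO", 30, 2),
                survey_row("B", 60, 30, "OO", 12, 1))
  ct1 <- read_consumption(write_survey_csv(rows), quiet = TRUE)
  ct2 <- read_consumption(write_survey_csv(rows[c(4, 3, 1, 2), ]),
                          quiet = TRUE)
  o <- function(x) x$intake[order(x$intake$subject_id, x$intake$subcategory), ]
  expect_equal(o(ct1), o(ct2), ignore_attr = TRUE)
})

test_that("subjects with missing body weight are dropped and counted", {
  rows <- rbind(survey_row("A", 70, 40, "OO", 10, 1),
                survey_row("B", NA, 40, "OO", 10, 1),
                survey_row("C", 55, 40, "OO", 10, 1))
  path <- write_survey_csv(rows)
  expect_message(ct <- read_consumption(path),
                 "Dropped 1 subject")
  expect_equal(n_subjects(ct), 2)
  expect_setequal(ct$subjects$subject_id, c("A", "C"))
})

test_that("adult filtering drops minors and is idempotent", {
  rows <- rbind(survey_row("A", 70, 40, "OO", 10, 1),
                survey_row("B", 50, 12, "OO", 10, 1))
  path <- write_survey_csv(rows)
  ct1 <- read_consumption(path, adult_only = TRUE, quiet = TRUE)
  expect_equal(ct1$subjects$subject_id, "A")
  # re-applying the filter to an already-adult table changes nothing
  p2 <- write_survey_csv(rows[rows$subject_id == "A", ])
  ct2 <- read_consumption(p2, adult_only = TRUE, quiet = TRUE)
  expect_equal(ct1$subjects, ct2$subjects, ignore_attr = TRUE)
})

test_that("degenerate consumption files are rejected with clear errors", {
  empty <- write_survey_csv(survey_row("A", 70, 40, "OO", 1, 1)[0, ])
  expect_error(read_consumption(empty), "empty consumer table")

  all_dropped <- write_survey_csv(survey_row("A", NA, 40, "OO", 1, 1))
  expect_error(suppressMessages(read_consumption(all_dropped)),
               "all subjects were dropped")

  bad <- survey_row("A", 70, 40, "OO", 1, 1)
  bad$amount_g <- "ten"
  expect_error(read_consumption(write_survey_csv(bad)),
               "malformed value in column 'amount_g' at row 1")
})

test_that("occurrence tables validate values and index strata", {
  df <- data.frame(sample_id = c("x1", "x2", "x3"),
                   category = "VO", subcategory = c("A", "B", "C"),
                   value = c(0.1, 0.2, 0.3), lod = 0.035, censored = FALSE)
  tab <- occurrence_table(df)
  st <- occurrence_strata(tab)
  expect_length(st, 3)
  expect_true(all(lengths(st) == 1))

  df$value[2] <- -1
  expect_error(occurrence_table(df), "sample_id x2")
  df$value[2] <- 0.2
  df$lod[3] <- 0
  expect_error(occurrence_table(df), "sample_id x3")
})

test_that("occurrence CSV round trip preserves every field", {
  tab <- seed_oil_fixture(rng_seed = 11)
  path <- tempfile(fileext = ".csv")
  write_occurrence(tab, path)
  back <- read_occurrence(path)
  expect_identical(back$sample_id, tab$sample_id)
  expect_identical(back$value, tab$value)
  expect_identical(back$lod, tab$lod)
  expect_identical(back$censored, tab$censored)
  expect_error(write_occurrence(tab, path), "refusing to overwrite")
})

test_that("a stratum map collapses fine oil types into one stratum", {
  tab <- seed_oil_fixture(rng_seed = 3)
  expect_equal(nrow(tab), 14)
  expect_equal(unique(tab$subcategory), "SO")
  counts <- table(tab$raw_label)
  expect_equal(unname(counts[c("corn oil", "mixed seeds oil", "peanut oil",
                               "rice oil", "soybean oil", "sunflower oil")]),
               c(3, 2, 3, 1, 1, 4), ignore_attr = TRUE)
  expect_true(all(tab$value > 0))
})

test_that("weight schemes enforce non-negativity and unit sum", {
  expect_s3_class(weight_scheme(c(A = 0.25, B = 0.75)), "weight_scheme")
  expect_error(weight_scheme(c(A = 0.5, B = 0.6)), "sum to 1")
  expect_error(weight_scheme(c(A = -0.1, B = 1.1)), ">= 0")
  expect_error(weight_scheme(c(0.5, 0.5)), "named")
})

test_that("estimate serialization round-trips bit-exactly", {
  cons <- toy_consumers(bw = c(50, 100), amount = c(10, 40))
  occ <- toy_occurrence()
  pe <- probabilistic_estimate(cons, occ, method_spec("sOIM"), B = 50,
                               seeds = c(5, 6))
  path <- tempfile(fileext = ".json")
  write_estimates(pe, path)
  back <- read_estimates(path)
  expect_identical(unname(back$de), unname(pe$de))
  expect_identical(unname(back$ci[, "lower"]), unname(pe$ci[, "lower"]))
  expect_identical(unname(back$ci[, "upper"]), unname(pe$ci[, "upper"]))
  expect_identical(back$B, pe$B)
  expect_identical(back$method$name, "sOIM")
  expect_error(write_estimates(pe, path), "refusing to overwrite")

  # DE-only estimates omit the CI fields
  de <- deterministic_estimate(cons, occ)
  p2 <- tempfile(fileext = ".json")
  write_estimates(de, p2)
  txt <- paste(readLines(p2), collapse = "")
  expect_false(grepl("ci_lower", txt))
  expect_null(read_estimates(p2)$ci)
})
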