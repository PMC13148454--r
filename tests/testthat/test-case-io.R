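test_that("shipped example case files parse and compute the documented results", {
  high <- read_case(system.file("extdata/high_risk_spine.json",
                                package = "cascade"))
  res <- cascade_decide(high)
  expect_equal(res$threshold, 78000)
  expect_identical(res$verdict, "reconstruction_favored")

  low <- read_case(system.file("extdata/low_risk.json", package = "cascade"))
  res_low <- cascade_decide(low)
  expect_equal(res_low$threshold, 5250)
  expect_identical(res_low$verdict, "closure_favored")
  expect_false(res_low$applicability$applicable)
})

test_that("validation collects all violations at once, not just the first", {
  raw <- list(factors = list("hardware", "bogus"), fct = 5, delta_c = -1,
              policy = "median", stray = 1)
  err <- tryCatch(validate_case(raw), error = conditionMessage)
  expect_match(err, "bogus")
  expect_match(err, "`fct` must be 1-4")
  expect_match(err, "`delta_c` must be a single non-negative number")
  expect_match(err, "midpoint, lower, upper")
  expect_match(err, "unknown field\\(s\\): stray")
})

test_that("overrides and flags are schema-checked", {
  base <- list(factors = list("hardware"), fct = 2, delta_c = 1000)
  expect_s3_class(validate_case(base), "cascade_case")
  expect_error(validate_case(c(base, list(overrides = list(p1 = 2)))),
               "\\[0, 1\\]")
  expect_error(validate_case(c(base, list(overrides = list(p1 = 0.1, p2 = 0.2)))),
               "no absolute risk reduction")
  expect_error(validate_case(c(base, list(overrides = list(gamma = 1)))),
               "unknown override")
  expect_error(validate_case(c(base, list(applicability_flags = list(x = TRUE)))),
               "unknown applicability flag")
  expect_error(validate_case(c(base, list(documentation = list(notes = TRUE)))),
               "unknown documentation element")
  expect_error(validate_case(c(base, list(documentation = list(crs_drivers = "yes")))),
               "true/false")
})

test_that("malformed files and missing files fail with parse errors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", path)
  expect_error(read_case(path), "could not parse")
  expect_error(read_case(file.path(tempdir(), "absent.json")), "not found")
})

test_that("cases round-trip through JSON and YAML files", {
  case <- high_risk_case(case_id = "rt")
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_case(case, path)
    back <- read_case(path)
    expect_identical(back$factors, case$factors)
    expect_identical(back$fct, case$fct)
    expect_equal(back$delta_c, case$delta_c)
    expect_equal(back$overrides, case$overrides)
  }
})

test_that("documentation report maps the five elements without gating computation", {
  full <- cascade_case(
    factors = "hardware", fct = 2, delta_c = 1000,
    documentation = list(crs_drivers = TRUE, expected_failure_trajectory = TRUE,
                         reason_routine_closure_inadequate = TRUE,
                         reconstructive_mechanism = TRUE,
                         anticipated_prevented_events = TRUE))
  rep_full <- documentation_report(full)
  expect_identical(attr(rep_full, "n_present"), 5L)

  partial <- cascade_case(
    factors = "hardware", fct = 2, delta_c = 1000,
    documentation = list(crs_drivers = TRUE))
  rep_partial <- documentation_report(partial)
  expect_identical(attr(rep_partial, "n_present"), 1L)
  missing_row <- rep_partial[rep_partial$element == "expected_failure_trajectory", ]
  expect_false(missing_row$present)
  expect_match(missing_row$model_function, "failure cost tier")

  empty <- cascade_case(factors = "hardware", fct = 2, delta_c = 1000)
  expect_identical(attr(documentation_report(empty), "n_present"), 0L)
  expect_s3_class(cascade_decide(empty), "cascade_decision")  # still computes
})

test_that("CLI subcommands produce stable JSON and CSV on stdout", {
  high_path <- system.file("extdata/high_risk_spine.json", package = "cascade")

  out <- capture.output(status <- cascade_cli(c("score", high_path, "--json")))
  expect_identical(status, 0L)
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_identical(parsed$crs, 8L)
  expect_identical(parsed$tier, "High")
  expect_true(parsed$applicability$applicable)

  out <- capture.output(status <- cascade_cli(c("decide", high_path, "--json")))
  expect_identical(status, 0L)
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(parsed$threshold, 78000)
  expect_identical(parsed$verdict, "reconstruction_favored")
  # stable field order
  expect_identical(names(parsed)[1:4], c("case_id", "crs", "tier",
                                         "applicability"))

  out <- capture.output(status <- cascade_cli(c("sensitivity", "--grid")))
  expect_identical(status, 0L)
  grid_csv <- utils::read.csv(textConnection(out), check.names = FALSE)
  expect_identical(nrow(grid_csv), 4L)
  expect_equal(grid_csv[3, "dP=0.13"], 78000)

  out <- capture.output(status <- cascade_cli(
    c("sensitivity", "--one-way", high_path, "--param", "c",
      "--values", "600000,800000")))
  expect_identical(status, 0L)
  sweep_csv <- utils::read.csv(textConnection(out))
  expect_equal(sweep_csv$threshold, c(78000, 104000))

  out <- capture.output(status <- cascade_cli(
    c("cohort", "--n", "100", "--baseline", "0.15:0.25",
      "--intervention", "0.05:0.10", "--cost", "400000:1000000", "--json")))
  expect_identical(status, 0L)
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(parsed$avoided_exposure$low, 4000000)
  expect_equal(parsed$avoided_exposure$high, 20000000)

  out <- capture.output(status <- cascade_cli(
    c("psa", high_path, "--seed", "42", "--n", "2000", "--json")))
  expect_identical(status, 0L)
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_true(parsed$probability_favored >= 0 && parsed$probability_favored <= 1)
  expect_identical(parsed$seed, 42L)
})

test_that("CLI reports usage errors with non-zero status, never for verdicts", {
  expect_identical(suppressMessages(cascade_cli(character())), 1L)
  expect_identical(suppressMessages(cascade_cli("frobnicate")), 1L)
  expect_identical(suppressMessages(cascade_cli(c("score", "/no/such.json"))),
                   1L)
  # closure-favored analysis still exits 0: the verdict is data
  low_path <- system.file("extdata/low_risk.json", package = "cascade")
  out <- capture.output(status <- cascade_cli(c("decide", low_path, "--json")))
  expect_identical(status, 0L)
  expect_identical(jsonlite::fromJSON(paste(out, collapse = "\n"))$verdict,
                   "closure_favored")
})

test_that("CLI generate writes decidable case files", {
  dir <- withr::local_tempdir()
  expect_identical(
    suppressMessages(cascade_cli(c("generate", "--n", "5", "--seed", "7",
                                   "--out", dir))),
    0L)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(manifest), 5L)
  first <- file.path(dir, paste0(manifest$case_id[1], ".json"))
  expect_s3_class(cascade_decide(first), "cascade_decision")
})
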