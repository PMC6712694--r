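fast_cfg <- function(seed = 1, ...) {
  comparison_config(reps = 60, max_components = 5, seed = seed, ...)
}

test_that("the comparison report contains every requested pattern", {
  ds <- generate_spectrum_dataset(synthetic_config(n_participants = 200,
                                                   seed = 12))
  rep <- run_comparison(ds$profiles, ds$outcome, fast_cfg())
  expect_setequal(names(rep$patterns),
                  c("bivariate", "mlr_raw", "mlr_ilr", "mpa_raw", "mpa_clr"))
  for (p in rep$patterns) expect_equal(nrow(p), 23)
  expect_length(rep$failures, 0)
  expect_s3_class(rep$correlations, "closure_report")
})

test_that("the traditional description yields four-bin patterns", {
  ds <- generate_spectrum_dataset(
    synthetic_config(n_participants = 200,
                     scheme = bin_scheme("traditional"),
                     effect_vector = c(0.1, 0, -0.2, -0.4), seed = 13))
  rep <- run_comparison(ds$profiles, ds$outcome, fast_cfg())
  expect_equal(unique(vapply(rep$patterns, nrow, integer(1))),
               4L, ignore_attr = TRUE)
})

test_that("regression on closed data fails with singularity while other models run", {
  rep <- end_to_end(synth = synthetic_config(n_participants = 150,
                                             scheme = small_scheme(),
                                             effect_vector = rep(0, 6)),
                    comparison = fast_cfg(use_proportions = TRUE),
                    seed = 3)
  expect_named(rep$failures, "mlr_raw")
  expect_match(rep$failures[["mlr_raw"]], "singular")
  expect_setequal(names(rep$patterns),
                  c("bivariate", "mlr_ilr", "mpa_raw", "mpa_clr"))
})

test_that("clr correlations carry the negative closure bias in every row", {
  ds <- generate_spectrum_dataset(synthetic_config(n_participants = 300,
                                                   seed = 8))
  clr <- clr_transform(close_composition(ds$profiles))
  v <- cov(clr)
  # rows of the clr covariance sum to zero: off-diagonals absorb -var_j
  expect_lt(max(abs(rowSums(v))), 1e-10)
  expect_equal(unname(rowSums(v) - diag(v)), unname(-diag(v)),
               tolerance = 1e-10)
})

test_that("regression on the spectrum is less stable than the multivariate pattern", {
  rep <- end_to_end(synth = synthetic_config(n_participants = 300),
                    comparison = fast_cfg(), seed = 5)
  rel_width <- function(p) {
    mean(p$ci_high - p$ci_low) / sd(p$estimate)
  }
  expect_gt(rel_width(rep$patterns$mlr_raw),
            rel_width(rep$patterns$mpa_raw))
})

test_that("rendering writes one CSV per pattern plus combined outputs", {
  ds <- generate_spectrum_dataset(small_config(seed = 2))
  rep <- run_comparison(ds$profiles, ds$outcome,
                        fast_cfg(seed = 2))
  out1 <- file.path(tempdir(), "report_a")
  out2 <- file.path(tempdir(), "report_b")
  render_report(rep, out1)
  render_report(rep, out2)
  csvs <- list.files(out1, pattern = "^pattern_.*csv$")
  expect_length(csvs, length(rep$patterns))
  combined <- utils::read.csv(file.path(out1, "patterns_combined.csv"))
  expect_equal(nrow(combined), length(rep$patterns) * 6)
  # deterministic rendering: identical bytes
  for (f in c(csvs, "patterns_combined.csv", "summary.txt")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("the full pipeline is deterministic under a fixed master seed", {
  a <- end_to_end(synth = small_config(), comparison = fast_cfg(), seed = 10)
  b <- end_to_end(synth = small_config(), comparison = fast_cfg(), seed = 10)
  expect_identical(a$patterns, b$patterns)
  c <- end_to_end(synth = small_config(), comparison = fast_cfg(), seed = 11)
  expect_false(identical(a$patterns$mpa_raw$estimate,
                         c$patterns$mpa_raw$estimate))
})

test_that("the panel-derived composite can drive the pipeline end to end", {
  rep <- end_to_end(synth = small_config(n = 150),
                    comparison = comparison_config(
                      models = c("bivariate", "mpa_raw"),
                      reps = 40, max_components = 4),
                    seed = 21, outcome_source = "panel")
  expect_setequal(names(rep$patterns), c("bivariate", "mpa_raw"))
  expect_true(all(is.finite(rep$patterns$mpa_raw$estimate)))
})
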