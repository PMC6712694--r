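#' Configuration for the model comparison
#'
#' Collects every tunable of the comparison in one place: which analytic
#' approaches to run, the Monte Carlo resampling settings (1000 repetitions
#' with a 50% holdout by default), the largest PLS model size tried, the
#' confidence level, the zero-replacement value for the compositional
#' transforms, and the seed.
#'
#' @param models Subset of `"bivariate"`, `"mlr_raw"`, `"mlr_ilr"`,
#'   `"mpa_raw"`, `"mpa_clr"`.
#' @param reps Monte Carlo repetitions.
#' @param holdout Validation fraction per repetition.
#' @param max_components Largest PLS size offered to [monte_carlo_cv()].
#' @param conf Confidence level for all intervals.
#' @param delta Zero-replacement value ([close_composition()]).
#' @param seed Integer seed for the resampling stages.
#' @param use_proportions Analyse proportions of wear time instead of
#'   min/day (the compositional transforms are invariant; the raw-data
#'   models are not).
#' @return A `comparison_config` list.
#' @export
comparison_config <- function(models = c("bivariate", "mlr_raw", "mlr_ilr",
                                         "mpa_raw", "mpa_clr"),
                              reps = 1000, holdout = 0.5,
                              max_components = 10, conf = 0.95,
                              delta = NULL, seed = 1L,
                              use_proportions = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  structure(list(models = models, reps = reps, holdout = holdout,
                 max_components = max_components, conf = conf,
                 delta = delta, seed = as.integer(seed),
                 use_proportions = isTRUE(use_proportions)),
            class = "comparison_config")
}

.fit_mpa <- function(x, y, config, seed_cv, seed_ci, tag) {
  mc <- monte_carlo_cv(x, y, reps = config$reps, holdout = config$holdout,
                       max_components = config$max_components,
                       seed = seed_cv)
  srci <- sr_confidence_intervals(x, y, mc$n_components,
                                  reps = config$reps,
                                  holdout = config$holdout,
                                  seed = seed_ci, conf = config$conf)
  pat <- .association_pattern(srci$variable, srci$sr, srci$ci_low,
                              srci$ci_high, tag,
                              attr(srci, "fitted_r2"))
  attr(pat, "cv_q2") <- mc$q2
  attr(pat, "n_components") <- mc$n_components
  pat
}

#' Run the full comparison of analytic approaches
#'
#' Applies, to one profile matrix and outcome, the bivariate correlations
#' and the four association models -- multiple linear regression on raw and
#' on pivot-coordinate ilr data, and PLS-based multivariate pattern
#' analysis (selectivity ratios with resampling CIs) on raw and on clr
#' data -- plus the raw-versus-clr correlation-structure diagnostics. A
#' model that fails (e.g. the expected singularity of regression on closed
#' data) is recorded under `failures` and the run continues. Deterministic
#' for a fixed config: the config seed fans out to the two resampling
#' stages of each multivariate pattern analysis by fixed offsets.
#'
#' @param profiles n x D matrix of bin minutes (columns named by bin).
#' @param outcome Numeric outcome (e.g. composite risk score), length n.
#' @param config A [comparison_config()].
#' @return A `comparison_report`: list with `patterns` (named list of
#'   `association_pattern` tibbles), `failures` (named character),
#'   `correlations` (a [closure_correlation_report()]), and `meta`.
#' @export
run_comparison <- function(profiles, outcome,
                           config = comparison_config()) {
  stopifnot(inherits(config, "comparison_config"))
  x <- as.matrix(profiles)
  y <- as.numeric(outcome)
  if (nrow(x) != length(y)) {
    stop("profiles and outcome sizes differ", call. = FALSE)
  }
  patterns <- list()
  failures <- character(0)
  grab <- function(tag, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[tag]] <<- conditionMessage(res)
    } else {
      patterns[[tag]] <<- res
    }
  }
  clr_data <- tryCatch(clr_transform(close_composition(x, config$delta)),
                       error = function(e) e)

  if ("bivariate" %in% config$models) {
    grab("bivariate", bivariate_correlations(x, y, config$conf))
  }
  if ("mlr_raw" %in% config$models) {
    grab("mlr_raw", fit_mlr(x, y, config$conf))
  }
  if ("mlr_ilr" %in% config$models) {
    grab("mlr_ilr", fit_ilr_mlr(x, y, config$conf, config$delta))
  }
  if ("mpa_raw" %in% config$models) {
    grab("mpa_raw", .fit_mpa(x, y, config, config$seed + 10L,
                             config$seed + 11L, "mpa_raw"))
  }
  if ("mpa_clr" %in% config$models) {
    if (inherits(clr_data, "error")) {
      failures[["mpa_clr"]] <- conditionMessage(clr_data)
    } else {
      grab("mpa_clr", .fit_mpa(clr_data, y, config, config$seed + 20L,
                               config$seed + 21L, "mpa_clr"))
    }
  }
  correlations <- if (inherits(clr_data, "error")) NULL else {
    closure_correlation_report(x, clr_data)
  }
  structure(list(
    patterns = patterns, failures = failures, correlations = correlations,
    meta = list(config = config, n = nrow(x), bins = colnames(x),
                version = as.character(utils::packageVersion("actipatterns")))
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> n = ", x$meta$n, ", ",
      length(x$meta$bins), " bins\n", sep = "")
  for (tag in names(x$patterns)) {
    p <- x$patterns[[tag]]
    r2 <- unique(p$model_r2)
    cat("  ", format(tag, width = 10), " R2 = ",
        ifelse(is.na(r2[1L]), "-", round(r2[1L], 3)), sep = "")
    q2 <- attr(p, "cv_q2")
    if (!is.null(q2)) cat("  Q2 = ", round(q2, 3), " (",
                          attr(p, "n_components"), " comp.)", sep = "")
    cat("\n")
  }
  for (tag in names(x$failures)) {
    cat("  ", format(tag, width = 10), " FAILED: ",
        substr(x$failures[[tag]], 1, 60), "...\n", sep = "")
  }
  invisible(x)
}

#' Write a comparison report to disk
#'
#' One CSV per association pattern, a combined long-format CSV, the raw and
#' clr correlation matrices, and a plain-text summary. Optionally one
#' estimate-with-CI plot per pattern (requires ggplot2). Re-rendering the
#' same report reproduces identical file contents.
#'
#' @param report A [run_comparison()] result.
#' @param out_dir Output directory (created if needed).
#' @param plots Also write PNG plots per pattern.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, out_dir, plots = FALSE) {
  stopifnot(inherits(report, "comparison_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory ", out_dir, call. = FALSE)
    }
  }
  paths <- character(0)
  for (tag in names(report$patterns)) {
    f <- file.path(out_dir, paste0("pattern_", tag, ".csv"))
    utils::write.csv(report$patterns[[tag]], f, row.names = FALSE)
    paths <- c(paths, f)
  }
  combined <- do.call(rbind, lapply(report$patterns, as.data.frame))
  f <- file.path(out_dir, "patterns_combined.csv")
  utils::write.csv(combined, f, row.names = FALSE)
  paths <- c(paths, f)
  if (!is.null(report$correlations)) {
    f1 <- file.path(out_dir, "raw_correlations.csv")
    f2 <- file.path(out_dir, "clr_correlations.csv")
    utils::write.csv(report$correlations$raw_cor, f1)
    utils::write.csv(report$correlations$transformed_cor, f2)
    paths <- c(paths, f1, f2)
  }
  f <- file.path(out_dir, "summary.txt")
  con <- file(f, "w")
  writeLines(c(
    sprintf("n = %d participants, %d bins", report$meta$n,
            length(report$meta$bins)),
    sprintf("seed = %d, reps = %d, holdout = %g",
            report$meta$config$seed, report$meta$config$reps,
            report$meta$config$holdout),
    vapply(names(report$patterns), function(tag) {
      p <- report$patterns[[tag]]
      q2 <- attr(p, "cv_q2")
      sprintf("%s: R2 = %s%s", tag,
              format(unique(p$model_r2)[1L], digits = 4),
              if (is.null(q2)) "" else
                sprintf(", Q2 = %s (%d components)",
                        format(q2, digits = 4), attr(p, "n_components")))
    }, character(1)),
    if (length(report$failures)) {
      paste0("FAILED ", names(report$failures), ": ",
             unlist(report$failures))
    } else "all requested models completed"
  ), con)
  close(con)
  paths <- c(paths, f)
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    for (tag in names(report$patterns)) {
      p <- report$patterns[[tag]]
      p$bin <- factor(p$bin, levels = unique(p$bin))
      g <- ggplot2::ggplot(p, ggplot2::aes(x = .data$bin,
                                           y = .data$estimate)) +
        ggplot2::geom_hline(yintercept = 0, linetype = 2) +
        ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                              ymax = .data$ci_high)) +
        ggplot2::labs(title = tag, x = NULL, y = "estimate (95% CI)") +
        ggplot2::theme_bw() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                           hjust = 1))
      f <- file.path(out_dir, paste0("pattern_", tag, ".png"))
      ggplot2::ggsave(f, g, width = 8, height = 4, dpi = 150)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}

#' Simulate-transform-fit: the whole pipeline in one call
#'
#' Generates a synthetic spectrum dataset, picks the outcome (the planted
#' composite by default, or the composite score recomputed from the
#' synthetic cardiometabolic panel), and runs the full comparison. A single
#' master seed fans out to the generator (`seed + 1`) and the resampling
#' stages (`seed + 2`), so the whole chain is reproducible from one
#' integer.
#'
#' @param synth A [synthetic_config()]; its seed is overridden by the
#'   master seed.
#' @param comparison A [comparison_config()]; its seed is likewise
#'   overridden.
#' @param seed Master seed.
#' @param outcome_source `"planted"` (the generator's outcome) or
#'   `"panel"` (recompute the composite from the synthetic panel).
#' @return A `comparison_report` whose `meta$truth` holds the planted
#'   effect vector.
#' @export
end_to_end <- function(synth = synthetic_config(),
                       comparison = comparison_config(),
                       seed = 1L,
                       outcome_source = c("planted", "panel")) {
  outcome_source <- match.arg(outcome_source)
  synth$seed <- as.integer(seed) + 1L
  comparison$seed <- as.integer(seed) + 2L
  ds <- generate_spectrum_dataset(synth)
  y <- switch(outcome_source,
              planted = ds$outcome,
              panel = composite_score(ds$panel)$composite)
  x <- ds$profiles
  if (comparison$use_proportions) x <- x / rowSums(x)
  report <- run_comparison(x, y, comparison)
  report$meta$truth <- ds$truth
  report
}
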