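.association_pattern <- function(bin, estimate, ci_low, ci_high,
                                 model_tag, model_r2 = NA_real_) {
  out <- tibble::tibble(
    bin = bin, estimate = as.numeric(estimate),
    ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
    model_tag = model_tag, model_r2 = as.numeric(model_r2)
  )
  class(out) <- c("association_pattern", class(out))
  out
}

#' Bivariate correlations of each bin with the outcome
#'
#' Per-bin Pearson correlation with a Fisher-z 95% confidence interval
#' (variables are not mutually adjusted). Constant columns are flagged and
#' reported as `NA`.
#'
#' @param x Matrix of explanatory variables (bins in columns).
#' @param y Outcome vector.
#' @param conf Confidence level.
#' @return An `association_pattern` tibble (tag `"bivariate"`).
#' @export
bivariate_correlations <- function(x, y, conf = 0.95) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  r <- rep(NA_real_, ncol(x))
  ok <- sds > 0 & stats::sd(y) > 0
  r[ok] <- drop(suppressWarnings(stats::cor(x[, ok, drop = FALSE], y)))
  zcrit <- stats::qnorm(1 - (1 - conf) / 2)
  se <- 1 / sqrt(n - 3)
  lo <- tanh(atanh(r) - zcrit * se)
  hi <- tanh(atanh(r) + zcrit * se)
  bins <- colnames(x)
  if (is.null(bins)) bins <- paste0("V", seq_len(ncol(x)))
  out <- .association_pattern(bins, r, lo, hi, "bivariate")
  attr(out, "undefined") <- bins[!ok]
  out
}

#' Multiple linear regression of the outcome on all bins
#'
#' Ordinary least squares with all bins entered jointly; reports each
#' coefficient with a t-based confidence interval and the model R-squared.
#' Before fitting, the condition number of the standardized design (with
#' intercept) is checked: values above `condition_limit` -- which is what
#' closed (constant-sum) explanatory data produce, since the parts are then
#' exactly collinear with the intercept -- raise an explicit singularity
#' error naming the dominant collinearity; merely ill-conditioned designs
#' (above `warn_limit`) fit with a warning.
#'
#' @param x Matrix of explanatory variables.
#' @param y Outcome vector.
#' @param conf Confidence level.
#' @param condition_limit Condition number treated as singular (default
#'   1e10).
#' @param warn_limit Condition number above which a warning is issued.
#' @param model_tag Tag stored in the pattern (default `"mlr_raw"`).
#' @return An `association_pattern` tibble.
#' @export
fit_mlr <- function(x, y, conf = 0.95, condition_limit = 1e10,
                    warn_limit = 1e6, model_tag = "mlr_raw") {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (n <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  bins <- colnames(x)
  if (is.null(bins)) bins <- paste0("V", seq_len(p))

  sds <- apply(x, 2L, stats::sd)
  design <- cbind(intercept = 1,
                  sweep(sweep(x, 2L, colMeans(x), "-"), 2L,
                        ifelse(sds > 0, sds, 1), "/"))
  sv <- svd(design)
  cond <- if (min(sv$d) == 0) Inf else max(sv$d) / min(sv$d)
  if (cond > condition_limit) {
    v <- sv$v[, ncol(sv$v)]
    top <- order(abs(v), decreasing = TRUE)[seq_len(min(4L, length(v)))]
    stop(structure(class = c("singularity_error", "error", "condition"),
                   list(message = paste0(
      "explanatory variables are singular or near-singular (condition ",
      "number ", format(cond, digits = 3), "); dominant collinearity ",
      "involves: ",
      paste(c("intercept", bins)[top], collapse = ", "),
      ". Closed (constant-sum) data cannot be analysed by multiple ",
      "linear regression."), call = NULL)))
  }
  if (cond > warn_limit) {
    warning("ill-conditioned explanatory matrix (condition number ",
            format(cond, digits = 3),
            "): coefficients will be unstable with large CIs",
            call. = FALSE)
  }
  df <- as.data.frame(x)
  names(df) <- make.names(bins)
  fit <- stats::lm(y ~ ., data = cbind(data.frame(y = y), df))
  est <- stats::coef(fit)[-1L]
  ci <- stats::confint(fit, level = conf)[-1L, , drop = FALSE]
  .association_pattern(bins, est, ci[, 1L], ci[, 2L], model_tag,
                       summary(fit)$r.squared)
}

#' Multiple linear regression on pivot-coordinate ilr data
#'
#' Closes the bin minutes, then fits one regression per all-first
#' permutation of the parts: for each of the `D` permutations the outcome
#' is regressed on the `D - 1` pivot coordinates and the coefficient (with
#' t-based CI) of the *first* coordinate -- the one contrasting the
#' permuted-first bin against the geometric mean of all others -- is
#' reported for that bin. `D` fits in total; all fit the same subspace, so
#' their fitted values and R-squared coincide.
#'
#' @param minutes Matrix of bin minutes (or any positive measure; the
#'   transform is scale-invariant).
#' @param y Outcome vector.
#' @param conf Confidence level.
#' @param delta Zero-replacement value passed to [close_composition()].
#' @return An `association_pattern` tibble (tag `"mlr_ilr"`) with one row
#'   per bin, plus attribute `n_fits`.
#' @export
fit_ilr_mlr <- function(minutes, y, conf = 0.95, delta = NULL) {
  minutes <- as.matrix(minutes); y <- as.numeric(y)
  comp <- close_composition(minutes, delta)
  d <- ncol(comp)
  bins <- colnames(minutes)
  if (is.null(bins)) bins <- paste0("V", seq_len(d))
  perms <- all_first_permutations(d)
  est <- lo <- hi <- numeric(d)
  r2 <- NA_real_
  for (k in seq_len(d)) {
    z <- ilr_pivot(comp, perms[[k]])
    fit <- stats::lm(y ~ z)
    est[k] <- stats::coef(fit)[2L]
    ci <- stats::confint(fit, level = conf)
    lo[k] <- ci[2L, 1L]; hi[k] <- ci[2L, 2L]
    if (k == 1L) r2 <- summary(fit)$r.squared
  }
  out <- .association_pattern(bins, est, lo, hi, "mlr_ilr", r2)
  attr(out, "n_fits") <- d
  out
}
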