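# NIPALS core for a single outcome. X and y are already centred/scaled.
# Returns weights W, x-loadings P, y-loadings q, scores TT, the projection
# matrix R (X %*% R = TT) and cumulative coefficient matrix B where
# B[, a] are the regression coefficients of the a-component model.
# For univariate y each component is a single pass (no inner iteration) and
# the fit is deterministic.
.nipals <- function(x, y, n_components) {
  n <- nrow(x); p <- ncol(x)
  a_max <- n_components
  w_mat <- matrix(0, p, a_max); p_mat <- matrix(0, p, a_max)
  r_mat <- matrix(0, p, a_max); b_mat <- matrix(0, p, a_max)
  t_mat <- matrix(0, n, a_max)
  q <- numeric(a_max)
  e <- x; f <- y
  b <- numeric(p)
  a_used <- 0L
  for (a in seq_len(a_max)) {
    w <- crossprod(e, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break   # no covariance left to model
    w <- w / nw
    tt <- e %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    pl <- crossprod(e, tt) / tt2
    qa <- sum(f * tt) / tt2
    e <- e - tcrossprod(tt, pl)
    f <- f - tt * qa
    # projection vector: r_a = w_a - R_{a-1} (P_{a-1}' w_a)
    r <- w
    if (a > 1L) {
      r <- w - r_mat[, seq_len(a - 1L), drop = FALSE] %*%
        crossprod(p_mat[, seq_len(a - 1L), drop = FALSE], w)
    }
    b <- b + drop(r) * qa
    w_mat[, a] <- w; p_mat[, a] <- pl; r_mat[, a] <- r
    t_mat[, a] <- tt; q[a] <- qa; b_mat[, a] <- b
    a_used <- a
  }
  if (a_used == 0L) {
    stop("degenerate model: no covariance between X and y", call. = FALSE)
  }
  keep <- seq_len(a_used)
  list(weights = w_mat[, keep, drop = FALSE],
       loadings = p_mat[, keep, drop = FALSE],
       projection = r_mat[, keep, drop = FALSE],
       scores = t_mat[, keep, drop = FALSE],
       y_loadings = q[keep],
       coefficients = b_mat[, keep, drop = FALSE],
       n_components = a_used)
}

.standardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2L, stats::sd)
    scale[scale == 0] <- 1   # constant columns carry no information
  }
  list(x = sweep(sweep(x, 2L, center, "-"), 2L, scale, "/"),
       center = center, scale = scale)
}

#' Fit a univariate partial least squares (PLS) regression
#'
#' NIPALS PLS with a single outcome. All variables are centred and scaled
#' to unit variance before fitting (the outcome too), so the regression
#' vector lives in standardized space. The fit is deterministic, tolerates
#' rank-deficient or exactly collinear explanatory matrices, and with as
#' many components as the rank of `X` reproduces ordinary least squares.
#'
#' @param x Numeric matrix of explanatory variables (n x p).
#' @param y Numeric outcome of length n.
#' @param n_components Number of latent components, between 1 and
#'   `min(n - 1, p)`. Fewer are kept if the residual covariance vanishes
#'   first (e.g. `x` of lower rank).
#' @param center,scale Standardize columns (default `TRUE`).
#' @return A `pls_model`: weights, loadings, scores, `y_loadings`,
#'   `regression_vector` (standardized space), `fitted_r2`, `scaling`, and
#'   the standardized data used.
#' @seealso [monte_carlo_cv()], [target_projection()]
#' @export
fit_pls <- function(x, y, n_components, center = TRUE, scale = TRUE) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("x and y sizes differ", call. = FALSE)
  if (n < 10) stop("PLS here requires at least 10 observations", call. = FALSE)
  if (n_components < 1 || n_components > min(n - 1, p)) {
    stop("n_components must lie in [1, min(n - 1, p)]", call. = FALSE)
  }
  xs <- if (center || scale) {
    .standardize(x, center = if (center) NULL else rep(0, p),
                 scale = if (scale) NULL else rep(1, p))
  } else {
    list(x = x, center = rep(0, p), scale = rep(1, p))
  }
  ym <- if (center) mean(y) else 0
  ysd <- if (scale) stats::sd(y) else 1
  if (ysd == 0) stop("outcome is constant", call. = FALSE)
  ys <- (y - ym) / ysd

  core <- .nipals(xs$x, ys, n_components)
  b <- core$coefficients[, core$n_components]
  fitted_std <- drop(xs$x %*% b)
  r2 <- 1 - sum((ys - fitted_std)^2) / sum(ys^2)

  structure(list(
    n_components = core$n_components,
    weights = core$weights, loadings = core$loadings,
    scores = core$scores, y_loadings = core$y_loadings,
    projection = core$projection,
    coefficient_path = core$coefficients,
    regression_vector = b,
    fitted_r2 = r2,
    scaling = list(x_center = xs$center, x_scale = xs$scale,
                   y_center = ym, y_scale = ysd),
    X_std = xs$x, y_std = ys,
    variable_names = colnames(x)
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$n_components, " component(s), ",
      length(x$regression_vector), " variables, fitted R2 = ",
      round(x$fitted_r2, 3), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix on the original variable scale.
#' @param n_components Number of components to use (defaults to all
#'   fitted).
#' @param ... Unused.
#' @return Predicted outcome on the original scale.
#' @export
predict.pls_model <- function(object, newdata,
                              n_components = object$n_components, ...) {
  if (n_components < 1 || n_components > object$n_components) {
    stop("n_components outside the fitted range", call. = FALSE)
  }
  m <- as.matrix(newdata)
  s <- object$scaling
  xs <- sweep(sweep(m, 2L, s$x_center, "-"), 2L, s$x_scale, "/")
  b <- object$coefficient_path[, n_components]
  drop(xs %*% b) * s$y_scale + s$y_center
}

#' Choose the number of PLS components by Monte Carlo cross-validation
#'
#' Repeatedly holds out a random fraction of participants (default 50%,
#' 1000 repetitions), fits PLS with up to `max_components` components on
#' the remainder (standardizing on the training half), and records the
#' held-out root-mean-squared error of prediction (RMSEP) per component
#' count. The chosen model size is the smallest one whose mean RMSEP lies
#' within one standard error of the minimum (a parsimony rule). `q2` is the
#' cross-validated explained variance at the chosen size,
#' `1 - PRESS / SS_holdout`, pooled over repetitions.
#'
#' @param x,y Data as in [fit_pls()]; n must be at least 20.
#' @param reps Number of random splits (>= 2).
#' @param holdout Fraction held out for validation.
#' @param max_components Largest model size tried; defaults to
#'   `min(p, 10, training size - 2)`.
#' @param seed Integer seed; identical seeds give identical curves.
#' @return List of class `mccv`: `n_components` (chosen), `rmsep` and
#'   `rmsep_se` per size, `q2`, plus the resampling settings.
#' @export
monte_carlo_cv <- function(x, y, reps = 1000, holdout = 0.5,
                           max_components = NULL, seed = 1L) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (n < 20) stop("Monte Carlo CV requires at least 20 observations",
                   call. = FALSE)
  if (reps < 2) stop("reps must be >= 2", call. = FALSE)
  if (holdout <= 0 || holdout >= 1) {
    stop("holdout must be a fraction in (0, 1)", call. = FALSE)
  }
  n_val <- max(1L, floor(n * holdout))
  n_train <- n - n_val
  a_max <- if (is.null(max_components)) {
    min(ncol(x), 10L, n_train - 2L)
  } else {
    min(max_components, ncol(x), n_train - 1L)
  }
  if (a_max < 1L) stop("too few observations for any component", call. = FALSE)

  press <- matrix(NA_real_, reps, a_max)
  sstot <- numeric(reps)
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      val <- sample.int(n, n_val)
      xt <- x[-val, , drop = FALSE]; yt <- y[-val]
      xv <- x[val, , drop = FALSE]; yv <- y[val]
      st <- .standardize(xt)
      ym <- mean(yt); ysd <- stats::sd(yt)
      if (ysd == 0) ysd <- 1
      core <- .nipals(st$x, (yt - ym) / ysd, a_max)
      xvs <- sweep(sweep(xv, 2L, st$center, "-"), 2L, st$scale, "/")
      pred_std <- xvs %*% core$coefficients          # n_val x a_used
      pred <- pred_std * ysd + ym
      err2 <- (pred - yv)^2
      msep <- colMeans(err2)
      # if fewer components were identifiable, later sizes equal the last
      press[r, ] <- msep[pmin(seq_len(a_max), core$n_components)]
      sstot[r] <- mean((yv - ym)^2)
    }
  })
  rmsep_rep <- sqrt(press)
  m <- colMeans(rmsep_rep)
  se <- apply(rmsep_rep, 2L, stats::sd) / sqrt(reps)
  a_min <- which.min(m)
  chosen <- min(which(m <= m[a_min] + se[a_min]))
  q2 <- 1 - sum(press[, chosen]) / sum(sstot)
  structure(list(n_components = chosen, rmsep = m, rmsep_se = se, q2 = q2,
                 reps = reps, holdout = holdout, seed = seed,
                 max_components = a_max),
            class = "mccv")
}

#' @export
print.mccv <- function(x, ...) {
  cat("<mccv> ", x$reps, " splits, ", round(100 * x$holdout),
      "% holdout: chose ", x$n_components, " component(s), Q2 = ",
      round(x$q2, 3), "\n", sep = "")
  invisible(x)
}

#' Target projection of a fitted PLS model
#'
#' Compresses all of a PLS model's predictive variance onto a single
#' component directed along the regression vector: the target-projected
#' weights are the unit-norm regression vector, the scores are the
#' standardized data projected onto it, and the loadings regress the data
#' back onto those scores. Prediction from the target-projected component
#' is identical to prediction from the full regression vector.
#'
#' @param model A fitted `pls_model`.
#' @return A `target_projection` list: `tp_weights` (unit norm),
#'   `tp_scores`, `tp_loadings`, and per-variable `explained_variance` and
#'   `total_variance` (sums of squares in standardized space).
#' @export
target_projection <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  b <- model$regression_vector
  nb <- sqrt(sum(b^2))
  if (nb < 1e-12) {
    stop("degenerate model: zero regression vector", call. = FALSE)
  }
  w <- b / nb
  t_tp <- drop(model$X_std %*% w)
  tt2 <- sum(t_tp^2)
  if (tt2 < 1e-12) {
    stop("degenerate model: zero target-projected scores", call. = FALSE)
  }
  p_tp <- drop(crossprod(model$X_std, t_tp)) / tt2
  explained <- p_tp^2 * tt2
  total <- colSums(model$X_std^2)
  structure(list(
    tp_weights = w, tp_scores = t_tp, tp_loadings = p_tp,
    explained_variance = explained, total_variance = total,
    variable_names = model$variable_names
  ), class = "target_projection")
}

#' Selectivity ratios from a target projection
#'
#' The selectivity ratio of variable `j` is the ratio of its target-
#' projection-explained variance to its total variance, signed by the
#' target-projection loading so the ratio carries the direction of the
#' association. The magnitude is bounded by 1 (Cauchy--Schwarz).
#'
#' @param tp A [target_projection()] result.
#' @return Tibble of class `selectivity_ratio` with columns `variable`,
#'   `sr`, `ci_low`, `ci_high` (CIs `NA` here; see
#'   [sr_confidence_intervals()]). Variables with zero total variance get
#'   `NA` and are listed in the `undefined` attribute.
#' @export
selectivity_ratio <- function(tp) {
  stopifnot(inherits(tp, "target_projection"))
  total <- tp$total_variance
  sr <- ifelse(total > 0,
               sign(tp$tp_loadings) * tp$explained_variance / total,
               NA_real_)
  vars <- tp$variable_names
  if (is.null(vars)) vars <- paste0("V", seq_along(sr))
  out <- tibble::tibble(variable = vars, sr = sr,
                        ci_low = NA_real_, ci_high = NA_real_)
  attr(out, "undefined") <- vars[total <= 0]
  class(out) <- c("selectivity_ratio", class(out))
  out
}

#' Resampling confidence intervals for selectivity ratios
#'
#' Point estimates come from the full-data model; intervals come from
#' refitting the PLS model, target projection and selectivity ratios on
#' each Monte Carlo training half (same resampling scheme as
#' [monte_carlo_cv()]) and taking percentile bounds across repetitions.
#' Because the target-projection axis is only defined up to sign, each
#' resample's ratios are sign-aligned to the full-data axis before the
#' percentiles are taken.
#'
#' @param x,y Data as in [fit_pls()].
#' @param n_components Model size (typically the [monte_carlo_cv()]
#'   choice).
#' @param reps Number of random splits.
#' @param holdout Fraction left out of each training half.
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A `selectivity_ratio` tibble with `ci_low`/`ci_high` filled in
#'   and attributes `resamples`, `n_components`, `fitted_r2`.
#' @export
sr_confidence_intervals <- function(x, y, n_components, reps = 1000,
                                    holdout = 0.5, seed = 1L, conf = 0.95) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (reps < 2) stop("reps must be >= 2", call. = FALSE)
  full <- fit_pls(x, y, n_components)
  tp_full <- target_projection(full)
  sr_full <- selectivity_ratio(tp_full)
  w_full <- tp_full$tp_weights

  n_val <- max(1L, floor(n * holdout))
  draws <- matrix(NA_real_, reps, p)
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      tr <- sample.int(n, n - n_val)
      s <- tryCatch({
        fit <- fit_pls(x[tr, , drop = FALSE], y[tr],
                       min(n_components, length(tr) - 1L))
        tp <- target_projection(fit)
        v <- selectivity_ratio(tp)$sr
        if (sum(tp$tp_weights * w_full) < 0) v <- -v
        v
      }, error = function(e) rep(NA_real_, p))
      draws[r, ] <- s
    }
  })
  alpha <- (1 - conf) / 2
  ci <- apply(draws, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  out <- sr_full
  out$ci_low <- ci[1L, ]
  out$ci_high <- ci[2L, ]
  attr(out, "resamples") <- reps
  attr(out, "n_components") <- full$n_components
  attr(out, "fitted_r2") <- full$fitted_r2
  out
}
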