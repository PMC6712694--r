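#' Close a vector or matrix of bin minutes to a composition
#'
#' Divides each row by its total so parts sum to 1, after multiplicative
#' zero replacement: zero entries are replaced by a small detection-limit
#' value `delta` (on the input scale) and the non-zero entries of that row
#' are shrunk proportionally so the row total is preserved. By default
#' `delta` is, per column, the smaller of 1/60 min (one 1-s epoch) and 0.65
#' times the smallest non-zero value of that column -- structural zeros are
#' expected in the highest intensity bins and log-ratios are undefined at 0.
#'
#' @param x Non-negative vector, or matrix/data frame with one row per
#'   participant.
#' @param delta Replacement value(s) on the input scale; scalar or one per
#'   column. `NULL` for the default rule.
#' @return Object of the same shape with rows summing to 1, carrying a
#'   `zero_replacement` attribute (tibble: `row`, `col`, `delta`; empty when
#'   nothing was replaced).
#' @examples
#' close_composition(c(2, 3, 5))
#' @export
close_composition <- function(x, delta = NULL) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), nrow = 1L,
                       dimnames = list(NULL, names(x)))
       else as.matrix(x)
  if (any(m < 0)) stop("bin minutes must be non-negative", call. = FALSE)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("all-zero row(s): composition undefined", call. = FALSE)
  }
  if (is.null(delta)) {
    delta <- apply(m, 2L, function(col) {
      nz <- col[col > 0]
      if (length(nz)) min(1 / 60, 0.65 * min(nz)) else 1 / 60
    })
  }
  delta <- rep_len(as.numeric(delta), ncol(m))
  zero <- m == 0
  log_rows <- integer(0); log_cols <- integer(0)
  if (any(zero)) {
    idx <- which(zero, arr.ind = TRUE)
    log_rows <- idx[, 1L]; log_cols <- idx[, 2L]
    add <- as.numeric(zero %*% delta)
    if (any(add >= tot)) {
      stop("zero replacement exceeds row total; supply a smaller delta",
           call. = FALSE)
    }
    m <- m * (1 - add / tot)
    m[zero] <- delta[log_cols]
  }
  parts <- m / rowSums(m)
  attr(parts, "zero_replacement") <- tibble::tibble(
    row = log_rows, col = log_cols, delta = delta[log_cols]
  )
  if (vec) {
    out <- parts[1L, ]
    attr(out, "zero_replacement") <- attr(parts, "zero_replacement")
    return(out)
  }
  parts
}

#' Centred log-ratio (clr) coordinates
#'
#' `clr_j = ln(x_j) - mean_k ln(x_k)` per row: each part expressed as its
#' log-ratio to the row geometric mean. Coordinates sum to zero in every
#' row, so clr data remain singular -- they are intended for the
#' multivariate pattern analysis, not for ordinary regression. The
#' transform is invariant to the row total, so minutes and proportions give
#' identical coordinates.
#'
#' @param x Positive vector or matrix (use [close_composition()] first if
#'   zeros may be present).
#' @return Same shape as `x`, clr coordinates.
#' @export
clr_transform <- function(x) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), nrow = 1L,
                       dimnames = list(NULL, names(x)))
       else as.matrix(x)
  if (any(m <= 0)) {
    stop("clr needs strictly positive parts; run close_composition() ",
         "to replace zeros", call. = FALSE)
  }
  l <- log(m)
  out <- l - rowMeans(l)
  if (vec) out[1L, ] else out
}

#' Pivot-coordinate isometric log-ratio (ilr) coordinates
#'
#' After reordering the parts by `permutation`, coordinate `i` contrasts
#' part `i` against the geometric mean of all following parts:
#' `z_i = sqrt((D - i) / (D - i + 1)) * ln(x_i / gm(x_{i+1}, ..., x_D))`,
#' for `i = 1, ..., D - 1`. The first coordinate therefore carries the
#' permuted-first part against everything else, which is the coordinate
#' interpreted when the transform is repeated over the all-first
#' permutations. Coordinates are an isometry of clr: the squared norms
#' agree for every composition and permutation.
#'
#' @param x Positive vector or matrix of `D` parts.
#' @param permutation Integer permutation of `1:D`; identity by default.
#' @return Matrix (or vector) of `D - 1` coordinates, columns `ilr_1` ...,
#'   with the permutation stored in the `permutation` attribute.
#' @export
ilr_pivot <- function(x, permutation = NULL) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), nrow = 1L,
                       dimnames = list(NULL, names(x)))
       else as.matrix(x)
  d <- ncol(m)
  if (d < 2L) stop("ilr needs at least two parts", call. = FALSE)
  if (is.null(permutation)) permutation <- seq_len(d)
  if (length(permutation) != d ||
      !identical(sort(as.integer(permutation)), seq_len(d))) {
    stop("permutation must be a bijection on 1:", d, call. = FALSE)
  }
  if (any(m <= 0)) {
    stop("ilr needs strictly positive parts; run close_composition() ",
         "to replace zeros", call. = FALSE)
  }
  l <- log(m[, permutation, drop = FALSE])
  # suffix sums of log-parts: cs[, i] = sum over columns i..D
  cs <- l
  if (d > 1L) for (j in (d - 1L):1L) cs[, j] <- cs[, j + 1L] + l[, j]
  z <- matrix(0, nrow(m), d - 1L)
  for (i in seq_len(d - 1L)) {
    z[, i] <- sqrt((d - i) / (d - i + 1)) *
      (l[, i] - cs[, i + 1L] / (d - i))
  }
  colnames(z) <- paste0("ilr_", seq_len(d - 1L))
  attr(z, "permutation") <- as.integer(permutation)
  if (vec) {
    out <- z[1L, ]
    attr(out, "permutation") <- as.integer(permutation)
    return(out)
  }
  z
}

#' All-first permutations of D parts
#'
#' The permutation list used to repeat the pivot-coordinate transform:
#' permutation `k` places part `k` first and keeps the remaining parts in
#' the original cyclic order, so every part leads exactly once across the
#' list.
#'
#' @param d Number of parts (>= 2).
#' @return List of `d` integer permutations.
#' @examples
#' all_first_permutations(4)
#' @export
all_first_permutations <- function(d) {
  d <- as.integer(d)
  if (d < 2L) stop("need at least two parts", call. = FALSE)
  lapply(seq_len(d), function(k) c(k:d, seq_len(k - 1L)))
}

#' Closure-distortion diagnostics: paired correlation structures
#'
#' Pearson correlation matrices of a raw data matrix and its transformed
#' counterpart, their elementwise difference, and a distortion summary
#' (mean absolute off-diagonal change and the number of variable pairs
#' whose correlation changed sign). Constant columns are flagged and their
#' correlations reported as `NA`.
#'
#' @param raw,transformed Matrices of identical dimension (e.g. bin minutes
#'   and their clr coordinates).
#' @return Object of class `closure_report`: list with `raw_cor`,
#'   `transformed_cor`, `difference`, `mean_abs_change`, `sign_flips`,
#'   `undefined_raw`, `undefined_transformed`.
#' @export
closure_correlation_report <- function(raw, transformed) {
  raw <- as.matrix(raw); transformed <- as.matrix(transformed)
  if (!all(dim(raw) == dim(transformed))) {
    stop("raw and transformed matrices must share dimensions", call. = FALSE)
  }
  const <- function(m) {
    s <- apply(m, 2L, stats::sd)
    nm <- colnames(m)
    if (is.null(nm)) nm <- paste0("V", seq_len(ncol(m)))
    nm[is.na(s) | s == 0]
  }
  cr <- suppressWarnings(stats::cor(raw))
  ct <- suppressWarnings(stats::cor(transformed))
  diff <- ct - cr
  off <- upper.tri(cr)
  flips <- sum(sign(cr[off]) * sign(ct[off]) < 0, na.rm = TRUE)
  structure(list(
    raw_cor = cr, transformed_cor = ct, difference = diff,
    mean_abs_change = mean(abs(diff[off]), na.rm = TRUE),
    sign_flips = flips,
    undefined_raw = const(raw),
    undefined_transformed = const(transformed)
  ), class = "closure_report")
}

#' @export
print.closure_report <- function(x, ...) {
  cat("<closure_report> ", ncol(x$raw_cor), " variables\n", sep = "")
  cat("  mean |delta r| (off-diagonal): ",
      signif(x$mean_abs_change, 3), "\n", sep = "")
  cat("  sign flips: ", x$sign_flips, " pair(s)\n", sep = "")
  if (length(x$undefined_raw) || length(x$undefined_transformed)) {
    cat("  constant columns flagged: ",
        paste(unique(c(x$undefined_raw, x$undefined_transformed)),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
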