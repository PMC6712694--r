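#' Intensity bin schemes on the counts-per-minute scale
#'
#' A bin scheme partitions the accelerometer intensity axis (counts per
#' minute, cpm) into named, left-closed/right-open intervals. Two schemes are
#' built in: the `"traditional"` four-category description using the
#' Evenson child cut points (SED 0--99, LPA 100--2295, MPA 2296--4011,
#' VPA >= 4012 cpm) and the `"spectrum"` description with 23 narrow
#' intervals (0--99, 100--249, 250--499, 500--999, then 500-cpm steps up to
#' >= 10000 cpm). Custom schemes are supported by passing `edges` directly.
#'
#' @param name `"traditional"`, `"spectrum"`, or an arbitrary label when
#'   `edges` is supplied.
#' @param edges Ascending numeric vector of lower bin bounds in cpm. The
#'   first edge must be 0; the last bin is unbounded above.
#' @param labels Optional character labels, one per bin.
#'
#' @return An object of class `bin_scheme`: a list with elements `name`,
#'   `edges` and `labels`.
#' @examples
#' bin_scheme("traditional")
#' n_bins(bin_scheme("spectrum"))
#' @export
bin_scheme <- function(name = c("traditional", "spectrum"),
                       edges = NULL, labels = NULL) {
  if (is.null(edges)) {
    name <- match.arg(name)
    edges <- switch(name,
      traditional = c(0, 100, 2296, 4012),
      spectrum    = c(0, 100, 250, 500, seq(1000, 10000, by = 500))
    )
    if (is.null(labels)) {
      labels <- switch(name,
        traditional = c("SED", "LPA", "MPA", "VPA"),
        spectrum    = .spectrum_labels(edges)
      )
    }
  } else {
    name <- if (length(name) == 1L && is.character(name)) name else "custom"
  }
  edges <- as.numeric(edges)
  if (length(edges) < 2L) {
    stop("a bin scheme needs at least two edges (two bins)", call. = FALSE)
  }
  if (edges[1L] != 0) {
    stop("the first bin edge must be 0 cpm", call. = FALSE)
  }
  if (any(diff(edges) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  if (is.null(labels)) labels <- .spectrum_labels(edges)
  if (length(labels) != length(edges)) {
    stop("`labels` must have one entry per bin", call. = FALSE)
  }
  structure(list(name = name, edges = edges, labels = labels),
            class = "bin_scheme")
}

.spectrum_labels <- function(edges) {
  upper <- c(edges[-1L] - 1, Inf)
  ifelse(is.finite(upper),
         paste0("cpm", edges, "_", upper),
         paste0("cpm", edges, "plus"))
}

#' Number of bins in a scheme
#'
#' @param scheme A [bin_scheme()].
#' @return Integer bin count.
#' @export
n_bins <- function(scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  length(scheme$edges)
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat("<bin_scheme> ", x$name, ": ", length(x$edges), " bins\n", sep = "")
  upper <- c(x$edges[-1L] - 1, Inf)
  rng <- ifelse(is.finite(upper),
                paste0(x$edges, "-", upper),
                paste0(">=", x$edges))
  cat("  ", paste0(x$labels, " [", rng, " cpm]", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
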