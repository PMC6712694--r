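#' Configuration for the synthetic intensity-spectrum generator
#'
#' Describes a population of children wearing accelerometers: how many
#' participants, which bin scheme, the wear-time distribution, the log-scale
#' location/spread of the active-intensity bins, the strength of the shared
#' activity factor that makes active bins mutually positively correlated,
#' and a planted per-bin effect on the cardiometabolic outcome.
#'
#' Active-bin minutes are generated as
#' `exp(log_mean + latent_loading * F + eps)` with a participant-level
#' factor `F ~ N(0, 1)` shared across bins, and `eps` an AR(1) perturbation
#' across adjacent bins (correlation `rho`, stationary sd `log_sd`) so that
#' inter-bin correlations are positive and decay with intensity distance.
#' With `sed_anticorrelation = TRUE` (default) the first (sedentary) bin
#' absorbs wear time minus total active time, which enforces closure and the
#' negative sedentary-versus-active correlation seen in real spectra; active
#' bins are shrunk proportionally on the rare rows where they would exceed
#' wear time. The outcome is `standardized bins %*% effect_vector` plus
#' Gaussian noise with sd `noise_sd`, so effects are in SD units.
#'
#' Defaults mirror an analytic sample of 841 ten-year-olds with mean wear
#' time 795 (sd 56) min/day and, for the 23-bin spectrum scheme, a planted
#' signature that is weakly positive for the sedentary bin (+0.1 SD), null
#' through the light/moderate range (bins 2--10) and monotonically negative
#' down to -0.4 SD at the top of the intensity spectrum.
#'
#' @param n_participants Number of participants; must be at least twice the
#'   number of bins.
#' @param scheme A [bin_scheme()]; defaults to the 23-bin spectrum.
#' @param wear_minutes_mean,wear_minutes_sd Daily wear time distribution
#'   (minutes/day).
#' @param log_mean Log-scale location per active bin (length `D - 1`);
#'   defaults to a geometric decay from 60 to 0.3 min/day.
#' @param log_sd Log-scale sd per active bin (> 0, recycled). The default
#'   grows linearly from 0.15 at the lightest active bin to 1.2 at the top
#'   of the spectrum: minutes in the highest bins are tiny, highly variable
#'   parts, and this heterogeneity is what makes the clr transform turn
#'   low-versus-high-intensity correlations negative, as observed in real
#'   spectrum data.
#' @param latent_loading Per-bin loading on the shared activity factor;
#'   recycled across the `D - 1` active bins.
#' @param rho AR(1) correlation of the log-scale perturbation across
#'   adjacent bins, in `[0, 1)`.
#' @param sed_anticorrelation If `TRUE`, the sedentary bin is wear time
#'   minus active time; if `FALSE` it is drawn lognormally with a negative
#'   loading and all bins are rescaled to wear time (closure either way).
#' @param effect_vector Planted standardized effect per bin (length `D`).
#'   Defaults to the spectrum signature described above for `D = 23`, and to
#'   all zeros otherwise.
#' @param noise_sd Outcome residual sd (>= 0). The default (5) is
#'   calibrated so that, under the default planted signature, the planted
#'   signal explains on the order of a fifth of the outcome variance --
#'   the magnitude of explained variance typical of spectrum analyses of
#'   cardiometabolic risk.
#' @param seed Integer seed; identical configurations give identical data.
#'
#' @return A `synthetic_config` list.
#' @seealso [generate_spectrum_dataset()]
#' @export
synthetic_config <- function(n_participants = 841,
                             scheme = bin_scheme("spectrum"),
                             wear_minutes_mean = 795,
                             wear_minutes_sd = 56,
                             log_mean = NULL,
                             log_sd = NULL,
                             latent_loading = 0.5,
                             rho = 0.8,
                             sed_anticorrelation = TRUE,
                             effect_vector = NULL,
                             noise_sd = 5,
                             seed = 1L) {
  stopifnot(inherits(scheme, "bin_scheme"))
  d <- n_bins(scheme)
  n_active <- d - 1L
  if (is.null(log_mean)) {
    log_mean <- log(60 * (0.3 / 60)^((seq_len(n_active) - 1) / (n_active - 1)))
  }
  if (is.null(log_sd)) {
    log_sd <- seq(0.15, 1.2, length.out = n_active)
  }
  log_sd <- rep_len(log_sd, n_active)
  if (is.null(effect_vector)) {
    effect_vector <- if (d == 23L) {
      c(0.1, rep(0, 9), seq(0, -0.4, length.out = 14)[-1])
    } else {
      rep(0, d)
    }
  }
  latent_loading <- rep_len(latent_loading, n_active)
  cfg <- list(
    n_participants = as.integer(n_participants), scheme = scheme,
    wear_minutes_mean = wear_minutes_mean, wear_minutes_sd = wear_minutes_sd,
    log_mean = log_mean, log_sd = log_sd, latent_loading = latent_loading,
    rho = rho, sed_anticorrelation = isTRUE(sed_anticorrelation),
    effect_vector = effect_vector, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  .validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

.validate_synthetic_config <- function(cfg) {
  d <- n_bins(cfg$scheme)
  if (cfg$n_participants < 2L * d) {
    stop("n_participants must be at least twice the number of bins",
         call. = FALSE)
  }
  if (any(cfg$log_sd <= 0)) stop("log_sd must be > 0", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(cfg$effect_vector) != d) {
    stop("effect_vector must have one entry per bin (", d, ")",
         call. = FALSE)
  }
  if (length(cfg$log_mean) != d - 1L) {
    stop("log_mean must have one entry per active bin (", d - 1L, ")",
         call. = FALSE)
  }
  if (cfg$rho < 0 || cfg$rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (cfg$wear_minutes_mean <= 0) {
    stop("wear_minutes_mean must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a synthetic spectrum dataset with a planted outcome signature
#'
#' Draws per-participant bin minutes with the closed, multicollinear
#' structure described in [synthetic_config()], the outcome
#' `scale(bins) %*% effect_vector + N(0, noise_sd^2)`, and a plausible
#' cardiometabolic panel whose indicators share variance with that outcome
#' (so the composite-score module can be exercised end to end).
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_dataset` list with elements `profiles` (n x D matrix
#'   of min/day, columns named by bin), `wear_minutes`, `outcome`, `panel`
#'   (a tibble in the layout [composite_score()] expects) and `truth`
#'   (planted `effect_vector` and `seed`).
#' @examples
#' ds <- generate_spectrum_dataset(synthetic_config(n_participants = 60,
#'   scheme = bin_scheme(edges = c(0, 100, 500, 1000, 4000)), seed = 3))
#' stopifnot(all(abs(rowSums(ds$profiles) - ds$wear_minutes) < 1e-9))
#' @export
generate_spectrum_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .validate_synthetic_config(config)
  d <- n_bins(config$scheme)
  n <- config$n_participants
  n_active <- d - 1L

  withr::with_seed(config$seed, {
    f <- stats::rnorm(n)
    # unit-variance AR(1) across bins, then scaled to the per-bin log sd
    innov <- matrix(stats::rnorm(n * n_active), n, n_active)
    u <- matrix(0, n, n_active)
    u[, 1L] <- innov[, 1L]
    if (n_active > 1L) {
      for (j in 2:n_active) {
        u[, j] <- config$rho * u[, j - 1L] +
          sqrt(1 - config$rho^2) * innov[, j]
      }
    }
    eps <- sweep(u, 2L, config$log_sd, "*")
    active <- exp(sweep(eps + outer(f, config$latent_loading), 2L,
                        config$log_mean, "+"))
    wear <- pmax(stats::rnorm(n, config$wear_minutes_mean,
                              config$wear_minutes_sd), 180)

    if (config$sed_anticorrelation) {
      tot <- rowSums(active)
      over <- tot > wear
      if (any(over)) {
        active[over, ] <- active[over, , drop = FALSE] *
          (wear[over] / tot[over])
      }
      sed <- pmax(wear - rowSums(active), 0)
      bins <- cbind(sed, active)
    } else {
      sed <- exp(log(0.75 * config$wear_minutes_mean) -
                   abs(config$latent_loading[1L]) * f +
                   stats::rnorm(n, sd = config$log_sd[1L]))
      bins <- cbind(sed, active)
      bins <- bins * (wear / rowSums(bins))
    }
    colnames(bins) <- config$scheme$labels

    z <- scale(bins)
    outcome <- drop(z %*% config$effect_vector) +
      stats::rnorm(n, sd = config$noise_sd)
    panel <- .synth_panel(n, outcome)
  })

  rownames(bins) <- panel$id
  structure(list(
    profiles = bins, wear_minutes = wear, outcome = outcome, panel = panel,
    truth = list(effect_vector = config$effect_vector, seed = config$seed,
                 config = config)
  ), class = "synthetic_dataset")
}

# Back-constructs a cardiometabolic panel whose six composite components each
# share half their variance with the planted outcome. Marginal means/sds are
# typical of 10-year-old cohorts. Andersen distance is reversed (fitness).
.synth_panel <- function(n, outcome, signal_share = 0.5) {
  o <- if (stats::sd(outcome) > 0) as.numeric(scale(outcome)) else rep(0, n)
  zc <- function() {
    sqrt(signal_share) * o + sqrt(1 - signal_share) * stats::rnorm(n)
  }
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::rnorm(n, 10.2, 0.3)
  sbp <- pmax(105.2 + 8.4 * zc() + 0.3 * sex, 70)
  tg <- pmax(0.78 + 0.38 * zc(), 0.15)
  tc_hdl <- pmax(2.91 + 0.71 * zc(), 1.2)
  hdl <- pmax(stats::rnorm(n, 1.59, 0.35), 0.6)
  tc <- tc_hdl * hdl
  homa_idx <- pmax(1.71 + 0.98 * zc(), 0.2)
  glucose <- pmax(stats::rnorm(n, 4.98, 0.32), 3.5)
  insulin <- homa_idx * 22.5 / glucose
  height <- pmax(stats::rnorm(n, 142.9, 6.7), 120)
  waist_height <- pmax(0.43 + 0.05 * zc(), 0.3)
  waist <- waist_height * height
  andersen <- pmax(898 - 103 * zc() + 27 * sex, 400)
  tibble::tibble(
    id = sprintf("P%04d", seq_len(n)), sex = sex, age = age,
    waist = waist, height = height, sbp = sbp, tg = tg, tc = tc, hdl = hdl,
    glucose = glucose, insulin = insulin, andersen = andersen
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$profiles), " participants x ",
      ncol(x$profiles), " bins (", x$truth$config$scheme$name,
      " scheme), seed ", x$truth$seed, "\n", sep = "")
  cat("  mean wear ", round(mean(x$wear_minutes), 1), " min/day; planted |effect| range [",
      round(min(abs(x$truth$effect_vector)), 2), ", ",
      round(max(abs(x$truth$effect_vector)), 2), "] SD\n", sep = "")
  invisible(x)
}

#' Generate a synthetic 1-s epoch count stream
#'
#' Builds one participant's epoch series from a daily wear pattern: a set of
#' blocks tiling 00:00--24:00, each with a counts-per-second level and a
#' wear flag. Non-wear blocks produce zero counts of the stated duration;
#' wear blocks produce either a constant level or (with
#' `jitter = "poisson"`) Poisson counts with that mean. The same pattern is
#' applied to every day.
#'
#' @param n_days Number of consecutive days.
#' @param wear_pattern Data frame with columns `start`, `end` (hours from
#'   midnight, tiling 0--24), `level` (counts per 1-s epoch, >= 0) and
#'   optionally `wear` (logical, default `TRUE`).
#' @param seed Integer seed; only consulted when `jitter = "poisson"`.
#' @param jitter `"none"` for constant levels, `"poisson"` for Poisson
#'   counts around them.
#' @param participant_id Identifier stored in the series.
#' @param start_date First calendar day (UTC).
#' @return An [epoch_series()] with one row per second.
#' @examples
#' wp <- data.frame(start = c(0, 8, 18), end = c(8, 18, 24),
#'                  level = c(0, 50, 0), wear = c(FALSE, TRUE, FALSE))
#' es <- generate_epoch_series(1, wp)
#' @export
generate_epoch_series <- function(n_days, wear_pattern, seed = NULL,
                                  jitter = c("none", "poisson"),
                                  participant_id = "synthetic-01",
                                  start_date = as.Date("2015-03-02")) {
  jitter <- match.arg(jitter)
  wp <- as.data.frame(wear_pattern)
  if (!all(c("start", "end", "level") %in% names(wp))) {
    stop("wear_pattern needs columns start, end, level", call. = FALSE)
  }
  if (is.null(wp$wear)) wp$wear <- TRUE
  wp <- wp[order(wp$start), , drop = FALSE]
  if (any(wp$level < 0)) stop("count levels must be >= 0", call. = FALSE)
  if (any(wp$end <= wp$start)) {
    stop("each block must end after it starts", call. = FALSE)
  }
  if (nrow(wp) > 1L && any(wp$start[-1L] < wp$end[-nrow(wp)])) {
    stop("overlapping blocks in wear_pattern", call. = FALSE)
  }
  if (wp$start[1L] != 0 || wp$end[nrow(wp)] != 24 ||
      (nrow(wp) > 1L && any(wp$start[-1L] != wp$end[-nrow(wp)]))) {
    stop("blocks must tile 00:00-24:00 exactly", call. = FALSE)
  }
  secs <- round((wp$end - wp$start) * 3600)
  level_day <- rep(wp$level, times = secs)
  wear_day <- rep(wp$wear, times = secs)
  level_day[!wear_day] <- 0

  counts <- rep(level_day, times = n_days)
  if (jitter == "poisson") {
    if (is.null(seed)) {
      stop("a seed is required for jitter = \"poisson\"", call. = FALSE)
    }
    counts <- withr::with_seed(seed, stats::rpois(length(counts), counts))
  }
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  ts <- t0 + (seq_along(counts) - 1)
  epoch_series(participant_id, ts, counts)
}

#' Two perfectly closed variables: the minimal closure demonstration
#'
#' Generates an `n` x 2 dataset whose rows sum exactly to `total`, the
#' textbook case in which closure forces the Pearson correlation between the
#' two parts to be exactly -1.
#'
#' @param n Number of rows (>= 3; correlation is degenerate below that).
#' @param total The fixed row sum (e.g. 960 waking minutes).
#' @param seed Integer seed.
#' @return An `n` x 2 numeric matrix with columns `part_1`, `part_2`.
#' @examples
#' m <- plant_two_variable_closure(100, 960, seed = 1)
#' cor(m[, 1], m[, 2])  # -1
#' @export
plant_two_variable_closure <- function(n, total, seed = 1L) {
  if (n < 3) {
    stop("n must be >= 3: correlation is degenerate for fewer rows",
         call. = FALSE)
  }
  if (total <= 0) stop("total must be positive", call. = FALSE)
  x <- withr::with_seed(seed, stats::runif(n, 0.05, 0.95) * total)
  cbind(part_1 = x, part_2 = total - x)
}
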