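#' Homeostasis-model insulin-resistance index (HOMA)
#'
#' Evaluates `glucose * insulin / 22.5`. By default insulin is taken in
#' pmol/L and enters the formula directly (`insulin_units = "pmol"`), which
#' is the form used for the composite score here. With
#' `insulin_units = "mU"` the pmol/L input is first converted to mU/L by
#' dividing by 6.945, giving the classic index for which the 22.5
#' denominator was derived. The two differ only by a constant factor, so
#' standardized downstream quantities are identical; the switch exists
#' because published insulin magnitudes are not always on the scale their
#' unit label claims.
#'
#' @param glucose Fasting glucose, mmol/L (> 0).
#' @param insulin Fasting insulin, pmol/L (> 0).
#' @param insulin_units `"pmol"` (formula as printed) or `"mU"` (classic
#'   scale after /6.945 conversion).
#' @return Numeric HOMA index.
#' @examples
#' homa(4.5, 9)      # 1.8
#' @export
homa <- function(glucose, insulin, insulin_units = c("pmol", "mU")) {
  insulin_units <- match.arg(insulin_units)
  if (any(glucose <= 0) || any(insulin <= 0)) {
    stop("glucose and insulin must be positive", call. = FALSE)
  }
  ins <- if (insulin_units == "mU") insulin / 6.945 else insulin
  glucose * ins / 22.5
}

#' Friedewald LDL cholesterol estimate
#'
#' `LDL = TC - HDL - TG / 2.2` (all in mmol/L). The formula is not valid
#' above TG 4.5 mmol/L; such values are still computed but flagged (via the
#' `"flagged"` attribute) and a warning is raised.
#'
#' @param tc,hdl,tg Total cholesterol, HDL cholesterol and triglycerides in
#'   mmol/L.
#' @return Numeric LDL estimate with logical attribute `flagged`.
#' @examples
#' friedewald_ldl(4.46, 1.59, 0.78)
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(tc < 0) || any(hdl < 0) || any(tg < 0)) {
    stop("lipid concentrations must be non-negative", call. = FALSE)
  }
  ldl <- tc - hdl - tg / 2.2
  flagged <- tg >= 4.5
  if (any(flagged)) {
    warning("triglycerides >= 4.5 mmol/L: Friedewald estimate outside its ",
            "validity range for ", sum(flagged), " value(s)", call. = FALSE)
  }
  attr(ldl, "flagged") <- flagged
  ldl
}

#' Derived ratios: TC:HDL and waist:height
#'
#' @param panel Data frame with columns `tc`, `hdl`, `waist`, `height`.
#' @return Tibble with `tc_hdl` and `waist_height`.
#' @examples
#' derived_ratios(data.frame(tc = 4.46, hdl = 1.59,
#'                           waist = 61.9, height = 142.9))
#' @export
derived_ratios <- function(panel) {
  if (any(panel$hdl <= 0) || any(panel$height <= 0)) {
    stop("hdl and height must be positive", call. = FALSE)
  }
  tibble::tibble(tc_hdl = panel$tc / panel$hdl,
                 waist_height = panel$waist / panel$height)
}

#' Composite cardiometabolic risk score
#'
#' Averages six standardized indicators -- systolic blood pressure,
#' triglycerides, TC:HDL ratio, HOMA, waist:height ratio, and the reversed
#' Andersen-test distance -- after adjusting each for sex and age. Each
#' indicator is residualized on sex (indicator) and age (continuous) by
#' least squares over the full analytic sample, the residuals are z-scored
#' (mean 0, sd 1), the Andersen z is negated (longer distance = better
#' fitness = lower risk), and the composite is the arithmetic mean of the
#' six z-scores. Higher values indicate higher cardiometabolic risk; the
#' sample mean of the composite is 0 by construction.
#'
#' Participants with any missing component are excluded (with a message).
#'
#' @param panel Data frame with columns `id`, `sex` (two levels), `age`,
#'   `waist`, `height`, `sbp`, `tg`, `tc`, `hdl`, `glucose`, `insulin`,
#'   `andersen`.
#' @param insulin_units Passed to [homa()].
#' @return Tibble with `id`, the six z-score columns (`z_andersen` already
#'   reversed) and `composite`.
#' @export
composite_score <- function(panel, insulin_units = c("pmol", "mU")) {
  insulin_units <- match.arg(insulin_units)
  needed <- c("id", "sex", "age", "waist", "height", "sbp", "tg", "tc",
              "hdl", "glucose", "insulin", "andersen")
  miss <- setdiff(needed, names(panel))
  if (length(miss)) {
    stop("panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- stats::complete.cases(panel[needed])
  if (any(!ok)) {
    message("excluding ", sum(!ok),
            " participant(s) with incomplete panels")
  }
  d <- panel[ok, , drop = FALSE]
  if (nrow(d) < 10) {
    stop("composite score needs at least 10 complete panels", call. = FALSE)
  }
  if (length(unique(d$sex)) < 2) {
    stop("both sexes must be present for the sex adjustment", call. = FALSE)
  }
  ratios <- derived_ratios(d)
  comp <- cbind(
    sbp = d$sbp, tg = d$tg, tc_hdl = ratios$tc_hdl,
    homa = homa(d$glucose, d$insulin, insulin_units),
    waist_height = ratios$waist_height, andersen = d$andersen
  )
  sexf <- factor(d$sex)
  z <- apply(comp, 2L, function(v) {
    if (stats::sd(v) == 0) {
      stop("degenerate (constant) component in composite score",
           call. = FALSE)
    }
    r <- stats::resid(stats::lm(v ~ sexf + d$age))
    r / stats::sd(r)
  })
  z[, "andersen"] <- -z[, "andersen"]
  zdf <- as.data.frame(z)
  names(zdf) <- paste0("z_", colnames(z))
  tibble::as_tibble(cbind(data.frame(id = d$id), zdf,
                          data.frame(composite = rowMeans(z))))
}
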