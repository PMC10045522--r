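#' Baseline-subtract DCFH-DA fluorescence readings
#'
#' DCFH-DA is loaded into seeds, oxidised by reactive species to
#' fluorescent DCF, and read on a fluorimeter as relative fluorescence
#' units (RFU). A dye-only well measured under the same assay
#' conditions is the technical blank; its signal is subtracted from
#' every sample reading. Negative net values are kept (they are
#' informative about blank drift) but flagged.
#'
#' @param readings Data frame with at least columns `sample` and
#'   `rfu_raw`; an optional `treatment` column is carried through.
#'   Optional assay-condition columns (`dye_uM`, `incubation_min`) are
#'   checked against the blank when present.
#' @param blank Either a single numeric RFU value or a one-row data
#'   frame shaped like `readings`.
#' @return `readings` with added columns `rfu_net` and `below_blank`.
#' @examples
#' r <- data.frame(sample = c("a", "b"), rfu_raw = c(1000, 150))
#' subtract_baseline(r, blank = 200)
#' @export
subtract_baseline <- function(readings, blank) {
  if (!is.data.frame(readings) || !"rfu_raw" %in% names(readings))
    stop("`readings` must be a data frame with an `rfu_raw` column",
         call. = FALSE)
  if (is.data.frame(blank)) {
    for (col in intersect(c("dye_uM", "incubation_min"), names(readings))) {
      if (col %in% names(blank) &&
          any(readings[[col]] != blank[[col]][1]))
        stop("blank measured under different assay conditions (", col, ")",
             call. = FALSE)
    }
    blank <- blank$rfu_raw[1]
  }
  if (!is.numeric(blank) || length(blank) != 1L || !is.finite(blank))
    stop("`blank` must be a single finite RFU value", call. = FALSE)
  readings$rfu_net <- readings$rfu_raw - blank
  readings$below_blank <- readings$rfu_net < 0
  readings
}

#' Fit a FOX-1 calibration curve
#'
#' In the ferrous oxidation-xylenol orange assay, peroxides oxidise
#' Fe2+ to Fe3+, which complexes xylenol orange into a chromophore read
#' at 560 nm. Standards of known hydrogen-peroxide concentration
#' (typically 0, 1.25, 2.50 and 5 uM) define a straight-line
#' calibration of absorbance on concentration, fitted by ordinary least
#' squares with a free intercept: the 0 uM standard is a real measured
#' blank with nonzero colour, so forcing the line through the origin
#' would bias inverse prediction.
#'
#' @param standards Data frame with columns `standard_conc_uM` and
#'   `a560` (absorbance units); at least 3 points spanning more than one
#'   distinct concentration.
#' @param r2_warn Warn when the fit's R squared falls below this value
#'   (default 0.98), a sign of a degraded working solution.
#' @return An object of class `fox_calibration` with elements `slope`
#'   (AU/uM), `intercept` (AU), `r_squared`, `n_points`,
#'   `concentration_range` and the underlying `lm` fit.
#' @seealso [predict_concentration()]
#' @examples
#' std <- data.frame(standard_conc_uM = c(0, 1.25, 2.5, 5),
#'                   a560 = 0.05 + 0.1 * c(0, 1.25, 2.5, 5))
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards, r2_warn = 0.98) {
  if (!is.data.frame(standards) ||
      !all(c("standard_conc_uM", "a560") %in% names(standards)))
    stop("`standards` needs columns `standard_conc_uM` and `a560`",
         call. = FALSE)
  conc <- standards$standard_conc_uM
  a560 <- standards$a560
  if (anyNA(conc) || anyNA(a560) || any(!is.finite(a560)) || any(conc < 0))
    stop("standards must be finite with non-negative concentrations",
         call. = FALSE)
  if (nrow(standards) < 3)
    stop("need at least 3 calibration standards", call. = FALSE)
  if (length(unique(conc)) < 2)
    stop("calibration standards must span at least 2 distinct concentrations",
         call. = FALSE)
  fit <- stats::lm(a560 ~ conc, data = data.frame(conc = conc, a560 = a560))
  # collinear standards are legitimate; silence lm's perfect-fit warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.nan(r2)) r2 <- 1  # exactly collinear response with zero residual SS
  if (r2 < r2_warn)
    warning(sprintf("calibration R^2 = %.4f below %.2f; check standards",
                    r2, r2_warn), call. = FALSE)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, n_points = nrow(standards),
         concentration_range = range(conc), fit = fit),
    class = "fox_calibration"
  )
}

#' @export
print.fox_calibration <- function(x, ...) {
  cat("FOX-1 calibration curve (A560 vs [H2O2])\n")
  cat(sprintf("  slope     %.5f AU/uM\n  intercept %.5f AU\n  R^2       %.5f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  %d standards over %.2f-%.2f uM\n", x$n_points,
              x$concentration_range[1], x$concentration_range[2]))
  invisible(x)
}

#' @export
coef.fox_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
plot.fox_calibration <- function(x, ...) {
  d <- x$fit$model
  plot(d$conc, d$a560, xlab = "[H2O2] (uM)", ylab = "A560 (AU)",
       main = "FOX-1 calibration", pch = 19, ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Inverse-predict peroxide concentration from absorbance
#'
#' Converts sample absorbances at 560 nm to hydroperoxide
#' concentrations through a fitted [fit_calibration()] line:
#' `conc = (a560 - intercept) / slope`. Concentrations cannot be
#' negative, so negative raw predictions are clipped to 0 and flagged;
#' predictions outside the standards' concentration range are flagged
#' as extrapolated.
#'
#' @param curve A `fox_calibration` object.
#' @param a560 Numeric vector of sample absorbances (AU).
#' @return A data frame with columns `a560`, `rooh_uM`, `clipped`,
#'   `extrapolated`.
#' @examples
#' std <- data.frame(standard_conc_uM = c(0, 1.25, 2.5, 5),
#'                   a560 = 0.05 + 0.1 * c(0, 1.25, 2.5, 5))
#' predict_concentration(fit_calibration(std), c(0.30, 0.02))
#' @export
predict_concentration <- function(curve, a560) {
  if (!inherits(curve, "fox_calibration"))
    stop("`curve` must be a `fox_calibration` object", call. = FALSE)
  # a slope indistinguishable from zero (flat response) cannot be inverted
  if (abs(curve$slope) <= sqrt(.Machine$double.eps) *
      max(1, abs(curve$intercept)))
    stop("calibration slope is zero: flat response, curve unusable",
         call. = FALSE)
  if (!is.numeric(a560) || any(!is.finite(a560)))
    stop("`a560` must be finite numeric", call. = FALSE)
  raw <- (a560 - curve$intercept) / curve$slope
  data.frame(
    a560 = a560,
    rooh_uM = pmax(raw, 0),
    clipped = raw < 0,
    extrapolated = raw < curve$concentration_range[1] |
      raw > curve$concentration_range[2]
  )
}
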