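# qPCR quantification: relative 2^-ddCT and absolute standard-curve methods.

#' Relative quantification by the 2^-ddCT method
#'
#' `ddCT = (CT_target,treated - CT_ref,treated) -
#' (CT_target,control - CT_ref,control)`; the fold change is `2^-ddCT`,
#' assuming perfect doubling per cycle. Replicate CTs should be averaged
#' arithmetically before calling. No efficiency correction is applied —
#' fitted efficiencies (see [fit_standard_curve()]) are reported for QC
#' only.
#'
#' @param target_ct_treated,ref_ct_treated CT of the target and the
#'   reference gene in the treated condition.
#' @param target_ct_control,ref_ct_control Same for the control condition.
#' @return Fold change (positive numeric), vectorised over inputs.
#' @examples
#' delta_delta_ct(25, 20, 24, 20) # ddCT = +1 -> 0.5
#' @export
delta_delta_ct <- function(target_ct_treated, ref_ct_treated,
                           target_ct_control, ref_ct_control) {
  cts <- c(target_ct_treated, ref_ct_treated,
           target_ct_control, ref_ct_control)
  if (any(!is.finite(cts))) abort("all CT inputs must be finite")
  ddct <- (target_ct_treated - ref_ct_treated) -
    (target_ct_control - ref_ct_control)
  2^(-ddct)
}

#' Fit a qPCR standard curve
#'
#' Least-squares line `CT = slope * log10(Q) + intercept` through the
#' dilution series. The amplification efficiency is derived as
#' `10^(-1/slope) - 1`: a slope of -3.32 cycles per decade corresponds to
#' perfect doubling (efficiency 100%). Efficiencies outside [70%, 130%]
#' are flagged `"suspect"`.
#'
#' @param log10_quantities log10 of the standard quantities (>= 2 distinct
#'   values).
#' @param ct_values Observed CT per standard.
#' @return A `standard_curve` object with `slope`, `intercept`,
#'   `efficiency`, `r_squared` and a `quality` flag.
#' @export
fit_standard_curve <- function(log10_quantities, ct_values) {
  if (length(unique(log10_quantities)) < 2) {
    abort("standard curve needs >= 2 distinct quantities")
  }
  fit <- lm(ct_values ~ log10_quantities)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    abort("standard-curve slope must be negative (CT falls as template rises)")
  }
  efficiency <- 10^(-1 / slope) - 1
  # computed directly: summary.lm() warns on exactly collinear standards
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((ct_values - mean(ct_values))^2)
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      efficiency = efficiency,
      r_squared = r2,
      quality = if (efficiency >= 0.7 && efficiency <= 1.3) "plausible" else "suspect"
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.3f cycles/decade, efficiency %.1f%% (%s), R^2 %.4f\n",
    x$slope, 100 * x$efficiency, x$quality, x$r_squared))
  invisible(x)
}

#' @describeIn fit_standard_curve Coefficients as a tibble.
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @describeIn fit_standard_curve One-row fit summary.
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         efficiency = x$efficiency, r_squared = x$r_squared,
         quality = x$quality)
}

#' Absolute quantification from a standard curve
#'
#' Inverts the fitted line: `Q = 10^((CT - intercept) / slope)`.
#'
#' @param ct Observed CT values.
#' @param curve A `standard_curve`.
#' @return Quantities on the standards' scale (positive numeric).
#' @export
absolute_quantify <- function(ct, curve) {
  if (curve$slope >= 0) abort("curve slope must be negative")
  10^((ct - curve$intercept) / curve$slope)
}
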