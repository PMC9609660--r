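#' @title Absolute qPCR quantification
#' @description
#' Microbial groups (total bacteria, fungi, protozoa, methanogens) are
#' quantified absolutely: standard masses are converted to copy numbers from
#' the amplicon length, a standard curve Ct = slope * log10(copies) +
#' intercept is fitted by least squares, amplification efficiency is derived
#' from the slope, and unknown Ct values are mapped back to copies and
#' reported as log10 copies per mL of sample.
#' @name qpcr_quant_module
NULL

#' Copies per microlitre from a DNA concentration
#'
#' Double-stranded amplicon at an average 660 g/mol per base pair:
#' `copies/uL = conc_ng_per_uL * 6.022e23 / (length_bp * 660 * 1e9)`.
#'
#' @param conc_ng_per_uL DNA concentration, ng/uL.
#' @param amplicon_length_bp amplicon length, bp.
#' @return copies per uL.
#' @examples
#' copies_from_concentration(10, 200)
#' @export
copies_from_concentration <- function(conc_ng_per_uL, amplicon_length_bp) {
  if (any(conc_ng_per_uL <= 0) || any(amplicon_length_bp <= 0))
    stop("concentration and amplicon length must be > 0", call. = FALSE)
  conc_ng_per_uL * 6.022e23 / (amplicon_length_bp * 660 * 1e9)
}

#' Fit a qPCR standard curve
#'
#' Least squares on `Ct = slope * log10(copies) + intercept` over a tenfold
#' dilution series. Efficiency is `10^(-1/slope) - 1`; a perfect doubling
#' per cycle gives slope -1/log10(2) = -3.3219 and efficiency 1.
#'
#' @param known_copies copy numbers of the standards (per reaction).
#' @param ct measured threshold cycles.
#' @param r2_warn warn when the fit's R-squared falls below this quality
#'   threshold (default 0.999).
#' @return object of class `qpcr_curve`: `slope`, `intercept`, `r_squared`,
#'   `efficiency`.
#' @export
fit_standard_curve <- function(known_copies, ct, r2_warn = 0.999) {
  if (length(known_copies) < 3)
    stop("need >= 3 standards", call. = FALSE)
  if (any(known_copies <= 0) || any(ct <= 0))
    stop("standards require copies > 0 and Ct > 0", call. = FALSE)
  lg <- log10(known_copies)
  if (stats::var(lg) == 0)
    stop("degenerate standards: no spread in log10(copies)", call. = FALSE)
  if (diff(range(lg)) < 2)
    stop("standards must span >= 2 log10 units", call. = FALSE)
  fit <- stats::lm(ct ~ lg)
  co <- stats::coef(fit)
  slope <- unname(co[2]); intercept <- unname(co[1])
  r2 <- if (stats::var(ct) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)
  eff <- if (slope < 0) 10^(-1 / slope) - 1 else NA_real_
  if (is.finite(r2) && r2 < r2_warn)
    warning(sprintf("standard-curve R^2 = %.4f below %.3f", r2, r2_warn),
            call. = FALSE)
  if (!is.na(eff) && (eff <= 0 || eff > 1.1))
    warning(sprintf("amplification efficiency %.2f outside (0, 1.1]", eff),
            call. = FALSE)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = eff),
            class = "qpcr_curve")
}

#' Quantify an unknown sample from its Ct
#'
#' @param ct threshold cycle(s) of the unknown.
#' @param curve a [fit_standard_curve()] result (slope must be negative).
#' @param dilution_to_per_mL multiplicative factor converting copies per
#'   reaction to copies per mL of the original sample (extraction and
#'   dilution chain collapsed into one factor).
#' @param group optional microbial group label.
#' @return data.frame with `group`, `copies_per_reaction`, `copies_per_mL`
#'   and `log10_copies_per_mL`.
#' @export
quantify_unknown <- function(ct, curve, dilution_to_per_mL = 1,
                             group = NA_character_) {
  if (!all(c("slope", "intercept") %in% names(curve)))
    stop("curve must carry slope and intercept", call. = FALSE)
  if (!is.finite(curve$slope) || curve$slope >= 0)
    stop("invalid standard curve: slope must be < 0", call. = FALSE)
  if (any(dilution_to_per_mL <= 0))
    stop("dilution factor must be > 0", call. = FALSE)
  copies <- 10^((ct - curve$intercept) / curve$slope)
  per_ml <- copies * dilution_to_per_mL
  data.frame(group = group, copies_per_reaction = copies,
             copies_per_mL = per_ml,
             log10_copies_per_mL = log10(per_ml))
}
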