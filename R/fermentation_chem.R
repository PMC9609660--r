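#' @title End-point fermentation chemistry
#' @description
#' Summaries computed from the 72 h end-point of each bottle: total VFA,
#' acetate:propionate ratio and molar proportions; dry-matter digestibility
#' from residue weights; linear standard-curve conversion for colorimetric
#' assays (microbial protein, ammonia nitrogen); and classification of the
#' 20-amino-acid panel into essential and non-essential totals.
#' @name fermentation_chem_module
NULL

#' Total VFA, acetate:propionate ratio and molar proportions
#'
#' @param profile named numeric of the six acid concentrations in mmol/L
#'   (see [vfa_profile()]).
#' @return list with `tvfa` (mmol/L), `ap_ratio` and `proportions`
#'   (named fractions of TVFA, summing to 1).
#' @examples
#' summarize_vfa(vfa_profile(39.2, 21.1, 13.45, 1.99, 2.16, 4.36))
#' @export
summarize_vfa <- function(profile) {
  x <- unclass(unlist(profile))
  .require_acids(as.list(x), .vfa_acids)
  x <- x[.vfa_acids]
  tvfa <- sum(x)
  if (x[["propionate"]] <= 0)
    stop("A/P ratio undefined: propionate must be > 0", call. = FALSE)
  if (tvfa <= 0)
    stop("molar proportions undefined: TVFA is 0", call. = FALSE)
  list(tvfa = tvfa,
       ap_ratio = x[["acetate"]] / x[["propionate"]],
       proportions = x / tvfa)
}

#' Dry-matter digestibility
#'
#' `DMD (%) = (1 - residue / substrate) * 100`.
#'
#' @param residue_g dried residue mass after digestion, g.
#' @param substrate_g substrate dry mass before digestion, g.
#' @return digestibility, percent. Values below 0 (residue heavier than
#'   substrate) are retained with a warning.
#' @export
dmd <- function(residue_g, substrate_g) {
  if (any(substrate_g <= 0))
    stop("substrate_g must be > 0", call. = FALSE)
  if (any(residue_g < 0))
    stop("residue_g must be >= 0", call. = FALSE)
  out <- (1 - residue_g / substrate_g) * 100
  if (any(out < 0))
    warning("DMD below 0% (residue exceeds substrate)", call. = FALSE)
  out
}

#' Fit a linear standard curve
#'
#' Least-squares fit `response = slope * quantity + intercept` for a
#' colorimetric assay.
#'
#' @param quantity known standard quantities (concentrations).
#' @param response measured responses (absorbances).
#' @return object of class `linear_curve`: `slope`, `intercept`,
#'   `r_squared`.
#' @export
fit_linear_curve <- function(quantity, response) {
  if (length(quantity) < 2 || length(unique(quantity)) < 2)
    stop("need >= 2 distinct standards", call. = FALSE)
  fit <- stats::lm(response ~ quantity)
  co <- stats::coef(fit)
  r2 <- if (stats::var(response) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2),
            class = "linear_curve")
}

#' Convert an absorbance to a concentration via a standard curve
#'
#' @param absorbance measured response(s).
#' @param curve a [fit_linear_curve()] result, or a list with `slope` and
#'   `intercept`.
#' @return `(absorbance - intercept) / slope`.
#' @export
colorimetric_quantity <- function(absorbance, curve) {
  if (!all(c("slope", "intercept") %in% names(curve)))
    stop("curve must carry slope and intercept", call. = FALSE)
  if (curve$slope == 0)
    stop("degenerate standard curve: slope is 0", call. = FALSE)
  (absorbance - curve$intercept) / curve$slope
}

# Panel groupings. Histidine is summed with the non-essential block,
# matching the reporting convention this analysis reproduces.
.essential_aa <- c("isoleucine", "leucine", "lysine", "methionine",
                   "phenylalanine", "threonine", "tryptophan", "valine")
.nonessential_aa <- c("histidine", "alanine", "arginine", "glycine",
                      "glutamine", "glutamate", "proline", "tyrosine",
                      "serine", "aspartic_acid", "asparagine", "cysteine")

#' Names of the 20 panel amino acids
#' @return character vector: 8 essential then 12 non-essential analytes.
#' @export
amino_acid_names <- function() c(.essential_aa, .nonessential_aa)

#' Classify an amino-acid panel into essential/non-essential totals
#'
#' @param panel named numeric of the 20 amino-acid concentrations (ng/mL),
#'   using the names of [amino_acid_names()].
#' @return list with `eaa_total`, `neaa_total`, `total` and the input
#'   `panel` (reordered).
#' @export
classify_amino_acids <- function(panel) {
  panel <- unlist(panel)
  missing <- setdiff(amino_acid_names(), names(panel))
  if (length(missing))
    stop("missing amino acid(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(panel), amino_acid_names())
  if (length(unknown))
    stop("unknown analyte(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  eaa <- sum(panel[.essential_aa])
  neaa <- sum(panel[.nonessential_aa])
  list(eaa_total = eaa, neaa_total = neaa, total = eaa + neaa,
       panel = panel[amino_acid_names()])
}
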