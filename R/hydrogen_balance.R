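#' @title Metabolic hydrogen balance from VFA and methane stoichiometry
#' @description
#' Rumen fermentation releases reducing equivalents when acetate and butyrate
#' are formed and consumes them through methanogenesis and propionate
#' synthesis. The Demeyer stoichiometry books these flows from the net molar
#' production of the volatile fatty acids (VFA) and methane:
#' \deqn{H_2 produced = 2A + P + 4B + 2iV + 2V}
#' \deqn{H_2 utilized = 4M + 2P + 3B + V}
#' \deqn{H_2 recovery (\%) = utilized / produced \times 100}
#' where A, P, B, iV, V are acetate, propionate, butyrate, isovalerate and
#' valerate amounts (mmol) and M is methane (mmol). Lactate, formate and
#' succinate are not part of this bookkeeping. Isobutyrate carries no term.
#' @name hydrogen_balance_module
NULL

# acid names recognised throughout the package
.vfa_acids <- c("acetate", "propionate", "butyrate", "isobutyrate",
                "valerate", "isovalerate")

#' Construct a VFA concentration profile
#'
#' @param acetate,propionate,butyrate,isobutyrate,valerate,isovalerate
#'   concentrations in mmol/L, all non-negative scalars.
#' @return named numeric vector of class `vfa_profile` (mmol/L).
#' @examples
#' vfa_profile(38.3, 21.4, 13.4, 2.05, 2.13, 4.47)
#' @export
vfa_profile <- function(acetate, propionate, butyrate, isobutyrate,
                        valerate, isovalerate) {
  x <- c(acetate = acetate, propionate = propionate, butyrate = butyrate,
         isobutyrate = isobutyrate, valerate = valerate,
         isovalerate = isovalerate)
  if (any(!is.finite(x)) || any(x < 0))
    stop("VFA concentrations must be finite and >= 0", call. = FALSE)
  structure(x, class = "vfa_profile")
}

#' Convert VFA concentrations to amounts
#'
#' @param profile named numeric of concentrations in mmol/L (a
#'   [vfa_profile()] or any vector naming the six acids).
#' @param liquid_volume_L incubation liquid volume in litres. The default
#'   0.06 L corresponds to a 20 mL rumen-fluid inoculum plus 40 mL buffer.
#' @return named numeric of per-acid amounts in mmol.
#' @export
vfa_to_mmol <- function(profile, liquid_volume_L = 0.06) {
  stopifnot(is.numeric(liquid_volume_L), length(liquid_volume_L) == 1L)
  if (liquid_volume_L <= 0)
    stop("liquid_volume_L must be > 0", call. = FALSE)
  x <- unclass(profile) * liquid_volume_L
  names(x) <- names(profile)
  x
}

#' Convert a methane volume to mmol
#'
#' @param volume_mL gas volume in mL.
#' @param molar_volume_L_per_mol molar volume of the gas; 22.4 L/mol (STP,
#'   default) or 25.6 L/mol at the 39 degree C incubation temperature.
#' @return amount in mmol (`volume_mL / molar_volume`).
#' @export
ch4_ml_to_mmol <- function(volume_mL, molar_volume_L_per_mol = 22.4) {
  if (any(molar_volume_L_per_mol <= 0))
    stop("molar volume must be > 0", call. = FALSE)
  volume_mL / molar_volume_L_per_mol
}

.require_acids <- function(amounts, need) {
  missing <- setdiff(need, names(amounts))
  if (length(missing))
    stop("missing VFA amounts for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- need[!is.finite(unlist(amounts)[need])]
  if (length(bad))
    stop("non-finite VFA amounts for: ", paste(bad, collapse = ", "),
         call. = FALSE)
}

#' Hydrogen produced by VFA synthesis
#'
#' `2A + P + 4B + 2iV + 2V`. Isobutyrate does not enter the formula.
#'
#' @param amounts_mmol named numeric of per-acid amounts in mmol (at least
#'   acetate, propionate, butyrate, isovalerate, valerate).
#' @return hydrogen produced, mmol.
#' @examples
#' h2_produced(vfa_to_mmol(vfa_profile(38.3, 21.4, 13.4, 2.05, 2.13, 4.47)))
#' @export
h2_produced <- function(amounts_mmol) {
  .require_acids(amounts_mmol,
                 c("acetate", "propionate", "butyrate", "isovalerate",
                   "valerate"))
  a <- unlist(amounts_mmol)
  unname(2 * a[["acetate"]] + a[["propionate"]] + 4 * a[["butyrate"]] +
           2 * a[["isovalerate"]] + 2 * a[["valerate"]])
}

#' Hydrogen utilized by methanogenesis and VFA synthesis
#'
#' `4M + 2P + 3B + V` with M the methane amount in mmol.
#'
#' @param ch4_mmol methane amount, mmol.
#' @param amounts_mmol named numeric of per-acid amounts in mmol.
#' @return hydrogen utilized, mmol.
#' @export
h2_utilized <- function(ch4_mmol, amounts_mmol) {
  if (!is.numeric(ch4_mmol) || any(!is.finite(ch4_mmol)))
    stop("ch4_mmol must be finite numeric", call. = FALSE)
  .require_acids(amounts_mmol, c("propionate", "butyrate", "valerate"))
  a <- unlist(amounts_mmol)
  unname(4 * ch4_mmol + 2 * a[["propionate"]] + 3 * a[["butyrate"]] +
           a[["valerate"]])
}

#' Hydrogen recovery percentage
#'
#' @param produced_mmol,utilized_mmol hydrogen produced and utilized, mmol.
#' @return `utilized / produced * 100`, percent.
#' @export
h2_recovery <- function(produced_mmol, utilized_mmol) {
  if (any(produced_mmol <= 0))
    stop("hydrogen recovery undefined: produced must be > 0", call. = FALSE)
  utilized_mmol / produced_mmol * 100
}

#' Full hydrogen balance for one fermentation bottle
#'
#' @param profile VFA concentrations, mmol/L (see [vfa_profile()]).
#' @param ch4_mmol methane amount in mmol; alternatively supply `ch4_mL`.
#' @param ch4_mL methane volume in mL, converted with
#'   `molar_volume_L_per_mol` when `ch4_mmol` is not given.
#' @param liquid_volume_L incubation liquid volume, litres.
#' @param molar_volume_L_per_mol molar volume used for the mL to mmol
#'   conversion.
#' @return data.frame with columns `h2_produced`, `h2_utilized` (mmol) and
#'   `h2_recovery` (percent).
#' @examples
#' hydrogen_balance(vfa_profile(38.3, 21.4, 13.4, 2.05, 2.13, 4.47),
#'                  ch4_mmol = 0.748)
#' @export
hydrogen_balance <- function(profile, ch4_mmol = NULL, ch4_mL = NULL,
                             liquid_volume_L = 0.06,
                             molar_volume_L_per_mol = 22.4) {
  if (is.null(ch4_mmol)) {
    if (is.null(ch4_mL))
      stop("supply ch4_mmol or ch4_mL", call. = FALSE)
    ch4_mmol <- ch4_ml_to_mmol(ch4_mL, molar_volume_L_per_mol)
  }
  amounts <- vfa_to_mmol(profile, liquid_volume_L)
  produced <- h2_produced(amounts)
  utilized <- h2_utilized(ch4_mmol, amounts)
  data.frame(h2_produced = produced, h2_utilized = utilized,
             h2_recovery = h2_recovery(produced, utilized))
}
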