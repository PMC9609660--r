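#' @title Gas production: blank correction, cumulation, normalisation
#' @description
#' Syringe readings taken from each incubation bottle at fixed timepoints are
#' corrected against substrate-free blank bottles, cumulated over the 72 h
#' incubation, and normalised per gram of substrate dry matter. Methane
#' interval volumes are the product of the interval net gas and the measured
#' CH4 volume fraction for that interval (optionally the gross gas). Bottles
#' whose 72 h cumulative net gas deviates by more than a threshold percent
#' from their group mean are rejected in a single pass.
#' @name gas_production_module
NULL

.reading_cols <- c("bottle_id", "treatment", "run", "is_blank",
                   "substrate_g", "time_h", "volume_mL")

.check_readings <- function(readings) {
  missing <- setdiff(.reading_cols, names(readings))
  if (length(missing))
    stop("gas readings lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(readings$volume_mL < 0))
    stop("gas volumes must be >= 0", call. = FALSE)
  if (any(readings$time_h <= 0))
    stop("timepoints must be > 0 h", call. = FALSE)
  if ("ch4_fraction" %in% names(readings)) {
    f <- readings$ch4_fraction
    if (any(!is.na(f) & (f < 0 | f > 1)))
      stop("ch4_fraction must lie in [0, 1]", call. = FALSE)
  }
  invisible(readings)
}

#' Mean blank volume per timepoint
#'
#' Blank bottles (no substrate) track the gas produced by the inoculum alone;
#' their per-timepoint mean is subtracted from every reading.
#'
#' @param readings long-format gas readings (see [cumulate_gas()] for the
#'   schema) containing at least one row with `is_blank = TRUE`.
#' @param time_h optional timepoints to report; defaults to all blank
#'   timepoints.
#' @return data.frame with columns `time_h` and `blank_mL`.
#' @export
blank_mean <- function(readings, time_h = NULL) {
  .check_readings(readings)
  bl <- readings[readings$is_blank, , drop = FALSE]
  if (!nrow(bl))
    stop("no blank bottles in readings", call. = FALSE)
  means <- aggregate(volume_mL ~ time_h, data = bl, FUN = mean)
  names(means)[2] <- "blank_mL"
  if (!is.null(time_h)) {
    miss <- setdiff(time_h, means$time_h)
    if (length(miss))
      stop("no blank reading at timepoint(s): ",
           paste(miss, collapse = ", "), " h", call. = FALSE)
    means <- means[match(time_h, means$time_h), , drop = FALSE]
  }
  rownames(means) <- NULL
  means
}

#' Net gas volume
#'
#' Gross syringe reading minus the mean blank volume for the same interval.
#' Negative nets are kept, not clipped, so that interval sums remain
#' conservative; a warning reports how many occurred.
#'
#' @param gross_mL gross interval volume(s), mL.
#' @param blank_mean_mL mean blank volume(s) for the matching interval, mL.
#' @return net volume(s), mL (possibly negative).
#' @export
net_gas <- function(gross_mL, blank_mean_mL) {
  if (any(blank_mean_mL < 0))
    stop("blank mean must be >= 0", call. = FALSE)
  net <- gross_mL - blank_mean_mL
  n_neg <- sum(net < 0)
  if (n_neg)
    warning(n_neg, " negative net gas interval(s) retained", call. = FALSE)
  net
}

#' Cumulative blank-corrected gas and methane curves
#'
#' @param readings long-format data.frame with columns `bottle_id`,
#'   `treatment`, `run`, `is_blank` (logical), `substrate_g`, `time_h`,
#'   `volume_mL` and optionally `ch4_fraction`. One row per bottle and
#'   timepoint; `volume_mL` is the gross interval volume read at `time_h`.
#' @param ch4_basis `"net"` (default) multiplies the CH4 fraction by the
#'   interval net gas; `"gross"` by the uncorrected interval reading.
#' @return list with `curves` (per bottle and timepoint: `cum_net_mL`,
#'   `cum_ch4_mL`) and `totals` (per bottle: 72 h — i.e. final-timepoint —
#'   totals plus `gas_per_gDM` and `ch4_per_gDM`).
#' @export
cumulate_gas <- function(readings, ch4_basis = c("net", "gross")) {
  ch4_basis <- match.arg(ch4_basis)
  .check_readings(readings)
  bl <- blank_mean(readings)
  live <- readings[!readings$is_blank, , drop = FALSE]
  if (!nrow(live)) stop("no non-blank bottles", call. = FALSE)
  if (any(live$substrate_g <= 0))
    stop("non-blank bottles must have substrate_g > 0", call. = FALSE)
  timepoints <- sort(unique(live$time_h))
  miss <- setdiff(timepoints, bl$time_h)
  if (length(miss))
    stop("no blank reading at timepoint(s): ",
         paste(miss, collapse = ", "), " h", call. = FALSE)
  if (!"ch4_fraction" %in% names(live)) live$ch4_fraction <- NA_real_

  pieces <- lapply(split(live, live$bottle_id), function(b) {
    b <- b[order(b$time_h), , drop = FALSE]
    if (anyDuplicated(b$time_h))
      stop("duplicate timepoint for bottle ", b$bottle_id[1], call. = FALSE)
    miss <- setdiff(timepoints, b$time_h)
    if (length(miss))
      stop("bottle ", b$bottle_id[1], " missing timepoint(s): ",
           paste(miss, collapse = ", "), " h", call. = FALSE)
    net <- suppressWarnings(
      net_gas(b$volume_mL, bl$blank_mL[match(b$time_h, bl$time_h)]))
    basis <- if (ch4_basis == "net") net else b$volume_mL
    ch4 <- ifelse(is.na(b$ch4_fraction), 0, b$ch4_fraction) * basis
    data.frame(bottle_id = b$bottle_id, treatment = b$treatment,
               run = b$run, substrate_g = b$substrate_g,
               time_h = b$time_h, net_mL = net,
               cum_net_mL = cumsum(net), cum_ch4_mL = cumsum(ch4))
  })
  curves <- do.call(rbind, pieces)
  rownames(curves) <- NULL
  n_neg <- sum(curves$net_mL < 0)
  if (n_neg)
    warning(n_neg, " negative net gas interval(s) retained", call. = FALSE)

  last <- curves[curves$time_h == max(timepoints), , drop = FALSE]
  totals <- data.frame(
    bottle_id = last$bottle_id, treatment = last$treatment, run = last$run,
    substrate_g = last$substrate_g,
    total_gas_mL = last$cum_net_mL, total_ch4_mL = last$cum_ch4_mL,
    gas_per_gDM = last$cum_net_mL / last$substrate_g,
    ch4_per_gDM = last$cum_ch4_mL / last$substrate_g)
  rownames(totals) <- NULL
  list(curves = curves, totals = totals)
}

#' Reject bottles deviating from their group mean
#'
#' Within each treatment-by-run group, a bottle is rejected when its 72 h
#' cumulative net gas deviates from the group mean by more than
#' `threshold_pct` percent. The reference mean is computed once from all
#' bottles in the group (single pass); it is not iterated after removal.
#'
#' @param totals the `totals` element of [cumulate_gas()].
#' @param threshold_pct rejection threshold, percent of the group mean.
#' @return list with `retained` and `rejected` (both shaped like `totals`;
#'   `rejected` gains a `deviation_pct` column).
#' @export
reject_deviant_bottles <- function(totals, threshold_pct = 10) {
  stopifnot(is.numeric(threshold_pct), length(threshold_pct) == 1L)
  groups <- split(totals, interaction(totals$treatment, totals$run,
                                      drop = TRUE))
  keep <- list(); drop <- list()
  for (g in groups) {
    if (nrow(g) < 2)
      stop("need >= 2 bottles per group for rejection screening",
           call. = FALSE)
    m <- mean(g$total_gas_mL)
    dev <- abs(g$total_gas_mL - m) / abs(m) * 100
    out <- is.finite(dev) & dev > threshold_pct
    if (all(out))
      stop("all bottles rejected in group ", g$treatment[1], "/run ",
           g$run[1], call. = FALSE)
    keep[[length(keep) + 1L]] <- g[!out, , drop = FALSE]
    if (any(out)) {
      r <- g[out, , drop = FALSE]
      r$deviation_pct <- dev[out]
      drop[[length(drop) + 1L]] <- r
    }
  }
  retained <- do.call(rbind, keep)
  rejected <- if (length(drop)) do.call(rbind, drop) else
    cbind(totals[0, , drop = FALSE], deviation_pct = numeric(0))
  rownames(retained) <- rownames(rejected) <- NULL
  if (nrow(rejected))
    warning(nrow(rejected), " bottle(s) rejected (> ", threshold_pct,
            "% deviation)", call. = FALSE)
  list(retained = retained, rejected = rejected)
}

#' Average retained bottles into run-level experimental units
#'
#' The experimental unit for the group statistics is the mean of the
#' retained bottles of one treatment within one run.
#'
#' @param df data.frame with `treatment` and `run` columns plus numeric
#'   measurement columns.
#' @param value_cols columns to average; defaults to all numeric columns
#'   other than `run` and `substrate_g`.
#' @return data.frame with one row per treatment-by-run unit.
#' @export
run_averages <- function(df, value_cols = NULL) {
  if (is.null(value_cols)) {
    num <- vapply(df, is.numeric, logical(1))
    value_cols <- setdiff(names(df)[num], c("run", "substrate_g"))
  }
  out <- aggregate(df[value_cols],
                   by = list(treatment = df$treatment, run = df$run),
                   FUN = mean)
  out[order(out$treatment, out$run), , drop = FALSE]
}
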