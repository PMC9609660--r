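#' @title Synthetic batch-culture experiments with known ground truth
#' @description
#' Generates complete synthetic in vitro experiments with the statistical
#' structure the analysis assumes: saturating single-pool gas curves with
#' multiplicative lognormal interval noise and matching blank bottles;
#' end-point chemistry, amino-acid and qPCR tables with additive truncated
#' Normal noise (Normal noise on Ct); and Dirichlet-multinomial OTU count
#' tables. Defaults emulate a 4-treatment (Control/SN/CS/CSN) x 5-bottle x
#' 2-run design read at 3, 6, 9, 12, 24, 48 and 72 h, with 0.5 g substrate
#' and 60 mL incubation liquid. A single global seed feeds an independent
#' substream per table so adding one table never perturbs another.
#' @name synthetic_data_module
NULL

# deterministic substream seed from (seed, tag); stays below 2^31
.substream <- function(seed, tag) {
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v)) %% 1000003
  as.integer((as.numeric(seed) %% 65521 * 31627 + h * 97 + 1) %% 2147483647)
}

# Normal(mean, sd) truncated at 0 by rejection; sd = 0 returns the mean
.rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Define a synthetic treatment
#'
#' @param label treatment name.
#' @param endpoint_means named numeric of population means for every
#'   measured end-point quantity (VFA fractions, pH, NH3-N, MCP, DMD, amino
#'   acids, microbial log10 counts).
#' @param endpoint_sds matching named numeric of standard deviations
#'   (>= 0; every mean must have an sd).
#' @param gas_asymptote_mL final cumulative net gas per bottle, mL.
#' @param gas_rate_per_h first-order rate constant of the gas curve, /h.
#' @param ch4_fraction_curve CH4 volume fraction of net gas per interval;
#'   scalar or one value per timepoint, each in [0, 1].
#' @return object of class `treatment_spec`.
#' @export
treatment_spec <- function(label, endpoint_means, endpoint_sds,
                           gas_asymptote_mL, gas_rate_per_h,
                           ch4_fraction_curve) {
  stopifnot(is.character(label), length(label) == 1L)
  if (is.null(names(endpoint_means)) || is.null(names(endpoint_sds)))
    stop("endpoint means and sds must be named", call. = FALSE)
  miss <- setdiff(names(endpoint_means), names(endpoint_sds))
  if (length(miss))
    stop("no sd for endpoint(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(endpoint_sds < 0)) stop("sds must be >= 0", call. = FALSE)
  if (gas_asymptote_mL < 0)
    stop("gas asymptote must be >= 0", call. = FALSE)
  if (gas_rate_per_h <= 0)
    stop("gas rate constant must be > 0", call. = FALSE)
  if (any(ch4_fraction_curve < 0 | ch4_fraction_curve > 1))
    stop("ch4 fractions must lie in [0, 1]", call. = FALSE)
  structure(list(label = label, endpoint_means = endpoint_means,
                 endpoint_sds = endpoint_sds[names(endpoint_means)],
                 gas_asymptote_mL = gas_asymptote_mL,
                 gas_rate_per_h = gas_rate_per_h,
                 ch4_fraction_curve = ch4_fraction_curve),
            class = "treatment_spec")
}

#' Configure a synthetic experiment
#'
#' @param n_bottles_per_treatment incubation bottles per treatment per run.
#' @param n_runs experimental runs.
#' @param n_blanks substrate-free blank bottles per run.
#' @param timepoints_h strictly increasing reading times, hours.
#' @param substrate_g substrate dry mass per bottle, g.
#' @param liquid_volume_mL incubation liquid volume, mL.
#' @param seed global integer RNG seed.
#' @param gas_noise_sd sdlog of the multiplicative lognormal noise on gas
#'   intervals (0 = noiseless).
#' @param blank_mL_per_interval inoculum-driven gas per interval in blanks,
#'   mL; also the drift added to every gross reading.
#' @param ct_noise_sd additive Normal noise on qPCR Ct values.
#' @param endpoint_noise overall multiplier on the endpoint sds (1 =
#'   configured sds, 0 = noiseless).
#' @param qpcr_slope,qpcr_intercept true standard-curve parameters used to
#'   emit Ct values.
#' @param dilution_to_per_mL factor from copies per reaction to copies per
#'   mL used when emitting unknowns.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_bottles_per_treatment = 5, n_runs = 2,
                             n_blanks = 3,
                             timepoints_h = c(3, 6, 9, 12, 24, 48, 72),
                             substrate_g = 0.5, liquid_volume_mL = 60,
                             seed = 1L, gas_noise_sd = 0.05,
                             blank_mL_per_interval = 2,
                             ct_noise_sd = 0.15,
                             endpoint_noise = 1,
                             qpcr_slope = -3.3219, qpcr_intercept = 38,
                             dilution_to_per_mL = 1e5) {
  if (is.unsorted(timepoints_h, strictly = TRUE))
    stop("timepoints must be strictly increasing", call. = FALSE)
  if (substrate_g <= 0) stop("substrate_g must be > 0", call. = FALSE)
  if (liquid_volume_mL <= 0)
    stop("liquid_volume_mL must be > 0", call. = FALSE)
  structure(list(n_bottles_per_treatment = n_bottles_per_treatment,
                 n_runs = n_runs, n_blanks = n_blanks,
                 timepoints_h = timepoints_h, substrate_g = substrate_g,
                 liquid_volume_mL = liquid_volume_mL,
                 seed = as.integer(seed), gas_noise_sd = gas_noise_sd,
                 blank_mL_per_interval = blank_mL_per_interval,
                 ct_noise_sd = ct_noise_sd,
                 endpoint_noise = endpoint_noise,
                 qpcr_slope = qpcr_slope, qpcr_intercept = qpcr_intercept,
                 dilution_to_per_mL = dilution_to_per_mL),
            class = "synthetic_config")
}

# quantity blocks used to split endpoint tables
.chem_quantities <- c("pH", .vfa_acids, "nh3_n", "mcp", "dmd")
.microbial_groups <- c("bacteria", "fungi", "protozoa", "methanogens")

#' Preset treatments for a nitrate/cysteamine batch-culture study
#'
#' Four treatments — Control, sodium nitrate (SN), cysteamine (CS) and
#' their combination (CSN) — parameterised to a published buffalo
#' low-protein-diet experiment: end-point means for fermentation chemistry,
#' the 20-amino-acid panel and microbial log10 counts, with per-bottle sds
#' back-derived from the pooled SEMs as `SEM * sqrt(2)` (two run-level
#' experimental units). Gas asymptotes are the reported 72 h mL/gDM totals
#' scaled by 0.5 g substrate; CH4 fractions are the CH4:gas volume ratios.
#'
#' @return named list of four [treatment_spec()] objects.
#' @export
preset_treatments <- function() {
  mk <- function(chem, aa, micro, sem_scale = sqrt(2)) {
    sems <- c(pH = 0.01, acetate = 0.46, propionate = 0.24,
              butyrate = 0.13, isobutyrate = 0.03, valerate = 0.03,
              isovalerate = 0.06, nh3_n = 0.19, mcp = 0.15, dmd = 1.92,
              isoleucine = 18.2, leucine = 18.2, lysine = 3.83,
              methionine = 13.0, phenylalanine = 27.0, threonine = 19.1,
              tryptophan = 8.56, valine = 23.2, histidine = 69.3,
              alanine = 38.3, arginine = 16.2, glycine = 14.2,
              glutamine = 4.84, glutamate = 233, proline = 6.55,
              tyrosine = 1.51, serine = 24.2, aspartic_acid = 1.44,
              asparagine = 7.05, cysteine = 0.47,
              bacteria = 0.03, fungi = 0.04, protozoa = 0.08,
              methanogens = 0.03)
    means <- c(chem, aa, micro)
    list(means = means, sds = sems[names(means)] * sem_scale)
  }
  chem <- list(
    Control = c(pH = 6.83, acetate = 38.3, propionate = 21.4,
                butyrate = 13.4, isobutyrate = 2.05, valerate = 2.13,
                isovalerate = 4.47, nh3_n = 18.7, mcp = 4.01, dmd = 43.0),
    SN = c(pH = 6.90, acetate = 42.0, propionate = 19.1, butyrate = 6.94,
           isobutyrate = 1.60, valerate = 1.61, isovalerate = 3.54,
           nh3_n = 18.1, mcp = 4.82, dmd = 39.8),
    CS = c(pH = 6.81, acetate = 39.2, propionate = 21.1, butyrate = 13.45,
           isobutyrate = 1.99, valerate = 2.16, isovalerate = 4.36,
           nh3_n = 18.8, mcp = 4.06, dmd = 42.0),
    CSN = c(pH = 6.89, acetate = 42.9, propionate = 18.6, butyrate = 6.75,
            isobutyrate = 1.53, valerate = 1.62, isovalerate = 3.43,
            nh3_n = 18.5, mcp = 5.65, dmd = 37.0))
  aa <- list(
    Control = c(isoleucine = 40.7, leucine = 45.7, lysine = 40.9,
                methionine = 22.5, phenylalanine = 68.3, threonine = 125,
                tryptophan = 26.9, valine = 236, histidine = 1119,
                alanine = 131, arginine = 289, glycine = 102,
                glutamine = 57.4, glutamate = 1690, proline = 95.7,
                tyrosine = 35.0, serine = 291, aspartic_acid = 20.9,
                asparagine = 44.0, cysteine = 4.00),
    SN = c(isoleucine = 209, leucine = 214, lysine = 28.4,
           methionine = 148, phenylalanine = 314, threonine = 281,
           tryptophan = 105, valine = 384, histidine = 759,
           alanine = 486, arginine = 197, glycine = 226,
           glutamine = 16.7, glutamate = 3851, proline = 29.4,
           tyrosine = 36.1, serine = 436, aspartic_acid = 11.8,
           asparagine = 204, cysteine = 4.38),
    CS = c(isoleucine = 140, leucine = 145, lysine = 13.4,
           methionine = 101, phenylalanine = 195, threonine = 205,
           tryptophan = 60.6, valine = 286, histidine = 639,
           alanine = 321, arginine = 126, glycine = 161,
           glutamine = 18.9, glutamate = 3160, proline = 44.6,
           tyrosine = 36.2, serine = 295, aspartic_acid = 8.91,
           asparagine = 141, cysteine = 4.96),
    CSN = c(isoleucine = 55.2, leucine = 60.2, lysine = 11.6,
            methionine = 44.2, phenylalanine = 69.5, threonine = 107,
            tryptophan = 25.4, valine = 460, histidine = 378,
            alanine = 149, arginine = 223, glycine = 98.2,
            glutamine = 10.1, glutamate = 1849, proline = 49.2,
            tyrosine = 40.9, serine = 204, aspartic_acid = 12.5,
            asparagine = 59.7, cysteine = 5.40))
  micro <- list(
    Control = c(bacteria = 11.9, fungi = 9.97, protozoa = 8.13,
                methanogens = 10.0),
    SN = c(bacteria = 12.1, fungi = 10.2, protozoa = 8.55,
           methanogens = 10.1),
    CS = c(bacteria = 12.0, fungi = 10.1, protozoa = 8.54,
           methanogens = 10.1),
    CSN = c(bacteria = 12.3, fungi = 10.4, protozoa = 8.52,
            methanogens = 10.3))
  gas <- c(Control = 117, SN = 69.9, CS = 120, CSN = 71.5)       # mL/gDM
  ch4 <- c(Control = 14.3, SN = 6.05, CS = 13.8, CSN = 5.84)     # mL/gDM
  out <- lapply(names(chem), function(g) {
    ms <- mk(chem[[g]], aa[[g]], micro[[g]])
    treatment_spec(g, ms$means, ms$sds,
                   gas_asymptote_mL = gas[[g]] * 0.5,
                   gas_rate_per_h = 0.08,
                   ch4_fraction_curve = ch4[[g]] / gas[[g]])
  })
  stats::setNames(out, names(chem))
}

#' Preset genus-level community compositions
#'
#' Per-treatment taxon probability vectors built from reported relative
#' abundances of the 15 major rumen genera, with the remainder pooled into
#' an `other` taxon so each vector sums to 1.
#'
#' @return matrix, taxa as rows, treatments (Control/SN/CS/CSN) as columns.
#' @export
preset_compositions <- function() {
  g <- rbind(
    Rikenellaceae_RC9_gut_group = c(13.4, 11.3, 12.6, 11.2),
    Christensenellaceae_R7_group = c(6.94, 7.61, 7.18, 10.57),
    Muribaculaceae = c(4.75, 7.71, 7.18, 9.04),
    NK4A214_group = c(6.21, 5.94, 6.61, 7.44),
    F082 = c(7.54, 6.07, 6.51, 4.15),
    Prevotella = c(2.62, 6.63, 3.31, 4.40),
    UCG_011 = c(4.04, 4.16, 4.41, 4.34),
    Succiniclasticum = c(4.65, 3.00, 3.16, 3.40),
    UCG_010 = c(2.84, 1.98, 2.75, 1.93),
    Campylobacter = c(0.01, 4.32, 0.01, 3.15),
    UCG_005 = c(1.68, 1.63, 1.75, 2.12),
    WCHB1_41 = c(3.21, 1.46, 1.40, 0.61),
    Butyrivibrio = c(1.24, 1.99, 1.45, 1.73),
    Eubacterium_coprostanoligenes_group = c(1.68, 1.08, 1.89, 1.21),
    Lachnospiraceae_NK3A20_group = c(1.23, 1.37, 1.56, 1.20))
  colnames(g) <- c("Control", "SN", "CS", "CSN")
  comp <- rbind(g, other = 100 - colSums(g)) / 100
  comp
}

#' Generate a gas and methane timecourse for one treatment
#'
#' Per-bottle interval net volumes derive from the single-pool saturating
#' curve `V(t) = A (1 - exp(-k t))` with multiplicative lognormal noise
#' (unit mean), reported as gross readings (net plus blank drift) together
#' with matching blank bottles. Deterministic under the config seed.
#'
#' @param config a [synthetic_config()].
#' @param spec a [treatment_spec()].
#' @param include_blanks emit the blank bottles too (default TRUE).
#' @return long-format data.frame in the [cumulate_gas()] schema.
#' @export
generate_gas_timecourse <- function(config, spec, include_blanks = TRUE) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(spec, "treatment_spec"))
  if (spec$gas_rate_per_h <= 0)
    stop("gas rate constant must be > 0", call. = FALSE)
  tp <- config$timepoints_h
  frac <- rep_len(spec$ch4_fraction_curve, length(tp))
  set.seed(.substream(config$seed, paste0("gas_", spec$label)))
  ideal <- diff(c(0, spec$gas_asymptote_mL *
                    (1 - exp(-spec$gas_rate_per_h * tp))))
  sdl <- config$gas_noise_sd
  rows <- list()
  for (r in seq_len(config$n_runs)) {
    for (b in seq_len(config$n_bottles_per_treatment)) {
      noise <- if (sdl > 0)
        stats::rlnorm(length(tp), -sdl^2 / 2, sdl) else rep(1, length(tp))
      net <- ideal * noise
      rows[[length(rows) + 1L]] <- data.frame(
        bottle_id = sprintf("%s_r%d_b%d", spec$label, r, b),
        treatment = spec$label, run = r, is_blank = FALSE,
        substrate_g = config$substrate_g, time_h = tp,
        volume_mL = net + config$blank_mL_per_interval,
        ch4_fraction = frac)
    }
    if (include_blanks) {
      for (b in seq_len(config$n_blanks)) {
        noise <- if (sdl > 0)
          stats::rlnorm(length(tp), -sdl^2 / 2, sdl) else rep(1, length(tp))
        rows[[length(rows) + 1L]] <- data.frame(
          bottle_id = sprintf("blank_r%d_b%d", r, b),
          treatment = "blank", run = r, is_blank = TRUE,
          substrate_g = 0, time_h = tp,
          volume_mL = config$blank_mL_per_interval * noise,
          ch4_fraction = 0)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate end-point chemistry, amino-acid and qPCR tables
#'
#' Per-bottle values are drawn independently from Normal(mean, sd)
#' truncated at 0 (sd scaled by `config$endpoint_noise`). qPCR unknowns are
#' emitted as Ct values computed from the configured true standard curve
#' plus Normal Ct noise, alongside tenfold-dilution standards per group.
#'
#' @param config a [synthetic_config()].
#' @param specs list of [treatment_spec()]; all must name the same
#'   quantity set.
#' @return list: `chemistry`, `amino_acids`, `qpcr` data.frames.
#' @export
generate_endpoint_tables <- function(config, specs) {
  stopifnot(inherits(config, "synthetic_config"))
  qsets <- lapply(specs, function(s) sort(names(s$endpoint_means)))
  if (length(unique(qsets)) != 1)
    stop("treatment specs name different quantity sets", call. = FALSE)
  qty <- names(specs[[1]]$endpoint_means)
  chem_q <- intersect(.chem_quantities, qty)
  aa_q <- intersect(amino_acid_names(), qty)
  mic_q <- intersect(.microbial_groups, qty)

  draw_block <- function(tag, quantities) {
    set.seed(.substream(config$seed, tag))
    rows <- list()
    for (s in specs) for (r in seq_len(config$n_runs))
      for (b in seq_len(config$n_bottles_per_treatment)) {
        vals <- vapply(quantities, function(q)
          .rnorm_trunc0(1, s$endpoint_means[[q]],
                        s$endpoint_sds[[q]] * config$endpoint_noise),
          numeric(1))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(bottle_id = sprintf("%s_r%d_b%d", s$label, r, b),
                     treatment = s$label, run = r),
          as.data.frame(as.list(vals)))
      }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }

  chemistry <- draw_block("chemistry", chem_q)
  if ("dmd" %in% names(chemistry))
    chemistry$residue_g <- config$substrate_g * (1 - chemistry$dmd / 100)
  amino_acids <- draw_block("amino_acids", aa_q)

  # qPCR plate: standards (tenfold dilutions) + unknowns per bottle x group
  set.seed(.substream(config$seed, "qpcr"))
  sl <- config$qpcr_slope; ic <- config$qpcr_intercept
  plate <- list()
  for (g in mic_q) {
    cp <- 10^(3:8)
    plate[[length(plate) + 1L]] <- data.frame(
      well = sprintf("std_%s_%d", g, seq_along(cp)), target_group = g,
      role = "standard", known_copies = cp,
      ct = sl * log10(cp) + ic +
        stats::rnorm(length(cp), 0, config$ct_noise_sd),
      sample_id = NA_character_,
      dilution_factor = config$dilution_to_per_mL)
  }
  for (s in specs) for (r in seq_len(config$n_runs))
    for (b in seq_len(config$n_bottles_per_treatment)) {
      id <- sprintf("%s_r%d_b%d", s$label, r, b)
      for (g in mic_q) {
        L <- .rnorm_trunc0(1, s$endpoint_means[[g]],
                           s$endpoint_sds[[g]] * config$endpoint_noise)
        copies_rxn <- 10^L / config$dilution_to_per_mL
        plate[[length(plate) + 1L]] <- data.frame(
          well = sprintf("unk_%s_%s", g, id), target_group = g,
          role = "unknown", known_copies = NA_real_,
          ct = sl * log10(copies_rxn) + ic +
            stats::rnorm(1, 0, config$ct_noise_sd),
          sample_id = id, dilution_factor = config$dilution_to_per_mL)
      }
    }
  qpcr <- do.call(rbind, plate)
  rownames(qpcr) <- NULL
  list(chemistry = chemistry, amino_acids = amino_acids, qpcr = qpcr)
}

#' Generate a Dirichlet-multinomial OTU count table
#'
#' Each sample's composition is drawn from a Dirichlet with concentration
#' `overdispersion * composition` for its group, then counts from a
#' multinomial at the given depth. `overdispersion = Inf` gives pure
#' multinomial sampling at the group composition.
#'
#' @param config a [synthetic_config()] (supplies the seed).
#' @param group_compositions matrix of taxon probabilities (taxa as rows,
#'   groups as columns, each column summing to 1), e.g.
#'   [preset_compositions()].
#' @param depth reads per sample (> 0).
#' @param overdispersion Dirichlet concentration parameter (larger = less
#'   sample-to-sample compositional variation).
#' @param n_samples_per_group samples per group; defaults to bottles x runs.
#' @return OTU table data.frame (`sample_id`, `group`, one column per
#'   taxon); row sums all equal `depth`.
#' @export
generate_otu_table <- function(config, group_compositions,
                               depth = 10000, overdispersion = 200,
                               n_samples_per_group = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  comp <- as.matrix(group_compositions)
  if (any(comp < 0))
    stop("taxon probabilities must be >= 0", call. = FALSE)
  if (any(abs(colSums(comp) - 1) > 1e-6))
    stop("each group composition must sum to 1", call. = FALSE)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (is.null(n_samples_per_group))
    n_samples_per_group <- config$n_bottles_per_treatment * config$n_runs
  set.seed(.substream(config$seed, "otu"))
  rows <- list()
  for (g in colnames(comp)) {
    p0 <- comp[, g]
    for (i in seq_len(n_samples_per_group)) {
      p <- if (is.infinite(overdispersion)) p0 else {
        a <- stats::rgamma(length(p0), shape = overdispersion * p0)
        if (sum(a) == 0) p0 else a / sum(a)
      }
      counts <- as.integer(stats::rmultinom(1, depth, p))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(sample_id = sprintf("%s_s%d", g, i), group = g),
        as.data.frame(as.list(stats::setNames(counts, rownames(comp)))))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic experiment
#'
#' @param config a [synthetic_config()].
#' @param specs treatments (default [preset_treatments()]).
#' @param compositions community compositions (default
#'   [preset_compositions()]); `NULL` skips the OTU table.
#' @param depth,overdispersion passed to [generate_otu_table()].
#' @return list: `gas`, `chemistry`, `amino_acids`, `qpcr`, `otu` (or
#'   NULL) and `ground_truth` (config + specs).
#' @export
simulate_experiment <- function(config = synthetic_config(),
                                specs = preset_treatments(),
                                compositions = preset_compositions(),
                                depth = 10000, overdispersion = 200) {
  gas <- do.call(rbind, c(
    list(generate_gas_timecourse(config, specs[[1]],
                                 include_blanks = TRUE)),
    lapply(specs[-1], generate_gas_timecourse, config = config,
           include_blanks = FALSE)))
  rownames(gas) <- NULL
  endp <- generate_endpoint_tables(config, specs)
  otu <- if (!is.null(compositions))
    generate_otu_table(config, compositions, depth, overdispersion)
  list(gas = gas, chemistry = endp$chemistry,
       amino_acids = endp$amino_acids, qpcr = endp$qpcr, otu = otu,
       ground_truth = list(config = config, specs = specs))
}

#' Write a simulated experiment to disk
#'
#' Emits the CSV/TSV schemas the analysis stages consume plus a JSON
#' manifest recording the config, seed and ground-truth parameters.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_experiment <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(gas = file.path(dir, "gas_readings.csv"),
             chemistry = file.path(dir, "chemistry.csv"),
             amino_acids = file.path(dir, "amino_acids.csv"),
             qpcr = file.path(dir, "qpcr_plate.csv"),
             otu = file.path(dir, "otu_table.tsv"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(sim$gas, paths["gas"], row.names = FALSE)
  utils::write.csv(sim$chemistry, paths["chemistry"], row.names = FALSE)
  utils::write.csv(sim$amino_acids, paths["amino_acids"],
                   row.names = FALSE)
  utils::write.csv(sim$qpcr, paths["qpcr"], row.names = FALSE)
  if (!is.null(sim$otu))
    utils::write.table(sim$otu, paths["otu"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
  gt <- sim$ground_truth
  manifest <- list(
    config = unclass(gt$config),
    treatments = lapply(gt$specs, function(s) {
      s <- unclass(s)
      s$endpoint_means <- as.list(s$endpoint_means)
      s$endpoint_sds <- as.list(s$endpoint_sds)
      s
    }))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
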