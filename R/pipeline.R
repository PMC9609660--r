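#' @title End-to-end pipeline orchestration
#' @description
#' Chains the analysis stages — gas cumulation and rejection, hydrogen
#' balance, fermentation chemistry, amino-acid classification, qPCR
#' quantification, community diversity and group statistics — over the
#' tabular inputs, producing publication-shaped summary tables and a run
#' manifest sufficient to reproduce the run.
#' @name cli_pipeline_module
NULL

#' Read an experiment directory
#'
#' Expects the file layout written by [write_experiment()]; the OTU table
#' is optional.
#'
#' @param dir directory containing `gas_readings.csv`, `chemistry.csv`,
#'   `amino_acids.csv`, `qpcr_plate.csv` and optionally `otu_table.tsv`.
#' @return list of data.frames (`gas`, `chemistry`, `amino_acids`,
#'   `qpcr`, `otu`).
#' @export
read_experiment <- function(dir) {
  need <- c(gas = "gas_readings.csv", chemistry = "chemistry.csv",
            amino_acids = "amino_acids.csv", qpcr = "qpcr_plate.csv")
  out <- lapply(need, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    utils::read.csv(p, stringsAsFactors = FALSE)
  })
  p_otu <- file.path(dir, "otu_table.tsv")
  out$otu <- if (file.exists(p_otu))
    utils::read.delim(p_otu, stringsAsFactors = FALSE, check.names = FALSE)
  out
}

.first_bad <- function(cond, what) {
  i <- which(cond)[1]
  sprintf("%s (first at row %d)", what, i)
}

#' Validate input tables against the expected schemas
#'
#' @param tables list with any of `gas`, `chemistry`, `amino_acids`,
#'   `qpcr`, `otu` data.frames.
#' @return data.frame with one row per table: `table`, `ok`, `message`.
#'   No side effects.
#' @export
validate_inputs <- function(tables) {
  check <- function(tab, fn) {
    if (is.null(tab)) return(c(TRUE, "absent (optional)"))
    msg <- fn(tab)
    if (is.null(msg)) c(TRUE, "ok") else c(FALSE, msg)
  }
  checks <- list(
    gas = function(t) {
      miss <- setdiff(.reading_cols, names(t))
      if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
      if (any(t$volume_mL < 0))
        return(.first_bad(t$volume_mL < 0, "negative volume_mL"))
      if ("ch4_fraction" %in% names(t)) {
        bad <- !is.na(t$ch4_fraction) &
          (t$ch4_fraction < 0 | t$ch4_fraction > 1)
        if (any(bad))
          return(.first_bad(bad, "ch4_fraction outside [0, 1]"))
      }
      NULL
    },
    chemistry = function(t) {
      need <- c("bottle_id", "treatment", "run", .vfa_acids)
      miss <- setdiff(need, names(t))
      if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
      for (a in .vfa_acids) {
        if (any(t[[a]] < 0))
          return(.first_bad(t[[a]] < 0,
                            paste("negative", a, "concentration")))
      }
      NULL
    },
    amino_acids = function(t) {
      miss <- setdiff(c("bottle_id", "treatment", "run",
                        amino_acid_names()), names(t))
      if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
      NULL
    },
    qpcr = function(t) {
      miss <- setdiff(c("target_group", "role", "known_copies", "ct",
                        "sample_id", "dilution_factor"), names(t))
      if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
      if (any(t$ct <= 0, na.rm = TRUE))
        return(.first_bad(!is.na(t$ct) & t$ct <= 0, "non-positive Ct"))
      NULL
    },
    otu = function(t) {
      miss <- setdiff(c("sample_id", "group"), names(t))
      if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
      m <- t[, setdiff(names(t), c("sample_id", "group")), drop = FALSE]
      bad <- vapply(m, function(x) any(x < 0 | x != round(x)), logical(1))
      if (any(bad))
        return(paste("non-integer or negative counts in taxon:",
                     names(m)[bad][1]))
      NULL
    })
  res <- lapply(names(checks), function(nm)
    check(tables[[nm]], checks[[nm]]))
  data.frame(table = names(checks),
             ok = vapply(res, function(r) as.logical(r[1]), logical(1)),
             message = vapply(res, function(r) r[2], character(1)))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes gas cumulation and deviant-bottle rejection, per-bottle
#' hydrogen balance, fermentation and amino-acid summaries, qPCR
#' quantification, optional community diversity, and treatment comparison
#' on run-level experimental units (mean of retained bottles per treatment
#' per run). Deterministic given the inputs and `seed`.
#'
#' @param tables input tables as from [read_experiment()] or
#'   [simulate_experiment()].
#' @param liquid_volume_L incubation liquid volume for the VFA unit bridge.
#' @param molar_volume_L_per_mol molar volume for CH4 mL to mmol.
#' @param reject_pct gas rejection threshold, percent (Inf disables).
#' @param ch4_basis `"net"` or `"gross"`, see [cumulate_gas()].
#' @param n_permutations PERMANOVA permutations.
#' @param seed integer seed for the permutation test.
#' @param out_dir optional directory; when given, summary tables and the
#'   manifest are written there as CSV/JSON.
#' @return list: `gas` (curves/totals/retained/rejected), `units`
#'   (run-level experimental units, all parameters), `summary` (per-block
#'   publication-shaped comparison tables), `diversity` (alpha table,
#'   dissimilarity matrix, PERMANOVA) or NULL, and `manifest`.
#' @export
run_full_pipeline <- function(tables, liquid_volume_L = 0.06,
                              molar_volume_L_per_mol = 22.4,
                              reject_pct = 10,
                              ch4_basis = c("net", "gross"),
                              n_permutations = 999, seed = 1L,
                              out_dir = NULL) {
  ch4_basis <- match.arg(ch4_basis)
  rep_ok <- validate_inputs(tables)
  if (!all(rep_ok$ok))
    stop("input validation failed: ",
         paste(rep_ok$table[!rep_ok$ok], rep_ok$message[!rep_ok$ok],
               collapse = "; "), call. = FALSE)

  # gas stage
  cum <- .stage("gas", cumulate_gas(tables$gas, ch4_basis))
  scr <- .stage("gas", suppressWarnings(
    reject_deviant_bottles(cum$totals, reject_pct)))
  retained <- scr$retained
  gas_units <- run_averages(
    retained[c("treatment", "run", "gas_per_gDM", "ch4_per_gDM")])

  # hydrogen balance per retained bottle
  chem <- tables$chemistry[tables$chemistry$bottle_id %in%
                             retained$bottle_id, , drop = FALSE]
  h2 <- .stage("hydrogen_balance", {
    idx <- match(chem$bottle_id, retained$bottle_id)
    ch4_mmol <- ch4_ml_to_mmol(retained$total_ch4_mL[idx],
                               molar_volume_L_per_mol)
    do.call(rbind, lapply(seq_len(nrow(chem)), function(i) {
      prof <- unlist(chem[i, .vfa_acids])
      hydrogen_balance(prof, ch4_mmol = ch4_mmol[i],
                       liquid_volume_L = liquid_volume_L)
    }))
  })
  h2 <- cbind(chem[c("bottle_id", "treatment", "run")], h2)

  # fermentation chemistry per bottle
  ferm <- .stage("fermentation_chem", {
    sv <- lapply(seq_len(nrow(chem)), function(i)
      summarize_vfa(unlist(chem[i, .vfa_acids])))
    out <- chem
    out$tvfa <- vapply(sv, `[[`, numeric(1), "tvfa")
    out$ap_ratio <- vapply(sv, `[[`, numeric(1), "ap_ratio")
    if ("residue_g" %in% names(out)) {
      sub_g <- if ("substrate_g" %in% names(out)) out$substrate_g else
        unique(tables$gas$substrate_g[!tables$gas$is_blank])[1]
      out$dmd <- dmd(out$residue_g, sub_g)
    }
    out
  })

  # amino acids per bottle
  aa <- tables$amino_acids[tables$amino_acids$bottle_id %in%
                             retained$bottle_id, , drop = FALSE]
  aa <- .stage("amino_acids", {
    cls <- lapply(seq_len(nrow(aa)), function(i)
      classify_amino_acids(unlist(aa[i, amino_acid_names()])))
    aa$eaa_total <- vapply(cls, `[[`, numeric(1), "eaa_total")
    aa$neaa_total <- vapply(cls, `[[`, numeric(1), "neaa_total")
    aa$total_aa <- vapply(cls, `[[`, numeric(1), "total")
    aa
  })

  # qPCR quantification
  micro <- .stage("qpcr", {
    plate <- tables$qpcr
    out <- NULL
    for (g in unique(plate$target_group)) {
      std <- plate[plate$target_group == g & plate$role == "standard", ]
      unk <- plate[plate$target_group == g & plate$role == "unknown", ]
      curve <- suppressWarnings(
        fit_standard_curve(std$known_copies, std$ct))
      q <- quantify_unknown(unk$ct, curve, unk$dilution_factor, group = g)
      q$sample_id <- unk$sample_id
      out <- rbind(out, q)
    }
    wide <- stats::reshape(
      out[c("sample_id", "group", "log10_copies_per_mL")],
      idvar = "sample_id", timevar = "group", direction = "wide")
    names(wide) <- sub("^log10_copies_per_mL\\.", "", names(wide))
    merge(chem[c("bottle_id", "treatment", "run")], wide,
          by.x = "bottle_id", by.y = "sample_id")
  })

  # run-level experimental units across all blocks
  drop_cols <- c("bottle_id", "residue_g", "substrate_g")
  unit_of <- function(df) run_averages(
    df[setdiff(names(df), drop_cols)])
  units <- list(gas = gas_units, hydrogen = unit_of(h2),
                chemistry = unit_of(ferm), amino_acids = unit_of(aa),
                microbial = unit_of(micro))

  summary <- .stage("group_stats", lapply(units, comparison_table))

  diversity <- if (!is.null(tables$otu)) .stage("diversity", {
    d <- bray_curtis(tables$otu)
    list(alpha = alpha_diversity(tables$otu), dissimilarity = d,
         permanova = permanova(d, tables$otu$group, n_permutations, seed))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("rumenbatch")),
    parameters = list(liquid_volume_L = liquid_volume_L,
                      molar_volume_L_per_mol = molar_volume_L_per_mol,
                      reject_pct = reject_pct, ch4_basis = ch4_basis,
                      n_permutations = n_permutations, seed = seed),
    rows = lapply(tables[!vapply(tables, is.null, logical(1))], nrow),
    rejected_bottles = scr$rejected$bottle_id,
    retained_bottles = retained$bottle_id,
    timestamp = format(Sys.time(), tz = "UTC"))

  result <- list(gas = c(cum, scr), units = units, summary = summary,
                 diversity = diversity, manifest = manifest)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(summary))
      utils::write.csv(summary[[nm]],
                       file.path(out_dir, paste0("summary_", nm, ".csv")),
                       row.names = FALSE)
    if (!is.null(diversity))
      utils::write.csv(diversity$alpha,
                       file.path(out_dir, "alpha_diversity.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
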