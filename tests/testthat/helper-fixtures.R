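# Shared fixtures built in code.

# VFA concentration columns (mmol/L) of the four preset treatments,
# as reported for the source experiment.
preset_vfa <- function() {
  list(
    Control = vfa_profile(38.3, 21.4, 13.4, 2.05, 2.13, 4.47),
    SN = vfa_profile(42.0, 19.1, 6.94, 1.60, 1.61, 3.54),
    CS = vfa_profile(39.2, 21.1, 13.45, 1.99, 2.16, 4.36),
    CSN = vfa_profile(42.9, 18.6, 6.75, 1.53, 1.62, 3.43))
}

# small long-format gas readings table: one bottle per treatment label,
# gross interval volumes given per timepoint, plus blank bottles.
make_readings <- function(net_by_bottle, blank_mL, times,
                          ch4_fraction = NA_real_, substrate_g = 0.5) {
  rows <- list()
  for (id in names(net_by_bottle)) {
    rows[[id]] <- data.frame(
      bottle_id = id, treatment = sub("_b.*", "", id), run = 1,
      is_blank = FALSE, substrate_g = substrate_g, time_h = times,
      volume_mL = net_by_bottle[[id]] + blank_mL,
      ch4_fraction = ch4_fraction)
  }
  rows$blank <- data.frame(
    bottle_id = "blank_1", treatment = "blank", run = 1, is_blank = TRUE,
    substrate_g = 0, time_h = times, volume_mL = blank_mL,
    ch4_fraction = 0)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# random VFA profile for property tests
random_profile <- function() {
  vfa_profile(runif(1, 0, 60), runif(1, 0.1, 30), runif(1, 0, 20),
              runif(1, 0, 5), runif(1, 0, 5), runif(1, 0, 8))
}

# random sparse count vector emulating an OTU sample
random_counts <- function(n_taxa = 60) {
  x <- rpois(n_taxa, lambda = rexp(n_taxa, 1 / 8))
  if (sum(x) == 0) x[1] <- 1L
  x
}

# OTU table with an exactly known presence/absence Venn partition:
# `shared` OTUs in all four groups, `unique_n[g]` OTUs private to group g.
venn_fixture <- function(groups = c("Control", "SN", "CS", "CSN"),
                         shared = 30, unique_n = c(4, 5, 3, 2)) {
  names(unique_n) <- groups
  n_taxa <- shared + sum(unique_n)
  taxa <- paste0("otu", seq_len(n_taxa))
  rows <- list()
  start <- shared
  priv <- lapply(groups, function(g) integer(0))
  names(priv) <- groups
  for (g in groups) {
    priv[[g]] <- start + seq_len(unique_n[[g]])
    start <- start + unique_n[[g]]
  }
  for (g in groups) for (i in 1:2) {
    counts <- integer(n_taxa)
    counts[seq_len(shared)] <- 5L
    counts[priv[[g]]] <- 3L
    rows[[paste(g, i)]] <- cbind(
      data.frame(sample_id = paste0(g, "_s", i), group = g),
      as.data.frame(as.list(setNames(counts, taxa))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
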