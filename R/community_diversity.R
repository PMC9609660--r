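#' @title OTU-table community analytics
#' @description
#' Within-sample (alpha) diversity indices in their Mothur formulations,
#' shared/unique OTU partitions across treatment groups, Bray-Curtis
#' dissimilarity, and a permutation PERMANOVA (Anderson's pseudo-F on the
#' dissimilarity matrix).
#'
#' An OTU table here is a data.frame whose first column is `sample_id`,
#' second column `group`, and remaining columns non-negative integer counts,
#' one per taxon.
#' @name community_diversity_module
NULL

#' Extract the count matrix of an OTU table
#' @param table OTU table data.frame (`sample_id`, `group`, counts...).
#' @return numeric matrix, samples as rows (named), taxa as columns.
#' @export
otu_counts <- function(table) {
  stopifnot(all(c("sample_id", "group") %in% names(table)))
  m <- as.matrix(table[, setdiff(names(table), c("sample_id", "group")),
                       drop = FALSE])
  if (any(m < 0) || any(m != round(m)))
    stop("OTU counts must be non-negative integers", call. = FALSE)
  rownames(m) <- table$sample_id
  storage.mode(m) <- "double"
  m
}

#' Alpha diversity indices of one sample
#'
#' Indices follow the Mothur definitions: Shannon `-sum p_i ln p_i`;
#' Simpson dominance `sum n_i (n_i - 1) / (N (N - 1))`; Chao1
#' `S_obs + F1^2 / (2 F2)` with the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` when F2 = 0; ACE with rare-taxon
#' cutoff `ace_cutoff`; Good's coverage `1 - F1 / N`.
#'
#' @param counts non-negative integer vector of per-taxon counts.
#' @param ace_cutoff abundance threshold separating rare from abundant taxa
#'   in the ACE estimator (default 10).
#' @return one-row data.frame: `observed_otus`, `shannon`, `simpson`,
#'   `chao1`, `ace`, `goods_coverage`.
#' @examples
#' alpha_indices(c(5, 3, 1, 1))
#' @export
alpha_indices <- function(counts, ace_cutoff = 10) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N <= 0) stop("empty sample: no counts", call. = FALSE)
  S <- length(counts)
  p <- counts / N
  shannon <- -sum(p * log(p))
  simpson <- if (N > 1) sum(counts * (counts - 1)) / (N * (N - 1)) else 1
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  chao1 <- if (F2 > 0) S + F1^2 / (2 * F2) else
    S + F1 * (F1 - 1) / (2 * (F2 + 1))
  # ACE: abundance-based coverage estimator
  rare <- counts[counts <= ace_cutoff]
  S_rare <- length(rare); S_abund <- S - S_rare
  N_rare <- sum(rare)
  if (S_rare == 0) {
    ace <- S
  } else {
    C_ace <- 1 - F1 / N_rare
    if (C_ace <= 0) {
      ace <- NA_real_  # all rare taxa are singletons; estimator undefined
    } else {
      i <- seq_len(ace_cutoff)
      Fi <- vapply(i, function(k) sum(counts == k), numeric(1))
      g2 <- max(S_rare / C_ace * sum(i * (i - 1) * Fi) /
                  (N_rare * (N_rare - 1)) - 1, 0)
      if (!is.finite(g2)) g2 <- 0
      ace <- S_abund + S_rare / C_ace + F1 / C_ace * g2
    }
  }
  data.frame(observed_otus = S, shannon = shannon, simpson = simpson,
             chao1 = chao1, ace = ace, goods_coverage = 1 - F1 / N)
}

#' Alpha diversity for every sample of an OTU table
#'
#' @param table OTU table data.frame.
#' @param ace_cutoff see [alpha_indices()].
#' @return data.frame with `sample_id`, `group` and the six indices.
#' @export
alpha_diversity <- function(table, ace_cutoff = 10) {
  m <- otu_counts(table)
  out <- do.call(rbind, lapply(seq_len(nrow(m)), function(i)
    alpha_indices(m[i, ], ace_cutoff)))
  cbind(sample_id = table$sample_id, group = table$group, out)
}

#' Rarefy an OTU table to a common depth
#'
#' Subsamples each sample's counts without replacement to `depth` reads.
#'
#' @param table OTU table data.frame.
#' @param depth target reads per sample; samples below it are dropped with
#'   a warning.
#' @param seed integer RNG seed.
#' @return rarefied OTU table.
#' @export
rarefy_counts <- function(table, depth, seed = 1L) {
  m <- otu_counts(table)
  tot <- rowSums(m)
  keep <- tot >= depth
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped",
            call. = FALSE)
  m <- m[keep, , drop = FALSE]
  set.seed(seed)
  out <- t(apply(m, 1, function(x) {
    picked <- sample(rep.int(seq_along(x), x), depth)
    tabulate(picked, nbins = length(x))
  }))
  colnames(out) <- colnames(m)
  cbind(table[keep, c("sample_id", "group"), drop = FALSE],
        as.data.frame(out))
}

#' Shared and unique OTU partition across groups
#'
#' An OTU is present in a group when its count summed over the group's
#' samples exceeds `min_count - 1` (default: any read). Returns the full
#' presence/absence Venn partition.
#'
#' @param table OTU table data.frame with >= 2 groups.
#' @param min_count minimum group-summed count for presence (default 1).
#' @return list with `regions` (named counts, names like `"A&B"`),
#'   `shared_all` and `unique` (named per group).
#' @export
otu_venn <- function(table, min_count = 1) {
  m <- otu_counts(table)
  groups <- unique(table$group)
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  pres <- vapply(groups, function(g)
    colSums(m[table$group == g, , drop = FALSE]) >= min_count,
    logical(ncol(m)))
  colnames(pres) <- groups
  key <- apply(pres, 1, function(r) paste(groups[r], collapse = "&"))
  key <- key[key != ""]
  tab <- table(key)
  regions <- stats::setNames(as.integer(tab), names(tab))
  region_of <- function(k) if (k %in% names(regions)) regions[[k]] else 0L
  list(regions = regions,
       shared_all = region_of(paste(groups, collapse = "&")),
       unique = stats::setNames(vapply(groups, region_of, integer(1)),
                                groups))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`.
#'
#' @param table OTU table data.frame (or a plain count matrix).
#' @return symmetric matrix of dissimilarities in `[0, 1]`, zero diagonal.
#' @export
bray_curtis <- function(table) {
  m <- if (is.matrix(table)) table else otu_counts(table)
  if (nrow(m) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(rowSums(m) == 0))
    stop("distance undefined for all-zero sample(s)", call. = FALSE)
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Permutation PERMANOVA on a dissimilarity matrix
#'
#' Anderson's pseudo-F from among/within sums of squared dissimilarities,
#' with a permutation p-value using the `(count + 1) / (n + 1)` convention.
#'
#' @param dist symmetric dissimilarity matrix (or `dist` object).
#' @param groups factor of group labels, one per sample.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer RNG seed for the permutations.
#' @return list: `pseudo_f`, `r_squared`, `p_value`, `n_permutations`.
#' @export
permanova <- function(dist, groups, n_permutations = 999, seed = 1L) {
  d <- as.matrix(dist)
  groups <- as.factor(groups)
  n <- nrow(d)
  if (length(groups) != n)
    stop("groups length must match distance matrix", call. = FALSE)
  if (nlevels(droplevels(groups)) < 2)
    stop("need >= 2 groups", call. = FALSE)
  if (n_permutations < 1)
    stop("n_permutations must be >= 1", call. = FALSE)
  if (any(table(groups) < 2))
    warning("group(s) with a single sample: design is degenerate",
            call. = FALSE)
  d2 <- d^2
  a <- nlevels(droplevels(groups))
  SS_T <- sum(d2[upper.tri(d2)]) / n
  if (SS_T <= 0)  # all samples identical: no structure to test
    return(list(pseudo_f = 0, r_squared = 0, p_value = 1,
                n_permutations = n_permutations))
  ss_within <- function(lab) {
    s <- 0
    for (g in levels(lab)) {
      idx <- which(lab == g)
      ng <- length(idx)
      if (ng > 1) s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / ng
    }
    s
  }
  f_stat <- function(lab) {
    SS_W <- ss_within(lab)
    SS_A <- SS_T - SS_W
    (SS_A / (a - 1)) / (SS_W / (n - a))
  }
  F_obs <- f_stat(groups)
  SS_W_obs <- ss_within(groups)
  set.seed(seed)
  count <- 0L
  for (i in seq_len(n_permutations)) {
    if (f_stat(groups[sample.int(n)]) >= F_obs) count <- count + 1L
  }
  list(pseudo_f = F_obs,
       r_squared = (SS_T - SS_W_obs) / SS_T,
       p_value = (count + 1) / (n_permutations + 1),
       n_permutations = n_permutations)
}
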