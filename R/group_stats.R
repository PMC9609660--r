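#' @title Treatment comparison and association analysis
#' @description
#' One-way ANOVA per parameter with pooled SEM and compact significance
#' letters driven by Tukey HSD pairwise comparisons (letters assigned in
#' descending-mean order starting at "a"), and starred Spearman rank
#' correlation matrices between taxon abundances and fermentation or
#' amino-acid parameters.
#' @name group_stats_module
NULL

# Compact letter display by insertion-absorption on a logical
# "significantly different" matrix; groups must be ordered by the caller
# (descending mean). Returns one letter string per group.
.compact_letters <- function(diff_mat) {
  k <- nrow(diff_mat)
  sets <- list(seq_len(k))              # start: everyone shares one letter
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (!diff_mat[i, j]) next
    for (s in seq_along(sets)) {
      if (all(c(i, j) %in% sets[[s]])) {
        sets <- c(sets, list(setdiff(sets[[s]], i)),
                  list(setdiff(sets[[s]], j)))
        sets[s] <- list(NULL)
      }
    }
    sets <- Filter(Negate(is.null), sets)
    # absorb subsets
    keep <- rep(TRUE, length(sets))
    for (s in seq_along(sets)) for (t in seq_along(sets)) {
      if (s != t && keep[s] && keep[t] &&
          all(sets[[s]] %in% sets[[t]])) keep[s] <- FALSE
    }
    sets <- sets[keep]
  }
  # order letter sets by their highest-mean (lowest-index) member
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  out <- character(k)
  for (s in seq_along(sets))
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  out
}

#' Compare treatment groups on one parameter
#'
#' One-way ANOVA, pooled SEM and a compact letter display from Tukey HSD.
#' Treatments sharing a letter do not differ pairwise at `alpha`; letters
#' are assigned in descending-mean order starting at "a".
#'
#' @param values numeric observations (one per experimental unit).
#' @param group treatment labels, same length as `values`; >= 2 groups with
#'   >= 2 units each.
#' @param alpha pairwise significance level (default 0.05).
#' @return list: `means` (named, descending), `sem` (pooled,
#'   `sqrt(MSE / n)` with n the per-group unit count), `p_value` (ANOVA F
#'   test), `letters` (named by group, in `means` order).
#' @examples
#' compare_groups(c(1, 1.1, 5, 5.2, 9, 9.1),
#'                rep(c("a", "b", "c"), each = 2))
#' @export
compare_groups <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
  n_per <- table(group)
  if (any(n_per < 2))
    stop("insufficient replication: every group needs >= 2 units",
         call. = FALSE)
  means <- sort(tapply(values, group, mean), decreasing = TRUE)
  ord <- names(means)
  fit <- stats::aov(values ~ group)
  sm <- summary(fit)[[1]]
  mse <- sm["Residuals", "Mean Sq"]
  p <- sm["group", "Pr(>F)"]
  k <- length(ord)
  diff_mat <- matrix(FALSE, k, k, dimnames = list(ord, ord))
  tot_var <- stats::var(values)
  degenerate <- tot_var == 0 || !is.finite(mse) ||
    mse < 1e-10 * tot_var
  if (!degenerate) {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    pw <- tk[, "p adj"]
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (idx in seq_along(pw)) {
      g1 <- pairs[[idx]][1]; g2 <- pairs[[idx]][2]
      sig <- is.finite(pw[idx]) && pw[idx] < alpha
      diff_mat[g1, g2] <- diff_mat[g2, g1] <- sig
    }
  } else {
    # zero within-group variance: groups differ iff their means differ
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      sig <- means[i] != means[j]
      diff_mat[i, j] <- diff_mat[j, i] <- sig
    }
    p <- if (any(diff_mat)) 0 else 1
  }
  letts <- stats::setNames(.compact_letters(diff_mat), ord)
  list(means = means, sem = sqrt(mse / mean(n_per)),
       p_value = unname(p), letters = letts)
}

#' Publication-shaped comparison table over many parameters
#'
#' @param data data.frame of experimental units with a grouping column and
#'   numeric parameter columns.
#' @param value_cols parameter columns to compare (default: all numeric).
#' @param group_col name of the grouping column (default `"treatment"`).
#' @param alpha pairwise significance level.
#' @return data.frame, one row per parameter: per-treatment means, matching
#'   `<treatment>_letter` columns, pooled `sem` and `p_value`.
#' @export
comparison_table <- function(data, value_cols = NULL,
                             group_col = "treatment", alpha = 0.05) {
  stopifnot(group_col %in% names(data))
  if (is.null(value_cols)) {
    num <- vapply(data, is.numeric, logical(1))
    value_cols <- setdiff(names(data)[num], c(group_col, "run"))
  }
  grp <- data[[group_col]]
  trt <- unique(as.character(grp))
  rows <- lapply(value_cols, function(v) {
    cg <- compare_groups(data[[v]], grp, alpha)
    out <- data.frame(parameter = v)
    for (g in trt) {
      out[[g]] <- unname(cg$means[g])
      out[[paste0(g, "_letter")]] <- unname(cg$letters[g])
    }
    out$sem <- cg$sem
    out$p_value <- cg$p_value
    out
  })
  do.call(rbind, rows)
}

#' Star annotation for a correlation cell
#'
#' `"*"` for 0.01 < p <= 0.05, `"**"` for 0.001 < p <= 0.01, `"***"` for
#' p <= 0.001 — in every case only when `|rho| > 0.1`.
#'
#' @param rho Spearman correlation.
#' @param p its p-value.
#' @return star string (possibly empty).
#' @export
correlation_stars <- function(rho, p) {
  if (is.na(rho) || is.na(p) || abs(rho) <= 0.1) return("")
  if (p <= 0.001) "***"
  else if (p <= 0.01) "**"
  else if (p <= 0.05) "*"
  else ""
}

#' Starred Spearman correlation matrix
#'
#' Rank correlation (average ranks on ties) between every column of `x` and
#' every column of `y`, with star annotations per [correlation_stars()].
#' No multiple-testing correction is applied.
#'
#' @param x,y data.frames or matrices with matched rows (>= 4).
#' @return list of matrices `rho`, `p`, `stars` (rows = columns of `x`,
#'   columns = columns of `y`). Constant columns yield NA cells.
#' @export
spearman_matrix <- function(x, y) {
  x <- as.data.frame(x); y <- as.data.frame(y)
  if (nrow(x) != nrow(y))
    stop("x and y must have matched rows", call. = FALSE)
  if (nrow(x) < 4)
    stop("need >= 4 paired observations", call. = FALSE)
  rho <- p <- matrix(NA_real_, ncol(x), ncol(y),
                     dimnames = list(names(x), names(y)))
  stars <- matrix("", ncol(x), ncol(y),
                  dimnames = list(names(x), names(y)))
  for (i in seq_len(ncol(x))) for (j in seq_len(ncol(y))) {
    xi <- x[[i]]; yj <- y[[j]]
    ok <- is.finite(xi) & is.finite(yj)
    if (sum(ok) < 4 || stats::sd(xi[ok]) == 0 || stats::sd(yj[ok]) == 0)
      next
    ct <- suppressWarnings(
      stats::cor.test(xi[ok], yj[ok], method = "spearman"))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
    stars[i, j] <- correlation_stars(rho[i, j], p[i, j])
  }
  list(rho = rho, p = p, stars = stars)
}
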