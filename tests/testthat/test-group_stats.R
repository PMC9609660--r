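test_that("group comparison handles degenerate and separated cases", {
  g <- rep(c("A", "B", "C"), each = 3)
  same <- compare_groups(rep(5, 9), g)
  expect_equal(same$p_value, 1)
  expect_true(all(same$letters == "a"))

  set.seed(2)
  sep <- compare_groups(c(0, 0, 0, 10, 10, 10) + rnorm(6, 0, 1e-3),
                        rep(c("lo", "hi"), each = 3))
  expect_equal(unname(sep$letters[c("hi", "lo")]), c("a", "b"))
  expect_equal(names(sep$means)[1], "hi")

  expect_error(compare_groups(1:3, c("A", "A", "B")), "replication")
  expect_error(compare_groups(1:4, rep("A", 4)), "2 groups")
})

test_that("pooled SEM is sqrt(MSE / n)", {
  set.seed(8)
  y <- rnorm(12); g <- rep(c("A", "B", "C"), each = 4)
  cg <- compare_groups(y, g)
  mse <- summary(stats::aov(y ~ factor(g)))[[1]]["Residuals", "Mean Sq"]
  expect_equal(cg$sem, sqrt(mse / 4))
})

test_that("compact letters respect the pairwise significance pattern", {
  set.seed(42)
  for (i in 1:30) {
    k <- sample(3:5, 1)
    n <- 6
    shift <- cumsum(c(0, runif(k - 1, 0, 3)))
    y <- rnorm(k * n, rep(shift, each = n), 1)
    g <- rep(paste0("g", seq_len(k)), each = n)
    cg <- compare_groups(y, g)
    tk <- stats::TukeyHSD(stats::aov(y ~ factor(g)))$`factor(g)`
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (idx in seq_along(pairs)) {
      l1 <- strsplit(cg$letters[[pairs[[idx]][1]]], "")[[1]]
      l2 <- strsplit(cg$letters[[pairs[[idx]][2]]], "")[[1]]
      share <- length(intersect(l1, l2)) > 0
      # sharing a letter must coincide with pairwise non-significance
      expect_equal(share, tk[idx, "p adj"] >= 0.05)
    }
    # order consistency: descending means receive alphabetical letters
    first_letter <- substr(unname(cg$letters), 1, 1)
    expect_true(all(diff(match(first_letter, letters)) >= 0))
  }
})

test_that("letter pattern of the preset A/P contrast is recoverable", {
  # four treatments at A/P means 1.79 / 2.20 / 1.86 / 2.31, per-unit sd
  # SEM*sqrt(2)/sqrt(5) (run average of five bottles), 2 runs
  means <- c(Control = 1.79, SN = 2.20, CS = 1.86, CSN = 2.31)
  unit_sd <- 0.01 * sqrt(2) / sqrt(5)
  set.seed(33)
  hits <- 0
  for (i in 1:50) {
    y <- rnorm(8, rep(means, each = 2), unit_sd)
    g <- rep(names(means), each = 2)
    cg <- compare_groups(y, g)
    if (identical(unname(cg$letters[c("Control", "SN", "CS", "CSN")]),
                  c("d", "b", "c", "a"))) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
})

test_that("ANOVA p-value is invariant under common affine transforms", {
  set.seed(6)
  y <- rnorm(12, rep(c(0, 1, 2), each = 4))
  g <- rep(c("A", "B", "C"), each = 4)
  p1 <- compare_groups(y, g)$p_value
  p2 <- compare_groups(3.2 * y - 17, g)$p_value
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("Spearman matrix follows rank logic and star rules", {
  x <- data.frame(a = 1:8)
  y <- data.frame(up = exp(1:8), down = -(1:8), flat = rep(1, 8))
  sm <- spearman_matrix(x, y)
  expect_equal(sm$rho["a", "up"], 1)      # monotone transform
  expect_equal(sm$rho["a", "down"], -1)
  expect_true(is.na(sm$rho["a", "flat"]))
  expect_equal(sm$stars["a", "flat"], "")

  expect_equal(correlation_stars(0.9, 0.0005), "***")
  expect_equal(correlation_stars(0.9, 0.005), "**")
  expect_equal(correlation_stars(0.9, 0.03), "*")
  expect_equal(correlation_stars(0.9, 0.2), "")
  expect_equal(correlation_stars(0.05, 0.001), "")  # |rho| gate

  # invariance under strictly monotone transform of either variable
  set.seed(12)
  a <- rnorm(10); b <- rnorm(10)
  r1 <- spearman_matrix(data.frame(a), data.frame(b))$rho[1, 1]
  r2 <- spearman_matrix(data.frame(a = exp(a)),
                        data.frame(b = b^3))$rho[1, 1]
  expect_equal(r1, r2)
  expect_error(spearman_matrix(data.frame(a = 1:3), data.frame(b = 1:3)),
               ">= 4")
})

test_that("comparison tables carry means, letters, SEM and p per row", {
  set.seed(14)
  df <- data.frame(treatment = rep(c("A", "B"), each = 4), run = 1:2,
                   x = c(rnorm(4, 0), rnorm(4, 10)),
                   y = rnorm(8, 5))
  ct <- comparison_table(df)
  expect_equal(ct$parameter, c("x", "y"))
  expect_true(all(c("A", "A_letter", "B", "B_letter", "sem", "p_value")
                  %in% names(ct)))
  expect_lt(ct$p_value[ct$parameter == "x"], 0.01)
  expect_false("run" %in% ct$parameter)
})
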