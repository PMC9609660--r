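test_that("alpha indices match hand-evaluated formulas", {
  # uniform community: Shannon hits its ln(k) maximum
  expect_equal(alpha_indices(rep(100, 10))$shannon, log(10))
  one <- alpha_indices(c(50))
  expect_equal(one$shannon, 0)
  expect_equal(one$simpson, 1)
  expect_equal(one$chao1, 1)
  expect_equal(one$observed_otus, 1)

  a <- alpha_indices(c(5, 3, 1, 1))
  expect_equal(a$observed_otus, 4)
  expect_equal(a$chao1, 5)              # bias-corrected: 4 + 2*1/(2*1)
  expect_equal(a$goods_coverage, 0.8)   # 1 - F1/N = 1 - 2/10
  expect_equal(a$simpson, (5 * 4 + 3 * 2) / (10 * 9))
  p <- c(5, 3, 1, 1) / 10
  expect_equal(a$shannon, -sum(p * log(p)))

  b <- alpha_indices(c(4, 2, 2, 1))     # F2 = 2: classic Chao1 form
  expect_equal(b$chao1, 4 + 1 / (2 * 2))
  expect_error(alpha_indices(c(0, 0)), "empty")
})

test_that("ACE and Shannon agree with the vegan implementations", {
  set.seed(9)
  for (i in 1:40) {
    x <- random_counts()
    mine <- alpha_indices(x)
    expect_equal(mine$shannon, unname(vegan::diversity(x, "shannon")))
    est <- vegan::estimateR(x)
    if (!is.na(mine$ace) && sum(x[x <= 10] == 1) < sum(x <= 10))
      expect_equal(mine$ace, unname(est["S.ACE"]), tolerance = 1e-8)
  }
})

test_that("richness estimators dominate observed richness", {
  set.seed(13)
  for (i in 1:1000) {
    x <- random_counts()
    a <- alpha_indices(x)
    expect_gte(a$chao1, a$observed_otus)
    if (!is.na(a$ace)) expect_gte(a$ace, a$observed_otus)
    expect_gte(a$shannon, 0)
    expect_true(a$simpson >= 0 && a$simpson <= 1)
    expect_true(a$goods_coverage >= 0 && a$goods_coverage <= 1)
  }
})

test_that("Bray-Curtis matches its formula, bounds and invariances", {
  bc_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)
  m <- rbind(a = c(6, 2), b = c(2, 2))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 1 / 3)
  expect_equal(bray_curtis(rbind(a = c(3, 1), b = c(3, 1)))["a", "b"], 0)
  expect_equal(bray_curtis(rbind(a = c(5, 0), b = c(0, 7)))["a", "b"], 1)

  set.seed(17)
  for (i in 1:30) {
    m <- matrix(rpois(5 * 20, 5), 5, 20,
                dimnames = list(paste0("s", 1:5), NULL))
    m[m == 0] <- 1
    d <- bray_curtis(m)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d[1, 2], bc_oracle(m[1, ], m[2, ]))
    # appending an all-zero taxon changes nothing
    expect_equal(bray_curtis(cbind(m, 0)), d)
  }
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 1))), "all-zero")
})

test_that("OTU Venn partition recovers constructed overlap structure", {
  tab <- venn_fixture(shared = 30, unique_n = c(4, 5, 3, 2))
  v <- otu_venn(tab)
  expect_equal(v$shared_all, 30)
  expect_equal(unname(v$unique),
               c(4, 5, 3, 2)[match(names(v$unique),
                                   c("Control", "SN", "CS", "CSN"))])
  expect_equal(sum(v$regions), 30 + 4 + 5 + 3 + 2)

  # identical groups: everything shared, nothing unique
  t2 <- tab; t2$group <- rep(c("A", "B"), length.out = nrow(t2))
  m <- otu_counts(tab)
  t2[, -(1:2)] <- rbind(m[1, ], m[1, ], m[1, ], m[1, ],
                        m[1, ], m[1, ], m[1, ], m[1, ])
  v2 <- otu_venn(t2)
  expect_equal(unname(v2$shared_all), sum(m[1, ] > 0))
  expect_equal(unname(v2$unique), c(0, 0))
})

test_that("PERMANOVA matches vegan and behaves under permutation null", {
  set.seed(19)
  m <- matrix(rpois(12 * 15, 10) + 1, 12, 15,
              dimnames = list(paste0("s", 1:12), NULL))
  gr <- rep(c("A", "B"), each = 6)
  d <- bray_curtis(m)
  mine <- permanova(d, gr, n_permutations = 199, seed = 4)
  ad <- vegan::adonis2(stats::as.dist(d) ~ gr, permutations = 199)
  expect_equal(mine$pseudo_f, ad$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, ad$R2[1], tolerance = 1e-10)

  # determinism and label/row co-reordering invariance
  expect_identical(permanova(d, gr, 99, seed = 7),
                   permanova(d, gr, 99, seed = 7))
  perm <- sample(12)
  expect_equal(permanova(d[perm, perm], gr[perm], 99, seed = 7)$pseudo_f,
               mine$pseudo_f)

  # identical samples: no structure
  d0 <- matrix(0, 6, 6)
  null_res <- permanova(d0, rep(c("A", "B"), 3), 99, seed = 1)
  expect_equal(null_res$pseudo_f, 0)
  expect_equal(null_res$p_value, 1)

  # minimum attainable p
  strong <- rbind(matrix(1, 4, 3), matrix(100, 4, 3))
  ds <- bray_curtis(strong + matrix(rpois(24, 2), 8, 3))
  ps <- permanova(ds, rep(c("lo", "hi"), each = 4), 49, seed = 2)$p_value
  expect_gte(ps, 1 / 50)

  expect_error(permanova(d, gr, 0), "permutations")
  expect_error(permanova(d, rep("A", 12)), "2 groups")
  expect_warning(permanova(d, c(rep("A", 11), "B"), 9), "single sample")
})

test_that("strongly different preset compositions are detected", {
  cfg <- synthetic_config(seed = 31)
  comp <- preset_compositions()[, c("Control", "SN")]
  tab <- generate_otu_table(cfg, comp, depth = 10000,
                            overdispersion = 200,
                            n_samples_per_group = 10)
  res <- permanova(bray_curtis(tab), tab$group, 999, seed = 1)
  expect_lte(res$p_value, 0.01)
})

test_that("rarefaction equalises depth deterministically", {
  cfg <- synthetic_config(seed = 23)
  tab <- generate_otu_table(cfg, preset_compositions(), depth = 5000,
                            n_samples_per_group = 3)
  r1 <- rarefy_counts(tab, 1000, seed = 2)
  r2 <- rarefy_counts(tab, 1000, seed = 2)
  expect_identical(r1, r2)
  expect_true(all(rowSums(otu_counts(r1)) == 1000))
})
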