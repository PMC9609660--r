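test_that("constructors validate their invariants", {
  expect_error(treatment_spec("x", c(a = 1), c(b = 1), 50, 0.1, 0.1),
               "no sd")
  expect_error(treatment_spec("x", c(a = 1), c(a = -1), 50, 0.1, 0.1),
               ">= 0")
  expect_error(treatment_spec("x", c(a = 1), c(a = 1), 50, 0, 0.1),
               "> 0")
  expect_error(treatment_spec("x", c(a = 1), c(a = 1), 50, 0.1, 1.2),
               "\\[0, 1\\]")
  expect_error(synthetic_config(timepoints_h = c(3, 3, 6)), "increasing")
  expect_error(synthetic_config(substrate_g = 0), "> 0")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 42)
  specs <- preset_treatments()
  expect_identical(simulate_experiment(cfg, specs, depth = 500),
                   simulate_experiment(cfg, specs, depth = 500))
  # independent substreams: gas draws are unaffected by other tables
  g1 <- generate_gas_timecourse(cfg, specs$Control)
  invisible(generate_endpoint_tables(cfg, specs))
  g2 <- generate_gas_timecourse(cfg, specs$Control)
  expect_identical(g1, g2)
})

test_that("noiseless gas curves hit the saturating-curve ground truth", {
  cfg <- synthetic_config(seed = 1, gas_noise_sd = 0,
                          blank_mL_per_interval = 5, n_blanks = 3)
  spec <- treatment_spec("T", c(pH = 7), c(pH = 0),
                         gas_asymptote_mL = 58.5,
                         gas_rate_per_h = 0.15, ch4_fraction_curve = 0.1)
  g <- generate_gas_timecourse(cfg, spec)
  # 72 h cumulative net approaches the asymptote
  res <- cumulate_gas(g)
  expect_equal(unique(res$totals$total_gas_mL),
               58.5 * (1 - exp(-0.15 * 72)), tolerance = 1e-10)
  expect_equal(unique(res$totals$total_gas_mL), 58.5, tolerance = 1e-4)
  # gross minus the 5 mL blank equals the noiseless net at every interval
  blanks <- g[g$is_blank, ]
  expect_true(all(blanks$volume_mL == 5))
  one <- g[g$bottle_id == "T_r1_b1", ]
  ideal <- diff(c(0, 58.5 * (1 - exp(-0.15 * cfg$timepoints_h))))
  expect_equal(one$volume_mL - 5, ideal)
  expect_error(
    treatment_spec("T", c(pH = 7), c(pH = 0), 58.5, -0.1, 0.1), "> 0")
})

test_that("zero-sd endpoints equal their means; truncation bars negatives", {
  cfg <- synthetic_config(seed = 3, endpoint_noise = 0, ct_noise_sd = 0)
  specs <- preset_treatments()
  tabs <- generate_endpoint_tables(cfg, specs)
  for (trt in names(specs)) {
    sub <- tabs$chemistry[tabs$chemistry$treatment == trt, ]
    expect_true(all(sub$acetate ==
                      specs[[trt]]$endpoint_means[["acetate"]]))
    expect_true(all(sub$dmd == specs[[trt]]$endpoint_means[["dmd"]]))
    aa <- tabs$amino_acids[tabs$amino_acids$treatment == trt, ]
    expect_true(all(aa$glutamate ==
                      specs[[trt]]$endpoint_means[["glutamate"]]))
  }

  # zero mean with sd 1: truncated draws never go negative
  set.seed(1)
  draws <- rumenbatch:::.rnorm_trunc0(2000, 0, 1)
  expect_true(all(draws >= 0))

  specs2 <- specs
  specs2$SN$endpoint_means <- specs2$SN$endpoint_means[-1]
  specs2$SN$endpoint_sds <- specs2$SN$endpoint_sds[-1]
  expect_error(generate_endpoint_tables(cfg, specs2), "quantity sets")
})

test_that("endpoint sample means obey the law of large numbers", {
  cfg <- synthetic_config(seed = 77, n_bottles_per_treatment = 100,
                          n_runs = 2)
  specs <- preset_treatments()
  tabs <- generate_endpoint_tables(cfg, specs)
  for (trt in c("Control", "CSN")) {
    s <- specs[[trt]]
    sub <- tabs$chemistry[tabs$chemistry$treatment == trt, ]
    for (q in c("acetate", "propionate", "mcp")) {
      sd_q <- s$endpoint_sds[[q]]
      expect_lt(abs(mean(sub[[q]]) - s$endpoint_means[[q]]),
                3 * sd_q / sqrt(200) + 1e-12)
    }
  }
})

test_that("OTU tables have exact depth and binomial-limit moments", {
  cfg <- synthetic_config(seed = 55)
  comp <- preset_compositions()
  tab <- generate_otu_table(cfg, comp, depth = 2000,
                            n_samples_per_group = 4)
  expect_true(all(rowSums(otu_counts(tab)) == 2000))
  expect_equal(nrow(tab), 16)

  # overdispersion -> Inf with p = (1/2, 1/2): counts are Binomial(1000, 1/2)
  comp2 <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("t1", "t2"), "G"))
  tab2 <- generate_otu_table(cfg, comp2, depth = 1000,
                             overdispersion = Inf,
                             n_samples_per_group = 500)
  m <- otu_counts(tab2)
  expect_lt(abs(mean(m[, 1]) - 500), 3 * sqrt(250) / sqrt(500))

  # degenerate composition puts every read in one taxon
  comp3 <- matrix(c(1, 0), 2, 1, dimnames = list(c("t1", "t2"), "G"))
  tab3 <- generate_otu_table(cfg, comp3, depth = 777,
                             n_samples_per_group = 3)
  expect_true(all(otu_counts(tab3)[, "t1"] == 777))

  expect_error(generate_otu_table(cfg, comp3 - 2), ">= 0")
  expect_error(generate_otu_table(cfg, comp3 / 2), "sum to 1")
})

test_that("two identical compositions give a calibrated PERMANOVA null", {
  cfg <- synthetic_config(seed = 101)
  p0 <- preset_compositions()[, "Control"]
  comp <- cbind(A = p0, B = p0)
  set.seed(101)
  rejections <- 0
  n_sims <- 120
  for (i in 1:n_sims) {
    cfg_i <- synthetic_config(seed = 1000 + i)
    tab <- generate_otu_table(cfg_i, comp, depth = 500,
                              overdispersion = 100,
                              n_samples_per_group = 5)
    p <- permanova(bray_curtis(tab), tab$group, 99, seed = i)$p_value
    if (p <= 0.05) rejections <- rejections + 1
  }
  expect_lt(abs(rejections / n_sims - 0.05), 0.05)
})

test_that("written experiments round-trip through the readers", {
  cfg <- synthetic_config(seed = 2)
  sim <- simulate_experiment(cfg, depth = 300, overdispersion = 100)
  dir <- tempfile("exp")
  paths <- write_experiment(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_experiment(dir)
  expect_equal(back$gas$volume_mL, sim$gas$volume_mL)
  expect_equal(back$chemistry$acetate, sim$chemistry$acetate)
  expect_equal(otu_counts(back$otu), otu_counts(sim$otu))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$config$seed, 2)
  unlink(dir, recursive = TRUE)
})
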