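test_that("generated tables have the configured design and are deterministic", {
  cfg <- sim_config(n_case = 9, n_control = 10, n_features = 120,
                    n_discriminant = 5, seed = 1)
  sim <- generate_feature_table(cfg)
  sm <- sim$table$sample_meta
  expect_equal(sum(sm$sample_type == "study"), 19)
  expect_equal(ncol(sim$table$intensities), 120)
  expect_equal(sum(sm$group == "case"), 9)
  expect_equal(length(sim$ground_truth$planted), 5)
  expect_equal(nrow(sim$table$intensities),
               19 + length(cfg$qc_dilutions) * cfg$n_qc_replicates)

  sim2 <- generate_feature_table(sim_config(n_case = 9, n_control = 10,
                                            n_features = 120,
                                            n_discriminant = 5, seed = 1))
  expect_identical(sim$table$intensities, sim2$table$intensities)
  expect_identical(sim$ground_truth, sim2$ground_truth)

  expect_error(sim_config(n_features = 5, n_discriminant = 6, seed = 1),
               "n_discriminant")
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(missing_rate = 1, seed = 1), "missing_rate")
})

test_that("planted features carry the configured log effect; nulls are null", {
  # noise-free, dilution-free: the group log-difference is exactly effect_size
  cfg <- sim_config(n_case = 6, n_control = 6, n_features = 30,
                    n_discriminant = 3, effect_size = 2, noise_sd = 0,
                    dilution_sd = 0, missing_rate = 0, n_qc_replicates = 0,
                    seed = 7)
  sim <- generate_feature_table(cfg)
  L <- log(sim$table$intensities)
  grp <- sim$table$sample_meta$group
  diffs <- colMeans(L[grp == "case", ]) - colMeans(L[grp == "control", ])
  planted <- sim$table$feature_meta$feature_id %in% sim$ground_truth$planted
  expect_equal(unname(diffs[planted]), rep(2, 3), tolerance = 1e-12)
  expect_equal(unname(diffs[!planted]), rep(0, 27), tolerance = 1e-12)

  # null config: t-test p-values roughly uniform across features
  cfg0 <- sim_config(n_case = 10, n_control = 10, n_features = 800,
                     n_discriminant = 0, effect_size = 0, missing_rate = 0,
                     dilution_sd = 0, n_qc_replicates = 0, seed = 21)
  sim0 <- generate_feature_table(cfg0)
  L0 <- log(sim0$table$intensities)
  g <- sim0$table$sample_meta$group
  pv <- apply(L0, 2, function(v) t.test(v[g == "case"], v[g == "control"],
                                        var.equal = TRUE)$p.value)
  # fraction below 0.05 within 99.9% binomial bounds of 0.05
  expect_lt(abs(mean(pv < 0.05) - 0.05), 3.3 * sqrt(0.05 * 0.95 / 800))
})

test_that("planted signals are recoverable with the stated power", {
  # effect 2 log-units, noise 0.5, n = 10/group: per-feature t-test power
  rej <- 0L
  for (r in 1:200) {
    cfg <- sim_config(n_case = 10, n_control = 10, n_features = 20,
                      n_discriminant = 1, effect_size = 2, noise_sd = 0.5,
                      dilution_sd = 0, missing_rate = 0, n_qc_replicates = 0,
                      seed = 1000 + r)
    sim <- generate_feature_table(cfg)
    j <- match(sim$ground_truth$planted, sim$table$feature_meta$feature_id)
    v <- log(sim$table$intensities[, j])
    g <- sim$table$sample_meta$group
    p <- t.test(v[g == "case"], v[g == "control"], var.equal = TRUE)$p.value
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / 200, 0.9)
})

test_that("per-sample median quotients recover the true dilution factors", {
  cfg <- sim_config(n_case = 8, n_control = 8, n_features = 400,
                    n_discriminant = 0, dilution_sd = 0.4, missing_rate = 0,
                    n_qc_replicates = 0, seed = 5)
  sim <- generate_feature_table(cfg)
  ref <- apply(sim$table$intensities, 2, median)
  est <- apply(sim$table$intensities, 1, function(s) median(s / ref))
  truth <- sim$ground_truth$dilution
  ratio <- est / truth
  rel_err <- abs(ratio / median(ratio) - 1)
  expect_lt(median(rel_err), 0.05)
})

test_that("QC dilution series follows d x base_profile", {
  base <- c(10, 50, 200, 1000)
  cfg0 <- sim_config(n_features = 4, noise_sd = 0, n_qc_replicates = 1,
                     seed = 3)
  qc <- generate_qc_dilution_series(cfg0, base)
  expect_equal(nrow(qc$intensities), 3)
  for (i in 1:3)
    expect_equal(unname(qc$intensities[i, ]),
                 qc$sample_meta$nominal_dilution[i] * base, tolerance = 1e-12)

  # replicate counting
  cfg2 <- sim_config(n_features = 4, n_qc_replicates = 2, seed = 3)
  expect_equal(nrow(generate_qc_dilution_series(cfg2, base)$intensities), 6)

  # OLS slope per feature recovers the base profile
  cfgn <- sim_config(n_features = 4, noise_sd = 0.05, n_qc_replicates = 5,
                     seed = 9)
  qcn <- generate_qc_dilution_series(cfgn, base)
  d <- qcn$sample_meta$nominal_dilution
  slopes <- apply(qcn$intensities, 2, function(y) coef(lm(y ~ d))[2])
  expect_equal(unname(slopes), base, tolerance = 0.2)

  cfg_bad <- sim_config(n_features = 4, qc_dilutions = numeric(0), seed = 1)
  expect_error(generate_qc_dilution_series(cfg_bad, base), "qc_dilutions")
  expect_error(generate_qc_dilution_series(cfg0, base[1:2]), "length")
})

test_that("clinical tables reproduce binary margins exactly", {
  tab <- generate_clinical_table(seed = 4)
  expect_equal(nrow(tab), 30)
  ct <- table(tab$group, tab$male_sex)
  expect_equal(unname(ct["case", "1"]), 7)
  expect_equal(unname(ct["control", "1"]), 5)
  # all-zero covariate cross-tabulates to [[0,15],[0,15]]
  tab0 <- generate_clinical_table(binary = list(z = c(0, 0)),
                                  numeric = list(), seed = 4)
  expect_true(all(tab0$z == 0))
  expect_error(generate_clinical_table(binary = list(z = c(16, 0)),
                                       numeric = list(), seed = 4),
               "infeasible")
  # numeric covariates drawn per group
  set.seed(NULL)
  big <- generate_clinical_table(n_case = 4000, n_control = 4000,
                                 binary = list(),
                                 numeric = list(ga = c(207, 17, 213, 16)),
                                 seed = 8)
  expect_equal(mean(big$ga[big$group == "case"]), 207, tolerance = 1)
  expect_equal(mean(big$ga[big$group == "control"]), 213, tolerance = 1)
})

test_that("bundled metabolite database loads with the expected content", {
  db <- load_metabolite_db()
  trp <- db_lookup(db, "L-Tryptophan")
  expect_equal(trp$hmdb_id, "HMDB0000929")
  expect_equal(trp$monoisotopic_mass, 204.0899, tolerance = 1e-4)
  kyn <- db_lookup(db, "kynurenine")
  expect_equal(kyn$hmdb_id, "HMDB0000684")
  expect_equal(nrow(db_lookup(db, "unobtainium")), 0)
  expect_gte(length(db$pathways), 10)
  expect_true(all(c("Glutathione metabolism", "Tryptophan metabolism") %in%
                    names(db$pathways)))
  expect_true(all(unlist(db$pathways) %in% db$metabolites$hmdb_id))
  expect_error(suppressWarnings(load_metabolite_db(tempfile())), "load")
})

test_that("feature tables round-trip through CSV", {
  tab <- tiny_table()
  stem <- file.path(tempdir(), "ft_test")
  write_feature_table(tab, stem)
  back <- read_feature_table(stem)
  expect_equal(back$intensities, tab$intensities)
  expect_equal(back$feature_meta$mz, tab$feature_meta$mz)
  expect_equal(back$sample_meta$group, tab$sample_meta$group)
})
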