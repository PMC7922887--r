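test_that("noiseless QC calibration is exact and filters non-linear features", {
  tab <- tiny_table()
  cal <- fit_qc_calibration(tab)
  expect_equal(unname(cal$r2), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(cal$slope), c(100, 200, 400, 800), tolerance = 1e-9)
  expect_true(all(cal$retained))

  # a feature constant across dilutions has R2 = 0 and is dropped at 0.7
  tab2 <- tiny_table()
  tab2$intensities[5:7, 2] <- 50
  cal2 <- fit_qc_calibration(tab2, r2_threshold = 0.7)
  expect_equal(cal2$r2[2], 0)
  expect_false(cal2$retained[2])
  expect_true(all(cal2$retained[c(1, 3, 4)]))

  no_qc <- tab[tab$sample_meta$sample_type == "study", ]
  expect_error(fit_qc_calibration(no_qc), "no QC rows")
  one_d <- tab[1:5, ]
  expect_error(fit_qc_calibration(one_d), "single dilution")
})

test_that("noisy QC calibration recovers slopes within 10% for most features", {
  set.seed(42)
  base <- exp(rnorm(200, 5, 1))
  cfg <- sim_config(n_features = 200, noise_sd = 0.1, n_qc_replicates = 25,
                    seed = 13)
  qc <- generate_qc_dilution_series(cfg, base)
  cal <- fit_qc_calibration(qc, r2_threshold = 0)
  rel <- abs(cal$slope - base) / base
  expect_gte(mean(rel < 0.10), 0.95)
})

test_that("calibration filter corrects intensities by the response factor", {
  tab <- tiny_table()
  cal <- fit_qc_calibration(tab)
  out <- apply_calibration_filter(tab, cal)
  # corrected QC row at dilution 1/5 is a constant vector of 0.2
  qc5 <- which(abs(tab$sample_meta$nominal_dilution - 0.2) < 1e-9)
  expect_equal(unname(out$intensities[qc5, ]), rep(0.2, 4), tolerance = 1e-9)

  # all slopes 1 leaves the table unchanged
  cal1 <- cal; cal1$slope <- rep(1, 4)
  expect_equal(apply_calibration_filter(tab, cal1)$intensities,
               tab$intensities)

  cal0 <- cal; cal0$retained <- rep(FALSE, 4)
  expect_error(apply_calibration_filter(tab, cal0), "r2_threshold")
  expect_error(apply_calibration_filter(tab[, 1:3], cal), "different feature")
})

test_that("PQN divides by the median quotient and is idempotent", {
  set.seed(2)
  ref <- exp(rnorm(50, 5, 1))
  X <- rbind(ref, ref, ref, 2 * ref)
  fm <- data.frame(feature_id = paste0("F", 1:50), mz = 1:50 + 0.5,
                   rt = 1, ion_mode = "NEG")
  sm <- data.frame(sample_id = paste0("S", 1:4), group = "case",
                   sample_type = "study")
  tab <- feature_table(X, fm, sm)
  res <- pqn_normalize(tab)
  expect_equal(unname(res$quotient_median["S4"]), 2)
  expect_equal(unname(res$table$intensities[4, ]), unname(ref))

  # identical samples: all quotients 1, table unchanged
  tab_id <- feature_table(rbind(ref, ref, ref), fm, sm[1:3, ])
  res_id <- pqn_normalize(tab_id)
  expect_equal(unname(res_id$quotient_median), rep(1, 3))
  expect_equal(res_id$table$intensities, tab_id$intensities)

  # idempotence: a second pass changes nothing
  twice <- pqn_normalize(res$table)
  expect_equal(unname(twice$quotient_median), rep(1, 4), tolerance = 1e-10)
  expect_equal(twice$table$intensities, res$table$intensities,
               tolerance = 1e-10)

  tab_bad <- tab
  tab_bad$intensities[2, ] <- NA
  expect_error(pqn_normalize(tab_bad), "S2")
})

test_that("PQN recovers simulated dilution factors", {
  errs <- numeric(20)
  for (r in 1:20) {
    cfg <- sim_config(n_case = 8, n_control = 8, n_features = 300,
                      n_discriminant = 0, dilution_sd = 0.3,
                      missing_rate = 0, n_qc_replicates = 0, seed = 100 + r)
    sim <- generate_feature_table(cfg)
    res <- pqn_normalize(sim$table)
    ratio <- res$quotient_median / sim$ground_truth$dilution
    errs[r] <- median(abs(ratio / median(ratio) - 1))
  }
  expect_lt(median(errs), 0.05)
})

test_that("missingness filter and half-minimum imputation follow the rule", {
  tab <- tiny_table()
  expect_equal(impute_and_filter(tab)$intensities, tab$intensities)

  tab$intensities[1:4, 2] <- NA            # missing in all study samples
  tab$intensities[1, 3] <- NA              # one missing cell
  out <- impute_and_filter(tab, max_missing_fraction = 0.5)
  expect_false("F2" %in% out$feature_meta$feature_id)
  mn <- min(tab$intensities[-1, 3], na.rm = TRUE)
  expect_equal(unname(out$intensities[1, "F3"]), mn / 2)
  expect_error(impute_and_filter(tab, 1), "max_missing_fraction")
})

test_that("scaling modes center and autoscale with n-1 SD, and round-trip", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  mc <- scale_features(X, "mean_center")
  expect_equal(unname(mc[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(mc)), c(0, 0))
  as <- scale_features(X, "autoscale")
  expect_equal(unname(as[, "a"]), c(-1, 0, 1))   # sd((1,2,3)) = 1
  expect_true(attr(as, "zero_variance")[2])
  expect_equal(unname(as[, "b"]), c(0, 0, 0))    # centered, not divided
  expect_equal(unscale_features(as), X, tolerance = 1e-10)
  expect_equal(unscale_features(mc), X, tolerance = 1e-10)
  expect_error(scale_features(X, "rank"), "arg")
  expect_error(scale_features(X[1, , drop = FALSE]), "2 samples")
})

test_that("calibration retention is invariant to sample order", {
  cfg <- sim_config(n_features = 50, noise_sd = 0.3, n_qc_replicates = 3,
                    seed = 31)
  qc <- generate_qc_dilution_series(cfg, exp(rnorm(50, 5, 1)))
  cal <- fit_qc_calibration(qc, 0.7)
  perm <- sample(nrow(qc$intensities))
  cal_p <- fit_qc_calibration(qc[perm, ], 0.7)
  expect_equal(cal$retained, cal_p$retained)
  expect_lte(sum(cal$retained), ncol(qc$intensities))
})
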