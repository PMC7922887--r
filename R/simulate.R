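#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator. The defaults
#' emulate the study design the pipeline is intended for: two groups of
#' roughly ten preterm neonates (9 cases vs 10 controls for the urine
#' cohort), a few thousand RT_mass features per ionization mode, log-normal
#' intensities with per-sample multiplicative dilution, a small set of
#' planted group-discriminant features, pooled-QC samples at nominal
#' dilutions 1:3, 1:5 and 1:7, and missing values inserted completely at
#' random.
#'
#' @param n_case,n_control study samples per group.
#' @param n_features number of RT_mass features.
#' @param n_discriminant number of planted group-discriminant features.
#' @param effect_size group mean difference on the natural-log intensity
#'   scale for planted features.
#' @param dilution_sd standard deviation of the per-sample log dilution
#'   factor.
#' @param noise_sd standard deviation of the log-intensity noise.
#' @param missing_rate proportion of entries set missing, in `[0, 1)`.
#' @param qc_dilutions nominal QC dilution fractions (default 1/3, 1/5, 1/7).
#' @param n_qc_replicates QC injections per dilution level.
#' @param ion_mode ionization mode label for the generated features.
#' @param n_db_features how many features receive m/z values copied (with
#'   small ppm jitter) from the bundled metabolite database, so that
#'   annotation can be exercised end to end; planted features are served
#'   first. Remaining features get uniform decoy m/z in 50-1200 Da.
#' @param mz_jitter_ppm standard deviation of the m/z jitter in ppm.
#' @param seed RNG seed (mandatory).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_case = 9, n_control = 10, n_features = 2394,
                       n_discriminant = min(10, n_features), effect_size = 2,
                       dilution_sd = 0.3, noise_sd = 0.5,
                       missing_rate = 0.05,
                       qc_dilutions = c(1 / 3, 1 / 5, 1 / 7),
                       n_qc_replicates = 1, ion_mode = "NEG",
                       n_db_features = n_discriminant, mz_jitter_ppm = 2,
                       seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory in sim_config")
  if (n_discriminant > n_features)
    stop("n_discriminant must not exceed n_features")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (length(qc_dilutions) && (any(qc_dilutions <= 0) || any(qc_dilutions > 1)))
    stop("qc_dilutions must be strictly positive and at most 1")
  if (!ion_mode %in% c("POS", "NEG")) stop("ion_mode must be POS or NEG")
  structure(list(n_case = n_case, n_control = n_control,
                 n_features = n_features, n_discriminant = n_discriminant,
                 effect_size = effect_size, dilution_sd = dilution_sd,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 qc_dilutions = qc_dilutions,
                 n_qc_replicates = n_qc_replicates, ion_mode = ion_mode,
                 n_db_features = n_db_features, mz_jitter_ppm = mz_jitter_ppm,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic untargeted feature table
#'
#' Log-intensity model: feature baseline + group effect (planted features
#' only) + per-sample log dilution factor + Normal(0, noise_sd) noise;
#' intensities are the exponential, so the table is log-normal and the
#' multiplicative-dilution assumption behind probabilistic quotient
#' normalization holds exactly. Planted features are elevated in the case
#' group by `effect_size` natural-log units. QC rows (pooled profile at the
#' nominal dilutions) are appended when `n_qc_replicates > 0`. Missing
#' entries are inserted completely at random.
#'
#' @param cfg a [sim_config()].
#' @param db optional metabolite database (see [load_metabolite_db()]) used
#'   to source realistic m/z values; loaded from the bundled table when `NULL`.
#' @return A list with elements `table` (a [feature_table()]) and
#'   `ground_truth` (planted feature ids, true per-sample dilution factors,
#'   the pooled base profile, and the feature-to-metabolite map).
#' @export
generate_feature_table <- function(cfg, db = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(db)) db <- load_metabolite_db()
  with_seed(cfg$seed, {
    n_study <- cfg$n_case + cfg$n_control
    p <- cfg$n_features
    baseline <- stats::rnorm(p, mean = 9, sd = 1)
    planted <- sort(sample.int(p, cfg$n_discriminant))
    group <- rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
    log_dil <- stats::rnorm(n_study, 0, cfg$dilution_sd)
    logI <- matrix(baseline, n_study, p, byrow = TRUE)
    logI[group == "case", planted] <- logI[group == "case", planted] +
      cfg$effect_size
    logI <- logI + log_dil +
      matrix(stats::rnorm(n_study * p, 0, cfg$noise_sd), n_study, p)
    ints <- exp(logI)

    # feature metadata: a subset carries database adduct masses (planted
    # features first) with small ppm jitter; the rest are uniform decoys
    feature_id <- sprintf("F%04d", seq_len(p))
    mz <- stats::runif(p, 50, 1200)
    met_map <- data.frame(feature_id = character(0), hmdb_id = character(0),
                          name = character(0), stringsAsFactors = FALSE)
    n_db <- min(cfg$n_db_features, p, nrow(db$metabolites))
    if (n_db > 0) {
      take <- c(planted, setdiff(seq_len(p), planted))[seq_len(n_db)]
      met_idx <- sample.int(nrow(db$metabolites), n_db)
      adduct <- if (cfg$ion_mode == "POS") "[M+H]+" else "[M-H]-"
      theo <- vapply(db$metabolites$monoisotopic_mass[met_idx], adduct_mass,
                     numeric(1), adduct = adduct)
      mz[take] <- theo * (1 + stats::rnorm(n_db, 0, cfg$mz_jitter_ppm) * 1e-6)
      met_map <- data.frame(feature_id = feature_id[take],
                            hmdb_id = db$metabolites$hmdb_id[met_idx],
                            name = db$metabolites$name[met_idx],
                            stringsAsFactors = FALSE)
    }
    feature_meta <- data.frame(feature_id = feature_id, mz = mz,
                               rt = stats::runif(p, 0.5, 11.5),
                               ion_mode = cfg$ion_mode,
                               stringsAsFactors = FALSE)
    sample_meta <- data.frame(
      sample_id = sprintf("S%02d", seq_len(n_study)),
      group = group, sample_type = "study",
      nominal_dilution = NA_real_, stringsAsFactors = FALSE)

    if (cfg$missing_rate > 0) {
      miss <- stats::runif(n_study * p) < cfg$missing_rate
      ints[matrix(miss, n_study, p)] <- NA_real_
    }
    tab <- feature_table(ints, feature_meta, sample_meta)

    if (cfg$n_qc_replicates > 0 && length(cfg$qc_dilutions)) {
      qc <- generate_qc_dilution_series(cfg, exp(baseline),
                                        feature_meta = feature_meta,
                                        seed = stats::runif(1, 1, 2^30))
      tab <- feature_table(rbind(tab$intensities, qc$intensities),
                           feature_meta,
                           rbind(sample_meta, qc$sample_meta))
    }
    list(table = tab,
         ground_truth = list(planted = feature_id[planted],
                             dilution = stats::setNames(exp(log_dil),
                                                        sample_meta$sample_id),
                             base_profile = exp(baseline),
                             metabolite_map = met_map))
  })
}

#' Generate a pooled-QC dilution series
#'
#' Each QC row has expected intensity `d * base_profile` at nominal dilution
#' fraction `d`, with multiplicative log-normal noise of standard deviation
#' `noise_sd`; the nominal dilution is recorded in the sample metadata.
#'
#' @param cfg a [sim_config()]; `qc_dilutions`, `n_qc_replicates` and
#'   `noise_sd` are used.
#' @param base_profile undiluted pooled intensity per feature (length
#'   `n_features`).
#' @param feature_meta optional feature metadata; a generic one is built
#'   when absent.
#' @param seed RNG seed; defaults to the config seed.
#' @return A [feature_table()] whose rows are all of sample type `"QC"`.
#' @export
generate_qc_dilution_series <- function(cfg, base_profile,
                                        feature_meta = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!length(cfg$qc_dilutions)) stop("qc_dilutions must be non-empty")
  if (length(base_profile) != cfg$n_features)
    stop("base_profile length must equal n_features")
  if (is.null(feature_meta))
    feature_meta <- data.frame(
      feature_id = sprintf("F%04d", seq_along(base_profile)),
      mz = stats::runif(length(base_profile), 50, 1200),
      rt = stats::runif(length(base_profile), 0.5, 11.5),
      ion_mode = cfg$ion_mode, stringsAsFactors = FALSE)
  with_seed(seed %||% cfg$seed, {
    d <- rep(cfg$qc_dilutions, each = cfg$n_qc_replicates)
    p <- length(base_profile)
    ints <- matrix(0, length(d), p)
    for (i in seq_along(d))
      ints[i, ] <- d[i] * base_profile *
        exp(stats::rnorm(p, 0, cfg$noise_sd))
    sample_meta <- data.frame(
      sample_id = sprintf("QC%02d", seq_along(d)),
      group = "none", sample_type = "QC", nominal_dilution = d,
      stringsAsFactors = FALSE)
    feature_table(ints, feature_meta, sample_meta)
  })
}

#' Generate a synthetic clinical covariate table
#'
#' Builds a per-subject table whose binary covariates reproduce requested
#' 2x2 margins exactly and whose numeric covariates are drawn from
#' per-group normal distributions. The defaults emulate a neonatal sepsis
#' case-control cohort of 15 cases and 15 controls (male sex 7 vs 5,
#' small-for-gestational-age 2 vs 6, positive maternal vaginal swab 3 vs 0,
#' premature rupture of membranes over 18 h 4 vs 2, C-reactive protein
#' below 2.9 mg/L at birth 12 vs 15, inotropes 0 vs 1, cesarean section
#' 14 vs 15, prenatal steroids 13 vs 13; gestational age in days
#' Normal(207, 17) vs Normal(213, 16); birth weight in grams
#' Normal(1269, 358) vs Normal(1300, 354)).
#'
#' @param n_case,n_control subjects per group.
#' @param binary named list; each element `c(case_count, control_count)` of
#'   subjects positive for the covariate.
#' @param numeric named list; each element
#'   `c(case_mean, case_sd, control_mean, control_sd)`.
#' @param seed RNG seed (mandatory).
#' @return A data.frame with `subject_id`, `group`, the binary covariates
#'   (0/1 integers) and the numeric covariates.
#' @export
generate_clinical_table <- function(n_case = 15, n_control = 15,
                                    binary = list(
                                      male_sex = c(7, 5),
                                      cesarean_section = c(14, 15),
                                      prenatal_steroids = c(13, 13),
                                      small_for_gestational_age = c(2, 6),
                                      maternal_vaginal_swab = c(3, 0),
                                      prom_over_18h = c(4, 2),
                                      inotropes = c(0, 1),
                                      crp_below_2.9 = c(12, 15)),
                                    numeric = list(
                                      gestational_age = c(207, 17, 213, 16),
                                      birth_weight = c(1269, 358, 1300, 354)),
                                    seed = NULL) {
  n <- c(n_case, n_control)
  for (nm in names(binary)) {
    k <- binary[[nm]]
    if (length(k) != 2 || any(k < 0) || any(k > n))
      stop("infeasible counts for binary covariate '", nm, "'")
  }
  with_seed(seed, {
    out <- data.frame(
      subject_id = sprintf("P%02d", seq_len(sum(n))),
      group = rep(c("case", "control"), n), stringsAsFactors = FALSE)
    for (nm in names(binary)) {
      k <- binary[[nm]]
      out[[nm]] <- c(sample(rep(c(1L, 0L), c(k[1], n[1] - k[1]))),
                     sample(rep(c(1L, 0L), c(k[2], n[2] - k[2]))))
    }
    for (nm in names(numeric)) {
      v <- numeric[[nm]]
      out[[nm]] <- c(stats::rnorm(n[1], v[1], v[2]),
                     stats::rnorm(n[2], v[3], v[4]))
    }
    out
  })
}
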