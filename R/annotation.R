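PROTON_MASS <- 1.007276

#' Expected m/z of an adduct
#'
#' `[M+H]+` adds and `[M-H]-` subtracts one proton mass (1.007276 Da).
#' Further adducts can be supplied through `extra`, a named vector of mass
#' shifts (e.g. `c("[M+Na]+" = 22.989218)`).
#'
#' @param monoisotopic_mass neutral monoisotopic mass M in Da (positive).
#' @param adduct adduct name.
#' @param extra optional named numeric vector of additional adduct shifts.
#' @return The expected m/z in Da.
#' @export
adduct_mass <- function(monoisotopic_mass, adduct = c("[M+H]+", "[M-H]-"),
                        extra = NULL) {
  if (monoisotopic_mass <= 0) stop("monoisotopic mass must be positive")
  shifts <- c("[M+H]+" = PROTON_MASS, "[M-H]-" = -PROTON_MASS, extra)
  if (!adduct[1] %in% names(shifts)) stop("unsupported adduct: ", adduct[1])
  monoisotopic_mass + shifts[[adduct[1]]]
}

adducts_for_mode <- function(ion_mode) {
  if (ion_mode == "POS") "[M+H]+" else "[M-H]-"
}

#' Match an observed m/z against the metabolite database
#'
#' Returns all database entries with an ion-mode-consistent adduct whose
#' theoretical m/z lies within the ppm tolerance, ranked by absolute ppm
#' error.
#'
#' @param mz observed m/z in Da.
#' @param ion_mode `"POS"` or `"NEG"`.
#' @param db a [load_metabolite_db()] result.
#' @param tolerance_ppm mass tolerance in ppm (default 10, appropriate for
#'   a Q-ToF instrument).
#' @return A data.frame of hits (possibly zero rows): name, hmdb_id,
#'   adduct, theoretical m/z, ppm error.
#' @export
mass_match <- function(mz, ion_mode, db, tolerance_ppm = 10) {
  stopifnot(inherits(db, "metabolite_db"))
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be positive")
  adduct <- adducts_for_mode(ion_mode)
  theo <- db$metabolites$monoisotopic_mass +
    if (ion_mode == "POS") PROTON_MASS else -PROTON_MASS
  ppm <- (mz - theo) / theo * 1e6
  hit <- which(abs(ppm) <= tolerance_ppm & theo > 0)
  out <- data.frame(name = db$metabolites$name[hit],
                    hmdb_id = db$metabolites$hmdb_id[hit],
                    adduct = rep_len(adduct, length(hit)),
                    theoretical_mz = theo[hit],
                    ppm_error = ppm[hit], stringsAsFactors = FALSE)
  out[order(abs(out$ppm_error)), , drop = FALSE]
}

#' Annotate relevant features by exact-mass matching
#'
#' One row per feature: the best database hit within tolerance (or an
#' unannotated marker), plus a direction-of-change field copied from the
#' univariate results when provided.
#'
#' @param features data.frame with `feature_id`, `mz`, `ion_mode` (e.g. the
#'   feature metadata of a [feature_table()] restricted to the relevant
#'   features).
#' @param db a [load_metabolite_db()] result.
#' @param tolerance_ppm mass tolerance in ppm (default 10).
#' @param direction optional named character vector (feature_id ->
#'   direction label such as `"case"`/`"control"`).
#' @return A data.frame with feature_id, mz, ion_mode, annotated flag,
#'   name, hmdb_id, adduct, ppm_error, direction.
#' @export
annotate_features <- function(features, db, tolerance_ppm = 10,
                              direction = NULL) {
  req <- c("feature_id", "mz", "ion_mode")
  if (!all(req %in% names(features)))
    stop("features must carry columns: ", paste(req, collapse = ", "))
  bad <- features$feature_id[is.na(features$mz)]
  if (length(bad))
    stop("missing m/z metadata for feature(s): ", paste(bad, collapse = ", "))
  n <- nrow(features)
  out <- data.frame(feature_id = features$feature_id, mz = features$mz,
                    ion_mode = features$ion_mode, annotated = FALSE,
                    name = NA_character_, hmdb_id = NA_character_,
                    adduct = NA_character_, ppm_error = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    hits <- mass_match(features$mz[i], features$ion_mode[i], db,
                       tolerance_ppm)
    if (nrow(hits)) {
      out$annotated[i] <- TRUE
      out$name[i] <- hits$name[1]
      out$hmdb_id[i] <- hits$hmdb_id[1]
      out$adduct[i] <- hits$adduct[1]
      out$ppm_error[i] <- hits$ppm_error[1]
    }
  }
  out$direction <- if (is.null(direction)) NA_character_
  else unname(direction[out$feature_id])
  out
}
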