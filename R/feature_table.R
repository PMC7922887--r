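#' Construct a feature table
#'
#' The container every pipeline stage transforms: a samples x features
#' intensity matrix together with per-feature metadata (m/z, retention time,
#' ionization mode) and per-sample metadata (group, sample type, nominal
#' dilution).
#'
#' @param intensities numeric matrix, samples in rows, features in columns.
#'   Non-negative; `NA` marks missing values.
#' @param feature_meta data.frame with columns `feature_id`, `mz` (Da),
#'   `rt` (minutes), `ion_mode` (`"POS"` or `"NEG"`), one row per column of
#'   `intensities`.
#' @param sample_meta data.frame with columns `sample_id`, `group`
#'   (`"case"`, `"control"` or `"none"`), `sample_type` (`"study"`, `"QC"` or
#'   `"blank"`) and optionally `nominal_dilution` (fraction in (0, 1]), one
#'   row per row of `intensities`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, feature_meta, sample_meta) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != nrow(sample_meta))
    stop("row count of intensities must equal number of sample_meta rows")
  if (ncol(intensities) != nrow(feature_meta))
    stop("column count of intensities must equal number of feature_meta rows")
  req_f <- c("feature_id", "mz", "rt", "ion_mode")
  if (!all(req_f %in% names(feature_meta)))
    stop("feature_meta must have columns: ", paste(req_f, collapse = ", "))
  req_s <- c("sample_id", "group", "sample_type")
  if (!all(req_s %in% names(sample_meta)))
    stop("sample_meta must have columns: ", paste(req_s, collapse = ", "))
  if (anyDuplicated(feature_meta$feature_id)) stop("feature_ids must be unique")
  if (anyDuplicated(sample_meta$sample_id)) stop("sample_ids must be unique")
  if (any(feature_meta$mz <= 0, na.rm = TRUE)) stop("m/z values must be positive")
  if (any(intensities < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  if (is.null(sample_meta$nominal_dilution))
    sample_meta$nominal_dilution <- NA_real_
  rownames(intensities) <- sample_meta$sample_id
  colnames(intensities) <- feature_meta$feature_id
  structure(list(intensities = intensities,
                 feature_meta = as.data.frame(feature_meta),
                 sample_meta = as.data.frame(sample_meta)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$sample_meta$sample_type)
  cat("feature_table:", nrow(x$intensities), "samples x",
      ncol(x$intensities), "features\n")
  cat("  sample types:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  grp <- table(x$sample_meta$group[x$sample_meta$sample_type == "study"])
  if (length(grp))
    cat("  study groups:",
        paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  miss <- mean(is.na(x$intensities))
  cat(sprintf("  missing: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Subset a feature table
#'
#' @param x a `feature_table`.
#' @param i sample index (logical, integer or sample_id character).
#' @param j feature index (logical, integer or feature_id character).
#' @param ... ignored.
#' @return A `feature_table` restricted to the selected rows/columns.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  if (is.character(i)) i <- match(i, x$sample_meta$sample_id)
  if (is.character(j)) j <- match(j, x$feature_meta$feature_id)
  feature_table(x$intensities[i, j, drop = FALSE],
                x$feature_meta[j, , drop = FALSE],
                x$sample_meta[i, , drop = FALSE])
}

#' Rows of the study samples
#' @param x a `feature_table`.
#' @return Logical vector marking study samples.
#' @export
is_study_sample <- function(x) x$sample_meta$sample_type == "study"

#' Write a feature table as CSV files
#'
#' Writes three plain-text files: `<stem>_intensities.csv` (sample_id index),
#' `<stem>_features.csv` and `<stem>_samples.csv`.
#'
#' @param x a `feature_table`.
#' @param stem path stem for the three files.
#' @return Invisibly, the paths written.
#' @export
write_feature_table <- function(x, stem) {
  p1 <- paste0(stem, "_intensities.csv")
  p2 <- paste0(stem, "_features.csv")
  p3 <- paste0(stem, "_samples.csv")
  df <- data.frame(sample_id = x$sample_meta$sample_id, x$intensities,
                   check.names = FALSE)
  utils::write.csv(df, p1, row.names = FALSE)
  utils::write.csv(x$feature_meta, p2, row.names = FALSE)
  utils::write.csv(x$sample_meta, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param stem path stem used when writing.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(stem) {
  ints <- utils::read.csv(paste0(stem, "_intensities.csv"), check.names = FALSE)
  fm <- utils::read.csv(paste0(stem, "_features.csv"))
  sm <- utils::read.csv(paste0(stem, "_samples.csv"))
  m <- as.matrix(ints[, -1, drop = FALSE])
  feature_table(m, fm, sm)
}
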