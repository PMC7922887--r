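#' Load the bundled miniature metabolite database
#'
#' The package ships a small curated mass table (name, HMDB identifier,
#' molecular formula, monoisotopic mass in Da, semicolon-separated pathway
#' memberships) covering the metabolites of the neonatal-sepsis urine and
#' plasma panels plus canonical members of the glutathione pathway. It is a
#' miniature stand-in for full metabolite databases such as HMDB and METLIN,
#' sufficient to exercise annotation and pathway over-representation end to
#' end; monoisotopic masses are computed from the molecular formulas.
#'
#' @param path optional path to an alternative TSV with the same columns.
#' @return A list of class `metabolite_db` with elements `metabolites`
#'   (data.frame) and `pathways` (named list of HMDB-id character vectors).
#' @export
load_metabolite_db <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "metabolite_db_mini.tsv",
                        package = "metabocc", mustWork = TRUE)
  db <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop("failed to load metabolite DB '", path, "': ",
                             conditionMessage(e)))
  req <- c("name", "hmdb_id", "formula", "monoisotopic_mass", "pathways")
  if (!all(req %in% names(db)))
    stop("malformed metabolite DB '", path, "': expected columns ",
         paste(req, collapse = ", "))
  bad <- which(!is.finite(db$monoisotopic_mass) | db$monoisotopic_mass <= 0)
  if (length(bad))
    stop("malformed metabolite DB '", path, "': non-positive mass at row(s) ",
         paste(bad + 1L, collapse = ", "))
  memb <- strsplit(db$pathways, ";", fixed = TRUE)
  pw <- list()
  for (i in seq_len(nrow(db)))
    for (nm in memb[[i]])
      if (nzchar(nm)) pw[[nm]] <- c(pw[[nm]], db$hmdb_id[i])
  structure(list(metabolites = db, pathways = pw), class = "metabolite_db")
}

#' @export
print.metabolite_db <- function(x, ...) {
  cat("metabolite_db:", nrow(x$metabolites), "metabolites,",
      length(x$pathways), "pathways\n")
  invisible(x)
}

#' Look up metabolites by name
#'
#' @param db a [load_metabolite_db()] result.
#' @param name metabolite name; matching is case-insensitive and tolerant
#'   of the "L-" stereo prefix.
#' @return The matching rows of the metabolite table (zero rows when the
#'   name is unknown).
#' @export
db_lookup <- function(db, name) {
  stopifnot(inherits(db, "metabolite_db"))
  norm <- function(x) sub("^l-", "", tolower(x))
  db$metabolites[norm(db$metabolites$name) == norm(name), , drop = FALSE]
}
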