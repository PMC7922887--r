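#' Hypergeometric over-representation p-value for one pathway
#'
#' With a universe of N metabolites of which K belong to the pathway and a
#' query of n metabolites of which k are pathway members, the p-value is
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n), computed by exact
#' summation. Query metabolites outside the universe are dropped with a
#' warning.
#'
#' @param query character vector of query metabolite ids.
#' @param pathway character vector of pathway member ids.
#' @param universe character vector of all metabolite ids considered.
#' @return A list with `p_value`, `k`, `K`, `n`, `N`.
#' @export
ora_test <- function(query, pathway, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  pathway <- intersect(unique(pathway), universe)
  drop_n <- sum(!unique(query) %in% universe)
  if (drop_n)
    warning(drop_n, " query metabolite(s) outside the universe dropped")
  query <- intersect(unique(query), universe)
  N <- length(universe); K <- length(pathway); n <- length(query)
  k <- length(intersect(query, pathway))
  p <- if (k == 0) 1 else
    sum(stats::dhyper(k:min(K, n), K, N - K, n))
  list(p_value = min(p, 1), k = k, K = K, n = n, N = N)
}

#' Over-representation pathway analysis
#'
#' Runs [ora_test()] for every pathway with at least one member in the
#' universe, adjusts the p-values by Benjamini-Hochberg across the tested
#' pathways, and flags pathways with q-value at most `delta`. The impact
#' column is the hit fraction k/K, a simple declared stand-in for
#' topology-based impact measures.
#'
#' @param query character vector of annotated metabolite ids (e.g. HMDB ids).
#' @param db a [load_metabolite_db()] result, or a named list of pathway
#'   member vectors.
#' @param delta q-value cutoff for flagging (default 0.15).
#' @param universe metabolite universe; defaults to all metabolites of the
#'   bundled database.
#' @return A data.frame sorted by p-value: pathway, k, K, n, N, p_value,
#'   q_value, impact, neg_log_p, flagged.
#' @export
run_ora <- function(query, db, delta = 0.15, universe = NULL) {
  pathways <- if (inherits(db, "metabolite_db")) db$pathways else db
  if (is.null(universe)) {
    if (!inherits(db, "metabolite_db"))
      stop("universe must be given when db is a plain pathway list")
    universe <- db$metabolites$hmdb_id
  }
  query <- unique(query[!is.na(query)])
  if (!length(query)) stop("no annotated metabolites to test")
  keep <- vapply(pathways, function(m) length(intersect(m, universe)) > 0,
                 logical(1))
  pathways <- pathways[keep]
  rows <- lapply(names(pathways), function(nm) {
    r <- suppressWarnings(ora_test(query, pathways[[nm]], universe))
    data.frame(pathway = nm, k = r$k, K = r$K, n = r$n, N = r$N,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$impact <- out$k / out$K
  out$neg_log_p <- -log10(out$p_value)
  out$flagged <- out$q_value <= delta
  out[order(out$p_value), , drop = FALSE]
}
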