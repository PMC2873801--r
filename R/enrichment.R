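# Gene-set over-representation by the one-sided Fisher exact test.

#' Fisher exact gene-set over-representation
#'
#' For each gene set, tests whether the query is enriched for the set's
#' members relative to the universe, using the one-sided (over-representation)
#' Fisher exact test: with overlap k, set size s, query size q and universe
#' size N, the p-value is the hypergeometric upper tail P(X >= k). Sets are
#' intersected with the universe first; sets empty after intersection are
#' dropped.
#'
#' @param query character vector of gene ids; must be a subset of
#'   \code{universe} and non-empty.
#' @param collection named list of character vectors (gene sets), e.g. from
#'   [readGmt()].
#' @param universe character vector of all testable gene ids (typically the
#'   genes on the platform after presence filtering).
#' @param adjust "none" (default, mirroring uncorrected P < 0.05 reporting)
#'   or "BH" to add a Benjamini-Hochberg adjusted column \code{p_adj}.
#' @return data.frame sorted ascending by p: \code{set_name},
#'   \code{overlap_count}, \code{set_size}, \code{query_size},
#'   \code{universe_size}, \code{p}, plus a list column
#'   \code{overlap_genes}.
#' @export
fisherEnrichment <- function(query, collection, universe,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  query <- unique(query)
  universe <- unique(universe)
  if (!length(universe)) stop("'universe' must be non-empty")
  if (!length(query)) stop("'query' must be non-empty")
  extra <- setdiff(query, universe)
  if (length(extra))
    stop("query genes outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  if (is.null(names(collection)) || any(names(collection) == ""))
    stop("'collection' must be a named list of gene sets")
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(collection[[nm]]), universe)
    if (!length(s)) return(NULL)
    ov <- intersect(query, s)
    k <- length(ov)
    p <- stats::phyper(k - 1, length(s), N - length(s), q,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, set_size = length(s),
               query_size = q, universe_size = N, p = p,
               overlap_genes = I(list(ov)), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(set_name = character(0), overlap_count = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), p = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$p), , drop = FALSE]
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Per-category p-value ranges over significant sets
#'
#' Groups enrichment results into categories and reports, per category, the
#' minimum and maximum p over member sets significant at \code{alpha}, plus
#' the distinct count of overlap genes contributed by those sets. Categories
#' with no significant member set are omitted.
#'
#' @param results data.frame from [fisherEnrichment()] (needs
#'   \code{set_name}, \code{p} and \code{overlap_genes}).
#' @param grouping data.frame with columns \code{set_name}, \code{category}.
#' @param alpha significance threshold on p (strict <; default 0.05).
#' @return data.frame: \code{category}, \code{p_min}, \code{p_max},
#'   \code{n_sets}, \code{n_genes}.
#' @export
summarizeCategoryRanges <- function(results, grouping, alpha = 0.05) {
  stopifnot(all(c("set_name", "category") %in% names(grouping)))
  sig <- results[results$p < alpha, , drop = FALSE]
  sig <- merge(sig, grouping, by = "set_name")
  if (!nrow(sig))
    return(data.frame(category = character(0), p_min = numeric(0),
                      p_max = numeric(0), n_sets = integer(0),
                      n_genes = integer(0)))
  out <- do.call(rbind, lapply(split(sig, sig$category), function(g) {
    data.frame(category = g$category[1],
               p_min = min(g$p), p_max = max(g$p), n_sets = nrow(g),
               n_genes = length(unique(unlist(g$overlap_genes))),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$p_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}
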