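# Core integration procedure: overlap differentially expressed genes with
# conservation-filtered miRNA target maps, keep inversely directed pairs,
# apply the magnitude cutoff, and report overlap summaries and per-pair
# concordance tables.

#' Filter a target map by conservation probability
#'
#' Keeps records whose conservation probability (P-org) is strictly below
#' \code{pOrgMax}, the standard false-positive guard on predicted targets.
#'
#' @param map a [TargetMap-class].
#' @param pOrgMax strict upper bound on P-org (default 0.05).
#' @return a filtered [TargetMap-class].
#' @export
filterTargetsByConservation <- function(map, pOrgMax = 0.05) {
  stopifnot(is(map, "TargetMap"))
  r <- targetRecords(map)
  targetMap(r[r$p_org < pOrgMax, , drop = FALSE])
}

#' Overlap DE genes with DE-miRNA targets
#'
#' One integration record per (DE miRNA, DE gene) pair present in the target
#' map, annotated with both group-average log2 ratios and the inverse flag
#' (opposite signs, i.e. product < 0). A gene targeted by several DE miRNAs
#' yields several records. Records whose miRNA or gene average is missing are
#' skipped with a warning.
#'
#' @param deGenes data.frame with columns \code{gene_id}, \code{avg_log2}.
#' @param deMirnas data.frame with columns \code{mirna_id}, \code{avg_log2}.
#' @param map a [TargetMap-class], already conservation-filtered.
#' @return data.frame with columns \code{mirna_id}, \code{gene_id},
#'   \code{mirna_avg_log2}, \code{gene_avg_log2}, \code{inverse}; attribute
#'   \code{"nDistinctGenes"} carries the distinct-gene count.
#' @export
overlapTargets <- function(deGenes, deMirnas, map) {
  stopifnot(is(map, "TargetMap"))
  stopifnot(all(c("gene_id", "avg_log2") %in% names(deGenes)),
            all(c("mirna_id", "avg_log2") %in% names(deMirnas)))
  r <- targetRecords(map)
  r <- r[r$mirna_id %in% deMirnas$mirna_id &
           r$gene_id %in% deGenes$gene_id, , drop = FALSE]
  mAvg <- stats::setNames(deMirnas$avg_log2, deMirnas$mirna_id)
  gAvg <- stats::setNames(deGenes$avg_log2, deGenes$gene_id)
  out <- data.frame(
    mirna_id = r$mirna_id,
    gene_id = r$gene_id,
    mirna_avg_log2 = unname(mAvg[r$mirna_id]),
    gene_avg_log2 = unname(gAvg[r$gene_id]),
    stringsAsFactors = FALSE)
  bad <- is.na(out$mirna_avg_log2) | is.na(out$gene_avg_log2)
  if (any(bad)) {
    warning(sum(bad), " record(s) skipped: missing expression average")
    out <- out[!bad, , drop = FALSE]
  }
  out$inverse <- out$mirna_avg_log2 * out$gene_avg_log2 < 0
  rownames(out) <- NULL
  attr(out, "nDistinctGenes") <- length(unique(out$gene_id))
  out
}

#' Keep inversely directed miRNA-target records
#'
#' Retains records whose miRNA and gene group averages have strictly opposite
#' signs. Genes with an average of exactly 0 have no direction and are
#' excluded.
#'
#' @param records data.frame from [overlapTargets()].
#' @return the filtered records.
#' @export
inverseFilter <- function(records) {
  records[!is.na(records$inverse) & records$inverse, , drop = FALSE]
}

#' Magnitude cutoff on the gene average
#'
#' Keeps records whose absolute gene-average log2 ratio is at least
#' \code{cutoff} (boundary inclusive, the "log2(ratio) >= +/- 0.4" rule).
#'
#' @param records data.frame with a \code{gene_avg_log2} column.
#' @param cutoff non-negative magnitude threshold (default 0.4).
#' @return the filtered records, with a \code{passes_cutoff} column set TRUE.
#' @export
magnitudeCutoff <- function(records, cutoff = 0.4) {
  if (cutoff < 0) stop("'cutoff' must be >= 0")
  keep <- abs(records$gene_avg_log2) >= cutoff
  out <- records[keep, , drop = FALSE]
  if (nrow(out)) out$passes_cutoff <- TRUE
  out
}

#' Summary of the DE-gene / target-map overlap
#'
#' Given the number of differentially expressed genes, reports how many
#' distinct genes are putative targets of the DE miRNAs and how many of those
#' change inversely, both as counts and as percentages of the DE genes
#' (exact fraction kept; display value rounded to the nearest integer).
#'
#' @param nDeGenes number of DE genes (denominator); must be > 0.
#' @param records integration records from [overlapTargets()]; alternatively
#'   pass \code{nTargetGenes}/\code{nInverseGenes} directly.
#' @param nTargetGenes,nInverseGenes distinct-gene counts, used when
#'   \code{records} is NULL.
#' @return list with \code{n_de_genes}, \code{n_target_genes},
#'   \code{pct_target}, \code{pct_target_display}, \code{n_inverse_genes},
#'   \code{pct_inverse}, \code{pct_inverse_display}.
#' @examples
#' overlapSummary(3905, nTargetGenes = 1406, nInverseGenes = 1053)
#' @export
overlapSummary <- function(nDeGenes, records = NULL, nTargetGenes = NULL,
                           nInverseGenes = NULL) {
  if (nDeGenes <= 0) stop("'nDeGenes' must be > 0: percentages undefined")
  if (!is.null(records)) {
    nTargetGenes <- length(unique(records$gene_id))
    nInverseGenes <- length(unique(records$gene_id[
      !is.na(records$inverse) & records$inverse]))
  }
  if (is.null(nTargetGenes) || is.null(nInverseGenes))
    stop("supply 'records' or both gene counts")
  pt <- 100 * nTargetGenes / nDeGenes
  pi <- 100 * nInverseGenes / nDeGenes
  list(n_de_genes = nDeGenes,
       n_target_genes = nTargetGenes,
       pct_target = pt, pct_target_display = round(pt),
       n_inverse_genes = nInverseGenes,
       pct_inverse = pi, pct_inverse_display = round(pi))
}

#' Per-pair concordance of one miRNA and one target gene
#'
#' Aligns per-pair log2 ratios of a miRNA and a putative target gene and
#' reports the trailing averages over non-missing entries, with 3-decimal
#' display rounding.
#'
#' @param mirnaRatios,geneRatios numeric vectors of per-pair log2 ratios,
#'   named by pair id (gene values may be NA).
#' @param mirnaId,geneId identifiers for labeling.
#' @return list with \code{mirna_id}, \code{gene_id}, \code{pair_ids},
#'   \code{mirna_values}, \code{gene_values}, \code{mirna_avg},
#'   \code{gene_avg} (full precision; NA when all values missing),
#'   \code{mirna_avg_display}, \code{gene_avg_display} (rounded to 3
#'   decimals), \code{n_mirna}, \code{n_gene}.
#' @export
concordanceRow <- function(mirnaRatios, geneRatios, mirnaId = "miRNA",
                           geneId = "gene") {
  if (is.null(names(mirnaRatios)) || is.null(names(geneRatios)))
    stop("per-pair ratio vectors must be named by pair id")
  shared <- intersect(names(mirnaRatios), names(geneRatios))
  if (!length(shared)) stop("no overlapping pairs between the two inputs")
  m <- mirnaRatios[shared]
  g <- geneRatios[shared]
  mAvg <- if (all(is.na(m))) NA_real_ else mean(m, na.rm = TRUE)
  gAvg <- if (all(is.na(g))) NA_real_ else mean(g, na.rm = TRUE)
  list(mirna_id = mirnaId, gene_id = geneId, pair_ids = shared,
       mirna_values = m, gene_values = g,
       mirna_avg = mAvg, gene_avg = gAvg,
       mirna_avg_display = round(mAvg, 3), gene_avg_display = round(gAvg, 3),
       n_mirna = sum(!is.na(m)), n_gene = sum(!is.na(g)))
}

#' Concordance table for several miRNA-gene pairs
#'
#' Builds one formatted row per requested (miRNA, gene) relation: per-pair
#' "miRNA(gene)" entries at 3 decimals ("NA" where the gene is missing) and
#' an Average column formed the same way, plus full-precision average columns.
#'
#' @param mirnaMatrix miRNAs x pairs matrix of log2 ratios.
#' @param geneMatrix genes x pairs matrix of log2 ratios (NAs allowed).
#' @param pairs data.frame with columns \code{mirna_id}, \code{gene_id}.
#' @return data.frame: \code{mirna_id}, \code{gene_id}, one character column
#'   per shared pair, \code{average} (formatted), \code{mirna_avg},
#'   \code{gene_avg} (numeric).
#' @export
concordanceTable <- function(mirnaMatrix, geneMatrix, pairs) {
  stopifnot(all(c("mirna_id", "gene_id") %in% names(pairs)))
  shared <- intersect(colnames(mirnaMatrix), colnames(geneMatrix))
  if (!length(shared)) stop("no overlapping pairs between the two inputs")
  fmt <- function(m, g) {
    gs <- ifelse(is.na(g), "NA", sprintf("%.3f", g))
    sprintf("%.3f(%s)", m, gs)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    mid <- pairs$mirna_id[i]
    gid <- pairs$gene_id[i]
    if (!mid %in% rownames(mirnaMatrix)) stop("miRNA not found: ", mid)
    if (!gid %in% rownames(geneMatrix)) stop("gene not found: ", gid)
    cr <- concordanceRow(mirnaMatrix[mid, shared], geneMatrix[gid, shared],
                         mid, gid)
    vals <- as.list(fmt(cr$mirna_values, cr$gene_values))
    names(vals) <- shared
    c(list(mirna_id = mid, gene_id = gid), vals,
      list(average = fmt(cr$mirna_avg, cr$gene_avg),
           mirna_avg = cr$mirna_avg, gene_avg = cr$gene_avg))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Run the full integration chain
#'
#' Convenience composition: conservation filter, DE overlap, inverse filter,
#' magnitude cutoff, and the overlap summary.
#'
#' @param deGenes,deMirnas as in [overlapTargets()].
#' @param map an unfiltered [TargetMap-class].
#' @param pOrgMax conservation threshold (strict <; default 0.05).
#' @param cutoff gene-magnitude threshold (inclusive >=; default 0.4).
#' @return list with \code{records} (post-overlap), \code{inverse},
#'   \code{final} (post-cutoff), and \code{summary} (see [overlapSummary()]).
#' @export
integratePairs <- function(deGenes, deMirnas, map, pOrgMax = 0.05,
                           cutoff = 0.4) {
  fmap <- filterTargetsByConservation(map, pOrgMax)
  records <- overlapTargets(deGenes, deMirnas, fmap)
  inv <- inverseFilter(records)
  fin <- magnitudeCutoff(inv, cutoff)
  list(records = records, inverse = inv, final = fin,
       summary = overlapSummary(nrow(deGenes), records))
}
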