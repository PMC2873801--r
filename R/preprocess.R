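# Spot-level preprocessing for two-color miRNA arrays and harmonization of
# reference-design mRNA data into case/control log2 ratios.

.spotCols <- function(kind) sprintf("rep%d_%s", 1:3, kind)

#' Summarize triplicate spots into per-probe net intensities
#'
#' Per probe and channel: the mean of the three replicate spot intensities
#' minus the mean of their local backgrounds. Net values may be negative;
#' downstream, non-positive nets yield missing log2 ratios (see
#' [flagDetectable()]).
#'
#' @param spots spot-table data.frame with columns \code{probe_id} and
#'   \code{repN_ch1/ch2/bg1/bg2} for N = 1..3 (the layout written by
#'   [generateMirnaSpotTables()] / [readSpotTable()]).
#' @return data.frame with columns \code{probe_id}, \code{net_ch1},
#'   \code{net_ch2}.
#' @examples
#' tab <- data.frame(probe_id = "p1",
#'   rep1_ch1 = 90, rep2_ch1 = 100, rep3_ch1 = 110,
#'   rep1_ch2 = 100, rep2_ch2 = 100, rep3_ch2 = 100,
#'   rep1_bg1 = 20, rep2_bg1 = 10, rep3_bg1 = 30,
#'   rep1_bg2 = 10, rep2_bg2 = 10, rep3_bg2 = 10)
#' summarizeSpots(tab)  # net_ch1 = 80, net_ch2 = 90
#' @export
summarizeSpots <- function(spots) {
  need <- c("probe_id", .spotCols("ch1"), .spotCols("ch2"),
            .spotCols("bg1"), .spotCols("bg2"))
  miss <- setdiff(need, names(spots))
  if (length(miss))
    stop("spot table is missing replicate columns: ",
         paste(miss, collapse = ", "))
  vals <- spots[, setdiff(need, "probe_id")]
  if (any(vals < 0, na.rm = TRUE))
    stop("spot intensities and backgrounds must be >= 0")
  data.frame(
    probe_id = spots$probe_id,
    net_ch1 = rowMeans(spots[, .spotCols("ch1")]) -
      rowMeans(spots[, .spotCols("bg1")]),
    net_ch2 = rowMeans(spots[, .spotCols("ch2")]) -
      rowMeans(spots[, .spotCols("bg2")]),
    stringsAsFactors = FALSE)
}

#' Flag probes detectable above background
#'
#' A probe is detectable iff both channels' background-subtracted net
#' intensities are strictly above \code{minNet}.
#'
#' @param netCh1,netCh2 numeric vectors of net intensities.
#' @param minNet detection threshold (default 0).
#' @return logical vector.
#' @export
flagDetectable <- function(netCh1, netCh2, minNet = 0) {
  stopifnot(length(netCh1) == length(netCh2))
  netCh1 > minNet & netCh2 > minNet
}

#' Within-array ratio-distribution normalization
#'
#' Iterative trimmed centering of an array's log2 ratios: compute the mean m
#' and SD s of the currently included ratios, exclude ratios outside
#' m +/- z*s where z is the two-sided normal quantile of the confidence level
#' (z = 2.5758 at 99.00), and repeat until the exclusion set stabilizes. The
#' final trimmed mean is subtracted from ALL ratios, excluded ones included.
#' If the included ratios are all identical (s = 0), their common value is
#' subtracted and iteration stops.
#'
#' @param ratios numeric vector of log2 ratios; NAs pass through unchanged
#'   (shifted like everything else they are NA).
#' @param confidence confidence level in percent (default 99.00).
#' @param maxIter iteration cap (safety; convergence is typically < 10).
#' @return numeric vector of the same length, centered; attribute
#'   \code{"trimmedMean"} records the subtracted value.
#' @export
withinArrayNormalize <- function(ratios, confidence = 99, maxIter = 100L) {
  if (confidence <= 0 || confidence >= 100)
    stop("'confidence' must be in (0, 100)")
  fin <- which(is.finite(ratios))
  if (length(fin) < 3)
    stop("need at least 3 finite ratios to normalize")
  z <- stats::qnorm(1 - (1 - confidence / 100) / 2)
  x <- ratios[fin]
  keep <- rep(TRUE, length(x))
  m <- mean(x)
  for (i in seq_len(maxIter)) {
    m <- mean(x[keep])
    s <- stats::sd(x[keep])
    if (is.na(s) || s == 0) break
    newKeep <- x >= m - z * s & x <= m + z * s
    if (identical(newKeep, keep)) break
    keep <- newKeep
    if (!any(keep)) { # degenerate; fall back to untrimmed mean
      keep <- rep(TRUE, length(x))
      m <- mean(x)
      break
    }
  }
  out <- ratios - m
  attr(out, "trimmedMean") <- m
  out
}

#' Quantile normalization across arrays
#'
#' Forces all columns to share one empirical distribution: each column's
#' value of rank k is replaced by the mean, over columns that have a k-th
#' order statistic, of their k-th smallest values. Ties within a column
#' receive the mean of their tied positions' reference values. Missing
#' values stay missing; ranks are computed on each column's available values
#' only, so the step is order-preserving per column.
#'
#' @param mat numeric matrix (rows = probes/genes, columns = arrays),
#'   possibly containing NA.
#' @return matrix of the same shape; a single-column matrix is returned
#'   unchanged.
#' @examples
#' quantileNormalize(cbind(a = c(1, 3), b = c(2, 4)))  # both columns 1.5, 3.5
#' @export
quantileNormalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) return(mat)
  nAvail <- colSums(!is.na(mat))
  maxN <- max(nAvail)
  if (maxN == 0) return(mat)
  sorted <- matrix(NA_real_, nrow = maxN, ncol = ncol(mat))
  for (j in seq_len(ncol(mat))) {
    v <- sort(mat[, j][!is.na(mat[, j])])
    if (length(v)) sorted[seq_along(v), j] <- v
  }
  ref <- rowMeans(sorted, na.rm = TRUE)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    idx <- which(!is.na(mat[, j]))
    if (!length(idx)) next
    v <- mat[idx, j]
    o <- order(v)
    grp <- cumsum(!duplicated(v[o])) # run id of tied values in sorted order
    refMean <- tapply(ref[seq_along(o)], grp, mean)
    out[idx[o], j] <- refMean[grp] # ties: mean of their positions' reference
  }
  out
}

#' Presence filter on a ratio matrix
#'
#' Keeps rows observed (non-missing) in at least \code{minPresent} of the
#' columns ("present in at least four out of seven comparisons" style
#' filtering); row order is preserved.
#'
#' @param mat numeric matrix with possible NAs.
#' @param minPresent minimum number of non-missing values per row (default 4).
#' @return the filtered matrix.
#' @export
presenceFilter <- function(mat, minPresent = 4) {
  mat <- as.matrix(mat)
  if (minPresent > ncol(mat))
    stop("'minPresent' (", minPresent, ") exceeds the column count (",
         ncol(mat), ")")
  mat[rowSums(!is.na(mat)) >= minPresent, , drop = FALSE]
}

#' Harmonize reference-design data into case/control log2 ratios
#'
#' Converts two sample-versus-common-reference log2 matrices into direct
#' case/control log2 ratios per pair:
#' \code{log2(case/ref) - log2(control/ref) = log2(case/control)}. The result
#' is missing wherever either input is missing.
#'
#' @param caseVsRef,controlVsRef numeric matrices of log2(sample/reference)
#'   values sharing row ids; columns named by sample id.
#' @param design a [PairedDesign-class]; every pair's case id must be a
#'   column of \code{caseVsRef} and its control id a column of
#'   \code{controlVsRef}.
#' @return genes x pairs matrix of log2(case/control), columns named
#'   "case/control".
#' @export
harmonizeReferenceDesign <- function(caseVsRef, controlVsRef, design) {
  stopifnot(is(design, "PairedDesign"))
  if (!identical(rownames(caseVsRef), rownames(controlVsRef)))
    stop("case and control matrices must share identical row ids")
  p <- designPairs(design)
  badCase <- setdiff(p$case_id, colnames(caseVsRef))
  badCtrl <- setdiff(p$control_id, colnames(controlVsRef))
  if (length(badCase) || length(badCtrl))
    stop("design pairs unmatched in the input matrices: ",
         paste(c(badCase, badCtrl), collapse = ", "))
  out <- caseVsRef[, p$case_id, drop = FALSE] -
    controlVsRef[, p$control_id, drop = FALSE]
  colnames(out) <- pairIds(design)
  out
}

#' Preprocess spot tables into a normalized miRNA log2-ratio matrix
#'
#' Per sample: triplicate spots are averaged and local backgrounds subtracted
#' ([summarizeSpots()]); probes not detectable above background in both
#' channels ([flagDetectable()]) get missing ratios; ratios are
#' log2(channel1/channel2) = log2(sample/reference); each array is centered by
#' ratio-distribution normalization ([withinArrayNormalize()]); across
#' samples, probes detectable everywhere are kept (if
#' \code{requireDetectableAll}) and quantile normalization is applied.
#'
#' @param spotTables named list of per-sample spot-table data.frames.
#' @param confidence within-array normalization confidence level (percent).
#' @param minNet detectability threshold on net intensities.
#' @param normalizeWithin apply within-array centering (default TRUE).
#' @param quantileAcross apply across-array quantile normalization
#'   (default TRUE).
#' @param requireDetectableAll drop probes with a missing ratio in any sample
#'   (default TRUE).
#' @return probes x samples matrix of log2(sample/reference) ratios.
#' @export
preprocessMirnaArrays <- function(spotTables, confidence = 99, minNet = 0,
                                  normalizeWithin = TRUE,
                                  quantileAcross = TRUE,
                                  requireDetectableAll = TRUE) {
  if (is.null(names(spotTables)) || any(names(spotTables) == ""))
    stop("'spotTables' must be a named list (names = sample ids)")
  cols <- lapply(names(spotTables), function(s) {
    net <- summarizeSpots(spotTables[[s]])
    ok <- flagDetectable(net$net_ch1, net$net_ch2, minNet)
    ratio <- ifelse(ok, log2(net$net_ch1 / net$net_ch2), NA_real_)
    if (normalizeWithin && sum(is.finite(ratio)) >= 3)
      ratio <- as.numeric(withinArrayNormalize(ratio, confidence))
    stats::setNames(ratio, net$probe_id)
  })
  probes <- names(cols[[1]])
  for (v in cols) if (!identical(names(v), probes))
    stop("all spot tables must list the same probes in the same order")
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(spotTables)
  if (requireDetectableAll)
    mat <- mat[rowSums(is.na(mat)) == 0, , drop = FALSE]
  if (quantileAcross) mat <- quantileNormalize(mat)
  mat
}
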