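# Differential expression: Pavlidis template matching on sample-level
# profiles and one-class t-tests on pair-level log2 ratios.

#' Pavlidis template matching
#'
#' Correlates every row of an expression matrix with a per-column template
#' (typically case = 1, control = 0) and converts the Pearson correlation r
#' to a two-sided p-value through \code{t = r * sqrt(n - 2) / sqrt(1 - r^2)}
#' on n - 2 degrees of freedom, where n is the number of columns with both a
#' non-missing row value and a template value (pairwise-complete; degrees of
#' freedom shrink with missingness). With a binary 0/1 template this is
#' numerically identical to the pooled equal-variance two-sample t-test.
#'
#' @param mat numeric matrix, rows = probes, columns = samples.
#' @param template numeric vector, one value per column; must not be constant.
#' @return data.frame with one row per probe: \code{probe_id}, \code{r},
#'   \code{p}, \code{group_log2_ratio} (mean over template-high columns minus
#'   mean over template-low columns, for binary templates; NA otherwise),
#'   \code{n_used}, and \code{flag} ("ok", "constant" for rows with no
#'   variance where r is undefined and p is set to 1, or "insufficient" for
#'   rows with fewer than 3 usable values, p = NA).
#' @examples
#' m <- rbind(p1 = c(1, 1, 0, 0), p2 = c(0, 1, 0, 1))
#' templateMatch(m, c(1, 1, 0, 0))
#' @export
templateMatch <- function(mat, template) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3) stop("need at least 3 columns")
  if (length(template) != ncol(mat))
    stop("'template' must have one value per column")
  if (stats::sd(template, na.rm = TRUE) == 0 || all(is.na(template)))
    stop("'template' must not be constant")
  binary <- length(unique(stats::na.omit(template))) == 2
  hi <- !is.na(template) & template == max(template, na.rm = TRUE)
  lo <- !is.na(template) & template == min(template, na.rm = TRUE)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))

  one <- function(x) {
    use <- !is.na(x) & !is.na(template)
    n <- sum(use)
    grat <- if (binary) {
      mean(x[use & hi]) - mean(x[use & lo])
    } else NA_real_
    if (n < 3 || stats::sd(template[use]) == 0)
      return(list(r = NA_real_, p = NA_real_, grat = grat, n = n,
                  flag = "insufficient"))
    if (stats::sd(x[use]) == 0)
      return(list(r = NA_real_, p = 1, grat = grat, n = n,
                  flag = "constant"))
    r <- stats::cor(x[use], template[use])
    r <- max(-1, min(1, r))
    tt <- r * sqrt(n - 2) / sqrt(max(0, 1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    list(r = r, p = p, grat = grat, n = n, flag = "ok")
  }
  res <- apply(mat, 1, one)
  data.frame(
    probe_id = ids,
    r = vapply(res, `[[`, numeric(1), "r"),
    p = vapply(res, `[[`, numeric(1), "p"),
    group_log2_ratio = vapply(res, `[[`, numeric(1), "grat"),
    n_used = vapply(res, `[[`, numeric(1), "n"),
    flag = vapply(res, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' One-class t-test on pair-level log2 ratios
#'
#' Tests, per row, whether the mean log2 case/control ratio differs from 0
#' (two-sided one-sample t-test). No multiple-testing correction is applied.
#' Rows with fewer than 2 non-missing values are dropped with a warning. A
#' zero-variance row gives t = 0, p = 1 when its mean is 0, and |t| = Inf,
#' p = 0 otherwise.
#'
#' @param mat numeric matrix of log2 ratios, rows = genes, columns = pairs.
#' @return data.frame with columns \code{gene_id}, \code{mean}, \code{t},
#'   \code{p}, \code{n_used}.
#' @export
oneClassTTest <- function(mat) {
  mat <- as.matrix(mat)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  n <- rowSums(!is.na(mat))
  skip <- n < 2
  if (any(skip))
    warning(sum(skip), " row(s) with fewer than 2 non-missing values skipped")
  keep <- which(!skip)
  mu <- rowMeans(mat[keep, , drop = FALSE], na.rm = TRUE)
  sd <- apply(mat[keep, , drop = FALSE], 1, stats::sd, na.rm = TRUE)
  nk <- n[keep]
  tt <- ifelse(sd == 0, ifelse(mu == 0, 0, sign(mu) * Inf),
               mu / (sd / sqrt(nk)))
  p <- 2 * stats::pt(-abs(tt), df = nk - 1)
  data.frame(gene_id = ids[keep], mean = mu, t = tt, p = p, n_used = nk,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a differential-expression table
#'
#' Filters test results at a significance threshold (strict \code{p < alpha}
#' by default) and partitions them into down-regulated (negative ratio,
#' sorted ascending so the strongest suppression leads) and up-regulated
#' (positive ratio, sorted descending) groups.
#'
#' @param results data.frame with a \code{p} column and a ratio column
#'   (\code{group_log2_ratio}, \code{log2_ratio} or \code{mean}); id columns
#'   (\code{probe_id}/\code{clone_id}/\code{gene_id}, optional
#'   \code{mirna_name}) are carried through.
#' @param alpha significance threshold (default 0.05).
#' @param strict if TRUE (default) keep \code{p < alpha}; if FALSE keep
#'   \code{p <= alpha}.
#' @return data.frame with columns \code{clone_id}, \code{mirna_name} (NA if
#'   absent), \code{log2_ratio}, \code{p}, \code{direction} ("down"/"up";
#'   a zero ratio gives "none" and sorts last), ordered down-block first.
#' @export
buildDETable <- function(results, alpha = 0.05, strict = TRUE) {
  ratioCol <- intersect(c("group_log2_ratio", "log2_ratio", "mean"),
                        names(results))[1]
  if (is.na(ratioCol)) stop("no ratio column found in 'results'")
  if (!"p" %in% names(results)) stop("'results' must have a 'p' column")
  idCol <- intersect(c("clone_id", "probe_id", "gene_id"), names(results))[1]
  if (is.na(idCol)) stop("no id column found in 'results'")
  keep <- if (strict) results$p < alpha else results$p <= alpha
  keep[is.na(keep)] <- FALSE
  r <- results[keep, , drop = FALSE]
  out <- data.frame(
    clone_id = r[[idCol]],
    mirna_name = if ("mirna_name" %in% names(r)) r$mirna_name else
      rep(NA_character_, nrow(r)),
    log2_ratio = r[[ratioCol]],
    p = r$p,
    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$log2_ratio < 0, "down",
                          ifelse(out$log2_ratio > 0, "up", "none"))
  down <- out[out$direction == "down", , drop = FALSE]
  up <- out[out$direction == "up", , drop = FALSE]
  none <- out[out$direction == "none", , drop = FALSE]
  down <- down[order(down$log2_ratio), , drop = FALSE]
  up <- up[order(-up$log2_ratio), , drop = FALSE]
  out <- rbind(down, up, none)
  rownames(out) <- NULL
  out
}
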