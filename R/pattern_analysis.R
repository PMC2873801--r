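# Class-separation diagnostics on the significant-probe matrix: UPGMA
# clustering of samples, K-means, PCA, and leave-one-out classification.

#' Hierarchical clustering of samples (UPGMA)
#'
#' Average-linkage clustering of the matrix columns on Euclidean distance.
#' Distances between columns with missing values are pairwise-complete,
#' rescaled to the full dimension (the behaviour of [stats::dist()]).
#' Columns are ordered lexicographically before clustering so merge-order
#' ties break deterministically by sample id.
#'
#' @param mat numeric matrix, rows = probes, columns = samples.
#' @return an object of class \code{hclust}.
#' @seealso [clusterTreeNewick()] to export the dendrogram.
#' @export
hierarchicalCluster <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 samples to cluster")
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("S%03d", seq_len(ncol(mat)))
  allNA <- colSums(!is.na(mat)) == 0
  if (any(allNA))
    stop("sample(s) with all-missing values: ",
         paste(colnames(mat)[allNA], collapse = ", "))
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  d <- stats::dist(t(mat))
  if (any(!is.finite(d)))
    stop("some sample pairs share no observed probes; distance undefined")
  stats::hclust(d, method = "average")
}

#' Export a sample dendrogram as a newick string
#'
#' @param hc an \code{hclust} object (e.g. from [hierarchicalCluster()]).
#' @param file optional path; when given the tree is also written there.
#' @return the newick string, invisibly when \code{file} is given.
#' @export
clusterTreeNewick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}

#' K-means clustering of samples
#'
#' Lloyd-style K-means (via [stats::kmeans()]) on the sample columns with
#' multiple seeded restarts, keeping the best within-cluster sum of squares.
#' Rows with missing values are dropped first.
#'
#' @param mat numeric matrix, rows = probes, columns = samples.
#' @param k number of clusters (default 2).
#' @param seed integer seed for the restarts.
#' @param nstart number of random restarts (default 10).
#' @return named integer vector of cluster labels, one per sample.
#' @export
kmeansCluster <- function(mat, k = 2, seed = 1, nstart = 10) {
  mat <- as.matrix(mat)
  if (k < 1) stop("'k' must be >= 1")
  if (k > ncol(mat)) stop("'k' must not exceed the number of samples")
  mat <- mat[rowSums(is.na(mat)) == 0, , drop = FALSE]
  if (!nrow(mat)) stop("no complete rows available")
  if (k == ncol(mat)) # trivial partition: every sample its own cluster
    return(stats::setNames(seq_len(ncol(mat)), colnames(mat)))
  set.seed(seed)
  km <- stats::kmeans(t(mat), centers = k, nstart = nstart)
  stats::setNames(km$cluster, colnames(mat))
}

#' Principal component projection of samples
#'
#' Column-centered PCA of the samples (rows with any missing value are
#' dropped first, with a message). Variance fractions are non-increasing and
#' sum to at most 1.
#'
#' @param mat numeric matrix, rows = probes, columns = samples.
#' @param nComponents number of components to return (default 2).
#' @return list with \code{coordinates} (samples x nComponents),
#'   \code{varianceFractions} (length nComponents), \code{loadings},
#'   \code{center}, and \code{sdev} (all components' standard deviations).
#' @export
pcaProject <- function(mat, nComponents = 2) {
  mat <- as.matrix(mat)
  incomplete <- rowSums(is.na(mat)) > 0
  if (any(incomplete))
    message("dropping ", sum(incomplete), " row(s) with missing values")
  mat <- mat[!incomplete, , drop = FALSE]
  if (nComponents > min(dim(mat)))
    stop("'nComponents' exceeds min(dim) = ", min(dim(mat)))
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(nComponents, ncol(pc$x))
  list(coordinates = pc$x[, seq_len(k), drop = FALSE],
       varianceFractions = vf[seq_len(k)],
       loadings = pc$rotation,
       center = pc$center,
       sdev = pc$sdev)
}

#' Leave-one-out accuracy of a linear maximum-margin classifier
#'
#' Each sample is predicted by a linear support vector machine (fixed cost,
#' no internal rescaling) trained on all other samples; the fraction of
#' correct predictions is returned.
#'
#' @param mat numeric matrix, rows = features, columns = samples; rows with
#'   missing values are dropped.
#' @param labels two-level factor (or coercible) of length ncol(mat), with at
#'   least 2 samples per class.
#' @param cost regularization constant of the margin classifier (default 1).
#' @return accuracy fraction in [0, 1].
#' @export
loocvAccuracy <- function(mat, labels, cost = 1) {
  mat <- as.matrix(mat)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("'labels' must contain two classes")
  if (length(labels) != ncol(mat))
    stop("'labels' must have one value per sample")
  if (any(table(labels) < 2)) stop("need at least 2 samples per class")
  mat <- mat[rowSums(is.na(mat)) == 0, , drop = FALSE]
  if (!nrow(mat)) stop("no complete feature rows available")
  x <- t(mat)
  correct <- vapply(seq_len(nrow(x)), function(i) {
    fit <- e1071::svm(x[-i, , drop = FALSE], labels[-i], kernel = "linear",
                      cost = cost, scale = FALSE)
    as.character(stats::predict(fit, x[i, , drop = FALSE])) ==
      as.character(labels[i])
  }, logical(1))
  mean(correct)
}
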