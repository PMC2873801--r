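# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles, sharing no code with the
# implementation they check.

# Small default simulation profile to keep unit tests fast.
tinyParams <- function(...) {
  args <- list(...)
  defaults <- list(nPairs = 5, nMirnaProbes = 60, nGenes = 300, nDeMirna = 6,
                   targetsPerMirnaRange = c(10, 20), seed = 11)
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  do.call(simulationParams, defaults)
}

# Iterative z-trimmed centering, written as an explicit index-set loop.
trimCenterOracle <- function(x, confidence = 99) {
  z <- qnorm(0.5 + confidence / 200)
  incl <- seq_along(x)
  repeat {
    m <- sum(x[incl]) / length(incl)
    s <- sqrt(sum((x[incl] - m)^2) / (length(incl) - 1))
    if (!is.finite(s) || s == 0) break
    nxt <- which(abs(x - m) <= z * s)
    if (identical(nxt, incl)) break
    incl <- nxt
  }
  x - m
}

# O(n^3) UPGMA on a distance matrix: clusters as index sets, merge height =
# unweighted mean of all between-cluster pairwise distances.
bruteUpgmaHeights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    bestH <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- mean(D[clusters[[i]], clusters[[j]]])
      if (h < bestH) { bestH <- h; best <- c(i, j) }
    }
    heights <- c(heights, bestH)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Hypergeometric upper tail P(X >= k) by exact binomial-coefficient sums.
hyperTailOracle <- function(k, N, s, q) {
  j <- seq(max(0, k), min(s, q))
  if (!length(j)) return(0)
  sum(choose(s, j) * choose(N - s, q - j)) / choose(N, q)
}

# Same tail by literal enumeration of all size-q draws from the universe.
hyperEnumOracle <- function(k, universe, set, q) {
  draws <- combn(universe, q)
  hits <- apply(draws, 2, function(d) sum(d %in% set) >= k)
  mean(hits)
}

# Exhaustive predicate-chain integration: loop over every (miRNA, gene)
# combination and test the three predicates directly.
integrationBruteForce <- function(deGenes, deMirnas, mapRecords, pOrgMax,
                                  cutoff) {
  out <- list()
  for (i in seq_len(nrow(deMirnas))) for (j in seq_len(nrow(deGenes))) {
    m <- deMirnas$mirna_id[i]
    g <- deGenes$gene_id[j]
    hit <- mapRecords[mapRecords$mirna_id == m & mapRecords$gene_id == g, ]
    for (rr in seq_len(nrow(hit))) {
      if (!(hit$p_org[rr] < pOrgMax)) next
      ma <- deMirnas$avg_log2[i]
      ga <- deGenes$avg_log2[j]
      if (!(ma * ga < 0)) next
      if (!(abs(ga) >= cutoff)) next
      out[[length(out) + 1]] <- paste(m, g)
    }
  }
  sort(unique(as.character(unlist(out))))
}

# One-sample t-test p-value from the textbook formula.
oneSampleTOracle <- function(x) {
  n <- length(x)
  tt <- mean(x) / (sd(x) / sqrt(n))
  list(t = tt, p = 2 * pt(-abs(tt), n - 1))
}

fixturePath <- function(name) {
  system.file("extdata", name, package = "mimico", mustWork = TRUE)
}
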