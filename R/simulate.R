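# Synthetic paired case-control miRNA/mRNA study generator. Every generator
# seeds the RNG from params@seed plus a fixed per-generator offset, so a
# SimulationParams object determines the full study byte-for-byte.

.seedOffset <- c(design = 0L, map = 101L, truth = 202L, spots = 303L,
                 mrna = 404L)

.mirnaIds <- function(params)
  sprintf("miR-sim-%04d", seq_len(params@nMirnaProbes))

.geneIds <- function(params)
  sprintf("GENE%05d", seq_len(params@nGenes))

#' Generate a paired case-control design
#'
#' Builds \code{nPairs} families, each contributing one case and one matched
#' control sample (the twin / sib-pair layout of discordant-pair studies).
#' Ids are deterministic functions of the pair index.
#'
#' @param params a [SimulationParams-class].
#' @return A [PairedDesign-class] with \code{nPairs} rows.
#' @examples
#' generateDesign(simulationParams(nPairs = 3, targetsPerMirnaRange = c(5, 10),
#'                                 nGenes = 50, nMirnaProbes = 20, nDeMirna = 2))
#' @export
generateDesign <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  i <- seq_len(params@nPairs)
  pairedDesign(data.frame(
    case_id = sprintf("A%03d", i),
    control_id = sprintf("C%03d", i),
    family_id = sprintf("F%03d", i),
    stringsAsFactors = FALSE))
}

#' Generate a conservation-scored miRNA target map
#'
#' Each miRNA receives a target count drawn uniformly from
#' \code{targetsPerMirnaRange}; targets are sampled without replacement from
#' the gene universe. Each record's conservation probability (P-org) falls
#' below 0.05 with probability \code{porgSigFraction} (uniform on [0, 0.05)
#' when it does, uniform on [0.05, 1) otherwise).
#'
#' @param params a [SimulationParams-class].
#' @return A [TargetMap-class].
#' @export
generateTargetMap <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  set.seed(params@seed + .seedOffset[["map"]])
  mirnas <- .mirnaIds(params)
  genes <- .geneIds(params)
  rng <- params@targetsPerMirnaRange
  counts <- sample(seq.int(rng[1], rng[2]), length(mirnas), replace = TRUE)
  recs <- do.call(rbind, lapply(seq_along(mirnas), function(i) {
    tg <- sample(genes, counts[i])
    data.frame(mirna_id = mirnas[i], gene_id = tg, stringsAsFactors = FALSE)
  }))
  n <- nrow(recs)
  sig <- stats::runif(n) < params@porgSigFraction
  recs$p_org <- ifelse(sig, stats::runif(n, 0, 0.05),
                       stats::runif(n, 0.05, 1))
  rownames(recs) <- NULL
  targetMap(recs)
}

# |effect| ~ N(mu, sd) truncated to (max(0, mu - 3 sd), mu + 3 sd), by
# resampling; sd = 0 degenerates to the constant mu.
.drawEffectMagnitudes <- function(n, mu, sd) {
  if (sd == 0) return(rep(mu, n))
  lo <- max(0, mu - 3 * sd)
  hi <- mu + 3 * sd
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * n, mu, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

#' Plant differential miRNA effects and inversely responding targets
#'
#' Picks \code{nDeMirna} miRNAs and assigns each a signed planted log2
#' effect: magnitudes from a truncated normal around \code{effectMu}, a
#' \code{downFraction} share of negative signs. For each planted miRNA, a
#' \code{respondFraction} share of its conserved targets (P-org < 0.05) is
#' marked as responding with gene effect
#' \code{-geneEffectScale * miRNA effect}; a gene responds to at most one
#' miRNA.
#'
#' @param params a [SimulationParams-class].
#' @param map the [TargetMap-class] the responding targets must come from.
#' @return A [PlantedTruth-class].
#' @export
generateTruth <- function(params, map) {
  stopifnot(is(params, "SimulationParams"), is(map, "TargetMap"))
  validObject(params)
  set.seed(params@seed + .seedOffset[["truth"]])
  mirnas <- .mirnaIds(params)
  de <- sort(sample(mirnas, params@nDeMirna))
  mag <- .drawEffectMagnitudes(params@nDeMirna, params@effectMu,
                               params@effectSd)
  nDown <- round(params@downFraction * params@nDeMirna)
  sgn <- rep(1, params@nDeMirna)
  if (nDown > 0) sgn[sample(params@nDeMirna, nDown)] <- -1
  effects <- stats::setNames(mag * sgn, de)

  recs <- targetRecords(map)
  sig <- recs[recs$p_org < 0.05, , drop = FALSE]
  used <- character(0)
  rt <- lapply(de, function(m) {
    cand <- sig$gene_id[sig$mirna_id == m]
    cand <- setdiff(cand, used)
    nTake <- round(params@respondFraction * length(cand))
    if (nTake == 0)
      return(data.frame(mirna_id = character(0), gene_id = character(0),
                        gene_effect = numeric(0)))
    take <- sample(cand, nTake)
    used <<- c(used, take)
    data.frame(mirna_id = m, gene_id = take,
               gene_effect = -params@geneEffectScale * effects[[m]],
               stringsAsFactors = FALSE)
  })
  rt <- do.call(rbind, rt)
  rownames(rt) <- NULL
  plantedTruth(effects, rt)
}

.oneSpotTable <- function(probes, trueLog2, params) {
  n <- length(probes)
  ref <- stats::rlnorm(n, meanlog = log(params@refMedian),
                       sdlog = params@refSdlog)
  noise <- if (params@noiseSd > 0) stats::rnorm(n, 0, params@noiseSd) else 0
  sig <- ref * 2^(trueLog2 + noise)
  tab <- data.frame(probe_id = probes, stringsAsFactors = FALSE)
  for (r in 1:3) {
    m1 <- if (params@triplicateCv > 0)
      pmax(stats::rnorm(n, 1, params@triplicateCv), 1e-6) else rep(1, n)
    m2 <- if (params@triplicateCv > 0)
      pmax(stats::rnorm(n, 1, params@triplicateCv), 1e-6) else rep(1, n)
    bg1 <- if (params@backgroundLevel > 0)
      stats::rexp(n, 1 / params@backgroundLevel) else rep(0, n)
    bg2 <- if (params@backgroundLevel > 0)
      stats::rexp(n, 1 / params@backgroundLevel) else rep(0, n)
    tab[[sprintf("rep%d_ch1", r)]] <- sig * m1 + bg1
    tab[[sprintf("rep%d_ch2", r)]] <- ref * m2 + bg2
    tab[[sprintf("rep%d_bg1", r)]] <- bg1
    tab[[sprintf("rep%d_bg2", r)]] <- bg2
  }
  tab
}

#' Generate per-sample two-color miRNA spot tables
#'
#' Emulates a two-color reference design: channel 1 carries the sample,
#' channel 2 a common reference. Per probe, the reference intensity is
#' log-normal; the sample intensity is \code{reference * 2^(true log2 ratio +
#' noise)}, where the true ratio equals the planted effect for DE probes in
#' case samples and 0 otherwise. Each probe is printed in triplicate with
#' relative spread \code{triplicateCv} and an additive exponential local
#' background recorded per spot.
#'
#' @param design a [PairedDesign-class].
#' @param truth a [PlantedTruth-class] (its miRNAs must be probes).
#' @param params a [SimulationParams-class].
#' @return Named list (by sample id) of spot-table data.frames with columns
#'   \code{probe_id}, then \code{repN_ch1/ch2/bg1/bg2} for N = 1..3.
#' @export
generateMirnaSpotTables <- function(design, truth, params) {
  stopifnot(is(design, "PairedDesign"), is(truth, "PlantedTruth"),
            is(params, "SimulationParams"))
  probes <- .mirnaIds(params)
  bad <- setdiff(names(deMirnaEffects(truth)), probes)
  if (length(bad))
    stop("planted miRNAs not among the simulated probes: ",
         paste(bad, collapse = ", "))
  set.seed(params@seed + .seedOffset[["spots"]])
  eff <- deMirnaEffects(truth)
  caseTrue <- stats::setNames(rep(0, length(probes)), probes)
  caseTrue[names(eff)] <- eff
  ctrlTrue <- stats::setNames(rep(0, length(probes)), probes)
  p <- designPairs(design)
  out <- list()
  for (i in seq_len(nrow(p))) {
    out[[p$case_id[i]]] <- .oneSpotTable(probes, caseTrue, params)
    out[[p$control_id[i]]] <- .oneSpotTable(probes, ctrlTrue, params)
  }
  out
}

#' Generate the gene x pair mRNA log2 case/control ratio matrix
#'
#' Responding targets get mean log2 ratio \code{-geneEffectScale * (their
#' miRNA's planted effect)}; every other gene has mean 0. Per-cell Gaussian
#' noise of SD \code{noiseSd} is added and a \code{naFraction} share of
#' cells is set missing uniformly at random.
#'
#' @param design a [PairedDesign-class].
#' @param truth a [PlantedTruth-class].
#' @param map the [TargetMap-class]; every responding target must be one of
#'   its records (consistency error otherwise).
#' @param params a [SimulationParams-class].
#' @return Numeric matrix, genes x pairs, with \code{NA} for missing cells;
#'   columns named "case/control".
#' @export
generateMrnaRatioMatrix <- function(design, truth, map, params) {
  stopifnot(is(design, "PairedDesign"), is(truth, "PlantedTruth"),
            is(map, "TargetMap"), is(params, "SimulationParams"))
  rt <- respondingTargets(truth)
  if (nrow(rt)) {
    key <- paste(rt$mirna_id, rt$gene_id)
    recs <- targetRecords(map)
    mkey <- paste(recs$mirna_id, recs$gene_id)
    missing <- setdiff(key, mkey)
    if (length(missing))
      stop("responding targets absent from the target map: ",
           paste(utils::head(missing, 5), collapse = "; "))
  }
  set.seed(params@seed + .seedOffset[["mrna"]])
  genes <- .geneIds(params)
  mu <- stats::setNames(rep(0, length(genes)), genes)
  if (nrow(rt)) mu[rt$gene_id] <- rt$gene_effect
  nP <- nPairs(design)
  m <- matrix(mu, nrow = length(genes), ncol = nP,
              dimnames = list(genes, pairIds(design)))
  if (params@noiseSd > 0)
    m <- m + matrix(stats::rnorm(length(m), 0, params@noiseSd), nrow(m))
  if (params@naFraction > 0)
    m[stats::runif(length(m)) < params@naFraction] <- NA_real_
  m
}

#' Simulate a complete paired miRNA/mRNA study
#'
#' Runs the full generator chain (design, target map, planted truth, spot
#' tables, mRNA ratio matrix) and preprocesses the spot tables into a
#' sample-level miRNA log2-ratio matrix with [preprocessMirnaArrays()].
#'
#' @param params a [SimulationParams-class].
#' @param normalizeWithin,quantileAcross passed to [preprocessMirnaArrays()].
#' @return A [SimulatedStudy-class].
#' @examples
#' study <- simulateStudy(simulationParams(nMirnaProbes = 60, nGenes = 300,
#'   nDeMirna = 6, targetsPerMirnaRange = c(10, 20), seed = 7))
#' study
#' @export
simulateStudy <- function(params, normalizeWithin = TRUE,
                          quantileAcross = TRUE) {
  design <- generateDesign(params)
  map <- generateTargetMap(params)
  truth <- generateTruth(params, map)
  spots <- generateMirnaSpotTables(design, truth, params)
  mirna <- preprocessMirnaArrays(spots, normalizeWithin = normalizeWithin,
                                 quantileAcross = quantileAcross)
  mrna <- generateMrnaRatioMatrix(design, truth, map, params)
  new("SimulatedStudy", params = params, design = design, truth = truth,
      targetMap = map, spotTables = spots, mirnaRatios = mirna,
      mrnaRatios = mrna)
}
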