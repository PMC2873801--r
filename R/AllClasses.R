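#' @import methods
NULL

.checkFraction <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
    return(sprintf("'%s' must be a single value in [0, 1]", name))
  NULL
}

.checkCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != round(x))
    return(sprintf("'%s' must be a single integer >= %d", name, min))
  NULL
}

#' Simulation parameters for a paired case-control miRNA/mRNA study
#'
#' Container for all knobs of the synthetic-data generator: study dimensions
#' (pairs, probes, genes), planted-effect model, target-map shape, array noise
#' model and missingness. All generators derive their random streams from
#' \code{seed}, so a given \code{SimulationParams} object pins down the whole
#' simulated study exactly.
#'
#' @slot nPairs number of case-control pairs.
#' @slot nMirnaProbes number of miRNA probes on the simulated array.
#' @slot nGenes number of genes on the simulated mRNA platform.
#' @slot nDeMirna number of miRNA probes that receive a planted effect.
#' @slot effectMu mean absolute planted miRNA effect (log2 units).
#' @slot effectSd spread of planted effect magnitudes (log2 units);
#'   magnitudes are drawn from a normal truncated to mu +/- 3 sd (and > 0).
#' @slot downFraction fraction of planted effects given a negative sign.
#' @slot noiseSd per-sample log2 noise standard deviation.
#' @slot targetsPerMirnaRange integer vector \code{c(low, high)}: each miRNA's
#'   target count is drawn uniformly from this range.
#' @slot porgSigFraction expected fraction of target records with a
#'   conservation probability (P-org) below 0.05.
#' @slot respondFraction fraction of a planted miRNA's conserved
#'   (P-org < 0.05) targets that respond inversely at the mRNA level.
#' @slot geneEffectScale multiplier mapping a miRNA effect to its responding
#'   target's (negated) mRNA effect.
#' @slot triplicateCv relative spread across the three replicate spots.
#' @slot backgroundLevel mean additive local background intensity (0 disables
#'   background).
#' @slot naFraction fraction of gene x pair cells set to missing.
#' @slot refMedian median of the log-normal reference-channel intensity.
#' @slot refSdlog log-scale spread of the reference-channel intensity.
#' @slot seed integer seed pinning all random draws.
#'
#' @seealso [simulationParams()] for the user-facing constructor,
#'   [simulateStudy()] to run the whole generator.
#' @export
setClass("SimulationParams",
  representation(
    nPairs = "numeric", nMirnaProbes = "numeric", nGenes = "numeric",
    nDeMirna = "numeric", effectMu = "numeric", effectSd = "numeric",
    downFraction = "numeric", noiseSd = "numeric",
    targetsPerMirnaRange = "numeric", porgSigFraction = "numeric",
    respondFraction = "numeric", geneEffectScale = "numeric",
    triplicateCv = "numeric", backgroundLevel = "numeric",
    naFraction = "numeric", refMedian = "numeric", refSdlog = "numeric",
    seed = "numeric"
  )
)

setValidity("SimulationParams", function(object) {
  msgs <- c(
    .checkCount(object@nPairs, "nPairs"),
    .checkCount(object@nMirnaProbes, "nMirnaProbes"),
    .checkCount(object@nGenes, "nGenes"),
    .checkCount(object@nDeMirna, "nDeMirna"),
    .checkFraction(object@porgSigFraction, "porgSigFraction"),
    .checkFraction(object@respondFraction, "respondFraction"),
    .checkFraction(object@naFraction, "naFraction"),
    .checkFraction(object@downFraction, "downFraction"),
    .checkCount(object@seed, "seed", min = 0L)
  )
  if (object@effectMu <= 0) msgs <- c(msgs, "'effectMu' must be > 0")
  if (object@effectSd < 0) msgs <- c(msgs, "'effectSd' must be >= 0")
  if (object@noiseSd < 0) msgs <- c(msgs, "'noiseSd' must be >= 0")
  if (object@triplicateCv < 0) msgs <- c(msgs, "'triplicateCv' must be >= 0")
  if (object@backgroundLevel < 0)
    msgs <- c(msgs, "'backgroundLevel' must be >= 0")
  if (object@geneEffectScale <= 0)
    msgs <- c(msgs, "'geneEffectScale' must be > 0")
  if (object@refMedian <= 0) msgs <- c(msgs, "'refMedian' must be > 0")
  if (object@refSdlog < 0) msgs <- c(msgs, "'refSdlog' must be >= 0")
  rng <- object@targetsPerMirnaRange
  if (length(rng) != 2L || any(rng < 1) || any(rng != round(rng)) ||
      rng[1] > rng[2])
    msgs <- c(msgs, paste0("'targetsPerMirnaRange' must be two integers ",
                           "c(low, high) with 1 <= low <= high"))
  else if (rng[2] > object@nGenes)
    msgs <- c(msgs, paste0("'targetsPerMirnaRange' high (", rng[2],
                           ") exceeds 'nGenes' (", object@nGenes, ")"))
  if (object@nDeMirna > object@nMirnaProbes)
    msgs <- c(msgs, "'nDeMirna' must not exceed 'nMirnaProbes'")
  if (length(msgs)) msgs else TRUE
})

#' Construct simulation parameters
#'
#' Defaults give the desk-scale study profile: 5 case-control pairs, 1,237
#' miRNA probes, 4,000 genes, 43 planted differentially expressed miRNAs with
#' effect magnitudes around 1.2 log2 units (half up, half down), per-sample
#' log2 noise 0.3, and 60-120 targets per miRNA. [paperScaleParams()] returns
#' the same profile with the full-size 600-1,200 targets-per-miRNA range.
#'
#' @param nPairs,nMirnaProbes,nGenes,nDeMirna study dimensions.
#' @param effectMu,effectSd,downFraction planted miRNA effect model.
#' @param noiseSd per-sample log2 noise SD.
#' @param targetsPerMirnaRange integer \code{c(low, high)} targets per miRNA.
#' @param porgSigFraction expected fraction of target records with
#'   P-org < 0.05.
#' @param respondFraction fraction of conserved targets of a planted miRNA
#'   that respond inversely.
#' @param geneEffectScale miRNA-to-gene effect multiplier (gene effect is
#'   \code{-geneEffectScale * miRNA effect}).
#' @param triplicateCv relative spread across triplicate spots.
#' @param backgroundLevel mean additive spot background intensity.
#' @param naFraction fraction of missing gene x pair cells.
#' @param refMedian,refSdlog reference-channel log-normal intensity model.
#' @param seed integer seed.
#' @return A validated [SimulationParams-class] object.
#' @examples
#' p <- simulationParams(nPairs = 3, nMirnaProbes = 50, nGenes = 200,
#'                       nDeMirna = 5, targetsPerMirnaRange = c(10, 20))
#' p
#' @export
simulationParams <- function(nPairs = 5, nMirnaProbes = 1237, nGenes = 4000,
                             nDeMirna = 43, effectMu = 1.2, effectSd = 0.15,
                             downFraction = 0.5, noiseSd = 0.3,
                             targetsPerMirnaRange = c(60, 120),
                             porgSigFraction = 0.5, respondFraction = 0.2,
                             geneEffectScale = 0.25, triplicateCv = 0.1,
                             backgroundLevel = 100, naFraction = 0.1,
                             refMedian = 1000, refSdlog = 1, seed = 1) {
  new("SimulationParams",
      nPairs = nPairs, nMirnaProbes = nMirnaProbes, nGenes = nGenes,
      nDeMirna = nDeMirna, effectMu = effectMu, effectSd = effectSd,
      downFraction = downFraction, noiseSd = noiseSd,
      targetsPerMirnaRange = as.numeric(targetsPerMirnaRange),
      porgSigFraction = porgSigFraction, respondFraction = respondFraction,
      geneEffectScale = geneEffectScale, triplicateCv = triplicateCv,
      backgroundLevel = backgroundLevel, naFraction = naFraction,
      refMedian = refMedian, refSdlog = refSdlog, seed = seed)
}

#' Full-size target-map profile
#'
#' Same defaults as [simulationParams()] but with 600-1,200 targets per miRNA,
#' the scale typical of conservation-filtered miRNA target predictions.
#'
#' @param ... overrides passed to [simulationParams()].
#' @return A [SimulationParams-class] object.
#' @export
paperScaleParams <- function(...) {
  args <- list(...)
  if (is.null(args$targetsPerMirnaRange))
    args$targetsPerMirnaRange <- c(600, 1200)
  do.call(simulationParams, args)
}

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams:", object@nPairs, "pairs,",
      object@nMirnaProbes, "miRNA probes,", object@nGenes, "genes,",
      object@nDeMirna, "planted DE miRNAs\n")
  cat("  effect |log2| ~ N(", object@effectMu, ",", object@effectSd,
      ") truncated, downFraction", object@downFraction,
      ", noise SD", object@noiseSd, "\n")
  cat("  targets/miRNA in [", object@targetsPerMirnaRange[1], ",",
      object@targetsPerMirnaRange[2], "], P-org sig fraction",
      object@porgSigFraction, ", respond fraction", object@respondFraction,
      "\n")
  cat("  seed", object@seed, "\n")
})

#' Paired case-control design
#'
#' Ordered set of case-control pairs; each row names one case sample, its
#' matched control sample and the family both belong to. Sample ids are
#' unique across the whole design.
#'
#' @slot pairs data.frame with columns \code{case_id}, \code{control_id},
#'   \code{family_id}.
#' @seealso [generateDesign()], [pairedDesign()]
#' @export
setClass("PairedDesign", representation(pairs = "data.frame"))

setValidity("PairedDesign", function(object) {
  p <- object@pairs
  need <- c("case_id", "control_id", "family_id")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns", paste(need, collapse = ", ")))
  ids <- c(p$case_id, p$control_id)
  if (anyDuplicated(ids))
    return("sample ids must be unique across the design")
  TRUE
})

#' @param pairs data.frame with columns \code{case_id}, \code{control_id},
#'   \code{family_id}.
#' @return A [PairedDesign-class] object.
#' @rdname PairedDesign-class
#' @export
pairedDesign <- function(pairs) new("PairedDesign", pairs = pairs)

#' Accessors for PairedDesign
#'
#' @param x a [PairedDesign-class].
#' @return \code{designPairs} returns the pairs data.frame; \code{sampleIds}
#'   the case then control sample ids; \code{pairIds} one "case/control" label
#'   per pair; \code{nPairs} the number of pairs.
#' @export
setGeneric("designPairs", function(x) standardGeneric("designPairs"))
#' @rdname designPairs
#' @export
setMethod("designPairs", "PairedDesign", function(x) x@pairs)

#' @rdname designPairs
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname designPairs
#' @export
setMethod("sampleIds", "PairedDesign",
          function(x) c(x@pairs$case_id, x@pairs$control_id))

#' @rdname designPairs
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))
#' @rdname designPairs
#' @export
setMethod("pairIds", "PairedDesign",
          function(x) paste(x@pairs$case_id, x@pairs$control_id, sep = "/"))

#' @rdname designPairs
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
#' @rdname designPairs
#' @export
setMethod("nPairs", "PairedDesign", function(x) nrow(x@pairs))

setMethod("show", "PairedDesign", function(object) {
  cat("PairedDesign with", nrow(object@pairs), "case-control pairs\n")
  print(utils::head(object@pairs, 5))
  if (nrow(object@pairs) > 5) cat("  ...\n")
})

#' miRNA target map with conservation probabilities
#'
#' One record per putative (miRNA, gene) target relation, scored by a
#' conservation probability (P-org): the estimated probability that the
#' target site is NOT conserved across an orthologous 3'UTR group, so low
#' values mark higher-confidence targets.
#'
#' @slot records data.frame with columns \code{mirna_id}, \code{gene_id},
#'   \code{p_org}; (miRNA, gene) pairs unique, p_org in [0, 1].
#' @seealso [generateTargetMap()], [filterTargetsByConservation()]
#' @export
setClass("TargetMap", representation(records = "data.frame"))

setValidity("TargetMap", function(object) {
  r <- object@records
  need <- c("mirna_id", "gene_id", "p_org")
  if (!all(need %in% names(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (nrow(r) && anyDuplicated(r[, c("mirna_id", "gene_id")]))
    return("(mirna_id, gene_id) records must be unique")
  if (nrow(r) && (any(r$p_org < 0) || any(r$p_org > 1)))
    return("p_org must lie in [0, 1]")
  TRUE
})

#' @param records data.frame with columns \code{mirna_id}, \code{gene_id},
#'   \code{p_org}.
#' @return A [TargetMap-class] object.
#' @rdname TargetMap-class
#' @export
targetMap <- function(records) new("TargetMap", records = records)

#' @param x a [TargetMap-class].
#' @return the records data.frame.
#' @rdname TargetMap-class
#' @export
setGeneric("targetRecords", function(x) standardGeneric("targetRecords"))
#' @rdname TargetMap-class
#' @export
setMethod("targetRecords", "TargetMap", function(x) x@records)

setMethod("show", "TargetMap", function(object) {
  r <- object@records
  cat("TargetMap:", nrow(r), "records,",
      length(unique(r$mirna_id)), "miRNAs,",
      length(unique(r$gene_id)), "genes;",
      sum(r$p_org < 0.05), "with P-org < 0.05\n")
})

#' Ground truth of planted simulation effects
#'
#' Ledger of which miRNAs carry a planted log2 effect and which (miRNA, gene)
#' target relations respond inversely at the mRNA level, used to score
#' recovery of the planted signal by the analysis pipeline.
#'
#' @slot deMirnas named numeric: miRNA id -> signed planted log2 effect.
#' @slot respondingTargets data.frame with columns \code{mirna_id},
#'   \code{gene_id}, \code{gene_effect} (= -geneEffectScale * miRNA effect).
#' @seealso [generateTruth()]
#' @export
setClass("PlantedTruth",
         representation(deMirnas = "numeric", respondingTargets = "data.frame"))

setValidity("PlantedTruth", function(object) {
  if (is.null(names(object@deMirnas)) ||
      anyDuplicated(names(object@deMirnas)))
    return("deMirnas must be a uniquely named numeric vector")
  rt <- object@respondingTargets
  need <- c("mirna_id", "gene_id", "gene_effect")
  if (!all(need %in% names(rt)))
    return(paste("respondingTargets must have columns",
                 paste(need, collapse = ", ")))
  if (nrow(rt) && !all(rt$mirna_id %in% names(object@deMirnas)))
    return("every responding target's miRNA must be a planted DE miRNA")
  if (nrow(rt)) {
    eff <- object@deMirnas[rt$mirna_id]
    if (any(sign(rt$gene_effect) != -sign(eff)))
      return("responding gene effects must oppose their miRNA's effect sign")
  }
  TRUE
})

#' @param deMirnas named numeric vector of planted miRNA log2 effects.
#' @param respondingTargets data.frame(mirna_id, gene_id, gene_effect).
#' @return A [PlantedTruth-class] object.
#' @rdname PlantedTruth-class
#' @export
plantedTruth <- function(deMirnas, respondingTargets) {
  new("PlantedTruth", deMirnas = deMirnas,
      respondingTargets = respondingTargets)
}

#' @param x a [PlantedTruth-class].
#' @return \code{deMirnaEffects}: the named effect vector;
#'   \code{respondingTargets}: the responding-target data.frame.
#' @rdname PlantedTruth-class
#' @export
setGeneric("deMirnaEffects", function(x) standardGeneric("deMirnaEffects"))
#' @rdname PlantedTruth-class
#' @export
setMethod("deMirnaEffects", "PlantedTruth", function(x) x@deMirnas)

#' @rdname PlantedTruth-class
#' @export
setGeneric("respondingTargets",
           function(x) standardGeneric("respondingTargets"))
#' @rdname PlantedTruth-class
#' @export
setMethod("respondingTargets", "PlantedTruth",
          function(x) x@respondingTargets)

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth:", length(object@deMirnas), "planted DE miRNAs (",
      sum(object@deMirnas < 0), "down /", sum(object@deMirnas > 0), "up ),",
      nrow(object@respondingTargets), "responding targets\n")
})

#' A complete simulated paired miRNA/mRNA study
#'
#' Bundle returned by [simulateStudy()]: the parameters, design and planted
#' truth, the target map, the per-sample spot tables, the preprocessed
#' sample-level miRNA log2-ratio matrix and the gene x pair mRNA log2-ratio
#' matrix.
#'
#' @slot params the [SimulationParams-class] used.
#' @slot design the [PairedDesign-class].
#' @slot truth the [PlantedTruth-class].
#' @slot targetMap the [TargetMap-class].
#' @slot spotTables named list of per-sample spot-level data.frames.
#' @slot mirnaRatios miRNA probes x samples log2(sample/reference) matrix
#'   after preprocessing.
#' @slot mrnaRatios genes x pairs log2(case/control) matrix (may contain NA).
#' @export
setClass("SimulatedStudy",
  representation(params = "SimulationParams", design = "PairedDesign",
                 truth = "PlantedTruth", targetMap = "TargetMap",
                 spotTables = "list", mirnaRatios = "matrix",
                 mrnaRatios = "matrix"))

setMethod("show", "SimulatedStudy", function(object) {
  cat("SimulatedStudy\n")
  show(object@params)
  cat("  miRNA ratio matrix:", nrow(object@mirnaRatios), "probes x",
      ncol(object@mirnaRatios), "samples\n")
  cat("  mRNA ratio matrix:", nrow(object@mrnaRatios), "genes x",
      ncol(object@mrnaRatios), "pairs (",
      sum(is.na(object@mrnaRatios)), "missing cells )\n")
})

#' Accessors for SimulatedStudy
#'
#' @param x a [SimulatedStudy-class].
#' @return the corresponding component.
#' @export
setGeneric("studyTruth", function(x) standardGeneric("studyTruth"))
#' @rdname studyTruth
#' @export
setMethod("studyTruth", "SimulatedStudy", function(x) x@truth)
#' @rdname studyTruth
#' @export
setGeneric("studyDesign", function(x) standardGeneric("studyDesign"))
#' @rdname studyTruth
#' @export
setMethod("studyDesign", "SimulatedStudy", function(x) x@design)
#' @rdname studyTruth
#' @export
setGeneric("studyTargetMap", function(x) standardGeneric("studyTargetMap"))
#' @rdname studyTruth
#' @export
setMethod("studyTargetMap", "SimulatedStudy", function(x) x@targetMap)
#' @rdname studyTruth
#' @export
setGeneric("mirnaRatios", function(x) standardGeneric("mirnaRatios"))
#' @rdname studyTruth
#' @export
setMethod("mirnaRatios", "SimulatedStudy", function(x) x@mirnaRatios)
#' @rdname studyTruth
#' @export
setGeneric("mrnaRatios", function(x) standardGeneric("mrnaRatios"))
#' @rdname studyTruth
#' @export
setMethod("mrnaRatios", "SimulatedStudy", function(x) x@mrnaRatios)
#' @rdname studyTruth
#' @export
setGeneric("spotTables", function(x) standardGeneric("spotTables"))
#' @rdname studyTruth
#' @export
setMethod("spotTables", "SimulatedStudy", function(x) x@spotTables)
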