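# Plain-text readers and writers: tab-delimited spot tables, ratio matrices,
# target maps, designs, truth ledgers, and GMT gene-set collections.

.writeTsv <- function(df, file, rowNames = FALSE) {
  utils::write.table(df, file = file, sep = "\t", quote = FALSE,
                     row.names = rowNames, col.names = TRUE, na = "NA")
  invisible(file)
}

#' Read / write a spot table
#'
#' Tab-delimited, one row per probe: \code{probe_id} then
#' \code{repN_ch1/ch2/bg1/bg2} for N = 1..3.
#'
#' @param file path.
#' @param spots spot-table data.frame.
#' @return \code{readSpotTable}: the data.frame; writers return the path,
#'   invisibly.
#' @export
readSpotTable <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname readSpotTable
#' @export
writeSpotTable <- function(spots, file) .writeTsv(spots, file)

#' Read / write a log2-ratio matrix
#'
#' Tab-delimited with a header of column ids and row ids in the first column;
#' missing values written as "NA".
#'
#' @param file path.
#' @param mat numeric matrix with dimnames.
#' @return \code{readRatioMatrix}: a numeric matrix.
#' @export
readRatioMatrix <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname readRatioMatrix
#' @export
writeRatioMatrix <- function(mat, file) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTsv(df, file)
}

#' Read / write a target map
#'
#' Tab-delimited with columns \code{mirna_id}, \code{gene_id}, \code{p_org}.
#'
#' @param file path.
#' @param map a [TargetMap-class].
#' @return \code{readTargetMap}: a [TargetMap-class].
#' @export
readTargetMap <- function(file) {
  targetMap(utils::read.delim(file, stringsAsFactors = FALSE))
}

#' @rdname readTargetMap
#' @export
writeTargetMap <- function(map, file) .writeTsv(targetRecords(map), file)

#' Read / write a paired design
#'
#' Tab-delimited with columns \code{case_id}, \code{control_id},
#' \code{family_id}.
#'
#' @param file path.
#' @param design a [PairedDesign-class].
#' @return \code{readDesign}: a [PairedDesign-class].
#' @export
readDesign <- function(file) {
  pairedDesign(utils::read.delim(file, stringsAsFactors = FALSE))
}

#' @rdname readDesign
#' @export
writeDesign <- function(design, file) .writeTsv(designPairs(design), file)

#' Write the planted-truth ledger
#'
#' Two tab-delimited tables: planted miRNA effects and responding targets.
#'
#' @param truth a [PlantedTruth-class].
#' @param mirnaFile,targetFile output paths.
#' @return the paths, invisibly.
#' @export
writeTruth <- function(truth, mirnaFile, targetFile) {
  eff <- deMirnaEffects(truth)
  .writeTsv(data.frame(mirna_id = names(eff), effect = unname(eff),
                       stringsAsFactors = FALSE), mirnaFile)
  .writeTsv(respondingTargets(truth), targetFile)
  invisible(c(mirnaFile, targetFile))
}

#' Read / write a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated set name, description, then
#' member gene ids. Reading is delegated to [fgsea::gmtPathways()].
#'
#' @param file path.
#' @param collection named list of character vectors.
#' @param descriptions optional character vector of set descriptions (second
#'   GMT column); defaults to the set names.
#' @return \code{readGmt}: a named list of character vectors.
#' @export
readGmt <- function(file) {
  fgsea::gmtPathways(file)
}

#' @rdname readGmt
#' @export
writeGmt <- function(collection, file, descriptions = NULL) {
  if (is.null(names(collection)))
    stop("'collection' must be a named list")
  if (is.null(descriptions)) descriptions <- names(collection)
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], descriptions[i], collection[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Write a whole simulated study to a directory
#'
#' Emits per-sample spot tables, the mRNA ratio matrix, the target map, the
#' design and the planted-truth ledger as plain TSV files.
#'
#' @param study a [SimulatedStudy-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "SimulatedStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(spotTables(study)))
    writeSpotTable(spotTables(study)[[s]],
                   file.path(dir, paste0("spots_", s, ".tsv")))
  writeRatioMatrix(mrnaRatios(study), file.path(dir, "mrna_ratios.tsv"))
  writeRatioMatrix(mirnaRatios(study), file.path(dir, "mirna_ratios.tsv"))
  writeTargetMap(studyTargetMap(study), file.path(dir, "target_map.tsv"))
  writeDesign(studyDesign(study), file.path(dir, "design.tsv"))
  writeTruth(studyTruth(study), file.path(dir, "truth_mirnas.tsv"),
             file.path(dir, "truth_targets.tsv"))
  invisible(dir)
}
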