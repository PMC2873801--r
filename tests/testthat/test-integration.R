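toyMap <- function() {
  targetMap(data.frame(
    mirna_id = c("m1", "m1", "m2", "m2", "m3"),
    gene_id = c("g1", "g2", "g2", "g3", "g4"),
    p_org = c(0.049, 0.05, 0.01, 0.2, 0.001),
    stringsAsFactors = FALSE))
}

test_that("conservation filtering is strictly below the threshold", {
  f <- filterTargetsByConservation(toyMap(), 0.05)
  recs <- targetRecords(f)
  expect_true(all(recs$p_org < 0.05))
  expect_true("g1" %in% recs$gene_id) # 0.049 kept
  expect_false(any(recs$mirna_id == "m1" & recs$gene_id == "g2")) # 0.05 out
  empty <- filterTargetsByConservation(targetMap(
    data.frame(mirna_id = character(0), gene_id = character(0),
               p_org = numeric(0))))
  expect_equal(nrow(targetRecords(empty)), 0)
})

test_that("overlap records annotate averages and the inverse flag", {
  deGenes <- data.frame(gene_id = c("g1", "g2", "g4"),
                        avg_log2 = c(-0.298, 0.5, 0.1))
  deMirnas <- data.frame(mirna_id = c("m1", "m2"),
                         avg_log2 = c(1.186, 1.0))
  fmap <- filterTargetsByConservation(toyMap())
  recs <- overlapTargets(deGenes, deMirnas, fmap)
  # m3 not DE, g3 not DE -> no records for them
  expect_false("m3" %in% recs$mirna_id)
  # miRNA +1.186 vs gene -0.298: inverse
  r1 <- recs[recs$mirna_id == "m1" & recs$gene_id == "g1", ]
  expect_true(r1$inverse)
  # both positive: not inverse
  r2 <- recs[recs$mirna_id == "m2" & recs$gene_id == "g2", ]
  expect_false(r2$inverse)
  expect_equal(attr(recs, "nDistinctGenes"), 2)

  # zero gene average is never inverse and is dropped by the filter
  recs$gene_avg_log2[1] <- 0
  recs$inverse <- recs$mirna_avg_log2 * recs$gene_avg_log2 < 0
  expect_equal(nrow(inverseFilter(recs)), 0)

  # missing average -> skipped with warning
  deGenesNA <- data.frame(gene_id = "g1", avg_log2 = NA_real_)
  expect_warning(r <- overlapTargets(deGenesNA, deMirnas, fmap), "skipped")
  expect_equal(nrow(r), 0)
})

test_that("inverse and magnitude filters apply the published boundaries", {
  recs <- data.frame(
    mirna_id = c("miR-219", "miR-29b", "x", "y"),
    gene_id = c("PLK2", "ID3", "zero", "same"),
    mirna_avg_log2 = c(-1.173, 1.186, 1.0, 1.0),
    gene_avg_log2 = c(0.333, -0.298, 0, 0.5))
  recs$inverse <- recs$mirna_avg_log2 * recs$gene_avg_log2 < 0
  inv <- inverseFilter(recs)
  expect_setequal(inv$gene_id, c("PLK2", "ID3"))

  cut <- data.frame(mirna_id = "m", gene_id = c("a", "b", "c"),
                    mirna_avg_log2 = 1,
                    gene_avg_log2 = c(-0.406, 0.4, 0.314),
                    inverse = TRUE)
  kept <- magnitudeCutoff(cut, 0.4)
  expect_setequal(kept$gene_id, c("a", "b")) # -0.406 and 0.4 kept, 0.314 out
  expect_error(magnitudeCutoff(cut, -1), "cutoff")

  # monotonicity: raising the cutoff never keeps more records
  set.seed(41)
  rr <- data.frame(mirna_id = "m", gene_id = as.character(1:100),
                   mirna_avg_log2 = 1, gene_avg_log2 = rnorm(100),
                   inverse = TRUE)
  ns <- vapply(seq(0, 2, 0.1), function(ct) nrow(magnitudeCutoff(rr, ct)),
               numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("overlap summary reproduces published-style percentages", {
  s <- overlapSummary(3905, nTargetGenes = 1406, nInverseGenes = 1053)
  expect_equal(s$pct_target_display, 36)
  expect_equal(s$pct_inverse_display, 27)
  expect_equal(s$pct_target, 100 * 1406 / 3905, tolerance = 1e-12)

  zero <- overlapSummary(10, data.frame(gene_id = character(0),
                                        inverse = logical(0)))
  expect_equal(zero$pct_target_display, 0)
  expect_equal(zero$pct_inverse_display, 0)
  expect_error(overlapSummary(0, nTargetGenes = 1, nInverseGenes = 1),
               "nDeGenes")
})

test_that("concordance rows average only the observed entries", {
  mir219 <- c(-1.447, -1.089, -2.330, -2.390, -0.175, 0.398, -1.176)
  plk2 <- c(0.414, 0.147, NA, NA, NA, 0.314, 0.456)
  prs <- paste0("p", 1:7)
  names(mir219) <- names(plk2) <- prs
  cr <- concordanceRow(mir219, plk2, "miR-219", "PLK2")
  expect_equal(cr$mirna_avg_display, -1.173)
  expect_equal(cr$gene_avg_display, 0.333)
  expect_equal(cr$n_gene, 4)

  allNA <- setNames(rep(NA_real_, 7), prs)
  cr2 <- concordanceRow(mir219, allNA)
  expect_true(is.na(cr2$gene_avg))

  expect_error(concordanceRow(mir219, setNames(1, "other")), "overlapping")
})

test_that("the integration chain equals exhaustive brute-force enumeration", {
  set.seed(47)
  for (rep in 1:5) {
    nm <- sample(5:20, 1)
    ng <- sample(30:200, 1)
    mirnas <- sprintf("m%02d", 1:nm)
    genes <- sprintf("g%03d", 1:ng)
    recs <- expand.grid(mirna_id = mirnas, gene_id = genes,
                        stringsAsFactors = FALSE)
    recs <- recs[runif(nrow(recs)) < 0.3, ]
    recs$p_org <- runif(nrow(recs))
    map <- targetMap(recs)
    deMirnas <- data.frame(mirna_id = sample(mirnas, nm %/% 2),
                           avg_log2 = rnorm(nm %/% 2))
    deGenes <- data.frame(gene_id = sample(genes, ng %/% 2),
                          avg_log2 = rnorm(ng %/% 2))
    res <- integratePairs(deGenes, deMirnas, map, pOrgMax = 0.05,
                          cutoff = 0.4)
    got <- sort(paste(res$final$mirna_id, res$final$gene_id))
    want <- integrationBruteForce(deGenes, deMirnas, recs, 0.05, 0.4)
    expect_identical(got, want)
    # set inclusions: inverse genes within target genes within DE genes
    expect_true(all(res$inverse$gene_id %in% res$records$gene_id))
    expect_true(all(res$records$gene_id %in% deGenes$gene_id))
    expect_lte(length(unique(res$records$gene_id)), nrow(res$records))
  }
})

test_that("lowering the conservation threshold never adds records", {
  set.seed(53)
  recs <- data.frame(mirna_id = "m1", gene_id = sprintf("g%03d", 1:200),
                     p_org = runif(200))
  map <- targetMap(recs)
  deM <- data.frame(mirna_id = "m1", avg_log2 = 1)
  deG <- data.frame(gene_id = recs$gene_id, avg_log2 = rnorm(200))
  ns <- vapply(c(0.5, 0.2, 0.1, 0.05, 0.01), function(pm)
    nrow(integratePairs(deG, deM, map, pOrgMax = pm)$records), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("with full response and no noise every planted target survives", {
  p <- tinyParams(respondFraction = 1, noiseSd = 0, naFraction = 0,
                  porgSigFraction = 0.7, seed = 13)
  s <- simulateStudy(p, normalizeWithin = FALSE, quantileAcross = FALSE)
  truth <- studyTruth(s)
  eff <- deMirnaEffects(truth)
  d <- designPairs(studyDesign(s))
  mirnaAvg <- rowMeans(mirnaRatios(s)[, d$case_id]) -
    rowMeans(mirnaRatios(s)[, d$control_id])
  deMirnas <- data.frame(mirna_id = names(eff),
                         avg_log2 = unname(mirnaAvg[names(eff)]))
  geneAvg <- rowMeans(mrnaRatios(s))
  deGenes <- data.frame(gene_id = rownames(mrnaRatios(s)),
                        avg_log2 = unname(geneAvg))
  fmap <- filterTargetsByConservation(studyTargetMap(s))
  recs <- inverseFilter(overlapTargets(deGenes, deMirnas, fmap))
  rt <- respondingTargets(truth)
  expect_true(all(paste(rt$mirna_id, rt$gene_id) %in%
                    paste(recs$mirna_id, recs$gene_id)))
})

test_that("the concordance table formats published-style rows", {
  path <- fixturePath("autism_lcl_concordance.tsv")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pairs <- unique(tab$pair_id)
  mir <- t(vapply(split(tab, tab$mirna_id),
                  function(g) setNames(g$mirna_log2, g$pair_id)[pairs],
                  numeric(length(pairs))))
  gene <- t(vapply(split(tab, tab$gene_id),
                   function(g) setNames(g$gene_log2, g$pair_id)[pairs],
                   numeric(length(pairs))))
  tab4 <- concordanceTable(mir, gene,
                           data.frame(mirna_id = c("miR-219", "miR-29b"),
                                      gene_id = c("PLK2", "ID3")))
  expect_equal(tab4$average,
               c("-1.173(0.333)", "1.186(-0.298)"))
  expect_equal(tab4[tab4$mirna_id == "miR-219", "A361/C360"],
               "-1.447(0.414)")
  expect_equal(tab4[tab4$mirna_id == "miR-219", "A809/C813"],
               "-2.330(NA)")
})
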