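test_that("simulationConfig validates its fields", {
  expect_error(simulationConfig(pCoding = 1.2), "pCoding")
  expect_error(simulationConfig(sourcePresence = c(0.5, 2, 0.5)),
               "presence")
  expect_error(simulationConfig(lengthRange = c(50, 400)), "lengthRange")
  expect_error(simulationConfig(mutationRate = 1.5), "mutationRate")
  expect_error(simulationConfig(
    spongePlan = list(list(lncrna = 1, mirnas = 1, nSites = -1))),
    "nSites")
})

test_that("degenerate configurations produce the forced outputs", {
  ## no clusters at all
  st0 <- simulateTranscriptomes(simulationConfig(seed = 1, nClusters = 0,
                                                 spongePlan = list()))
  expect_equal(length(transcripts(st0)), 0L)
  expect_equal(nrow(groundTruth(st0)$plantedSites), 0L)
  ## zero mutation + certain presence: the three copies are identical
  cfg <- simulationConfig(seed = 2, nClusters = 1, mutationRate = 0,
                          sourcePresence = 1, spongePlan = list())
  st1 <- simulateTranscriptomes(cfg)
  seqs <- as.character(transcripts(st1))
  expect_equal(length(seqs), 3L)
  expect_equal(length(unique(seqs)), 1L)
})

test_that("same configuration and seed reproduce identical artifacts", {
  cfg <- simulationConfig(seed = 5, nClusters = 12)
  a <- simulateSpongeStudy(cfg)
  b <- simulateSpongeStudy(cfg)
  expect_identical(as.character(transcripts(a)),
                   as.character(transcripts(b)))
  expect_identical(as.character(mirnaSet(a)), as.character(mirnaSet(b)))
  expect_identical(SummarizedExperiment::assay(countData(a)),
                   SummarizedExperiment::assay(countData(b)))
  expect_identical(groundTruth(a), groundTruth(b))
  ## a different seed changes the sequences
  c2 <- simulateTranscriptomes(simulationConfig(seed = 6, nClusters = 12))
  expect_false(identical(as.character(transcripts(a)),
                         as.character(transcripts(c2))))
})

test_that("the coding fraction concentrates around pCoding across seeds", {
  fracs <- vapply(1:20, function(sd) {
    st <- simulateTranscriptomes(simulationConfig(
      seed = sd, nClusters = 50, pCoding = 0.4, spongePlan = list(),
      lengthRange = c(200, 500), sourcePresence = c(1, 0, 0),
      mutationRate = 0))
    mc <- S4Vectors::mcols(transcripts(st))
    mean(tapply(mc$class == "coding", mc$cluster, any))
  }, numeric(1))
  ## binomial 95% CI for the mean of 20 x Bin(50, 0.4)/50
  se <- sqrt(0.4 * 0.6 / (50 * 20))
  expect_lte(abs(mean(fracs) - 0.4), 1.96 * se * 1.5)
})

test_that("planted ORFs and the noncoding guarantee hold in every copy", {
  cfg <- simulationConfig(seed = 11, nClusters = 15, spongePlan = list())
  st <- simulateTranscriptomes(cfg)
  tx <- transcripts(st)
  mc <- S4Vectors::mcols(tx)
  for (k in seq_along(tx)) {
    orfs <- findOrfs(as.character(tx[[k]]))
    if (mc$class[k] == "coding") {
      expect_gt(nrow(orfs), 0)
    }
  }
  ## coding translations are in the reference set and gate as hits
  prots <- referenceProteins(st)
  expect_gt(length(prots), 0)
})

test_that("simulateCounts plants the configured fold-change structure", {
  ## Poisson limit: dispersion 0 gives variance ~ mean
  cfg0 <- simulationConfig(seed = 3, nClusters = 30, dispersion = 0,
                           sourcePresence = c(1, 0, 0), mutationRate = 0,
                           deFraction = 0, nSamplesPerGroup = 10,
                           spongePlan = list())
  st <- simulateSpongeStudy(cfg0)
  se <- countData(st)
  cnt <- SummarizedExperiment::assay(se)
  tab <- as.data.frame(SummarizedExperiment::colData(se))
  ## de_fraction 0: nothing flagged
  expect_equal(sum(groundTruth(st)$deTable$isDE), 0L)
  grpCols <- tab$tissue == "midgut" & tab$condition == "unfed"
  ## per-sample library factors differ, so normalize them out first
  lf <- exp(colMeans(log(cnt[, grpCols, drop = FALSE] + 0.5)))
  y <- sweep(cnt[, grpCols, drop = FALSE], 2, lf / mean(lf), "/")
  ratio <- apply(y, 1, var) / rowMeans(y)
  expect_lt(abs(median(ratio) - 1), 0.3)

  ## planted log2FC = 2 recovered from group means (n = 10 per group)
  cfg2 <- simulationConfig(seed = 4, nClusters = 40, deFraction = 1,
                           deLog2fc = 2, nSamplesPerGroup = 10,
                           sourcePresence = c(1, 0, 0), mutationRate = 0,
                           dispersion = 0.05, spongePlan = list())
  st2 <- simulateSpongeStudy(cfg2)
  se2 <- countData(st2)
  cnt2 <- SummarizedExperiment::assay(se2)
  tab2 <- as.data.frame(SummarizedExperiment::colData(se2))
  truth <- groundTruth(st2)$deTable
  mid <- tab2$tissue == "midgut"
  ## divide out the known per-sample library factors before comparing
  y <- sweep(cnt2[, mid], 2, tab2$libFactor[mid], "/")
  fed <- tab2$condition[mid] == "fed"
  lfc <- log2(rowMeans(y[, fed]) + 0.5) - log2(rowMeans(y[, !fed]) + 0.5)
  expect_lt(abs(mean(lfc * sign(truth$trueLog2FC)) - 2), 0.2)
  ## fewer than 2 samples per group is rejected
  expect_error(simulateCounts(st2, simulationConfig(
    seed = 1, nSamplesPerGroup = 1)), "at least 2")
})

test_that("plantSpongeSites writes detectable non-overlapping sites", {
  set.seed(61)
  mir <- c(mirA = paste(sample(c("A", "C", "G", "U"), 22, TRUE),
                        collapse = ""),
           mirB = paste(sample(c("A", "C", "G", "U"), 22, TRUE),
                        collapse = ""))
  lnc <- c(L1 = randomDnaStr(300))
  ## zero sites leaves sequences untouched
  p0 <- plantSpongeSites(lnc, mir, list(list(lncrna = "L1",
                                             mirnas = "mirA",
                                             nSites = 0L)), seed = 1)
  expect_identical(p0$sequences[["L1"]], lnc[["L1"]])
  ## planted 8mer is later detected at its coordinate
  p1 <- plantSpongeSites(lnc, mir, list(list(lncrna = "L1",
                                             mirnas = "mirB",
                                             nSites = 1L)), seed = 2)
  s <- findSeedSites(mir[["mirB"]], p1$sequences[["L1"]])
  expect_true(any(s$start == p1$sites$start & s$siteType == "8mer"))
  ## packing feasibility: 10 x 8-nt sites fit in 300 nt, 40 do not
  p10 <- plantSpongeSites(lnc, mir, list(list(lncrna = "L1",
                                              mirnas = "mirA",
                                              nSites = 10L)), seed = 3)
  st <- sort(p10$sites$start)
  expect_true(all(diff(st) >= 8))              # non-overlapping
  expect_error(plantSpongeSites(lnc, mir,
    list(list(lncrna = "L1", mirnas = "mirA", nSites = 40L)), seed = 4),
    "L1")
})
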