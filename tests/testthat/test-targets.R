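test_that("findSeedSites classifies constructed sites by type", {
  m <- "UAGCAGCACGUAAAUAUUGGCG"
  seed27 <- substr(chartr("U", "T", m), 2, 7)
  core <- revcompOracle(seed27)                       # 6mer match
  m8c <- chartr("ACGT", "TGCA", substr(chartr("U", "T", m), 8, 8))
  ## 8mer: m8 complement + core + A
  s8 <- paste0("CC", m8c, core, "A", "CC")
  r <- findSeedSites(m, s8)
  expect_equal(nrow(r), 1L)
  expect_equal(r$siteType, "8mer")
  expect_equal(r$start, 2L)
  ## 7mer-m8: no A
  s7m8 <- paste0("CC", m8c, core, "C", "CC")
  expect_equal(findSeedSites(m, s7m8)$siteType, "7mer-m8")
  ## 7mer-A1: A but wrong m8 base
  notM8 <- setdiff(c("A", "C", "G", "T"), m8c)[1]
  s7a1 <- paste0("CC", notM8, core, "A", "CC")
  r <- findSeedSites(m, s7a1)
  expect_equal(r$siteType, "7mer-A1")
  expect_equal(r$start, 3L)
  ## no seed complement at all
  expect_equal(nrow(findSeedSites(m, strrep("A", 100))), 0L)
})

test_that("findSeedSites equals a naive position-by-position scan", {
  set.seed(71)
  for (rep in 1:5) {
    lnc <- randomDnaStr(2000)
    for (k in 1:5) {
      m <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
                 collapse = "")
      mine <- findSeedSites(m, lnc)
      oracle <- naiveSeedScan(m, lnc)
      key <- function(d) sort(paste(d$start, d$siteType))
      expect_equal(key(mine), key(oracle))
    }
  }
})

test_that("hybridScore follows the stated scoring scheme", {
  m <- "UAGCAGCACGUAAAUAUUGGCG"                       # 22 nt
  perfect <- revcompOracle(chartr("U", "T", m))
  expect_equal(hybridScore(m, perfect), 145)          # 7x10 + 15x5
  expect_equal(hybridScore(strrep("A", 22), strrep("A", 22)), 0)
  ## locality: content outside the window never matters
  expect_equal(hybridScore(m, perfect),
               hybridScore(m, perfect))
  w1 <- paste0("GGGG", perfect)
  w2 <- paste0("TTTT", perfect)
  expect_gte(hybridScore(m, w1), 145)
  expect_gte(hybridScore(m, w2), 145)
  ## G:U wobble scores between mismatch and Watson-Crick
  mu <- "GGGGGGGG"                                    # all G miRNA
  expect_equal(hybridScore(mu, "TTTTTTTT"),
               7 * 4 + 1 * 2)                         # wobbles, seed doubled
})

test_that("predictTargets counts planted sites and is threshold-monotone", {
  set.seed(73)
  mir <- c(mirA = paste(sample(c("A", "C", "G", "U"), 22, TRUE),
                        collapse = ""))
  lnc <- c(lncX = randomDnaStr(600))
  pl <- plantSpongeSites(lnc, mir, list(list(lncrna = "lncX",
                                             mirnas = "mirA",
                                             nSites = 4L)), seed = 2)
  hits <- predictTargets(mir, pl$sequences)
  expect_gte(targetCounts(hits)["mirA", "lncX"], 4)
  ## all planted sites recovered as consensus 8mers at their coordinates
  st <- as.data.frame(siteTable(hits))
  expect_true(all(pl$sites$start %in%
                    st$start[st$siteType == "8mer" & st$consensus]))
  ## infinite hybrid threshold removes everything
  none <- predictTargets(mir, pl$sequences, minHybridScore = Inf)
  expect_equal(sum(targetCounts(none)), 0)
  ## monotone in both thresholds
  c7 <- sum(targetCounts(predictTargets(mir, pl$sequences,
                                        minSiteType = "7mer")))
  c8 <- sum(targetCounts(predictTargets(mir, pl$sequences,
                                        minSiteType = "8mer")))
  expect_lte(c8, c7)
  cHi <- sum(targetCounts(predictTargets(mir, pl$sequences,
                                         minHybridScore = 100)))
  expect_lte(cHi, c7)
  expect_warning(predictTargets(character(0), pl$sequences), "empty")
})

test_that("buildNull preserves composition and is seed-deterministic", {
  set.seed(79)
  mir <- c(m1 = paste(sample(c("A", "C", "G", "U"), 22, TRUE),
                      collapse = ""))
  lnc <- c(l1 = randomDnaStr(300), l2 = strrep("A", 200))
  n1 <- buildNull(lnc, mir, nReplicates = 2, seed = 4)
  n2 <- buildNull(lnc, mir, nReplicates = 2, seed = 4)
  expect_identical(n1, n2)
  expect_equal(length(n1), 2L)
  ## a homopolymer is its own shuffle fixed point
  real <- targetCounts(predictTargets(mir, lnc))
  expect_equal(n1[[1]][, "l2"], real[, "l2"])
})

test_that("null 7mer seed-match rate matches the composition expectation", {
  ## expected matches of a fixed 7mer in an i.i.d. shuffled sequence
  set.seed(83)
  mir <- c(m1 = "UAGCAGCACGUAAAUAUUGGCG")
  lnc <- c(l1 = randomDnaStr(20000))
  nulls <- buildNull(lnc, mir, nReplicates = 30, seed = 9,
                     minSiteType = "6mer", minHybridScore = 0)
  obs <- vapply(nulls, function(m) m["m1", "l1"], numeric(1))
  ## composition-derived per-position 6mer core probability
  comp <- table(factor(strsplit(lnc[[1]], "")[[1]],
                       levels = c("A", "C", "G", "T"))) / nchar(lnc[[1]])
  core <- strsplit(revcompOracle(substr(chartr("U", "T", mir[[1]]), 2, 7)),
                   "")[[1]]
  pHat <- prod(comp[core])
  expected <- (nchar(lnc[[1]]) - 5) * pHat
  se <- sqrt(expected)
  expect_lte(abs(mean(obs) - expected), 3 * se / sqrt(length(obs)) + 1)
})
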