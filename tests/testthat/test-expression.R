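test_that("computeFpkm matches the closed form and is scale invariant", {
  cnt <- matrix(c(10, 999990), ncol = 1,
                dimnames = list(c("a", "b"), "s1"))
  f <- computeFpkm(cnt, c(a = 1000, b = 1000))
  expect_equal(f["a", 1], 10)                  # 10 / 1kb / 1M
  set.seed(77)
  cnt2 <- matrix(rpois(80, 50) + 1, nrow = 20,
                 dimnames = list(paste0("t", 1:20), paste0("s", 1:4)))
  lens <- setNames(sample(200:2000, 20), rownames(cnt2))
  f1 <- computeFpkm(cnt2, lens)
  expect_equal(f1, computeFpkm(2 * cnt2, lens))  # doubling all counts
  ## independent formula evaluation
  oracle <- matrix(0, 20, 4, dimnames = dimnames(cnt2))
  for (i in 1:20) for (j in 1:4)
    oracle[i, j] <- cnt2[i, j] / (lens[i] / 1000) /
      (sum(cnt2[, j]) / 1e6)
  expect_equal(f1, oracle)
  cnt2[, 2] <- 0
  expect_error(computeFpkm(cnt2, lens), "zero library")
})

test_that("expressionFilter keeps transcripts passing in any one group", {
  st <- data.frame(condition = c("unfed", "unfed", "fed", "fed"),
                   timepoint = c(NA, NA, "24h", "72h"))
  fpkm <- rbind(atBoundary = c(5, 5, 1, 1),
                below = c(4.9, 10, 4.9, 4.9),
                fedOnly = c(1, 1, 6, 1))
  colnames(fpkm) <- paste0("s", 1:4)
  kept <- expressionFilter(fpkm, st)
  expect_true("atBoundary" %in% kept)          # >= is inclusive
  expect_false("below" %in% kept)
  expect_true("fedOnly" %in% kept)             # its own fed timepoint group
  ## planted pass/fail recount
  set.seed(3)
  n <- 100
  st2 <- data.frame(condition = rep(c("unfed", "fed"), each = 4),
                    timepoint = NA)
  pass <- sample(n, 30)
  f <- matrix(runif(n * 8, 0, 4.99), nrow = n,
              dimnames = list(paste0("t", 1:n), paste0("s", 1:8)))
  f[pass, 1:4] <- runif(30 * 4, 5, 50)
  expect_setequal(expressionFilter(f, st2), paste0("t", pass))
})

test_that("tmmFactors equals a step-by-step trimmed-mean evaluation and
           the reference implementation", {
  set.seed(9)
  mu <- exp(rnorm(200, log(100), 1))
  cnt <- matrix(rnbinom(200 * 4, mu = rep(mu, 4), size = 5), ncol = 4,
                dimnames = list(paste0("t", 1:200), paste0("s", 1:4)))
  f <- tmmFactors(cnt)
  expect_equal(unname(f), tmmOracle(cnt), tolerance = 1e-10)
  expect_equal(unname(f),
               unname(edgeR::calcNormFactors(cnt, method = "TMM")),
               tolerance = 1e-8)
  expect_equal(prod(f), 1, tolerance = 1e-12)  # geometric-mean convention
  ## trivials
  two <- cbind(s1 = cnt[, 1], s2 = cnt[, 1])
  expect_equal(unname(tmmFactors(two)), c(1, 1))
  scaled <- cbind(s1 = cnt[, 1], s2 = 3 * cnt[, 1])
  expect_equal(unname(tmmFactors(scaled)), c(1, 1))
})

test_that("estimateCommonDispersion recovers the generating dispersion", {
  set.seed(13)
  mu <- exp(rnorm(1000, log(100), 0.8))
  nb <- matrix(rnbinom(1000 * 10, mu = rep(mu, 10), size = 1 / 0.2),
               ncol = 10, dimnames = list(paste0("g", 1:1000), NULL))
  grp <- rep(c("a", "b"), each = 5)
  phi <- estimateCommonDispersion(nb, grp)
  expect_gte(phi, 0.1); expect_lte(phi, 0.3)
  pois <- matrix(rpois(500 * 8, rep(mu[1:500], 8)), ncol = 8,
                 dimnames = list(paste0("g", 1:500), NULL))
  expect_lte(estimateCommonDispersion(pois, rep(c("a", "b"), each = 4)),
             0.05)
  flat <- matrix(5, nrow = 3, ncol = 4,
                 dimnames = list(paste0("g", 1:3), NULL))
  expect_equal(estimateCommonDispersion(flat, c("a", "a", "b", "b")), 0)
  expect_error(estimateCommonDispersion(flat, c("a", "b", "c", "d")),
               "replicates")
})

test_that("nbExactTest agrees with closed forms and is label-exchangeable", {
  ## symmetric split at phi = 0 is the most probable outcome: p = 1
  cm <- matrix(c(5, 5, 5, 5), nrow = 1,
               dimnames = list("t1", paste0("s", 1:4)))
  r <- nbExactTest(cm, factor(c("a", "a", "b", "b")), phi = 0)
  expect_equal(r$pvalue, 1)
  ## 10 vs 0 with equal sizes reduces to a two-sided binomial tail
  cm2 <- matrix(c(10, 0), nrow = 1, dimnames = list("t1", c("s1", "s2")))
  r2 <- nbExactTest(cm2, factor(c("a", "b")), phi = 0,
                    libSizes = c(100, 100))
  probs <- dbinom(0:10, 10, 0.5)
  oracle <- sum(probs[probs <= dbinom(10, 10, 0.5) + 1e-12])
  expect_equal(r2$pvalue, oracle)
  expect_lt(r2$log2FC, 0)                # second level (b, count 0) vs a
  ## swapping group labels keeps p, negates the fold change
  set.seed(5)
  cnt <- matrix(rnbinom(60 * 8, mu = 80, size = 8), ncol = 8,
                dimnames = list(paste0("g", 1:60), paste0("s", 1:8)))
  g <- factor(rep(c("a", "b"), each = 4))
  gSwap <- factor(rep(c("b", "a"), each = 4))  # levels a, b: roles swapped
  ra <- nbExactTest(cnt, g, 0.1)
  rb <- nbExactTest(cnt, gSwap, 0.1)
  expect_equal(ra$pvalue, rb$pvalue, tolerance = 1e-12)
  expect_equal(ra$log2FC, -rb$log2FC, tolerance = 1e-12)
})

test_that("the exact test holds its size under the null", {
  set.seed(11)
  n <- 1000
  mu <- exp(rnorm(n, log(60), 0.8))
  cnt <- matrix(rnbinom(n * 8, mu = rep(mu, 8), size = 1 / 0.1), ncol = 8,
                dimnames = list(paste0("g", 1:n), paste0("s", 1:8)))
  g <- factor(rep(c("a", "b"), each = 4))
  r <- nbExactTest(cnt, g, phi = 0.1, factors = tmmFactors(cnt))
  frac <- mean(r$pvalue < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})

test_that("bhAdjust reproduces the hand-evaluated step-up", {
  expect_equal(bhAdjust(0.02), 0.02)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(21)
  p <- runif(50)
  expect_equal(bhAdjust(p), bhOracle(p))
  expect_true(all(diff(sort(bhAdjust(p))) >= -1e-15))
  expect_error(bhAdjust(c(0.5, 1.2)))
})

test_that("classifyDe labels directions by FDR and fold-change sign", {
  de <- data.frame(transcript = c("a", "b", "c"),
                   log2FC = c(2, -1, 3),
                   fdr = c(0.04, 0.01, 0.5))
  r <- classifyDe(de)
  expect_equal(r$direction, c("up_fed", "up_unfed", "ns"))
  expect_equal(unname(attr(r, "summary")), c(1L, 1L, 1L))
})

test_that("planted differential expression is recovered with controlled
           error", {
  cfg <- simulationConfig(seed = 29, nClusters = 40, sourcePresence = 1,
                          nSamplesPerGroup = 6, deFraction = 0.2,
                          deLog2fc = 2, spongePlan = list())
  st <- simulateSpongeStudy(cfg)
  se <- countData(st)
  cnt <- SummarizedExperiment::assay(se)
  tab <- as.data.frame(SummarizedExperiment::colData(se))
  cols <- tab$tissue == "midgut"
  grp <- factor(tab$condition[cols], levels = c("unfed", "fed"))
  fac <- tmmFactors(cnt[, cols])
  phi <- estimateCommonDispersion(cnt[, cols], grp, fac)
  de <- nbExactTest(cnt[, cols], grp, phi, fac)
  de$fdr <- bhAdjust(de$pvalue)
  de <- classifyDe(de)
  truth <- SummarizedExperiment::rowData(se)
  called <- de$direction != "ns"
  sens <- sum(called & truth$isDE) / sum(truth$isDE)
  obsFdr <- if (sum(called)) sum(called & !truth$isDE) / sum(called) else 0
  expect_gte(sens, 0.8)
  expect_lte(obsFdr, 0.1)
  ## called directions agree with the planted fold-change signs
  up <- de$direction == "up_fed" & truth$isDE
  expect_true(all(truth$trueLog2FC[up] > 0))
})
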