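test_that("normalizedTargetRatio follows the two-step normalization", {
  fed <- c(m1 = 10, m2 = 5, m3 = 0)
  expect_equal(normalizedTargetRatio(fed, fed)$ratio, rep(1, 3))
  ## dominant miRNA: max in fed, zero in unfed
  fed2 <- c(m1 = 20, m2 = 5, m3 = 2)
  unf2 <- c(m1 = 0, m2 = 10, m3 = 8)
  r <- normalizedTargetRatio(fed2, unf2)
  expect_equal(r$mirna[1], "m1")
  ## independent evaluation of the formula on random vectors
  set.seed(31)
  for (rep in 1:10) {
    a <- setNames(rpois(8, 20), paste0("m", 1:8))
    b <- setNames(rpois(8, 20), paste0("m", 1:8))
    r <- normalizedTargetRatio(a, b)
    na <- (a + 1) / max(a + 1)
    nb <- (b + 1) / max(b + 1)
    oracle <- sort(na / nb, decreasing = TRUE)
    expect_equal(r$ratio, unname(oracle[r$mirna]))
  }
  expect_error(normalizedTargetRatio(numeric(0), numeric(0)), "empty")
})

test_that("topByCount and topByDensity pick deterministic maxima", {
  cm <- matrix(0L, 3, 4, dimnames = list(paste0("m", 1:3),
                                         paste0("L", 1:4)))
  cm["m2", "L3"] <- 17L
  r <- topByCount(cm)
  expect_equal(r[, c("lncrna", "mirna", "score")],
               data.frame(lncrna = "L3", mirna = "m2", score = 17))
  ## tie broken lexicographically by (lncrna, mirna)
  cm["m1", "L1"] <- 17L
  expect_equal(topByCount(cm)$lncrna, "L1")
  expect_equal(topByCount(cm)$mirna, "m1")
  ## density: 10 targets on 2000 nt = 5 per kb; shorter lncRNA wins ties
  cm2 <- matrix(10L, 1, 2, dimnames = list("m1", c("La", "Lb")))
  lens <- c(La = 2000, Lb = 1000)
  d <- topByDensity(cm2, lens)
  expect_equal(d$score, 10)
  expect_equal(d$lncrna, "Lb")
  expect_equal(topByDensity(cm2[, "La", drop = FALSE], lens)$score, 5)
  ## all-zero matrix yields no candidate
  expect_warning(r0 <- topByCount(matrix(0, 2, 2,
    dimnames = list(c("m1", "m2"), c("L1", "L2")))), "all-zero")
  expect_equal(nrow(r0), 0L)
  ## null comparison uses the shuffled mean plus pseudocount
  nulls <- list(cm * 0L, cm * 0L + 1L)
  expect_equal(topByCount(cm, nulls)$nullComparison, 17 / (0.5 + 1))
})

test_that("mineItemsets equals exhaustive enumeration and respects
           downward closure", {
  empty <- matrix(0L, 3, 5, dimnames = list(paste0("m", 1:3),
                                            paste0("L", 1:5)))
  expect_equal(nrow(mineItemsets(empty, minSupport = 1)), 0L)
  expect_error(mineItemsets(empty, minSupport = 0), "at least 1")
  ## forced pair
  cm <- matrix(0L, 2, 3, dimnames = list(c("m1", "m2"), paste0("L", 1:3)))
  cm[] <- 1L
  r <- mineItemsets(cm, minSupport = 3)
  expect_equal(r$itemset, "m1+m2")
  expect_equal(r$support, 3L)
  expect_setequal(r$lncrnas[[1]], paste0("L", 1:3))
  ## random instance vs brute force
  set.seed(37)
  for (rep in 1:5) {
    cm <- matrix(rbinom(8 * 30, 1, 0.35), 8, 30,
                 dimnames = list(paste0("m", 1:8), paste0("L", 1:30)))
    mine <- mineItemsets(cm, minSupport = 3)
    oracle <- enumerateItemsets(cm, minSupport = 3)
    expect_setequal(paste(mine$itemset, mine$support),
                    paste(oracle$itemset, oracle$support))
    ## downward closure: subsets of size >= 2 of any result are present
    for (k in seq_len(nrow(mine))) {
      it <- mine$mirnas[[k]]
      if (length(it) < 3) next
      for (d in seq_along(it)) {
        expect_true(paste(it[-d], collapse = "+") %in% mine$itemset)
      }
    }
  }
})

test_that("itemsetSignificance applies the permutation p-value formula", {
  cm <- matrix(1L, 2, 5, dimnames = list(c("m1", "m2"), paste0("L", 1:5)))
  its <- mineItemsets(cm, minSupport = 3)
  nullAbsent <- replicate(19, cm * 0L, simplify = FALSE)
  p <- itemsetSignificance(its, nullAbsent)$empiricalP
  expect_equal(p, 1 / 20)
  nullEqual <- replicate(19, cm, simplify = FALSE)
  expect_equal(itemsetSignificance(its, nullEqual)$empiricalP, 1)
  expect_error(itemsetSignificance(its, list()), "at least one")
})

test_that("selectSpongeCandidates keeps disjoint significant groups", {
  ## three planted co-targeting blocks + an overlapping weaker itemset
  cm <- matrix(0L, 9, 12, dimnames = list(paste0("m", 1:9),
                                          sprintf("L%02d", 1:12)))
  cm[1:3, 1:4] <- 1L
  cm[4:6, 5:8] <- 1L
  cm[7:9, 9:12] <- 1L
  nulls <- replicate(19, cm * 0L, simplify = FALSE)
  rep1 <- selectSpongeCandidates(cm, setNames(rep(1000, 12),
                                              colnames(cm)), nulls)
  grp <- spongeGroups(rep1)
  expect_equal(length(grp), 3L)
  got <- lapply(grp, function(g) sort(g$lncrnas))
  expect_setequal(got, list(sprintf("L%02d", 1:4), sprintf("L%02d", 5:8),
                            sprintf("L%02d", 9:12)))
  ## supporting sets are pairwise disjoint
  expect_equal(anyDuplicated(unlist(got)), 0L)
  ## no significant itemsets: only the two single-miRNA candidates remain
  nullsEqual <- replicate(19, cm, simplify = FALSE)
  rep2 <- selectSpongeCandidates(cm, setNames(rep(1000, 12),
                                              colnames(cm)), nullsEqual)
  expect_equal(length(spongeGroups(rep2)), 0L)
  expect_equal(nrow(candidateTable(rep2)), 2L)
})
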