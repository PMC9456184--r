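## Sponge-candidate detection: the normalized target-ratio statistic for
## miRNA prioritization and the three candidate-selection approaches
## (maximum count, maximum density, Apriori itemset groups), each compared
## against the shuffled-sequence null.

#' Normalized target-ratio statistic for miRNA prioritization
#'
#' Each per-miRNA target total is normalized by the maximum total within
#' its set (lncRNAs upregulated in fed vs upregulated in unfed ticks, with
#' a pseudocount so that the ratio is defined at zero), and the ratio of
#' normalized values ranks miRNAs by their enrichment for feeding-induced
#' lncRNA targets.
#'
#' @param countsUpFed,countsUpUnfed Named per-miRNA target totals for the
#'   two lncRNA sets (same miRNA universe).
#' @param pseudocount Added to every total before normalization (default 1).
#' @param topK How many top miRNAs to flag for export (default 3).
#' @return data.frame sorted by decreasing ratio with columns `mirna`,
#'   `targetsFed`, `targetsUnfed`, `normFed`, `normUnfed`, `ratio`,
#'   `rank`; attribute `"top"` holds the first `topK` miRNA ids.
#' @export
normalizedTargetRatio <- function(countsUpFed, countsUpUnfed,
                                  pseudocount = 1, topK = 3L) {
  stopIfNot(length(countsUpFed) > 0L, "empty miRNA set")
  ids <- names(countsUpFed)
  stopIfNot(!is.null(ids) && setequal(ids, names(countsUpUnfed)),
            "the two count vectors must cover the same miRNAs")
  fed <- countsUpFed[ids] + pseudocount
  unfed <- countsUpUnfed[ids] + pseudocount
  normFed <- fed / max(fed)
  normUnfed <- unfed / max(unfed)
  ratio <- normFed / normUnfed
  ord <- order(-ratio, ids)
  out <- data.frame(mirna = ids, targetsFed = unname(countsUpFed[ids]),
                    targetsUnfed = unname(countsUpUnfed[ids]),
                    normFed = unname(normFed),
                    normUnfed = unname(normUnfed),
                    ratio = unname(ratio),
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "top") <- utils::head(out$mirna, topK)
  out
}

nullMeanMatrix <- function(nullMatrices, template) {
  if (is.null(nullMatrices) || !length(nullMatrices))
    return(matrix(0, nrow(template), ncol(template),
                  dimnames = dimnames(template)))
  Reduce(`+`, lapply(nullMatrices, function(m)
    m[rownames(template), colnames(template), drop = FALSE])) /
    length(nullMatrices)
}

#' Sponge candidate with the maximum target count
#'
#' Selects the (miRNA, lncRNA) pair with the highest consensus-site count;
#' ties are broken by (lncRNA id, miRNA id), ascending. The null comparison
#' is the real count over the shuffled-null mean plus a pseudocount of 1.
#'
#' @param countMatrix Consensus-count matrix (miRNAs x lncRNAs).
#' @param nullMatrices Optional list of null count matrices.
#' @return One-row data.frame `approach`, `lncrna`, `mirna`, `score`,
#'   `nullComparison`; zero rows (with a warning) if the matrix is all
#'   zero.
#' @export
topByCount <- function(countMatrix, nullMatrices = NULL) {
  stopIfNot(length(countMatrix) > 0L, "empty count matrix")
  if (all(countMatrix == 0)) {
    warning("all-zero count matrix: no max-count candidate")
    return(data.frame(approach = character(0), lncrna = character(0),
                      mirna = character(0), score = numeric(0),
                      nullComparison = numeric(0)))
  }
  idx <- which(countMatrix == max(countMatrix), arr.ind = TRUE)
  pick <- data.frame(lncrna = colnames(countMatrix)[idx[, 2]],
                     mirna = rownames(countMatrix)[idx[, 1]])
  pick <- pick[order(pick$lncrna, pick$mirna), , drop = FALSE][1, ]
  nullMean <- nullMeanMatrix(nullMatrices, countMatrix)
  data.frame(approach = "max_count", lncrna = pick$lncrna,
             mirna = pick$mirna, score = max(countMatrix),
             nullComparison = max(countMatrix) /
               (nullMean[pick$mirna, pick$lncrna] + 1),
             stringsAsFactors = FALSE)
}

#' Sponge candidate with the maximum target density
#'
#' As [topByCount()] but maximizing targets per kilobase:
#' `count * 1000 / length`.
#'
#' @param countMatrix Consensus-count matrix (miRNAs x lncRNAs).
#' @param lengths Named lncRNA lengths (nt), positive.
#' @param nullMatrices Optional list of null count matrices.
#' @return One-row data.frame as in [topByCount()], `score` in targets/kb.
#' @export
topByDensity <- function(countMatrix, lengths, nullMatrices = NULL) {
  stopIfNot(all(lengths[colnames(countMatrix)] > 0),
            "lncRNA lengths must be positive")
  dens <- sweep(countMatrix, 2, lengths[colnames(countMatrix)] / 1000, "/")
  if (all(countMatrix == 0)) {
    warning("all-zero count matrix: no max-density candidate")
    return(data.frame(approach = character(0), lncrna = character(0),
                      mirna = character(0), score = numeric(0),
                      nullComparison = numeric(0)))
  }
  idx <- which(dens == max(dens), arr.ind = TRUE)
  pick <- data.frame(lncrna = colnames(dens)[idx[, 2]],
                     mirna = rownames(dens)[idx[, 1]])
  pick <- pick[order(pick$lncrna, pick$mirna), , drop = FALSE][1, ]
  nullMean <- nullMeanMatrix(nullMatrices, countMatrix)
  data.frame(approach = "density", lncrna = pick$lncrna,
             mirna = pick$mirna, score = max(dens),
             nullComparison = countMatrix[pick$mirna, pick$lncrna] /
               (nullMean[pick$mirna, pick$lncrna] + 1),
             stringsAsFactors = FALSE)
}

binarize <- function(countMatrix) countMatrix >= 1

itemsetSupport <- function(binMatrix, items) {
  sub <- binMatrix[items, , drop = FALSE]
  colnames(binMatrix)[colSums(sub) == length(items)]
}

#' Apriori mining of recurrent miRNA combinations
#'
#' Classic level-wise Apriori over the binarized target matrix:
#' transactions are lncRNAs, items are miRNAs (an item is in a transaction
#' when the miRNA has at least one consensus site on the lncRNA). Returns
#' every itemset of at least `minSize` miRNAs whose support (number of
#' lncRNAs containing all of them) reaches `minSupport`; downward closure
#' holds across the result.
#'
#' @param countMatrix Consensus-count matrix (miRNAs x lncRNAs).
#' @param minSupport Minimum support; default `max(3, ceiling(0.05 *`
#'   number of lncRNA transactions`))`. Must be at least 1.
#' @param minSize Minimum itemset size reported (default 2).
#' @return data.frame with columns `itemset` (items joined by `+`), `size`,
#'   `support` and list-columns `mirnas`, `lncrnas` (the supporting set).
#' @export
mineItemsets <- function(countMatrix, minSupport = NULL, minSize = 2L) {
  bin <- binarize(countMatrix)
  nTrans <- ncol(bin)
  if (is.null(minSupport)) minSupport <- max(3L, ceiling(0.05 * nTrans))
  if (minSupport < 1L) stop("'minSupport' must be at least 1")
  emptyRes <- data.frame(itemset = character(0), size = integer(0),
                         support = integer(0))
  emptyRes$mirnas <- list(); emptyRes$lncrnas <- list()
  if (!nTrans || !nrow(bin)) return(emptyRes)
  items <- sort(rownames(bin))
  freq <- list()
  ## level 1
  Lk <- lapply(items, function(i) i)
  Lk <- Filter(function(it) sum(bin[it, ]) >= minSupport, Lk)
  level <- 1L
  while (length(Lk)) {
    if (level >= minSize)
      freq <- c(freq, Lk)
    ## candidate generation: join sets sharing the first k-1 items
    keys <- vapply(Lk, function(x) paste(x[-length(x)], collapse = "\r"),
                   character(1))
    cand <- list()
    grp <- split(Lk, keys)
    for (g in grp) {
      if (length(g) < 2L) next
      lastItems <- sort(vapply(g, function(x) x[length(x)], character(1)))
      pre <- g[[1]][-length(g[[1]])]
      for (a in seq_along(lastItems))
        for (b in seq_along(lastItems))
          if (a < b)
            cand[[length(cand) + 1L]] <- c(pre, lastItems[a], lastItems[b])
    }
    ## prune: all (k-1)-subsets must be frequent
    known <- vapply(Lk, paste, character(1), collapse = "\r")
    cand <- Filter(function(it) {
      all(vapply(seq_along(it), function(d)
        paste(it[-d], collapse = "\r") %in% known, logical(1)))
    }, cand)
    Lk <- Filter(function(it)
      length(itemsetSupport(bin, it)) >= minSupport, cand)
    level <- level + 1L
  }
  if (!length(freq)) return(emptyRes)
  out <- data.frame(
    itemset = vapply(freq, paste, character(1), collapse = "+"),
    size = vapply(freq, length, integer(1)),
    support = vapply(freq, function(it)
      length(itemsetSupport(bin, it)), integer(1)),
    stringsAsFactors = FALSE)
  out$mirnas <- freq
  out$lncrnas <- lapply(freq, function(it) itemsetSupport(bin, it))
  out <- out[order(-out$support, out$itemset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Empirical significance of mined itemsets against the shuffled null
#'
#' For each itemset, counts the null replicates in which the itemset's
#' support (recomputed on the binarized null matrix) reaches the observed
#' support; the empirical p-value is `(r + 1) / (n + 1)`, which never
#' returns 0. p-values are BH-adjusted across itemsets.
#'
#' @param itemsets Output of [mineItemsets()].
#' @param nullMatrices List of null count matrices (>= 1).
#' @return `itemsets` with columns `empiricalP` and `fdr` added.
#' @export
itemsetSignificance <- function(itemsets, nullMatrices) {
  stopIfNot(length(nullMatrices) >= 1L, "at least one null matrix needed")
  if (!nrow(itemsets)) {
    itemsets$empiricalP <- numeric(0)
    itemsets$fdr <- numeric(0)
    return(itemsets)
  }
  bins <- lapply(nullMatrices, binarize)
  nRep <- length(bins)
  itemsets$empiricalP <- vapply(seq_len(nrow(itemsets)), function(k) {
    it <- itemsets$mirnas[[k]]
    obs <- itemsets$support[k]
    r <- sum(vapply(bins, function(b)
      length(itemsetSupport(b, it)) >= obs, logical(1)))
    (1 + r) / (1 + nRep)
  }, numeric(1))
  itemsets$fdr <- bhAdjust(itemsets$empiricalP)
  itemsets
}

#' Assemble the final sponge-candidate report
#'
#' Combines the three candidate approaches: the maximum-count candidate,
#' the maximum-density candidate, and up to `maxGroups` significant miRNA
#' itemset groups chosen greedily by ascending empirical p (ties: larger
#' itemsets, then higher support, then itemset id) subject to pairwise
#' disjoint supporting lncRNA sets. When a per-transcript log2
#' fold-change table is supplied, the candidates' fed-vs-unfed fold
#' changes per tissue are attached (the heat-map table).
#'
#' @param countMatrix Consensus-count matrix (miRNAs x lncRNAs).
#' @param lengths Named lncRNA lengths (nt).
#' @param nullMatrices List of null count matrices.
#' @param itemsets Output of [itemsetSignificance()]; `NULL` to mine and
#'   score here.
#' @param alpha Significance threshold on the empirical p (default 0.05).
#' @param maxGroups Maximum number of disjoint groups (default 3).
#' @param log2fcTable Optional data.frame `transcript`, `tissue`, `log2FC`.
#' @return A [SpongeReport-class].
#' @export
selectSpongeCandidates <- function(countMatrix, lengths, nullMatrices,
                                   itemsets = NULL, alpha = 0.05,
                                   maxGroups = 3L, log2fcTable = NULL) {
  if (is.null(itemsets)) {
    itemsets <- itemsetSignificance(mineItemsets(countMatrix),
                                    nullMatrices)
  }
  cand <- rbind(
    suppressWarnings(topByCount(countMatrix, nullMatrices)),
    suppressWarnings(topByDensity(countMatrix, lengths, nullMatrices)))
  groups <- list()
  if (nrow(itemsets)) {
    sig <- itemsets[itemsets$empiricalP <= alpha, , drop = FALSE]
    if (nrow(sig)) {
      ord <- order(sig$empiricalP, -sig$size, -sig$support, sig$itemset)
      sig <- sig[ord, , drop = FALSE]
      used <- character(0)
      for (k in seq_len(nrow(sig))) {
        supp <- sig$lncrnas[[k]]
        if (length(intersect(supp, used))) next
        groups[[length(groups) + 1L]] <- list(
          mirnas = sig$mirnas[[k]], lncrnas = supp,
          support = sig$support[k], empiricalP = sig$empiricalP[k])
        used <- c(used, supp)
        if (length(groups) >= maxGroups) break
      }
    }
  }
  allLnc <- unique(c(cand$lncrna,
                     unlist(lapply(groups, `[[`, "lncrnas"))))
  log2fc <- data.frame(lncrna = character(0))
  if (!is.null(log2fcTable) && length(allLnc)) {
    sub <- log2fcTable[log2fcTable$transcript %in% allLnc, , drop = FALSE]
    if (nrow(sub)) {
      wide <- stats::reshape(
        sub[, c("transcript", "tissue", "log2FC")],
        idvar = "transcript", timevar = "tissue", direction = "wide")
      colnames(wide) <- sub("^log2FC\\.", "", colnames(wide))
      colnames(wide)[1] <- "lncrna"
      rownames(wide) <- NULL
      log2fc <- wide
    }
  }
  methods::new("SpongeReport", candidates = cand, itemsets = itemsets,
               groups = groups, log2fc = log2fc)
}
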