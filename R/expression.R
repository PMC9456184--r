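#' FPKM from expected counts
#'
#' `FPKM = count / (length / 1000) / (librarySize / 1e6)` with
#' `librarySize` the column sum of the count matrix.
#'
#' @param counts Numeric matrix, transcripts x samples (expected counts,
#'   possibly fractional).
#' @param lengths Effective transcript lengths (nt), recycled by name when
#'   named, else positional.
#' @return FPKM matrix of the same shape.
#' @export
computeFpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  stopIfNot(length(lengths) == nrow(counts),
            "'lengths' must match rows of 'counts'")
  stopIfNot(all(lengths > 0), "transcript lengths must be positive")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib <= 0], collapse = ", "))
  sweep(sweep(counts, 1, lengths / 1000, "/"), 2, lib / 1e6, "/")
}

#' Expression filter on FPKM groups
#'
#' A transcript is retained when there exists at least one sample group in
#' which every sample has `FPKM >= minFpkm`. Groups are the unfed condition
#' as a whole, and each fed time point separately (samples fed to the same
#' time point form one group); without time points the fed condition is a
#' single group.
#'
#' @param fpkm FPKM matrix (transcripts x samples).
#' @param sampleTable data.frame with one row per sample (same order as
#'   columns of `fpkm`), columns `condition` (`"unfed"`/`"fed"`) and
#'   optionally `timepoint`.
#' @param minFpkm Threshold, inclusive (default 5).
#' @return Character vector of retained transcript ids.
#' @export
expressionFilter <- function(fpkm, sampleTable, minFpkm = 5) {
  stopIfNot(nrow(sampleTable) == ncol(fpkm),
            "sampleTable must have one row per fpkm column")
  grp <- ifelse(sampleTable$condition == "unfed", "unfed",
                if (!is.null(sampleTable$timepoint))
                  paste0("fed_", sampleTable$timepoint) else "fed")
  keep <- rep(FALSE, nrow(fpkm))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (!length(cols)) {
      warning("skipping empty sample group: ", g)
      next
    }
    keep <- keep | apply(fpkm[, cols, drop = FALSE] >= minFpkm, 1, all)
  }
  rownames(fpkm)[keep]
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Robinson-Oshlack TMM: each sample is compared with a reference sample
#' (the one whose library-scaled upper quartile is closest to the mean upper
#' quartile) via gene-wise M-values (log2 ratio of library-scaled
#' proportions) and A-values; M is trimmed 30% and A 5%, two-sided, and the
#' factor is 2 to the precision-weighted mean of the surviving M-values.
#' Factors are rescaled so their geometric mean is 1.
#'
#' @param counts Count matrix, transcripts x samples (at least 2 samples).
#' @param refSample Column index or name of the reference sample; default
#'   `NULL` selects it by the upper-quartile rule.
#' @param logratioTrim,sumTrim Two-sided trim fractions for M and A.
#' @return Named numeric vector of normalization factors.
#' @export
tmmFactors <- function(counts, refSample = NULL, logratioTrim = 0.30,
                       sumTrim = 0.05) {
  counts <- as.matrix(counts)
  stopIfNot(ncol(counts) >= 2L, "TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("all-zero sample(s): ",
                          paste(which(lib <= 0), collapse = ", "))
  if (is.null(refSample)) {
    uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
    refSample <- which.min(abs(uq - mean(uq)))
  } else if (is.character(refSample)) {
    refSample <- match(refSample, colnames(counts))
  }
  ref <- counts[, refSample]
  nR <- lib[refSample]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]
    nO <- lib[j]
    ok <- obs > 0 & ref > 0
    if (!any(ok)) return(1)
    o <- obs[ok]; r <- ref[ok]
    M <- log2((o / nO) / (r / nR))
    A <- (log2(o / nO) + log2(r / nR)) / 2
    if (max(abs(M)) < 1e-6) return(1)
    v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)   # asymptotic var of M
    n <- length(M)
    loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Method-of-moments common dispersion
#'
#' On counts normalized to a common effective library size, computes per
#' transcript the pooled within-group moments and the moment estimate
#' `phi = max(0, (s^2 - m) / m^2)`; the common dispersion is the median
#' over transcripts with mean above 1.
#'
#' @param counts Count matrix (transcripts x samples).
#' @param groups Factor/vector of group labels per sample; at least one
#'   group needs 2 or more replicates.
#' @param factors Optional TMM factors; default all 1.
#' @return The common dispersion estimate (non-negative scalar).
#' @export
estimateCommonDispersion <- function(counts, groups, factors = NULL) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (!any(table(groups) >= 2L))
    stop("no group with >= 2 replicates: supply a dispersion manually")
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  eff <- colSums(counts) * factors
  common <- exp(mean(log(eff)))
  y <- sweep(counts, 2, common / eff, "*")
  idx <- split(seq_len(ncol(y)), groups)
  idx <- idx[vapply(idx, length, 1L) >= 2L]
  phiT <- apply(y, 1, function(row) {
    ss <- 0; df <- 0; msum <- 0; nm <- 0
    for (cols in idx) {
      v <- row[cols]
      ss <- ss + sum((v - mean(v))^2)
      df <- df + length(v) - 1L
      msum <- msum + mean(v); nm <- nm + 1L
    }
    m <- msum / nm
    if (m <= 1) return(NA_real_)
    s2 <- ss / df
    max(0, (s2 - m) / m^2)
  })
  phiT <- phiT[!is.na(phiT)]
  if (!length(phiT)) return(0)
  stats::median(phiT)
}

#' Exact negative-binomial two-group test
#'
#' Counts are scaled by the product of TMM factor and library size to a
#' common effective size (geometric mean), group sums are rounded, and,
#' conditioning on each transcript's total, the two-sided p-value sums the
#' probabilities of all splits no more probable than the observed one under
#' independent negative-binomial group sums with means proportional to
#' group sizes and common dispersion `phi` (for `phi = 0` this is the
#' binomial-conditioned Poisson exact test). The log2 fold change is
#' computed from normalized group means with a prior count of 0.125.
#'
#' @param counts Count matrix (transcripts x samples).
#' @param groups Two-level factor per sample; the reported `log2FC` is the
#'   second level versus the first.
#' @param phi Common dispersion (>= 0).
#' @param factors Optional normalization factors (default all 1).
#' @param libSizes Optional library sizes (default column sums).
#' @param priorCount Prior count for the fold-change (default 0.125).
#' @return data.frame `transcript`, `log2FC`, `pvalue`.
#' @export
nbExactTest <- function(counts, groups, phi, factors = NULL,
                        libSizes = NULL, priorCount = 0.125) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  stopIfNot(nlevels(groups) == 2L, "exactly two groups required")
  stopIfNot(all(table(groups) >= 1L), "both groups need samples")
  stopIfNot(phi >= 0, "'phi' must be non-negative")
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (is.null(libSizes)) libSizes <- colSums(counts)
  stopIfNot(all(libSizes > 0), "library sizes must be positive")
  eff <- libSizes * factors
  common <- exp(mean(log(eff)))
  y <- sweep(counts, 2, common / eff, "*")
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  s1 <- rowSums(y[, g1, drop = FALSE])
  s2 <- rowSums(y[, !g1, drop = FALSE])
  m1 <- s1 / n1; m2 <- s2 / n2
  log2FC <- log2((m2 + priorCount) / (m1 + priorCount))
  y1 <- round(s1); y2 <- round(s2)
  p <- vapply(seq_along(y1), function(i)
    exactSplitPvalue(y1[i], y2[i], n1, n2, phi), numeric(1))
  data.frame(transcript = rownames(counts) %||%
               paste0("t", seq_along(p)),
             log2FC = log2FC, pvalue = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Two-sided conditional exact p for an observed split (y1, y2) of the
## total between groups of sizes n1, n2 at common dispersion phi. The
## conditional law is free of the mean: binomial for phi = 0, negative
## hypergeometric otherwise.
exactSplitPvalue <- function(y1, y2, n1, n2, phi) {
  t <- y1 + y2
  if (t == 0) return(1)
  s <- 0:t
  if (phi == 0) {
    logp <- stats::dbinom(s, t, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi
    logp <- stats::dnbinom(s, size = r1, prob = 0.5, log = TRUE) +
            stats::dnbinom(t - s, size = r2, prob = 0.5, log = TRUE)
    logp <- logp - logSumExp(logp)
  }
  obs <- logp[y1 + 1L]
  min(1, sum(exp(logp[logp <= obs + 1e-8])))
}

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control with monotonicity enforcement;
#' wraps [stats::p.adjust()].
#'
#' @param pvals Numeric vector in `[0, 1]`.
#' @return FDR values in the input order.
#' @export
bhAdjust <- function(pvals) {
  stopIfNot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE),
            "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Call differential-expression direction
#'
#' Labels each transcript `up_fed` (FDR below `alpha`, positive log2FC,
#' i.e. overexpressed while actively feeding), `up_unfed` (FDR below
#' `alpha`, negative log2FC) or `ns`.
#'
#' @param deResults data.frame with columns `log2FC` and `fdr` (fed vs
#'   unfed orientation).
#' @param alpha FDR threshold (default 0.05).
#' @return The input with a `direction` column added, plus a `"summary"`
#'   attribute (named counts).
#' @export
classifyDe <- function(deResults, alpha = 0.05) {
  dir <- ifelse(deResults$fdr < alpha & deResults$log2FC > 0, "up_fed",
         ifelse(deResults$fdr < alpha & deResults$log2FC < 0, "up_unfed",
                "ns"))
  deResults$direction <- dir
  attr(deResults, "summary") <- c(
    up_fed = sum(dir == "up_fed"),
    up_unfed = sum(dir == "up_unfed"),
    ns = sum(dir == "ns"))
  deResults
}
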