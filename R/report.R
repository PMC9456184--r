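## Summary statistics: DE percentages, cross-study overlap, expression
## share and length distributions.

#' Percentage of differentially expressed transcripts
#'
#' `100 * nDe / nTotal`, rounded half-up to one decimal place.
#'
#' @param nDe Number of DE transcripts (0 <= nDe <= nTotal).
#' @param nTotal Total transcripts (> 0).
#' @return Percentage with one decimal.
#' @examples
#' deSummary(1110, 3118)
#' @export
deSummary <- function(nDe, nTotal) {
  stopIfNot(nTotal > 0, "'nTotal' must be positive")
  stopIfNot(nDe >= 0 && nDe <= nTotal, "'nDe' must lie in [0, nTotal]")
  roundHalfUp(100 * nDe / nTotal, 1L)
}

#' Cross-study overlap of DE transcript sets
#'
#' Venn counts and overlap percentage for two id sets; the headline
#' percentage uses the union denominator (`100 * |A n B| / |A u B|`), and
#' per-study denominators are reported alongside since either convention
#' appears in practice.
#'
#' @param setA,setB Character vectors of transcript ids.
#' @return List with `nA`, `nB`, `intersection`, `onlyA`, `onlyB`,
#'   `overlapPct` (union denominator), `overlapPctA`, `overlapPctB`.
#' @export
overlapAnalysis <- function(setA, setB) {
  a <- unique(setA); b <- unique(setB)
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both sets empty: overlap undefined, reported as 0")
    pct <- 0; pctA <- 0; pctB <- 0
  } else {
    pct <- 100 * i / u
    pctA <- if (length(a)) 100 * i / length(a) else 0
    pctB <- if (length(b)) 100 * i / length(b) else 0
  }
  list(nA = length(a), nB = length(b), intersection = i,
       onlyA = length(a) - i, onlyB = length(b) - i,
       overlapPct = pct, overlapPctA = pctA, overlapPctB = pctB)
}

#' Share of total expression contributed by lncRNAs
#'
#' Per sample, the lncRNA share is the summed normalized expression of
#' lncRNAs over the summed expression of all transcripts; shares are then
#' averaged per condition group.
#'
#' @param normExpr Normalized expression matrix (transcripts x samples).
#' @param classLabels Per-transcript class (`"lncRNA"`/`"coding"`), named
#'   or in row order.
#' @param sampleTable data.frame with one row per sample; its `condition`
#'   column (or `tissue:condition` if `tissue` is present) defines the
#'   averaging groups.
#' @return List with `perSample` (named shares) and `perCondition`
#'   (group means).
#' @export
expressionShare <- function(normExpr, classLabels, sampleTable) {
  normExpr <- as.matrix(normExpr)
  if (!is.null(names(classLabels)) && !is.null(rownames(normExpr)))
    classLabels <- classLabels[rownames(normExpr)]
  stopIfNot(length(classLabels) == nrow(normExpr),
            "one class label per transcript required")
  tot <- colSums(normExpr)
  if (any(tot <= 0)) stop("zero total expression in sample(s): ",
                          paste(which(tot <= 0), collapse = ", "))
  isLnc <- classLabels == "lncRNA"
  share <- colSums(normExpr[isLnc, , drop = FALSE]) / tot
  grp <- if (!is.null(sampleTable$tissue))
    paste(sampleTable$tissue, sampleTable$condition, sep = ":")
  else as.character(sampleTable$condition)
  list(perSample = share,
       perCondition = tapply(share, grp, mean))
}

#' Length histogram with half-open bins
#'
#' Bins `[k * binWidth, (k + 1) * binWidth)`; counts conserve the total.
#'
#' @param sequences Character vector, [Biostrings::XStringSet], or numeric
#'   lengths.
#' @param binWidth Positive bin width (nt).
#' @return data.frame `binStart`, `binEnd`, `count` (non-empty bins only).
#' @export
lengthHistogram <- function(sequences, binWidth = 100) {
  stopIfNot(binWidth > 0, "'binWidth' must be positive")
  lens <- if (is.numeric(sequences)) sequences
          else if (is.character(sequences)) nchar(sequences)
          else Biostrings::width(sequences)
  if (!length(lens))
    return(data.frame(binStart = numeric(0), binEnd = numeric(0),
                      count = integer(0)))
  k <- floor(lens / binWidth)
  tab <- table(k)
  data.frame(binStart = as.numeric(names(tab)) * binWidth,
             binEnd = (as.numeric(names(tab)) + 1) * binWidth,
             count = as.integer(tab))
}
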