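#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom Biostrings DNAStringSet RNAStringSet AAStringSet
NULL

#' SpongeStudy: a simulated multi-source transcriptome study
#'
#' Container for one synthetic study: the pooled transcript contigs (with
#' their source transcriptome, true class and true cluster in `mcols`), the
#' mature miRNA set, the reference proteins derived from planted open reading
#' frames, an expected-count experiment, and the ground-truth tables used to
#' validate planted-structure recovery.
#'
#' @slot transcripts A [Biostrings::DNAStringSet] of contigs; `mcols` carries
#'   `source` (one of `MG_SG`, `SG`, `WB`), `class` (`coding`/`noncoding`)
#'   and `cluster` (integer id of the true cluster).
#' @slot mirnas A [Biostrings::RNAStringSet] of mature miRNA sequences.
#' @slot proteins An [Biostrings::AAStringSet] of reference proteins
#'   (translations of the planted ORFs).
#' @slot counts A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, per-transcript effective lengths in `rowData` and the sample
#'   table in `colData`, or `NULL` before counts are simulated.
#' @slot truth A list with elements `deTable` (transcript, trueLog2FC, isDE)
#'   and `plantedSites` (lncrna, mirna, start, siteType; 0-based starts).
#'
#' @export
setClass("SpongeStudy",
  representation(
    transcripts = "DNAStringSet",
    mirnas = "RNAStringSet",
    proteins = "AAStringSet",
    counts = "ANY",
    truth = "list"
  )
)

setValidity("SpongeStudy", function(object) {
  msg <- character()
  mc <- S4Vectors::mcols(object@transcripts)
  need <- c("source", "class", "cluster")
  if (length(object@transcripts) > 0L) {
    if (is.null(mc) || !all(need %in% colnames(mc)))
      msg <- c(msg, "transcripts must carry mcols 'source', 'class', 'cluster'")
    if (anyDuplicated(names(object@transcripts)))
      msg <- c(msg, "transcript ids must be unique")
  }
  if (!is.null(object@counts) &&
      !is(object@counts, "SummarizedExperiment"))
    msg <- c(msg, "counts must be NULL or a SummarizedExperiment")
  if (length(msg)) msg else TRUE
})

#' TargetHits: predicted miRNA target sites and per-pair tallies
#'
#' @slot sites A [S4Vectors::DataFrame] with columns `lncrna`, `mirna`,
#'   `start` (0-based), `siteType`, `hybridScore`, `consensus`.
#' @slot counts Integer matrix of consensus-site counts, rows = miRNAs,
#'   columns = lncRNAs.
#' @slot lncLengths Named numeric vector of lncRNA lengths (nt).
#' @slot params List of prediction parameters used.
#'
#' @export
setClass("TargetHits",
  representation(
    sites = "DataFrame",
    counts = "matrix",
    lncLengths = "numeric",
    params = "list"
  )
)

setValidity("TargetHits", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (!all(colnames(object@counts) %in% names(object@lncLengths)))
    msg <- c(msg, "every counted lncRNA needs a length")
  if (length(msg)) msg else TRUE
})

#' SpongeReport: the final sponge-candidate report
#'
#' @slot candidates data.frame of single-miRNA candidates (approach,
#'   lncrna, mirna, score, nullComparison).
#' @slot itemsets data.frame of mined miRNA itemsets with support and
#'   empirical significance.
#' @slot groups List of up to three disjoint co-targeting groups; each entry
#'   has `mirnas`, `lncrnas`, `support`, `empiricalP`.
#' @slot log2fc data.frame of per-candidate log2 fold changes (fed vs
#'   unfed) per tissue, the heat-map table.
#'
#' @export
setClass("SpongeReport",
  representation(
    candidates = "data.frame",
    itemsets = "data.frame",
    groups = "list",
    log2fc = "data.frame"
  )
)

## ---- generics -------------------------------------------------------------

#' @export
setGeneric("transcripts", function(x, ...) standardGeneric("transcripts"))
#' @export
setGeneric("mirnaSet", function(x, ...) standardGeneric("mirnaSet"))
#' @export
setGeneric("referenceProteins", function(x, ...)
  standardGeneric("referenceProteins"))
#' @export
setGeneric("countData", function(x, ...) standardGeneric("countData"))
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))
#' @export
setGeneric("siteTable", function(x, ...) standardGeneric("siteTable"))
#' @export
setGeneric("targetCounts", function(x, ...) standardGeneric("targetCounts"))
#' @export
setGeneric("lncLengths", function(x, ...) standardGeneric("lncLengths"))
#' @export
setGeneric("candidateTable", function(x, ...) standardGeneric("candidateTable"))
#' @export
setGeneric("itemsetTable", function(x, ...) standardGeneric("itemsetTable"))
#' @export
setGeneric("spongeGroups", function(x, ...) standardGeneric("spongeGroups"))

#' @describeIn SpongeStudy-class Pooled transcript contigs.
#' @param x,object A `SpongeStudy`.
#' @param ... Ignored.
#' @export
setMethod("transcripts", "SpongeStudy", function(x, ...) x@transcripts)
#' @describeIn SpongeStudy-class Mature miRNA set.
#' @export
setMethod("mirnaSet", "SpongeStudy", function(x, ...) x@mirnas)
#' @describeIn SpongeStudy-class Reference proteins from planted ORFs.
#' @export
setMethod("referenceProteins", "SpongeStudy", function(x, ...) x@proteins)
#' @describeIn SpongeStudy-class The count SummarizedExperiment (or NULL).
#' @export
setMethod("countData", "SpongeStudy", function(x, ...) x@counts)
#' @describeIn SpongeStudy-class Ground-truth tables.
#' @export
setMethod("groundTruth", "SpongeStudy", function(x, ...) x@truth)

#' @describeIn TargetHits-class The per-site table.
#' @param x,object A `TargetHits`.
#' @param ... Ignored.
#' @export
setMethod("siteTable", "TargetHits", function(x, ...) x@sites)
#' @describeIn TargetHits-class Consensus-site count matrix (miRNA x lncRNA).
#' @export
setMethod("targetCounts", "TargetHits", function(x, ...) x@counts)
#' @describeIn TargetHits-class lncRNA lengths (nt).
#' @export
setMethod("lncLengths", "TargetHits", function(x, ...) x@lncLengths)

#' @describeIn SpongeReport-class Single-miRNA candidate table.
#' @param x,object A `SpongeReport`.
#' @param ... Ignored.
#' @export
setMethod("candidateTable", "SpongeReport", function(x, ...) x@candidates)
#' @describeIn SpongeReport-class Mined itemsets with significance.
#' @export
setMethod("itemsetTable", "SpongeReport", function(x, ...) x@itemsets)
#' @describeIn SpongeReport-class Disjoint co-targeting groups.
#' @export
setMethod("spongeGroups", "SpongeReport", function(x, ...) x@groups)

#' @describeIn SpongeStudy-class Compact display.
#' @export
setMethod("show", "SpongeStudy", function(object) {
  mc <- S4Vectors::mcols(object@transcripts)
  cat("SpongeStudy with", length(object@transcripts), "transcripts (",
      sum(mc$class == "coding"), "coding /",
      sum(mc$class == "noncoding"), "noncoding ),",
      length(object@mirnas), "miRNAs\n")
  if (!is.null(object@counts))
    cat("  counts:", nrow(object@counts), "x", ncol(object@counts),
        "expected-count matrix\n")
  if (nrow(object@truth$plantedSites))
    cat("  planted sponge sites:", nrow(object@truth$plantedSites), "\n")
})

#' @describeIn TargetHits-class Compact display.
#' @export
setMethod("show", "TargetHits", function(object) {
  cat("TargetHits:", nrow(object@sites), "sites (",
      sum(object@sites$consensus), "consensus ) over",
      nrow(object@counts), "miRNAs x", ncol(object@counts), "lncRNAs\n")
})

#' @describeIn SpongeReport-class Compact display.
#' @export
setMethod("show", "SpongeReport", function(object) {
  cat("SpongeReport:", nrow(object@candidates), "single-miRNA candidates,",
      nrow(object@itemsets), "itemsets,",
      length(object@groups), "disjoint co-targeting groups\n")
})
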