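#' Identity and coverage of a sequence pair
#'
#' Aligns the shorter sequence against the longer with a global-local
#' alignment (free end gaps on the longer sequence only; match +1,
#' mismatch -1, gap -2 per position). Identity is the fraction of matching
#' columns over the aligned span of the shorter sequence; coverage is the
#' fraction of the shorter sequence present in the alignment.
#'
#' @param a,b DNA sequences (character or [Biostrings::DNAString]).
#' @return Named numeric vector `c(identity =, coverage =)`.
#' @examples
#' pairwiseIdentity("ACGTACGT", "TTACGTACGTTT")
#' @export
pairwiseIdentity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  if (identical(a, b)) return(c(identity = 1, coverage = 1))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  alnPattern <- as.character(Biostrings::alignedPattern(aln))
  cols <- nchar(alnPattern)                # alignment columns (with gaps)
  ident <- Biostrings::nmatch(aln) / cols
  cov <- nchar(gsub("-", "", alnPattern, fixed = TRUE)) / nchar(a)
  c(identity = ident, coverage = cov)
}

#' Greedy incremental clustering of transcripts
#'
#' CD-HIT-style clustering: sequences are sorted by decreasing length (ties
#' by id, ascending) and processed in order. Each sequence joins the first
#' existing cluster whose *representative* it matches at
#' `identity >= idThr` and `coverage >= covThr` (membership is checked
#' against the representative only, as in the cited greedy algorithm);
#' otherwise it founds a new cluster and becomes its representative.
#'
#' A conservative shared-k-mer prefilter (k = 8) skips the alignment when
#' the number of k-mers the candidate shares with a representative cannot
#' reach `idThr`; the bound never rejects a pair that would pass.
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet]
#'   pooled across sources.
#' @param sources Optional character vector (recycled-checked) of source
#'   labels per sequence, same order as `sequences`.
#' @param idThr Identity threshold (default 0.98).
#' @param covThr Coverage-of-shorter threshold (default 0.80).
#' @param kmerFilter Use the k-mer prefilter (default `TRUE`).
#' @return A data.frame with one row per input sequence: `cluster`
#'   (integer id in representative-creation order), `transcript`, `source`,
#'   `length`, `representative` (id), `isRepresentative`.
#' @export
greedyCluster <- function(sequences, sources = NULL, idThr = 0.98,
                          covThr = 0.80, kmerFilter = TRUE) {
  seqs <- namedStrings(sequences)
  ids <- names(seqs)
  stopIfNot(!is.null(ids) && !anyDuplicated(ids),
            "sequences must have unique names")
  if (is.null(sources)) sources <- rep(NA_character_, length(seqs))
  stopIfNot(length(sources) == length(seqs),
            "'sources' must match 'sequences' in length")
  names(sources) <- ids
  ord <- order(-nchar(seqs), ids)
  seqs <- seqs[ord]
  k <- 8L
  repId <- character(0)
  repSeq <- character(0)
  repKmers <- list()
  assign_cluster <- integer(length(seqs))
  kmersOf <- function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
  }
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    Ls <- nchar(s)
    placed <- 0L
    myKmers <- if (kmerFilter) {
      if (Ls >= k) substring(s, seq_len(Ls - k + 1L),
                             seq_len(Ls - k + 1L) + k - 1L)
      else character(0)
    } else character(0)
    ## max columns that can fail identity while still passing the threshold
    maxBad <- ceiling((1 - idThr) * Ls * (1 + 1 / idThr))
    need <- (Ls - k + 1L) - k * maxBad
    for (j in seq_along(repId)) {
      if (kmerFilter && Ls >= k && need > 0L) {
        shared <- sum(myKmers %in% repKmers[[j]])
        if (shared < need) next
      }
      m <- pairwiseIdentity(s, repSeq[[j]])
      if (m[["identity"]] >= idThr && m[["coverage"]] >= covThr) {
        placed <- j
        break
      }
    }
    if (placed == 0L) {
      repId <- c(repId, names(seqs)[i])
      repSeq <- c(repSeq, s)
      repKmers[[length(repId)]] <- kmersOf(s)
      placed <- length(repId)
    }
    assign_cluster[i] <- placed
  }
  data.frame(
    cluster = assign_cluster,
    transcript = names(seqs),
    source = unname(sources[names(seqs)]),
    length = nchar(seqs),
    representative = repId[assign_cluster],
    isRepresentative = names(seqs) == repId[assign_cluster],
    stringsAsFactors = FALSE)
}

#' Select consensus representatives across sources
#'
#' A cluster is retained when its members include at least one transcript
#' from the primary source (`MG_SG`, the most stringently filtered set) and
#' at least one from any of the secondary sources (`SG`, `WB`). The
#' consensus sequence of a retained cluster is its longest member (ties by
#' id, ascending); set `requirePrimaryRepresentative = TRUE` to restrict the
#' representative to primary-source members instead.
#'
#' @param clusterTable Output of [greedyCluster()] (needs columns `cluster`,
#'   `transcript`, `source`, `length`).
#' @param primarySource Source label that must be present (default
#'   `"MG_SG"`).
#' @param secondarySources Labels of which at least one must also be present
#'   (default `c("SG", "WB")`).
#' @param requirePrimaryRepresentative Restrict the consensus representative
#'   to primary-source members (default `FALSE`: longest member of any
#'   source).
#' @return A data.frame with one row per cluster: `cluster`, `consensus`
#'   (representative transcript id), `length`, `nPrimary`, `nSecondary`,
#'   `retained`. The consensus set is the retained rows.
#' @export
selectConsensus <- function(clusterTable, primarySource = "MG_SG",
                            secondarySources = c("SG", "WB"),
                            requirePrimaryRepresentative = FALSE) {
  stopIfNot(all(c("cluster", "transcript", "source", "length") %in%
                  colnames(clusterTable)),
            "clusterTable lacks required columns")
  out <- lapply(split(clusterTable, clusterTable$cluster), function(cl) {
    nP <- sum(cl$source %in% primarySource)
    nS <- sum(cl$source %in% secondarySources)
    retained <- nP >= 1L && nS >= 1L
    pool <- if (requirePrimaryRepresentative && nP >= 1L)
      cl[cl$source %in% primarySource, , drop = FALSE] else cl
    pool <- pool[order(-pool$length, pool$transcript), , drop = FALSE]
    data.frame(cluster = cl$cluster[1], consensus = pool$transcript[1],
               length = pool$length[1], nPrimary = nP, nSecondary = nS,
               retained = retained, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}
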