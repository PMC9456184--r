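## miRNA target prediction: seed matching plus a hybridization-score
## filter, and the shuffled-sequence null model.

SITE_TYPE_RANK <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L,
                    "8mer" = 4L)
SITE_TYPE_LEN <- c("6mer" = 6L, "7mer-A1" = 7L, "7mer-m8" = 7L,
                   "8mer" = 8L)

#' Find miRNA seed-match sites on a lncRNA
#'
#' Scans the sense strand of the lncRNA for exact reverse complements of
#' the miRNA seed (positions 2-7; 6mer core) and classifies each anchor
#' upward: complementarity extending through miRNA position 8 gives
#' `7mer-m8`, an `A` on the target opposite miRNA position 1 gives
#' `7mer-A1`, and both give `8mer`. Overlapping sites at distinct starts
#' are all reported; `U`/`T` are equivalent; `N` never matches.
#'
#' @param mirna Mature miRNA sequence (RNA or DNA alphabet, length >= 8).
#' @param lncrna lncRNA sequence (DNA alphabet).
#' @return data.frame with 0-based `start` (5' end of the site on the
#'   lncRNA), `siteType` and `length`.
#' @examples
#' m <- "UAGCAGCACGUAAAUAUUGGCG"
#' site <- paste0(as.character(
#'   Biostrings::reverseComplement(Biostrings::DNAString("AGCAGCA"))), "A")
#' findSeedSites(m, paste0("CCCCC", site, "CCCCC"))
#' @export
findSeedSites <- function(mirna, lncrna) {
  m <- toupper(chartr("U", "T", as.character(mirna)))
  stopIfNot(nchar(m) >= 8L, "miRNA must be at least 8 nt")
  s <- toupper(chartr("U", "T", as.character(lncrna)))
  L <- nchar(s)
  core <- revcompDna(substr(m, 2L, 7L))            # 6mer match
  empty <- data.frame(start = integer(0), siteType = character(0),
                      length = integer(0))
  if (L < 6L) return(empty)
  hits <- gregexprAll(core, s)                     # 0-based anchors
  if (!length(hits)) return(empty)
  p8 <- DNA_COMPLEMENT[[substr(m, 8L, 8L)]]        # target base pairing m8
  res <- lapply(hits, function(a) {
    hasM8 <- a > 0L && substr(s, a, a) == p8
    hasA1 <- a + 6L < L && substr(s, a + 7L, a + 7L) == "A"
    type <- if (hasM8 && hasA1) "8mer"
            else if (hasM8) "7mer-m8"
            else if (hasA1) "7mer-A1"
            else "6mer"
    start <- if (hasM8) a - 1L else a
    data.frame(start = start, siteType = type,
               length = SITE_TYPE_LEN[[type]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## All 0-based start positions of fixed pattern `pat` in `s`, overlapping.
gregexprAll <- function(pat, s) {
  hits <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)
    if (i == -1L) break
    at <- from + i - 1L
    hits <- c(hits, at - 1L)
    from <- at + 1L
  }
  hits
}

#' Hybridization score of a miRNA against a lncRNA window
#'
#' Local alignment (Smith-Waterman with affine gaps) of the full miRNA,
#' taken 3' to 5', against the window read 5' to 3', scoring antiparallel
#' base pairs: Watson-Crick +5, G:U wobble +2, mismatch -3; gap open -8,
#' gap extend -2 (a length-k gap costs 8 + 2(k-1)). Pair scores at miRNA
#' seed positions 2-8 are doubled. Scores below zero are reported as 0.
#'
#' @param mirna Mature miRNA (RNA or DNA alphabet), 5' to 3'.
#' @param lncrnaWindow Target window (DNA), 5' to 3'.
#' @return Best local alignment score (numeric, >= 0).
#' @export
hybridScore <- function(mirna, lncrnaWindow) {
  m <- toupper(chartr("T", "U", as.character(mirna)))
  w <- toupper(chartr("U", "T", as.character(lncrnaWindow)))
  M <- nchar(m); W <- nchar(w)
  if (M == 0L || W == 0L) return(0)
  mc <- rev(strsplit(m, "")[[1]])                 # 3' -> 5'
  pos <- rev(seq_len(M))                          # miRNA position per row
  wc <- strsplit(w, "")[[1]]
  pairScore <- function(mb, tb, p) {
    wcPair <- (mb == "A" && tb == "T") || (mb == "U" && tb == "A") ||
              (mb == "G" && tb == "C") || (mb == "C" && tb == "G")
    gu <- (mb == "G" && tb == "T") || (mb == "U" && tb == "G")
    s <- if (wcPair) 5 else if (gu) 2 else -3
    if (s > 0 && p >= 2L && p <= 8L) s <- s * 2
    s
  }
  S <- matrix(0, M, W)
  for (i in seq_len(M))
    for (j in seq_len(W))
      S[i, j] <- pairScore(mc[i], wc[j], pos[i])
  GO <- -8; GE <- -2
  H <- matrix(0, M + 1L, W + 1L)
  E <- matrix(-Inf, M + 1L, W + 1L)
  F <- matrix(-Inf, M + 1L, W + 1L)
  best <- 0
  for (i in 2:(M + 1L)) {
    for (j in 2:(W + 1L)) {
      E[i, j] <- max(H[i, j - 1L] + GO, E[i, j - 1L] + GE)
      F[i, j] <- max(H[i - 1L, j] + GO, F[i - 1L, j] + GE)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + S[i - 1L, j - 1L],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

#' Predict consensus miRNA target sites on lncRNAs
#'
#' Two-stage consensus: the seed stage reports exact seed matches
#' ([findSeedSites()]) and the hybridization stage scores each site's
#' surrounding window ([hybridScore()]); a site is a consensus site when
#' its type reaches `minSiteType` and its hybridization score reaches
#' `minHybridScore`. The scored window is the site plus `windowFlank`
#' nucleotides 5'-ward on the lncRNA (where the miRNA 3' region can pair).
#'
#' @param mirnas Named [Biostrings::RNAStringSet] or character vector.
#' @param lncrnas Named [Biostrings::DNAStringSet] or character vector.
#' @param minSiteType Minimum site class for consensus: `"6mer"`, `"7mer"`
#'   (default; admits 7mer-A1, 7mer-m8 and 8mer) or `"8mer"`.
#' @param minHybridScore Hybridization-score cutoff (default 70, the score
#'   of a perfectly paired seed).
#' @param windowFlank Window extension in nt (default 30).
#' @return A [TargetHits-class]: per-site table and consensus-count matrix
#'   (miRNAs x lncRNAs).
#' @export
predictTargets <- function(mirnas, lncrnas, minSiteType = "7mer",
                           minHybridScore = 70, windowFlank = 30L) {
  mir <- namedStrings(mirnas)
  lnc <- namedStrings(lncrnas, dna = TRUE)
  if (is.null(names(mir))) names(mir) <- sprintf("mir-%03d", seq_along(mir))
  if (is.null(names(lnc))) names(lnc) <- sprintf("lnc%03d", seq_along(lnc))
  minRank <- switch(minSiteType, "6mer" = 1L, "7mer" = 2L, "8mer" = 4L,
                    stop("unknown minSiteType: ", minSiteType))
  counts <- matrix(0L, nrow = length(mir), ncol = length(lnc),
                   dimnames = list(names(mir), names(lnc)))
  lens <- setNames(nchar(lnc), names(lnc))
  if (length(mir) == 0L || length(lnc) == 0L) {
    warning("empty miRNA or lncRNA set: no targets predicted")
    return(methods::new("TargetHits",
      sites = S4Vectors::DataFrame(lncrna = character(0),
                                   mirna = character(0),
                                   start = integer(0),
                                   siteType = character(0),
                                   hybridScore = numeric(0),
                                   consensus = logical(0)),
      counts = counts, lncLengths = lens,
      params = list(minSiteType = minSiteType,
                    minHybridScore = minHybridScore,
                    windowFlank = windowFlank)))
  }
  rows <- list()
  for (mi in names(mir)) {
    for (li in names(lnc)) {
      s <- findSeedSites(mir[[mi]], lnc[[li]])
      if (!nrow(s)) next
      hs <- vapply(seq_len(nrow(s)), function(k) {
        from <- max(0L, s$start[k] - windowFlank)
        to <- s$start[k] + s$length[k]            # half-open
        hybridScore(mir[[mi]], substr(lnc[[li]], from + 1L, to))
      }, numeric(1))
      cons <- SITE_TYPE_RANK[s$siteType] >= minRank & hs >= minHybridScore
      counts[mi, li] <- sum(cons)
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna = li, mirna = mi, start = s$start, siteType = s$siteType,
        hybridScore = hs, consensus = unname(cons),
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows)
           else data.frame(lncrna = character(0), mirna = character(0),
                           start = integer(0), siteType = character(0),
                           hybridScore = numeric(0), consensus = logical(0))
  methods::new("TargetHits",
    sites = S4Vectors::DataFrame(sites),
    counts = counts, lncLengths = lens,
    params = list(minSiteType = minSiteType,
                  minHybridScore = minHybridScore,
                  windowFlank = windowFlank))
}

#' Shuffled-sequence null target counts
#'
#' For each replicate, every lncRNA is shuffled ([shuffleSequence()], with
#' a replicate- and sequence-indexed seed) and target prediction is re-run
#' with identical parameters; the consensus-count matrices form the null
#' distribution for sponge scoring.
#'
#' @param lncrnas Named character vector or [Biostrings::DNAStringSet].
#' @param mirnas Named character vector or [Biostrings::RNAStringSet].
#' @param nReplicates Number of null replicates (>= 1).
#' @param seed Master seed.
#' @param mode Shuffle mode, `"mono"` (default) or `"di"`.
#' @param ... Passed to [predictTargets()].
#' @return List of `nReplicates` count matrices (miRNAs x lncRNAs).
#' @export
buildNull <- function(lncrnas, mirnas, nReplicates = 19L, seed = 1L,
                      mode = "mono", ...) {
  stopIfNot(nReplicates >= 1L, "'nReplicates' must be at least 1")
  lnc <- namedStrings(lncrnas, dna = TRUE)
  if (is.null(names(lnc))) names(lnc) <- sprintf("lnc%03d", seq_along(lnc))
  lapply(seq_len(nReplicates), function(r) {
    shuffled <- vapply(seq_along(lnc), function(i)
      shuffleSequence(lnc[[i]], seed = deriveSeed(seed, r * 10000L + i),
                      mode = mode), character(1))
    names(shuffled) <- names(lnc)
    suppressWarnings(targetCounts(predictTargets(mirnas, shuffled, ...)))
  })
}
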