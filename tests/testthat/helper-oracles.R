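## Independent oracles used to validate the package's implementations.
## Each oracle deliberately takes a different computational route from the
## code under test.

## Six-frame ORF scan via regex on translated frames.
bruteForceOrfs <- function(seq, minAa = 50L) {
  seq <- toupper(seq)
  L <- nchar(seq)
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  gc <- Biostrings::GENETIC_CODE
  out <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") seq else rc
    for (f in 0:2) {
      ncod <- (nchar(ss) - f) %/% 3L
      if (ncod < 2L) next
      starts <- f + 1L + 3L * (0:(ncod - 1L))
      prot <- paste(gc[substring(ss, starts, starts + 2L)], collapse = "")
      ## every M .. first * afterwards
      for (mm in gregexpr("M", prot, fixed = TRUE)[[1]]) {
        if (mm < 0) next
        rest <- substr(prot, mm, nchar(prot))
        st <- regexpr("*", rest, fixed = TRUE)
        if (st < 0) next
        aa <- st - 1L
        if (aa <= minAa) next
        i <- mm; j <- mm + st - 1L     # codon indices of ATG and stop
        s0 <- (i - 1L) * 3L + f
        e0 <- j * 3L + f
        if (strand == "+") { fs <- s0; fe <- e0 }
        else { fs <- L - e0; fe <- L - s0 }
        out[[length(out) + 1L]] <- data.frame(
          strand = strand, start = fs, end = fe, aaLength = aa,
          protein = substr(rest, 1L, aa), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), aaLength = integer(0),
                      protein = character(0)))
  do.call(rbind, out)
}

## Position-by-position seed-site scan.
naiveSeedScan <- function(mirna, lncrna) {
  m <- chartr("U", "T", toupper(mirna))
  s <- chartr("U", "T", toupper(lncrna))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  mch <- strsplit(m, "")[[1]]
  sch <- strsplit(s, "")[[1]]
  L <- length(sch)
  out <- list()
  for (a in 0:(L - 6L)) {                      # 0-based anchor of the 6mer
    ok <- TRUE
    for (k in 1:6) {                           # miRNA positions 2..7
      ## antiparallel: miRNA position p pairs target index a + (8 - p)
      p <- k + 1L
      tpos <- a + (7L - p)                     # 0-based
      if (sch[tpos + 1L] != comp[[mch[p]]]) { ok <- FALSE; break }
    }
    if (!ok) next
    hasM8 <- a - 1L >= 0L && sch[a] == comp[[mch[8]]]
    hasA1 <- a + 6L <= L - 1L && sch[a + 7L] == "A"
    type <- if (hasM8 && hasA1) "8mer" else if (hasM8) "7mer-m8" else
            if (hasA1) "7mer-A1" else "6mer"
    out[[length(out) + 1L]] <- data.frame(
      start = if (hasM8) a - 1L else a, siteType = type,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(0), siteType = character(0)))
  do.call(rbind, out)
}

## Exhaustive frequent-itemset enumeration over all miRNA subsets.
enumerateItemsets <- function(countMatrix, minSupport, minSize = 2L) {
  bin <- countMatrix >= 1
  items <- sort(rownames(bin))
  out <- list()
  for (k in minSize:length(items)) {
    sets <- utils::combn(items, k, simplify = FALSE)
    for (it in sets) {
      supp <- sum(colSums(bin[it, , drop = FALSE]) == length(it))
      if (supp >= minSupport)
        out[[length(out) + 1L]] <- list(itemset = paste(it, collapse = "+"),
                                        support = supp)
    }
  }
  if (!length(out))
    return(data.frame(itemset = character(0), support = integer(0)))
  data.frame(itemset = vapply(out, `[[`, character(1), "itemset"),
             support = vapply(out, `[[`, integer(1), "support"),
             stringsAsFactors = FALSE)
}

## Step-by-step trimmed-mean TMM evaluation (sort, trim, weight, average).
tmmOracle <- function(counts, logratioTrim = 0.30, sumTrim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    keep <- counts[, j] > 0 & counts[, ref] > 0
    o <- counts[keep, j]; r <- counts[keep, ref]
    M <- log2(o / lib[j]) - log2(r / lib[ref])
    A <- 0.5 * (log2(o / lib[j]) + log2(r / lib[ref]))
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    w <- 1 / ((lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r))
    n <- length(M)
    loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
    sel <- rank(M) >= loM & rank(M) <= hiM &
           rank(A) >= loA & rank(A) <= hiA
    f[j] <- 2^(sum((M * w)[sel]) / sum(w[sel]))
  }
  f / exp(mean(log(f)))
}

## Hand-evaluated Benjamini-Hochberg step-up.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## Dinucleotide count vector over the 16 dinucleotides.
dinucCounts <- function(s) {
  di <- substring(s, 1:(nchar(s) - 1L), 2:nchar(s))
  alph <- c("A", "C", "G", "T")
  all16 <- as.vector(outer(alph, alph, paste0))
  table(factor(di, levels = all16))
}

## Adjusted Rand index between two labelings.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- ai * bj / n2
  (nij - exp_) / ((ai + bj) / 2 - exp_)
}

randomDnaStr <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

revcompOracle <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
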