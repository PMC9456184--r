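## Synthetic-data module: generates every input the pipeline consumes with
## known ground truth, emulating a three-source transcriptome study
## (a stringently filtered midgut+salivary-gland set, a salivary-gland set
## and a whole-body set) with planted clusters, ORFs, fold changes and
## miRNA seed-site clusters.

STOP_CODONS <- c("TAA", "TAG", "TGA")
SIM_SOURCES <- c("MG_SG", "SG", "WB")

#' Build a validated simulation configuration
#'
#' The defaults define the study conditions used throughout the package's
#' validation: 60 true transcript clusters over three overlapping sources,
#' about a third coding, near-identical within-cluster copies (0.5%
#' substitution rate, i.e. about 1% divergence between two copies), negative-binomial counts with dispersion 0.1 and a
#' quarter of clusters differentially expressed at |log2FC| = 2 between
#' unfed and fed ticks, 20 host miRNAs, and a sponge plan with three
#' disjoint three-miRNA co-targeting groups plus one high-count sponge.
#'
#' @param seed Master RNG seed.
#' @param nClusters Number of true transcript clusters.
#' @param pCoding Fraction of clusters that are coding.
#' @param sourcePresence Probability of a cluster appearing in each source;
#'   scalar or named vector over `MG_SG`, `SG`, `WB`.
#' @param lengthRange Transcript length bounds (nt), within `[100, 5000]`.
#' @param mutationRate Per-base substitution rate between same-cluster
#'   copies.
#' @param nSamplesPerGroup Replicates per (tissue, condition) group.
#' @param dispersion Negative-binomial dispersion (0 gives Poisson counts).
#' @param deFraction,deLog2fc Fraction of clusters with planted
#'   differential expression and the planted |log2 fold change|.
#' @param nMirnas Number of mature miRNAs to generate.
#' @param spongePlan List of entries `list(lncrna =, mirnas =, nSites =)`:
#'   `lncrna` indexes the noncoding clusters in order, `mirnas` indexes the
#'   miRNA set, and `nSites` seed sites are planted per miRNA. `NULL` uses
#'   the default plan described above; `list()` plants nothing.
#' @return A validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(seed = 1L, nClusters = 60L, pCoding = 0.35,
                             sourcePresence = c(MG_SG = 0.75, SG = 0.6,
                                                WB = 0.5),
                             lengthRange = c(200L, 1200L),
                             mutationRate = 0.005, nSamplesPerGroup = 5L,
                             dispersion = 0.1, deFraction = 0.25,
                             deLog2fc = 2, nMirnas = 20L,
                             spongePlan = NULL) {
  if (length(sourcePresence) == 1L)
    sourcePresence <- setNames(rep(sourcePresence, 3L), SIM_SOURCES)
  stopIfNot(all(sourcePresence >= 0 & sourcePresence <= 1),
            "source presence probabilities must lie in [0, 1]")
  stopIfNot(pCoding >= 0 && pCoding <= 1, "'pCoding' must lie in [0, 1]")
  stopIfNot(deFraction >= 0 && deFraction <= 1,
            "'deFraction' must lie in [0, 1]")
  stopIfNot(length(lengthRange) == 2L && lengthRange[1] >= 100 &&
              lengthRange[2] <= 5000 && lengthRange[1] <= lengthRange[2],
            "'lengthRange' must lie within [100, 5000]")
  stopIfNot(mutationRate >= 0 && mutationRate < 1,
            "'mutationRate' must lie in [0, 1)")
  stopIfNot(nClusters >= 0, "'nClusters' must be non-negative")
  stopIfNot(dispersion >= 0, "'dispersion' must be non-negative")
  if (is.null(spongePlan)) spongePlan <- defaultSpongePlan()
  for (e in spongePlan) {
    stopIfNot(all(c("lncrna", "mirnas", "nSites") %in% names(e)),
              "sponge plan entries need fields lncrna, mirnas, nSites")
    stopIfNot(all(e$nSites >= 0), "nSites must be non-negative")
  }
  structure(list(seed = as.integer(seed), nClusters = as.integer(nClusters),
                 pCoding = pCoding, sourcePresence = sourcePresence,
                 lengthRange = as.integer(lengthRange),
                 mutationRate = mutationRate,
                 nSamplesPerGroup = as.integer(nSamplesPerGroup),
                 dispersion = dispersion, deFraction = deFraction,
                 deLog2fc = deLog2fc, nMirnas = as.integer(nMirnas),
                 spongePlan = spongePlan),
            class = "SimulationConfig")
}

## Three disjoint three-miRNA co-targeting groups + one high-count sponge.
defaultSpongePlan <- function() {
  plan <- list()
  for (g in 0:2) {
    for (l in 1:3) {
      plan[[length(plan) + 1L]] <- list(lncrna = g * 3L + l,
                                        mirnas = g * 3L + 1:3,
                                        nSites = 3L)
    }
  }
  plan[[length(plan) + 1L]] <- list(lncrna = 10L, mirnas = 10L,
                                    nSites = 10L)
  plan
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

randomMirnas <- function(n, len = 22L) {
  if (n == 0L) return(Biostrings::RNAStringSet())
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
          collapse = ""), character(1))
  out <- Biostrings::RNAStringSet(seqs)
  names(out) <- sprintf("mir-%03d", seq_len(n))
  out
}

## Random non-stop codons for planted ORF bodies.
randomCodons <- function(n) {
  all <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                               paste0), c("A", "C", "G", "T"), paste0))
  pool <- setdiff(all, STOP_CODONS)
  sample(pool, n, replace = TRUE)
}

#' Plant miRNA seed sites into lncRNA sequences
#'
#' For each plan entry, writes `nSites` exact 8mer-type seed sites (the
#' reverse complement of miRNA positions 2-8 followed by an `A` opposite
#' miRNA position 1) at non-overlapping, uniformly drawn positions of the
#' lncRNA. Positions are drawn by the order-statistics construction, so
#' planting always succeeds when the sites fit.
#'
#' @param lncrnas Named character vector or [Biostrings::DNAStringSet].
#' @param mirnas Named character vector or [Biostrings::RNAStringSet] of
#'   mature miRNAs (length >= 8).
#' @param spongePlan List of `list(lncrna =, mirnas =, nSites =)`; entries
#'   may index by position or name into `lncrnas` / `mirnas`.
#' @param seed Integer seed.
#' @return `list(sequences = , sites = )`: the modified sequences (same
#'   type as input order) and a data.frame of planted sites with 0-based
#'   `start` and `siteType = "8mer"`.
#' @export
plantSpongeSites <- function(lncrnas, mirnas, spongePlan, seed) {
  seqs <- namedStrings(lncrnas)
  mir <- namedStrings(mirnas, dna = TRUE)
  stopIfNot(!is.null(names(seqs)), "lncRNAs must be named")
  if (is.null(names(mir))) names(mir) <- sprintf("mir-%03d", seq_along(mir))
  resolve <- function(key, pool) {
    if (is.numeric(key)) names(pool)[key] else as.character(key)
  }
  ## gather per-lncRNA motif lists
  perLnc <- list()
  for (e in spongePlan) {
    lid <- resolve(e$lncrna, seqs)
    if (is.na(lid) || !lid %in% names(seqs))
      stop("sponge plan references unknown lncRNA: ", e$lncrna)
    mids <- vapply(e$mirnas, resolve, character(1), pool = mir)
    nS <- rep(e$nSites, length.out = length(mids))
    for (k in seq_along(mids)) {
      m <- mir[[mids[k]]]
      stopIfNot(nchar(m) >= 8L, "miRNA shorter than 8 nt")
      motif <- paste0(revcompDna(substr(m, 2L, 8L)), "A")
      perLnc[[lid]] <- rbind(perLnc[[lid]],
        data.frame(mirna = mids[k], motif = motif,
                   n = as.integer(nS[k]), stringsAsFactors = FALSE))
    }
  }
  sites <- list()
  withSeed(seed, {
    for (lid in names(perLnc)) {
      tab <- perLnc[[lid]]
      motifs <- rep(tab$motif, tab$n)
      mirIds <- rep(tab$mirna, tab$n)
      n <- length(motifs)
      if (n == 0L) next
      L <- nchar(seqs[[lid]])
      m <- nchar(motifs[1])
      if (n * m > L)
        stop("lncRNA ", lid, " too short (", L, " nt) for ", n,
             " planted sites of ", m, " nt")
      gaps <- sort(sample.int(L - n * m + 1L, n, replace = TRUE)) - 1L
      starts <- gaps + (seq_len(n) - 1L) * m        # 0-based
      ord <- sample.int(n)                           # random assignment
      s <- seqs[[lid]]
      for (k in seq_len(n)) {
        at <- starts[k]
        substr(s, at + 1L, at + m) <- motifs[ord[k]]
      }
      seqs[[lid]] <- s
      sites[[length(sites) + 1L]] <- data.frame(
        lncrna = lid, mirna = mirIds[ord], start = starts,
        siteType = "8mer", stringsAsFactors = FALSE)
    }
  })
  sites <- if (length(sites)) do.call(rbind, sites)
           else data.frame(lncrna = character(0), mirna = character(0),
                           start = integer(0), siteType = character(0))
  list(sequences = seqs, sites = sites)
}

## Substitute bases at rate `rate`, never touching `protect`ed positions;
## inside a planted ORF body, substitutions that would create an in-frame
## stop codon are reverted.
mutateCopy <- function(base, rate, protect = NULL, orf = NULL) {
  L <- nchar(base)
  if (rate <= 0) return(base)
  pos <- which(stats::runif(L) < rate)
  if (!is.null(protect)) pos <- pos[!protect[pos]]
  if (!length(pos)) return(base)
  chars <- strsplit(base, "")[[1]]
  alts <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(alts, chars[p]), 1L)
  }
  if (!is.null(orf)) {
    body <- seq(orf$start + 4L, orf$end - 3L)   # 1-based, excludes ATG/stop
    touched <- intersect(pos, body)
    if (length(touched)) {
      codStart <- orf$start + 1L + 3L * ((touched - orf$start - 1L) %/% 3L)
      for (cs in unique(codStart)) {
        cod <- paste(chars[cs:(cs + 2L)], collapse = "")
        if (cod %in% STOP_CODONS) {
          orig <- substring(base, cs, cs + 2L)
          chars[cs:(cs + 2L)] <- strsplit(orig, "")[[1]]
        }
      }
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a three-source transcriptome study with ground truth
#'
#' Generates miRNAs, true transcript clusters (coding clusters carry a
#' planted forward-frame ORF whose translation is added to the reference
#' protein set; noncoding clusters are rejection-sampled to contain no ORF
#' of 50+ amino acids in any frame), plants miRNA seed-site clusters into
#' the noncoding clusters named by the sponge plan, and emits near-identical
#' copies of each cluster into the sources where it is present. Planted
#' seed sites and ORF boundaries are shielded from the substitution process
#' so that every copy carries the planted structure intact.
#'
#' Clusters referenced by the sponge plan are forced to be present in the
#' primary source and one secondary source, so that planted sponges survive
#' consensus selection.
#'
#' @param config A [simulationConfig()].
#' @return A [SpongeStudy-class] (without counts; see [simulateCounts()]).
#' @export
simulateTranscriptomes <- function(config) {
  stopIfNot(inherits(config, "SimulationConfig"),
            "'config' must come from simulationConfig()")
  nC <- config$nClusters
  mirnas <- withSeed(deriveSeed(config$seed, 11L),
                     randomMirnas(config$nMirnas))
  empty <- function() {
    tx <- Biostrings::DNAStringSet()
    S4Vectors::mcols(tx) <- S4Vectors::DataFrame(
      source = character(0), class = character(0), cluster = integer(0))
    methods::new("SpongeStudy", transcripts = tx, mirnas = mirnas,
                 proteins = Biostrings::AAStringSet(), counts = NULL,
                 truth = list(
                   deTable = data.frame(transcript = character(0),
                                        trueLog2FC = numeric(0),
                                        isDE = logical(0)),
                   plantedSites = data.frame(lncrna = character(0),
                                             mirna = character(0),
                                             start = integer(0),
                                             siteType = character(0))))
  }
  if (nC == 0L) return(empty())
  withSeed(deriveSeed(config$seed, 23L), {
    isCoding <- stats::runif(nC) < config$pCoding
    noncodingIdx <- which(!isCoding)
    planClusters <- integer(0)
    if (length(config$spongePlan)) {
      wanted <- max(vapply(config$spongePlan,
                           function(e) max(as.integer(e$lncrna)), 1L))
      if (wanted > length(noncodingIdx)) {
        ## promote trailing coding clusters to noncoding to honour the plan
        short <- wanted - length(noncodingIdx)
        flip <- utils::tail(which(isCoding), short)
        isCoding[flip] <- FALSE
        noncodingIdx <- which(!isCoding)
      }
      planClusters <- noncodingIdx[vapply(config$spongePlan,
        function(e) as.integer(e$lncrna), 1L)]
    }
    lens <- round(stats::runif(nC, config$lengthRange[1],
                               config$lengthRange[2]))
    ## sponge clusters need room for their sites
    if (length(planClusters)) {
      siteLoad <- tapply(
        vapply(config$spongePlan, function(e)
          sum(rep(e$nSites, length.out = length(e$mirnas))) * 8L, 1L),
        planClusters, sum)
      for (nm in names(siteLoad)) {
        cl <- as.integer(nm)
        lens[cl] <- max(lens[cl], 4L * siteLoad[[nm]])
      }
    }
    baseSeq <- character(nC)
    orfInfo <- vector("list", nC)
    proteins <- character(0)
    for (cl in seq_len(nC)) {
      L <- lens[cl]
      if (isCoding[cl]) {
        maxAa <- (L - 12L) %/% 3L - 1L
        stopIfNot(maxAa > 51L, "coding cluster length too short for an ORF")
        aa <- sample(52L:min(120L, maxAa), 1L)
        orfNt <- 3L * (aa + 1L)
        start0 <- 3L * sample.int((L - orfNt) %/% 3L, 1L)  # frame 0
        body <- randomCodons(aa - 1L)
        orf <- paste0("ATG", paste(body, collapse = ""),
                      sample(STOP_CODONS, 1L))
        s <- randomDna(L)
        substr(s, start0 + 1L, start0 + orfNt) <- orf
        baseSeq[cl] <- s
        orfInfo[[cl]] <- list(start = start0, end = start0 + orfNt)
        prot <- paste0("M", paste(GENETIC_CODE_TABLE[body], collapse = ""))
        proteins[sprintf("cl%03d_prot", cl)] <- prot
      } else {
        ok <- FALSE
        for (try in seq_len(500L)) {
          s <- randomDna(L)
          if (!hasOrfOfLength(s, 50L)) { ok <- TRUE; break }
        }
        if (!ok)
          stop("could not generate an ORF-free noncoding cluster ", cl,
               " after 500 attempts")
        baseSeq[cl] <- s
      }
    }
    names(baseSeq) <- sprintf("cl%03d", seq_len(nC))
    ## plant sponge sites into the named noncoding clusters
    plantedBase <- data.frame(lncrna = character(0), mirna = character(0),
                              start = integer(0), siteType = character(0))
    if (length(config$spongePlan)) {
      planByCluster <- lapply(seq_along(config$spongePlan), function(i) {
        e <- config$spongePlan[[i]]
        list(lncrna = sprintf("cl%03d", planClusters[i]),
             mirnas = e$mirnas, nSites = e$nSites)
      })
      pl <- plantSpongeSites(baseSeq, mirnas, planByCluster,
                             seed = deriveSeed(config$seed, 37L))
      for (i in seq_len(500L)) {
        plantedIds <- unique(pl$sites$lncrna)
        bad <- plantedIds[vapply(plantedIds, function(id)
          hasOrfOfLength(pl$sequences[[id]], 50L), logical(1))]
        if (!length(bad)) break
        ## regenerate ORF-free backgrounds for violators and replant
        for (id in bad) {
          repeat {
            s <- randomDna(nchar(baseSeq[[id]]))
            if (!hasOrfOfLength(s, 50L)) break
          }
          baseSeq[[id]] <- s
        }
        pl <- plantSpongeSites(baseSeq, mirnas, planByCluster,
                               seed = deriveSeed(config$seed, 37L + i))
      }
      baseSeq[names(pl$sequences)] <- pl$sequences
      plantedBase <- pl$sites
    }
    ## presence per source, with forced presence for sponge clusters
    pres <- matrix(stats::runif(nC * 3L) <
                     rep(config$sourcePresence, each = nC),
                   nrow = nC, dimnames = list(NULL, SIM_SOURCES))
    pres[planClusters, "MG_SG"] <- TRUE
    pres[planClusters, "SG"] <- TRUE
    ## emit copies
    ids <- character(0); seqs <- character(0)
    src <- character(0); clu <- integer(0)
    protectOf <- function(cl) {
      L <- nchar(baseSeq[[cl]])
      p <- rep(FALSE, L)
      nm <- sprintf("cl%03d", cl)
      ps <- plantedBase[plantedBase$lncrna == nm, , drop = FALSE]
      if (nrow(ps))
        for (k in seq_len(nrow(ps)))
          p[(ps$start[k] + 1L):(ps$start[k] + 8L)] <- TRUE
      if (!is.null(orfInfo[[cl]])) {
        o <- orfInfo[[cl]]
        p[(o$start + 1L):(o$start + 3L)] <- TRUE
        p[(o$end - 2L):o$end] <- TRUE
      }
      p
    }
    for (cl in seq_len(nC)) {
      prot <- protectOf(cl)
      for (s in SIM_SOURCES) {
        if (!pres[cl, s]) next
        cp <- mutateCopy(baseSeq[[cl]], config$mutationRate, prot,
                         orfInfo[[cl]])
        ids <- c(ids, sprintf("cl%03d_%s", cl, s))
        seqs <- c(seqs, cp)
        src <- c(src, s)
        clu <- c(clu, cl)
      }
    }
    tx <- Biostrings::DNAStringSet(seqs)
    names(tx) <- ids
    S4Vectors::mcols(tx) <- S4Vectors::DataFrame(
      source = src,
      class = ifelse(isCoding[clu], "coding", "noncoding"),
      cluster = clu)
    ## expand planted sites to every emitted copy of the cluster
    planted <- plantedBase
    if (nrow(plantedBase)) {
      rows <- lapply(seq_len(nrow(plantedBase)), function(k) {
        clName <- plantedBase$lncrna[k]
        copies <- ids[clu == as.integer(sub("^cl", "", clName))]
        if (!length(copies)) return(NULL)
        data.frame(lncrna = copies, mirna = plantedBase$mirna[k],
                   start = plantedBase$start[k], siteType = "8mer",
                   cluster = clName, stringsAsFactors = FALSE)
      })
      planted <- do.call(rbind, rows)
    } else {
      planted$cluster <- character(0)
    }
    prots <- Biostrings::AAStringSet(proteins)
    methods::new("SpongeStudy", transcripts = tx, mirnas = mirnas,
                 proteins = prots, counts = NULL,
                 truth = list(
                   deTable = data.frame(transcript = character(0),
                                        trueLog2FC = numeric(0),
                                        isDE = logical(0)),
                   plantedSites = planted))
  })
}

#' Simulate negative-binomial expected counts with planted fold changes
#'
#' Draws per-sample expected counts for every transcript of a study under a
#' two-tissue (midgut, salivary gland), two-condition (unfed, fed) design
#' with `nSamplesPerGroup` replicates per group. A `deFraction` of clusters
#' receives a planted fed/unfed log2 fold change of `+/- deLog2fc` (random
#' sign, shared by both tissues and all copies of the cluster). Library
#' sizes vary by a per-sample factor drawn log-uniformly in `[0.5, 2]`.
#'
#' @param study A [SpongeStudy-class] from [simulateTranscriptomes()].
#' @param config The same [simulationConfig()].
#' @return The study with its `counts` slot filled by a
#'   [SummarizedExperiment::SummarizedExperiment] and `truth$deTable`
#'   populated.
#' @export
simulateCounts <- function(study, config) {
  stopIfNot(is(study, "SpongeStudy"), "'study' must be a SpongeStudy")
  stopIfNot(config$nSamplesPerGroup >= 2L,
            "at least 2 samples per group are required")
  tx <- study@transcripts
  n <- length(tx)
  mc <- S4Vectors::mcols(tx)
  tissues <- c("midgut", "salivary_gland")
  conditions <- c("unfed", "fed")
  nrep <- config$nSamplesPerGroup
  samples <- expand.grid(rep = seq_len(nrep), condition = conditions,
                         tissue = tissues, stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%s_%d", substr(samples$tissue, 1, 2),
                            samples$condition, samples$rep)
  withSeed(deriveSeed(config$seed, 53L), {
    clusters <- sort(unique(mc$cluster))
    isDE <- stats::runif(length(clusters)) < config$deFraction
    sgn <- sample(c(-1, 1), length(clusters), replace = TRUE)
    lfc <- ifelse(isDE, sgn * config$deLog2fc, 0)
    names(lfc) <- clusters
    baseMean <- stats::rlnorm(length(clusters), meanlog = log(80),
                              sdlog = 0.7)
    names(baseMean) <- clusters
    libFac <- exp(stats::runif(nrow(samples), log(0.5), log(2)))
    mat <- matrix(0, nrow = n, ncol = nrow(samples),
                  dimnames = list(names(tx), samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu0 <- baseMean[as.character(mc$cluster)]
      if (samples$condition[j] == "fed")
        mu0 <- mu0 * 2^lfc[as.character(mc$cluster)]
      mu <- mu0 * libFac[j]
      mat[, j] <- if (config$dispersion > 0)
        stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
      else stats::rpois(n, lambda = mu)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = mat),
      rowData = S4Vectors::DataFrame(
        length = Biostrings::width(tx), source = mc$source,
        class = mc$class, cluster = mc$cluster,
        trueLog2FC = unname(lfc[as.character(mc$cluster)]),
        isDE = unname(isDE[match(mc$cluster, clusters)])),
      colData = S4Vectors::DataFrame(
        sample = samples$sample, tissue = samples$tissue,
        condition = samples$condition, timepoint = NA_character_,
        study = "synthetic", libFactor = libFac,
        row.names = samples$sample))
    study@counts <- se
    study@truth$deTable <- data.frame(
      transcript = names(tx),
      trueLog2FC = unname(lfc[as.character(mc$cluster)]),
      isDE = unname(isDE[match(mc$cluster, clusters)]),
      stringsAsFactors = FALSE)
    study
  })
}

#' Simulate a complete sponge study
#'
#' Convenience wrapper: [simulateTranscriptomes()] followed by
#' [simulateCounts()].
#'
#' @param config A [simulationConfig()]; also accepts arguments to build
#'   one via `...`.
#' @param ... Passed to [simulationConfig()] when `config` is missing.
#' @return A [SpongeStudy-class] with counts.
#' @export
simulateSpongeStudy <- function(config = NULL, ...) {
  if (is.null(config)) config <- simulationConfig(...)
  simulateCounts(simulateTranscriptomes(config), config)
}
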