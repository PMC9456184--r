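## End-to-end driver: classify -> cluster/consensus -> expression/DE ->
## targets/null -> sponge -> report, with TSV artifacts per stage.

PIPELINE_SCHEMA <- list(
  seed = NULL, outdir = NULL,
  simulation = c("nClusters", "pCoding", "sourcePresence", "lengthRange",
                 "mutationRate", "nSamplesPerGroup", "dispersion",
                 "deFraction", "deLog2fc", "nMirnas"),
  inputs = c("transcripts", "sources", "counts", "sampleTable", "mirnas",
             "hitTable", "lengths"),
  classify = c("minAa", "scoreThreshold", "bothStrands"),
  lncrna = c("minLen", "maxLen"),
  cluster = c("idThr", "covThr"),
  consensus = c("requirePrimaryRepresentative"),
  expression = c("minFpkm", "alpha"),
  targets = c("minSiteType", "minHybridScore", "windowFlank"),
  nullModel = c("nReplicates", "mode"),
  sponge = c("minSupport", "alpha", "maxGroups"))

validateConfig <- function(config) {
  bad <- setdiff(names(config), names(PIPELINE_SCHEMA))
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "))
  for (sec in names(config)) {
    allowed <- PIPELINE_SCHEMA[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad)) stop("unknown config key(s) in '", sec, "': ",
                          paste(bad, collapse = ", "))
  }
  invisible(config)
}

writeTsv <- function(x, dir, name) {
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full sponge-detection pipeline
#'
#' Executes all stages on either a simulated study (config section
#' `simulation`) or user-supplied files (section `inputs`: transcript
#' FASTAs with source labels, an expected-count TSV, a sample table TSV, a
#' mature-miRNA FASTA and optionally a homology hit table). Every stage
#' writes its tables under `outdir` together with a run log recording the
#' seed and parameters; rerunning with an identical configuration and seed
#' reproduces the artifacts byte for byte.
#'
#' @param config A configuration list or path to a YAML file. Unknown keys
#'   are an error. See the package vignette for the full key set.
#' @param outdir Output directory (created if needed); overrides
#'   `config$outdir`.
#' @return Invisibly, a list with the main in-memory artifacts:
#'   `study`, `classification`, `consensusLnc`, `consensusCoding`, `de`,
#'   `targets`, `nullMatrices`, `ratio`, `report`, `summary`.
#' @export
runPipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validateConfig(config)
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  cfg <- function(sec, key, default) config[[sec]][[key]] %||% default

  ## ---- stage 0: inputs ----------------------------------------------
  if (!is.null(config$simulation) || is.null(config$inputs)) {
    simArgs <- config$simulation %||% list()
    simArgs$seed <- seed
    simCfg <- do.call(simulationConfig, simArgs)
    study <- simulateSpongeStudy(simCfg)
    tx <- transcripts(study)
    sources <- S4Vectors::mcols(tx)$source
    mirnas <- mirnaSet(study)
    refProteins <- referenceProteins(study)
    hitTable <- NULL
    se <- countData(study)
    counts <- SummarizedExperiment::assay(se, "counts")
    sampleTable <- as.data.frame(SummarizedExperiment::colData(se))
    lengths <- setNames(Biostrings::width(tx), names(tx))
    writeFasta(tx, file.path(outdir, "transcripts.fa"))
    writeFasta(mirnas, file.path(outdir, "mirnas.fa"))
    if (length(refProteins))
      writeFasta(refProteins, file.path(outdir, "reference_proteins.fa"))
    writeTsv(data.frame(transcript = names(tx), source = sources,
                        trueClass = S4Vectors::mcols(tx)$class,
                        trueCluster = S4Vectors::mcols(tx)$cluster),
             outdir, "truth_transcripts.tsv")
    writeTsv(study@truth$deTable, outdir, "truth_de.tsv")
    writeTsv(study@truth$plantedSites, outdir, "truth_planted_sites.tsv")
    writeTsv(cbind(transcript = rownames(counts), as.data.frame(counts)),
             outdir, "counts.tsv")
    writeTsv(sampleTable, outdir, "sample_table.tsv")
  } else {
    inp <- config$inputs
    for (f in c("transcripts", "counts", "sampleTable", "mirnas"))
      if (is.null(inp[[f]])) stop("missing required input: ", f)
    fastas <- inp$transcripts
    srcLabels <- inp$sources %||% names(fastas) %||%
      stop("missing input: sources")
    sets <- lapply(fastas, readFasta, alphabet = "DNA")
    tx <- do.call(c, sets)
    sources <- rep(srcLabels, times = vapply(sets, length, 1L))
    if (anyDuplicated(names(tx))) stop("duplicate transcript ids across sets")
    mirnas <- readFasta(inp$mirnas, alphabet = "RNA")
    ctab <- utils::read.delim(inp$counts, check.names = FALSE)
    counts <- as.matrix(ctab[, -1, drop = FALSE])
    rownames(counts) <- ctab[[1]]
    sampleTable <- utils::read.delim(inp$sampleTable)
    hitTable <- NULL
    refProteins <- NULL
    if (!is.null(inp$hitTable)) {
      ht <- utils::read.delim(inp$hitTable)
      hitTable <- setNames(as.logical(ht[[2]]), ht[[1]])
    }
    lengths <- setNames(Biostrings::width(tx), names(tx))
    study <- NULL
  }

  log <- c(sprintf("lncSponge %s", utils::packageVersion("lncSponge")),
           sprintf("R %s", getRversion()),
           sprintf("seed: %d", seed),
           sprintf("config: %s",
                   paste(utils::capture.output(utils::str(config)),
                         collapse = " | ")))

  ## ---- stage 1: expression filter on the primary source -------------
  minFpkm <- cfg("expression", "minFpkm", 5)
  fpkm <- computeFpkm(counts, lengths)
  passFilter <- expressionFilter(fpkm, sampleTable, minFpkm = minFpkm)
  primary <- names(tx)[sources == "MG_SG"]
  dropped <- setdiff(primary, passFilter)
  keep <- !(names(tx) %in% dropped)
  tx <- tx[keep]
  sources <- sources[keep]
  log <- c(log, sprintf("expression filter: dropped %d / %d MG_SG contigs",
                        length(dropped), length(primary)))

  ## ---- stage 2: classification --------------------------------------
  classification <- classifyTranscripts(
    tx, hitTable = hitTable, referenceProteins = refProteins,
    minAa = cfg("classify", "minAa", 50L),
    scoreThreshold = cfg("classify", "scoreThreshold", 60),
    bothStrands = cfg("classify", "bothStrands", TRUE))
  classification$source <- sources
  writeTsv(classification, outdir, "classification.tsv")
  noncoding <- tx[classification$class == "noncoding"]
  coding <- tx[classification$class == "coding"]

  ## ---- stage 3: lncRNA gate + clustering + consensus -----------------
  lncCand <- filterLncrnaCandidates(
    noncoding, minLen = cfg("lncrna", "minLen", 200L),
    maxLen = cfg("lncrna", "maxLen", 1800L))
  consensusOf <- function(set, tag) {
    if (!length(set)) {
      return(list(clusters = NULL, consensus = character(0)))
    }
    cl <- greedyCluster(set,
                        sources = sources[match(names(set), names(tx))],
                        idThr = cfg("cluster", "idThr", 0.98),
                        covThr = cfg("cluster", "covThr", 0.80))
    cons <- selectConsensus(cl,
      requirePrimaryRepresentative =
        cfg("consensus", "requirePrimaryRepresentative", FALSE))
    writeTsv(cl, outdir, sprintf("clusters_%s.tsv", tag))
    writeTsv(cons, outdir, sprintf("consensus_%s.tsv", tag))
    list(clusters = cl, consensus = cons$consensus[cons$retained])
  }
  lncRes <- consensusOf(lncCand, "lncrna")
  codRes <- consensusOf(coding, "coding")
  consensusLnc <- lncRes$consensus
  consensusCoding <- codRes$consensus
  log <- c(log, sprintf("consensus: %d lncRNAs, %d coding RNAs",
                        length(consensusLnc), length(consensusCoding)))

  ## ---- stage 4: differential expression per tissue -------------------
  alpha <- cfg("expression", "alpha", 0.05)
  deAll <- list()
  consAll <- c(consensusLnc, consensusCoding)
  for (tis in unique(sampleTable$tissue)) {
    colsT <- which(sampleTable$tissue == tis)
    sub <- counts[consAll, colsT, drop = FALSE]
    grp <- factor(sampleTable$condition[colsT],
                  levels = c("unfed", "fed"))
    fac <- tmmFactors(sub)
    phi <- estimateCommonDispersion(sub, grp, fac)
    de <- nbExactTest(sub, grp, phi = phi, factors = fac)
    de$fdr <- bhAdjust(de$pvalue)
    de <- classifyDe(de, alpha = alpha)
    de$tissue <- tis
    de$class <- ifelse(de$transcript %in% consensusLnc, "lncRNA", "coding")
    deAll[[tis]] <- de
    writeTsv(de, outdir, sprintf("de_%s.tsv", tis))
    log <- c(log, sprintf("DE %s: phi=%.3f, %d up_fed / %d up_unfed", tis,
                          phi, sum(de$direction == "up_fed"),
                          sum(de$direction == "up_unfed")))
  }
  deTable <- do.call(rbind, deAll)
  rownames(deTable) <- NULL

  ## ---- stage 5: target prediction + shuffled null --------------------
  lncSeqs <- as.character(tx[consensusLnc])
  hits <- predictTargets(
    as.character(mirnas), lncSeqs,
    minSiteType = cfg("targets", "minSiteType", "7mer"),
    minHybridScore = cfg("targets", "minHybridScore", 70),
    windowFlank = cfg("targets", "windowFlank", 30L))
  st <- as.data.frame(siteTable(hits))
  st$start <- st$start + 1L            # 1-based in output tables
  writeTsv(st, outdir, "target_sites.tsv")
  writeTsv(cbind(mirna = rownames(targetCounts(hits)),
                 as.data.frame(targetCounts(hits))),
           outdir, "target_counts.tsv")
  nullMats <- buildNull(
    lncSeqs, as.character(mirnas),
    nReplicates = cfg("nullModel", "nReplicates", 19L),
    seed = deriveSeed(seed, 71L),
    mode = cfg("nullModel", "mode", "mono"),
    minSiteType = cfg("targets", "minSiteType", "7mer"),
    minHybridScore = cfg("targets", "minHybridScore", 70),
    windowFlank = cfg("targets", "windowFlank", 30L))

  ## ---- stage 6: miRNA ratio statistic + sponge candidates ------------
  ratio <- list()
  for (tis in names(deAll)) {
    de <- deAll[[tis]]
    upFed <- intersect(de$transcript[de$direction == "up_fed"],
                       consensusLnc)
    upUnfed <- intersect(de$transcript[de$direction == "up_unfed"],
                         consensusLnc)
    cm <- targetCounts(hits)
    tFed <- rowSums(cm[, upFed, drop = FALSE])
    tUnfed <- rowSums(cm[, upUnfed, drop = FALSE])
    r <- normalizedTargetRatio(tFed, tUnfed)
    r$tissue <- tis
    ratio[[tis]] <- r
    writeTsv(r, outdir, sprintf("mirna_ratio_%s.tsv", tis))
  }
  itemsets <- itemsetSignificance(
    mineItemsets(targetCounts(hits),
                 minSupport = cfg("sponge", "minSupport", NULL)),
    nullMats)
  report <- selectSpongeCandidates(
    targetCounts(hits), lncLengths(hits), nullMats, itemsets,
    alpha = cfg("sponge", "alpha", 0.05),
    maxGroups = cfg("sponge", "maxGroups", 3L),
    log2fcTable = deTable)
  writeTsv(candidateTable(report), outdir, "sponge_candidates.tsv")
  if (nrow(itemsetTable(report)))
    writeTsv(itemsetTable(report)[, c("itemset", "size", "support",
                                      "empiricalP", "fdr")],
             outdir, "itemsets.tsv")
  grp <- spongeGroups(report)
  if (length(grp))
    writeTsv(data.frame(
      group = seq_along(grp),
      mirnas = vapply(grp, function(g) paste(g$mirnas, collapse = "+"),
                      character(1)),
      lncrnas = vapply(grp, function(g) paste(g$lncrnas, collapse = ","),
                       character(1)),
      support = vapply(grp, `[[`, numeric(1), "support"),
      empiricalP = vapply(grp, `[[`, numeric(1), "empiricalP")),
      outdir, "sponge_groups.tsv")
  if (nrow(report@log2fc))
    writeTsv(report@log2fc, outdir, "candidate_log2fc.tsv")

  ## ---- stage 7: summary report ---------------------------------------
  summaryRows <- list()
  for (tis in names(deAll)) {
    de <- deAll[[tis]]
    for (cls in c("lncRNA", "coding")) {
      d <- de[de$class == cls, , drop = FALSE]
      nDE <- sum(d$direction != "ns")
      if (nrow(d))
        summaryRows[[length(summaryRows) + 1L]] <- data.frame(
          tissue = tis, class = cls, nTotal = nrow(d), nDE = nDE,
          pctDE = deSummary(nDE, nrow(d)),
          pctUpFed = if (nDE) roundHalfUp(
            100 * sum(d$direction == "up_fed") / nDE, 1) else NA_real_)
    }
  }
  summaryTab <- do.call(rbind, summaryRows)
  writeTsv(summaryTab, outdir, "de_summary.tsv")
  writeTsv(lengthHistogram(tx[consensusLnc], binWidth = 100),
           outdir, "length_histogram_consensus_lncrna.tsv")
  classLab <- ifelse(names(tx) %in% names(lncCand), "lncRNA", "coding")
  names(classLab) <- names(tx)
  fac <- tmmFactors(counts[names(tx), , drop = FALSE])
  normAll <- sweep(counts[names(tx), , drop = FALSE], 2,
                   colSums(counts[names(tx), , drop = FALSE]) * fac / 1e6,
                   "/")
  share <- expressionShare(normAll, classLab, sampleTable)
  writeTsv(data.frame(group = names(share$perCondition),
                      lncrnaShare = as.numeric(share$perCondition)),
           outdir, "expression_share.tsv")
  writeLines(log, file.path(outdir, "run_log.txt"))

  invisible(list(study = study, classification = classification,
                 consensusLnc = consensusLnc,
                 consensusCoding = consensusCoding, de = deTable,
                 targets = hits, nullMatrices = nullMats, ratio = ratio,
                 report = report, summary = summaryTab,
                 expressionShare = share))
}
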