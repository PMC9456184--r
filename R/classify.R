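#' Find open reading frames in a transcript
#'
#' Enumerates ORFs (`ATG` .. first in-frame stop, stop codon required) in
#' all reading frames, optionally on both strands, and reports those whose
#' protein is strictly longer than `minAa` amino acids. Coordinates are
#' 0-based half-open on the forward strand and include the stop codon;
#' `aaLength` excludes the stop.
#'
#' @param sequence A single DNA string (character or
#'   [Biostrings::DNAString]).
#' @param minAa ORFs must encode more than `minAa` amino acids (default 50,
#'   read strictly).
#' @param bothStrands Scan the reverse complement too (default `TRUE`);
#'   assembled contigs have unknown orientation.
#' @return A data.frame with columns `frame` (0..2, on the scanned strand),
#'   `strand` (`+`/`-`), `start`, `end` (forward-strand, 0-based half-open),
#'   `protein`, `aaLength`, sorted by decreasing `aaLength` then by
#'   `(strand, start)`.
#' @examples
#' orf <- paste0("ATG", strrep("GCT", 60), "TAA")
#' findOrfs(paste0("TT", orf, "AC"))
#' @export
findOrfs <- function(sequence, minAa = 50L, bothStrands = TRUE) {
  seq <- toupper(as.character(sequence))
  L <- nchar(seq)
  strands <- if (bothStrands) c("+", "-") else "+"
  res <- list()
  for (strand in strands) {
    ss <- if (strand == "+") seq else revcompDna(seq)
    for (f in 0:2) {
      ncod <- (nchar(ss) - f) %/% 3L
      if (ncod < 2L) next
      starts <- f + 1L + 3L * (seq_len(ncod) - 1L)
      codons <- substring(ss, starts, starts + 2L)
      isStart <- codons == "ATG"
      isStop <- codons %in% c("TAA", "TAG", "TGA")
      if (!any(isStart) || !any(isStop)) next
      stopIdx <- which(isStop)
      for (i in which(isStart)) {
        j <- stopIdx[stopIdx > i]
        if (!length(j)) next
        j <- j[1]
        aa <- j - i
        if (aa <= minAa) next
        s0 <- (i - 1L) * 3L + f       # on scanned strand, 0-based
        e0 <- j * 3L + f              # half-open, includes stop codon
        if (strand == "+") {
          fs <- s0; fe <- e0
        } else {
          fs <- L - e0; fe <- L - s0
        }
        prot <- paste(GENETIC_CODE_TABLE[codons[i:(j - 1L)]], collapse = "")
        res[[length(res) + 1L]] <- list(frame = f, strand = strand,
                                        start = fs, end = fe,
                                        protein = prot, aaLength = aa)
      }
    }
  }
  if (!length(res))
    return(data.frame(frame = integer(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      protein = character(0), aaLength = integer(0)))
  out <- data.frame(
    frame = vapply(res, `[[`, integer(1), "frame"),
    strand = vapply(res, `[[`, character(1), "strand"),
    start = vapply(res, `[[`, integer(1), "start"),
    end = vapply(res, `[[`, integer(1), "end"),
    protein = vapply(res, `[[`, character(1), "protein"),
    aaLength = vapply(res, `[[`, integer(1), "aaLength"),
    stringsAsFactors = FALSE)
  out <- out[order(-out$aaLength, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## TRUE when the sequence contains any six-frame ORF encoding `aa` or more
## amino acids (stop required); short-circuiting scan used by the
## synthetic-data rejection sampler.
hasOrfOfLength <- function(seq, aa = 50L) {
  seq <- toupper(as.character(seq))
  for (ss in c(seq, revcompDna(seq))) {
    for (f in 0:2) {
      ncod <- (nchar(ss) - f) %/% 3L
      if (ncod < 2L) next
      starts <- f + 1L + 3L * (seq_len(ncod) - 1L)
      codons <- substring(ss, starts, starts + 2L)
      stopIdx <- which(codons %in% STOP_CODONS)
      for (i in which(codons == "ATG")) {
        j <- stopIdx[stopIdx > i]
        if (length(j) && j[1] - i >= aa) return(TRUE)
      }
    }
  }
  FALSE
}

## Codon -> amino acid lookup (stops marked "*", never emitted in ORFs).
GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

#' Local-alignment homology gate for a single protein
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11, gap extend 1) of a
#' query protein against a reference protein set; a hit is a best raw score
#' at or above `scoreThreshold`. This is the pipeline's built-in stand-in
#' for an external protein-database search when no precomputed hit table is
#' supplied.
#'
#' @param proteinQuery Single amino-acid string.
#' @param referenceProteins Character vector or [Biostrings::AAStringSet].
#' @param scoreThreshold Raw-score cutoff (default 60).
#' @return `TRUE` if any reference scores at or above the threshold.
#' @export
homologyHit <- function(proteinQuery, referenceProteins,
                        scoreThreshold = 60) {
  stopIfNot(nzchar(as.character(proteinQuery)[1]),
            "'proteinQuery' must be non-empty")
  if (length(referenceProteins) == 0L) return(FALSE)
  refs <- Biostrings::AAStringSet(as.character(referenceProteins))
  sc <- Biostrings::pairwiseAlignment(
    pattern = refs, subject = Biostrings::AAString(proteinQuery),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  max(sc) >= scoreThreshold
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Partition transcripts into coding RNAs and noncoding RNAs
#'
#' A transcript is coding when it has at least one ORF longer than `minAa`
#' amino acids *and* the homology gate reports a hit for one of those ORFs;
#' everything else is noncoding. The gate is either a precomputed hit table
#' (transcript id -> logical, e.g. from an external protein-database search)
#' or a reference protein set screened with the built-in local aligner.
#'
#' @param transcriptSet A named [Biostrings::DNAStringSet] (or named
#'   character vector).
#' @param hitTable Named logical vector: does the transcript have a protein
#'   database hit? Transcripts absent from the table count as no-hit.
#' @param referenceProteins Reference proteins for the built-in aligner;
#'   used only when `hitTable` is `NULL`.
#' @param minAa,scoreThreshold,bothStrands Passed to [findOrfs()] and
#'   [homologyHit()].
#' @return A data.frame with columns `transcript`, `nOrfs` (count of
#'   qualifying ORFs) and `class` (`"coding"`/`"noncoding"`); the partition
#'   is exhaustive and disjoint.
#' @export
classifyTranscripts <- function(transcriptSet, hitTable = NULL,
                                referenceProteins = NULL, minAa = 50L,
                                scoreThreshold = 60, bothStrands = TRUE) {
  seqs <- namedStrings(transcriptSet)
  stopIfNot(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
            "transcripts must have unique names")
  useTable <- !is.null(hitTable)
  if (!useTable && (is.null(referenceProteins) ||
                    length(referenceProteins) == 0L)) {
    warning("empty reference protein set: all transcripts called noncoding")
    referenceProteins <- character(0)
  }
  cls <- character(length(seqs))
  nOrfs <- integer(length(seqs))
  for (k in seq_along(seqs)) {
    orfs <- findOrfs(seqs[[k]], minAa = minAa, bothStrands = bothStrands)
    nOrfs[k] <- nrow(orfs)
    if (nrow(orfs) == 0L) {
      cls[k] <- "noncoding"
      next
    }
    hit <- if (useTable) {
      isTRUE(hitTable[[names(seqs)[k]]])
    } else if (length(referenceProteins) == 0L) {
      FALSE
    } else {
      any(vapply(orfs$protein, homologyHit, logical(1),
                 referenceProteins = referenceProteins,
                 scoreThreshold = scoreThreshold))
    }
    cls[k] <- if (hit) "coding" else "noncoding"
  }
  data.frame(transcript = names(seqs), nOrfs = nOrfs, class = cls,
             stringsAsFactors = FALSE)
}

#' Apply the lncRNA length gate to noncoding transcripts
#'
#' Retains noncoding transcripts whose length lies between `minLen` and
#' `maxLen` nucleotides, inclusive at both bounds.
#'
#' @param noncoding A [Biostrings::DNAStringSet] (or named character vector)
#'   of noncoding transcripts.
#' @param minLen,maxLen Inclusive length bounds (defaults 200 and 1800 nt).
#' @return The retained subset, same container type as the input.
#' @export
filterLncrnaCandidates <- function(noncoding, minLen = 200L,
                                   maxLen = 1800L) {
  w <- if (is.character(noncoding)) nchar(noncoding)
       else Biostrings::width(noncoding)
  noncoding[w >= minLen & w <= maxLen]
}
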