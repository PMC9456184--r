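#' Read a FASTA file into a Biostrings set
#'
#' Light validating reader: record order is preserved, ids are the first
#' whitespace-delimited token of each header, sequences are upper-cased, and
#' `U` is normalized to `T` when a DNA alphabet is expected. Malformed
#' headers and empty records are reported with their line number; duplicate
#' ids are an error.
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of `"DNA"`, `"RNA"`, `"AA"`; selects the returned
#'   [Biostrings::XStringSet] class and the normalization applied.
#' @return A `DNAStringSet`, `RNAStringSet` or `AAStringSet`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgu"), tf)
#' readFasta(tf, "DNA")
#' @export
readFasta <- function(path, alphabet = c("DNA", "RNA", "AA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA: first non-blank line ", nonblank[1],
         " is not a header")
  headers <- integer(0)
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  curseq <- character(0)
  flush <- function(at) {
    if (is.null(cur)) return(invisible())
    s <- paste(curseq, collapse = "")
    if (!nzchar(s))
      stop("malformed FASTA: empty sequence for record ending at line ", at)
    ids <<- c(ids, cur)
    seqs <<- c(seqs, s)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush(i - 1L)
      id <- strsplit(sub("^>", "", ln), "\\s+")[[1]][1]
      if (is.na(id) || !nzchar(id))
        stop("malformed FASTA: empty header id at line ", i)
      cur <- id
      curseq <- character(0)
    } else {
      curseq <- c(curseq, ln)
    }
  }
  flush(length(lines))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  if (alphabet == "DNA") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  set <- switch(alphabet,
    DNA = Biostrings::DNAStringSet(seqs),
    RNA = Biostrings::RNAStringSet(seqs),
    AA  = Biostrings::AAStringSet(seqs))
  names(set) <- ids
  set
}

#' Write sequences to FASTA
#'
#' @param x A named character vector or an [Biostrings::XStringSet].
#' @param path Output path.
#' @param width Line width (default 60).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Shuffle a sequence while preserving its composition
#'
#' The randomized-control generator. `mode = "mono"` draws a uniform random
#' permutation of the characters (mononucleotide composition is preserved
#' exactly). `mode = "di"` preserves the exact dinucleotide count vector via
#' a random Euler path on the de Bruijn multigraph of the sequence
#' (Altschul-Erickson construction): every dinucleotide occurs in the output
#' exactly as often as in the input.
#'
#' @param sequence A single non-empty character string.
#' @param seed Integer seed; the shuffle is a deterministic function of
#'   `(sequence, seed, mode)`.
#' @param mode `"mono"` (default) or `"di"`.
#' @return The shuffled string.
#' @examples
#' shuffleSequence("ACGTACGTACGT", seed = 1)
#' shuffleSequence("ACGTACGTACGT", seed = 1, mode = "di")
#' @export
shuffleSequence <- function(sequence, seed, mode = c("mono", "di")) {
  mode <- match.arg(mode)
  stopIfNot(is.character(sequence) && length(sequence) == 1L &&
              nzchar(sequence), "'sequence' must be a non-empty string")
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n == 1L || length(unique(chars)) == 1L) return(sequence)
  withSeed(seed, {
    if (mode == "mono") {
      paste(sample(chars), collapse = "")
    } else {
      paste(eulerShuffle(chars), collapse = "")
    }
  })
}

## Random Euler path on the de Bruijn multigraph over single characters.
## Returns a character vector with identical dinucleotide counts.
eulerShuffle <- function(chars) {
  n <- length(chars)
  verts <- unique(chars)
  from <- chars[-n]
  to <- chars[-1]
  edges <- split(to, factor(from, levels = verts))
  last <- chars[n]
  first <- chars[1]
  others <- setdiff(verts, last)
  ## Pick a random "last exit" edge per non-terminal vertex such that the
  ## chosen edges form an arborescence into the terminal vertex.
  pickLast <- function() {
    sel <- vapply(others, function(v) {
      outs <- edges[[v]]
      outs[sample.int(length(outs), 1L)]
    }, character(1))
    names(sel) <- others
    ## reachability of `last` by following selections
    for (v in others) {
      seen <- character(0)
      cur <- v
      while (cur != last) {
        if (cur %in% seen) return(NULL)
        seen <- c(seen, cur)
        cur <- sel[[cur]]
      }
    }
    sel
  }
  sel <- NULL
  for (i in seq_len(2000L)) {
    sel <- pickLast()
    if (!is.null(sel)) break
  }
  if (is.null(sel))
    stop("dinucleotide shuffle: failed to sample an Euler path")
  ## Order each vertex's out-edges: random permutation with the selected
  ## last-exit edge moved to the end.
  order_edges <- function(v) {
    outs <- edges[[v]]
    if (v %in% others) {
      idx <- which(outs == sel[[v]])[1]
      rest <- outs[-idx]
      c(if (length(rest)) sample(rest, length(rest)) else character(0),
        outs[idx])
    } else {
      if (length(outs) > 1L) sample(outs) else outs
    }
  }
  ordered <- lapply(setNames(verts, verts), order_edges)
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- first
  cur <- first
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  out
}
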