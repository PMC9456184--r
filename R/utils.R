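## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded operations never
#' perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stage/replicate seed from a master seed; keeps results < 2^31.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97L + as.numeric(offset)) %% 2147483587)
}

## Round half away from zero (base round() is half-even).
roundHalfUp <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Fast character-level reverse complement for plain DNA strings.
revcompDna <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

## Complement table used in site classification (DNA alphabet).
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## Character vector of sequences with names preserved (base string ops such
## as toupper()/chartr() drop attributes), optionally DNA-normalized.
namedStrings <- function(x, dna = FALSE) {
  nm <- names(x)
  s <- toupper(as.character(x))
  if (dna) s <- chartr("U", "T", s)
  names(s) <- nm
  s
}
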