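# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that equal
# seeds give byte-identical results without clobbering the session RNG.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# round() in R rounds half to even; printed figures in assembly reports use
# conventional half-up rounding (e.g. integer coverage folds, 2-dp ploidy).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

asmqcLog <- function(...) {
  if (isTRUE(getOption("asmqc.verbose", TRUE))) message("[asmqc] ", ...)
  invisible(NULL)
}

# Uppercase and collapse IUPAC ambiguity codes other than N to N; the k-mer
# and anchor stages assume the 5-letter alphabet {A,C,G,T,N}.
normalizeAlphabet <- function(x, what = "sequence") {
  x <- toupper(x)
  other <- sum(vapply(
    gregexpr("[^ACGTN]", x),
    function(g) if (g[1L] == -1L) 0L else length(g), integer(1)))
  if (other > 0) {
    x <- gsub("[^ACGTN]", "N", x)
    asmqcLog(other, " non-ACGTN base(s) in ", what, " mapped to N")
  }
  x
}

isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
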