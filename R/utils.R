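## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a stream-specific seed from a master seed
#'
#' All stochastic functions in the package accept one `seed`; when a function
#' needs several independent random streams it derives one sub-seed per
#' stream with this splitter. The multiplier/increment pair is a standard
#' 32-bit LCG step, and results are folded into `[0, 2^31 - 2]` so they stay
#' valid R integer seeds.
#'
#' @param seed master seed (integer).
#' @param stream stream index (integer >= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647            # 2^31 - 1, Mersenne prime modulus
  x <- (as.double(seed) %% m) + 1
  for (i in seq_len(stream + 1L)) {
    x <- (16807 * x) %% m    # minimal-standard LCG
  }
  as.integer(x %% (m - 1))
}

## Run `expr` under a local RNG state seeded with `seed`; the caller's
## RNG state is untouched. `seed = NULL` uses the current state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Random DNA of length n with given per-base probabilities (A,C,G,T).
random_dna <- function(n, prob = rep(0.25, 4)) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Normalize U->T, uppercase; used on all sequence input.
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

## Fast per-position character matrix for equal-length strings.
str_to_mat <- function(x) {
  do.call(rbind, strsplit(x, "", fixed = TRUE))
}
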