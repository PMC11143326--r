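#' @keywords internal
"_PACKAGE"

# Nucleotide order used everywhere: A, C, G, T (N handled as missing).
DNA_BASES <- c("A", "C", "G", "T")

#' Stable log(sum(exp(x))) for log-space probability arithmetic
#' @param x numeric vector of log values (may contain -Inf)
#' @return log(sum(exp(x))), never overflowing
#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Reverse complement of an A/C/G/T/N string
#' @param seq character scalar
#' @return character scalar
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

# Encode a sequence string as integers 1..4 (A,C,G,T); N and anything else -> NA.
BASE_LOOKUP <- local({
  m <- rep(NA_integer_, 128L)
  m[utf8ToInt("ACGTacgt")] <- rep(1:4, 2L)
  m
})

encode_seq <- function(seq) {
  BASE_LOOKUP[utf8ToInt(seq)]
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards (the stats::simulate convention).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Format-error helper: all reader errors funnel through here so they share a
# recognizable condition class.
format_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("concordTF_format_error", "error")))
}

chk_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", nm))
  invisible(x)
}

chk_num <- function(x, nm, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", nm))
  if (x < min || (strict_min && x == min) || x > max)
    stop(sprintf("'%s' = %g out of range", nm, x))
  invisible(x)
}
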