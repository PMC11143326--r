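# PWM log-odds construction and double-stranded maximum-score scanning of
# peak sequences.

#' Convert a position probability matrix to a log2-odds scanner
#'
#' Each entry becomes \code{log2((p * (1 - 4e) + e) / background)} with
#' smoothing \code{e = pseudocount}, which keeps rows normalized and all
#' entries finite.
#'
#' @param motif a motif object from [read_meme_motifs()] (or any list with
#'   motif_id and an L x 4 probability matrix)
#' @param background 4-vector of A,C,G,T probabilities, all > 0, summing to 1
#' @param pseudocount smoothing constant > 0 (default 0.01)
#' @return object of class "log_odds_matrix"
#' @export
pwm_to_log_odds <- function(motif, background = rep(0.25, 4),
                            pseudocount = 0.01) {
  stopifnot(length(background) == 4L)
  if (any(background <= 0)) stop("background probabilities must all be > 0")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  chk_num(pseudocount, "pseudocount", min = 0, strict_min = TRUE)
  p <- motif$matrix
  stopifnot(is.matrix(p), ncol(p) == 4L, nrow(p) >= 1L)
  sm <- p * (1 - 4 * pseudocount) + pseudocount
  lom <- log2(sweep(sm, 2L, background, "/"))
  structure(list(motif_id = motif$motif_id, lom = unname(lom),
                 background = background, pseudocount = pseudocount),
            class = "log_odds_matrix")
}

# All window scores of an integer-encoded sequence against an L x 4 log-odds
# matrix; windows containing N come out NA.
window_scores <- function(ints, lom) {
  n <- length(ints); L <- nrow(lom)
  if (n < L) return(numeric(0))
  npos <- n - L + 1L
  tot <- numeric(npos)
  for (i in seq_len(L))
    tot <- tot + lom[i, ][ints[i:(i + npos - 1L)]]
  tot
}

#' Score one sequence against a log-odds matrix (max over both strands)
#'
#' The score is the maximum log2-odds over all windows of the sequence and of
#' its reverse complement; windows containing N are skipped. If no valid
#' window exists the score is \code{-Inf} and the sequence is excluded from
#' enrichment downstream.
#'
#' @param seq character scalar (A/C/G/T/N)
#' @param lom a [pwm_to_log_odds()] object
#' @return list with score, position (0-based start of the best window on the
#'   forward strand) and strand ("+" or "-")
#' @export
score_sequence <- function(seq, lom) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  ints <- encode_seq(seq)
  L <- nrow(lom$lom); n <- length(ints)
  fw <- window_scores(ints, lom$lom)
  rc <- window_scores(rev(5L - ints), lom$lom)
  best <- list(score = -Inf, position = NA_integer_, strand = NA_character_)
  if (length(fw) && any(!is.na(fw))) {
    i <- which.max(fw)
    best <- list(score = fw[i], position = i - 1L, strand = "+")
  }
  if (length(rc) && any(!is.na(rc))) {
    j <- which.max(rc)
    if (rc[j] > best$score)
      best <- list(score = rc[j], position = n - (j - 1L) - L, strand = "-")
  }
  best
}

#' Maximum log-odds scores for many sequences
#'
#' Fast path over [score_sequence()]: returns only the max score per
#' sequence (named), with \code{-Inf} for sequences without a valid window.
#'
#' @param seqs named character vector of sequences
#' @param lom a [pwm_to_log_odds()] object
#' @return named numeric vector of scores
#' @export
score_sequences <- function(seqs, lom) {
  m <- lom$lom
  vapply(seqs, function(s) {
    ints <- encode_seq(s)
    v <- c(window_scores(ints, m), window_scores(rev(5L - ints), m))
    v <- v[!is.na(v)]
    if (length(v)) max(v) else -Inf
  }, 0)
}

#' Genome-wide mononucleotide background frequencies
#'
#' @param genome named character vector of sequences
#' @return 4-vector of A,C,G,T frequencies (N excluded), summing to 1
#' @export
genome_background <- function(genome) {
  counts <- numeric(4L)
  for (s in genome) {
    tab <- tabulate(utf8ToInt(s), nbins = 128L)
    counts <- counts + tab[utf8ToInt("ACGT")] + tab[utf8ToInt("acgt")]
  }
  if (sum(counts) == 0) stop("genome contains no A/C/G/T bases")
  counts / sum(counts)
}
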