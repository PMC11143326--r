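# One-tailed Fisher (hypergeometric upper-tail) testing in log space and the
# optimal-score-threshold enrichment statistic built on it.

#' One-tailed Fisher exact test, upper tail, in log space
#'
#' Computes \code{P(X >= fg_hits)} for the 2x2 table (fg_hits, fg_total -
#' fg_hits; bg_hits, bg_total - bg_hits) under the hypergeometric null, from
#' \code{lchoose} terms combined with a log-sum-exp, so p-values far below
#' double underflow (1e-5000 and beyond) remain representable as log values.
#'
#' @param fg_hits,fg_total,bg_hits,bg_total nonnegative integers with hits <=
#'   totals
#' @param log if TRUE return the natural-log p-value
#' @return p-value (or its natural log)
#' @export
fisher_upper_tail <- function(fg_hits, fg_total, bg_hits, bg_total,
                              log = FALSE) {
  vals <- c(fg_hits, fg_total, bg_hits, bg_total)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("all arguments must be nonnegative integers")
  if (fg_hits > fg_total || bg_hits > bg_total)
    stop("hits cannot exceed totals")
  if (fg_hits == 0) return(if (log) 0 else 1)  # upper tail from 0 is exact
  h <- fg_hits + bg_hits
  N <- fg_total + bg_total
  ks <- fg_hits:min(h, fg_total)
  lp <- min(0, logsumexp(lchoose(h, ks) + lchoose(N - h, fg_total - ks) -
                           lchoose(N, fg_total)))
  if (log) lp else exp(lp)
}

#' Optimal-score-threshold Fisher enrichment
#'
#' For every distinct observed foreground score t, sequences with score >= t
#' are counted as hits in foreground and background and a one-tailed Fisher
#' exact test is computed; the reported p-value is the minimum over all
#' thresholds, Bonferroni-adjusted by the number of candidate thresholds.
#' Restricting candidates to foreground score values loses nothing for the
#' upper-tail statistic (verified in the test suite against an exhaustive
#' threshold scan that includes background values). Non-finite scores
#' (sequences without a valid window) are excluded from both sets.
#'
#' @param fg_scores numeric vector of foreground sequence scores
#' @param bg_scores numeric vector of background sequence scores
#' @return list with threshold_star (smallest threshold attaining the
#'   minimum), p_raw, log_p_raw, log_p_adj_thresholds, n_thresholds and the
#'   2x2 counts at threshold_star
#' @export
ame_optimal_enrichment <- function(fg_scores, bg_scores) {
  fg <- fg_scores[is.finite(fg_scores)]
  bg <- bg_scores[is.finite(bg_scores)]
  if (!length(fg) || !length(bg))
    stop("need at least one finite foreground and background score")
  thresholds <- sort(unique(fg))
  fg_s <- sort(fg); bg_s <- sort(bg)
  n_fg <- length(fg); n_bg <- length(bg)
  logps <- vapply(thresholds, function(t) {
    a <- n_fg - findInterval(t, fg_s, left.open = TRUE)   # fg scores >= t
    b <- n_bg - findInterval(t, bg_s, left.open = TRUE)   # bg scores >= t
    fisher_upper_tail(a, n_fg, b, n_bg, log = TRUE)
  }, 0)
  m <- min(logps)
  star <- min(thresholds[logps == m])
  a <- n_fg - findInterval(star, fg_s, left.open = TRUE)
  b <- n_bg - findInterval(star, bg_s, left.open = TRUE)
  list(threshold_star = star,
       p_raw = exp(m),
       log_p_raw = m,
       log_p_adj_thresholds = min(0, m + log(length(thresholds))),
       n_thresholds = length(thresholds),
       fg_hits = a, fg_total = n_fg, bg_hits = b, bg_total = n_bg)
}
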