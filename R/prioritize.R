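# Consensus calling across the six backgrounds, representative -log2(p)
# scores, summed condition-pair scores, and the four-set exclusivity
# classification of candidate TFs.

PEAK_CONDITIONS <- c("fasted_opened", "fasted_closed",
                     "leptin_opened", "leptin_closed")

#' Consensus call for one motif in one peak-set condition
#'
#' A motif is "enriched" when its Bonferroni-adjusted p-value is below
#' \code{alpha} in at least 5 of the 6 background analyses. The
#' representative p-value is the most significant of the significant ones
#' when enriched, and the most significant of the non-significant ones
#' otherwise; its \code{-log2} is computed from the log-space value so no
#' clamping is ever needed.
#'
#' @param results either a numeric vector of six adjusted p-values, a numeric
#'   vector of six natural-log adjusted p-values (with \code{log_p = TRUE}),
#'   or a 6-row data.frame carrying a \code{log_p_adj} column
#' @param alpha significance cutoff (default 0.05)
#' @param log_p whether a numeric `results` is already on the natural-log
#'   scale
#' @param clamp_log if TRUE, floor the representative p-value at exp(-300)
#'   before taking -log2, mimicking tools that impute a cap for p-values too
#'   small to log-transform in linear space; the default (FALSE) keeps the
#'   exact log-space value, which never under- or overflows
#' @return list with n_significant, enriched, log_rep_p, rep_p, rep_log2p
#' @export
consensus_call <- function(results, alpha = 0.05, log_p = FALSE,
                           clamp_log = FALSE) {
  lp <- if (is.data.frame(results)) {
    stopifnot("log_p_adj" %in% names(results))
    results$log_p_adj
  } else if (log_p) results else log(results)
  if (length(lp) != 6L)
    stop("exactly six background results are required, got ", length(lp))
  if (any(lp > 0)) stop("p-values above 1 are not valid")
  sig <- lp < log(alpha)
  n_sig <- sum(sig)
  enriched <- n_sig >= 5L
  log_rep_p <- if (enriched) min(lp[sig]) else min(lp[!sig])
  display_lp <- if (clamp_log) max(log_rep_p, -300) else log_rep_p
  list(n_significant = n_sig, enriched = enriched, log_rep_p = log_rep_p,
       rep_p = exp(log_rep_p), rep_log2p = -display_lp / log(2))
}

#' Four-set exclusivity category of a motif
#'
#' @param flags named logical vector with elements fasted_opened,
#'   fasted_closed, leptin_opened, leptin_closed (the consensus enriched
#'   flags)
#' @return one of hunger_pair_exclusive, hunger_single_exclusive,
#'   satiety_pair_exclusive, satiety_single_exclusive, mixed, none
#' @export
classify_tf_category <- function(flags) {
  stopifnot(all(PEAK_CONDITIONS %in% names(flags)))
  fo <- isTRUE(flags[["fasted_opened"]]); fc <- isTRUE(flags[["fasted_closed"]])
  lo <- isTRUE(flags[["leptin_opened"]]); lc <- isTRUE(flags[["leptin_closed"]])
  if (fo && lc && !lo && !fc) return("hunger_pair_exclusive")
  if (fo && !fc && !lo && !lc) return("hunger_single_exclusive")
  if (lo && fc && !fo && !lc) return("satiety_pair_exclusive")
  if (lo && !fo && !fc && !lc) return("satiety_single_exclusive")
  if (fo || fc || lo || lc) return("mixed")
  "none"
}

#' Summed condition-pair score
#'
#' The hunger pair is fasted_opened + leptin_closed; the satiety pair is
#' leptin_opened + fasted_closed. The score is the sum of the two
#' representative -log2(p) values and is defined only when both members are
#' enriched (NA otherwise, never 0).
#'
#' @param consensus named list of four [consensus_call()] results (names as
#'   in \code{PEAK_CONDITIONS})
#' @param pair "hunger" or "satiety"
#' @return numeric score, or NA when undefined
#' @export
summed_pair_score <- function(consensus, pair = c("hunger", "satiety")) {
  pair <- match.arg(pair)
  members <- if (pair == "hunger") c("fasted_opened", "leptin_closed")
             else c("leptin_opened", "fasted_closed")
  a <- consensus[[members[1L]]]; b <- consensus[[members[2L]]]
  if (isTRUE(a$enriched) && isTRUE(b$enriched))
    a$rep_log2p + b$rep_log2p
  else NA_real_
}

#' Prioritize TF motifs from the full enrichment matrix
#'
#' Applies [consensus_call()] per motif and condition, the exclusivity
#' classification and both summed pair scores.
#'
#' @param enrichment data.frame from the enrichment stage with columns
#'   motif_id, condition, background_label, log_p_adj (one row per motif x
#'   condition x background; six backgrounds per condition)
#' @param alpha consensus significance cutoff (default 0.05)
#' @return data.frame of class "tf_priority": per motif, the four enriched
#'   flags, four n_significant counts, four rep_log2p scores, both summed
#'   scores and the category
#' @export
prioritize_tfs <- function(enrichment, alpha = 0.05) {
  need <- c("motif_id", "condition", "background_label", "log_p_adj")
  stopifnot(all(need %in% names(enrichment)))
  motifs <- sort(unique(enrichment$motif_id))
  rows <- lapply(motifs, function(m) {
    sub <- enrichment[enrichment$motif_id == m, , drop = FALSE]
    cons <- lapply(PEAK_CONDITIONS, function(cond) {
      s <- sub[sub$condition == cond, , drop = FALSE]
      consensus_call(s, alpha = alpha)
    })
    names(cons) <- PEAK_CONDITIONS
    flags <- vapply(cons, `[[`, TRUE, "enriched")
    rec <- data.frame(motif_id = m, stringsAsFactors = FALSE)
    for (cond in PEAK_CONDITIONS) {
      rec[[paste0("enriched_", cond)]] <- flags[[cond]]
      rec[[paste0("n_sig_", cond)]] <- cons[[cond]]$n_significant
      rec[[paste0("rep_log2p_", cond)]] <- cons[[cond]]$rep_log2p
    }
    rec$summed_score_hunger <- summed_pair_score(cons, "hunger")
    rec$summed_score_satiety <- summed_pair_score(cons, "satiety")
    rec$category <- classify_tf_category(flags)
    rec
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tf_priority", class(out))
  out
}

#' Rank prioritized motifs and assemble radar-plot data
#'
#' Pair-exclusive motifs are ranked by descending summed pair score,
#' single-exclusive motifs by the rep_log2p of their single condition; ties
#' break lexicographically on motif_id. The radar data carries, per motif,
#' the four rep_log2p axes with negative values (rep_p >= 1) floored at 0.
#'
#' @param records a [prioritize_tfs()] data.frame
#' @return list with elements hunger_pair, hunger_single, satiety_pair,
#'   satiety_single (ranked data.frames with a rank column) and radar (one
#'   row per motif, four axis columns)
#' @export
rank_and_export <- function(records) {
  rank_by <- function(df, score_col) {
    if (!nrow(df)) {
      df$rank <- integer(0)
      return(df)
    }
    o <- order(-df[[score_col]], df$motif_id)
    df <- df[o, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    df
  }
  pick <- function(cat) records[records$category == cat, , drop = FALSE]
  radar <- data.frame(motif_id = records$motif_id, stringsAsFactors = FALSE)
  for (cond in PEAK_CONDITIONS)
    radar[[cond]] <- pmax(0, records[[paste0("rep_log2p_", cond)]])
  list(hunger_pair = rank_by(pick("hunger_pair_exclusive"),
                             "summed_score_hunger"),
       hunger_single = rank_by(pick("hunger_single_exclusive"),
                               "rep_log2p_fasted_opened"),
       satiety_pair = rank_by(pick("satiety_pair_exclusive"),
                              "summed_score_satiety"),
       satiety_single = rank_by(pick("satiety_single_exclusive"),
                                "rep_log2p_leptin_opened"),
       radar = radar)
}

#' Write radar-plot data as JSON (four axes per motif)
#'
#' @param records a [prioritize_tfs()] data.frame
#' @param path output path
#' @param meta named list of run metadata stored alongside
#' @return invisibly, `path`
#' @export
write_radar_json <- function(records, path, meta = list()) {
  radar <- rank_and_export(records)$radar
  axes <- lapply(seq_len(nrow(radar)), function(i)
    list(motif_id = radar$motif_id[i],
         axes = as.list(radar[i, PEAK_CONDITIONS])))
  jsonlite::write_json(
    list(metadata = c(list(package = "concordTF", n_axes = 4L), meta),
         motifs = axes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
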