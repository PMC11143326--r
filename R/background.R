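# The six background control sets for motif enrichment, and the
# dinucleotide-preserving shuffle used for the sixth.

#' Dinucleotide-preserving sequence shuffle (Altschul-Erickson)
#'
#' Permutes a sequence while preserving its exact dinucleotide count multiset
#' and its first and last residue, by sampling a random Eulerian path through
#' the dinucleotide transition multigraph: a random "last exit" edge is drawn
#' for every non-terminal vertex until the chosen edges form an arborescence
#' into the terminal residue, remaining edges are permuted, and the path is
#' walked from the first residue.
#'
#' @param seq character scalar (length >= 2 for a nontrivial shuffle)
#' @param seed optional integer seed for reproducibility (caller RNG state is
#'   restored)
#' @return shuffled sequence
#' @export
dinuc_shuffle <- function(seq, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  with_seed(seed, {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    if (n < 2L) return(seq)
    verts <- unique(ch)
    if (length(verts) == 1L) return(seq)
    from <- ch[-n]; to <- ch[-1L]
    terminal <- ch[n]
    adj <- split(to, factor(from, levels = verts))
    nonterm <- setdiff(names(adj)[lengths(adj) > 0L], terminal)
    last_edge <- character(0)
    if (length(nonterm)) {
      repeat {
        last_edge <- vapply(nonterm, function(v) {
          a <- adj[[v]]; a[[sample.int(length(a), 1L)]]
        }, "")
        ok <- TRUE
        for (v in nonterm) {
          cur <- v; steps <- 0L
          while (cur != terminal) {
            if (!(cur %in% nonterm) || steps > length(verts)) {
              ok <- FALSE; break
            }
            cur <- last_edge[[cur]]
            steps <- steps + 1L
          }
          if (!ok) break
        }
        if (ok) break
      }
    }
    lists <- list()
    for (v in names(adj)) {
      a <- adj[[v]]
      if (!length(a)) next
      if (v %in% nonterm) {
        a <- a[-match(last_edge[[v]], a)]
        if (length(a) > 1L) a <- a[sample.int(length(a))]
        a <- c(a, last_edge[[v]])
      } else if (length(a) > 1L) {
        a <- a[sample.int(length(a))]
      }
      lists[[v]] <- a
    }
    ptr <- stats::setNames(rep(1L, length(lists)), names(lists))
    out <- character(n)
    out[1L] <- ch[1L]
    cur <- ch[1L]
    for (i in 2:n) {
      nxt <- lists[[cur]][[ptr[[cur]]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  })
}

# Contrast bookkeeping for a peak-set condition.
condition_contrast <- function(condition) {
  if (startsWith(condition, "fasted"))
    list(peak_sets = c("fasted_opened", "fasted_closed"),
         gene_sets = c("fasting_induced", "fasting_repressed"))
  else
    list(peak_sets = c("leptin_opened", "leptin_closed"),
         gene_sets = c("leptin_induced", "leptin_repressed"))
}

#' Build the six background control sets for one condition
#'
#' Neutral peaks are peaks significant in neither direction of the
#' condition's contrast; neutral genes are genes (of the supplied, expressed,
#' gene table) significant in neither direction of either contrast, so that
#' sets 2 and 3 partition the "near a gene" neutral peaks cleanly. The six
#' sets: (1) neutral peaks genome-wide; (2) neutral peaks within the TSS
#' window of a neutral gene; (3) neutral peaks within the window of a gene
#' significant in either contrast; (4) neutral peaks within the window of any
#' TSS; (5) all peaks not concordant for the condition; (6)
#' dinucleotide-shuffled copies of the foreground (concordant) sequences,
#' size- and length-matched by construction.
#'
#' @param condition one of fasted_opened, fasted_closed, leptin_opened,
#'   leptin_closed
#' @param concordant the condition's "concordant_set" from
#'   [assign_concordant_peaks()]
#' @param peaks data.frame of all peaks (chrom, start, end, peak_id)
#' @param reg a [regulated_sets()] object
#' @param genes data.frame of expressed genes (gene_id, chrom, tss)
#' @param genome named character vector of sequences
#' @param window_bp TSS window half-width (same as used for concordance)
#' @param seed seed for the shuffle (required for reproducibility)
#' @param max_n_frac N-fraction above which a sequence is dropped
#' @return object of class "background_suite": named list of six sets, each
#'   with label, peak_ids and seqs
#' @export
build_background_suite <- function(condition, concordant, peaks, reg, genes,
                                   genome, window_bp = 200000L, seed = NULL,
                                   max_n_frac = 0.5) {
  stopifnot(condition %in% names(CONDITION_PAIRING))
  cc <- condition_contrast(condition)
  sig_peaks <- unique(unlist(reg[cc$peak_sets], use.names = FALSE))
  neutral_peaks <- peaks[!peaks$peak_id %in% sig_peaks, , drop = FALSE]
  sig_genes_any <- unique(unlist(reg[c("fasting_induced", "fasting_repressed",
                                       "leptin_induced", "leptin_repressed")],
                                 use.names = FALSE))
  neutral_genes <- genes[!genes$gene_id %in% sig_genes_any, , drop = FALSE]
  near <- function(p, g) {
    if (!nrow(p) || !nrow(g)) return(p[0, , drop = FALSE])
    p[IRanges::overlapsAny(peaks_gr(p), tss_window_gr(g, window_bp)), ,
      drop = FALSE]
  }
  sets <- list(
    neutral_genomewide = neutral_peaks,
    neutral_near_neutral_genes = near(neutral_peaks, neutral_genes),
    neutral_near_significant_genes =
      near(neutral_peaks,
           genes[genes$gene_id %in% sig_genes_any, , drop = FALSE]),
    neutral_near_any_tss = near(neutral_peaks, genes),
    non_concordant = peaks[!peaks$peak_id %in% concordant$peak_ids, ,
                           drop = FALSE])
  out <- lapply(names(sets), function(lbl) {
    p <- sets[[lbl]]
    if (!nrow(p)) stop("background set '", lbl, "' is empty")
    seqs <- extract_peak_sequences(genome, p, max_n_frac = max_n_frac)
    if (!length(seqs)) stop("background set '", lbl, "' is empty")
    list(label = lbl, peak_ids = names(seqs), seqs = seqs)
  })
  names(out) <- names(sets)
  fg_peaks <- peaks[peaks$peak_id %in% concordant$peak_ids, , drop = FALSE]
  if (!nrow(fg_peaks)) stop("foreground (concordant) set is empty")
  fg_seqs <- extract_peak_sequences(genome, fg_peaks, max_n_frac = max_n_frac)
  shuf <- with_seed(seed, vapply(fg_seqs, dinuc_shuffle, ""))
  names(shuf) <- paste0(names(fg_seqs), "_shuf")
  out$shuffled_concordant <- list(label = "shuffled_concordant",
                                  peak_ids = names(fg_seqs), seqs = shuf)
  structure(out, class = "background_suite", condition = condition,
            seed = seed, window_bp = window_bp)
}

#' Precompute max log-odds scores for a set of sequences and motifs
#'
#' @param seqs named character vector of sequences
#' @param motifs list of motif objects
#' @param background 4-vector of A,C,G,T probabilities for the log-odds model
#' @param pseudocount smoothing constant
#' @return numeric matrix, sequences x motifs
#' @export
precompute_motif_scores <- function(seqs, motifs, background = rep(0.25, 4),
                                    pseudocount = 0.01) {
  ids <- vapply(motifs, `[[`, "", "motif_id")
  out <- matrix(-Inf, nrow = length(seqs), ncol = length(motifs),
                dimnames = list(names(seqs), ids))
  for (j in seq_along(motifs)) {
    lom <- pwm_to_log_odds(motifs[[j]], background, pseudocount)
    out[, j] <- score_sequences(seqs, lom)
  }
  out
}

#' Run AME-style enrichment of every motif against every background set
#'
#' For each motif and each of the six background sets, scores foreground and
#' background sequences (max log2-odds over positions and strands), computes
#' the optimal-threshold Fisher enrichment, and Bonferroni-adjusts: first by
#' the number of candidate thresholds, then by the number of motifs in the
#' library. All p-values are carried in log space.
#'
#' @param fg_seqs named character vector of foreground (concordant) sequences
#' @param suite a [build_background_suite()] object
#' @param motifs list of motif objects
#' @param background 4-vector of A,C,G,T probabilities for the log-odds model
#' @param pseudocount smoothing constant
#' @param score_cache optional matrix from [precompute_motif_scores()] (rows
#'   indexed by peak_id) reused for foreground and background sets 1-5
#' @return data.frame with one row per motif x background: motif_id,
#'   background_label, threshold_star, p_raw, log_p_raw, p_adj, log_p_adj,
#'   n_thresholds, fg_hits, fg_total, bg_hits, bg_total
#' @export
run_enrichment_suite <- function(fg_seqs, suite, motifs,
                                 background = rep(0.25, 4),
                                 pseudocount = 0.01, score_cache = NULL) {
  stopifnot(length(motifs) >= 1L, inherits(suite, "background_suite"))
  n_motifs <- length(motifs)
  rows <- vector("list", n_motifs * length(suite))
  k <- 0L
  for (mo in motifs) {
    lom <- NULL
    get_scores <- function(seqs) {
      ids <- names(seqs)
      if (!is.null(score_cache) && mo$motif_id %in% colnames(score_cache) &&
          all(ids %in% rownames(score_cache)))
        return(score_cache[ids, mo$motif_id])
      if (is.null(lom))
        lom <<- pwm_to_log_odds(mo, background, pseudocount)
      score_sequences(seqs, lom)
    }
    fg <- get_scores(fg_seqs)
    for (set in suite) {
      bg <- get_scores(set$seqs)
      e <- ame_optimal_enrichment(fg, bg)
      log_p_adj <- min(0, e$log_p_adj_thresholds + log(n_motifs))
      k <- k + 1L
      rows[[k]] <- data.frame(
        motif_id = mo$motif_id, background_label = set$label,
        threshold_star = e$threshold_star, p_raw = e$p_raw,
        log_p_raw = e$log_p_raw, p_adj = exp(log_p_adj),
        log_p_adj = log_p_adj, n_thresholds = e$n_thresholds,
        fg_hits = e$fg_hits, fg_total = e$fg_total,
        bg_hits = e$bg_hits, bg_total = e$bg_total,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
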