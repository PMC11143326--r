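# Assignment of direction-concordant differential peaks to differential genes
# within a +/- window of the TSS, association statistics, and genomic-feature
# annotation of peaks.

# Fixed direction pairing between peak conditions and gene sets.
CONDITION_PAIRING <- c(fasted_opened = "fasting_induced",
                       fasted_closed = "fasting_repressed",
                       leptin_opened = "leptin_induced",
                       leptin_closed = "leptin_repressed")

# GRanges from 0-based half-open peak coordinates (inclusive internal form).
peaks_gr <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start,
                                          end = peaks$end - 1L))
}

# GRanges of closed TSS windows [tss - w, tss + w] (strand-independent).
tss_window_gr <- function(genes, window_bp) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(start = genes$tss - window_bp,
                                          end = genes$tss + window_bp))
}

#' Assign direction-concordant peaks to genes near their TSS
#'
#' For each of the four conditions a peak is concordant iff its interval
#' overlaps the closed window \code{[tss - window_bp, tss + window_bp]} of at
#' least one direction-matched regulated gene on the same chromosome (any
#' overlapping base qualifies; the window is strand-independent). The pairing
#' is fixed: fasted_opened with fasting_induced, fasted_closed with
#' fasting_repressed, leptin_opened with leptin_induced, leptin_closed with
#' leptin_repressed. Peaks on chromosomes outside \code{chrom_allow} (when
#' given) can never be concordant, mirroring scaffold filtering.
#'
#' @param peaks data.frame with chrom, start, end, peak_id
#' @param genes data.frame with gene_id, chrom, tss
#' @param reg a [regulated_sets()] object
#' @param window_bp window half-width in bp (default 200000); must be >= 0
#' @param chrom_allow optional character vector of allowed chromosomes
#' @return named list (one "concordant_set" per condition) with elements
#'   condition, peak_ids (sorted), peak2genes and gene2peaks mappings
#' @export
assign_concordant_peaks <- function(peaks, genes, reg, window_bp = 200000L,
                                    chrom_allow = NULL) {
  if (!is.numeric(window_bp) || length(window_bp) != 1L || window_bp < 0)
    stop("window_bp must be a single number >= 0")
  stopifnot(all(c("chrom", "start", "end", "peak_id") %in% names(peaks)),
            all(c("gene_id", "chrom", "tss") %in% names(genes)))
  if (!is.null(chrom_allow)) peaks <- peaks[peaks$chrom %in% chrom_allow, ]
  out <- list()
  for (cond in names(CONDITION_PAIRING)) {
    gset <- reg[[CONDITION_PAIRING[[cond]]]]
    pset <- reg[[cond]]
    p <- peaks[peaks$peak_id %in% pset, , drop = FALSE]
    g <- genes[genes$gene_id %in% gset, , drop = FALSE]
    if (nrow(p) && nrow(g)) {
      hits <- GenomicRanges::findOverlaps(peaks_gr(p),
                                          tss_window_gr(g, window_bp))
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    } else {
      qh <- sh <- integer()
    }
    pid <- p$peak_id[qh]; gid <- g$gene_id[sh]
    o <- order(pid, gid)
    pid <- pid[o]; gid <- gid[o]
    peak_ids <- sort(unique(pid))
    out[[cond]] <- structure(
      list(condition = cond,
           peak_ids = peak_ids,
           peak2genes = split(gid, factor(pid, levels = peak_ids)),
           gene2peaks = split(pid, gid)),
      class = "concordant_set")
  }
  out
}

#' Association statistics between regulated genes and nearby regulated peaks
#'
#' Counts, for every condition gene and every neutral gene, the number of
#' peaks from \code{cond_peak_set} whose interval overlaps the closed
#' \code{[tss - window_bp, tss + window_bp]} window, and tests whether
#' condition genes are more likely than neutral genes to have at least one
#' such peak (one-tailed Fisher exact test, upper tail). Also reports the
#' peaks-per-gene histogram and the Spearman correlation between peak count
#' and |log2FC| over the condition genes.
#'
#' @param cond_gene_set character vector of condition gene ids
#' @param cond_peak_set character vector of same-direction differential peak
#'   ids
#' @param neutral_gene_set character vector of expressed genes significant in
#'   neither direction
#' @param genes data.frame with gene_id, chrom, tss
#' @param peaks data.frame with chrom, start, end, peak_id
#' @param window_bp window half-width in bp
#' @param lfc optional named numeric, gene_id -> log2FC (needed for rho)
#' @return object of class "association_stats": n_genes, n_genes_with_peak,
#'   fraction, p_value, log_p, peaks_per_gene histogram, rho
#' @export
association_stats <- function(cond_gene_set, cond_peak_set, neutral_gene_set,
                              genes, peaks, window_bp = 200000L, lfc = NULL) {
  if (!length(cond_gene_set)) stop("empty condition gene set")
  count_near <- function(gene_ids) {
    g <- genes[genes$gene_id %in% gene_ids, , drop = FALSE]
    p <- peaks[peaks$peak_id %in% cond_peak_set, , drop = FALSE]
    n <- stats::setNames(integer(nrow(g)), g$gene_id)
    if (nrow(p) && nrow(g)) {
      # the two range sets may live on disjoint chromosomes; that is a
      # legitimate zero-overlap case, not a seqlevels mismatch worth warning
      hits <- suppressWarnings(
        GenomicRanges::findOverlaps(tss_window_gr(g, window_bp),
                                    peaks_gr(p)))
      tab <- table(S4Vectors::queryHits(hits))
      n[as.integer(names(tab))] <- as.integer(tab)
    }
    n
  }
  nc <- count_near(cond_gene_set)
  nn <- count_near(neutral_gene_set)
  k_c <- sum(nc > 0); k_n <- sum(nn > 0)
  logp <- fisher_upper_tail(k_c, length(nc), k_n, length(nn), log = TRUE)
  rho <- NA_real_
  if (!is.null(lfc)) {
    l <- abs(lfc[names(nc)])
    if (sum(!is.na(l)) >= 3L && stats::sd(nc) > 0 && stats::sd(l, na.rm = TRUE) > 0)
      rho <- suppressWarnings(
        stats::cor(nc, l, method = "spearman", use = "complete.obs"))
  }
  hist <- table(nc[nc > 0])
  structure(list(n_genes = length(nc), n_genes_with_peak = k_c,
                 fraction = k_c / length(nc),
                 n_neutral = length(nn), n_neutral_with_peak = k_n,
                 neutral_fraction = if (length(nn)) k_n / length(nn) else NA_real_,
                 p_value = exp(logp), log_p = logp,
                 peaks_per_gene = hist, rho = rho,
                 peak_counts = nc),
            class = "association_stats")
}

#' Annotate peaks with genomic features
#'
#' Assigns each peak to promoter, exonic, intronic or intergenic with
#' precedence promoter > exonic > intronic > intergenic. The promoter is the
#' strand-aware 1 kb window immediately upstream of the TSS:
#' \code{[tss - promoter_bp, tss)} on the plus strand, mirrored on the minus
#' strand. When the gene models carry no exon intervals, exonic/intronic
#' collapse to "genic".
#'
#' @param peaks data.frame with chrom, start, end, peak_id
#' @param genes data.frame with gene_id, chrom, strand, tss, start, end and
#'   optionally \code{attr(,"exons")}
#' @param promoter_bp promoter width upstream of the TSS (default 1000)
#' @return named character vector peak_id -> feature, with a "fractions"
#'   attribute giving per-feature proportions
#' @export
annotate_peak_features <- function(peaks, genes, promoter_bp = 1000L) {
  pg <- peaks_gr(peaks)
  overlaps_any <- function(gr) {
    if (!length(gr)) return(logical(length(pg)))
    IRanges::overlapsAny(pg, gr)
  }
  plus <- genes$strand == "+"
  prom_start <- ifelse(plus, genes$tss - promoter_bp, genes$tss + 1L)
  prom_end <- ifelse(plus, genes$tss - 1L, genes$tss + promoter_bp)
  prom <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(prom_start, prom_end))
  exons <- attr(genes, "exons")
  has_exons <- !is.null(exons) && nrow(exons) > 0
  body <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start,
                                                  pmax(genes$end - 1L,
                                                       genes$start)))
  feat <- rep("intergenic", nrow(peaks))
  if (has_exons) {
    eg <- GenomicRanges::GRanges(exons$chrom,
                                 IRanges::IRanges(exons$start,
                                                  pmax(exons$end - 1L,
                                                       exons$start)))
    feat[overlaps_any(body)] <- "intronic"
    feat[overlaps_any(eg)] <- "exonic"
  } else {
    feat[overlaps_any(body)] <- "genic"
  }
  feat[overlaps_any(prom)] <- "promoter"
  names(feat) <- peaks$peak_id
  attr(feat, "fractions") <- prop.table(table(feat))
  feat
}
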