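# Classification of differential genes and peaks into regulated sets, the
# bidirectional gene sets, and a simple stand-in differential test for fully
# synthetic end-to-end runs.

#' Threshold configuration for differential classification
#'
#' Genes use a strict \code{>} cutoff on |log2FC| while peaks use an inclusive
#' \code{>=} cutoff, mirroring the asymmetry of the conventional definitions
#' for expression vs. accessibility; both are configurable. The CPM filter
#' requires the mean CPM to pass in at least one compared group by default
#' (\code{cpm_rule = "any"}), or in both (\code{"both"}).
#'
#' @param gene_lfc_min minimum |log2FC| for genes (strict >), default 0.5
#' @param peak_lfc_min minimum |log2FC| for peaks (inclusive >=), default 0.5
#' @param fdr_max FDR cutoff (strict <), default 0.05
#' @param gene_cpm_min minimum mean CPM for genes (strict >), default 1
#' @param peak_cpm_min minimum mean CPM for peaks (inclusive >=), default 1
#' @param cpm_rule "any": filter passes if any compared group passes; "both":
#'   all compared groups must pass
#' @return object of class "threshold_config"
#' @export
threshold_config <- function(gene_lfc_min = 0.5, peak_lfc_min = 0.5,
                             fdr_max = 0.05, gene_cpm_min = 1,
                             peak_cpm_min = 1, cpm_rule = c("any", "both")) {
  chk_num(gene_lfc_min, "gene_lfc_min", min = 0)
  chk_num(peak_lfc_min, "peak_lfc_min", min = 0)
  chk_num(fdr_max, "fdr_max", min = 0, max = 1, strict_min = TRUE)
  chk_num(gene_cpm_min, "gene_cpm_min", min = 0)
  chk_num(peak_cpm_min, "peak_cpm_min", min = 0)
  structure(list(gene_lfc_min = gene_lfc_min, peak_lfc_min = peak_lfc_min,
                 fdr_max = fdr_max, gene_cpm_min = gene_cpm_min,
                 peak_cpm_min = peak_cpm_min, cpm_rule = match.arg(cpm_rule)),
            class = "threshold_config")
}

# mean_cpm filter over the mean_cpm_<group> columns of a diff table.
cpm_pass <- function(table, cpm_min, inclusive, rule) {
  cols <- grep("^mean_cpm_", names(table), value = TRUE)
  m <- as.matrix(table[, cols, drop = FALSE])
  hit <- if (inclusive) m >= cpm_min else m > cpm_min
  if (rule == "any") rowSums(hit) > 0 else rowSums(hit) == ncol(m)
}

check_diff_cols <- function(table) {
  miss <- setdiff(c("id", "log2fc", "fdr"), names(table))
  if (length(miss))
    format_error("differential table lacks column(s): ",
                 paste(miss, collapse = ", "))
  if (!any(startsWith(names(table), "mean_cpm_")))
    format_error("differential table lacks mean_cpm_<group> columns")
}

#' Classify differential genes into induced and repressed sets
#'
#' A gene is induced when \code{log2fc > gene_lfc_min}, \code{fdr < fdr_max}
#' and its mean CPM exceeds \code{gene_cpm_min} in at least one compared group
#' (strict inequalities); repressed analogously with \code{log2fc <
#' -gene_lfc_min}.
#'
#' @param table differential gene table (id, log2fc, fdr, mean_cpm_<group>)
#' @param cfg a [threshold_config()]
#' @return list with character vectors `induced` and `repressed`
#' @export
classify_diff_genes <- function(table, cfg = threshold_config()) {
  check_diff_cols(table)
  expr_ok <- cpm_pass(table, cfg$gene_cpm_min, inclusive = FALSE,
                      rule = cfg$cpm_rule)
  sig <- table$fdr < cfg$fdr_max & expr_ok
  list(induced = table$id[sig & table$log2fc > cfg$gene_lfc_min],
       repressed = table$id[sig & table$log2fc < -cfg$gene_lfc_min])
}

#' Classify differential peaks into opened and closed sets
#'
#' A peak is opened when \code{log2fc >= peak_lfc_min}, \code{fdr < fdr_max}
#' and mean CPM \code{>= peak_cpm_min} (inclusive, unlike genes); closed
#' analogously with \code{log2fc <= -peak_lfc_min}.
#'
#' @inheritParams classify_diff_genes
#' @return list with character vectors `opened` and `closed`
#' @export
classify_diff_peaks <- function(table, cfg = threshold_config()) {
  check_diff_cols(table)
  cpm_ok <- cpm_pass(table, cfg$peak_cpm_min, inclusive = TRUE,
                     rule = cfg$cpm_rule)
  sig <- table$fdr < cfg$fdr_max & cpm_ok
  list(opened = table$id[sig & table$log2fc >= cfg$peak_lfc_min],
       closed = table$id[sig & table$log2fc <= -cfg$peak_lfc_min])
}

#' Build the eight regulated sets from the two contrasts
#'
#' @param gene_tables named list of differential gene tables with elements
#'   `fasted_vs_fed` and `leptin_vs_fasted`
#' @param peak_tables named list of differential peak tables, same elements
#' @param cfg a [threshold_config()]
#' @return object of class "regulated_sets": character-vector sets
#'   fasting_induced/fasting_repressed/leptin_induced/leptin_repressed (genes)
#'   and fasted_opened/fasted_closed/leptin_opened/leptin_closed (peaks)
#' @export
regulated_sets <- function(gene_tables, peak_tables,
                           cfg = threshold_config()) {
  need <- c("fasted_vs_fed", "leptin_vs_fasted")
  stopifnot(all(need %in% names(gene_tables)),
            all(need %in% names(peak_tables)))
  gf <- classify_diff_genes(gene_tables$fasted_vs_fed, cfg)
  gl <- classify_diff_genes(gene_tables$leptin_vs_fasted, cfg)
  pf <- classify_diff_peaks(peak_tables$fasted_vs_fed, cfg)
  pl <- classify_diff_peaks(peak_tables$leptin_vs_fasted, cfg)
  structure(list(fasting_induced = gf$induced,
                 fasting_repressed = gf$repressed,
                 leptin_induced = gl$induced,
                 leptin_repressed = gl$repressed,
                 fasted_opened = pf$opened, fasted_closed = pf$closed,
                 leptin_opened = pl$opened, leptin_closed = pl$closed),
            class = "regulated_sets")
}

#' Bidirectionally regulated gene sets
#'
#' Genes induced by fasting and repressed by leptin, and vice versa.
#'
#' @param reg a [regulated_sets()] object (or compatible list)
#' @return list with `fast_up_leptin_down` and `fast_down_leptin_up`
#' @export
bidirectional_sets <- function(reg) {
  list(fast_up_leptin_down = intersect(reg$fasting_induced,
                                       reg$leptin_repressed),
       fast_down_leptin_up = intersect(reg$fasting_repressed,
                                       reg$leptin_induced))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (monotone, capped at 1, returned in input
#' order); a validated front-end to \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvalues numeric vector of p-values in [0,1]
#' @return adjusted p-values, same order
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("pvalues must be numeric")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Simple stand-in differential test on a count matrix
#'
#' Computes, per feature, the log2 fold change of group-mean CPM (with a
#' pseudo-CPM offset equivalent to 0.5 counts at the mean library size, so an
#' all-zero feature has log2FC exactly 0) and a Welch two-sample t-test on
#' log2 CPM, BH-adjusted. This is a deterministic, dependency-free stand-in
#' for a negative-binomial GLM framework (edgeR and friends), intended for
#' synthetic data; externally computed differential tables are the recommended
#' input for real experiments.
#'
#' @param counts integer matrix, features x samples (rownames = feature ids)
#' @param groups character vector, one condition label per sample column
#' @param contrast length-2 character vector c(treatment, reference); log2FC
#'   is treatment minus reference
#' @return differential table data.frame: id, log2fc, pvalue, fdr and
#'   mean_cpm_<group> for the two compared groups
#' @export
simple_de_test <- function(counts, groups, contrast) {
  stopifnot(is.matrix(counts), length(groups) == ncol(counts),
            length(contrast) == 2L, all(contrast %in% groups))
  i1 <- which(groups == contrast[1L])   # treatment
  i0 <- which(groups == contrast[2L])   # reference
  if (length(i1) < 2L || length(i0) < 2L)
    stop("each compared group needs >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero total counts")
  pseudo <- 0.5 / mean(lib) * 1e6          # 0.5-count-equivalent CPM offset
  cpm <- t(t(counts) / lib * 1e6)
  lcpm <- log2(cpm + pseudo)
  m1 <- rowMeans(cpm[, i1, drop = FALSE])
  m0 <- rowMeans(cpm[, i0, drop = FALSE])
  log2fc <- log2(m1 + pseudo) - log2(m0 + pseudo)
  x1 <- lcpm[, i1, drop = FALSE]; x0 <- lcpm[, i0, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  mu1 <- rowMeans(x1); mu0 <- rowMeans(x0)
  v1 <- rowSums((x1 - mu1)^2) / (n1 - 1L)
  v0 <- rowSums((x0 - mu0)^2) / (n0 - 1L)
  se2 <- v1 / n1 + v0 / n0
  tt <- (mu1 - mu0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v0 / n0)^2 / (n0 - 1L))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  # degenerate features (zero variance in both groups): p = 1 when means agree
  degen <- se2 == 0
  p[degen] <- ifelse(abs(mu1[degen] - mu0[degen]) < 1e-12, 1, 0)
  p[!is.finite(p)] <- 1
  ids <- rownames(counts) %||% sprintf("feature_%d", seq_len(nrow(counts)))
  out <- data.frame(id = ids, log2fc = log2fc, pvalue = p,
                    fdr = bh_adjust(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  out[[paste0("mean_cpm_", contrast[1L])]] <- m1
  out[[paste0("mean_cpm_", contrast[2L])]] <- m0
  out
}
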