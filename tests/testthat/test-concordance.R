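# Window-overlap concordance assignment, association statistics and
# genomic-feature annotation.

# Minimal fixture: one regulated gene per condition-matched set.
toy_concordance <- function(peak_start, peak_end, tss = 1000000L,
                            window = 200000L) {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = tss, start = tss, end = tss + 1000L,
                      stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = peak_start, end = peak_end,
                      peak_id = sprintf("p%d", seq_along(peak_start)),
                      stringsAsFactors = FALSE)
  reg <- list(fasting_induced = "g1", fasting_repressed = character(),
              leptin_induced = character(), leptin_repressed = character(),
              fasted_opened = peaks$peak_id, fasted_closed = character(),
              leptin_opened = character(), leptin_closed = character())
  assign_concordant_peaks(peaks, genes, reg, window_bp = window)
}

test_that("window boundaries are closed at exactly +/-200 kb", {
  # overlapping the window end at 1,200,000 qualifies
  cs <- toy_concordance(1199900L, 1200100L)
  expect_identical(cs$fasted_opened$peak_ids, "p1")
  # starting one base past the window end does not
  cs <- toy_concordance(1200001L, 1200050L)
  expect_length(cs$fasted_opened$peak_ids, 0)
  # a peak whose first base sits exactly on tss + w qualifies
  cs <- toy_concordance(1200000L, 1200050L)
  expect_identical(cs$fasted_opened$peak_ids, "p1")
  # symmetric on the left edge: last base exactly on tss - w
  cs <- toy_concordance(799900L, 800001L)
  expect_identical(cs$fasted_opened$peak_ids, "p1")
  cs <- toy_concordance(799900L, 800000L)
  expect_length(cs$fasted_opened$peak_ids, 0)
})

test_that("a peak at +d is concordant iff its mirror at -d is", {
  for (d in c(0L, 1234L, 199999L, 200000L, 200001L)) {
    # nearest base at +d: peak starts at tss + d; mirror: peak's last base
    # (end - 1) sits at tss - d
    right <- toy_concordance(1000000L + d, 1000000L + d + 50L)
    left <- toy_concordance(1000000L - d - 49L, 1000000L - d + 1L)
    expect_identical(length(right$fasted_opened$peak_ids) > 0,
                     length(left$fasted_opened$peak_ids) > 0,
                     info = sprintf("d=%d", d))
  }
})

test_that("window_bp = 0 reduces to overlap with the single-base TSS window", {
  cs <- toy_concordance(999990L, 1000001L, window = 0L)  # covers the TSS base
  expect_identical(cs$fasted_opened$peak_ids, "p1")
  cs <- toy_concordance(999990L, 1000000L, window = 0L)  # stops short
  expect_length(cs$fasted_opened$peak_ids, 0)
  expect_error(toy_concordance(0L, 10L, window = -1L), "window_bp")
})


test_that("assignment equals the all-pairs brute-force oracle", {
  for (seed in c(7, 8, 9)) {
    fx <- random_concordance_fixture(1000, 200, seed)
    reg <- list(fasting_induced = fx$gset, fasting_repressed = character(),
                leptin_induced = character(), leptin_repressed = character(),
                fasted_opened = fx$pset, fasted_closed = character(),
                leptin_opened = character(), leptin_closed = character())
    cs <- assign_concordant_peaks(fx$peaks, fx$genes, reg)
    oracle <- brute_concordant_ids(fx$peaks, fx$genes, fx$gset, fx$pset,
                                   200000L)
    expect_identical(cs$fasted_opened$peak_ids, oracle)
  }
})

test_that("assignment is invariant to input row order", {
  fx <- random_concordance_fixture(500, 100, 21)
  reg <- list(fasting_induced = fx$gset, fasting_repressed = character(),
              leptin_induced = character(), leptin_repressed = character(),
              fasted_opened = fx$pset, fasted_closed = character(),
              leptin_opened = character(), leptin_closed = character())
  a <- assign_concordant_peaks(fx$peaks, fx$genes, reg)
  set.seed(1)
  b <- assign_concordant_peaks(fx$peaks[sample(nrow(fx$peaks)), ],
                               fx$genes[sample(nrow(fx$genes)), ], reg)
  expect_identical(a$fasted_opened$peak_ids, b$fasted_opened$peak_ids)
  expect_identical(a$fasted_opened$peak2genes, b$fasted_opened$peak2genes)
})

test_that("peaks on disallowed chromosomes are never concordant", {
  genes <- data.frame(gene_id = "g1", chrom = "scaffold_1", strand = "+",
                      tss = 1000L, stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "scaffold_1", start = 900L, end = 1100L,
                      peak_id = "p1", stringsAsFactors = FALSE)
  reg <- list(fasting_induced = "g1", fasting_repressed = character(),
              leptin_induced = character(), leptin_repressed = character(),
              fasted_opened = "p1", fasted_closed = character(),
              leptin_opened = character(), leptin_closed = character())
  with_allow <- assign_concordant_peaks(peaks, genes, reg,
                                        chrom_allow = "chr1")
  expect_length(with_allow$fasted_opened$peak_ids, 0)
  without <- assign_concordant_peaks(peaks, genes, reg)
  expect_identical(without$fasted_opened$peak_ids, "p1")
})

test_that("peak-to-gene and gene-to-peak mappings are mutually consistent", {
  fx <- random_concordance_fixture(800, 150, 33)
  reg <- list(fasting_induced = fx$gset, fasting_repressed = character(),
              leptin_induced = character(), leptin_repressed = character(),
              fasted_opened = fx$pset, fasted_closed = character(),
              leptin_opened = character(), leptin_closed = character())
  cs <- assign_concordant_peaks(fx$peaks, fx$genes, reg)$fasted_opened
  for (p in names(cs$peak2genes))
    for (g in cs$peak2genes[[p]])
      expect_true(p %in% cs$gene2peaks[[g]])
  expect_true(all(unlist(cs$peak2genes) %in% fx$gset))
  expect_false(anyDuplicated(cs$peak_ids) > 0)
})

test_that("association statistics match hypergeometric enumeration", {
  # 10/10 condition genes with peaks vs 0/100 neutral genes
  genes <- data.frame(
    gene_id = sprintf("g%03d", 1:110),
    chrom = c(rep("chr1", 10), rep("chr2", 100)),
    strand = "+",
    tss = c(seq(1e6, by = 1e6, length.out = 10),
            seq(1e6, by = 1e6, length.out = 100)),
    stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1",
                      start = seq(1e6, by = 1e6, length.out = 10) + 100,
                      end = seq(1e6, by = 1e6, length.out = 10) + 300,
                      peak_id = sprintf("p%02d", 1:10),
                      stringsAsFactors = FALSE)
  st <- association_stats(genes$gene_id[1:10], peaks$peak_id,
                          genes$gene_id[11:110], genes, peaks)
  expect_identical(st$fraction, 1)
  expect_identical(st$n_neutral_with_peak, 0L)
  expect_lt(st$p_value, 1e-6)
  expect_equal(st$p_value, enum_fisher_upper(10, 10, 0, 100),
               tolerance = 1e-10)
  expect_error(association_stats(character(), peaks$peak_id,
                                 genes$gene_id, genes, peaks), "empty")
})

test_that("association p is ~1 when condition matches the neutral composition", {
  set.seed(9)
  fx <- random_concordance_fixture(300, 120, 17)
  g <- fx$genes$gene_id
  st <- association_stats(g[1:60], fx$pset, g[61:120], fx$genes, fx$peaks)
  expect_gt(st$p_value, 0.05)
})

test_that("rho is positive when peak count grows with fold change", {
  # construct genes whose concordant peak count is proportional to |lfc|
  n <- 30
  genes <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
                      strand = "+", tss = seq(2e6, by = 2e6, length.out = n),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (i in 1:n) {
    k <- ceiling(i / 6)          # 1..5 peaks
    for (j in seq_len(k)) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = "chr1", start = genes$tss[i] + j * 1000L,
        end = genes$tss[i] + j * 1000L + 200L,
        peak_id = sprintf("p_%02d_%d", i, j), stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, rows)
  lfc <- stats::setNames(0.6 + 0.1 * seq_len(n), genes$gene_id)
  st <- association_stats(genes$gene_id, peaks$peak_id,
                          genes$gene_id[1:2], genes, peaks, lfc = lfc)
  expect_gt(st$rho, 0.8)
  expect_identical(sum(st$peaks_per_gene), st$n_genes_with_peak)
})

test_that("feature annotation applies promoter > exonic > intronic > intergenic", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(10000L, 30000L),
                      start = c(10000L, 22001L), end = c(18000L, 30001L),
                      stringsAsFactors = FALSE)
  attr(genes, "exons") <- data.frame(
    gene_id = c("gp", "gp"), chrom = "chr1",
    start = c(10000L, 17000L), end = c(10500L, 18000L),
    stringsAsFactors = FALSE)
  peaks <- data.frame(
    chrom = "chr1",
    start = c(9200L, 10100L, 12000L, 50000L, 30200L, 16900L),
    end = c(9900L, 10400L, 12500L, 50500L, 30800L, 17100L),
    peak_id = c("prom_plus", "exon1", "intron", "far", "prom_minus",
                "exon_edge"),
    stringsAsFactors = FALSE)
  f <- annotate_peak_features(peaks, genes)
  expect_identical(unname(f["prom_plus"]), "promoter")   # [tss-1000, tss)
  expect_identical(unname(f["exon1"]), "exonic")
  expect_identical(unname(f["intron"]), "intronic")
  expect_identical(unname(f["far"]), "intergenic")
  expect_identical(unname(f["prom_minus"]), "promoter")  # mirrored window
  expect_identical(unname(f["exon_edge"]), "exonic")

  # promoter wins over another gene's exon
  genes2 <- genes
  attr(genes2, "exons") <- data.frame(gene_id = "gp", chrom = "chr1",
                                      start = 29200L, end = 30400L,
                                      stringsAsFactors = FALSE)
  f2 <- annotate_peak_features(
    data.frame(chrom = "chr1", start = 30100L, end = 30900L,
               peak_id = "conflict", stringsAsFactors = FALSE), genes2)
  expect_identical(unname(f2["conflict"]), "promoter")

  # no exon information: genic collapse
  genes3 <- genes
  attr(genes3, "exons") <- NULL
  f3 <- annotate_peak_features(peaks, genes3)
  expect_identical(unname(f3["intron"]), "genic")
})
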