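# Independent oracles and small fixture builders shared across the suite.
# Every oracle here is written from the definition (enumeration, brute
# force), never by calling the code path it checks.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exhaustive hypergeometric upper tail: P(X >= a) for the 2x2 table
# (a, A - a; b, B - b), by direct summation of choose() ratios (exact in
# double arithmetic for the small totals it is used with).
enum_fisher_upper <- function(a, A, b, B) {
  h <- a + b
  N <- A + B
  ks <- a:min(h, A)
  sum(choose(h, ks) * choose(N - h, A - ks)) / choose(N, A)
}

# Brute-force best double-strand window score, straight from the definition:
# every offset of the sequence and of its reverse complement, summing
# log-odds entries one base at a time; windows containing N are skipped.
brute_best_score <- function(seq, lom_mat) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
  L <- nrow(lom_mat)
  best <- -Inf
  for (s in c(seq, rc)) {
    ch <- strsplit(s, "")[[1]]
    if (length(ch) < L) next
    for (i in seq_len(length(ch) - L + 1)) {
      w <- ch[i:(i + L - 1)]
      if (any(w == "N")) next
      sc <- sum(vapply(seq_len(L), function(k)
        lom_mat[k, match(w[k], c("A", "C", "G", "T"))], 0))
      best <- max(best, sc)
    }
  }
  best
}

# Brute-force optimal-threshold enrichment: scan every candidate threshold,
# including background score values.
brute_optimal_p <- function(fg, bg) {
  ts <- sort(unique(c(fg, bg)))
  min(vapply(ts, function(t)
    fisher_upper_tail(sum(fg >= t), length(fg), sum(bg >= t), length(bg)),
    0))
}

# All-pairs concordance oracle: a peak is concordant iff, for some
# direction-matched gene on the same chromosome, the peak interval
# [start, end) overlaps the closed window [tss - w, tss + w].
brute_concordant_ids <- function(peaks, genes, gene_ids, peak_ids, w) {
  p <- peaks[peaks$peak_id %in% peak_ids, , drop = FALSE]
  g <- genes[genes$gene_id %in% gene_ids, , drop = FALSE]
  hit <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    same <- g$chrom == p$chrom[i]
    if (!any(same)) next
    tss <- g$tss[same]
    hit[i] <- any(p$start[i] <= tss + w & p$end[i] - 1 >= tss - w)
  }
  sort(p$peak_id[hit])
}

dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) < 2) return(table(character()))
  table(paste0(ch[-length(ch)], ch[-1]))
}

# A sharply peaked random PWM (for decoy/null motif batteries).
random_pwm <- function(id, width = 8, sharp = 4) {
  m <- matrix(stats::runif(width * 4)^sharp, ncol = 4)
  m <- m / rowSums(m)
  colnames(m) <- c("A", "C", "G", "T")
  structure(list(motif_id = id, alt_name = id, matrix = m, nsites = 20L,
                 background = rep(0.25, 4)),
            class = "pwm_motif")
}

# Uniform-probability PWM of a given width.
uniform_pwm <- function(width = 4, id = "UNIF") {
  m <- matrix(0.25, nrow = width, ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  structure(list(motif_id = id, alt_name = id, matrix = m, nsites = 20L,
                 background = rep(0.25, 4)),
            class = "pwm_motif")
}

# Strong consensus PWM helper mirroring a laboratory-style motif.
consensus_test_pwm <- function(consensus, id = "CONS", dominance = 0.97) {
  bases <- c("A", "C", "G", "T")
  idx <- match(strsplit(consensus, "")[[1]], bases)
  m <- matrix((1 - dominance) / 3, nrow = length(idx), ncol = 4,
              dimnames = list(NULL, bases))
  m[cbind(seq_along(idx), idx)] <- dominance
  structure(list(motif_id = id, alt_name = id, matrix = m, nsites = 20L,
                 background = rep(0.25, 4)),
            class = "pwm_motif")
}

# Tiny deterministic differential-table builder.
make_diff_table <- function(ids, log2fc, fdr, cpm_a, cpm_b = cpm_a) {
  data.frame(id = ids, log2fc = log2fc, fdr = fdr,
             mean_cpm_x = cpm_a, mean_cpm_y = cpm_b,
             stringsAsFactors = FALSE)
}

# Small cached simulation shared by tests that only need one realization.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_hunger_study(sim_config(seed = 11L))
    cache
  }
})

# Differential tables for both contrasts of a simulation.
sim_diff_tables <- function(sim) {
  de <- function(m)
    list(fasted_vs_fed = simple_de_test(m, sim$counts$groups,
                                        c("fasted", "fed")),
         leptin_vs_fasted = simple_de_test(m, sim$counts$groups,
                                           c("leptin", "fasted")))
  list(genes = de(sim$counts$gene_counts), peaks = de(sim$counts$peak_counts))
}

# Full pipeline run for a simulation (in-memory).
run_sim_pipeline <- function(sim, ...) {
  dt <- sim_diff_tables(sim)
  run_hunger_tf(sim$genes, sim$peaks, dt$genes, dt$peaks, sim$motifs,
                sim$genome, seed = sim$cfg$seed, ...)
}

# Random peak/gene fixture for concordance oracle checks.
random_concordance_fixture <- function(n_peaks, n_genes, seed) {
  set.seed(seed)
  chroms <- c("chr1", "chr2", "chr3")
  glen <- 5e6
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    chrom = sample(chroms, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    tss = as.integer(runif(n_genes, 0, glen)), stringsAsFactors = FALSE)
  start <- as.integer(runif(n_peaks, 0, glen - 500))
  peaks <- data.frame(
    chrom = sample(chroms, n_peaks, replace = TRUE), start = start,
    end = start + as.integer(runif(n_peaks, 100, 500)),
    peak_id = sprintf("p%05d", seq_len(n_peaks)), stringsAsFactors = FALSE)
  # force some window-boundary peaks at exactly +/- 200,000 bp
  k <- min(20L, n_peaks, n_genes)
  bidx <- seq_len(k)
  peaks$chrom[bidx] <- genes$chrom[bidx]
  peaks$start[bidx] <- genes$tss[bidx] +
    sample(c(200000L, -200000L, 200001L, -200001L), k, replace = TRUE)
  peaks$end[bidx] <- peaks$start[bidx] + 1L
  gset <- sample(genes$gene_id, ceiling(n_genes / 3))
  pset <- sample(peaks$peak_id, ceiling(n_peaks / 2))
  list(genes = genes, peaks = peaks, gset = gset, pset = pset)
}
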