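# Self-contained simulator: a random genome, gene models and peaks with
# designed concordant links, negative-binomial count matrices across the
# three conditions (fed, fasted, leptin), and a motif library whose causal
# members are planted into condition-concordant peaks at elevated rate.

#' Simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the test
#' suite: three conditions with 4 replicates each, |log2 effect| = 2 on
#' regulated features, NB dispersion 0.05 (Var = mu + 0.05 mu^2), at least
#' 50 designed concordant peaks per condition, causal motifs planted with
#' probability 0.8 in their designated concordant peaks and 0.05 elsewhere,
#' and a +/-200 kb concordance window.
#'
#' @param seed integer master seed; every artifact is a pure function of the
#'   config
#' @param n_chroms number of chromosomes
#' @param chrom_length_bp length of each chromosome
#' @param base_comp 4-vector of A,C,G,T genome composition
#' @param n_genes_per_class named integer vector over classes fasting_up,
#'   fasting_down, leptin_up, leptin_down, bidir_fast_up, bidir_fast_down,
#'   neutral
#' @param n_concordant designed concordant peaks per condition
#' @param n_nonconcordant regulated but deliberately non-concordant peaks per
#'   condition (placed beyond \code{nonconc_min_bp} of every matched gene)
#' @param n_neutral_peaks neutral peaks scattered genome-wide
#' @param peak_len_range min/max peak length in bp
#' @param n_reps replicates per condition (>= 2)
#' @param effect_size planted |log2 fold change| on regulated features
#' @param dispersion NB dispersion alpha in Var = mu + alpha mu^2
#' @param base_mean_meanlog,base_mean_sdlog log-normal base-mean parameters
#' @param lib_factor_sd sd of log-normal per-sample library-size factors
#' @param p_fg plant probability in designated concordant peaks
#' @param p_bg plant probability in all other peaks
#' @param n_decoys decoy motifs (column-shuffled copies of the causal PWMs)
#' @param motif_width causal motif width in bp
#' @param window_bp concordance window half-width
#' @param link_max_bp maximum designed TSS-peak distance (inside the window)
#' @param nonconc_min_bp minimum distance of designed non-links (beyond the
#'   window)
#' @param tss_min_spacing minimum spacing between TSSs
#' @param scaffold_peaks neutral peaks placed on a non-chromosomal scaffold
#'   (exercises allow-list filtering); 0 disables the scaffold
#' @return object of class "sim_config"
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L,
                       chrom_length_bp = 3e6,
                       base_comp = rep(0.25, 4),
                       n_genes_per_class = c(fasting_up = 15L,
                                             fasting_down = 15L,
                                             leptin_up = 15L,
                                             leptin_down = 15L,
                                             bidir_fast_up = 12L,
                                             bidir_fast_down = 6L,
                                             neutral = 150L),
                       n_concordant = 60L,
                       n_nonconcordant = 25L,
                       n_neutral_peaks = 500L,
                       peak_len_range = c(300L, 500L),
                       n_reps = 4L,
                       effect_size = 2,
                       dispersion = 0.05,
                       base_mean_meanlog = log(100),
                       base_mean_sdlog = 0.5,
                       lib_factor_sd = 0.1,
                       p_fg = 0.8,
                       p_bg = 0.05,
                       n_decoys = 6L,
                       motif_width = 10L,
                       window_bp = 200000L,
                       link_max_bp = 190000L,
                       nonconc_min_bp = 210000L,
                       tss_min_spacing = 5000L,
                       scaffold_peaks = 8L) {
  stopifnot(n_reps >= 2L, p_fg >= 0, p_fg <= 1, p_bg >= 0, p_bg <= 1,
            abs(sum(base_comp) - 1) < 1e-6, effect_size >= 0,
            dispersion > 0, length(peak_len_range) == 2L)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

GENE_CLASSES <- c("fasting_up", "fasting_down", "leptin_up", "leptin_down",
                  "bidir_fast_up", "bidir_fast_down", "neutral")

# log2 effects (fasted vs fed, leptin vs fasted) per gene class
gene_class_effects <- function(class, e) {
  switch(class,
         fasting_up = c(e, 0), fasting_down = c(-e, 0),
         leptin_up = c(0, e), leptin_down = c(0, -e),
         bidir_fast_up = c(e, -e), bidir_fast_down = c(-e, e),
         neutral = c(0, 0))
}

peak_class_effects <- function(class, e) {
  switch(class,
         fasted_opened = c(e, 0), fasted_closed = c(-e, 0),
         leptin_opened = c(0, e), leptin_closed = c(0, -e),
         neutral = c(0, 0))
}

# Gene sets matched to each peak condition in the generator's truth.
truth_matched_classes <- list(
  fasted_opened = c("fasting_up", "bidir_fast_up"),
  fasted_closed = c("fasting_down", "bidir_fast_down"),
  leptin_opened = c("leptin_up", "bidir_fast_down"),
  leptin_closed = c("leptin_down", "bidir_fast_up"))

#' Generate a random genome
#'
#' I.i.d. nucleotides at the configured base composition; deterministic given
#' the config seed.
#'
#' @param cfg a [sim_config()]
#' @return named character vector of chromosome sequences (plus a scaffold
#'   when configured)
#' @export
generate_genome <- function(cfg) {
  with_seed(cfg$seed, {
    chrom_names <- sprintf("chr%d", seq_len(cfg$n_chroms))
    genome <- vapply(chrom_names, function(nm) {
      idx <- sample.int(4L, cfg$chrom_length_bp, replace = TRUE,
                        prob = cfg$base_comp)
      intToUtf8(c(65L, 67L, 71L, 84L)[idx])
    }, "")
    if (cfg$scaffold_peaks > 0L) {
      idx <- sample.int(4L, 50000L, replace = TRUE, prob = cfg$base_comp)
      genome <- c(genome, scaffold_1 = intToUtf8(c(65L, 67L, 71L, 84L)[idx]))
    }
    genome
  })
}

#' Generate gene models, peaks and designed concordant links
#'
#' TSSs are placed on a jittered grid with guaranteed minimum spacing, gene
#' classes are assigned at random, and three peak groups are placed: designed
#' concordant peaks within \code{link_max_bp} of a matched regulated gene's
#' TSS, designed non-concordant regulated peaks beyond \code{nonconc_min_bp}
#' of every matched gene, and neutral peaks anywhere (including the scaffold
#' when configured).
#'
#' @param cfg a [sim_config()]
#' @param genome from [generate_genome()]
#' @return list with genes (data.frame, exons in attr), peaks (data.frame),
#'   and truth (gene_classes, peak_classes, designed_links, designed_nonlinks)
#' @export
generate_annotation <- function(cfg, genome) {
  chroms <- grep("^chr", names(genome), value = TRUE)
  clen <- nchar(genome[chroms])
  margin <- cfg$link_max_bp + 10000L
  with_seed(cfg$seed + 1L, {
    n_genes <- sum(cfg$n_genes_per_class)
    per_chrom <- diff(round(seq(0, n_genes, length.out = length(chroms) + 1L)))
    tss <- integer(0); gchrom <- character(0)
    for (i in seq_along(chroms)) {
      usable <- clen[i] - 2 * margin
      k <- per_chrom[i]
      if (k == 0L) next
      slot <- usable / k
      if (slot <= cfg$tss_min_spacing)
        stop("chromosome too short for requested gene count and spacing")
      off <- runif(k, 0, slot - cfg$tss_min_spacing)
      tss <- c(tss, as.integer(margin + (seq_len(k) - 1L) * slot + off))
      gchrom <- c(gchrom, rep(chroms[i], k))
    }
    classes <- sample(rep(names(cfg$n_genes_per_class),
                          cfg$n_genes_per_class))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    body_len <- as.integer(runif(n_genes, 2000, 10000))
    gstart <- ifelse(strand == "+", tss, tss - body_len + 1L)
    gend <- gstart + body_len
    gene_id <- sprintf("gene_%03d", seq_len(n_genes))
    genes <- data.frame(gene_id = gene_id, chrom = gchrom, strand = strand,
                        tss = tss, start = as.integer(gstart),
                        end = as.integer(gend), stringsAsFactors = FALSE)
    # two exons per gene: one at each end of the body
    exons <- rbind(
      data.frame(gene_id = gene_id, chrom = gchrom,
                 start = as.integer(gstart),
                 end = as.integer(gstart + 300L), stringsAsFactors = FALSE),
      data.frame(gene_id = gene_id, chrom = gchrom,
                 start = as.integer(gend - 500L), end = as.integer(gend),
                 stringsAsFactors = FALSE))
    attr(genes, "exons") <- exons[order(exons$gene_id, exons$start), ]
    gene_classes <- stats::setNames(classes, gene_id)

    plen <- function(n) as.integer(runif(n, cfg$peak_len_range[1L],
                                         cfg$peak_len_range[2L]))
    peaks <- list(); links <- list(); nonlinks <- list()
    pclass <- character(0)
    for (cond in PEAK_CONDITIONS) {
      matched <- gene_id[gene_classes %in% truth_matched_classes[[cond]]]
      host <- rep_len(matched, cfg$n_concordant)
      d <- as.integer(runif(cfg$n_concordant, -cfg$link_max_bp,
                            cfg$link_max_bp))
      ht <- genes$tss[match(host, genes$gene_id)]
      len <- plen(cfg$n_concordant)
      start <- pmax(0L, pmin(ht + d, clen[genes$chrom[match(host, genes$gene_id)]] - len))
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = genes$chrom[match(host, genes$gene_id)],
        start = as.integer(start), end = as.integer(start + len),
        stringsAsFactors = FALSE)
      pclass <- c(pclass, rep(cond, cfg$n_concordant))
      links[[cond]] <- data.frame(condition = cond, gene_id = host,
                                  stringsAsFactors = FALSE)
      # non-concordant regulated peaks: beyond nonconc_min_bp of every
      # matched gene
      mt <- genes[genes$gene_id %in% matched, , drop = FALSE]
      placed <- 0L; tries <- 0L
      nstart <- integer(0); nchr <- character(0); nlen <- integer(0)
      while (placed < cfg$n_nonconcordant && tries < 20000L) {
        tries <- tries + 1L
        ci <- sample.int(length(chroms), 1L)
        len1 <- plen(1L)
        s <- as.integer(runif(1, 0, clen[ci] - len1))
        same <- mt$chrom == chroms[ci]
        if (any(same)) {
          dmin <- min(pmax(mt$tss[same] - (s + len1 - 1L),
                           s - mt$tss[same]))
          if (dmin < cfg$nonconc_min_bp) next
        }
        placed <- placed + 1L
        nstart <- c(nstart, s); nchr <- c(nchr, chroms[ci])
        nlen <- c(nlen, len1)
      }
      if (placed < cfg$n_nonconcordant)
        stop("could not place non-concordant peaks; genome too crowded")
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = nchr, start = nstart, end = nstart + nlen,
        stringsAsFactors = FALSE)
      pclass <- c(pclass, rep(cond, cfg$n_nonconcordant))
      nonlinks[[cond]] <- placed
    }
    # neutral peaks
    nn <- cfg$n_neutral_peaks
    ci <- sample.int(length(chroms), nn, replace = TRUE)
    len <- plen(nn)
    s <- as.integer(runif(nn, 0, clen[ci] - len))
    peaks[[length(peaks) + 1L]] <- data.frame(
      chrom = chroms[ci], start = s, end = s + len, stringsAsFactors = FALSE)
    pclass <- c(pclass, rep("neutral", nn))
    if (cfg$scaffold_peaks > 0L) {
      len <- plen(cfg$scaffold_peaks)
      s <- as.integer(runif(cfg$scaffold_peaks, 0, 50000L - len))
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = "scaffold_1", start = s, end = s + len,
        stringsAsFactors = FALSE)
      pclass <- c(pclass, rep("neutral", cfg$scaffold_peaks))
    }
    peaks <- do.call(rbind, peaks)
    peaks$peak_id <- sprintf("peak_%04d", seq_len(nrow(peaks)))
    peaks$class <- pclass
    designed <- do.call(rbind, links)
    designed$peak_id <- peaks$peak_id[
      unlist(lapply(seq_along(PEAK_CONDITIONS), function(i)
        (i - 1L) * (cfg$n_concordant + cfg$n_nonconcordant) +
          seq_len(cfg$n_concordant)))]
    truth <- list(gene_classes = gene_classes,
                  peak_classes = stats::setNames(pclass, peaks$peak_id),
                  designed_links = designed[, c("condition", "peak_id",
                                                "gene_id")])
    list(genes = genes, peaks = peaks[, c("chrom", "start", "end", "peak_id")],
         truth = truth)
  })
}

# Deterministic strong-consensus PWM.
consensus_pwm <- function(motif_id, consensus, dominance = 0.88) {
  idx <- match(strsplit(consensus, "", fixed = TRUE)[[1L]], DNA_BASES)
  stopifnot(!anyNA(idx))
  mat <- matrix((1 - dominance) / 3, nrow = length(idx), ncol = 4L,
                dimnames = list(NULL, DNA_BASES))
  mat[cbind(seq_along(idx), idx)] <- dominance
  structure(list(motif_id = motif_id, alt_name = motif_id, matrix = mat,
                 nsites = 50L, background = rep(0.25, 4)),
            class = "pwm_motif")
}

# Decoy: permute positions and, within each position, the 4 probabilities —
# same information content, unrelated sequence preference.
decoy_pwm <- function(causal, motif_id, seed) {
  with_seed(seed, {
    m <- causal$matrix[sample.int(nrow(causal$matrix)), , drop = FALSE]
    m <- t(apply(m, 1L, function(r) r[sample.int(4L)]))
    colnames(m) <- DNA_BASES
    structure(list(motif_id = motif_id, alt_name = motif_id, matrix = m,
                   nsites = 50L, background = rep(0.25, 4)),
              class = "pwm_motif")
  })
}

#' The simulator's motif library
#'
#' Two causal motifs — a hunger motif designated for concordant fasted-opened
#' and leptin-closed peaks, and a satiety motif for leptin-opened and
#' fasted-closed peaks — plus `n_decoys` column-shuffled decoys.
#'
#' @param cfg a [sim_config()]
#' @return list of motif objects; causal designations in
#'   \code{attr(,"causal")}
#' @export
simulated_motif_library <- function(cfg) {
  hunger <- consensus_pwm("HUNGER_TF", "TGACGTCATG")
  satiety <- consensus_pwm("SATIETY_TF", "GATAAGGCTA")
  decoys <- lapply(seq_len(cfg$n_decoys), function(i)
    decoy_pwm(if (i %% 2L) hunger else satiety,
              sprintf("DECOY_%02d", i), seed = cfg$seed + 100L + i))
  motifs <- c(list(hunger, satiety), decoys)
  attr(motifs, "causal") <- list(
    HUNGER_TF = c("fasted_opened", "leptin_closed"),
    SATIETY_TF = c("leptin_opened", "fasted_closed"))
  motifs
}

# Draw one instance sequence from a PWM.
sample_pwm_instance <- function(mat) {
  paste(DNA_BASES[apply(mat, 1L, function(r) sample.int(4L, 1L, prob = r))],
        collapse = "")
}

#' Plant motif instances into peak sequences
#'
#' For each causal motif, every designated concordant peak of its condition
#' pair receives one PWM-sampled instance with probability \code{p_fg}
#' (uniform position, random strand); every other peak receives one with
#' probability \code{p_bg}. Instances overwrite genome bases so coordinates
#' stay stable.
#'
#' @param cfg a [sim_config()]
#' @param genome from [generate_genome()]
#' @param ann from [generate_annotation()]
#' @param motifs from [simulated_motif_library()]
#' @return list with the mutated genome and a data.frame of placements
#'   (motif_id, peak_id, position, strand)
#' @export
plant_motif_instances <- function(cfg, genome, ann, motifs) {
  causal <- attr(motifs, "causal")
  peaks <- ann$peaks
  links <- ann$truth$designed_links
  placements <- list()
  with_seed(cfg$seed + 2L, {
    for (mid in names(causal)) {
      mo <- motifs[[which(vapply(motifs, `[[`, "", "motif_id") == mid)]]
      L <- nrow(mo$matrix)
      fg_ids <- links$peak_id[links$condition %in% causal[[mid]]]
      for (i in seq_len(nrow(peaks))) {
        p_plant <- if (peaks$peak_id[i] %in% fg_ids) cfg$p_fg else cfg$p_bg
        if (stats::runif(1) >= p_plant) next
        if (peaks$end[i] - peaks$start[i] <= L) next
        inst <- sample_pwm_instance(mo$matrix)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") inst <- revcomp(inst)
        pos <- peaks$start[i] +
          sample.int(peaks$end[i] - peaks$start[i] - L + 1L, 1L) - 1L
        placements[[length(placements) + 1L]] <- data.frame(
          motif_id = mid, peak_id = peaks$peak_id[i],
          chrom = peaks$chrom[i], position = pos, strand = strand,
          instance = inst, stringsAsFactors = FALSE)
      }
    }
    pl <- if (length(placements)) do.call(rbind, placements)
          else data.frame(motif_id = character(), peak_id = character(),
                          chrom = character(), position = integer(),
                          strand = character(), instance = character())
    # apply all edits chromosome by chromosome (one split/paste each)
    for (chrom in unique(pl$chrom)) {
      ch <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1L]]
      sub <- pl[pl$chrom == chrom, , drop = FALSE]
      for (j in seq_len(nrow(sub))) {
        letters <- strsplit(sub$instance[j], "", fixed = TRUE)[[1L]]
        ch[(sub$position[j] + 1L):(sub$position[j] + length(letters))] <-
          letters
      }
      genome[[chrom]] <- paste(ch, collapse = "")
    }
    list(genome = genome,
         placements = pl[, c("motif_id", "peak_id", "position", "strand")])
  })
}

#' Simulate gene and peak count matrices
#'
#' Counts are negative binomial with per-feature log-normal base means,
#' per-condition mean multipliers \code{2^(planted log2 effect)}, shared
#' dispersion (Var = mu + alpha mu^2) and log-normal per-sample library-size
#' factors. Condition means compose along the contrast chain: fed 1, fasted
#' \code{2^e_fast}, leptin \code{2^(e_fast + e_lept)}.
#'
#' @param cfg a [sim_config()]
#' @param truth the truth component of [generate_annotation()]
#' @return list with gene_counts, peak_counts (feature x sample matrices) and
#'   groups (condition label per column)
#' @export
simulate_counts <- function(cfg, truth) {
  conds <- c("fed", "fasted", "leptin")
  groups <- rep(conds, each = cfg$n_reps)
  nb_matrix <- function(classes, effects_fun, seed_off) {
    with_seed(cfg$seed + seed_off, {
      nfeat <- length(classes)
      base <- stats::rlnorm(nfeat, cfg$base_mean_meanlog, cfg$base_mean_sdlog)
      eff <- t(vapply(classes, effects_fun, numeric(2L)))
      mult <- cbind(fed = rep(1, nfeat),
                    fasted = 2^eff[, 1L],
                    leptin = 2^(eff[, 1L] + eff[, 2L]))
      lib <- stats::rlnorm(length(groups), 0, cfg$lib_factor_sd)
      mu <- base * mult[, groups] * rep(lib, each = nfeat)
      m <- matrix(stats::rnbinom(nfeat * length(groups), mu = mu,
                                 size = 1 / cfg$dispersion),
                  nrow = nfeat,
                  dimnames = list(names(classes),
                                  sprintf("%s_rep%d", groups,
                                          sequence(rep(cfg$n_reps, 3L)))))
      m
    })
  }
  gene_counts <- nb_matrix(truth$gene_classes,
                           function(cl) gene_class_effects(cl, cfg$effect_size),
                           3L)
  peak_counts <- nb_matrix(truth$peak_classes,
                           function(cl) peak_class_effects(cl, cfg$effect_size),
                           4L)
  list(gene_counts = gene_counts, peak_counts = peak_counts, groups = groups)
}

#' Run the full simulator in memory
#'
#' @param cfg a [sim_config()]
#' @return list: genome (with planted instances), genes, peaks, motifs,
#'   counts, truth (including placements), cfg
#' @export
simulate_hunger_study <- function(cfg = sim_config()) {
  genome <- generate_genome(cfg)
  ann <- generate_annotation(cfg, genome)
  motifs <- simulated_motif_library(cfg)
  planted <- plant_motif_instances(cfg, genome, ann, motifs)
  counts <- simulate_counts(cfg, ann$truth)
  truth <- ann$truth
  truth$placements <- planted$placements
  list(genome = planted$genome, genes = ann$genes, peaks = ann$peaks,
       motifs = motifs, counts = counts, truth = truth, cfg = cfg)
}

# Plain-text hash of a config (no external digest dependency): md5 of the
# deparsed object written to a temp file.
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[order(names(unclass(cfg)))]), f)
  unname(tools::md5sum(f))
}

#' Write the complete fixture bundle to disk
#'
#' Writes genome.fa, genes.gtf, peaks.bed, counts_genes.tsv,
#' counts_peaks.tsv, motifs.meme, truth.json and manifest.json — all in the
#' formats the readers of this package consume. Byte-identical given the
#' same config.
#'
#' @param cfg a [sim_config()]
#' @param outdir writable output directory (created if needed)
#' @return invisibly, the named vector of file paths
#' @export
generate_fixture_bundle <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_hunger_study(cfg)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             genes = file.path(outdir, "genes.gtf"),
             peaks = file.path(outdir, "peaks.bed"),
             counts_genes = file.path(outdir, "counts_genes.tsv"),
             counts_peaks = file.path(outdir, "counts_peaks.tsv"),
             motifs = file.path(outdir, "motifs.meme"),
             truth = file.path(outdir, "truth.json"),
             manifest = file.path(outdir, "manifest.json"))
  write_fasta(sim$genome, paths[["genome"]])
  g <- sim$genes
  exons <- attr(g, "exons")
  gtf <- c(sprintf(
    "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    g$chrom, g$start + 1L, g$end, g$strand, g$gene_id))
  ex <- sprintf(
    "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    exons$chrom, exons$start + 1L, exons$end,
    g$strand[match(exons$gene_id, g$gene_id)], exons$gene_id)
  writeLines(c(gtf, ex), paths[["genes"]])
  write_bed(sim$peaks, paths[["peaks"]])
  wtab <- function(m, p) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wtab(sim$counts$gene_counts, paths[["counts_genes"]])
  wtab(sim$counts$peak_counts, paths[["counts_peaks"]])
  write_meme_motifs(sim$motifs, paths[["motifs"]])
  jsonlite::write_json(
    list(gene_classes = as.list(sim$truth$gene_classes),
         peak_classes = as.list(sim$truth$peak_classes),
         designed_links = sim$truth$designed_links,
         placements = sim$truth$placements,
         causal = attr(sim$motifs, "causal")),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(package = "concordTF",
         version = as.character(utils::packageVersion("concordTF")),
         seed = cfg$seed, config_hash = config_hash(cfg),
         files = as.list(basename(paths[names(paths) != "manifest"]))),
    paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
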