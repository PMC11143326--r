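# Orchestration: classify -> assign concordant peaks -> enrich against six
# backgrounds x four conditions -> prioritize, with optional staged file
# output and a run manifest.

#' Run configuration for the file-based pipeline
#'
#' @param genome path to genome FASTA
#' @param genes path to gene models (GTF or TSS TSV)
#' @param peaks path to peak BED
#' @param motifs path to MEME motif file
#' @param counts_genes,counts_peaks paths to count TSVs (id column + one
#'   column per sample named <condition>_repN); used with the built-in
#'   differential test when no differential tables are supplied
#' @param diff_genes,diff_peaks optional named lists of paths to externally
#'   computed differential tables (elements fasted_vs_fed, leptin_vs_fasted);
#'   these take precedence over count matrices
#' @param outdir output directory (NULL: no files written)
#' @param window_bp TSS window half-width in bp
#' @param alpha consensus significance cutoff
#' @param pseudocount log-odds smoothing constant
#' @param seed seed for the shuffled background
#' @param chrom_allow chromosome allow-list (NULL: all); "auto" keeps
#'   chromosomes whose name starts with "chr"
#' @param thresholds a [threshold_config()]
#' @return object of class "run_config"
#' @export
run_config <- function(genome, genes, peaks, motifs,
                       counts_genes = NULL, counts_peaks = NULL,
                       diff_genes = NULL, diff_peaks = NULL,
                       outdir = NULL, window_bp = 200000L, alpha = 0.05,
                       pseudocount = 0.01, seed = 1L, chrom_allow = "auto",
                       thresholds = threshold_config()) {
  cfg <- as.list(environment())
  for (f in c("genome", "genes", "peaks", "motifs")) {
    if (!file.exists(cfg[[f]]))
      stop("input file for '", f, "' not found: ", cfg[[f]])
  }
  if (is.null(diff_genes) && is.null(counts_genes))
    stop("provide either counts_genes or diff_genes")
  if (is.null(diff_peaks) && is.null(counts_peaks))
    stop("provide either counts_peaks or diff_peaks")
  structure(cfg, class = "run_config")
}

# Differential tables for both contrasts from a counts TSV via the stand-in
# test. Sample columns must be named <condition>_repN.
diff_tables_from_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  groups <- sub("_rep[0-9]+$", "", colnames(m))
  list(fasted_vs_fed = simple_de_test(m, groups, c("fasted", "fed")),
       leptin_vs_fasted = simple_de_test(m, groups, c("leptin", "fasted")))
}

#' Run the full TF-prioritization analysis on in-memory inputs
#'
#' Executes the three analysis steps — differential classification,
#' direction-concordant peak assignment within the TSS window, and
#' optimal-threshold Fisher motif enrichment against six backgrounds per
#' condition — followed by consensus prioritization and exclusivity
#' classification.
#'
#' @param genes gene model data.frame (gene_id, chrom, strand, tss, ...)
#' @param peaks peak data.frame (chrom, start, end, peak_id)
#' @param gene_tables named list of differential gene tables (fasted_vs_fed,
#'   leptin_vs_fasted)
#' @param peak_tables named list of differential peak tables, same names
#' @param motifs list of motif objects
#' @param genome named character vector of chromosome sequences
#' @param thresholds a [threshold_config()]
#' @param window_bp TSS window half-width in bp (default 200000)
#' @param alpha consensus significance cutoff (default 0.05)
#' @param pseudocount log-odds smoothing constant
#' @param seed seed for the shuffled background sets
#' @param chrom_allow chromosome allow-list; "auto" keeps names starting
#'   with "chr"; NULL keeps all
#' @param background 4-vector of A,C,G,T log-odds background probabilities
#'   (default: genome-wide mononucleotide frequencies)
#' @return object of class "tf_report"
#' @export
run_hunger_tf <- function(genes, peaks, gene_tables, peak_tables, motifs,
                          genome, thresholds = threshold_config(),
                          window_bp = 200000L, alpha = 0.05,
                          pseudocount = 0.01, seed = 1L,
                          chrom_allow = "auto", background = NULL) {
  if (identical(chrom_allow, "auto"))
    chrom_allow <- grep("^chr", names(genome), value = TRUE)
  if (is.null(background)) background <- genome_background(genome)

  reg <- regulated_sets(gene_tables, peak_tables, thresholds)
  bidir <- bidirectional_sets(reg)

  expressed <- union(gene_tables$fasted_vs_fed$id,
                     gene_tables$leptin_vs_fasted$id)
  genes_expr <- genes[genes$gene_id %in% expressed, , drop = FALSE]
  if (!nrow(genes_expr)) genes_expr <- genes

  conc <- assign_concordant_peaks(peaks, genes_expr, reg,
                                  window_bp = window_bp,
                                  chrom_allow = chrom_allow)

  score_cache <- precompute_motif_scores(
    extract_peak_sequences(genome, peaks), motifs, background, pseudocount)

  enrichment <- list()
  for (i in seq_along(PEAK_CONDITIONS)) {
    cond <- PEAK_CONDITIONS[i]
    if (!length(conc[[cond]]$peak_ids))
      stop("enrichment stage: no concordant peaks for condition ", cond)
    suite <- build_background_suite(cond, conc[[cond]], peaks, reg,
                                    genes_expr, genome,
                                    window_bp = window_bp,
                                    seed = seed + i)
    fg_seqs <- extract_peak_sequences(
      genome, peaks[peaks$peak_id %in% conc[[cond]]$peak_ids, , drop = FALSE])
    e <- run_enrichment_suite(fg_seqs, suite, motifs, background,
                              pseudocount, score_cache = score_cache)
    e$condition <- cond
    enrichment[[cond]] <- e
  }
  enrichment <- do.call(rbind, enrichment)
  rownames(enrichment) <- NULL

  priority <- prioritize_tfs(enrichment, alpha = alpha)
  ranked <- rank_and_export(priority)

  association <- list()
  for (cond in PEAK_CONDITIONS) {
    gset <- reg[[CONDITION_PAIRING[[cond]]]]
    contrast <- if (startsWith(cond, "fasted")) "fasted_vs_fed"
                else "leptin_vs_fasted"
    gt <- gene_tables[[contrast]]
    cc <- condition_contrast(cond)
    neutral <- setdiff(genes_expr$gene_id,
                       unlist(reg[cc$gene_sets], use.names = FALSE))
    if (length(gset) && length(neutral)) {
      lfc <- stats::setNames(gt$log2fc, gt$id)
      association[[cond]] <- association_stats(
        gset, reg[[cond]], neutral, genes_expr,
        if (is.null(chrom_allow)) peaks
        else peaks[peaks$chrom %in% chrom_allow, , drop = FALSE],
        window_bp = window_bp, lfc = lfc)
    }
  }

  structure(list(regulated = reg, bidirectional = bidir, concordant = conc,
                 association = association, enrichment = enrichment,
                 priority = priority, ranked = ranked,
                 params = list(thresholds = thresholds,
                               window_bp = window_bp, alpha = alpha,
                               pseudocount = pseudocount, seed = seed,
                               chrom_allow = chrom_allow,
                               background = background)),
            class = "tf_report")
}

#' Run the file-based pipeline
#'
#' Reads every input named in the [run_config()], derives differential
#' tables (from external tables when given, else from counts via
#' [simple_de_test()]), runs [run_hunger_tf()], and — when `outdir` is set —
#' writes the per-condition concordant-peak TSVs, the enrichment matrix, the
#' priority table, radar JSON, association JSON and a run manifest.
#'
#' @param config a [run_config()]
#' @return the "tf_report", invisibly when writing files
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  genome <- read_fasta(config$genome)
  genes <- read_gene_models(config$genes)
  peaks <- read_bed(config$peaks)
  motifs <- read_meme_motifs(config$motifs)
  gene_tables <- if (!is.null(config$diff_genes))
    lapply(config$diff_genes, read_diff_table, kind = "gene")
  else diff_tables_from_counts(config$counts_genes)
  peak_tables <- if (!is.null(config$diff_peaks))
    lapply(config$diff_peaks, read_diff_table, kind = "peak")
  else diff_tables_from_counts(config$counts_peaks)

  report <- run_hunger_tf(genes, peaks, gene_tables, peak_tables, motifs,
                          genome, thresholds = config$thresholds,
                          window_bp = config$window_bp,
                          alpha = config$alpha,
                          pseudocount = config$pseudocount,
                          seed = config$seed,
                          chrom_allow = config$chrom_allow)
  if (!is.null(config$outdir)) {
    write_report_files(report, config)
    return(invisible(report))
  }
  report
}

# Stage outputs + manifest under config$outdir.
write_report_files <- function(report, config) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  peaks <- read_bed(config$peaks)
  for (cond in PEAK_CONDITIONS) {
    cs <- report$concordant[[cond]]
    p <- peaks[match(cs$peak_ids, peaks$peak_id), , drop = FALSE]
    df <- data.frame(peak_id = cs$peak_ids, chrom = p$chrom,
                     start = p$start, end = p$end,
                     supporting_gene_ids = vapply(
                       cs$peak2genes[cs$peak_ids],
                       function(g) paste(sort(g), collapse = ","), ""),
                     n_support = lengths(cs$peak2genes[cs$peak_ids]),
                     stringsAsFactors = FALSE)
    write_results(df, file.path(outdir, paste0("concordant_", cond, ".tsv")))
  }
  write_results(report$enrichment, file.path(outdir, "enrichment.tsv"))
  write_results(report$priority, file.path(outdir, "priority.tsv"))
  write_radar_json(report$priority, file.path(outdir, "radar.json"),
                   meta = list(seed = config$seed))
  assoc <- lapply(report$association, function(a)
    a[c("n_genes", "n_genes_with_peak", "fraction", "neutral_fraction",
        "p_value", "rho")])
  jsonlite::write_json(assoc, file.path(outdir, "association.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(package = "concordTF",
         version = as.character(utils::packageVersion("concordTF")),
         seed = config$seed, window_bp = config$window_bp,
         alpha = config$alpha, config_hash = config_hash(unclass(config))),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.tf_report <- function(x, ...) {
  cat("TF prioritization report\n")
  cat(sprintf("  window: +/-%d kb; alpha = %g\n",
              round(x$params$window_bp / 1000), x$params$alpha))
  r <- x$regulated
  cat(sprintf("  genes: %d fasting-induced, %d fasting-repressed, %d leptin-induced, %d leptin-repressed\n",
              length(r$fasting_induced), length(r$fasting_repressed),
              length(r$leptin_induced), length(r$leptin_repressed)))
  cat(sprintf("  bidirectional: %d fast-up/leptin-down, %d fast-down/leptin-up\n",
              length(x$bidirectional$fast_up_leptin_down),
              length(x$bidirectional$fast_down_leptin_up)))
  cat(sprintf("  peaks: %d fasted-opened, %d fasted-closed, %d leptin-opened, %d leptin-closed\n",
              length(r$fasted_opened), length(r$fasted_closed),
              length(r$leptin_opened), length(r$leptin_closed)))
  nconc <- vapply(x$concordant, function(cs) length(cs$peak_ids), 0L)
  cat("  concordant peaks:",
      paste(sprintf("%s=%d", names(nconc), nconc), collapse = ", "), "\n")
  cat("  motif categories:\n")
  print(table(x$priority$category))
  invisible(x)
}

#' @method summary tf_report
#' @export
summary.tf_report <- function(object, n = 5L, ...) {
  print(object)
  for (nm in c("hunger_pair", "hunger_single", "satiety_pair",
               "satiety_single")) {
    tab <- object$ranked[[nm]]
    if (!nrow(tab)) next
    cat("\nTop", nm, "motifs:\n")
    cols <- c("rank", "motif_id", "summed_score_hunger",
              "summed_score_satiety")
    print(utils::head(tab[, intersect(cols, names(tab))], n),
          row.names = FALSE)
  }
  invisible(object)
}

#' Radar (star) plot of the four representative motif scores
#'
#' @param x a "tf_report"
#' @param motifs motif ids to draw (default: top-ranked pair-exclusive
#'   motifs, up to 8)
#' @param ... passed to [graphics::stars()]
#' @method plot tf_report
#' @export
plot.tf_report <- function(x, motifs = NULL, ...) {
  radar <- x$ranked$radar
  if (is.null(motifs)) {
    motifs <- c(x$ranked$hunger_pair$motif_id, x$ranked$satiety_pair$motif_id,
                x$ranked$hunger_single$motif_id,
                x$ranked$satiety_single$motif_id)
    if (!length(motifs)) motifs <- radar$motif_id
    motifs <- utils::head(motifs, 8L)
  }
  m <- as.matrix(radar[match(motifs, radar$motif_id), PEAK_CONDITIONS])
  rownames(m) <- motifs
  graphics::stars(log2(m + 1), key.loc = c(14, 2), scale = FALSE,
                  main = "Representative motif scores (log2(1 - log2 p))",
                  ...)
  invisible(x)
}
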