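# Readers/writers for the standard formats the pipeline touches, normalizing
# everything onto one internal convention: coordinates are 0-based, half-open
# (BED-style); GTF's 1-based inclusive intervals are converted on read.

#' Read a FASTA genome into a named vector of uppercase sequences
#'
#' Sequences are uppercased and validated against the A/C/G/T/N alphabet.
#' Multi-line records are concatenated.
#'
#' @param path path to a FASTA file
#' @return named character vector, one uppercase sequence per chromosome
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) format_error("FASTA file not found: ", path)
  dss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) format_error("malformed FASTA '", path, "': ",
                                     conditionMessage(e)))
  if (!length(dss)) format_error("FASTA '", path, "' contains no records")
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(names(seqs)))
    format_error("duplicate chromosome names in '", path, "'")
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]]))
      format_error("empty sequence for record '", names(seqs)[i], "'")
    bad <- gsub("[ACGTN]", "", seqs[[i]])
    if (nzchar(bad))
      format_error("record '", names(seqs)[i],
                   "' contains non-ACGTN character '", substr(bad, 1, 1), "'")
  }
  seqs
}

#' Write a genome to FASTA
#' @param genome named character vector of sequences
#' @param path output path
#' @param width line width
#' @return invisibly, `path`
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read peaks from a BED3/BED6 file
#'
#' Coordinates are kept 0-based half-open as in BED. A missing name column
#' auto-generates peak ids of the form \code{chrom:start-end}.
#'
#' @param path path to BED file
#' @return data.frame with columns chrom, start, end, peak_id (input order)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) format_error("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_id = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L))
    format_error("BED line ", which(n < 3L)[1L], " has fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  s_chr <- vapply(fields, `[[`, "", 2L)
  e_chr <- vapply(fields, `[[`, "", 3L)
  if (any(grepl("\\D", s_chr)) || any(grepl("\\D", e_chr)))
    format_error("non-integer coordinate at BED line ",
                 which(grepl("\\D", s_chr) | grepl("\\D", e_chr))[1L])
  start <- as.integer(s_chr); end <- as.integer(e_chr)
  if (any(start >= end))
    format_error("start >= end at BED line ", which(start >= end)[1L])
  peak_id <- ifelse(n >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                    sprintf("%s:%d-%d", chrom, start, end))
  peak_id[!nzchar(peak_id) | peak_id == "."] <-
    sprintf("%s:%d-%d", chrom, start, end)[!nzchar(peak_id) | peak_id == "."]
  data.frame(chrom = chrom, start = start, end = end, peak_id = peak_id,
             stringsAsFactors = FALSE)
}

#' Write peaks to BED
#' @param peaks data.frame with chrom, start, end, peak_id
#' @param path output path
#' @return invisibly, `path`
#' @export
write_bed <- function(peaks, path) {
  stopifnot(all(c("chrom", "start", "end", "peak_id") %in% names(peaks)))
  writeLines(sprintf("%s\t%d\t%d\t%s", peaks$chrom, as.integer(peaks$start),
                     as.integer(peaks$end), peaks$peak_id), path)
  invisible(path)
}

# Parse the gene_id "..." attribute out of a GTF attribute field.
gtf_gene_id <- function(attr) {
  m <- regmatches(attr, regexpr('gene_id "[^"]*"', attr))
  ifelse(lengths(regmatches(attr, gregexpr('gene_id "[^"]*"', attr))) > 0,
         sub('gene_id "([^"]*)"', "\\1", m), NA_character_)
}

#' Read gene models from GTF or a TSS TSV
#'
#' For GTF input (1-based inclusive), coordinates are converted to 0-based
#' half-open and the TSS is the first transcribed base: \code{start-1} on the
#' plus strand, \code{end-1} on the minus strand (both 0-based). Records with
#' strand "." lack a resolvable TSS and are dropped (count reported via
#' \code{attr(,"n_dropped")} and a message). A TSS TSV must carry columns
#' gene_id, chrom, strand, tss (already 0-based).
#'
#' @param path path to a .gtf/.gff file or a TSV
#' @param format "auto" (by extension), "gtf" or "tsv"
#' @return data.frame with gene_id, chrom, strand, tss, start, end; exon
#'   intervals (0-based half-open), when present, in \code{attr(,"exons")}
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) format_error("gene model file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE))
      "gtf" else "tsv"
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss")
    if (!all(need %in% names(df)))
      format_error("TSS TSV must have columns ", paste(need, collapse = ", "))
    if (!all(df$strand %in% c("+", "-")))
      format_error("unknown strand symbol '",
                   setdiff(df$strand, c("+", "-"))[1L], "' in ", path)
    out <- data.frame(gene_id = as.character(df$gene_id), chrom = df$chrom,
                      strand = df$strand, tss = as.integer(df$tss),
                      start = as.integer(df$tss), end = as.integer(df$tss) + 1L,
                      stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 9L
  fields <- fields[ok]
  feat <- vapply(fields, `[[`, "", 3L)
  keep <- feat %in% c("gene", "exon")
  fields <- fields[keep]; feat <- feat[keep]
  chrom <- vapply(fields, `[[`, "", 1L)
  start1 <- as.integer(vapply(fields, `[[`, "", 4L))
  end1 <- as.integer(vapply(fields, `[[`, "", 5L))
  strand <- vapply(fields, `[[`, "", 7L)
  gid <- gtf_gene_id(vapply(fields, `[[`, "", 9L))
  bad <- !strand %in% c("+", "-", ".")
  if (any(bad))
    format_error("unknown strand symbol '", strand[bad][1L], "' in ", path)
  g <- feat == "gene"
  dropped <- g & (strand == "." | is.na(gid))
  n_dropped <- sum(dropped)
  if (n_dropped)
    message(n_dropped, " gene record(s) without a resolvable TSS dropped")
  gk <- g & !dropped
  start0 <- start1 - 1L                       # to 0-based half-open
  tss <- ifelse(strand == "+", start0, end1 - 1L)
  out <- data.frame(gene_id = gid[gk], chrom = chrom[gk], strand = strand[gk],
                    tss = as.integer(tss[gk]), start = start0[gk],
                    end = end1[gk], stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id))
    format_error("duplicate gene_id in ", path)
  ek <- feat == "exon" & !is.na(gid) & gid %in% out$gene_id
  exons <- data.frame(gene_id = gid[ek], chrom = chrom[ek],
                      start = start0[ek], end = end1[ek],
                      stringsAsFactors = FALSE)
  attr(out, "exons") <- exons
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read motifs in MEME minimal format
#'
#' Parses the version line, an optional "Background letter frequencies" block
#' and every MOTIF block with its letter-probability matrix. Matrix rows must
#' sum to 1 within 0.05 (then row-renormalized exactly) and the declared width
#' must match the row count.
#'
#' @param path path to a MEME minimal motif file
#' @return list of motif objects (motif_id, alt_name, matrix L x 4 with
#'   columns A,C,G,T, nsites, background)
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) format_error("motif file not found: ", path)
  lines <- readLines(path)
  bg <- NULL
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1L] + 1L]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks[c(FALSE, TRUE)]))
    names(vals) <- toks[c(TRUE, FALSE)]
    if (all(DNA_BASES %in% names(vals)) && !anyNA(vals))
      bg <- unname(vals[DNA_BASES])
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) format_error("no MOTIF blocks in ", path)
  motifs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    hdr <- strsplit(trimws(lines[starts[k]]), "\\s+")[[1L]]
    motif_id <- if (length(hdr) >= 2L) hdr[2L] else
      format_error("MOTIF line ", starts[k], " lacks an identifier")
    alt_name <- if (length(hdr) >= 3L) hdr[3L] else ""
    lp <- grep("^letter-probability matrix", lines[starts[k]:length(lines)])[1L]
    if (is.na(lp))
      format_error("motif '", motif_id, "' lacks a letter-probability matrix")
    lp <- starts[k] + lp - 1L
    hdr2 <- lines[lp]
    getnum <- function(key) {
      m <- regmatches(hdr2, regexpr(paste0(key, "=\\s*[0-9.eE+-]+"), hdr2))
      if (length(m)) as.numeric(sub(paste0(key, "=\\s*"), "", m)) else NA_real_
    }
    w <- getnum("w")
    nsites <- getnum("nsites")
    rows <- list(); i <- lp + 1L
    while (i <= length(lines)) {
      tl <- trimws(lines[i])
      if (!nzchar(tl) || grepl("^(MOTIF|URL)", tl)) break
      vals <- suppressWarnings(as.numeric(strsplit(tl, "\\s+")[[1L]]))
      if (anyNA(vals) || length(vals) != 4L)
        format_error("bad matrix row at line ", i, " of ", path)
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    mat <- do.call(rbind, rows)
    if (is.null(mat) || !nrow(mat))
      format_error("motif '", motif_id, "' has an empty matrix")
    if (!is.na(w) && nrow(mat) != w)
      format_error("motif '", motif_id, "': declared w=", w,
                   " but ", nrow(mat), " matrix rows")
    rs <- rowSums(mat)
    if (any(abs(rs - 1) > 0.05) || any(mat < 0))
      format_error("motif '", motif_id,
                   "': matrix row does not sum to 1 (row ",
                   which(abs(rs - 1) > 0.05 | apply(mat < 0, 1, any))[1L], ")")
    mat <- mat / rs
    colnames(mat) <- DNA_BASES
    motifs[[k]] <- structure(
      list(motif_id = motif_id, alt_name = alt_name, matrix = mat,
           nsites = if (is.na(nsites)) NULL else as.integer(nsites),
           background = bg),
      class = "pwm_motif")
  }
  if (anyDuplicated(vapply(motifs, `[[`, "", "motif_id")))
    format_error("duplicate motif ids in ", path)
  motifs
}

#' Write motifs in MEME minimal format
#' @param motifs list of motif objects as returned by [read_meme_motifs()]
#' @param path output path
#' @param background optional 4-vector of A,C,G,T frequencies
#' @return invisibly, `path`
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, background),
                     collapse = " "), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m$motif_id,
                       if (nzchar(m$alt_name %||% "")) m$alt_name else m$motif_id),
               con)
    nsites <- if (is.null(m$nsites)) 20L else m$nsites
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(m$matrix), nsites), con)
    writeLines(apply(m$matrix, 1L,
                     function(r) paste(sprintf("%.6f", r), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract peak sequences from a genome
#'
#' Returns \code{genome[[chrom]][start+1 .. end]} for each peak (0-based
#' half-open coordinates). Peaks whose sequence is more than
#' \code{max_n_frac} N are dropped with a message.
#'
#' @param genome named character vector from [read_fasta()]
#' @param peaks data.frame with chrom, start, end, peak_id
#' @param max_n_frac maximum tolerated fraction of N bases (default 0.5)
#' @return named character vector, peak_id -> sequence
#' @export
extract_peak_sequences <- function(genome, peaks, max_n_frac = 0.5) {
  stopifnot(all(c("chrom", "start", "end", "peak_id") %in% names(peaks)))
  miss <- setdiff(unique(peaks$chrom), names(genome))
  if (length(miss))
    stop("peak chromosome(s) absent from genome: ", paste(miss, collapse = ", "))
  lens <- nchar(genome)[peaks$chrom]
  over <- peaks$end > lens
  if (any(over))
    stop("peak '", peaks$peak_id[over][1L], "' extends beyond chromosome end")
  seqs <- substring(genome[peaks$chrom], peaks$start + 1L, peaks$end)
  names(seqs) <- peaks$peak_id
  nfrac <- vapply(seqs, function(s) {
    n <- nchar(s)
    (n - nchar(gsub("N", "", s, fixed = TRUE))) / n
  }, 0)
  drop <- nfrac > max_n_frac
  if (any(drop))
    message(sum(drop), " peak(s) dropped: sequence > ",
            round(100 * max_n_frac), "% N")
  seqs[!drop]
}

#' Write a results table to TSV or JSON
#'
#' Column order is preserved deterministically; numeric columns keep full
#' precision. JSON output wraps the records with run metadata.
#'
#' @param records a data.frame
#' @param path output path
#' @param format "tsv" or "json"
#' @param meta named list of run metadata (seed, config hash, ...) stored in
#'   JSON output
#' @return invisibly, `path`
#' @export
write_results <- function(records, path, format = c("tsv", "json"),
                          meta = list()) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  if (format == "tsv") {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    payload <- list(
      metadata = c(list(package = "concordTF",
                        version = as.character(utils::packageVersion("concordTF"))),
                   meta),
      records = records)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a differential table (TSV)
#'
#' Expects columns id, log2fc, fdr and one or more mean_cpm_<group> columns.
#'
#' @param path TSV path
#' @param kind "gene" or "peak"
#' @param contrast contrast label, e.g. "fasted_vs_fed"
#' @return data.frame with attributes "kind" and "contrast"
#' @export
read_diff_table <- function(path, kind = c("gene", "peak"), contrast = NULL) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("id", "log2fc", "fdr")
  if (!all(need %in% names(df)))
    format_error("differential table must have columns ",
                 paste(need, collapse = ", "))
  if (!any(startsWith(names(df), "mean_cpm_")))
    format_error("differential table lacks mean_cpm_<group> columns")
  if (anyDuplicated(df$id)) format_error("duplicate ids in ", path)
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE))
    format_error("fdr outside [0,1] in ", path)
  attr(df, "kind") <- kind
  attr(df, "contrast") <- contrast
  df
}
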