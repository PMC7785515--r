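#' Read peak calls from BED3+ or narrowPeak
#'
#' Intervals are kept 0-based half-open (BED native) and returned sorted
#' by (chrom, start). For narrowPeak-style files (>= 7 columns) the score
#' is the signalValue in column 7; otherwise 0.
#'
#' @param path BED or narrowPeak file (no header).
#' @param condition optional condition tag stored on every peak.
#' @return Data frame: `chrom`, `start`, `end`, `score`, `condition`,
#'   `peak_id`.
#' @export
read_peaks <- function(path, condition = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      score = numeric(), condition = character(),
                      peak_id = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3)) stopf("peak file '%s' line %d: fewer than 3 columns",
                            path, which(ncols < 3)[1])
  chrom <- vapply(fields, `[[`, "", 1)
  start <- as.integer(vapply(fields, `[[`, "", 2))
  end <- as.integer(vapply(fields, `[[`, "", 3))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) stopf("peak file '%s' line %d: invalid interval (start >= end)",
                         path, bad[1])
  score <- ifelse(ncols >= 7,
                  suppressWarnings(as.numeric(vapply(fields, function(f)
                    if (length(f) >= 7) f[[7]] else "0", ""))), 0)
  score[is.na(score)] <- 0
  peaks <- data.frame(chrom = chrom, start = start, end = end, score = score,
                      condition = condition, stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  peaks$peak_id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  rownames(peaks) <- NULL
  peaks
}

#' Write peaks as BED (score in column 7, narrowPeak-compatible layout)
#' @param peaks peak data frame from [read_peaks()] or the simulator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   peaks$peak_id, 0L, ".", peaks$score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GWAS index-SNP table
#'
#' Minimal TSV dialect: `trait`, `rsid`, `chrom`, `pos` (1-based in the
#' file, converted to 0-based internally), `ref`, `alt`, `pvalue`.
#' Multi-allelic records (comma-separated alt) are split into one row per
#' alternate allele.
#'
#' @param path TSV file.
#' @return Data frame with 0-based `pos`.
#' @export
read_snp_table <- function(path) {
  snp <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("trait", "rsid", "chrom", "pos", "ref", "alt", "pvalue")
  miss <- setdiff(need, names(snp))
  if (length(miss)) stopf("SNP table missing columns: %s",
                          paste(miss, collapse = ", "))
  multi <- grepl(",", snp$alt, fixed = TRUE)
  if (any(multi)) {
    alts <- strsplit(snp$alt, ",", fixed = TRUE)
    snp <- snp[rep(seq_len(nrow(snp)), lengths(alts)), , drop = FALSE]
    snp$alt <- unlist(alts)
  }
  if (any(nchar(snp$ref) != 1 | nchar(snp$alt) != 1))
    stopf("SNP alleles must be single bases (indels unsupported)")
  if (any(snp$pvalue <= 0 | snp$pvalue > 1))
    stopf("SNP p-values must lie in (0, 1]")
  snp$pos <- as.integer(snp$pos) - 1L
  rownames(snp) <- NULL
  snp
}

#' Write a GWAS index-SNP table (positions re-emitted 1-based)
#' @param snp SNP data frame (0-based `pos`).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snp, path) {
  out <- snp[, c("trait", "rsid", "chrom", "pos", "ref", "alt", "pvalue")]
  out$pos <- out$pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype-dosage panel
#'
#' Samples in rows, SNPs in columns; first column sample ids; values
#' 0/1/2 copies of the alternate allele.
#'
#' @param path TSV file.
#' @return Numeric matrix samples x SNPs with dimnames.
#' @export
read_dosage <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat) || any(!mat %in% 0:2))
    stopf("dosage values must be 0, 1 or 2")
  rownames(mat) <- as.character(tab[[1]])
  mat
}

#' Write a genotype-dosage panel
#' @param dosage samples x SNPs matrix.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_dosage <- function(dosage, path) {
  df <- data.frame(sample_id = rownames(dosage), dosage, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, all
#' tab-separated.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stopf("GMT line %d has fewer than 3 fields", bad[1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
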