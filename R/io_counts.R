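#' Read a gene-by-sample count matrix
#'
#' Tab-separated file whose first column holds gene ids and remaining
#' columns one sample each. Cells must be non-negative integers; fractional
#' or negative values are format errors naming the offending row and
#' column.
#'
#' @param path TSV file.
#' @param design optional validated design sheet; sample columns are
#'   reconciled against `design$sample_id`.
#' @return Integer matrix with gene-id rownames and sample-id colnames.
#' @export
read_counts <- function(path, design = NULL) {
  tab <- tryCatch(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
                  error = function(e) stopf("no genes in counts file '%s'", path))
  if (nrow(tab) == 0 || ncol(tab) < 2) stopf("no genes in counts file '%s'", path)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stopf("duplicate gene id(s) in '%s': %s", path,
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)[1, ]
    stopf("non-numeric count at gene '%s', sample '%s'",
          genes[bad[1]], colnames(tab)[-1][bad[2]])
  }
  bad <- which(mat < 0 | mat != floor(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-integer or negative count at gene '%s', sample '%s' (value %s)",
          genes[bad[1, 1]], colnames(mat)[bad[1, 2]], mat[bad[1, 1], bad[1, 2]])
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- genes
  if (!is.null(design)) {
    if (!setequal(colnames(mat), design$sample_id))
      stopf("sample mismatch between counts and design: counts-only {%s}, design-only {%s}",
            paste(setdiff(colnames(mat), design$sample_id), collapse = ","),
            paste(setdiff(design$sample_id, colnames(mat)), collapse = ","))
    mat <- mat[, design$sample_id, drop = FALSE]
  }
  mat
}

#' Write a count matrix readable by [read_counts()]
#'
#' @param counts integer matrix with dimnames.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design sheet
#'
#' @param path TSV with columns `sample_id`, `cell_type`, `tcr_dose`,
#'   `cd28_dose`, `donor`, `batch`.
#' @param allow_custom_grid permit dose pairs off the 7-condition grid.
#' @return Validated design data frame with a `condition` column.
#' @export
read_design <- function(path, allow_custom_grid = FALSE) {
  design <- read.delim(path, stringsAsFactors = FALSE,
                       colClasses = c(sample_id = "character",
                                      donor = "character",
                                      batch = "character"))
  validate_design(design, allow_custom_grid = allow_custom_grid)
}

#' Write a sample design sheet
#' @param design design data frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Columns `gene_id`, `chrom`, `start`, `end`, `strand`. Internally all
#' coordinates are 0-based half-open; set `one_based = TRUE` if the file
#' uses 1-based inclusive starts (GTF-style), in which case starts are
#' shifted down by one on read.
#'
#' @param path TSV file.
#' @param one_based whether starts in the file are 1-based inclusive.
#' @return Data frame with a `length` column (`end - start`).
#' @export
read_annotation <- function(path, one_based = FALSE) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stopf("annotation missing columns: %s",
                          paste(miss, collapse = ", "))
  if (one_based) ann$start <- ann$start - 1L
  if (anyDuplicated(ann$gene_id)) stopf("duplicate gene ids in annotation")
  bad <- which(ann$start >= ann$end)
  if (length(bad)) stopf("annotation line %d: start >= end for gene '%s'",
                         bad[1] + 1L, ann$gene_id[bad[1]])
  ann$length <- ann$end - ann$start
  ann
}

#' Write a gene annotation table
#' @param ann annotation data frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  write.table(ann[, c("gene_id", "chrom", "start", "end", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
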