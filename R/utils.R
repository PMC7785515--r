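#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor dnbinom lm median model.matrix optimize
#'   p.adjust pchisq pnorm prcomp quantile rbinom rgamma rlnorm rnbinom
#'   rnorm runif sd setNames t.test var binom.test ks.test pt rexp
#' @importFrom utils combn head read.delim write.table packageVersion
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Convert 0-based half-open intervals to a GRanges
#'
#' Internal coordinates are 0-based half-open (BED convention); GRanges is
#' 1-based closed, so `[start, end)` maps to `start+1 .. end`.
#'
#' @param df data frame with columns `chrom`, `start`, `end`.
#' @return A `GRanges` object preserving row order.
#' @keywords internal
granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

# 31-bit polynomial rolling hash of a character scalar; used to stamp
# output headers with a config fingerprint without a digest dependency.
# Pure double arithmetic keeps every intermediate exactly representable.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a results table with a provenance header
#'
#' Tab-separated output preceded by comment lines recording the package
#' version, the seed and a hash of the configuration, so any table can be
#' traced back to `(inputs, config, seed)`.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param seed integer seed recorded in the header.
#' @param config configuration list (hashed into the header).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, seed = NA, config = NULL) {
  hash <- if (is.null(config)) "none" else config_hash(yaml::as.yaml(config))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stimgrid_version=%s seed=%s config_hash=%s",
                     as.character(packageVersion("stimgrid")),
                     as.character(seed), hash), con)
  write.table(format(df, trim = TRUE, digits = 10, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
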