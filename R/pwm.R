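#' Build a position weight matrix from base counts
#'
#' Counts are converted to log2-odds against the background after adding a
#' pseudocount to every cell: `log2(((c + eps) / (N + 4*eps)) / bg)`, where
#' `N` is the column total. Scores are therefore in bits.
#'
#' @param counts 4 x L numeric matrix, rows A, C, G, T.
#' @param name motif name.
#' @param pseudocount pseudocount added per cell (default 1).
#' @param background base composition, length 4, sums to 1.
#' @return Object of class `pwm`: counts, log-odds `mat`, `max_score`,
#'   `consensus`, `length`.
#' @export
pwm_from_counts <- function(counts, name = "motif", pseudocount = 1,
                            background = c(0.25, 0.25, 0.25, 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stopf("PWM counts must have 4 rows (A,C,G,T)")
  if (any(counts < 0)) stopf("PWM counts must be non-negative")
  rownames(counts) <- c("A", "C", "G", "T")
  totals <- colSums(counts)
  prob <- sweep(counts + pseudocount, 2, totals + 4 * pseudocount, "/")
  mat <- log2(prob / background)
  consensus <- paste(rownames(mat)[apply(mat, 2, which.max)], collapse = "")
  structure(list(name = name, counts = counts, mat = mat,
                 max_score = sum(apply(mat, 2, max)),
                 consensus = consensus, length = ncol(mat)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, consensus %s, max score %.2f bits\n",
              x$name, x$length, x$consensus, x$max_score))
  invisible(x)
}

#' Read motifs from a JASPAR-style counts file
#'
#' Each motif is a `>id name` header followed by four rows of counts for
#' A, C, G and T. Rows may be bare numbers or JASPAR bracketed form
#' (`A [ 10 3 ... ]`). All four rows must have equal length.
#'
#' @param path motif file.
#' @param pseudocount,background passed to [pwm_from_counts()].
#' @return Named list of `pwm` objects.
#' @export
read_pwms <- function(path, pseudocount = 1,
                      background = c(0.25, 0.25, 0.25, 0.25)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stopf("no motif headers ('>') in '%s'", path)
  ends <- c(heads[-1] - 1L, length(lines))
  pwms <- lapply(seq_along(heads), function(i) {
    block <- lines[(heads[i] + 1L):ends[i]]
    if (length(block) != 4)
      stopf("motif '%s': expected 4 count rows, found %d",
            lines[heads[i]], length(block))
    rows <- lapply(block, function(ln) {
      ln <- gsub("^[ACGTacgt]?\\s*\\[?|\\]$", "", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1)
      stopf("motif '%s': ragged count rows", lines[heads[i]])
    nm <- sub("^>\\s*", "", lines[heads[i]])
    nm <- strsplit(nm, "\\s+")[[1]][1]
    pwm_from_counts(do.call(rbind, rows), name = nm,
                    pseudocount = pseudocount, background = background)
  })
  setNames(pwms, vapply(pwms, `[[`, "", "name"))
}

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

seq_to_code <- function(seq) {
  code <- BASE_CODE[strsplit(toupper(seq), "")[[1]]]
  code[is.na(code)] <- 5L  # ambiguous bases score as background (0 bits)
  unname(code)
}

#' Reverse complement of a DNA string
#' @param seq DNA string (A/C/G/T/N).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# score every placement of pwm on coded sequence (one strand); returns a
# numeric vector of length n - L + 1 (empty if sequence shorter than motif)
pwm_scores <- function(code, pwm) {
  L <- pwm$length
  n <- length(code)
  if (n < L) return(numeric(0))
  lookup <- rbind(pwm$mat, 0)  # row 5: N contributes 0
  scores <- numeric(n - L + 1L)
  for (j in seq_len(L)) {
    scores <- scores + lookup[cbind(code[j:(j + n - L)], j)]
  }
  scores
}

#' Scan a sequence for PWM hits on both strands
#'
#' A placement is a hit when its log-odds score reaches
#' `threshold_frac * max_score` of the motif. Positions are 0-based
#' relative to the sequence start and always refer to the forward strand
#' interval covered by the hit. Ambiguous bases (N) contribute 0 bits.
#'
#' @param seq DNA string.
#' @param pwm a `pwm` object.
#' @param threshold_frac fraction of the maximal achievable score.
#' @return Data frame: `start`, `end` (half-open), `strand`, `score`.
#' @export
scan_pwm <- function(seq, pwm, threshold_frac = 0.8) {
  code <- seq_to_code(seq)
  if (length(code) < pwm$length)
    stopf("sequence shorter than motif '%s'", pwm$name)
  thr <- threshold_frac * pwm$max_score
  fwd <- pwm_scores(code, pwm)
  rev_code <- seq_to_code(revcomp(seq))
  rev <- pwm_scores(rev_code, pwm)
  n <- length(code)
  hit_f <- which(fwd >= thr)
  hit_r <- which(rev >= thr)
  out <- data.frame(
    start = c(hit_f - 1L, n - (hit_r - 1L) - pwm$length),
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(fwd[hit_f], rev[hit_r]),
    stringsAsFactors = FALSE
  )
  out$end <- out$start + pwm$length
  out <- out[order(out$start, out$strand), c("start", "end", "strand", "score")]
  rownames(out) <- NULL
  out
}
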