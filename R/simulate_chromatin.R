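#' Random DNA sequences
#' @param n number of sequences.
#' @param len length of each (recycled).
#' @param names optional names.
#' @return Named character vector.
#' @export
random_sequences <- function(n, len = 300, names = sprintf("seq_%04d", seq_len(n))) {
  len <- rep_len(len, n)
  setNames(vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""), ""),
    names)
}

#' Embed a motif consensus into a fraction of sequences
#'
#' Each selected sequence gets one copy of `consensus` written at a
#' uniformly drawn offset (random strand).
#'
#' @param seqs named character vector.
#' @param consensus motif string to plant.
#' @param rate fraction of sequences to plant into.
#' @return List: `seqs` (modified), `planted` (logical vector).
#' @export
embed_motif <- function(seqs, consensus, rate) {
  if (rate < 0 || rate > 1) stopf("rate must lie in [0, 1]")
  n <- length(seqs)
  planted <- rep(FALSE, n)
  if (n == 0 || rate == 0) return(list(seqs = seqs, planted = planted))
  pick <- sample(n, round(rate * n))
  for (i in pick) {
    s <- seqs[[i]]
    L <- nchar(consensus)
    if (nchar(s) < L) next
    ins <- if (runif(1) < 0.5) consensus else revcomp(consensus)
    at <- sample(nchar(s) - L + 1, 1)
    substr(s, at, at + L - 1) <- ins
    seqs[[i]] <- s
    planted[i] <- TRUE
  }
  list(seqs = seqs, planted = planted)
}

#' Simulate condition-specific chromatin data
#'
#' Emulates post-peak-calling output: per condition, peaks near the TSS of
#' every gene (1-3 peaks within 50 kb, width ~ 200-600 bp, exponential
#' signal scores); per gene-window read mass drawn from a gamma
#' distribution, multiplied by `stim_factor` in conditions where the
#' stimulus matches the gene's planted sensitivity; and peak sequences
#' with motif consensus strings embedded in a `planted_motif_rate`
#' fraction of the peaks belonging to sensitive-gene windows under
#' stimulation.
#'
#' @param conditions character vector of condition labels (from the
#'   seven-condition grid); must include `"resting"`.
#' @param genes gene annotation.
#' @param truth gene truth (naive-cell classes drive the planted signal).
#' @param pwms named list of `pwm` objects whose consensus strings are
#'   planted; may be empty.
#' @param planted_motif_rate fraction of foreground peaks receiving a
#'   planted motif.
#' @param stim_factor multiplicative coverage gain of matching windows in
#'   stimulated conditions.
#' @param noise_sd sd (log2) of multiplicative coverage noise.
#' @param seq_len_range peak sequence length range.
#' @param seed integer seed.
#' @return List: `peaks` (per condition), `coverage` (per condition data
#'   frame gene_id/mass/total), `sequences` (per condition, keyed by
#'   peak id), `planted` (per condition logical of motif planting).
#' @export
simulate_chromatin <- function(conditions, genes, truth, pwms = list(),
                               planted_motif_rate = 0.5, stim_factor = 2,
                               noise_sd = 0.2, seq_len_range = c(200, 500),
                               seed = 1L) {
  if (planted_motif_rate < 0 || planted_motif_rate > 1)
    stopf("planted_motif_rate must lie in [0, 1]")
  set.seed(seed %% 2147480000)
  grid <- condition_grid()
  if (!all(conditions %in% grid$condition))
    stopf("unknown condition(s): %s",
          paste(setdiff(conditions, grid$condition), collapse = ", "))
  G <- nrow(genes)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  sens_class <- truth$class_naive[match(genes$gene_id, truth$gene_id)]
  stim_of <- function(cls) {
    if (cls %in% c("tcr_linear", "tcr_switch")) "TCR"
    else if (cls %in% c("cd28_linear", "cd28_switch")) "CD28"
    else if (cls == "both") "both" else "none"
  }
  gene_stim <- vapply(sens_class, stim_of, "", USE.NAMES = FALSE)
  base_mass <- rgamma(G, shape = 4, rate = 1 / 250)  # ~1000 reads per window

  peaks <- list(); coverage <- list(); sequences <- list(); planted <- list()
  for (cond in conditions) {
    tcr <- grid$tcr_dose[grid$condition == cond]
    cd28 <- grid$cd28_dose[grid$condition == cond]
    matched <- (gene_stim == "TCR" & tcr > 0) |
      (gene_stim == "CD28" & cd28 > 0) |
      (gene_stim == "both" & (tcr > 0 | cd28 > 0))
    if (G > 0) {
      npk <- sample(1:3, G, replace = TRUE)
      pk <- do.call(rbind, lapply(seq_len(G), function(g) {
        width <- round(runif(npk[g], 200, 600))
        start <- pmax(0L, as.integer(tss[g] +
                                       round(runif(npk[g], -50000, 50000))))
        data.frame(chrom = genes$chrom[g], start = start,
                   end = as.integer(start + width),
                   score = round(rexp(npk[g], 1 / 8), 3),
                   gene_id = genes$gene_id[g],
                   fg = matched[g], stringsAsFactors = FALSE)
      }))
      pk <- pk[order(pk$chrom, pk$start, pk$end), ]
      pk$condition <- cond
      pk$peak_id <- sprintf("%s_peak_%05d", cond, seq_len(nrow(pk)))
      rownames(pk) <- NULL
    } else {
      pk <- data.frame(chrom = character(), start = integer(),
                       end = integer(), score = numeric(),
                       gene_id = character(), fg = logical(),
                       condition = character(), peak_id = character(),
                       stringsAsFactors = FALSE)
    }
    mass <- base_mass * 2^rnorm(G, 0, noise_sd)
    mass[matched] <- mass[matched] * stim_factor
    mass <- round(mass)
    coverage[[cond]] <- data.frame(gene_id = genes$gene_id,
                                   condition = rep(cond, G), mass = mass,
                                   total = rep(sum(mass) + 1e6, G),
                                   stringsAsFactors = FALSE)
    seqs <- random_sequences(nrow(pk),
                             round(runif(nrow(pk), seq_len_range[1],
                                         seq_len_range[2])),
                             names = pk$peak_id)
    pl <- rep(FALSE, length(seqs))
    is_stim <- cond != "resting"
    if (length(pwms) && is_stim && any(pk$fg)) {
      fg_idx <- which(pk$fg)
      for (pw in pwms) {
        emb <- embed_motif(seqs[fg_idx], pw$consensus, planted_motif_rate)
        seqs[fg_idx] <- emb$seqs
        pl[fg_idx] <- pl[fg_idx] | emb$planted
      }
    }
    peaks[[cond]] <- pk
    sequences[[cond]] <- seqs
    planted[[cond]] <- setNames(pl, pk$peak_id)
  }
  list(peaks = peaks, coverage = coverage, sequences = sequences,
       planted = planted)
}
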