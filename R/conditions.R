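#' The seven-condition stimulation grid
#'
#' T cells are stimulated on a titration grid of TCR (signal 1) and CD28
#' (signal 2) doses. Seven (tcr_dose, cd28_dose) combinations are used:
#' resting (0,0), lowTCR+lowCD28 (1,1), lowTCR+highCD28 (1,2),
#' highTCR+lowCD28 (2,1), highTCR+highCD28 (2,2), highTCR alone (2,0) and
#' highCD28 alone (0,2).
#'
#' @return data frame with columns `condition`, `tcr_dose`, `cd28_dose`.
#' @export
condition_grid <- function() {
  data.frame(
    condition = c("resting", "lowTCR_lowCD28", "lowTCR_highCD28",
                  "highTCR_lowCD28", "highTCR_highCD28", "highTCR",
                  "highCD28"),
    tcr_dose  = c(0L, 1L, 1L, 2L, 2L, 2L, 0L),
    cd28_dose = c(0L, 1L, 2L, 1L, 2L, 0L, 2L),
    stringsAsFactors = FALSE
  )
}

# condition label for a (tcr, cd28) dose pair, NA if off-grid
condition_label <- function(tcr_dose, cd28_dose) {
  grid <- condition_grid()
  key <- paste(tcr_dose, cd28_dose)
  grid$condition[match(key, paste(grid$tcr_dose, grid$cd28_dose))]
}

#' Validate a sample design sheet
#'
#' Checks uniqueness of sample ids, the allowed cell types, and that every
#' (tcr_dose, cd28_dose) pair lies on the seven-condition grid unless
#' `allow_custom_grid` is set.
#'
#' @param design data frame with columns `sample_id`, `cell_type`,
#'   `tcr_dose`, `cd28_dose`, `donor`, `batch`.
#' @param allow_custom_grid allow dose pairs off the seven-condition grid.
#' @return The design with a `condition` column added.
#' @export
validate_design <- function(design, allow_custom_grid = FALSE) {
  need <- c("sample_id", "cell_type", "tcr_dose", "cd28_dose", "donor", "batch")
  miss <- setdiff(need, names(design))
  if (length(miss)) stopf("design sheet missing columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stopf("duplicate sample ids in design: %s",
          paste(unique(design$sample_id[duplicated(design$sample_id)]),
                collapse = ", "))
  bad <- setdiff(unique(design$cell_type), c("naive", "memory"))
  if (length(bad)) stopf("unknown cell type(s): %s", paste(bad, collapse = ", "))
  design$condition <- condition_label(design$tcr_dose, design$cd28_dose)
  if (!allow_custom_grid && anyNA(design$condition)) {
    off <- which(is.na(design$condition))[1]
    stopf("sample '%s' has dose pair (%d,%d) off the 7-condition grid",
          design$sample_id[off], design$tcr_dose[off], design$cd28_dose[off])
  }
  design
}

#' Dose encoding for a single stimulus
#'
#' Returns the per-sample ordinal dose (0/1/2) of the stimulus under test.
#' Samples that received none of that stimulus are grouped at dose 0
#' regardless of the other signal: when testing CD28, the highTCR-alone
#' condition is grouped with resting because neither received CD28.
#'
#' @param design validated sample design.
#' @param stimulus `"TCR"` or `"CD28"`.
#' @return Integer vector of doses, one per sample.
#' @export
dose_encoding <- function(design, stimulus = c("TCR", "CD28")) {
  stimulus <- match.arg(stimulus)
  if (stimulus == "TCR") as.integer(design$tcr_dose)
  else as.integer(design$cd28_dose)
}
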