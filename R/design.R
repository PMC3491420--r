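#' Multi-sample study design with six-base barcodes
#'
#' Barcoded adapters tag each sample so that many libraries can be pooled and
#' sequenced in one lane; barcodes are pairwise-distinct six-base tags.
#'
#' @param n_samples Number of samples.
#' @param barcodes Character vector of distinct 6-base ACGT tags, one per
#'   sample; autogenerated when `NULL`.
#' @param reads_per_sample Reads to simulate per sample.
#' @param seed Optional integer seed for the read simulation.
#' @export
study_design <- function(n_samples = 12L, barcodes = NULL,
                         reads_per_sample = 20000L, seed = NULL) {
  n_samples <- assert_count(n_samples, "n_samples", min = 1L)
  reads_per_sample <- assert_count(reads_per_sample, "reads_per_sample", min = 1L)
  if (is.null(barcodes)) barcodes <- default_barcodes(n_samples)
  barcodes <- toupper(barcodes)
  if (length(barcodes) != n_samples) {
    stop("need exactly one barcode per sample", call. = FALSE)
  }
  if (any(nchar(barcodes) != 6L) || any(grepl("[^ACGT]", barcodes))) {
    stop("barcodes must be six-base ACGT tags", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("barcodes must be pairwise distinct", call. = FALSE)
  }
  structure(list(n_samples = n_samples, barcodes = barcodes,
                 reads_per_sample = reads_per_sample, seed = seed,
                 samples = sprintf("S%02d", seq_len(n_samples))),
            class = "study_design")
}

# Deterministic distinct 6-mers: base-4 encoding of well-spaced integers.
default_barcodes <- function(n) {
  stopifnot(n <= 4^6)
  idx <- (seq_len(n) - 1L) * 619L %% 4^6  # 619 coprime with 4^6 spreads tags
  vapply(idx, function(i) {
    d <- integer(6)
    for (k in 6:1) {
      d[k] <- i %% 4L
      i <- i %/% 4L
    }
    paste(c("A", "C", "G", "T")[d + 1L], collapse = "")
  }, character(1))
}
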