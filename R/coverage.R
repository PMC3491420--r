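#' Count distinct CpGs covered at depth thresholds
#'
#' The coverage of a CpG is its number of methylation calls (methylated +
#' unmethylated), not merely overlapping reads. `cpg_count_at[t]` is the
#' number of distinct CpGs with coverage >= t; counts are necessarily
#' non-increasing in t.
#'
#' @param calls A `cpg_calls` data.frame (possibly several samples).
#' @param thresholds Strictly increasing depth thresholds (default 1, 5, 10).
#' @param samples Optional sample universe; samples absent from `calls` get
#'   zero counts.
#' @return data.frame with one row per sample and one `cpg_<t>x` column per
#'   threshold.
#' @export
summarize_coverage <- function(calls, thresholds = c(1L, 5L, 10L),
                               samples = NULL) {
  stopifnot(length(thresholds) >= 1L, all(thresholds >= 1L),
            !is.unsorted(thresholds, strictly = TRUE))
  df <- as.data.frame(calls)
  if (is.null(samples)) samples <- unique(df$sample)
  out <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (t in thresholds) {
    cnt <- vapply(samples, function(s) {
      sum(df$sample == s & df$coverage >= t)
    }, integer(1))
    out[[sprintf("cpg_%dx", t)]] <- cnt
  }
  rownames(out) <- NULL
  out
}

#' Filter samples by a minimum total read count
#'
#' High-quality sample selection: retain samples whose total read count meets
#' the cutoff (default 5 million reads), preserving input order.
#'
#' @param samples A data.frame with columns `sample` and `total_reads`, or a
#'   named numeric vector of read counts.
#' @param min_total_reads Read-count cutoff (default 5e6).
#' @return The passing subset, same representation as the input.
#' @export
filter_high_quality <- function(samples, min_total_reads = 5e6) {
  if (is.data.frame(samples)) {
    stopifnot("total_reads" %in% names(samples))
    samples[samples$total_reads >= min_total_reads, , drop = FALSE]
  } else {
    samples[samples >= min_total_reads]
  }
}

#' Coverage profile by fragment length
#'
#' Attributes every mapped read to its fragment and reports, per fragment
#' length bin: the percentage of fragments covered by at least one read, and
#' the mean per-fragment read depth. Fragments not covered by any read —
#' including those excluded from the alignment target — are included in the
#' mean, which therefore understates per-covered-fragment depth by design.
#'
#' @param alignments An `rrbs_alignments` data.frame.
#' @param fragments The full `rrbs_fragments` table (covered or not).
#' @param bin_width Length bin width in bp (default 1).
#' @return data.frame `length` (bin start), `n_fragments`, `percent_covered`,
#'   `mean_depth`. `sum(n_fragments * mean_depth)` equals the number of
#'   mapped reads.
#' @export
fragment_profile <- function(alignments, fragments, bin_width = 1L) {
  al <- alignments[alignments$mapped, , drop = FALSE]
  fkey <- paste(fragments$chrom, fragments$start, fragments$end)
  depth <- integer(nrow(fragments))
  if (nrow(al)) {
    akey <- paste(al$chrom, al$frag_start, al$frag_end)
    tab <- table(akey)
    m <- match(names(tab), fkey)
    if (anyNA(m)) stop("mapped reads refer to fragments absent from `fragments`",
                       call. = FALSE)
    depth[m] <- as.integer(tab)
  }
  bin <- (fragments$length %/% bin_width) * bin_width
  dt <- data.table::data.table(bin = bin, depth = depth)
  out <- dt[, .(n_fragments = .N,
                percent_covered = 100 * mean(depth >= 1L),
                mean_depth = mean(depth)), by = "bin"]
  data.table::setorder(out, bin)
  data.table::setnames(out, "bin", "length")
  as.data.frame(out)
}

#' Correlation of per-CpG methylation between two runs of one sample
#'
#' Restricted to CpGs covered at `min_coverage` or more in both tables;
#' deeper cutoffs trade CpG count for better-estimated methylation fractions,
#' which is why replicate agreement improves with the coverage threshold.
#'
#' @param calls_a,calls_b Single-sample `cpg_calls` tables.
#' @param min_coverage Depth required in both runs (default 5).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `correlation` (`NA` when fewer than 2 CpGs are shared)
#'   and `n_cpgs`, the number of CpGs entering the correlation.
#' @export
replicate_correlation <- function(calls_a, calls_b, min_coverage = 5L,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- as.data.frame(calls_a)
  b <- as.data.frame(calls_b)
  if (length(unique(a$sample)) > 1L || length(unique(b$sample)) > 1L) {
    stop("replicate_correlation expects single-sample call tables", call. = FALSE)
  }
  m <- merge(a[, c("chrom", "pos", "meth", "coverage")],
             b[, c("chrom", "pos", "meth", "coverage")],
             by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  m <- m[m$coverage_a >= min_coverage & m$coverage_b >= min_coverage, ,
         drop = FALSE]
  if (nrow(m) < 2L) {
    return(list(correlation = NA_real_, n_cpgs = nrow(m)))
  }
  fa <- m$meth_a / m$coverage_a
  fb <- m$meth_b / m$coverage_b
  list(correlation = cor(fa, fb, method = method), n_cpgs = nrow(m))
}
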