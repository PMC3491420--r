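#' Classify a read by its CpG methylation calls
#'
#' A read whose CpG calls are all methylated is `completely_methylated`, all
#' unmethylated is `completely_unmethylated`, mixed is `partial`; a read
#' covering no CpG is `no_cpg` and is excluded from class proportions (the
#' classes are defined by methylation state, which requires >= 1 CpG).
#'
#' @param calls Character vector of per-CpG calls (`"M"`/`"U"`) for one read,
#'   or a logical vector (TRUE = methylated).
#' @return One of `"completely_methylated"`, `"completely_unmethylated"`,
#'   `"partial"`, `"no_cpg"`.
#' @export
classify_read <- function(calls) {
  if (is.logical(calls)) calls <- ifelse(calls, "M", "U")
  calls <- calls[calls %in% c("M", "U")]
  if (!length(calls)) return("no_cpg")
  if (all(calls == "M")) return("completely_methylated")
  if (all(calls == "U")) return("completely_unmethylated")
  "partial"
}

#' Vectorized read classification from comma-joined call strings
#'
#' @param states Character vector like `"M,U,M"` (empty string = no CpGs).
#' @return Factor with levels `completely_methylated`,
#'   `completely_unmethylated`, `partial`, `no_cpg`.
#' @export
classify_reads <- function(states) {
  n_m <- nchar(gsub("[^M]", "", states))
  n_u <- nchar(gsub("[^U]", "", states))
  out <- rep("partial", length(states))
  out[n_m == 0L & n_u == 0L] <- "no_cpg"
  out[n_m > 0L & n_u == 0L] <- "completely_methylated"
  out[n_m == 0L & n_u > 0L] <- "completely_unmethylated"
  factor(out, levels = c("completely_methylated", "completely_unmethylated",
                         "partial", "no_cpg"))
}

#' Observe per-read CpG states from read bases
#'
#' Reads the base at each CpG offset of the read's labeled origin fragment
#' end: `C` observes methylated, `T` unmethylated, anything else no call.
#' This is the barcode-anchored view of a library — chimeric reads are read
#' out against the fragment their barcode claims, which is exactly how a
#' pooled-amplification artifact would surface as a class-proportion shift.
#'
#' @param reads An `rrbs_reads` data.frame.
#' @param genome The genome the reads were simulated from.
#' @param read_length Read length used in the simulation.
#' @return Character vector of comma-joined observed states, parallel to
#'   `reads` rows.
#' @export
observe_read_states <- function(reads, genome,
                                read_length = attr(reads, "read_length")) {
  genome <- as_genome(genome)
  frags <- data.frame(chrom = reads$chrom, start = reads$fragment_start,
                      end = reads$fragment_end, stringsAsFactors = FALSE)
  ukey <- paste(frags$chrom, frags$start, frags$end)
  uniq <- !duplicated(ukey)
  ufr <- data.frame(chrom = frags$chrom[uniq], start = frags$start[uniq],
                    end = frags$end[uniq],
                    length = frags$end[uniq] - frags$start[uniq],
                    right_cut = TRUE, stringsAsFactors = FALSE)
  prof <- end_profiles(genome, ufr, read_length)
  pid <- paste(ufr$chrom[prof$frag], ufr$start[prof$frag], ufr$end[prof$frag],
               prof$end)
  ridx <- match(paste(ukey, reads$end_used), pid)
  out <- character(nrow(reads))
  for (p in unique(ridx)) {
    rows <- which(ridx == p)
    off <- prof$cpg_off[[p]]
    if (!length(off)) {
      out[rows] <- ""
      next
    }
    seqs <- reads$sequence[rows]
    base <- vapply(off, function(o) substr(seqs, o + 1L, o + 1L),
                   character(length(rows)))
    if (length(rows) == 1L) base <- matrix(base, nrow = 1L)
    st <- matrix("", nrow(base), ncol(base))
    st[base == "C"] <- "M"
    st[base == "T"] <- "U"
    joined <- do.call(paste, c(as.data.frame(st, stringsAsFactors = FALSE),
                               sep = ","))
    out[rows] <- gsub("^,+|,+$", "", gsub(",{2,}", ",", joined))
  }
  out
}

class_proportions <- function(classes) {
  keep <- classes != "no_cpg"
  tab <- table(factor(as.character(classes[keep]),
                      levels = c("completely_methylated",
                                 "completely_unmethylated", "partial")))
  list(n = sum(keep), prop = as.numeric(tab) / max(1L, sum(keep)),
       counts = as.integer(tab))
}

two_prop_z <- function(x1, n1, x2, n2) {
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  if (se == 0) return(0)
  (x1 / n1 - x2 / n2) / se
}

#' Pooled-amplification chimera experiment
#'
#' Reproduces the chimera assessment in silico: one barcoded library from
#' fully CpG-methylated DNA (sample A) and one from DNA with many
#' unmethylated regions (sample B, tuned so roughly `frac_unmethylated` of
#' its reads are completely unmethylated). Each library is simulated
#' amplified separately (`chimera_rate` 0) and as a pool (given
#' `chimera_rate`); reads are classified per barcode and the per-class
#' proportions compared with two-proportion z statistics. Template switching
#' in the pool moves sample-B (unmethylated) sequence onto sample-A barcodes
#' and vice versa, surfacing as a rise in partial/discordant reads; with no
#' chimerism the pooled and separate proportions agree to sampling noise.
#'
#' @param n_reads_per_sample Reads per library (default 50000).
#' @param chimera_rate Template-switch probability in the pooled run.
#' @param frac_unmethylated Fraction of the genome unmethylated in sample B
#'   (region-level blocks; default 0.45).
#' @param block_size Methylation block size for sample B, bp (default 2000).
#' @param genome Optional `rrbs_genome`; a compact island-rich genome is
#'   generated when `NULL`.
#' @param selection,conversion Size-selection and conversion models.
#' @param read_length Read length (default 29).
#' @param seed Optional seed.
#' @return Object of class `pool_comparison`: `table` (per barcode x class:
#'   counts, proportions separate/pooled and z), `max_abs_diff`,
#'   `max_abs_z`, and the settings used.
#' @export
pooled_amplification_experiment <- function(n_reads_per_sample = 50000L,
                                            chimera_rate = 0,
                                            frac_unmethylated = 0.45,
                                            block_size = 2000L, genome = NULL,
                                            selection = size_selection_model(),
                                            conversion = conversion_model(),
                                            read_length = 29L, seed = NULL) {
  assert_prob(chimera_rate, "chimera_rate")
  assert_prob(frac_unmethylated, "frac_unmethylated")
  with_seed_if(seed, {
    if (is.null(genome)) {
      genome <- generate_genome(genome_spec(n_chroms = 2L,
                                            chrom_length = 40000L,
                                            island_count = 10L,
                                            island_cpg_rate = 0.12))
    }
    frags <- digest_genome(genome)
    cpgs <- cpg_sites(genome)
    if (is.null(cpgs) || !nrow(cpgs)) stop("genome has no CpGs", call. = FALSE)
    meth_a <- data.frame(chrom = cpgs$chrom, pos = cpgs$pos,
                         truth_probability = 1, stringsAsFactors = FALSE)
    # sample B: region-level methylation — unmethylated blocks of block_size
    blk <- paste(cpgs$chrom, cpgs$pos %/% block_size)
    ublk <- unique(blk)
    unmeth_blk <- ublk[runif(length(ublk)) < frac_unmethylated]
    meth_b <- data.frame(chrom = cpgs$chrom, pos = cpgs$pos,
                         truth_probability = ifelse(blk %in% unmeth_blk, 0, 1),
                         stringsAsFactors = FALSE)
    design2 <- study_design(n_samples = 2L, barcodes = c("ACGTAC", "TGCAGT"),
                            reads_per_sample = n_reads_per_sample)
    meth_list <- list(S01 = meth_a, S02 = meth_b)

    sep <- generate_reads(frags, meth_list, design2, genome, selection,
                          conversion, chimera_model(0), read_length)
    pooled <- generate_reads(frags, meth_list, design2, genome, selection,
                             conversion, chimera_model(chimera_rate),
                             read_length)
    cls_sep <- classify_reads(observe_read_states(sep, genome, read_length))
    cls_pool <- classify_reads(observe_read_states(pooled, genome, read_length))
    lev <- c("completely_methylated", "completely_unmethylated", "partial")
    rows <- list()
    for (si in 1:2) {
      smp <- design2$samples[si]
      ps <- class_proportions(cls_sep[sep$sample == smp])
      pp <- class_proportions(cls_pool[pooled$sample == smp])
      if (ps$n == 0L || pp$n == 0L) {
        stop("degenerate sample ", smp, ": no CpG-bearing reads", call. = FALSE)
      }
      z <- vapply(seq_along(lev), function(k) {
        two_prop_z(ps$counts[k], ps$n, pp$counts[k], pp$n)
      }, numeric(1))
      rows[[si]] <- data.frame(barcode = design2$barcodes[si], sample = smp,
                               class = lev, n_separate = ps$counts,
                               prop_separate = ps$prop,
                               n_pooled = pp$counts, prop_pooled = pp$prop,
                               z = z, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    structure(list(table = tab,
                   max_abs_diff = max(abs(tab$prop_separate - tab$prop_pooled)),
                   max_abs_z = max(abs(tab$z), na.rm = TRUE),
                   chimera_rate = chimera_rate,
                   n_reads_per_sample = n_reads_per_sample),
              class = "pool_comparison")
  })
}

#' @export
print.pool_comparison <- function(x, ...) {
  cat("pooled-amplification comparison (chimera rate ", x$chimera_rate,
      ", ", x$n_reads_per_sample, " reads/sample)\n", sep = "")
  print(x$table, digits = 4)
  cat("max |prop difference|:", signif(x$max_abs_diff, 4),
      " max |z|:", signif(x$max_abs_z, 4), "\n")
  invisible(x)
}
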