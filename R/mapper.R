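#' Build the MspI-end-anchored alignment target
#'
#' Reduced-representation reads begin at MspI cut sites by construction, so
#' instead of general alignment the mapper indexes, for every fragment up to
#' `max_target_length` and each of its two ends/strands, the C-to-T-collapsed
#' read-length prefix of the sequenced molecule, keyed for exact lookup.
#' Fragments longer than `max_target_length` (default 300 bp) are excluded
#' from the alignment target. Prefixes shorter than `read_length` (short
#' fragments) are stored at their full molecule length. Entries whose
#' collapsed key collides with another entry's are flagged ambiguous.
#'
#' This anchored design is deliberately not a general-purpose aligner: reads
#' map at offset 0 or not at all, and collapsing C to T on both read and
#' reference means bisulfite conversion never counts as a mismatch.
#'
#' @param fragments An `rrbs_fragments` data.frame.
#' @param genome The genome the fragments came from.
#' @param read_length Read length (default 29).
#' @param max_target_length Longest fragment admitted to the target (default 300).
#' @return An object of class `rrbs_target`.
#' @export
build_alignment_target <- function(fragments, genome, read_length = 29L,
                                   max_target_length = 300L) {
  genome <- as_genome(genome)
  keep <- which(fragments$length <= max_target_length)
  prof <- end_profiles(genome, fragments, read_length, frag_idx = keep)
  prof$key <- chartr("C", "T", prof$seq)
  kid <- paste(prof$plen, prof$key)
  prof$ambiguous <- kid %in% kid[duplicated(kid)]
  structure(list(entries = prof, read_length = as.integer(read_length),
                 max_target_length = as.integer(max_target_length),
                 chrom_lengths = chrom_lengths_of(genome)),
            class = "rrbs_target")
}

#' @export
print.rrbs_target <- function(x, ...) {
  cat("rrbs_target:", nrow(x$entries), "end entries (",
      sum(x$entries$ambiguous), "ambiguous ), fragments <=",
      x$max_target_length, "bp, read length", x$read_length, "\n")
  invisible(x)
}

#' Map bisulfite reads to the anchored target
#'
#' Each read is C-to-T collapsed and looked up against the collapsed target
#' prefixes of its own length. A unique best hit within the mismatch budget
#' (mismatches counted on the collapsed alphabet) yields a mapped read; zero
#' hits give `no_hit`, and ties at the best mismatch count — or a hit on an
#' ambiguous entry — give `ambiguous`, since the informative-read definition
#' requires unique mapping.
#'
#' @param reads An `rrbs_reads` data.frame (or any data.frame with `read_id`,
#'   `sample` and `sequence` columns).
#' @param target An `rrbs_target` from [build_alignment_target()].
#' @param max_mismatches Mismatch budget on the collapsed alphabet (default 2).
#' @return A data.frame of class `rrbs_alignments`: per read, `mapped`,
#'   `reason` (`no_hit`/`ambiguous` when unmapped), the hit entry and its
#'   anchoring (`chrom`, `frag_start`, `frag_end`, `end`, `strand`),
#'   `mismatches`, `n_cpg` (genomic CpGs under the aligned span) and
#'   `informative` (mapped uniquely and `n_cpg >= 1`).
#' @export
map_reads <- function(reads, target, max_mismatches = 2L) {
  stopifnot(inherits(target, "rrbs_target"))
  ent <- target$entries
  n <- nrow(reads)
  collapsed <- chartr("C", "T", reads$sequence)
  rlen <- nchar(collapsed)
  if (any(rlen > target$read_length)) {
    stop("reads longer than the target read length", call. = FALSE)
  }
  kid <- paste(ent$plen, ent$key)
  hit <- match(paste(rlen, collapsed), kid)
  mism <- ifelse(is.na(hit), NA_integer_, 0L)

  # mismatch-tolerant fallback for reads without an exact collapsed hit
  todo <- which(is.na(hit))
  if (length(todo) && max_mismatches > 0L) {
    by_len <- split(seq_len(nrow(ent)), ent$plen)
    mats <- new.env(parent = emptyenv())
    for (i in todo) {
      li <- as.character(rlen[i])
      idx <- by_len[[li]]
      if (is.null(idx)) next
      if (is.null(mats[[li]])) {
        mats[[li]] <- do.call(rbind, strsplit(ent$key[idx], "", fixed = TRUE))
      }
      rc <- strsplit(collapsed[i], "", fixed = TRUE)[[1]]
      mm <- rowSums(mats[[li]] != matrix(rc, nrow = length(idx),
                                         ncol = rlen[i], byrow = TRUE))
      best <- min(mm)
      if (best <= max_mismatches) {
        if (sum(mm == best) == 1L) {
          hit[i] <- idx[which.min(mm)]
          mism[i] <- as.integer(best)
        } else {
          hit[i] <- -1L  # tie -> ambiguous
        }
      }
    }
  }

  mapped <- !is.na(hit) & hit > 0L & !ifelse(is.na(hit) | hit < 0L, FALSE,
                                             ent$ambiguous[pmax(hit, 1L)])
  reason <- rep(NA_character_, n)
  reason[is.na(hit)] <- "no_hit"
  reason[!is.na(hit) & hit < 0L] <- "ambiguous"
  amb_hit <- !is.na(hit) & hit > 0L & ent$ambiguous[pmax(hit, 1L)]
  reason[amb_hit] <- "ambiguous"
  eidx <- ifelse(mapped, hit, NA_integer_)
  n_cpg <- ifelse(mapped, lengths(ent$cpg_off)[pmax(eidx, 1L)], NA_integer_)
  al <- data.frame(
    read_id = reads$read_id, sample = reads$sample,
    sequence = reads$sequence, mapped = mapped, reason = reason,
    entry = eidx,
    chrom = ifelse(mapped, ent$chrom[pmax(eidx, 1L)], NA_character_),
    frag_start = ifelse(mapped, ent$frag_start[pmax(eidx, 1L)], NA_integer_),
    frag_end = ifelse(mapped, ent$frag_end[pmax(eidx, 1L)], NA_integer_),
    end = ifelse(mapped, ent$end[pmax(eidx, 1L)], NA_character_),
    strand = ifelse(mapped, ent$strand[pmax(eidx, 1L)], NA_character_),
    mismatches = ifelse(mapped, mism, NA_integer_),
    n_cpg = n_cpg,
    informative = mapped & !is.na(n_cpg) & n_cpg >= 1L,
    stringsAsFactors = FALSE)
  class(al) <- c("rrbs_alignments", "data.frame")
  attr(al, "max_mismatches") <- as.integer(max_mismatches)
  al
}

# Tabulate read bases at a set of local offsets for all mapped reads,
# grouped by target entry; `which` selects CpG or non-CpG cytosine offsets.
collect_base_observations <- function(alignments, target, which = c("cpg", "c")) {
  which <- match.arg(which)
  ent <- target$entries
  al <- alignments[alignments$mapped, , drop = FALSE]
  if (!nrow(al)) return(data.table::data.table())
  parts <- list()
  for (e in unique(al$entry)) {
    off <- if (which == "cpg") ent$cpg_off[[e]] else ent$c_off[[e]]
    if (!length(off)) next
    rows <- which(al$entry == e)
    seqs <- al$sequence[rows]
    base <- vapply(off, function(o) substr(seqs, o + 1L, o + 1L),
                   character(length(rows)))
    if (length(rows) == 1L) base <- matrix(base, nrow = 1L)
    key <- if (which == "cpg") ent$cpg_key[[e]] else
      (if (ent$strand[e] == "+") ent$mol_start[e] + off
       else ent$mol_end[e] - 1L - off)
    parts[[length(parts) + 1L]] <- data.table::data.table(
      sample = rep(al$sample[rows], times = length(off)),
      chrom = ent$chrom[e],
      pos = rep(key, each = length(rows)),
      base = as.vector(base))
  }
  if (!length(parts)) return(data.table::data.table())
  data.table::rbindlist(parts)
}

#' Call per-CpG methylation from mapped reads
#'
#' Methylation is called by observing the bisulfite transformation in the
#' read (not the genome): at each genomic CpG under an aligned read, a read
#' base `C` is a methylated call and `T` an unmethylated call; any other base
#' (sequencing error) yields no call. Minus-strand reads report the
#' complementary cytosine of the same CpG unit, and both strands' evidence is
#' keyed by the plus-strand C coordinate, matching single-count CpG
#' bookkeeping.
#'
#' @param alignments An `rrbs_alignments` data.frame from [map_reads()].
#' @param target The `rrbs_target` the reads were mapped against.
#' @return A data.frame of class `cpg_calls`: `sample`, `chrom`, `pos`
#'   (0-based plus-strand C), `meth`, `unmeth`, `coverage` (= meth + unmeth,
#'   always >= 1; CpGs with no calls are absent).
#' @export
call_methylation <- function(alignments, target) {
  obs <- collect_base_observations(alignments, target, "cpg")
  if (!nrow(obs)) {
    out <- data.frame(sample = character(), chrom = character(),
                      pos = integer(), meth = integer(), unmeth = integer(),
                      coverage = integer(), stringsAsFactors = FALSE)
    class(out) <- c("cpg_calls", "data.frame")
    return(out)
  }
  base <- NULL; meth <- NULL; unmeth <- NULL  # NSE guards
  calls <- obs[base %in% c("C", "T"),
               .(meth = sum(base == "C"), unmeth = sum(base == "T")),
               by = .(sample, chrom, pos)]
  calls <- calls[meth + unmeth >= 1L]
  data.table::setorder(calls, sample, chrom, pos)
  out <- as.data.frame(calls)
  out$coverage <- out$meth + out$unmeth
  class(out) <- c("cpg_calls", "data.frame")
  out
}

#' Estimate bisulfite conversion efficiency from non-CpG cytosines
#'
#' Non-CpG cytosines are essentially unmethylated in somatic DNA, so the
#' fraction reading T estimates the conversion rate:
#' `T / (T + C)` over all covered non-CpG cytosine positions, per sample.
#'
#' @inheritParams call_methylation
#' @return data.frame `sample`, `n_obs`, `estimate` (fraction in `[0, 1]`;
#'   `NA` when a sample covers no non-CpG cytosine).
#' @export
estimate_conversion <- function(alignments, target) {
  obs <- collect_base_observations(alignments, target, "c")
  samples <- unique(alignments$sample)
  if (!nrow(obs)) {
    return(data.frame(sample = samples, n_obs = 0L, estimate = NA_real_,
                      stringsAsFactors = FALSE))
  }
  base <- NULL
  est <- obs[base %in% c("C", "T"),
             .(n_obs = .N, estimate = sum(base == "T") / .N), by = "sample"]
  out <- merge(data.frame(sample = samples, stringsAsFactors = FALSE),
               as.data.frame(est), by = "sample", all.x = TRUE)
  out$n_obs[is.na(out$n_obs)] <- 0L
  out[order(out$sample), , drop = FALSE]
}

#' Fraction of mapped reads with at least one mismatch
#'
#' Mismatches are counted on the C-to-T-collapsed alphabet, so bisulfite
#' conversion itself never contributes; residual mismatches reflect
#' sequencing errors or chimeric joins.
#'
#' @param alignments An `rrbs_alignments` data.frame with >= 1 mapped read.
#' @return A single fraction.
#' @export
mismatch_rate <- function(alignments) {
  m <- alignments$mismatches[alignments$mapped]
  if (!length(m)) stop("no mapped reads", call. = FALSE)
  mean(m >= 1L)
}

#' Export mapped reads as SAM
#'
#' Minimal single-end SAM: flag 0/16, 1-based POS, full-length match CIGAR,
#' `NM` tag carrying the collapsed-alphabet mismatch count.
#'
#' @inheritParams call_methylation
#' @param path Output SAM path.
#' @export
write_sam <- function(alignments, target, path) {
  lens <- target$chrom_lengths
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)))
  al <- alignments[alignments$mapped, , drop = FALSE]
  ent <- target$entries
  lines <- hdr
  if (nrow(al)) {
    plen <- nchar(al$sequence)
    minus <- al$strand == "-"
    pos1 <- ifelse(minus, ent$mol_end[al$entry] - plen + 1L,
                   ent$mol_start[al$entry] + 1L)
    seq_out <- al$sequence
    seq_out[minus] <- revcomp_chr(al$sequence[minus])
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                              al$read_id, ifelse(minus, 16L, 0L), al$chrom,
                              pos1, plen, seq_out, strrep("I", plen),
                              al$mismatches))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a bedGraph-style CpG report
#'
#' Columns: chrom, pos, pos + 1, methylation percent, methylated count,
#' unmethylated count. With several samples in the table, counts are summed
#' across samples unless one `sample` is selected.
#'
#' @param calls A `cpg_calls` data.frame.
#' @param path Output TSV path.
#' @param sample Optional single sample to report.
#' @export
write_cpg_report <- function(calls, path, sample = NULL) {
  df <- as.data.frame(calls)
  if (!is.null(sample)) df <- df[df$sample == sample, , drop = FALSE]
  dt <- data.table::as.data.table(df)
  meth <- NULL; unmeth <- NULL
  agg <- dt[, .(meth = sum(meth), unmeth = sum(unmeth)), by = .(chrom, pos)]
  data.table::setorder(agg, chrom, pos)
  out <- data.frame(chrom = agg$chrom, start = agg$pos, end = agg$pos + 1L,
                    methylation_percent = round(100 * agg$meth /
                                                  (agg$meth + agg$unmeth), 3),
                    methylated_count = agg$meth,
                    unmethylated_count = agg$unmeth)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
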