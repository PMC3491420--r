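#' In silico restriction digestion
#'
#' Enumerates the fragments produced by digesting a genome with a restriction
#' enzyme, by default MspI (recognition site `CCGG`, cut `C^CGG`, i.e. between
#' the first and second base). A cut is placed at every site occurrence; `N`
#' bases never match the site, and the fragments of one chromosome tile it
#' exactly. Because the MspI cut leaves `CGG` at the start of every internal
#' fragment (and a `C` completing the site at its end), every internal
#' fragment carries at least one CpG — the property that makes the digest a
#' reduced representation of the methylome.
#'
#' Chromosome-end fragments are retained and flagged `is_terminal`; the
#' >=1-CpG guarantee is asserted only for internal fragments, since it derives
#' from the cut chemistry.
#'
#' @param genome An `rrbs_genome`, `DNAStringSet`, character vector or FASTA
#'   path. Sequences must be uppercase ACGTN.
#' @param site Recognition sequence (default `"CCGG"`).
#' @param cut_offset Cut position within the site: the cut falls between base
#'   `cut_offset` and `cut_offset + 1` of each occurrence (default 1, i.e.
#'   `C^CGG`).
#' @return A data.frame of class `rrbs_fragments`, one row per fragment in
#'   coordinate order: `chrom`, `start`, `end` (0-based half-open), `length`,
#'   `n_cpg`, `is_terminal`, `left_cut`, `right_cut`, and a list-column `cpg`
#'   of 0-based plus-strand C positions within `[start, end)`. Chromosome
#'   lengths are attached as attribute `chrom_lengths`.
#' @examples
#' frags <- digest_genome(c(chrA = "ACCGGT"))
#' frags[, c("chrom", "start", "end")]  # [0,2) "AC" and [2,6) "CGGT"
#' @export
digest_genome <- function(genome, site = "CCGG", cut_offset = 1L) {
  genome <- as_genome(genome)
  stopifnot(nchar(site) >= 1L, cut_offset >= 0L, cut_offset <= nchar(site))
  lens <- chrom_lengths_of(genome)
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    ch <- names(lens)[i]
    L <- lens[[i]]
    if (L == 0L) {
      out[[i]] <- NULL
      next
    }
    hits <- Biostrings::start(
      Biostrings::matchPattern(site, genome$seq[[ch]], fixed = TRUE)) - 1L
    cuts <- sort(unique(hits + as.integer(cut_offset)))
    cuts <- cuts[cuts > 0L & cuts < L]
    bounds <- c(0L, cuts, L)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L]
    n <- length(starts)
    cg <- Biostrings::start(
      Biostrings::matchPattern("CG", genome$seq[[ch]], fixed = TRUE)) - 1L
    # assign each CpG to the fragment containing its C
    frag_of <- findInterval(cg, starts)
    cpg <- split(cg, factor(frag_of, levels = seq_len(n)))
    df <- data.frame(chrom = rep(ch, n), start = starts, end = ends,
                     length = ends - starts,
                     n_cpg = as.integer(lengths(cpg)),
                     is_terminal = seq_len(n) == 1L | seq_len(n) == n,
                     left_cut = seq_len(n) > 1L,
                     right_cut = seq_len(n) < n,
                     stringsAsFactors = FALSE)
    df$cpg <- unname(cpg)
    out[[i]] <- df
  }
  out <- out[!vapply(out, is.null, logical(1))]
  frags <- if (length(out)) do.call(rbind, out) else {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     length = integer(), n_cpg = integer(),
                     is_terminal = logical(), left_cut = logical(),
                     right_cut = logical(), stringsAsFactors = FALSE)
    df$cpg <- list()
    df
  }
  rownames(frags) <- NULL
  attr(frags, "chrom_lengths") <- lens
  attr(frags, "site") <- site
  attr(frags, "cut_offset") <- as.integer(cut_offset)
  class(frags) <- c("rrbs_fragments", "data.frame")
  frags
}

#' Fragment length histogram
#'
#' Counts fragments per length bin; the bins partition the input exhaustively,
#' so the counts sum to the number of fragments.
#'
#' @param fragments An `rrbs_fragments` data.frame.
#' @param bin_width Bin width in bases (default 1: one bin per length).
#' @return data.frame `length` (bin start), `count`.
#' @export
fragment_length_histogram <- function(fragments, bin_width = 1L) {
  stopifnot(bin_width >= 1L)
  if (nrow(fragments) == 0L) {
    return(data.frame(length = integer(), count = integer()))
  }
  bin <- (fragments$length %/% bin_width) * bin_width
  tab <- table(bin)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}

#' Write fragments as BED6
#'
#' name = `chrom:start-end`, score = CpG count, strand = ".".
#' @param fragments An `rrbs_fragments` data.frame.
#' @param path Output BED path.
#' @export
write_fragments_bed <- function(fragments, path) {
  df <- data.frame(chrom = fragments$chrom, start = fragments$start,
                   end = fragments$end,
                   name = sprintf("%s:%d-%d", fragments$chrom,
                                  fragments$start, fragments$end),
                   score = fragments$n_cpg, strand = ".",
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
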