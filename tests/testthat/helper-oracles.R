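# Independent oracles and fixture builders used across the suite.

# Regex-based digestion oracle: find (possibly overlapping) site occurrences
# with a lookahead and split at `cut_offset` inside each.
oracle_digest <- function(seq, site = "CCGG", cut_offset = 1L) {
  hits <- gregexpr(paste0("(?=", site, ")"), seq, perl = TRUE)[[1]]
  hits <- hits[hits > 0]
  L <- nchar(seq)
  cuts <- sort(unique(hits - 1L + cut_offset))
  cuts <- cuts[cuts > 0 & cuts < L]
  data.frame(start = c(0L, cuts), end = c(cuts, L))
}

# Brute-force island oracle: for every candidate start, enumerate all ends
# and keep the longest qualifying one; cluster overlapping-or-adjacent
# qualifying intervals and report the longest interval per cluster
# (leftmost on ties). Criteria: GC >= min_gc, O/E >= min_oe (undefined when
# a window lacks C or G), length >= min_len; a CpG is counted when both its
# bases lie in the window.
oracle_islands <- function(seq, min_oe = 0.6, min_gc = 0.5, min_len = 700L,
                           max_len = nchar(seq)) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  empty <- data.frame(start = integer(), end = integer())
  if (n < min_len) return(empty)
  P_C <- c(0L, cumsum(v == "C"))
  P_G <- c(0L, cumsum(v == "G"))
  is_cg <- c(v[-n] == "C" & v[-1] == "G", FALSE)
  P_CG <- c(0L, cumsum(is_cg))
  starts <- integer(0)
  ends <- integer(0)
  for (s in 0:(n - min_len)) {
    e <- (s + min_len):min(n, s + max_len)
    L <- e - s
    nC <- P_C[e + 1L] - P_C[s + 1L]
    nG <- P_G[e + 1L] - P_G[s + 1L]
    nCG <- P_CG[e] - P_CG[s + 1L]
    ok <- nC > 0 & nG > 0 & (nC + nG) >= min_gc * L & nCG * L >= min_oe * nC * nG
    if (any(ok)) {
      starts <- c(starts, s)
      ends <- c(ends, e[max(which(ok))])
    }
  }
  if (!length(starts)) return(empty)
  # cluster + maximum, written independently of the package implementation
  res_s <- integer(0)
  res_e <- integer(0)
  cl_idx <- list()
  cur <- c(1L)
  max_end <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > max_end) {
      cl_idx[[length(cl_idx) + 1L]] <- cur
      cur <- integer(0)
      max_end <- ends[i]
    } else {
      max_end <- max(max_end, ends[i])
    }
    cur <- c(cur, i)
  }
  cl_idx[[length(cl_idx) + 1L]] <- cur
  for (cl in cl_idx) {
    lens <- ends[cl] - starts[cl]
    b <- cl[which.max(lens)]
    res_s <- c(res_s, starts[b])
    res_e <- c(res_e, ends[b])
  }
  data.frame(start = res_s, end = res_e)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# A compact island-rich genome that digests into plenty of short fragments.
small_test_genome <- function(seed, n_chroms = 1L, chrom_length = 20000L,
                              island_count = 4L, island_cpg_rate = 0.12,
                              background_cpg_rate = 0.01) {
  generate_genome(genome_spec(n_chroms = n_chroms, chrom_length = chrom_length,
                              island_count = island_count,
                              island_cpg_rate = island_cpg_rate,
                              background_cpg_rate = background_cpg_rate,
                              seed = seed))
}

chrom_string <- function(genome, chrom = 1L) {
  as.character(genome$seq[[chrom]])
}
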