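#' Specification of a synthetic genome
#'
#' Describes a genome with a CpG-poor background and planted CpG-dense,
#' island-like segments — the dichotomy that motivates reduced-representation
#' protocols: MspI (C^CGG) sites concentrate where CpGs concentrate, so the
#' digest preferentially samples island-like sequence.
#'
#' Outside planted CpGs the sequence is i.i.d. with the stated GC fraction;
#' CpG dinucleotides are then planted at the requested per-base rate
#' (`background_cpg_rate` genome-wide, `island_cpg_rate` inside islands), so
#' that the empirical CG dinucleotide rate matches the nominal rate. With the
#' defaults, islands have GC ~0.56 and CpG observed/expected ~1.3, i.e. they
#' satisfy the island criteria of [find_cpg_islands()], while the background
#' (GC ~0.46, O/E ~0.2, human-like) does not.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param background_gc GC fraction of the non-CpG background, in `[0, 1]`.
#' @param background_cpg_rate Expected CpGs per base outside islands.
#' @param island_count Number of islands planted per chromosome.
#' @param island_length_range Length-2 vector, min and max island length (bp).
#' @param island_cpg_rate Expected CpGs per base inside islands; must be
#'   `>= background_cpg_rate`.
#' @param seed Optional integer seed; when given, generation is reproducible
#'   and the caller's RNG stream is left untouched.
#' @return An object of class `genome_spec`.
#' @seealso [generate_genome()]
#' @export
genome_spec <- function(n_chroms = 2L, chrom_length = 50000L,
                        background_gc = 0.45, background_cpg_rate = 0.01,
                        island_count = 5L, island_length_range = c(800L, 1500L),
                        island_cpg_rate = 0.10, seed = NULL) {
  n_chroms <- assert_count(n_chroms, "n_chroms", min = 1L)
  chrom_length <- assert_count(chrom_length, "chrom_length", min = 1L)
  island_count <- assert_count(island_count, "island_count", min = 0L)
  assert_prob(background_gc, "background_gc")
  if (background_cpg_rate <= 0 || background_cpg_rate >= 1) {
    stop("`background_cpg_rate` must lie in (0, 1)", call. = FALSE)
  }
  if (island_cpg_rate <= 0 || island_cpg_rate >= 1) {
    stop("`island_cpg_rate` must lie in (0, 1)", call. = FALSE)
  }
  if (island_cpg_rate < background_cpg_rate) {
    stop("`island_cpg_rate` must be >= `background_cpg_rate`", call. = FALSE)
  }
  stopifnot(length(island_length_range) == 2L,
            island_length_range[1] >= 1, island_length_range[2] >= island_length_range[1])
  if (island_count * island_length_range[2] > chrom_length) {
    stop("planted islands cannot fit: island_count * max island length (",
         island_count * island_length_range[2], ") exceeds chrom_length (",
         chrom_length, ")", call. = FALSE)
  }
  structure(list(n_chroms = n_chroms, chrom_length = chrom_length,
                 background_gc = background_gc,
                 background_cpg_rate = background_cpg_rate,
                 island_count = island_count,
                 island_length_range = as.integer(island_length_range),
                 island_cpg_rate = island_cpg_rate, seed = seed),
            class = "genome_spec")
}

new_rrbs_genome <- function(seq, islands, spec) {
  structure(list(seq = seq, islands = islands, spec = spec),
            class = "rrbs_genome")
}

base_freqs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

# i.i.d. background, then remove every chance CG dinucleotide by redrawing the
# G; a redraw to C can create a new CG one base downstream, hence the loop.
random_cpg_free_bases <- function(n, gc) {
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = base_freqs(gc))
  p <- base_freqs(gc)[c("A", "C", "T")]
  p <- p / sum(p)
  for (it in 1:12) {
    i <- which(x[-length(x)] == "C" & x[-1] == "G")
    if (!length(i)) return(x)
    x[i + 1L] <- sample(c("A", "C", "T"), length(i), replace = TRUE, prob = p)
  }
  i <- which(x[-length(x)] == "C" & x[-1] == "G")
  if (length(i)) x[i + 1L] <- "A"
  x
}

# Plant CG dinucleotides at per-base rate `rate[i]` (position-specific).
# Candidate C positions are Bernoulli(q) with q = r/(1-r); a greedy >=2 bp
# spacing rule prevents overlapping plants, and the thinning is what the
# q = r/(1-r) adjustment compensates for, so the realized CpG rate is ~r.
plant_cpgs <- function(x, rate) {
  n <- length(x)
  if (n < 2L) return(x)
  q <- rate / (1 - rate)
  cand <- which(runif(n - 1L) < q[seq_len(n - 1L)])
  if (!length(cand)) return(x)
  last <- -2L
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (cand[i] - last >= 2L) {
      keep[i] <- TRUE
      last <- cand[i]
    }
  }
  pos <- cand[keep]
  x[pos] <- "C"
  x[pos + 1L] <- "G"
  x
}

# Rejection-sample `count` non-overlapping island intervals in [0, L).
place_islands <- function(L, count, len_range, max_tries = 1000L * max(1L, count)) {
  if (count == 0L) return(data.frame(start = integer(), end = integer()))
  starts <- integer(count)
  ends <- integer(count)
  placed <- 0L
  tries <- 0L
  while (placed < count) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", count, " non-overlapping islands in a ",
           L, " bp chromosome", call. = FALSE)
    }
    len <- if (len_range[1] == len_range[2]) len_range[1] else
      sample(seq.int(len_range[1], len_range[2]), 1L)
    if (len > L) {
      stop("island length ", len, " exceeds chromosome length ", L, call. = FALSE)
    }
    s <- sample.int(L - len + 1L, 1L) - 1L
    e <- s + len
    if (placed > 0L) {
      ov <- any(s < ends[seq_len(placed)] & e > starts[seq_len(placed)])
      if (ov) next
    }
    placed <- placed + 1L
    starts[placed] <- s
    ends[placed] <- e
  }
  o <- order(starts)
  data.frame(start = starts[o], end = ends[o])
}

#' Generate a synthetic genome with planted CpG islands
#'
#' Builds `n_chroms` chromosomes according to a [genome_spec()]: a CpG-free
#' i.i.d. background at the stated GC fraction, CpGs planted at the background
#' rate genome-wide and at the (higher) island rate inside non-overlapping
#' planted intervals. The planted intervals are recorded in the returned
#' object so island-detection and recovery can be validated against truth.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `rrbs_genome`: a list with elements `seq`
#'   (a [Biostrings::DNAStringSet]), `islands` (data.frame `chrom`, `start`,
#'   `end`; 0-based half-open truth intervals) and `spec`.
#' @examples
#' g <- generate_genome(genome_spec(n_chroms = 1, chrom_length = 5000,
#'                                  island_count = 1, seed = 1))
#' g$islands
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed_if(spec$seed, {
    chroms <- character(spec$n_chroms)
    isl_list <- vector("list", spec$n_chroms)
    for (i in seq_len(spec$n_chroms)) {
      L <- spec$chrom_length
      isl <- place_islands(L, spec$island_count, spec$island_length_range)
      x <- random_cpg_free_bases(L, spec$background_gc)
      rate <- rep(spec$background_cpg_rate, L)
      if (nrow(isl)) {
        for (k in seq_len(nrow(isl))) {
          rate[(isl$start[k] + 1L):isl$end[k]] <- spec$island_cpg_rate
        }
      }
      x <- plant_cpgs(x, rate)
      chroms[i] <- paste(x, collapse = "")
      isl_list[[i]] <- if (nrow(isl)) {
        data.frame(chrom = paste0("chr", i), start = isl$start, end = isl$end,
                   stringsAsFactors = FALSE)
      } else empty_intervals()
    }
    seq <- Biostrings::DNAStringSet(chroms)
    names(seq) <- paste0("chr", seq_len(spec$n_chroms))
    new_rrbs_genome(seq, do.call(rbind, isl_list), spec)
  })
}

#' @export
print.rrbs_genome <- function(x, ...) {
  cat("rrbs_genome:", length(x$seq), "chromosome(s),",
      sum(Biostrings::width(x$seq)), "bp total,",
      nrow(x$islands), "truth island(s)\n")
  invisible(x)
}

#' Positions of CpG dinucleotides
#'
#' CpGs are identified on the plus strand (position of the C); the paired
#' minus-strand G is the same CpG unit (symmetric methylation), matching
#' single-count CpG bookkeeping.
#'
#' @param genome An `rrbs_genome`, `DNAStringSet`, character vector or FASTA path.
#' @return data.frame `chrom`, `pos` (0-based plus-strand C position).
#' @export
cpg_sites <- function(genome) {
  genome <- as_genome(genome)
  out <- lapply(names(genome$seq), function(ch) {
    m <- Biostrings::matchPattern("CG", genome$seq[[ch]], fixed = TRUE)
    data.frame(chrom = rep(ch, length(m)), pos = Biostrings::start(m) - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a genome as FASTA (uppercase, 80-column wrapped)
#' @param genome An `rrbs_genome` (or coercible).
#' @param path Output file path.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome$seq, filepath = path, width = 80L)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file path.
#' @return An `rrbs_genome` (with no truth islands).
#' @export
read_genome_fasta <- function(path) {
  seq <- Biostrings::readDNAStringSet(path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  new_rrbs_genome(seq, islands = empty_intervals(), spec = NULL)
}
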