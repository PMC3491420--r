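# All genomic coordinates in this package are 0-based half-open [start, end),
# as in BED. Conversions to the 1-based closed convention happen only at the
# boundaries with Biostrings/IRanges and SAM output.

clamp01 <- function(x) pmin(1, pmax(0, x))

# Evaluate `code` under a fixed RNG seed when one is supplied, leaving the
# caller's RNG stream untouched; otherwise use the ambient stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Coerce the various genome representations (rrbs_genome, DNAStringSet, named
# character vector, FASTA path) to an rrbs_genome.
as_genome <- function(genome) {
  if (inherits(genome, "rrbs_genome")) return(genome)
  if (is(genome, "DNAStringSet")) {
    return(new_rrbs_genome(genome, islands = empty_intervals(), spec = NULL))
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(read_genome_fasta(genome))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
    return(new_rrbs_genome(Biostrings::DNAStringSet(toupper(genome)),
                           islands = empty_intervals(), spec = NULL))
  }
  stop("cannot interpret `genome`; supply an rrbs_genome, DNAStringSet, ",
       "named character vector or FASTA path", call. = FALSE)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

chrom_lengths_of <- function(genome) {
  genome <- as_genome(genome)
  setNames(Biostrings::width(genome$seq), names(genome$seq))
}
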