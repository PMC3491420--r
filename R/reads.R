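# Sequenced-molecule model
# ------------------------
# A fragment [s, e) with an MspI cut at its right end is sequenced as the
# molecule [s, e + 2): end repair fills in the 5' CG overhang of the
# downstream cut, so the duplex extends two bases past the fragment end. A
# read takes `read_length` bases inward from one of the two cut ends:
#   5p end -> plus strand, starting at s;
#   3p end -> minus strand, starting at the filled-in G opposite position
#             e + 1, i.e. the reverse complement of [s, e + 2) read 5'->3'.
# Both reads therefore begin [C/T]GG on internal fragments, and the first
# base reports the methylation state of the MspI-site CpG (plus-strand C at
# s for 5p reads, at e for 3p reads). Only fragments with cuts at BOTH ends
# enter a library: adapter ligation requires two repaired MspI ends.

# Per-chromosome caches used by the profile builder.
chrom_cache <- function(genome) {
  genome <- as_genome(genome)
  lens <- chrom_lengths_of(genome)
  out <- lapply(names(lens), function(ch) {
    str <- as.character(genome$seq[[ch]])
    cgpos <- Biostrings::start(
      Biostrings::matchPattern("CG", genome$seq[[ch]], fixed = TRUE)) - 1L
    flag <- logical(lens[[ch]])
    flag[cgpos + 1L] <- TRUE
    list(str = str, cg = flag, len = lens[[ch]])
  })
  names(out) <- names(lens)
  out
}

# For each (fragment, end) build the read-length prefix of the sequenced
# molecule on the read strand, with the local offsets of CpG cytosines (and
# their plus-strand CpG keys) and of non-CpG cytosines.
end_profiles <- function(genome, fragments, read_length = 29L,
                         frag_idx = seq_len(nrow(fragments)), cache = NULL) {
  read_length <- as.integer(read_length)
  if (is.null(cache)) cache <- chrom_cache(genome)
  rows <- vector("list", 2L * length(frag_idx))
  r <- 0L
  for (fi in frag_idx) {
    ch <- fragments$chrom[fi]
    cc <- cache[[ch]]
    s <- fragments$start[fi]
    e <- fragments$end[fi]
    mol_end <- if (fragments$right_cut[fi]) min(e + 2L, cc$len) else e
    mol_len <- mol_end - s
    plen <- min(read_length, mol_len)
    for (end in c("5p", "3p")) {
      if (end == "5p") {
        prefix <- substr(cc$str, s + 1L, s + plen)
        v <- strsplit(prefix, "", fixed = TRUE)[[1]]
        gpos <- s + seq_len(plen) - 1L             # genomic pos of each local
        is_cpg <- cc$cg[gpos + 1L]
        cpg_off <- which(is_cpg) - 1L
        cpg_key <- s + cpg_off
        c_off <- which(v == "C" & !is_cpg) - 1L
        strand <- "+"
      } else {
        tailseq <- substr(cc$str, mol_end - plen + 1L, mol_end)
        prefix <- revcomp_chr(tailseq)
        v <- strsplit(prefix, "", fixed = TRUE)[[1]]
        # local j pairs plus-strand position p_g = mol_end - 1 - j; a minus
        # strand C there is a CpG C iff the plus strand has CG at p_g - 1
        p <- mol_end - 2L - (seq_len(plen) - 1L)
        is_cpg <- v == "C" & p >= 0L & ifelse(p >= 0L, cc$cg[pmax(p, 0L) + 1L], FALSE)
        cpg_off <- which(is_cpg) - 1L
        cpg_key <- mol_end - 2L - cpg_off
        c_off <- which(v == "C" & !is_cpg) - 1L
        strand <- "-"
      }
      r <- r + 1L
      rows[[r]] <- list(frag = fi, chrom = ch, frag_start = s, frag_end = e,
                        frag_length = fragments$length[fi], end = end,
                        strand = strand, mol_start = s, mol_end = mol_end,
                        plen = plen, seq = prefix, cpg_off = cpg_off,
                        cpg_key = cpg_key, c_off = c_off)
    }
  }
  df <- data.frame(
    frag = vapply(rows, `[[`, integer(1), "frag"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    frag_start = vapply(rows, `[[`, integer(1), "frag_start"),
    frag_end = vapply(rows, `[[`, integer(1), "frag_end"),
    frag_length = vapply(rows, `[[`, integer(1), "frag_length"),
    end = vapply(rows, `[[`, character(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    mol_start = vapply(rows, `[[`, integer(1), "mol_start"),
    mol_end = vapply(rows, `[[`, integer(1), "mol_end"),
    plen = vapply(rows, `[[`, integer(1), "plen"),
    seq = vapply(rows, `[[`, character(1), "seq"),
    stringsAsFactors = FALSE)
  df$cpg_off <- lapply(rows, `[[`, "cpg_off")
  df$cpg_key <- lapply(rows, `[[`, "cpg_key")
  df$c_off <- lapply(rows, `[[`, "c_off")
  df
}

# Vectorized conversion of m reads sharing one (fragment, end) profile.
# `probs` are truth methylation probabilities per profile CpG. Returns the
# converted read sequences plus the drawn truth states ("M"/"U", comma-joined).
convert_group <- function(prefix, cpg_off, c_off, probs, m, model) {
  chars <- strsplit(prefix, "", fixed = TRUE)[[1]]
  plen <- length(chars)
  M <- matrix(chars, nrow = m, ncol = plen, byrow = TRUE)
  k <- length(cpg_off)
  states_str <- rep("", m)
  if (k > 0L) {
    st <- matrix(runif(m * k) < rep(probs, each = m), m, k)
    meth_reads_t <- matrix(runif(m * k) < model$failure_rate, m, k)
    unmeth_reads_t <- matrix(runif(m * k) < model$conversion_rate, m, k)
    to_t <- ifelse(st, meth_reads_t, unmeth_reads_t)
    M[, cpg_off + 1L] <- ifelse(to_t, "T", "C")
    stchar <- ifelse(st, "M", "U")
    states_str <- do.call(paste, c(as.data.frame(stchar, stringsAsFactors = FALSE),
                                   sep = ","))
  }
  j <- length(c_off)
  if (j > 0L) {
    conv <- matrix(runif(m * j) < model$conversion_rate, m, j)
    M[, c_off + 1L] <- ifelse(conv, "T", "C")
  }
  if (model$sequencing_error_rate > 0) {
    idx <- which(runif(m * plen) < model$sequencing_error_rate)
    if (length(idx)) {
      alt <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
      bad <- alt == M[idx]
      while (any(bad)) {
        alt[bad] <- sample(c("A", "C", "G", "T"), sum(bad), replace = TRUE)
        bad <- alt == M[idx]
      }
      M[idx] <- alt
    }
  }
  seqs <- do.call(paste0, as.data.frame(M, stringsAsFactors = FALSE))
  list(seq = seqs, states = states_str)
}

# chrom -> numeric vector of truth probabilities indexed by 0-based position
methylome_lookup <- function(methylome, chrom_lengths) {
  out <- lapply(names(chrom_lengths), function(ch) {
    v <- rep(NA_real_, chrom_lengths[[ch]])
    sel <- methylome$chrom == ch
    if (any(sel)) v[methylome$pos[sel] + 1L] <- methylome$truth_probability[sel]
    v
  })
  names(out) <- names(chrom_lengths)
  out
}

#' Simulate a barcoded bisulfite sequencing library
#'
#' Draws reads from the size-selected digest: each read picks a retained
#' fragment (probability proportional to [retention_probability()]), one of
#' its two MspI ends (and hence strand) uniformly, takes `read_length` bases
#' inward (truncated at the molecule end for short fragments), draws per-CpG
#' truth methylation states from the methylome, bisulfite-converts the read,
#' and attaches the sample barcode. Only fragments with MspI cuts at both
#' ends are sequenced (adapter ligation requires two repaired ends), which is
#' why every simulated read begins `[C/T]GG`. With `chimera_rate > 0`,
#' template-switch products splice another pooled molecule's post-conversion
#' suffix at a uniform internal position, keeping the first molecule's
#' barcode.
#'
#' @param fragments An `rrbs_fragments` data.frame from [digest_genome()].
#' @param methylome Truth methylome data.frame (`chrom`, `pos`,
#'   `truth_probability`), or a named list of such tables keyed by sample name
#'   for per-sample methylomes.
#' @param design A [study_design()].
#' @param genome The genome the fragments came from.
#' @param selection A [size_selection_model()].
#' @param conversion A [conversion_model()].
#' @param chimera A [chimera_model()].
#' @param read_length Read length in bases (default 29).
#' @param seed Optional seed (defaults to `design$seed`).
#' @return A data.frame of class `rrbs_reads`: `read_id`, `sample`, `barcode`,
#'   `sequence`, truth columns (`chrom`, `fragment_start`, `fragment_end`,
#'   `end_used`, `strand`, `cpg_pos`, `truth_states`, `is_chimera`).
#' @export
generate_reads <- function(fragments, methylome, design, genome,
                           selection = size_selection_model(),
                           conversion = conversion_model(),
                           chimera = chimera_model(), read_length = 29L,
                           seed = design$seed) {
  stopifnot(inherits(design, "study_design"),
            inherits(selection, "size_selection_model"),
            inherits(conversion, "conversion_model"),
            inherits(chimera, "chimera_model"), read_length >= 4L)
  genome <- as_genome(genome)
  lens <- chrom_lengths_of(genome)
  per_sample_meth <- !is.data.frame(methylome)
  if (per_sample_meth) {
    if (!all(design$samples %in% names(methylome))) {
      stop("per-sample methylome list must be keyed by sample names (",
           paste(design$samples, collapse = ", "), ")", call. = FALSE)
    }
    lookups <- lapply(methylome[design$samples], methylome_lookup, chrom_lengths = lens)
  } else {
    lk <- methylome_lookup(methylome, lens)
    lookups <- setNames(rep(list(lk), design$n_samples), design$samples)
  }

  eligible <- which(!fragments$is_terminal)
  ret <- retention_probability(pmax(fragments$length, 1L), selection)
  ret[setdiff(seq_len(nrow(fragments)), eligible)] <- 0
  keep <- which(ret > 0)
  if (!length(keep)) {
    stop("empty library: no fragment is retained under the size-selection model",
         call. = FALSE)
  }

  with_seed_if(seed, {
    cache <- chrom_cache(genome)
    prof <- end_profiles(genome, fragments, read_length, frag_idx = keep,
                         cache = cache)
    prof_id <- paste(prof$frag, prof$end)
    out <- vector("list", design$n_samples)
    for (si in seq_len(design$n_samples)) {
      smp <- design$samples[si]
      n <- design$reads_per_sample
      frag_draw <- keep[sample.int(length(keep), n, replace = TRUE,
                                   prob = ret[keep])]
      end_draw <- c("5p", "3p")[sample.int(2L, n, replace = TRUE)]
      grp <- paste(frag_draw, end_draw)
      ord <- order(match(grp, prof_id))
      frag_draw <- frag_draw[ord]
      end_draw <- end_draw[ord]
      grp <- grp[ord]
      lk <- lookups[[smp]]
      seqs <- character(n)
      states <- character(n)
      runs <- rle(grp)
      at <- 1L
      for (g in seq_along(runs$values)) {
        m <- runs$lengths[g]
        p <- match(runs$values[g], prof_id)
        probs <- lk[[prof$chrom[p]]][prof$cpg_key[[p]] + 1L]
        probs[is.na(probs)] <- 0
        cg <- convert_group(prof$seq[p], prof$cpg_off[[p]], prof$c_off[[p]],
                            probs, m, conversion)
        seqs[at:(at + m - 1L)] <- cg$seq
        states[at:(at + m - 1L)] <- cg$states
        at <- at + m
      }
      pidx <- match(grp, prof_id)
      out[[si]] <- data.frame(
        read_id = sprintf("%s_%06d", smp, seq_len(n)),
        sample = smp, barcode = design$barcodes[si], sequence = seqs,
        chrom = prof$chrom[pidx], fragment_start = prof$frag_start[pidx],
        fragment_end = prof$frag_end[pidx],
        fragment_length = prof$frag_length[pidx],
        end_used = end_draw, strand = prof$strand[pidx],
        cpg_pos = vapply(prof$cpg_key[pidx], paste, character(1), collapse = ","),
        truth_states = states, is_chimera = FALSE,
        stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, out)
    rownames(reads) <- NULL
    if (chimera$chimera_rate > 0) {
      reads <- inject_chimeras(reads, chimera$chimera_rate)
    }
    attr(reads, "read_length") <- as.integer(read_length)
    attr(reads, "conversion") <- conversion
    attr(reads, "selection") <- selection
    class(reads) <- c("rrbs_reads", "data.frame")
    reads
  })
}

# PCR template switching acts on the pooled, already-converted library: a
# chimeric read keeps its own prefix (and barcode) up to a uniform internal
# switch point and continues with another pooled molecule's suffix.
inject_chimeras <- function(reads, rate) {
  n <- nrow(reads)
  len <- nchar(reads$sequence)
  flag <- which(runif(n) < rate & len >= 2L)
  if (!length(flag)) return(reads)
  partner <- sample.int(n, length(flag), replace = TRUE)
  for (it in 1:10) {
    bad <- nchar(reads$sequence[partner]) < len[flag] | partner == flag
    if (!any(bad)) break
    partner[bad] <- sample.int(n, sum(bad), replace = TRUE)
  }
  ok <- nchar(reads$sequence[partner]) >= len[flag] & partner != flag
  flag <- flag[ok]
  partner <- partner[ok]
  if (!length(flag)) return(reads)
  sp <- 1L + floor(runif(length(flag)) * (len[flag] - 1L))
  reads$sequence[flag] <- paste0(
    substr(reads$sequence[flag], 1L, sp),
    substr(reads$sequence[partner], sp + 1L, len[flag]))
  reads$is_chimera[flag] <- TRUE
  reads
}

#' Write simulated reads as FASTQ (constant quality "I")
#'
#' Read names encode sample and serial number plus the sample barcode, e.g.
#' `S01_000001:ACGTAC`.
#' @param reads An `rrbs_reads` data.frame.
#' @param path Output FASTQ path.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- paste0(reads$read_id, ":", reads$barcode)
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Write the truth sidecar TSV for a simulated library
#' @param reads An `rrbs_reads` data.frame.
#' @param path Output TSV path.
#' @export
write_truth_tsv <- function(reads, path) {
  cols <- c("read_id", "sample", "chrom", "fragment_start", "fragment_end",
            "end_used", "strand", "cpg_pos", "truth_states", "is_chimera")
  data.table::fwrite(as.data.frame(reads)[, cols], path, sep = "\t")
  invisible(path)
}
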