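#' Bisulfite conversion and chimera models
#'
#' Bisulfite chemistry converts unmethylated cytosine to uracil (read as T)
#' while methylated cytosine is protected; `conversion_rate` is the
#' probability that an unmethylated C reads T, `failure_rate` the probability
#' that a *methylated* C nonetheless reads T, and `sequencing_error_rate` a
#' uniform per-base substitution probability applied after conversion.
#'
#' @param conversion_rate Probability an unmethylated C reads T (default 0.99).
#' @param failure_rate Probability a methylated C reads T (default 0).
#' @param sequencing_error_rate Per-base substitution probability (default 0).
#' @export
conversion_model <- function(conversion_rate = 0.99, failure_rate = 0,
                             sequencing_error_rate = 0) {
  assert_prob(conversion_rate, "conversion_rate")
  assert_prob(failure_rate, "failure_rate")
  assert_prob(sequencing_error_rate, "sequencing_error_rate")
  structure(list(conversion_rate = conversion_rate, failure_rate = failure_rate,
                 sequencing_error_rate = sequencing_error_rate),
            class = "conversion_model")
}

#' @rdname conversion_model
#' @param chimera_rate Probability that a read is a PCR template-switch
#'   product splicing a second molecule's (post-conversion) suffix at a
#'   uniform internal position, while keeping the first molecule's barcode.
#' @export
chimera_model <- function(chimera_rate = 0) {
  assert_prob(chimera_rate, "chimera_rate")
  structure(list(chimera_rate = chimera_rate), class = "chimera_model")
}

#' Bisulfite-convert one fragment sequence
#'
#' Applies the conversion model to the chosen strand of a fragment: CpG
#' cytosines read T iff (unmethylated and converted) or (methylated and
#' conversion failed); every other cytosine reads T with probability
#' `conversion_rate`. For `strand = "-"` the reverse complement is converted
#' and returned 5'->3'; the cytosines examined are then the minus-strand
#' partners of the given CpGs.
#'
#' @param sequence Plus-strand fragment sequence (single string, ACGT).
#' @param strand `"+"` or `"-"`.
#' @param cpg_positions 0-based offsets of CpG cytosines on the plus strand of
#'   `sequence` (i.e. positions where `CG` begins).
#' @param cpg_states Logical (or 0/1) methylation state per CpG in
#'   `cpg_positions`, for the chosen strand.
#' @param model A [conversion_model()].
#' @param seed Optional seed.
#' @return The converted sequence, 5'->3' on the chosen strand.
#' @examples
#' # CpG at offset 1 methylated, non-CpG C at offset 4 converts:
#' bisulfite_convert("ACGTCT", "+", 1, TRUE,
#'                   conversion_model(conversion_rate = 1))  # "ACGTTT"
#' @export
bisulfite_convert <- function(sequence, strand = c("+", "-"), cpg_positions,
                              cpg_states, model = conversion_model(),
                              seed = NULL) {
  strand <- match.arg(strand)
  stopifnot(length(sequence) == 1L, inherits(model, "conversion_model"),
            length(cpg_positions) == length(cpg_states))
  n <- nchar(sequence)
  if (strand == "+") {
    local_seq <- sequence
    cpg_local <- as.integer(cpg_positions)
  } else {
    local_seq <- revcomp_chr(sequence)
    # minus-strand C of the CpG sits opposite the plus-strand G at pos + 1
    cpg_local <- n - as.integer(cpg_positions) - 2L
  }
  keep <- cpg_local >= 0L & cpg_local < n
  cpg_local <- cpg_local[keep]
  states <- as.logical(cpg_states)[keep]
  with_seed_if(seed, {
    x <- strsplit(local_seq, "", fixed = TRUE)[[1]]
    is_c <- x == "C"
    is_cpg <- rep(FALSE, n)
    is_cpg[cpg_local + 1L] <- TRUE
    # non-CpG cytosines on this strand
    i <- which(is_c & !is_cpg)
    if (length(i)) {
      conv <- runif(length(i)) < model$conversion_rate
      x[i[conv]] <- "T"
    }
    if (length(cpg_local)) {
      j <- cpg_local + 1L
      to_t <- ifelse(states, runif(length(j)) < model$failure_rate,
                     runif(length(j)) < model$conversion_rate)
      x[j] <- ifelse(to_t, "T", "C")
    }
    if (model$sequencing_error_rate > 0) {
      x <- apply_sequencing_errors(x, model$sequencing_error_rate)
    }
    paste(x, collapse = "")
  })
}

# Uniform substitutions: each flagged base is replaced by one of the three
# other bases uniformly.
apply_sequencing_errors <- function(x, rate) {
  idx <- which(runif(length(x)) < rate)
  if (!length(idx)) return(x)
  alt <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
  bad <- alt == x[idx]
  while (any(bad)) {
    alt[bad] <- sample(c("A", "C", "G", "T"), sum(bad), replace = TRUE)
    bad <- alt == x[idx]
  }
  x[idx] <- alt
  x
}
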