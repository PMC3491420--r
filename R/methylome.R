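#' Specification of a bimodal truth methylome
#'
#' Assigns every genomic CpG a truth methylation probability: CpGs inside
#' planted islands are drawn around `island_meth_level`, all others around
#' `background_meth_level`. The defaults give the canonical bimodal somatic
#' pattern — hypomethylated islands against a hypermethylated background.
#'
#' @param island_meth_level Mean methylation probability of island CpGs.
#' @param background_meth_level Mean methylation probability elsewhere.
#' @param per_cpg_noise_sd Gaussian noise SD on the probability scale; values
#'   are clamped to `[0, 1]`.
#' @param seed Optional integer seed.
#' @export
methylome_spec <- function(island_meth_level = 0.1, background_meth_level = 0.9,
                           per_cpg_noise_sd = 0.05, seed = NULL) {
  assert_prob(island_meth_level, "island_meth_level")
  assert_prob(background_meth_level, "background_meth_level")
  stopifnot(is.numeric(per_cpg_noise_sd), per_cpg_noise_sd >= 0)
  structure(list(island_meth_level = island_meth_level,
                 background_meth_level = background_meth_level,
                 per_cpg_noise_sd = per_cpg_noise_sd, seed = seed),
            class = "methylome_spec")
}

#' Generate per-CpG truth methylation probabilities
#'
#' @param genome An `rrbs_genome`; its recorded truth islands decide which CpGs
#'   take the island level. A genome without islands gets the background level
#'   everywhere.
#' @param spec A [methylome_spec()].
#' @return data.frame `chrom`, `pos` (0-based C position), `truth_probability`;
#'   one row per genomic CpG (possibly zero rows).
#' @export
generate_methylome <- function(genome, spec = methylome_spec()) {
  genome <- as_genome(genome)
  stopifnot(inherits(spec, "methylome_spec"))
  cpgs <- cpg_sites(genome)
  if (is.null(cpgs) || nrow(cpgs) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      truth_probability = numeric(), stringsAsFactors = FALSE))
  }
  in_island <- rep(FALSE, nrow(cpgs))
  isl <- genome$islands
  if (!is.null(isl) && nrow(isl)) {
    for (ch in unique(isl$chrom)) {
      sel <- cpgs$chrom == ch
      if (!any(sel)) next
      ir_cpg <- IRanges::IRanges(start = cpgs$pos[sel] + 1L, width = 1L)
      ir_isl <- IRanges::IRanges(start = isl$start[isl$chrom == ch] + 1L,
                                 end = isl$end[isl$chrom == ch])
      in_island[sel] <- IRanges::overlapsAny(ir_cpg, ir_isl)
    }
  }
  with_seed_if(spec$seed, {
    mu <- ifelse(in_island, spec$island_meth_level, spec$background_meth_level)
    p <- if (spec$per_cpg_noise_sd > 0) {
      clamp01(mu + rnorm(length(mu), 0, spec$per_cpg_noise_sd))
    } else mu
    data.frame(chrom = cpgs$chrom, pos = cpgs$pos, truth_probability = p,
               stringsAsFactors = FALSE)
  })
}

#' Write / read a truth methylome as TSV (chrom, pos, truth_probability)
#' @param methylome data.frame from [generate_methylome()].
#' @param path File path.
#' @export
write_methylome_tsv <- function(methylome, path) {
  data.table::fwrite(methylome, path, sep = "\t")
  invisible(path)
}

#' @rdname write_methylome_tsv
#' @export
read_methylome_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
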