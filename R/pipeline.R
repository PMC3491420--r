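#' Pipeline configuration
#'
#' Bundles every stage's parameters into one reproducible configuration.
#' `seed` is mandatory: a pipeline run is a pure function of its config.
#'
#' @param genome A [genome_spec()] (or an `rrbs_genome` to reuse).
#' @param methylome A [methylome_spec()].
#' @param design A [study_design()].
#' @param selection A [size_selection_model()].
#' @param conversion A [conversion_model()].
#' @param chimera A [chimera_model()].
#' @param read_length Read length (default 29).
#' @param max_target_length Alignment-target fragment cap (default 300).
#' @param max_mismatches Mapper mismatch budget (default 2).
#' @param coverage_thresholds Depth thresholds (default 1, 5, 10).
#' @param hq_min_reads High-quality sample cutoff on total reads (default 0:
#'   desk-scale libraries are far below the 5e6 production cutoff).
#' @param islands An [island_criteria()].
#' @param tile_size Genome tile size (default 5000).
#' @param shore_width Shore width (default 2000).
#' @param promoter_up,promoter_down Promoter window (defaults 1000/1000).
#' @param min_sample_fraction Feature-scoring sample fraction (default 0.8).
#' @param tss Optional TSS data.frame for promoter derivation.
#' @param enhancers Optional enhancer feature data.frame (user BED).
#' @param seed Integer seed (required).
#' @param out_dir Optional directory for the report TSV bundle.
#' @export
pipeline_config <- function(genome = genome_spec(),
                            methylome = methylome_spec(),
                            design = study_design(),
                            selection = size_selection_model(),
                            conversion = conversion_model(),
                            chimera = chimera_model(), read_length = 29L,
                            max_target_length = 300L, max_mismatches = 2L,
                            coverage_thresholds = c(1L, 5L, 10L),
                            hq_min_reads = 0, islands = island_criteria(),
                            tile_size = 5000L, shore_width = 2000L,
                            promoter_up = 1000L, promoter_down = 1000L,
                            min_sample_fraction = 0.8, tss = NULL,
                            enhancers = NULL, seed, out_dir = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory: a pipeline run must be reproducible from its config",
         call. = FALSE)
  }
  structure(list(genome = genome, methylome = methylome, design = design,
                 selection = selection, conversion = conversion,
                 chimera = chimera, read_length = as.integer(read_length),
                 max_target_length = as.integer(max_target_length),
                 max_mismatches = as.integer(max_mismatches),
                 coverage_thresholds = as.integer(coverage_thresholds),
                 hq_min_reads = hq_min_reads, islands = islands,
                 tile_size = as.integer(tile_size),
                 shore_width = as.integer(shore_width),
                 promoter_up = as.integer(promoter_up),
                 promoter_down = as.integer(promoter_down),
                 min_sample_fraction = min_sample_fraction, tss = tss,
                 enhancers = enhancers, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage_msg <- function(...) message("[mrrbsim] ", ...)

#' Run the full simulation-and-analytics pipeline
#'
#' simulate -> digest -> map -> call -> coverage / feature / (optional)
#' chimera analytics. Stages log input/output record counts; the returned
#' bundle contains every intermediate object, and a TSV report bundle is
#' written when `out_dir` is set. Two runs from the same config are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return A list of class `rrbs_report`: `genome`, `methylome`, `fragments`,
#'   `reads`, `target`, `alignments`, `calls`, `conversion_estimates`,
#'   `coverage_summary` (per-sample totals, informative reads, conversion,
#'   CpG counts at each threshold), `fragment_profile`, `features`,
#'   `feature_scores`, `read_classes`, `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- if (quiet) function(...) invisible() else stage_msg
  withr::with_seed(config$seed, {
    genome <- if (inherits(config$genome, "rrbs_genome")) config$genome else
      generate_genome(config$genome)
    say("genome: ", length(genome$seq), " chromosome(s), ",
        sum(Biostrings::width(genome$seq)), " bp")
    methylome <- generate_methylome(genome, config$methylome)
    say("methylome: ", nrow(methylome), " CpGs")
    fragments <- digest_genome(genome)
    say("digest: ", nrow(fragments), " fragments (",
        sum(fragments$length <= config$max_target_length), " <= ",
        config$max_target_length, " bp)")
    reads <- generate_reads(fragments, methylome, config$design, genome,
                            config$selection, config$conversion,
                            config$chimera, config$read_length)
    say("simulate: ", nrow(reads), " reads / ", config$design$n_samples,
        " samples")
    target <- build_alignment_target(fragments, genome, config$read_length,
                                     config$max_target_length)
    alignments <- map_reads(reads, target, config$max_mismatches)
    say("map: ", sum(alignments$mapped), " mapped, ",
        sum(alignments$informative), " informative of ", nrow(alignments))
    calls <- call_methylation(alignments, target)
    say("call: ", nrow(calls), " sample x CpG records")
    conv <- estimate_conversion(alignments, target)

    cov <- summarize_coverage(calls, config$coverage_thresholds,
                              samples = config$design$samples)
    acc <- data.frame(sample = config$design$samples,
                      total_reads = vapply(config$design$samples, function(s)
                        sum(reads$sample == s), integer(1)),
                      informative_reads = vapply(config$design$samples,
                        function(s) sum(alignments$informative &
                                          alignments$sample == s), integer(1)),
                      stringsAsFactors = FALSE)
    summary_tab <- merge(merge(acc, conv[, c("sample", "estimate")],
                               by = "sample"), cov, by = "sample")
    names(summary_tab)[names(summary_tab) == "estimate"] <- "conversion_rate"
    summary_tab <- summary_tab[order(summary_tab$sample), , drop = FALSE]
    rownames(summary_tab) <- NULL

    profile <- fragment_profile(alignments, fragments)

    islands <- find_cpg_islands(genome, config$islands)
    shores <- derive_shores(islands, config$shore_width)
    tiles <- tile_genome(genome, config$tile_size)
    features <- rbind(islands, shores, tiles)
    if (!is.null(config$tss)) {
      features <- rbind(features,
                        derive_promoters(config$tss, config$promoter_up,
                                         config$promoter_down,
                                         chrom_lengths_of(genome)))
    }
    if (!is.null(config$enhancers)) {
      enh <- config$enhancers
      enh$label <- "enhancer"
      features <- rbind(features, enh[, c("chrom", "start", "end", "label")])
    }
    say("features: ", nrow(islands), " islands, ", nrow(shores), " shores, ",
        nrow(tiles), " tiles")
    scores <- do.call(rbind, lapply(config$coverage_thresholds, function(t) {
      score_feature_cpgs(calls, features, min_coverage = t,
                         min_sample_fraction = config$min_sample_fraction,
                         n_samples = config$design$n_samples)
    }))
    read_classes <- classify_reads(observe_read_states(reads, genome,
                                                       config$read_length))
    bundle <- structure(list(genome = genome, methylome = methylome,
                             fragments = fragments, reads = reads,
                             target = target, alignments = alignments,
                             calls = calls, conversion_estimates = conv,
                             coverage_summary = summary_tab,
                             fragment_profile = profile,
                             features = features, feature_scores = scores,
                             read_classes = read_classes, config = config),
                        class = "rrbs_report")
    if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
    bundle
  })
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) {
    data.table::fwrite(as.data.frame(df), file.path(out_dir, f), sep = "\t")
  }
  write_genome_fasta(bundle$genome, file.path(out_dir, "genome.fa"))
  write_methylome_tsv(bundle$methylome, file.path(out_dir, "truth_methylome.tsv"))
  write_fragments_bed(bundle$fragments, file.path(out_dir, "fragments.bed"))
  write_reads_fastq(bundle$reads, file.path(out_dir, "reads.fastq"))
  write_truth_tsv(bundle$reads, file.path(out_dir, "reads_truth.tsv"))
  w(bundle$coverage_summary, "coverage_summary.tsv")
  w(bundle$fragment_profile, "fragment_profile.tsv")
  w(bundle$conversion_estimates, "conversion_estimates.tsv")
  w(bundle$feature_scores, "feature_scores.tsv")
  write_features_bed(bundle$features, file.path(out_dir, "features.bed"))
  calls_out <- as.data.frame(bundle$calls)
  w(calls_out, "cpg_calls.tsv")
  cls <- as.data.frame(table(sample = bundle$reads$sample,
                             class = bundle$read_classes))
  w(cls, "read_classes.tsv")
  invisible(out_dir)
}

#' Compare two protocols (e.g. gel-based RRBS vs gel-free mRRBS)
#'
#' Runs two pipeline configurations that differ in their selection model (and
#' possibly conversion/chimera settings) over matched designs, and reports a
#' side-by-side table of per-protocol medians of the per-sample summary
#' columns.
#'
#' @param config_a,config_b Two [pipeline_config()]s with identical sample
#'   counts and read budgets.
#' @param labels Protocol labels for the output rows.
#' @param quiet Suppress stage messages.
#' @return list with `table` (one row per protocol: median total reads,
#'   informative reads, conversion, CpG counts per threshold) and the two
#'   report bundles (`report_a`, `report_b`).
#' @export
compare_protocols <- function(config_a, config_b,
                              labels = c("protocol_a", "protocol_b"),
                              quiet = FALSE) {
  if (config_a$design$n_samples != config_b$design$n_samples ||
      config_a$design$reads_per_sample != config_b$design$reads_per_sample) {
    stop("designs must match: same sample count and reads per sample",
         call. = FALSE)
  }
  rep_a <- run_pipeline(config_a, quiet = quiet)
  rep_b <- run_pipeline(config_b, quiet = quiet)
  med_row <- function(rep, lab) {
    s <- rep$coverage_summary
    num <- s[, setdiff(names(s), "sample"), drop = FALSE]
    out <- data.frame(protocol = lab, stringsAsFactors = FALSE)
    for (cn in names(num)) out[[cn]] <- median(num[[cn]], na.rm = TRUE)
    out
  }
  tab <- rbind(med_row(rep_a, labels[1]), med_row(rep_b, labels[2]))
  list(table = tab, report_a = rep_a, report_b = rep_b)
}

#' @export
print.rrbs_report <- function(x, ...) {
  cat("rrbs_report (seed ", x$config$seed, ")\n", sep = "")
  cat("coverage summary:\n")
  print(x$coverage_summary, digits = 4)
  invisible(x)
}
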