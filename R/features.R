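# Feature tables are data.frames with columns chrom, start, end (0-based
# half-open) and label; chromosome lengths travel in attr "chrom_lengths".

new_features <- function(chrom, start, end, label, chrom_lengths = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), label = as.character(label),
                   stringsAsFactors = FALSE)
  attr(df, "chrom_lengths") <- chrom_lengths
  df
}

#' CpG island criteria
#'
#' An island is a maximal interval satisfying, jointly: CpG observed/expected
#' ratio `(N_CpG * L)/(N_C * N_G) >= min_oe_ratio`, GC content
#' `(N_C + N_G)/L >= min_gc`, and length `L >= min_length`. A window with
#' `N_C = 0` or `N_G = 0` has undefined O/E and fails.
#'
#' @param min_oe_ratio Minimum CpG observed/expected ratio (default 0.6).
#' @param min_gc Minimum GC content (default 0.5).
#' @param min_length Minimum island length in bp (default 700).
#' @export
island_criteria <- function(min_oe_ratio = 0.6, min_gc = 0.5,
                            min_length = 700L) {
  stopifnot(min_oe_ratio > 0, min_gc > 0, min_length >= 2L)
  structure(list(min_oe_ratio = min_oe_ratio, min_gc = min_gc,
                 min_length = as.integer(min_length)),
            class = "island_criteria")
}

# cluster candidate intervals (sorted by start) into overlap-or-abut
# components and keep the longest interval per component (leftmost on ties)
pick_component_maxima <- function(start, end) {
  if (!length(start)) return(data.frame(start = integer(), end = integer()))
  comp <- integer(length(start))
  cur <- 1L
  max_end <- end[1]
  comp[1] <- 1L
  for (i in seq_along(start)[-1]) {
    if (start[i] > max_end) {
      cur <- cur + 1L
      max_end <- end[i]
    } else {
      max_end <- max(max_end, end[i])
    }
    comp[i] <- cur
  }
  len <- end - start
  out_s <- integer(cur)
  out_e <- integer(cur)
  for (k in seq_len(cur)) {
    sel <- which(comp == k)
    best <- sel[which.max(len[sel])]  # which.max takes the leftmost on ties
    out_s[k] <- start[best]
    out_e[k] <- end[best]
  }
  data.frame(start = out_s, end = out_e)
}

#' Detect CpG islands
#'
#' Exhaustively scans each chromosome for intervals satisfying the island
#' criteria (every candidate start is paired with its longest qualifying end,
#' up to `max_length`), clusters overlapping or adjacent qualifying intervals
#' into components, and reports one maximal qualifying interval per component
#' (the longest; leftmost on ties). The result is a deterministic set of
#' disjoint islands.
#'
#' @param genome An `rrbs_genome`, `DNAStringSet`, character vector or FASTA path.
#' @param criteria An [island_criteria()].
#' @param max_length Longest island interval considered (default 10000 bp);
#'   bounds the quadratic scan.
#' @return Feature data.frame (`chrom`, `start`, `end`, `label =
#'   "cpg_island"`) with `chrom_lengths` attached.
#' @export
find_cpg_islands <- function(genome, criteria = island_criteria(),
                             max_length = 10000L) {
  genome <- as_genome(genome)
  stopifnot(inherits(criteria, "island_criteria"),
            max_length >= criteria$min_length)
  lens <- chrom_lengths_of(genome)
  out <- lapply(names(lens), function(ch) {
    code <- encode_dna(as.character(genome$seq[[ch]]))
    cand <- scan_island_candidates(code, criteria$min_oe_ratio,
                                   criteria$min_gc, criteria$min_length,
                                   as.integer(max_length))
    isl <- pick_component_maxima(cand$start, cand$end)
    if (!nrow(isl)) return(NULL)
    new_features(ch, isl$start, isl$end, "cpg_island")
  })
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else
    new_features(character(), integer(), integer(), character())
  rownames(res) <- NULL
  attr(res, "chrom_lengths") <- lens
  res
}

encode_dna <- function(x) {
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  code <- match(v, c("A", "C", "G", "T")) - 1L
  code[is.na(code)] <- 4L
  code
}

#' Derive CpG island shores
#'
#' Shores are the flanking regions adjacent to each island (2 kb by default),
#' clipped to chromosome bounds, with any overlap with islands removed and
#' overlapping shores merged — so shores never double-count bases and never
#' intersect islands.
#'
#' @param islands Island feature data.frame (from [find_cpg_islands()] or
#'   read from BED); must carry `chrom_lengths` as attribute unless supplied.
#' @param width Shore width in bp (default 2000).
#' @param chrom_lengths Named lengths, if not attached to `islands`.
#' @return Feature data.frame with `label = "cpg_island_shore"`.
#' @export
derive_shores <- function(islands, width = 2000L, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) chrom_lengths <- attr(islands, "chrom_lengths")
  out <- lapply(unique(islands$chrom), function(ch) {
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else NA_integer_
    ir_isl <- IRanges::IRanges(start = isl$start + 1L, end = isl$end)
    fl <- c(IRanges::IRanges(start = isl$start - width + 1L, end = isl$start),
            IRanges::IRanges(start = isl$end + 1L, end = isl$end + width))
    fl <- IRanges::restrict(fl, start = 1L,
                            end = if (is.na(L)) .Machine$integer.max else L)
    sh <- IRanges::setdiff(IRanges::reduce(fl), ir_isl)
    sh <- sh[IRanges::width(sh) > 0L]
    if (!length(sh)) return(NULL)
    new_features(ch, IRanges::start(sh) - 1L, IRanges::end(sh),
                 "cpg_island_shore")
  })
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else
    new_features(character(), integer(), integer(), character())
  rownames(res) <- NULL
  attr(res, "chrom_lengths") <- chrom_lengths
  res
}

#' Derive promoter windows from a TSS table
#'
#' Promoters are the windows from `up` bases upstream to `down` bases
#' downstream of each transcription start site, clipped to chromosome bounds.
#' With the default symmetric 1 kb/1 kb window, orientation is irrelevant;
#' rows with unknown strand are treated as plus-strand with a warning.
#' Duplicate windows are removed.
#'
#' @param tss data.frame with columns `chrom`, `pos` (0-based TSS), `strand`.
#' @param up,down Window extent in bp (defaults 1000/1000).
#' @param chrom_lengths Optional named lengths for right clipping.
#' @return Feature data.frame with `label = "promoter"`.
#' @export
derive_promoters <- function(tss, up = 1000L, down = 1000L,
                             chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "pos") %in% names(tss)))
  strand <- if ("strand" %in% names(tss)) tss$strand else rep("+", nrow(tss))
  unknown <- !strand %in% c("+", "-")
  if (any(unknown)) {
    warning(sum(unknown), " TSS row(s) with unknown strand treated as '+'")
    strand[unknown] <- "+"
  }
  start <- ifelse(strand == "+", tss$pos - up, tss$pos - down)
  end <- ifelse(strand == "+", tss$pos + down, tss$pos + up)
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    end <- pmin(end, as.integer(chrom_lengths[tss$chrom]))
  }
  keep <- !duplicated(paste(tss$chrom, start, end)) & end > start
  res <- new_features(tss$chrom[keep], start[keep], end[keep], "promoter",
                      chrom_lengths)
  rownames(res) <- NULL
  res
}

#' Tile the genome into fixed-size windows
#'
#' Consecutive non-overlapping half-open tiles from position 0; the final
#' partial tile is retained, so tile lengths sum to the chromosome length.
#'
#' @param genome Genome (or named chromosome lengths).
#' @param size Tile size in bp (default 5000).
#' @return Feature data.frame with `label = "tile_5kb"` (label reflects the
#'   actual size, e.g. `tile_2kb` for `size = 2000`).
#' @export
tile_genome <- function(genome, size = 5000L) {
  size <- assert_count(size, "size", min = 1L)
  lens <- if (is.numeric(genome) && !is.null(names(genome))) genome else
    chrom_lengths_of(genome)
  label <- if (size %% 1000L == 0L) sprintf("tile_%dkb", size %/% 1000L) else
    sprintf("tile_%dbp", size)
  out <- lapply(names(lens), function(ch) {
    L <- lens[[ch]]
    starts <- seq.int(0L, L - 1L, by = size)
    new_features(ch, starts, pmin(starts + size, L), label)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "chrom_lengths") <- lens
  res
}

#' Count well-measured CpGs per feature class
#'
#' A CpG qualifies at a coverage level iff it is covered at
#' `>= min_coverage` in at least `min_sample_fraction` of the samples
#' (`count / n_samples >= min_sample_fraction`, so 4 of 5 samples passes at
#' 0.8). Each feature class is scored independently: a qualifying CpG counts
#' once per class whose features contain it (deduplicated within class).
#'
#' @param calls Multi-sample `cpg_calls` data.frame.
#' @param features Feature data.frame (`chrom`, `start`, `end`, `label`).
#' @param min_coverage Depth threshold per sample (default 1).
#' @param min_sample_fraction Fraction of samples required (default 0.8).
#' @param n_samples Number of samples in the study; defaults to the number of
#'   distinct samples present in `calls`.
#' @return data.frame `feature_class`, `min_coverage`, `qualifying_cpg_count`.
#' @export
score_feature_cpgs <- function(calls, features, min_coverage = 1L,
                               min_sample_fraction = 0.8, n_samples = NULL) {
  df <- as.data.frame(calls)
  if (is.null(n_samples)) n_samples <- length(unique(df$sample))
  if (n_samples < 1L) stop("need at least one sample", call. = FALSE)
  dt <- data.table::as.data.table(df)
  coverage <- NULL; n_cov <- NULL
  qual <- dt[, .(n_cov = sum(coverage >= min_coverage)), by = c("chrom", "pos")]
  qual <- qual[n_cov / n_samples >= min_sample_fraction]
  classes <- unique(features$label)
  counts <- vapply(classes, function(cl) {
    fc <- features[features$label == cl, , drop = FALSE]
    total <- 0L
    for (ch in unique(fc$chrom)) {
      q <- qual[qual$chrom == ch]
      if (!nrow(q)) next
      ir_cpg <- IRanges::IRanges(start = q$pos + 1L, width = 1L)
      ir_f <- IRanges::IRanges(start = fc$start[fc$chrom == ch] + 1L,
                               end = fc$end[fc$chrom == ch])
      total <- total + sum(IRanges::overlapsAny(ir_cpg, ir_f))
    }
    total
  }, integer(1))
  data.frame(feature_class = classes, min_coverage = as.integer(min_coverage),
             qualifying_cpg_count = counts, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read / write feature intervals as BED
#'
#' BED is 0-based half-open, matching the package's internal convention.
#' `read_bed` keeps the first three columns (plus name as `label` when
#' `label = NULL` and a name column exists).
#'
#' @param features Feature data.frame.
#' @param path BED file path.
#' @param label Label to assign to intervals read from BED; when `NULL`, the
#'   BED name column (or `"user"`) is used.
#' @export
write_features_bed <- function(features, path) {
  df <- data.frame(chrom = features$chrom, start = features$start,
                   end = features$end,
                   name = if ("label" %in% names(features)) features$label else ".",
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_features_bed
#' @export
read_bed <- function(path, label = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  lab <- if (!is.null(label)) label else {
    nm <- gr$name
    if (is.null(nm) || all(is.na(nm))) "user" else nm
  }
  new_features(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr), lab)
}

#' Read a TSS table (TSV: chrom, pos, strand[, name])
#' @param path TSV path with header.
#' @export
read_tss_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
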