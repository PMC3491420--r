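test_that("island arithmetic on degenerate sequences is exact", {
  # (CG)x400: GC 1.0, O/E 2.0, length 800 -> one island spanning the repeat
  isl <- find_cpg_islands(c(chr1 = strrep("CG", 400)))
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 0)
  expect_equal(isl$end, 800)
  # poly-A: nothing
  expect_equal(nrow(find_cpg_islands(c(chr1 = strrep("A", 1000)))), 0)
  # all-G passes GC but O/E is undefined (no C): no island
  expect_equal(nrow(find_cpg_islands(c(chr1 = strrep("G", 1000)))), 0)
})

test_that("island detection equals the brute-force oracle on random sequences", {
  set.seed(121)
  for (i in 1:8) {
    s <- if (i %% 2 == 0) {
      chrom_string(small_test_genome(121 + i, chrom_length = 3000,
                                     island_count = 1,
                                     island_cpg_rate = 0.1))
    } else {
      random_dna(3000, gc = runif(1, 0.4, 0.55))
    }
    got <- find_cpg_islands(c(chrZ = s), max_length = 3000)
    want <- oracle_islands(s, max_len = 3000)
    expect_equal(got$start, want$start, info = paste("seq", i))
    expect_equal(got$end, want$end, info = paste("seq", i))
  }
})

test_that("detected islands recover planted island bases", {
  g <- small_test_genome(131, n_chroms = 2, chrom_length = 30000,
                         island_count = 3)
  isl <- find_cpg_islands(g)
  truth <- g$islands
  recovered <- 0
  total <- 0
  for (k in seq_len(nrow(truth))) {
    total <- total + truth$end[k] - truth$start[k]
    hits <- isl[isl$chrom == truth$chrom[k], , drop = FALSE]
    if (!nrow(hits)) next
    ov <- pmin(hits$end, truth$end[k]) - pmax(hits$start, truth$start[k])
    recovered <- recovered + sum(pmax(ov, 0))
  }
  expect_gte(recovered / total, 0.9)
})

test_that("shores flank islands without overlapping them", {
  lens <- c(chr1 = 20000L)
  isl <- data.frame(chrom = "chr1", start = 5000L, end = 6000L,
                    label = "cpg_island")
  sh <- derive_shores(isl, chrom_lengths = lens)
  expect_equal(sh$start, c(3000, 6000))
  expect_equal(sh$end, c(5000, 8000))
  # island at the chromosome start: left shore clipped away
  isl0 <- data.frame(chrom = "chr1", start = 0L, end = 900L,
                     label = "cpg_island")
  sh0 <- derive_shores(isl0, chrom_lengths = lens)
  expect_equal(sh0$start, 900)
  expect_equal(sh0$end, 2900)
  # two islands 1 kb apart: the inter-island shore covers the gap once
  isl2 <- data.frame(chrom = "chr1", start = c(3000L, 5000L),
                     end = c(4000L, 6000L), label = "cpg_island")
  sh2 <- derive_shores(isl2, chrom_lengths = lens)
  expect_equal(sh2$start, c(1000, 4000, 6000))
  expect_equal(sh2$end, c(3000, 5000, 8000))
  # property: shores never intersect islands
  both <- rbind(isl2[, c("chrom", "start", "end")],
                sh2[, c("chrom", "start", "end")])
  both <- both[order(both$start), ]
  expect_true(all(both$start[-1] >= both$end[-nrow(both)]))
})

test_that("promoter windows clip, deduplicate and warn on unknown strand", {
  tss <- data.frame(chrom = "chr1", pos = c(10000L, 300L, 10000L),
                    strand = c("+", "-", "+"))
  pr <- derive_promoters(tss, chrom_lengths = c(chr1 = 20000L))
  expect_equal(nrow(pr), 2)
  expect_equal(pr$start, c(9000, 0))
  expect_equal(pr$end, c(11000, 1300))
  expect_warning(derive_promoters(data.frame(chrom = "chr1", pos = 500L,
                                             strand = "?")),
                 "unknown strand")
})

test_that("genome tiles partition each chromosome exactly", {
  tiles <- tile_genome(c(chr1 = 12345L), size = 5000)
  expect_equal(tiles$start, c(0, 5000, 10000))
  expect_equal(tiles$end, c(5000, 10000, 12345))
  expect_equal(sum(tiles$end - tiles$start), 12345)
  one <- tile_genome(c(chrS = 800L), size = 5000)
  expect_equal(nrow(one), 1)
  expect_equal(one$label, "tile_5kb")
})

test_that("the 80%-of-samples rule scores feature CpGs at the exact boundary", {
  # 5 samples; CpG 100 covered >=5x in 4 (qualifies at 4/5 = 0.8),
  # CpG 200 in 3 (does not)
  mk <- function(smp, pos, cov) {
    data.frame(sample = smp, chrom = "chr1", pos = pos,
               meth = cov, unmeth = 0, coverage = cov,
               stringsAsFactors = FALSE)
  }
  calls <- rbind(mk(sprintf("S%d", 1:4), 100, 5),
                 mk("S5", 100, 1),
                 mk(sprintf("S%d", 1:3), 200, 8))
  feats <- data.frame(chrom = "chr1", start = c(0L), end = c(1000L),
                      label = "cpg_island")
  sc <- score_feature_cpgs(calls, feats, min_coverage = 5, n_samples = 5)
  expect_equal(sc$qualifying_cpg_count, 1)
  # monotone in coverage and in the sample fraction
  sc1 <- score_feature_cpgs(calls, feats, min_coverage = 1, n_samples = 5)
  expect_gte(sc1$qualifying_cpg_count, sc$qualifying_cpg_count)
  sc_strict <- score_feature_cpgs(calls, feats, min_coverage = 5,
                                  min_sample_fraction = 0.9, n_samples = 5)
  expect_lte(sc_strict$qualifying_cpg_count, sc$qualifying_cpg_count)
})

test_that("feature scoring agrees with a brute-force membership scan", {
  g <- small_test_genome(141)
  fr <- digest_genome(g)
  m <- generate_methylome(g, methylome_spec(seed = 1))
  d <- study_design(n_samples = 3, reads_per_sample = 3000, seed = 2)
  rd <- generate_reads(fr, m, d, g)
  tg <- build_alignment_target(fr, g)
  calls <- call_methylation(map_reads(rd, tg), tg)
  isl <- find_cpg_islands(g)
  feats <- rbind(isl, tile_genome(g))
  sc <- score_feature_cpgs(calls, feats, min_coverage = 2,
                           min_sample_fraction = 0.8, n_samples = 3)
  # brute force: which CpGs are covered >=2x in >=80% of 3 samples?
  df <- as.data.frame(calls)
  key <- paste(df$chrom, df$pos)
  qual_tab <- tapply(df$coverage >= 2, key, sum)
  qual <- names(qual_tab)[qual_tab / 3 >= 0.8]
  for (cl in unique(feats$label)) {
    fc <- feats[feats$label == cl, ]
    inside <- vapply(strsplit(qual, " "), function(kp) {
      p <- as.integer(kp[2])
      any(fc$chrom == kp[1] & fc$start <= p & p < fc$end)
    }, logical(1))
    expect_equal(sc$qualifying_cpg_count[sc$feature_class == cl],
                 sum(inside), info = cl)
  }
})

test_that("feature BED round-trips through rtracklayer", {
  feats <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 100L),
                      end = c(500L, 900L), label = c("enhancer", "enhancer"))
  f <- tempfile(fileext = ".bed")
  write_features_bed(feats, f)
  back <- read_bed(f)
  expect_equal(back$chrom, feats$chrom)
  expect_equal(back$start, feats$start)
  expect_equal(back$end, feats$end)
  expect_equal(back$label, feats$label)
})
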