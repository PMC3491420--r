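test_that("genome generation is deterministic, byte for byte", {
  spec <- genome_spec(n_chroms = 2, chrom_length = 8000, island_count = 2,
                      seed = 11)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  expect_identical(g1$islands, g2$islands)
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1)
  write_genome_fasta(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  m1 <- generate_methylome(g1, methylome_spec(seed = 4))
  m2 <- generate_methylome(g2, methylome_spec(seed = 4))
  expect_identical(m1, m2)
})

test_that("island-free genomes hit the nominal CpG rate within binomial noise", {
  spec <- genome_spec(n_chroms = 1, chrom_length = 100000, island_count = 0,
                      background_cpg_rate = 0.01, seed = 21)
  g <- generate_genome(spec)
  n_cg <- nrow(cpg_sites(g))
  expected <- spec$chrom_length * spec$background_cpg_rate
  sd3 <- 3 * sqrt(spec$chrom_length * spec$background_cpg_rate *
                    (1 - spec$background_cpg_rate))
  expect_lt(abs(n_cg - expected), sd3)
})

test_that("islands at the background rate are indistinguishable from background", {
  spec <- genome_spec(n_chroms = 1, chrom_length = 60000, island_count = 5,
                      island_cpg_rate = 0.01, background_cpg_rate = 0.01,
                      seed = 31)
  g <- generate_genome(spec)
  cg <- cpg_sites(g)
  isl <- g$islands
  in_isl <- rep(FALSE, nrow(cg))
  for (k in seq_len(nrow(isl))) {
    in_isl <- in_isl | (cg$pos >= isl$start[k] & cg$pos < isl$end[k])
  }
  n_isl_bp <- sum(isl$end - isl$start)
  n_bg_bp <- spec$chrom_length - n_isl_bp
  # two-proportion z on CpG density, planted intervals vs background
  p1 <- sum(in_isl) / n_isl_bp
  p2 <- sum(!in_isl) / n_bg_bp
  p <- nrow(cg) / spec$chrom_length
  z <- (p1 - p2) / sqrt(p * (1 - p) * (1 / n_isl_bp + 1 / n_bg_bp))
  expect_lt(abs(z), 4)
})

test_that("island intervals respect bounds and never overlap; oversized plans fail", {
  g <- generate_genome(genome_spec(n_chroms = 3, chrom_length = 10000,
                                   island_count = 4, seed = 7))
  for (ch in unique(g$islands$chrom)) {
    isl <- g$islands[g$islands$chrom == ch, ]
    isl <- isl[order(isl$start), ]
    expect_true(all(isl$start >= 0 & isl$end <= 10000 & isl$start < isl$end))
    if (nrow(isl) > 1) expect_true(all(isl$start[-1] >= isl$end[-nrow(isl)]))
  }
  expect_error(genome_spec(chrom_length = 5000, island_count = 10,
                           island_length_range = c(800, 1500)),
               "cannot fit")
})

test_that("methylome assigns exactly one probability per CpG, bimodally", {
  g <- small_test_genome(41)
  m <- generate_methylome(g, methylome_spec(seed = 42))
  cg <- cpg_sites(g)
  expect_equal(nrow(m), nrow(cg))
  expect_identical(paste(m$chrom, m$pos), paste(cg$chrom, cg$pos))
  expect_true(all(m$truth_probability >= 0 & m$truth_probability <= 1))
  # bimodal: high mass near the island and background levels, modes >= 0.5 apart
  h <- hist(m$truth_probability, breaks = seq(0, 1, by = 0.1), plot = FALSE)
  lo_mode <- (which.max(h$counts[1:5]) - 0.5) * 0.1
  hi_mode <- (which.max(h$counts[6:10]) + 5 - 0.5) * 0.1
  expect_gte(hi_mode - lo_mode, 0.5)
  expect_gt(min(sum(m$truth_probability < 0.5), sum(m$truth_probability > 0.5)), 0)
})

test_that("noise-free extreme methylomes are exact; CpG-free genomes give empty tables", {
  g <- small_test_genome(43)
  m <- generate_methylome(g, methylome_spec(island_meth_level = 0,
                                            background_meth_level = 1,
                                            per_cpg_noise_sd = 0))
  isl <- g$islands
  in_isl <- rep(FALSE, nrow(m))
  for (k in seq_len(nrow(isl))) {
    sel <- m$chrom == isl$chrom[k] & m$pos >= isl$start[k] & m$pos < isl$end[k]
    in_isl <- in_isl | sel
  }
  expect_true(all(m$truth_probability[in_isl] == 0))
  expect_true(all(m$truth_probability[!in_isl] == 1))

  m0 <- generate_methylome(c(chrA = "ATATATATTA"), methylome_spec())
  expect_equal(nrow(m0), 0)
})

test_that("study designs enforce distinct six-base barcodes", {
  d <- study_design(n_samples = 24)
  expect_length(unique(d$barcodes), 24)
  expect_true(all(nchar(d$barcodes) == 6))
  expect_false(any(grepl("[^ACGT]", d$barcodes)))
  expect_error(study_design(n_samples = 2, barcodes = c("ACGTAC", "ACGTAC")),
               "distinct")
  expect_error(study_design(n_samples = 1, barcodes = "ACGT"), "six-base")
})

test_that("methylome TSV round-trips", {
  g <- small_test_genome(44, chrom_length = 5000, island_count = 1)
  m <- generate_methylome(g, methylome_spec(seed = 1))
  f <- tempfile(fileext = ".tsv")
  write_methylome_tsv(m, f)
  m2 <- read_methylome_tsv(f)
  expect_equal(m$chrom, m2$chrom)
  expect_equal(m$pos, m2$pos)
  expect_equal(m$truth_probability, m2$truth_probability, tolerance = 1e-12)
})
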