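# A chromosome whose single internal fragment has a chosen length:
# [terminal][CCGG][interior making length L][CCGG][terminal]
chrom_with_internal_fragment <- function(L, seed = 1) {
  set.seed(seed)
  # fragment starts at the cut: "CGG" + interior; ends with "C" of next site
  interior <- paste(sample(c("A", "T", "G"), L - 4, replace = TRUE),
                    collapse = "")
  paste0("AATTAAC", "CGG", interior, "C", "CGGTTAA")
}

test_that("the target indexes two end entries per admissible fragment", {
  g <- c(chr1 = chrom_with_internal_fragment(100))
  fr <- digest_genome(g)
  expect_equal(sum(!fr$is_terminal), 1)
  tg <- build_alignment_target(fr[!fr$is_terminal, , drop = FALSE], g)
  expect_equal(nrow(tg$entries), 2)
  expect_setequal(tg$entries$end, c("5p", "3p"))
  # a 301 bp fragment is excluded from the target
  g2 <- c(chr1 = chrom_with_internal_fragment(301))
  fr2 <- digest_genome(g2)
  expect_equal(fr2$length[2], 301)
  tg2 <- build_alignment_target(fr2[!fr2$is_terminal, , drop = FALSE], g2)
  expect_equal(nrow(tg2$entries), 0)
})

test_that("identical fragments on different chromosomes are flagged ambiguous", {
  s <- chrom_with_internal_fragment(80)
  g <- c(chr1 = s, chr2 = s)
  fr <- digest_genome(g)
  tg <- build_alignment_target(fr, g)
  expect_true(all(tg$entries$ambiguous[!fr$is_terminal[tg$entries$frag]]))
  # reads matching the duplicated entries come back unmapped(ambiguous)
  internal <- which(!fr$is_terminal)
  prof_seq <- tg$entries$seq[tg$entries$frag == internal[1] &
                               tg$entries$end == "5p"]
  read <- data.frame(read_id = "r1", sample = "S01",
                     sequence = chartr("C", "T", prof_seq),
                     stringsAsFactors = FALSE)
  al <- map_reads(read, tg)
  expect_false(al$mapped)
  expect_equal(al$reason, "ambiguous")
})

test_that("exact reads map with zero mismatches; ties are ambiguous", {
  g <- c(chr1 = chrom_with_internal_fragment(120, seed = 3))
  fr <- digest_genome(g)
  tg <- build_alignment_target(fr, g)
  internal <- which(!fr$is_terminal)
  e5 <- which(tg$entries$frag == internal & tg$entries$end == "5p")
  read <- data.frame(read_id = "r1", sample = "S01",
                     sequence = chartr("C", "T", tg$entries$seq[e5]),
                     stringsAsFactors = FALSE)
  al <- map_reads(read, tg)
  expect_true(al$mapped)
  expect_equal(al$mismatches, 0)
  expect_equal(al$end, "5p")
  expect_equal(al$frag_start, fr$start[internal])
})

test_that("simulated reads map back to their truth fragment end", {
  g <- small_test_genome(91, n_chroms = 2, chrom_length = 30000)
  fr <- digest_genome(g)
  m <- generate_methylome(g, methylome_spec(seed = 92))
  d <- study_design(n_samples = 2, reads_per_sample = 4000, seed = 93)
  rd <- generate_reads(fr, m, d, g)
  tg <- build_alignment_target(fr, g)
  al <- map_reads(rd, tg)
  # restrict truth comparison to reads from unambiguous target entries
  ent <- tg$entries
  ekey <- paste(ent$chrom, ent$frag_start, ent$frag_end, ent$end)
  rkey <- paste(rd$chrom, rd$fragment_start, rd$fragment_end, rd$end_used)
  eidx <- match(rkey, ekey)
  from_target <- !is.na(eidx)
  unamb <- from_target & !ent$ambiguous[pmax(eidx, 1L)]
  expect_gt(mean(unamb), 0.5)
  mapped_ok <- al$mapped & paste(al$chrom, al$frag_start, al$frag_end, al$end) == rkey
  expect_gte(mean(mapped_ok[unamb]), 0.99)
  # informative-read accounting: informative <= mapped <= total
  expect_lte(sum(al$informative), sum(al$mapped))
  expect_lte(sum(al$mapped), nrow(al))
  expect_true(all(al$n_cpg[al$informative] >= 1))
})

test_that("methylation calls are strand-consistent and only at CpGs", {
  g <- small_test_genome(94)
  fr <- digest_genome(g)
  cg <- cpg_sites(g)
  meth_all <- data.frame(chrom = cg$chrom, pos = cg$pos, truth_probability = 1)
  d <- study_design(n_samples = 1, reads_per_sample = 5000, seed = 95)
  rd <- generate_reads(fr, meth_all, d, g)
  tg <- build_alignment_target(fr, g)
  al <- map_reads(rd, tg)
  calls <- call_methylation(al, tg)
  expect_gt(nrow(calls), 0)
  # fully methylated sample: every call is methylated, from both strands
  expect_true(all(calls$meth == calls$coverage))
  expect_true(all(calls$unmeth == 0))
  both <- unique(al$strand[al$mapped])
  expect_setequal(both, c("+", "-"))
  # no call outside the genomic CpG set
  expect_true(all(paste(calls$chrom, calls$pos) %in% paste(cg$chrom, cg$pos)))
  expect_true(all(calls$coverage >= 1))
})

test_that("per-CpG methylation fractions recover truth at depth", {
  g <- small_test_genome(96, n_chroms = 2, chrom_length = 30000)
  fr <- digest_genome(g)
  m <- generate_methylome(g, methylome_spec(per_cpg_noise_sd = 0.1, seed = 97))
  d <- study_design(n_samples = 1, reads_per_sample = 20000, seed = 98)
  rd <- generate_reads(fr, m, d, g,
                       conversion = conversion_model(conversion_rate = 1))
  tg <- build_alignment_target(fr, g)
  al <- map_reads(rd, tg)
  calls <- call_methylation(al, tg)
  deep <- calls[calls$coverage >= 50, ]
  expect_gt(nrow(deep), 20)
  truth <- m$truth_probability[match(paste(deep$chrom, deep$pos),
                                     paste(m$chrom, m$pos))]
  frac <- deep$meth / deep$coverage
  sd3 <- 3 * sqrt(pmax(truth * (1 - truth), 1e-9) / deep$coverage)
  within <- abs(frac - truth) <= pmax(sd3, 1e-9)
  expect_gte(mean(within), 0.97)
})

test_that("conversion estimation: exact arithmetic and simulation recovery", {
  # one internal fragment whose 5p read prefix has exactly one non-CpG C;
  # 100 fully-converted reads, one with that C unconverted: estimate 99/100
  g <- c(chr1 = paste0("AATTAAC", "CGG", "ATTACT", strrep("TA", 25),
                       "C", "CGGTTAA"))
  fr <- digest_genome(g)
  tg <- build_alignment_target(fr, g)
  ent <- tg$entries
  pick <- which(!fr$is_terminal[ent$frag] & ent$end == "5p")
  expect_length(ent$c_off[[pick]], 1)
  conv <- chartr("C", "T", ent$seq[pick])
  unconv <- conv
  off <- ent$c_off[[pick]][1]
  substr(unconv, off + 1, off + 1) <- "C"
  reads <- data.frame(read_id = sprintf("r%03d", 1:100), sample = "S01",
                      sequence = c(rep(conv, 99), unconv),
                      stringsAsFactors = FALSE)
  al <- map_reads(reads, tg)
  expect_true(all(al$mapped))
  est <- estimate_conversion(al, tg)
  expect_equal(est$estimate, 0.99)
  expect_equal(est$n_obs, 100)

  # simulation at conversion 1: estimate is exactly 1
  m <- generate_methylome(g, methylome_spec(seed = 1))
  d <- study_design(n_samples = 1, reads_per_sample = 2000, seed = 2)
  rd <- generate_reads(fr, m, d, g,
                       conversion = conversion_model(conversion_rate = 1))
  al2 <- map_reads(rd, tg)
  est2 <- estimate_conversion(al2, tg)
  expect_equal(est2$estimate, 1)
})

test_that("mismatch rates: zero without errors, bracketed with them, 1 when forced", {
  g <- small_test_genome(100)
  fr <- digest_genome(g)
  m <- generate_methylome(g, methylome_spec(seed = 3))
  d <- study_design(n_samples = 1, reads_per_sample = 4000, seed = 4)
  tg <- build_alignment_target(fr, g)

  rd0 <- generate_reads(fr, m, d, g)
  al0 <- map_reads(rd0, tg)
  expect_equal(mismatch_rate(al0), 0)

  # uniform substitution errors: a substitution at a C/T reference position
  # is invisible on the collapsed alphabet 1/3 of the time, so the observed
  # rate lies between 1-(1-2e/3)^29 and 1-(1-e)^29 (+/- binomial noise)
  e <- 0.004
  rde <- generate_reads(fr, m, d, g,
                        conversion = conversion_model(sequencing_error_rate = e))
  ale <- map_reads(rde, tg)
  r <- mismatch_rate(ale)
  hi <- 1 - (1 - e)^29
  lo <- 1 - (1 - 2 * e / 3)^29
  n <- sum(ale$mapped)
  noise <- 3 * sqrt(hi * (1 - hi) / n)
  expect_lt(r, hi + noise)
  expect_gt(r, lo - noise)

  # one forced visible substitution per read (mapped reads only)
  rd1 <- rd0[al0$mapped, ][1:50, ]
  substr(rd1$sequence, 5, 5) <- ifelse(substr(rd1$sequence, 5, 5) == "A", "G", "A")
  al1 <- map_reads(rd1, tg)
  expect_true(all(al1$mapped))
  expect_equal(mismatch_rate(al1), 1)
})

test_that("SAM and CpG-report exports are well-formed", {
  g <- small_test_genome(101)
  fr <- digest_genome(g)
  m <- generate_methylome(g, methylome_spec(seed = 5))
  d <- study_design(n_samples = 1, reads_per_sample = 300, seed = 6)
  rd <- generate_reads(fr, m, d, g)
  tg <- build_alignment_target(fr, g)
  al <- map_reads(rd, tg)
  sam <- tempfile(fileext = ".sam")
  write_sam(al, tg, sam)
  # samtools-free structural check
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), sum(al$mapped))
  f <- strsplit(body[1], "\t")[[1]]
  expect_true(f[2] %in% c("0", "16"))
  expect_match(f[6], "^[0-9]+M$")
  calls <- call_methylation(al, tg)
  rep_f <- tempfile(fileext = ".tsv")
  write_cpg_report(calls, rep_f)
  tab <- read.table(rep_f, sep = "\t")
  expect_equal(tab$V3, tab$V2 + 1)
  expect_true(all(tab$V4 >= 0 & tab$V4 <= 100))
})
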