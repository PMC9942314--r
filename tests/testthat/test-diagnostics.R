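test_that("mapq_summary matches hand arithmetic and a per-record oracle", {
  L <- c(chrA = 3000L)
  rec <- data.frame(
    qname = sprintf("q%d", 1:6),
    flag = c(99L, 99L, 99L, 99L, 99L, 2147L),
    rname = "chrA", pos = c(1000L, 1050L, 1100L, 1150L, 2500L, 1100L),
    mapq = c(0L, 0L, 60L, 40L, 60L, 60L),
    mrnm = "chrA", mpos = c(1000L, 1050L, 1100L, 1150L, 2500L, 1100L),
    stringsAsFactors = FALSE
  )
  bam <- toy_bam(rec, L)
  region <- genomic_intervals("chrA", 1000, 1400, "r1")
  out <- mapq_summary(bam, region)
  # MAPQs {0, 0, 60, 40}: the supplementary record is excluded by the mask
  expect_equal(out$n_records, 4L)
  expect_equal(out$mean_mapq, 25)
  expect_equal(out$frac_mapq0, 0.5)
  expect_equal(out$n_mapq0, 2L)

  # an empty region reports n 0 and NA summaries
  out0 <- mapq_summary(bam, genomic_intervals("chrA", 2900, 2950, "empty"))
  expect_equal(out0$n_records, 0L)
  expect_true(is.na(out0$mean_mapq))

  # per-record oracle on a larger random file
  set.seed(41)
  n <- 300L
  rec2 <- data.frame(
    qname = sprintf("r%03d", seq_len(n)), flag = 99L, rname = "chrA",
    pos = sample.int(2800, n, replace = TRUE) - 1L,
    mapq = sample(c(0L, 17L, 33L, 60L), n, replace = TRUE),
    mrnm = "chrA", mpos = 1L, stringsAsFactors = FALSE
  )
  bam2 <- toy_bam(rec2, L)
  region2 <- genomic_intervals("chrA", 500, 1500, "big")
  out2 <- mapq_summary(bam2, region2)
  inside <- rec2$pos < 1500 & rec2$pos + 100 > 500
  expect_equal(out2$n_records, sum(inside))
  expect_equal(out2$mean_mapq, mean(rec2$mapq[inside]))
  expect_equal(out2$frac_mapq0, mean(rec2$mapq[inside] == 0))
})

test_that("depth_summary equals per-position brute force", {
  L <- c(chrA = 3000L)
  # single 100 bp read fully inside a 1000 bp region: mean depth 0.1
  rec <- data.frame(qname = "a", flag = 99L, rname = "chrA", pos = 1200L,
                    mrnm = "chrA", mpos = 1200L, stringsAsFactors = FALSE)
  bam <- toy_bam(rec, L)
  out <- depth_summary(bam, genomic_intervals("chrA", 1000, 2000, "r"),
                       baseline = genomic_intervals("chrA", 0, 1000))
  expect_equal(out$mean_depth, 0.1)

  set.seed(42)
  n <- 200L
  rec2 <- data.frame(
    qname = sprintf("d%03d", seq_len(n)), flag = 99L, rname = "chrA",
    pos = sample.int(2900, n, replace = TRUE) - 1L,
    mrnm = "chrA", mpos = 1L, stringsAsFactors = FALSE
  )
  bam2 <- toy_bam(rec2, L)
  region <- genomic_intervals("chrA", 800, 1800, "r")
  out2 <- depth_summary(bam2, region, genomic_intervals("chrA", 0, 500))
  cover <- integer(1000L)
  for (i in seq_len(n)) {
    hit <- intersect(seq(rec2$pos[i], rec2$pos[i] + 99L), 800:1799)
    cover[hit - 799L] <- cover[hit - 799L] + 1L
  }
  expect_equal(out2$mean_depth, sum(cover) / 1000)
  base <- integer(500L)
  for (i in seq_len(n)) {
    hit <- intersect(seq(rec2$pos[i], rec2$pos[i] + 99L), 0:499)
    base[hit + 1L] <- base[hit + 1L] + 1L
  }
  expect_equal(out2$baseline_mean_depth, sum(base) / 500)
  expect_equal(out2$depth_ratio, out2$mean_depth / out2$baseline_mean_depth)

  # baseline overlapping the region is refused
  expect_error(depth_summary(bam2, region, genomic_intervals("chrA", 900, 950)),
               class = "refix_validation_error")
})

test_that("inbreeding coefficient reproduces the closed-form examples", {
  expect_equal(inbreeding_coefficient(25, 50, 25), 0)
  expect_equal(inbreeding_coefficient(0, 10, 0), -1)
  # p = 0.45, H_exp = 0.495, H_obs = 0.3 -> F = 0.393939...
  expect_equal(inbreeding_coefficient(30, 30, 40), 1 - 0.3 / 0.495,
               tolerance = 1e-12)
  expect_equal(round(inbreeding_coefficient(30, 30, 40), 6), 0.393939)
  # monomorphic or empty sites are undefined
  expect_true(is.na(inbreeding_coefficient(10, 0, 0)))
  expect_true(is.na(inbreeding_coefficient(0, 0, 0)))
})

test_that("F is zero for any counts in exact Hardy-Weinberg proportions", {
  set.seed(43)
  for (i in 1:25) {
    k <- sample(3:40, 1)
    p <- sample(1:(k - 1), 1) / k
    n <- k^2
    counts <- c(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
    expect_equal(inbreeding_coefficient(counts[1], counts[2], counts[3]), 0,
                 tolerance = 1e-12)
  }
})

test_that("cohort_site_stats matches hand computation on a 20-sample VCF", {
  # site 1: 10 het / 10 hom-ref, DP 30 everywhere -> F = 1 - .5/.375 = -1/3
  # site 2: 20 het -> F = -1; site 3 (outside region): 5/10/5 -> F = 0
  calls <- lapply(1:20, function(i) {
    rows <- list()
    if (i <= 10) rows <- c(rows, list(data.frame(
      contig = "chrA", pos = 149L, ref = "A", alt = "T", genotype = "het",
      depth = 30L)))
    rows <- c(rows, list(data.frame(
      contig = "chrA", pos = 249L, ref = "C", alt = "G", genotype = "het",
      depth = 40L)))
    if (i <= 5) rows <- c(rows, list(data.frame(
      contig = "chrB", pos = 10L, ref = "G", alt = "A", genotype = "hom_alt",
      depth = 10L)))
    if (i > 5 && i <= 15) rows <- c(rows, list(data.frame(
      contig = "chrB", pos = 10L, ref = "G", alt = "A", genotype = "het",
      depth = 10L)))
    do.call(rbind, rows)
  })
  names(calls) <- sprintf("s%d", 1:20)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(calls, vcf, contig_lengths = c(chrA = 1000L, chrB = 1000L))
  region <- genomic_intervals("chrA", 100, 300, "locus")
  st <- cohort_site_stats(vcf, region)
  ps <- st$per_site
  expect_equal(nrow(ps), 3L)
  f1 <- ps$f[ps$contig == "chrA" & ps$pos == 149]
  expect_equal(f1, 1 - 0.5 / 0.375, tolerance = 1e-12)
  expect_equal(ps$f[ps$contig == "chrA" & ps$pos == 249], -1)
  expect_equal(ps$f[ps$contig == "chrB"], 0, tolerance = 1e-12)
  expect_equal(ps$class, c("locus", "locus", "rest"))
  # depth averages only called samples with DP present
  expect_equal(ps$mean_depth[ps$contig == "chrA" & ps$pos == 149], 30)
  summ <- st$summary
  expect_equal(summ$n[summ$class == "locus" & summ$metric == "F"], 2L)
})

test_that("region_diagnostics assembles the combined per-region record", {
  L <- c(chrA = 3000L)
  rec <- data.frame(
    qname = sprintf("q%d", 1:4), flag = 99L, rname = "chrA",
    pos = c(1000L, 1100L, 200L, 300L), mapq = c(0L, 60L, 60L, 60L),
    mrnm = "chrA", mpos = 1L, stringsAsFactors = FALSE
  )
  bam <- toy_bam(rec, L)
  regions <- error_region_set(error_region(
    "COLLAPSED", genomic_intervals("chrA", 1000, 1400, "r1"),
    decoy_names = "d1"))
  out <- region_diagnostics(bam, regions, genomic_intervals("chrA", 0, 600))
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_records, 2L)
  expect_true(all(c("mean_mapq", "depth_ratio", "median_F") %in% names(out)))
})
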