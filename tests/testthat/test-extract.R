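# A toy alignment file with every flag class the selection filter must
# handle: primary proper pairs, secondary, supplementary, unmapped mates,
# and records outside the regions.
toy_extraction_bam <- function() {
  L <- c(chrA = 5000L, chrB = 5000L)
  rec <- data.frame(
    qname = c("p1", "p1", "p2", "p2", "sup", "sup", "sec", "unm",
              "out", "out", "p3", "p3"),
    flag  = c(99L, 147L, 99L, 147L, 99L, 2147L, 355L, 73L,
              99L, 147L, 99L, 147L),
    rname = c("chrA", "chrA", "chrA", "chrA", "chrA", "chrB", "chrA", "chrA",
              "chrB", "chrB", "chrA", "chrA"),
    stringsAsFactors = FALSE
  )
  rec$pos <- c(1000L, 1200L, 1050L, 1230L, 1100L, 2000L, 1010L, 1020L,
               4000L, 4200L, 980L, 1500L)
  rec$mrnm <- rec$rname
  rec$mpos <- c(1200L, 1000L, 1230L, 1050L, 2000L, 1100L, 1210L, 1020L,
                4200L, 4000L, 1500L, 980L)
  toy_bam(rec, L)
}

toy_regions <- function() {
  # two overlapping homolog intervals on chrA
  error_region_set(error_region(
    "FALSE_DUPLICATION", genomic_intervals("chrA", 1000, 1400, "r"),
    mask_intervals = genomic_intervals("chrB", 1900, 2400),
    homolog_intervals = genomic_intervals(c("chrA", "chrA"), c(900, 1200),
                                          c(1300, 1600))
  ))
}

test_that("select_alignments applies the 2316 exclusion mask and overlap rule", {
  bam <- toy_extraction_bam()
  regions <- toy_regions()
  sel <- select_alignments(bam, regions)
  # supplementary (0x800), secondary (0x100) and mate-unmapped (0x8) excluded
  expect_false("sec" %in% sel$qname)
  expect_false("unm" %in% sel$qname)
  expect_false(any(bitwAnd(sel$flag, 0x800) != 0))
  # proper primary pairs inside the intervals are retained
  expect_equal(sum(sel$qname == "p1"), 2L)
  # each record reported once despite two overlapping query intervals
  expect_false(any(duplicated(paste(sel$qname, sel$flag, sel$pos))))

  # linear-scan oracle: read everything, apply mask + overlap by hand
  all_rec <- refix::read_alignments(bam, apply_mask = FALSE)
  hom <- homolog_union(regions)
  span <- oracle_ref_span(all_rec$cigar)
  pass <- bitwAnd(all_rec$flag, exclusion_mask()) == 0L
  ovl <- vapply(seq_len(nrow(all_rec)), function(i) {
    any(hom$contig == all_rec$rname[i] &
          hom$start < all_rec$pos[i] + span[i] &
          hom$end > all_rec$pos[i])
  }, logical(1))
  expect_equal(nrow(sel), sum(pass & ovl))
  expect_setequal(paste(sel$qname, sel$flag), paste(all_rec$qname[pass & ovl],
                                                    all_rec$flag[pass & ovl]))
})

test_that("pair_and_dedup emits complete pairs with restored orientation", {
  seqf <- "ACGTACGTACGTACGTACGT"
  L <- c(chrA = 5000L)
  rec <- data.frame(
    qname = c("a", "a"), flag = c(99L, 147L), rname = "chrA",
    pos = c(1000L, 1100L), mrnm = "chrA", mpos = c(1100L, 1000L),
    seq = c(seqf, revcomp(seqf)), qual = c(strrep("I", 20), "ABCDEFGHIJKLMNOPQRST"),
    cigar = "20M", stringsAsFactors = FALSE
  )
  bam <- toy_bam(rec, L)
  res <- pair_and_dedup(select_alignments(
    bam, genomic_intervals("chrA", 900, 1300)), bam)
  expect_equal(nrow(res$pairs), 1L)
  # mate2 was stored reverse-complemented; extraction restores original read
  expect_equal(res$pairs$seq2, seqf)
  expect_equal(res$pairs$qual2, paste(rev(strsplit("ABCDEFGHIJKLMNOPQRST", "")[[1]]),
                                      collapse = ""))
  expect_equal(res$stats$n_pairs, 1L)
})

test_that("mate rescue fetches a mate outside the region within the window", {
  L <- c(chrA = 5000L)
  rec <- data.frame(
    qname = c("r", "r"), flag = c(99L, 147L), rname = "chrA",
    pos = c(1000L, 1500L), mrnm = "chrA", mpos = c(1500L, 1000L),
    stringsAsFactors = FALSE
  )
  bam <- toy_bam(rec, L)
  region <- genomic_intervals("chrA", 950, 1150) # only mate1 overlaps
  sel <- select_alignments(bam, region)
  expect_equal(nrow(sel), 1L)
  res <- pair_and_dedup(sel, bam, rescue_window = 1000L)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$stats$n_rescued, 1L)

  # when the mate only exists as a secondary record, rescue obeys the same
  # exclusion mask, finds nothing, and the singleton is dropped
  rec2 <- data.frame(
    qname = c("r", "r"), flag = c(99L, 403L), rname = "chrA",
    pos = c(1000L, 1500L), mrnm = "chrA", mpos = c(1500L, 1000L),
    stringsAsFactors = FALSE
  )
  bam2 <- toy_bam(rec2, L)
  sel2 <- select_alignments(bam2, region)
  res2 <- pair_and_dedup(sel2, bam2, rescue_window = 1000L)
  expect_equal(nrow(res2$pairs), 0L)
  expect_equal(res2$stats$n_dropped_singleton, 1L)
})

test_that("irreconcilable duplicates are dropped entirely and counted", {
  L <- c(chrA = 5000L)
  rec <- data.frame(
    qname = c("d", "d", "ok", "ok"),
    flag = c(99L, 99L, 99L, 147L), # 'd' appears twice as mate1
    rname = "chrA", pos = c(1000L, 1010L, 1020L, 1120L),
    mrnm = "chrA", mpos = c(1100L, 1110L, 1120L, 1020L),
    stringsAsFactors = FALSE
  )
  bam <- toy_bam(rec, L)
  res <- pair_and_dedup(select_alignments(
    bam, genomic_intervals("chrA", 900, 1300)), bam)
  expect_equal(res$pairs$name, "ok")
  expect_gte(res$stats$n_dropped_multi, 1L)
  expect_false(any(duplicated(res$pairs$name)))
})

test_that("FASTQ emission round-trips byte for byte", {
  pairs <- data.frame(
    name = c("x", "y", "z"),
    seq1 = c("ACGT", "GGGG", "TTAA"), qual1 = c("IIII", "JJJJ", "KKKK"),
    seq2 = c("CCCC", "AAAA", "GTGT"), qual2 = c("FFFF", "GGGG", "HHHH"),
    rg = NA_character_, stringsAsFactors = FALSE
  )
  fq1 <- tempfile(fileext = ".fastq"); fq2 <- tempfile(fileext = ".fastq")
  pairs_to_fastq(pairs, fq1, fq2)
  lines1 <- readLines(fq1)
  expect_equal(length(lines1), 12L)
  expect_equal(lines1[1], "@x")
  back <- read_fastq_pairs(fq1, fq2)
  expect_equal(back[, c("name", "seq1", "qual1", "seq2", "qual2")],
               pairs[, c("name", "seq1", "qual1", "seq2", "qual2")])
  fq1b <- tempfile(); fq2b <- tempfile()
  pairs_to_fastq(back, fq1b, fq2b)
  expect_identical(readLines(fq1b), readLines(fq1))
  expect_identical(readLines(fq2b), readLines(fq2))
  # empty input gives two empty streams
  pairs_to_fastq(pairs[0, ], fq1b, fq2b)
  expect_equal(length(readLines(fq1b)), 0L)
})

test_that("extraction is complete and unique against a whole-file scan", {
  set.seed(21)
  L <- c(chrA = 3000L)
  n <- 60L
  pos1 <- sample.int(2500, n) - 1L
  gap <- sample.int(300, n) + 50L
  rec <- data.frame(
    qname = rep(sprintf("q%03d", seq_len(n)), each = 2),
    flag = rep(c(99L, 147L), n),
    rname = "chrA",
    pos = as.vector(rbind(pos1, pmin(pos1 + gap, 2900L))),
    stringsAsFactors = FALSE
  )
  rec$mrnm <- "chrA"
  rec$mpos <- as.vector(rbind(pmin(pos1 + gap, 2900L), pos1))
  bam <- toy_bam(rec, L)
  region <- genomic_intervals("chrA", 1000, 1500)
  res <- extract_reads(bam, region, rescue_window = 1000L)
  # oracle: pairs with >= 1 base of overlap from either mate (all primaries,
  # both mates mapped, window large enough to rescue every partner)
  touch <- (pos1 < 1500 & pos1 + 100 > 1000) |
    (rec$pos[seq(2, 2 * n, 2)] < 1500 & rec$pos[seq(2, 2 * n, 2)] + 100 > 1000)
  expect_setequal(res$pairs$name, sprintf("q%03d", which(touch)))
  expect_false(any(duplicated(res$pairs$name)))
})
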