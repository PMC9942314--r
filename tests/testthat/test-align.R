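test_that("builtin mapper places exact, tied, and mismatched reads per contract", {
  set.seed(31)
  g <- random_seq(3000)
  ref <- Biostrings::DNAStringSet(c(g = g))
  idx <- build_mapper_index(ref)

  # exact unique 100-mer: that offset, 100M, mapq 60
  r <- builtin_map_read(substr(g, 501, 600), idx)
  expect_equal(r$pos, 500L)
  expect_equal(r$cigar, "100M")
  expect_equal(r$mapq, 60L)
  expect_equal(r$strand, "+")

  # a read present identically at two loci gets MAPQ 0
  dup <- paste0(g, strrep("T", 50), substr(g, 1001, 1100))
  idx2 <- build_mapper_index(Biostrings::DNAStringSet(c(g = dup)))
  r2 <- builtin_map_read(substr(g, 1001, 1100), idx2)
  expect_equal(r2$mapq, 0L)
  # deterministic tie-break: lowest coordinate
  expect_equal(r2$pos, 1000L)

  # reads shorter than k are unmapped
  expect_false(builtin_map_read("ACGTACGTAC", idx)$mapped)
})

test_that("a 1-mismatch locus beats a 3-mismatch locus with the documented score", {
  set.seed(32)
  core <- random_seq(100)
  gA <- mutate_seq(core, 10)        # 1 mismatch vs the read
  gB <- mutate_seq(core, c(30, 50, 70)) # 3 mismatches vs the read
  ref <- Biostrings::DNAStringSet(c(
    A = paste0(random_seq(500), gA, random_seq(500)),
    B = paste0(random_seq(500), gB, random_seq(500))
  ))
  r <- builtin_map_read(core, ref)
  expect_equal(r$contig, "A")
  expect_equal(r$score, 95L)          # 99 matches - 4
  expect_equal(sort(r$candidates$score, decreasing = TRUE)[2], 85L)
  expect_equal(r$mapq, 60L)           # min(60, 6 * (95 - 85))
  o <- oracle_best(core, ref)
  expect_equal(r$score, o$score)
  expect_equal(r$pos, o$pos)
})

test_that("builtin mapper agrees with the exhaustive all-offset oracle", {
  set.seed(33)
  ref <- Biostrings::DNAStringSet(c(c1 = random_seq(1500), c2 = random_seq(800)))
  idx <- build_mapper_index(ref)
  for (i in 1:25) {
    ctg <- sample(names(ref), 1)
    L <- Biostrings::width(ref)[match(ctg, names(ref))]
    off <- sample.int(L - 100, 1) - 1L
    read <- substr(as.character(ref[[ctg]]), off + 1, off + 100)
    nmut <- sample(0:3, 1)
    if (nmut > 0) read <- mutate_seq(read, sample.int(100, nmut) - 1L)
    if (i %% 2 == 0) read <- revcomp(read)
    r <- builtin_map_read(read, idx)
    o <- oracle_best(read, ref)
    expect_equal(r$score, o$score)
    if (o$n == 1L) {
      expect_equal(r$contig, o$contig)
      expect_equal(r$pos, o$pos)
      expect_equal(r$nmis, o$nmis)
    } else {
      expect_equal(r$mapq, 0L)
    }
  }
})

test_that("pair compatibility resolves and rescores ambiguous mates", {
  set.seed(34)
  # two near-identical copies of a locus; mate1 is unique to copy A's flank,
  # mate2 lies in the duplicated core and is individually tied
  core <- random_seq(400)
  flankA <- random_seq(300); flankB <- random_seq(300)
  ref <- Biostrings::DNAStringSet(c(
    A = paste0(flankA, core, random_dnaA <- random_seq(100)),
    B = paste0(flankB, core, random_seq(100))
  ))
  backend <- builtin_aligner()
  idx <- build_mapper_index(ref, backend)
  m1 <- substr(flankA, 151, 250)            # unique to A
  m2 <- revcomp(substr(core, 101, 200))     # tied between A and B
  r1 <- builtin_map_read(m1, idx)
  r2 <- builtin_map_read(m2, idx)
  expect_equal(r1$mapq, 60L)
  expect_equal(r2$mapq, 0L)
  res <- pair_rescue(r1$candidates, r2$candidates, 100L, 100L, backend)
  expect_true(res$proper)
  # the tie is resolved by compatibility and MAPQ is recomputed
  chosen2 <- r2$candidates[res$placement2$row, ]
  expect_equal(chosen2$contig, "A")
  expect_equal(res$placement2$mapq, 60L)

  # both mates tied across two complete copies: compatibility cannot
  # resolve the tie, MAPQ stays 0
  m1b <- substr(core, 1, 100)
  m2b <- revcomp(substr(core, 201, 300))
  r1b <- builtin_map_read(m1b, idx); r2b <- builtin_map_read(m2b, idx)
  resb <- pair_rescue(r1b$candidates, r2b$candidates, 100L, 100L, backend)
  expect_equal(resb$placement1$mapq, 0L)
  expect_equal(resb$placement2$mapq, 0L)

  # no compatible combination: mates placed independently, not proper
  m2c <- substr(flankA, 1, 100) # same strand as m1 -> no FR combo
  r2c <- builtin_map_read(m2c, idx)
  resc <- pair_rescue(r1$candidates, r2c$candidates, 100L, 100L, backend)
  expect_false(resc$proper)
})

test_that("align_pairs writes a complete, deterministic, indexed BAM", {
  set.seed(35)
  cfg <- simulation_config("CLEAN", seed = 101, coverage = 10)
  b <- simulate_bundle(cfg)
  ref <- b$truth$err_ref

  # zero pairs: valid empty BAM with a full header
  empty_bam <- align_pairs(b$reads$s1$pairs[0, ], ref,
                           bam_out = tempfile(fileext = ".bam"))
  expect_true(file.exists(empty_bam))
  hdr <- Rsamtools::scanBamHeader(empty_bam)[[1]]
  expect_setequal(names(hdr$targets), names(ref))
  expect_equal(nrow(refix::read_alignments(empty_bam, apply_mask = FALSE)), 0L)

  # every input pair appears, and repeated runs are byte-identical
  out1 <- align_pairs(b$reads$s1$pairs, ref, bam_out = tempfile(fileext = ".bam"))
  out2 <- align_pairs(b$reads$s1$pairs, ref, bam_out = tempfile(fileext = ".bam"))
  expect_identical(unname(tools::md5sum(out1)), unname(tools::md5sum(out2)))
  rec <- refix::read_alignments(out1, apply_mask = FALSE)
  expect_setequal(rec$qname, b$reads$s1$pairs$name)
  expect_equal(nrow(rec), 2L * nrow(b$reads$s1$pairs))
})

test_that("error-free reads from unique sequence map back to their origin", {
  cfg <- simulation_config("CLEAN", seed = 77, base_error_rate = 0,
                           het_snv_rate = 0, coverage = 15)
  b <- simulate_bundle(cfg)
  bam <- align_pairs(b$reads$s1$pairs, b$truth$err_ref,
                     bam_out = tempfile(fileext = ".bam"))
  rec <- refix::read_alignments(bam, apply_mask = FALSE)
  tp <- b$reads$s1$truth_placements
  first <- bitwAnd(rec$flag, 0x40) != 0
  r1 <- rec[first, ]
  m <- match(r1$qname, tp$name)
  ok <- r1$rname == tp$contig[m] & r1$pos == tp$start[m]
  expect_gte(mean(ok), 0.999)
  expect_gte(mean(bitwAnd(rec$flag, 0x2) != 0), 0.99) # proper pairs
})

test_that("splice_back replaces extracted names wholesale", {
  L <- c(chrA = 3000L)
  orig <- data.frame(
    qname = c("k1", "k1", "x1", "x1", "x1"),
    flag = c(99L, 147L, 99L, 147L, 2147L),
    rname = "chrA", pos = c(100L, 300L, 500L, 700L, 2500L),
    mrnm = "chrA", mpos = c(300L, 100L, 700L, 500L, 700L),
    stringsAsFactors = FALSE
  )
  obam <- toy_bam(orig, L)
  corr <- data.frame(
    qname = c("x1", "x1"), flag = c(99L, 147L), rname = "chrA",
    pos = c(510L, 710L), mrnm = "chrA", mpos = c(710L, 510L),
    stringsAsFactors = FALSE
  )
  cbam <- toy_bam(corr, c(chrA = 3000L, decoy1 = 500L))
  out <- tempfile(fileext = ".bam")
  splice_back(obam, cbam, "x1", out)
  rec <- refix::read_alignments(out, apply_mask = FALSE)
  # the far-away supplementary record of x1 is gone too; k1 untouched
  expect_equal(sum(rec$qname == "x1"), 2L)
  expect_setequal(rec$pos[rec$qname == "x1"], c(510L, 710L))
  expect_equal(sum(rec$qname == "k1"), 2L)
  # header carries the patched reference contigs
  expect_true("decoy1" %in% names(Rsamtools::scanBamHeader(out)[[1]]$targets))

  # empty extracted set: record-identical to the original
  out2 <- tempfile(fileext = ".bam")
  splice_back(obam, toy_bam(corr[0, ], c(chrA = 3000L, decoy1 = 500L)),
              character(0), out2)
  rec2 <- refix::read_alignments(out2, apply_mask = FALSE)
  expect_equal(nrow(rec2), nrow(orig))
  # name accounting: original - removed + corrected
  expect_equal(nrow(rec), nrow(orig) - 3L + 2L)

  # contig length mismatch is an error
  cbad <- toy_bam(corr, c(chrA = 2999L))
  expect_error(splice_back(obam, cbad, "x1", tempfile(fileext = ".bam")),
               class = "refix_validation_error")
})
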