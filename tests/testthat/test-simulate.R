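test_that("configuration invariants are enforced", {
  expect_silent(simulation_config("CLEAN"))
  expect_error(simulation_config("CLEAN", base_error_rate = 1),
               class = "refix_validation_error")
  expect_error(simulation_config("CLEAN", read_length = 400, insert_mean = 350),
               class = "refix_validation_error")
  expect_error(simulation_config("CLEAN", locus_length = 500),
               class = "refix_validation_error")
  # scenario-specific divergence defaults
  expect_equal(simulation_config("FALSE_DUP")$paralog_divergence, 0.002)
  expect_equal(simulation_config("COLLAPSE")$paralog_divergence, 0.01)
})

test_that("CLEAN truth equals the reference and the plan is empty", {
  b <- build_truth_and_reference(simulation_config("CLEAN", seed = 5))
  expect_identical(as.character(b$err_ref), as.character(b$truth_ref))
  expect_equal(nrow(b$plan$masks), 0L)
  expect_equal(length(b$plan$decoys), 0L)
  expect_equal(length(b$regions), 0L)
  expect_equal(nrow(b$psv_sites), 0L)
})

test_that("FALSE_DUP with zero divergence yields byte-identical copies", {
  cfg <- simulation_config("FALSE_DUP", seed = 6, paralog_divergence = 0)
  b <- build_truth_and_reference(cfg)
  expect_identical(as.character(b$err_ref[["chrA"]]),
                   as.character(b$err_ref[["chrB"]]))
  expect_equal(nrow(b$psv_sites), 0L)
})

test_that("the scenario geometries satisfy their own patch plans", {
  fd <- build_truth_and_reference(simulation_config("FALSE_DUP", seed = 7))
  patched <- apply_patch(fd$err_ref, fd$plan)
  # masking preserves contig lengths
  expect_equal(Biostrings::width(patched), Biostrings::width(fd$err_ref))
  expect_equal(Biostrings::countPattern("N", patched[["chrB"]]),
               Biostrings::width(fd$err_ref)[2])
  # PSV positions really differ between the copies and sit in the target
  ca <- strsplit(as.character(fd$err_ref[["chrA"]]), "")[[1]]
  cb <- strsplit(as.character(fd$err_ref[["chrB"]]), "")[[1]]
  expect_true(all(ca[fd$psv_sites$pos + 1] != cb[fd$psv_sites$pos + 1]))
  expect_true(all(fd$psv_sites$ref == ca[fd$psv_sites$pos + 1]))
  tgt <- fd$confident
  expect_true(all(fd$psv_sites$pos >= tgt$start & fd$psv_sites$pos < tgt$end))

  co <- build_truth_and_reference(simulation_config("COLLAPSE", seed = 8))
  patched2 <- apply_patch(co$err_ref, co$plan)
  expect_true("chrP" %in% names(patched2))
  expect_identical(as.character(patched2[["chrP"]]),
                   as.character(co$truth_ref[["chrP"]]))
  # PSVs stay two read lengths clear of the locus edges
  rl <- co$config$read_length
  expect_true(all(co$psv_sites$pos >= tgt$start + 2 * rl &
                    co$psv_sites$pos < tgt$end - 2 * rl))
})

test_that("read simulation honours coverage, error rate and determinism", {
  cfg <- simulation_config("CLEAN", seed = 9, coverage = 0)
  b <- build_truth_and_reference(cfg)
  expect_equal(nrow(simulate_reads(b$samples$s1, cfg)$pairs), 0L)

  # error-free CLEAN reads are exact substrings of a truth haplotype
  cfg2 <- simulation_config("CLEAN", seed = 10, base_error_rate = 0,
                            coverage = 6)
  b2 <- build_truth_and_reference(cfg2)
  rd <- simulate_reads(b2$samples$s1, cfg2)
  hay <- c(as.character(b2$samples$s1$h1), as.character(b2$samples$s1$h2))
  hay <- paste(c(hay, revcomp(hay)), collapse = "|")
  ok <- vapply(sample(rd$pairs$seq1, 50), function(s) grepl(s, hay, fixed = TRUE),
               logical(1))
  expect_true(all(ok))

  # realized depth is within 3 binomial standard errors of the target
  cfg3 <- simulation_config("CLEAN", seed = 11, coverage = 40)
  b3 <- build_truth_and_reference(cfg3)
  rd3 <- simulate_reads(b3$samples$s1, cfg3)
  glen <- sum(Biostrings::width(b3$truth_ref)) * 2 # diploid
  base_total <- 2 * 100 * nrow(rd3$pairs)
  exp_total <- 40 * glen / 2
  se <- sqrt(exp_total * 100) # fragment-count sampling, ~100 bp granularity
  expect_lt(abs(base_total - exp_total), 3 * se + 400)

  # identical seeds give identical reads; different samples differ
  rd_a <- simulate_reads(b3$samples$s1, cfg3)
  expect_identical(rd_a$pairs, rd3$pairs)
  rd_b <- simulate_reads(b3$samples$s1, cfg3, seed = 123)
  expect_false(identical(rd_b$pairs$seq1, rd3$pairs$seq1))
})

test_that("bundles are byte-identical when regenerated with the same seed", {
  cfg <- simulation_config("FALSE_DUP", seed = 12, coverage = 8)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in setdiff(f1, "manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # the manifest's recorded checksums agree too
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_identical(m1$md5, m2$md5)
  expect_identical(m1$config, m2$config)
})

test_that("a written bundle parses back through the package readers", {
  cfg <- simulation_config("COLLAPSE", seed = 13, coverage = 8)
  d <- tempfile()
  b <- simulate_bundle(cfg, d)
  regions <- read_region_config(file.path(d, "regions.tsv"))
  expect_equal(length(regions), 1L)
  expect_equal(regions$locus$kind, "COLLAPSED")
  expect_equal(regions$locus$decoy_names, "chrP")
  plan <- read_patch_plan(file.path(d, "patch_plan.json"))
  expect_identical(as.character(plan$decoys), as.character(b$truth$plan$decoys))
  patched_disk <- read_ref_fasta(file.path(d, "patched_ref.fasta"))
  expect_identical(as.character(patched_disk),
                   as.character(apply_patch(b$truth$err_ref, b$truth$plan)))
  pairs <- read_fastq_pairs(file.path(d, "reads_s1_R1.fastq"),
                            file.path(d, "reads_s1_R2.fastq"))
  expect_equal(nrow(pairs), nrow(b$reads$s1$pairs))
  truth <- read_vcf_calls(file.path(d, "truth.s1.vcf"))
  expect_equal(nrow(truth), nrow(b$truth$samples$s1$truth))
})

test_that("after patching, error-free truth reads recover their origin (CLEAN equivalence)", {
  # false duplication: once the extra copy is masked, every error-free truth
  # read has a unique best placement at its sampling position
  cfg <- simulation_config("FALSE_DUP", seed = 14, base_error_rate = 0,
                           het_snv_rate = 0, coverage = 4)
  b <- simulate_bundle(cfg)
  patched <- apply_patch(b$truth$err_ref, b$truth$plan)
  bam <- align_pairs(b$reads$s1$pairs, patched,
                     bam_out = tempfile(fileext = ".bam"))
  rec <- refix::read_alignments(bam, apply_mask = FALSE)
  mapped <- bitwAnd(rec$flag, 0x4) == 0
  expect_gte(mean(mapped), 0.99)
  expect_gte(mean(rec$mapq[mapped] > 0), 0.999)
  tp <- b$reads$s1$truth_placements
  first <- rec[bitwAnd(rec$flag, 0x40) != 0 & mapped[seq_len(nrow(rec))], ]
  m <- match(first$qname, tp$name)
  expect_gte(mean(first$rname == tp$contig[m] & first$pos == tp$start[m]), 0.999)

  # collapse: with the decoy in place, every read covering a PSV places
  # confidently on its own paralog; only zero-PSV reads can still tie
  cfg2 <- simulation_config("COLLAPSE", seed = 15, base_error_rate = 0,
                            het_snv_rate = 0, coverage = 4)
  b2 <- simulate_bundle(cfg2)
  patched2 <- apply_patch(b2$truth$err_ref, b2$truth$plan)
  bam2 <- align_pairs(b2$reads$s1$pairs, patched2,
                      bam_out = tempfile(fileext = ".bam"))
  rec2 <- refix::read_alignments(bam2, apply_mask = FALSE)
  conf <- rec2[rec2$mapq > 0 & bitwAnd(rec2$flag, 0x40) != 0 &
                 bitwAnd(rec2$flag, 0x4) == 0, ]
  tp2 <- b2$reads$s1$truth_placements
  m2 <- match(conf$qname, tp2$name)
  expect_gte(mean(conf$rname == tp2$contig[m2] & conf$pos == tp2$start[m2]),
             0.995)
})
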