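#' Run the built-in false-duplication recovery experiment
#'
#' Simulates the false-duplication study conditions (5 kb locus in 2 kb
#' flanks, whole-span extra copy at divergence 0.002, one diploid sample at
#' 40x with 2x100 bp reads and 0.2% base error), aligns the reads to the
#' erroneous reference with seeded-random tie-breaking, then corrects the
#' alignment with [fix_alignments()] (splice mode) against the patched
#' reference and genotypes both alignments. The returned metrics are the
#' region's MAPQ-0 fraction, depth ratio, and SNV recall/precision against
#' the simulated truth before and after the fix.
#'
#' @param seed master seed; every random draw derives from it.
#' @param config optional [simulation_config()] overriding the defaults.
#' @return a list with `pre` and `post` metric lists (`frac_mapq0`,
#'   `mean_mapq`, `depth_ratio`, `recall`, `precision`, `f_measure`) plus
#'   `n_truth_snvs` and `n_psv`.
#' @export
run_false_duplication_study <- function(seed = 42L, config = NULL) {
  cfg <- config %||% simulation_config("FALSE_DUP", seed = seed)
  b <- simulate_bundle(cfg)
  tr <- b$truth
  dir <- tempfile("fdstudy")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)

  set.seed(seed + 1001L)
  pre_bam <- align_pairs(b$reads$s1$pairs, tr$err_ref,
                         builtin_aligner(tie_break = "random"),
                         bam_out = file.path(dir, "pre.bam"))
  patched <- apply_patch(tr$err_ref, tr$plan)
  post_bam <- file.path(dir, "post.bam")
  fix_alignments(pre_bam, tr$regions, patched,
                 backend = builtin_aligner(tie_break = "random"),
                 bam_out = post_bam, splice = TRUE, seed = seed + 2001L)

  metrics <- function(bam, ref) {
    mq <- mapq_summary(bam, tr$regions)
    dp <- depth_summary(bam, tr$regions, tr$baseline)
    calls <- pileup_genotype(bam, ref, tr$regions)
    bench <- compare_to_truth(calls, tr$samples$s1$truth, tr$confident)
    list(frac_mapq0 = mq$frac_mapq0, mean_mapq = mq$mean_mapq,
         n_records = mq$n_records, depth_ratio = dp$depth_ratio,
         recall = bench$recall, precision = bench$precision,
         f_measure = bench$f_measure, n_calls = bench$tp + bench$fp)
  }
  truth_in <- tr$samples$s1$truth
  truth_in <- truth_in[overlaps_any(
    genomic_intervals(truth_in$contig, truth_in$pos, truth_in$pos + 1L),
    tr$confident), , drop = FALSE]
  list(pre = metrics(pre_bam, tr$err_ref),
       post = metrics(post_bam, patched),
       n_truth_snvs = nrow(truth_in), n_psv = nrow(tr$psv_sites),
       config = cfg)
}

#' Run the built-in collapsed-duplication recovery experiment
#'
#' Simulates the collapse study conditions (two paralogs at 1% divergence,
#' one of which is missing from the reference, ten diploid samples at 40x),
#' aligns every sample to the erroneous reference, corrects each with
#' [fix_alignments()] (decoy added, splice mode), genotypes all samples,
#' and summarises the cohort: mean depth ratio over the collapsed target,
#' the pooled fraction of paralogous-sequence-variant (PSV) sites called
#' heterozygous, the cohort median inbreeding coefficient over PSV sites,
#' and pooled SNV recall/precision against the per-sample truth.
#'
#' A PSV site with no called variant in any sample contributes F = 0 (no
#' detectable Hardy-Weinberg departure) to the PSV-site median, since the
#' plain estimator is undefined at monomorphic sites.
#'
#' @param seed master seed.
#' @param config optional [simulation_config()] overriding the defaults.
#' @return a list with `pre` and `post` metric lists (`depth_ratio`,
#'   `mean_mapq`, `psv_het_frac`, `median_F_psv`, `recall`, `precision`)
#'   plus `n_psv` and `n_samples`.
#' @export
run_collapse_study <- function(seed = 42L, config = NULL) {
  cfg <- config %||% simulation_config("COLLAPSE", seed = seed,
                                       n_samples = 10L)
  b <- simulate_bundle(cfg)
  tr <- b$truth
  patched <- apply_patch(tr$err_ref, tr$plan)
  dir <- tempfile("costudy")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)

  snames <- names(tr$samples)
  ratio_pre <- ratio_post <- mapq_pre <- mapq_post <- numeric(length(snames))
  calls_pre <- calls_post <- list()
  for (i in seq_along(snames)) {
    s <- snames[i]
    set.seed(seed + 3000L + i)
    pre <- align_pairs(b$reads[[s]]$pairs, tr$err_ref,
                       builtin_aligner(tie_break = "random"),
                       bam_out = file.path(dir, paste0("pre_", s, ".bam")))
    post <- file.path(dir, paste0("post_", s, ".bam"))
    fix_alignments(pre, tr$regions, patched,
                   backend = builtin_aligner(tie_break = "random"),
                   bam_out = post, splice = TRUE, seed = seed + 4000L + i)
    ratio_pre[i] <- depth_summary(pre, tr$regions, tr$baseline)$depth_ratio
    ratio_post[i] <- depth_summary(post, tr$regions, tr$baseline)$depth_ratio
    mapq_pre[i] <- mapq_summary(pre, tr$regions)$mean_mapq
    mapq_post[i] <- mapq_summary(post, tr$regions)$mean_mapq
    calls_pre[[s]] <- pileup_genotype(pre, tr$err_ref, tr$regions)
    calls_post[[s]] <- pileup_genotype(post, patched, tr$regions)
  }

  psv_key <- paste(tr$psv_sites$contig, tr$psv_sites$pos)
  psv_het_frac <- function(calls) {
    hits <- vapply(calls, function(cl) {
      k <- paste(cl$contig, cl$pos)
      sum(psv_key %in% k[cl$genotype == "het"])
    }, numeric(1))
    sum(hits) / (length(psv_key) * length(calls))
  }
  median_f_psv <- function(calls, vcf_path) {
    write_vcf(calls, vcf_path, contig_lengths = contig_lengths(patched))
    st <- cohort_site_stats(vcf_path, tr$regions)$per_site
    f <- st$f[match(psv_key, paste(st$contig, st$pos))]
    f[is.na(f)] <- 0
    stats::median(f)
  }
  pooled_bench <- function(calls) {
    parts <- lapply(snames, function(s) {
      compare_to_truth(calls[[s]], tr$samples[[s]]$truth, tr$confident)
    })
    benchmark_summary(sum(vapply(parts, `[[`, numeric(1), "tp")),
                      sum(vapply(parts, `[[`, numeric(1), "fp")),
                      sum(vapply(parts, `[[`, numeric(1), "fn")))
  }
  bench_pre <- pooled_bench(calls_pre)
  bench_post <- pooled_bench(calls_post)
  list(
    pre = list(depth_ratio = mean(ratio_pre), mean_mapq = mean(mapq_pre),
               psv_het_frac = psv_het_frac(calls_pre),
               median_F_psv = median_f_psv(calls_pre,
                                           file.path(dir, "pre.vcf")),
               recall = bench_pre$recall, precision = bench_pre$precision),
    post = list(depth_ratio = mean(ratio_post), mean_mapq = mean(mapq_post),
                psv_het_frac = psv_het_frac(calls_post),
                median_F_psv = median_f_psv(calls_post,
                                            file.path(dir, "post.vcf")),
                recall = bench_post$recall,
                precision = bench_post$precision),
    n_psv = nrow(tr$psv_sites), n_samples = length(snames), config = cfg
  )
}
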