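#' Configure the reference-error simulator
#'
#' The simulator emulates the two classes of reference error the package
#' corrects, at desk scale:
#'
#' * `FALSE_DUP` -- the truth genome has ONE copy of a locus but the
#'   erroneous reference carries a second, near-identical copy (divergence
#'   `paralog_divergence`) embedded in its own unique flanks; the patch
#'   plan hard-masks the extra copy.
#' * `COLLAPSE` -- the truth genome has TWO diverged paralogs but the
#'   erroneous reference carries only one; the patch plan appends the
#'   missing paralog (with its flanks) as a decoy contig.
#' * `CLEAN` -- truth and reference agree; empty patch plan.
#'
#' Heterozygous SNVs are planted per sample on one haplotype at
#' `het_snv_rate`; paralog-distinguishing positions (PSVs) are recorded
#' separately and are kept at least two read lengths away from the locus
#' edges so that every PSV is coverable by fully internal reads.
#'
#' @param scenario `"FALSE_DUP"`, `"COLLAPSE"` or `"CLEAN"`.
#' @param seed integer seed; all randomness in the bundle derives from it.
#' @param flank_length,locus_length sizes in bp.
#' @param paralog_divergence substitution rate between the two copies
#'   (default 0.002 for `FALSE_DUP` -- a false duplication is a
#'   near-identical artifactual copy -- and 0.01 for `COLLAPSE` -- real
#'   paralogs are more diverged).
#' @param het_snv_rate per-bp heterozygous SNV rate per sample (human-like
#'   default 0.001).
#' @param coverage total diploid fold coverage.
#' @param read_length,insert_mean,insert_sd paired-end geometry in bp.
#' @param base_error_rate per-base substitution sequencing error rate.
#' @param n_samples number of diploid samples.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(scenario = c("FALSE_DUP", "COLLAPSE", "CLEAN"),
                              seed = 1L, flank_length = 2000L,
                              locus_length = 5000L,
                              paralog_divergence = NULL,
                              het_snv_rate = 0.001, coverage = 40,
                              read_length = 100L, insert_mean = 350,
                              insert_sd = 50, base_error_rate = 0.002,
                              n_samples = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(paralog_divergence)) {
    paralog_divergence <- switch(scenario, FALSE_DUP = 0.002,
                                 COLLAPSE = 0.01, CLEAN = 0)
  }
  cfg <- list(scenario = scenario, seed = as.integer(seed),
              flank_length = as.integer(flank_length),
              locus_length = as.integer(locus_length),
              paralog_divergence = paralog_divergence,
              het_snv_rate = het_snv_rate, coverage = coverage,
              read_length = as.integer(read_length),
              insert_mean = insert_mean, insert_sd = insert_sd,
              base_error_rate = base_error_rate,
              n_samples = as.integer(n_samples))
  rates <- c(cfg$paralog_divergence, cfg$het_snv_rate, cfg$base_error_rate)
  if (any(rates < 0 | rates >= 1)) {
    stop_validation("simulation_config: rates must lie in [0, 1)")
  }
  if (cfg$read_length >= cfg$insert_mean) {
    stop_validation("simulation_config: read_length must be < insert_mean")
  }
  if (cfg$locus_length < 10L * cfg$read_length) {
    stop_validation("simulation_config: locus_length must be >= 10 * read_length")
  }
  edge <- cfg$insert_mean + 4 * cfg$insert_sd
  if (cfg$flank_length < edge + 500) {
    stop_validation("simulation_config: flank_length too short for the ",
                    "insert-size distribution (need >= ", ceiling(edge + 500), ")")
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: %s  seed %d\n  locus %d bp, flanks %d bp, divergence %.4g\n  het SNV rate %.4g, coverage %gx, reads 2x%d bp, insert %g+/-%g, error %.4g\n  samples: %d\n",
    x$scenario, x$seed, x$locus_length, x$flank_length, x$paralog_divergence,
    x$het_snv_rate, x$coverage, x$read_length, x$insert_mean, x$insert_sd,
    x$base_error_rate, x$n_samples))
  invisible(x)
}

mutate_at <- function(seq, pos0, alt) {
  if (length(pos0) == 0L) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  x[pos0 + 1L] <- alt
  paste(x, collapse = "")
}

#' Build the truth genome, erroneous reference and correcting patch plan
#'
#' @param config a [simulation_config()].
#' @return a `simulated_truth` list with elements `err_ref` (erroneous
#'   reference, `DNAStringSet`), `truth_ref` (sample-independent truth
#'   backbone), `plan` (the [patch_plan()] that corrects `err_ref`),
#'   `regions` ([error_region_set()]), `baseline` (unaffected intervals for
#'   depth ratios), `confident` (evaluation intervals: the target),
#'   `psv_sites` (data frame of paralog-distinguishing positions on the
#'   kept copy), and `samples` (per sample: `h1`/`h2` haplotype
#'   `DNAStringSet`s and `truth` variant data frame).
#' @export
build_truth_and_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  fl <- config$flank_length
  ll <- config$locus_length
  rl <- config$read_length
  scen <- config$scenario

  locus <- random_dna(1L, ll)
  f1 <- random_dna(1L, fl); f2 <- random_dna(1L, fl)
  chrA <- paste0(f1, locus, f2)
  alen <- fl + ll + fl
  # an unaffected contig carrying the depth baseline and background SNVs
  chrC <- random_dna(1L, alen)

  target <- genomic_intervals("chrA", fl, fl + ll, "locus")
  edge <- as.integer(round(config$insert_mean + 4 * config$insert_sd))
  baseline <- genomic_intervals("chrC", edge, alen - edge, "baseline")

  if (scen == "FALSE_DUP") {
    # the WHOLE of chrA is falsely duplicated as chrB (flanks included, as a
    # real duplication artifact copies a span, not a gene boundary); the
    # divergence between the copies is spread over the full span
    eligible <- seq.int(2L * rl, alen - 2L * rl - 1L)
    n_div <- min(stats::rbinom(1L, alen, config$paralog_divergence),
                 length(eligible))
    div_pos <- sort(sample(eligible, n_div))
    chrA_chars <- strsplit(chrA, "", fixed = TRUE)[[1L]]
    div_ref <- chrA_chars[div_pos + 1L]
    div_alt <- other_base(div_ref)
    chrB <- mutate_at(chrA, div_pos, div_alt)
    err_ref <- Biostrings::DNAStringSet(c(chrA = chrA, chrB = chrB,
                                          chrC = chrC))
    truth_ref <- Biostrings::DNAStringSet(c(chrA = chrA, chrC = chrC))
    plan <- patch_plan(
      base_reference_id = "simulated_err_ref",
      masks = genomic_intervals("chrB", 0L, alen, "false_copy")
    )
    hom <- rbind_intervals(genomic_intervals("chrA", 0L, alen, "locus"),
                           genomic_intervals("chrB", 0L, alen, "locus"))
    regions <- error_region_set(error_region(
      "FALSE_DUPLICATION", target, mask_intervals = plan$masks,
      homolog_intervals = hom, label = "locus"
    ))
    in_target <- div_pos >= fl & div_pos < fl + ll
    psv <- data.frame(contig = rep("chrA", sum(in_target)),
                      pos = div_pos[in_target],
                      ref = div_ref[in_target], alt = div_alt[in_target],
                      stringsAsFactors = FALSE)
  } else if (scen == "COLLAPSE") {
    # two real paralogs diverged inside the locus; the reference carries
    # only chrA. PSVs stay >= 2 read lengths from the locus edges so every
    # PSV is coverable by fully internal read pairs.
    interior <- seq.int(2L * rl, ll - 2L * rl - 1L)
    n_div <- min(stats::rbinom(1L, ll, config$paralog_divergence),
                 length(interior))
    div_pos <- sort(sample(interior, n_div))
    locus_chars <- strsplit(locus, "", fixed = TRUE)[[1L]]
    div_ref <- locus_chars[div_pos + 1L]
    div_alt <- other_base(div_ref)
    locus2 <- mutate_at(locus, div_pos, div_alt)
    f3 <- random_dna(1L, fl); f4 <- random_dna(1L, fl)
    chrP <- paste0(f3, locus2, f4)
    err_ref <- Biostrings::DNAStringSet(c(chrA = chrA, chrC = chrC))
    truth_ref <- Biostrings::DNAStringSet(c(chrA = chrA, chrP = chrP,
                                            chrC = chrC))
    plan <- patch_plan(
      base_reference_id = "simulated_err_ref",
      decoys = Biostrings::DNAStringSet(c(chrP = chrP)),
      decoy_description = "synthetic missing paralog of the chrA locus"
    )
    hom <- pad_intervals(target, edge, contig_lengths(err_ref))
    regions <- error_region_set(error_region(
      "COLLAPSED", target, decoy_names = "chrP",
      homolog_intervals = hom, label = "locus"
    ))
    psv <- data.frame(contig = rep("chrA", length(div_pos)),
                      pos = fl + div_pos, ref = div_ref,
                      alt = div_alt, stringsAsFactors = FALSE)
  } else { # CLEAN
    div_pos <- integer(0)
    err_ref <- Biostrings::DNAStringSet(c(chrA = chrA, chrC = chrC))
    truth_ref <- err_ref
    plan <- patch_plan(base_reference_id = "simulated_err_ref")
    regions <- error_region_set()
    psv <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE)
  }

  # keep het SNVs off the PSV positions so paralog-distinguishing sites stay
  # interpretable in the truth bookkeeping
  excl_by_ctg <- switch(scen,
    FALSE_DUP = list(chrA = div_pos),
    COLLAPSE = list(chrA = fl + div_pos, chrP = fl + div_pos),
    CLEAN = list()
  )
  truth_contigs <- names(truth_ref)
  samples <- lapply(seq_len(config$n_samples), function(s) {
    hap <- list(as.character(truth_ref), as.character(truth_ref))
    truth_rows <- list()
    for (ctg in truth_contigs) {
      clen <- nchar(hap[[1L]][[ctg]])
      cand <- setdiff(seq.int(0L, clen - 1L),
                      excl_by_ctg[[ctg]] %||% integer(0))
      hit <- cand[stats::runif(length(cand)) < config$het_snv_rate]
      if (length(hit) == 0L) next
      refb <- strsplit(hap[[1L]][[ctg]], "", fixed = TRUE)[[1L]][hit + 1L]
      altb <- other_base(refb)
      which_hap <- sample.int(2L, length(hit), replace = TRUE)
      for (h in 1:2) {
        sel <- which_hap == h
        hap[[h]][[ctg]] <- mutate_at(hap[[h]][[ctg]], hit[sel], altb[sel])
      }
      truth_rows[[ctg]] <- data.frame(contig = ctg, pos = hit, ref = refb,
                                      alt = altb, genotype = "het",
                                      stringsAsFactors = FALSE)
    }
    truth <- if (length(truth_rows)) {
      do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
    } else {
      data.frame(contig = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), genotype = character(0),
                 stringsAsFactors = FALSE)
    }
    list(name = sprintf("s%d", s),
         h1 = Biostrings::DNAStringSet(hap[[1L]]),
         h2 = Biostrings::DNAStringSet(hap[[2L]]),
         truth = truth)
  })
  names(samples) <- vapply(samples, `[[`, character(1), "name")

  structure(
    list(config = config, err_ref = err_ref, truth_ref = truth_ref,
         plan = plan, regions = regions, baseline = baseline,
         confident = target, psv_sites = psv, samples = samples),
    class = "simulated_truth"
  )
}

#' @export
print.simulated_truth <- function(x, ...) {
  cat(sprintf(
    "simulated_truth (%s): err ref %d contig(s) / %d bp; %d PSV site(s); %d sample(s)\n",
    x$config$scenario, length(x$err_ref), sum(Biostrings::width(x$err_ref)),
    nrow(x$psv_sites), length(x$samples)))
  invisible(x)
}

# Plant substitution sequencing errors at rate `rate` into reads of equal
# length; returns the mutated vector.
plant_errors <- function(seqs, rate) {
  n <- length(seqs)
  if (n == 0L || rate <= 0) return(seqs)
  L <- nchar(seqs[1L])
  m <- stats::rbinom(1L, n * L, rate)
  if (m == 0L) return(seqs)
  at <- sample.int(n * L, m)
  read_i <- (at - 1L) %/% L + 1L
  pos_i <- (at - 1L) %% L
  for (i in unique(read_i)) {
    p <- pos_i[read_i == i]
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    ch[p + 1L] <- other_base(ch[p + 1L])
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate paired-end reads from one diploid sample
#'
#' Fragments are drawn uniformly over each haplotype contig with length
#' `Normal(insert_mean, insert_sd)` truncated to `[read_length, contig]`;
#' mate 1 is the forward end of the fragment, mate 2 the
#' reverse-complemented other end. Substitution errors are planted at
#' `base_error_rate`; base qualities are a constant Phred 40. The number of
#' pairs is chosen so the expected diploid depth equals `coverage`. True
#' sampling coordinates are recorded for oracle checks.
#'
#' @param sample one element of `build_truth_and_reference()$samples`.
#' @param config the [simulation_config()].
#' @param seed RNG seed for this sample's reads (defaults to a value
#'   derived from the bundle seed and the sample name).
#' @return list with `pairs` (read-pair data frame) and `truth_placements`
#'   (`name, contig, hap, start, frag_len`).
#' @export
simulate_reads <- function(sample, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(seed)) {
    s_idx <- as.integer(sub("^s", "", sample$name))
    seed <- (config$seed + 7919L * s_idx) %% .Machine$integer.max
  }
  set.seed(seed)
  rl <- config$read_length
  out_names <- character(0); s1 <- character(0); s2 <- character(0)
  tp <- list()
  for (h in 1:2) {
    haps <- if (h == 1L) sample$h1 else sample$h2
    for (ctg in names(haps)) {
      contig <- as.character(haps[[ctg]])
      clen <- nchar(contig)
      n <- round(config$coverage * clen / (4 * rl))
      if (n <= 0) next
      frag <- pmin(clen, pmax(rl, round(stats::rnorm(n, config$insert_mean,
                                                     config$insert_sd))))
      start <- floor(stats::runif(n, 0, clen - frag + 1))
      m1 <- substring(contig, start + 1L, start + rl)
      m2 <- revcomp_chr(substring(contig, start + frag - rl + 1L, start + frag))
      nm <- sprintf("%s_h%d_%s_%05d", sample$name, h, ctg, seq_len(n))
      out_names <- c(out_names, nm)
      s1 <- c(s1, m1)
      s2 <- c(s2, m2)
      tp[[paste0(ctg, h)]] <- data.frame(name = nm, contig = ctg, hap = h,
                                         start = as.integer(start),
                                         frag_len = as.integer(frag),
                                         stringsAsFactors = FALSE)
    }
  }
  s1 <- plant_errors(s1, config$base_error_rate)
  s2 <- plant_errors(s2, config$base_error_rate)
  qual <- rep(strrep("I", rl), length(out_names))
  pairs <- data.frame(name = out_names, seq1 = s1, qual1 = qual, seq2 = s2,
                      qual2 = qual,
                      rg = rep(sample$name, length(out_names)),
                      stringsAsFactors = FALSE)
  placements <- if (length(tp)) do.call(rbind, c(tp, list(make.row.names = FALSE)))
                else data.frame(name = character(0), contig = character(0),
                                hap = integer(0), start = integer(0),
                                frag_len = integer(0))
  list(pairs = pairs, truth_placements = placements)
}

#' Simulate a complete bundle (truth, reference, reads for every sample)
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, [write_bundle()] is
#'   called.
#' @return a list with `truth` (the `simulated_truth`) and `reads` (named
#'   list per sample as returned by [simulate_reads()]); with `out_dir`,
#'   also `files` (the manifest of written files).
#' @export
simulate_bundle <- function(config, out_dir = NULL) {
  truth <- build_truth_and_reference(config)
  reads <- lapply(truth$samples, simulate_reads, config = config)
  out <- list(truth = truth, reads = reads)
  if (!is.null(out_dir)) {
    out$files <- write_bundle(truth, reads, out_dir)
  }
  out
}

#' Write a simulated bundle to disk
#'
#' Emits `truth_ref.fasta`, `err_ref.fasta`, `patched_ref.fasta` (each with
#' a `.fai` sidecar), `patch_plan.json`, `regions.tsv` with companion
#' `homologs.bed`/`masks.bed`, `baseline.bed`, `confident.bed`,
#' `psv_sites.tsv`, per-sample `reads_<s>_R1.fastq`/`_R2.fastq` and
#' `truth.<s>.vcf`, plus a `manifest.json` recording the configuration,
#' seed and MD5 checksums. Identical config and seed reproduce the bundle
#' byte for byte.
#'
#' @param truth a `simulated_truth`.
#' @param reads list of per-sample read sets ([simulate_reads()] output).
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_bundle <- function(truth, reads, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  files <- c(truth_ref = p("truth_ref.fasta"), err_ref = p("err_ref.fasta"),
             patched_ref = p("patched_ref.fasta"),
             patch_plan = p("patch_plan.json"), regions = p("regions.tsv"),
             homologs = p("homologs.bed"), masks = p("masks.bed"),
             baseline = p("baseline.bed"), confident = p("confident.bed"),
             psv_sites = p("psv_sites.tsv"))
  write_ref_fasta(truth$truth_ref, files[["truth_ref"]])
  write_ref_fasta(truth$err_ref, files[["err_ref"]])
  write_ref_fasta(apply_patch(truth$err_ref, truth$plan),
                  files[["patched_ref"]])
  write_patch_plan(truth$plan, files[["patch_plan"]])
  write_region_config(truth$regions, files[["regions"]],
                      homologs = files[["homologs"]], masks = files[["masks"]])
  write_bed(truth$baseline, files[["baseline"]])
  write_bed(truth$confident, files[["confident"]])
  utils::write.table(truth$psv_sites, files[["psv_sites"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  contigs <- contig_lengths(apply_patch(truth$err_ref, truth$plan))
  for (s in names(truth$samples)) {
    fq1 <- p(sprintf("reads_%s_R1.fastq", s))
    fq2 <- p(sprintf("reads_%s_R2.fastq", s))
    pairs_to_fastq(reads[[s]]$pairs, fq1, fq2)
    vcf <- p(sprintf("truth.%s.vcf", s))
    write_vcf(truth$samples[[s]]$truth, vcf, contig_lengths = contigs,
              sample = s)
    files[paste0("reads_", s, "_R1")] <- fq1
    files[paste0("reads_", s, "_R2")] <- fq2
    files[paste0("truth_", s)] <- vcf
  }
  manifest <- list(
    schema_version = 1L,
    config = unclass(truth$config),
    files = as.list(stats::setNames(basename(files), names(files))),
    md5 = as.list(stats::setNames(unname(tools::md5sum(files)), names(files)))
  )
  mf <- p("manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files["manifest"] <- mf
  invisible(files)
}
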