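#' Desk-scale pileup SNV genotyper
#'
#' A deliberately simple caller used to exercise the re-alignment workflow
#' end to end: per reference position inside the regions, bases from
#' records passing the exclusion mask with `MAPQ >= min_mapq` and base
#' quality `>= min_baseq` are counted; the most frequent non-reference base
#' at a position with total passing depth `>= min_depth` yields a
#' heterozygous call when its fraction lies inside `het_band` and a
#' homozygous-alternate call when it exceeds the band. Positions whose
#' reference base is `N` (masked) are skipped. Substitutions only: the
#' builtin mapper is ungapped, so INDEL calling is left to external tools.
#'
#' @param bam indexed BAM.
#' @param ref the reference the BAM is aligned to ([Biostrings::DNAStringSet]
#'   or FASTA path).
#' @param regions [error_region_set()], or [genomic_intervals()] to
#'   genotype directly.
#' @param min_mapq,min_baseq,min_depth,het_band calling thresholds.
#' @return a data frame of variant calls: `contig, pos` (0-based), `ref,
#'   alt, genotype` (`"het"`/`"hom_alt"`), `depth, alt_count,
#'   alt_fraction`.
#' @export
pileup_genotype <- function(bam, ref, regions, min_mapq = 20L,
                            min_baseq = 13L, min_depth = 4L,
                            het_band = c(0.2, 0.8)) {
  if (is.character(ref)) ref <- read_ref_fasta(ref)
  iv <- if (inherits(regions, "error_region_set")) region_targets(regions)
        else normalize_intervals(as_genomic_intervals(regions))
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genotype = character(0), depth = integer(0),
                      alt_count = integer(0), alt_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(iv) == 0L) return(empty)
  check_bam_index(bam)
  len <- bam_seqlengths(bam)
  iv <- iv[iv$contig %in% names(len), , drop = FALSE]
  if (nrow(iv) == 0L) return(empty)
  iv$end <- pmin(iv$end, as.integer(len[iv$contig]))
  gr <- intervals_to_granges(iv, seqlengths = len)
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(flag = exclusion_scan_flag(),
                                           which = gr),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 100000L, min_base_quality = as.integer(min_baseq),
      min_mapq = as.integer(min_mapq), min_nucleotide_depth = 1L,
      distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
      include_deletions = FALSE, include_insertions = FALSE
    )
  )
  if (nrow(p) == 0L) return(empty)
  p <- p[p$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
  # a position can be returned once per query interval; dedupe
  key <- paste(p$seqnames, p$pos, p$nucleotide, sep = "\r")
  p <- p[!duplicated(key), , drop = FALSE]
  if (nrow(p) == 0L) return(empty)
  p$contig <- as.character(p$seqnames)
  p$pos0 <- p$pos - 1L
  p$nucleotide <- as.character(p$nucleotide)
  refbase <- reference_base(ref, p$contig, p$pos0)
  keep <- refbase != "N"
  p <- p[keep, , drop = FALSE]
  refbase <- refbase[keep]
  if (nrow(p) == 0L) return(empty)
  sitekey <- paste(p$contig, p$pos0, sep = "\r")
  depth <- rowsum(p$count, sitekey)
  nonref <- which(p$nucleotide != refbase)
  if (length(nonref) == 0L) return(empty)
  nr <- p[nonref, , drop = FALSE]
  nr$refbase <- refbase[nonref]
  nr$key <- sitekey[nonref]
  # per site, the most frequent non-reference base (alphabetical tie-break)
  o <- order(nr$key, -nr$count, nr$nucleotide, method = "radix")
  nr <- nr[o, , drop = FALSE]
  nr <- nr[!duplicated(nr$key), , drop = FALSE]
  d <- depth[nr$key, 1L]
  f <- nr$count / d
  gt <- ifelse(f > het_band[2L], "hom_alt",
               ifelse(f >= het_band[1L], "het", NA_character_))
  ok <- d >= min_depth & !is.na(gt)
  if (!any(ok)) return(empty)
  out <- data.frame(contig = nr$contig[ok], pos = nr$pos0[ok],
                    ref = nr$refbase[ok], alt = nr$nucleotide[ok],
                    genotype = gt[ok], depth = as.integer(d[ok]),
                    alt_count = as.integer(nr$count[ok]),
                    alt_fraction = f[ok], stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Vectorised single-base lookup in a DNAStringSet, 0-based positions.
reference_base <- function(ref, contig, pos0) {
  out <- character(length(contig))
  for (ctg in unique(contig)) {
    i <- contig == ctg
    out[i] <- as.character(Biostrings::extractAt(
      ref[[ctg]], IRanges::IRanges(start = pos0[i] + 1L, width = 1L)
    ))
  }
  out
}

#' Summarise a truth comparison
#'
#' `recall = tp / (tp + fn)`, `precision = tp / (tp + fp)` and the
#' F-measure is their harmonic mean `2 P R / (P + R)`; each is `NA` when
#' its denominator is zero.
#'
#' @param tp,fp,fn counts.
#' @return a `benchmark_summary` object.
#' @export
benchmark_summary <- function(tp, fp, fn) {
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         recall = recall, precision = precision,
         f_measure = f_measure(precision, recall)),
    class = "benchmark_summary"
  )
}

#' Harmonic-mean F-measure from precision and recall
#' @param precision,recall numeric (vectors recycle).
#' @return `2 * precision * recall / (precision + recall)`; `NA` when the
#'   denominator is zero or either input is `NA`.
#' @export
f_measure <- function(precision, recall) {
  ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
         2 * precision * recall / (precision + recall), NA_real_)
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("benchmark: TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  recall %.4f  precision %.4f  F-measure %.4f\n",
              x$recall, x$precision, x$f_measure))
  invisible(x)
}

normalize_callset <- function(x) {
  data.frame(contig = as.character(x$contig), pos = as.integer(x$pos),
             ref = toupper(as.character(x$ref)),
             alt = toupper(as.character(x$alt)),
             genotype = as.character(x$genotype), stringsAsFactors = FALSE)
}

#' Compare SNV calls against a truth set
#'
#' Exact-genotype matching: a truth record is a true positive when a call
#' matches its contig, position, reference allele, alternate allele, and
#' genotype; unmatched truth records are false negatives, unmatched calls
#' false positives. A genotype mismatch at the same site therefore counts
#' as one FP plus one FN (the conservative convention). Both sets are
#' restricted to the confident regions before matching; multiallelic truth
#' records are skipped and counted. This is a deliberately strict
#' comparator: no haplotype-aware rescue or allele decomposition.
#'
#' @param calls call data frame (`contig, pos` 0-based, `ref, alt,
#'   genotype`) or a VCF path.
#' @param truth truth data frame in the same shape, or a VCF path.
#' @param confident [genomic_intervals()] confining the comparison; `NULL`
#'   compares everywhere.
#' @return a [benchmark_summary()] with an extra `n_multiallelic_skipped`
#'   field.
#' @export
compare_to_truth <- function(calls, truth, confident = NULL) {
  if (is.character(calls)) calls <- read_vcf_calls(calls)
  if (is.character(truth)) truth <- read_vcf_calls(truth)
  skipped <- 0L
  multi <- grepl(",", truth$alt %||% character(0))
  if (any(multi)) {
    skipped <- sum(multi)
    truth <- truth[!multi, , drop = FALSE]
  }
  calls <- normalize_callset(calls)
  truth <- normalize_callset(truth)
  snv <- nchar(truth$ref) == 1L & nchar(truth$alt) == 1L
  truth <- truth[snv, , drop = FALSE]
  if (!is.null(confident)) {
    confident <- as_genomic_intervals(confident)
    keep_in <- function(x) {
      if (nrow(x) == 0L) return(x)
      iv <- genomic_intervals(x$contig, x$pos, x$pos + 1L)
      x[overlaps_any(iv, confident), , drop = FALSE]
    }
    calls <- keep_in(calls)
    truth <- keep_in(truth)
  }
  keyc <- paste(calls$contig, calls$pos, calls$ref, calls$alt, calls$genotype)
  keyt <- paste(truth$contig, truth$pos, truth$ref, truth$alt, truth$genotype)
  tp <- sum(keyt %in% keyc)
  fn <- nrow(truth) - tp
  fp <- nrow(calls) - sum(keyc %in% keyt)
  out <- benchmark_summary(tp, fp, fn)
  out$n_multiallelic_skipped <- skipped
  out
}

GT_CODE <- c(het = "0/1", hom_alt = "1/1", hom_ref = "0/0")

#' Write SNV calls as a VCF (4.2, GT:DP)
#'
#' Positions convert from the package's 0-based convention to VCF 1-based
#' on output. For multi-sample output, pass a named list of call frames;
#' sites absent from a sample are written as `0/0` with missing depth.
#'
#' @param calls a call data frame, or a named list of them (one per
#'   sample).
#' @param path output path.
#' @param contig_lengths named integer vector for `##contig` header lines.
#' @param sample sample name for single-sample output.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, contig_lengths = NULL, sample = "sample1") {
  if (is.data.frame(calls)) {
    samples <- stats::setNames(list(calls), sample)
  } else {
    samples <- calls
    stopifnot(!is.null(names(samples)))
  }
  sites <- unique(do.call(rbind, lapply(samples, function(s) {
    normalize_callset(s)[, c("contig", "pos", "ref", "alt")]
  })))
  sites <- sites[order(sites$contig, sites$pos, sites$alt), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(samples)), collapse = "\t")
  )
  body <- character(nrow(sites))
  keyfun <- function(x) paste(x$contig, x$pos, x$ref, x$alt)
  site_key <- keyfun(sites)
  persample <- lapply(samples, function(s) {
    ns <- normalize_callset(s)
    ns$depth <- s$depth %||% rep(NA_integer_, nrow(ns))
    ns$key <- keyfun(ns)
    ns
  })
  for (i in seq_len(nrow(sites))) {
    cells <- vapply(persample, function(s) {
      j <- match(site_key[i], s$key)
      if (is.na(j)) "0/0:." else {
        dp <- s$depth[j]
        paste0(GT_CODE[[s$genotype[j]]], ":", if (is.na(dp)) "." else dp)
      }
    }, character(1))
    body[i] <- paste(c(sites$contig[i], sites$pos[i] + 1L, ".", sites$ref[i],
                       sites$alt[i], ".", "PASS", ".", "GT:DP", cells),
                     collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read SNV calls from a (single-sample) VCF
#'
#' Uses VariantAnnotation; returns the package-internal call shape with
#' 0-based positions. Genotypes map `0/1` and `1/0` to `"het"`, `1/1` to
#' `"hom_alt"`, `0/0` to `"hom_ref"`. Multiallelic ALT fields are kept
#' verbatim (comma-joined) so that [compare_to_truth()] can count and skip
#' them.
#'
#' @param path VCF path.
#' @param sample sample name or index (default: first).
#' @return call data frame with `contig, pos, ref, alt, genotype, depth`.
#' @export
read_vcf_calls <- function(path, sample = 1L) {
  gt <- read_vcf_genotypes(path)
  samples <- unique(gt$sample)
  pick <- if (is.numeric(sample)) samples[sample] else sample
  gt <- gt[gt$sample == pick, , drop = FALSE]
  code <- c("0/0" = "hom_ref", "0/1" = "het", "1/0" = "het", "1/1" = "hom_alt")
  norm <- gsub("\\|", "/", gt$gt)
  data.frame(contig = gt$contig, pos = gt$pos, ref = gt$ref, alt = gt$alt,
             genotype = unname(code[norm]),
             depth = suppressWarnings(as.integer(gt$dp)),
             stringsAsFactors = FALSE)
}

#' Read per-sample genotypes from a VCF into a long data frame
#'
#' @param path VCF path.
#' @return data frame `contig, pos` (0-based), `ref, alt, sample, gt, dp`.
#' @export
read_vcf_genotypes <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  n <- nrow(v)
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      sample = character(0), gt = character(0),
                      dp = integer(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- vapply(as.list(rr$ALT), function(a) {
    paste(as.character(a), collapse = ",")
  }, character(1))
  gtm <- VariantAnnotation::geno(v)$GT
  dpm <- if ("DP" %in% names(VariantAnnotation::geno(v))) {
    VariantAnnotation::geno(v)$DP
  } else matrix(NA_integer_, nrow = n, ncol = ncol(gtm))
  samples <- colnames(gtm)
  do.call(rbind, lapply(seq_along(samples), function(j) {
    data.frame(
      contig = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr) - 1L,
      ref = as.character(rr$REF), alt = alt,
      sample = samples[j], gt = as.character(gtm[, j]),
      dp = suppressWarnings(as.integer(dpm[, j])),
      stringsAsFactors = FALSE
    )
  }))
}
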