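#' Per-region mapping-quality summary
#'
#' Statistics are computed over records passing the same exclusion mask as
#' extraction (2316); a record is counted once per region it overlaps, so a
#' read spanning two regions contributes to both.
#'
#' MAPQ 0 conventionally marks reads with multiple equally good placements;
#' the fraction of MAPQ-0 records is the direct signature of a false
#' duplication (reads split between the copies), and its disappearance
#' after masking is the signature of a successful fix. For an
#' [error_region_set()], each region is summarised over its full affected
#' span -- the target plus any extra-copy (mask) intervals -- because the
#' tied reads of a false duplication are spread across both copies; after
#' masking, the extra copy holds no records and the summary collapses onto
#' the kept copy.
#'
#' @param bam indexed BAM.
#' @param regions an [error_region_set()] (summarised over target + masks)
#'   or labelled [genomic_intervals()] (used as given).
#' @return a data frame with one row per region: `label, n_records,
#'   mean_mapq, n_mapq0, frac_mapq0` (`NA` summaries for empty regions).
#' @export
mapq_summary <- function(bam, regions) {
  tg <- if (inherits(regions, "error_region_set")) {
    spans <- lapply(regions, function(r) {
      iv <- normalize_intervals(rbind_intervals(r$target, r$mask_intervals))
      iv$label <- r$label
      iv
    })
    do.call(rbind_intervals, spans)
  } else as_genomic_intervals(regions)
  empty <- data.frame(label = character(0), n_records = integer(0),
                      mean_mapq = numeric(0), n_mapq0 = integer(0),
                      frac_mapq0 = numeric(0), stringsAsFactors = FALSE)
  if (nrow(tg) == 0L) return(empty)
  labels <- unique(tg$label)
  rows <- lapply(labels, function(lb) {
    iv <- tg[which(tg$label %in% lb), , drop = FALSE]
    rec <- read_alignments(bam, which = iv, apply_mask = TRUE)
    n <- nrow(rec)
    data.frame(
      label = lb,
      n_records = n,
      mean_mapq = if (n) mean(rec$mapq) else NA_real_,
      n_mapq0 = sum(rec$mapq == 0L),
      frac_mapq0 = if (n) mean(rec$mapq == 0L) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Mean per-position pileup depth over a set of intervals, counting records
# that pass the exclusion mask (duplicates retained unless asked otherwise).
mean_depth_over <- function(bam, intervals, exclude_duplicates = FALSE) {
  intervals <- normalize_intervals(as_genomic_intervals(intervals))
  if (nrow(intervals) == 0L) return(NA_real_)
  len <- bam_seqlengths(bam)
  intervals <- intervals[intervals$contig %in% names(len), , drop = FALSE]
  if (nrow(intervals) == 0L) return(NA_real_)
  intervals$end <- pmin(intervals$end, as.integer(len[intervals$contig]))
  flag <- if (exclude_duplicates) {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
                           isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE,
                           isDuplicate = FALSE)
  } else exclusion_scan_flag()
  gr <- intervals_to_granges(intervals, seqlengths = len)
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(flag = flag, which = gr),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 100000L, min_base_quality = 0L, min_mapq = 0L,
      min_nucleotide_depth = 1L, distinguish_strands = FALSE,
      distinguish_nucleotides = FALSE, include_deletions = FALSE,
      include_insertions = FALSE
    )
  )
  total <- sum(as.numeric(p$count))
  total / sum(intervals$end - intervals$start)
}

#' Per-region depth summary against a baseline
#'
#' Mean depth is the per-position pileup depth summed over the region
#' divided by the region length, over records passing the exclusion mask.
#' The baseline is computed identically over baseline intervals (which must
#' be disjoint from the error regions); `depth_ratio = mean_depth /
#' baseline_mean_depth`. A ratio near 0.5 over a target flags a false
#' duplication (reads split across two copies); a ratio near 2 flags a
#' collapse (reads from two paralogs piled on one copy); a ratio near 1
#' after re-alignment confirms the fix.
#'
#' @param bam indexed BAM.
#' @param regions an [error_region_set()] or labelled [genomic_intervals()].
#' @param baseline [genomic_intervals()] of unaffected sequence.
#' @param exclude_duplicates drop duplicate-flagged records (default keeps
#'   them, consistent with the extraction mask).
#' @return a data frame `label, mean_depth, baseline_mean_depth,
#'   depth_ratio`.
#' @export
depth_summary <- function(bam, regions, baseline, exclude_duplicates = FALSE) {
  tg <- if (inherits(regions, "error_region_set")) region_targets(regions)
        else as_genomic_intervals(regions)
  baseline <- as_genomic_intervals(baseline)
  if (interval_bases(baseline) == 0L) {
    stop_validation("depth_summary: baseline intervals are empty")
  }
  if (nrow(tg) && any(overlaps_any(baseline, tg))) {
    stop_validation("depth_summary: baseline intervals overlap the regions")
  }
  empty <- data.frame(label = character(0), mean_depth = numeric(0),
                      baseline_mean_depth = numeric(0),
                      depth_ratio = numeric(0), stringsAsFactors = FALSE)
  if (nrow(tg) == 0L) return(empty)
  base_mean <- mean_depth_over(bam, baseline, exclude_duplicates)
  rows <- lapply(seq_len(nrow(tg)), function(i) {
    md <- mean_depth_over(bam, tg[i, , drop = FALSE], exclude_duplicates)
    data.frame(label = tg$label[i] %||% NA_character_, mean_depth = md,
               baseline_mean_depth = base_mean,
               depth_ratio = if (!is.na(base_mean) && base_mean > 0)
                 md / base_mean else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inbreeding coefficient from biallelic genotype counts
#'
#' The plain single-population estimator: with allele frequency
#' `p = (2 n_AA + n_Aa) / 2n`, observed heterozygosity `H_obs = n_Aa / n`
#' and expected heterozygosity `H_exp = 2 p (1 - p)`,
#' `F = 1 - H_obs / H_exp`. Positive F flags heterozygote deficiency (the
#' false-duplication signature: alt-carrying reads defect to the extra
#' copy); negative F flags heterozygote excess (the collapse signature:
#' paralogous sequence variants masquerade as ~50% allele-fraction
#' heterozygotes in every sample). `F` is `NA` when `H_exp = 0`
#' (monomorphic) or no genotypes are called. No small-sample or
#' population-structure correction is applied.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectors recycle).
#' @return numeric vector of F in `[-1, 1]` (or `NA`).
#' @examples
#' inbreeding_coefficient(25, 50, 25) # 0: exact Hardy-Weinberg proportions
#' inbreeding_coefficient(0, 10, 0)   # -1: maximal heterozygote excess
#' @export
inbreeding_coefficient <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- ifelse(n > 0, (2 * n_AA + n_Aa) / (2 * n), NA_real_)
  h_obs <- ifelse(n > 0, n_Aa / n, NA_real_)
  h_exp <- 2 * p * (1 - p)
  ifelse(!is.na(h_exp) & h_exp > 0, 1 - h_obs / h_exp, NA_real_)
}

#' Per-variant cohort statistics from a multi-sample VCF
#'
#' For every biallelic site with per-sample `GT` (and optionally `DP`),
#' computes the mean depth across called samples and the inbreeding
#' coefficient, then groups sites into region classes (each error region's
#' label via target overlap, `"rest"` elsewhere) and summarises each class
#' Tukey-style: mean, quartiles, and min/max within 1.5 IQR of the
#' quartiles. Sites without `DP` are skipped for depth but kept for F.
#'
#' @param vcf path to a VCF (4.x, `GT` required) or a data frame as
#'   returned by [read_vcf_genotypes()].
#' @param regions an [error_region_set()] (or labelled intervals).
#' @return a list with `per_site` (site-level data frame: contig, pos,
#'   class, mean_depth, F) and `summary` (one row per class and metric).
#' @export
cohort_site_stats <- function(vcf, regions) {
  gt <- if (is.character(vcf)) read_vcf_genotypes(vcf) else vcf
  tg <- if (inherits(regions, "error_region_set")) region_targets(regions)
        else as_genomic_intervals(regions)
  per_site <- do.call(rbind, lapply(split(gt, list(gt$contig, gt$pos), drop = TRUE),
                                    function(site) {
    counts <- genotype_counts(site$gt)
    dp <- suppressWarnings(as.numeric(site$dp))
    data.frame(
      contig = site$contig[1L], pos = site$pos[1L],
      mean_depth = if (all(is.na(dp))) NA_real_ else mean(dp, na.rm = TRUE),
      f = inbreeding_coefficient(counts["hom_ref"], counts["het"],
                                 counts["hom_alt"]),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(per_site)) {
    per_site <- data.frame(contig = character(0), pos = integer(0),
                           mean_depth = numeric(0), f = numeric(0))
  }
  rownames(per_site) <- NULL
  per_site$class <- "rest"
  if (nrow(tg) && nrow(per_site)) {
    site_iv <- genomic_intervals(per_site$contig, per_site$pos,
                                 per_site$pos + 1L)
    for (i in seq_len(nrow(tg))) {
      hit <- overlaps_any(site_iv, tg[i, , drop = FALSE])
      per_site$class[hit] <- tg$label[i] %||% "region"
    }
  }
  per_site <- per_site[order(per_site$contig, per_site$pos), , drop = FALSE]
  rownames(per_site) <- NULL
  summ <- do.call(rbind, lapply(split(per_site, per_site$class), function(cl) {
    rbind(summarise_metric(cl$class[1L], "mean_depth", cl$mean_depth),
          summarise_metric(cl$class[1L], "F", cl$f))
  }))
  rownames(summ) <- NULL
  list(per_site = per_site, summary = summ)
}

summarise_metric <- function(class, metric, x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(data.frame(class = class, metric = metric, n = 0L,
                      mean = NA_real_, q1 = NA_real_, median = NA_real_,
                      q3 = NA_real_, whisker_lo = NA_real_,
                      whisker_hi = NA_real_, stringsAsFactors = FALSE))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  inlo <- x[x >= q[1L] - 1.5 * iqr]
  inhi <- x[x <= q[3L] + 1.5 * iqr]
  data.frame(class = class, metric = metric, n = length(x), mean = mean(x),
             q1 = q[1L], median = q[2L], q3 = q[3L],
             whisker_lo = min(inlo), whisker_hi = max(inhi),
             stringsAsFactors = FALSE)
}

genotype_counts <- function(gt) {
  gt <- gsub("\\|", "/", gt)
  gt[gt %in% c("1/0")] <- "0/1"
  c(hom_ref = sum(gt == "0/0", na.rm = TRUE),
    het = sum(gt == "0/1", na.rm = TRUE),
    hom_alt = sum(gt == "1/1", na.rm = TRUE))
}

#' Full per-region diagnostic report
#'
#' Combines [mapq_summary()] and [depth_summary()] (and, when a cohort VCF
#' is given, the median per-site inbreeding coefficient within each region)
#' into one table -- the per-region record used to detect reference errors
#' and to confirm fixes.
#'
#' @inheritParams depth_summary
#' @param vcf optional multi-sample VCF path or genotype data frame.
#' @return a data frame, one row per region.
#' @export
region_diagnostics <- function(bam, regions, baseline, vcf = NULL) {
  mq <- mapq_summary(bam, regions)
  dp <- depth_summary(bam, regions, baseline)
  out <- merge(mq, dp, by = "label", sort = FALSE)
  out$median_F <- NA_real_
  if (!is.null(vcf)) {
    cs <- cohort_site_stats(vcf, regions)
    med <- tapply(cs$per_site$f, cs$per_site$class, stats::median, na.rm = TRUE)
    hit <- match(out$label, names(med))
    out$median_F <- as.numeric(med[hit])
  }
  out
}
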