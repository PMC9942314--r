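REGION_KINDS <- c("FALSE_DUPLICATION", "COLLAPSED")

#' Describe one reference-error region
#'
#' An error region couples the interval where corrected variant calling is
#' desired (`target`) with the reference edit that fixes it and with the
#' intervals from which affected reads must be gathered.
#'
#' * `FALSE_DUPLICATION`: the reference carries one or more extra,
#'   near-identical copies of the target locus; `mask_intervals` lists the
#'   extra copies to hard-mask.
#' * `COLLAPSED`: two real paralogs are represented by a single reference
#'   copy; `decoy_names` lists the decoy contig(s) carrying the missing
#'   paralog.
#'
#' `homolog_intervals` always contains at least the target and all mask
#' intervals; reads overlapping any homolog interval are re-aligned.
#'
#' @param kind `"FALSE_DUPLICATION"` or `"COLLAPSED"`.
#' @param target single-row [genomic_intervals()]: where fixed calls are
#'   wanted.
#' @param mask_intervals intervals of the extra copies
#'   (`FALSE_DUPLICATION` only).
#' @param decoy_names names of decoy contigs (`COLLAPSED` only).
#' @param homolog_intervals intervals homologous to the target from which
#'   reads are collected; the target and mask intervals are added
#'   automatically.
#' @param label region name; defaults to the target's label.
#' @return an `error_region` object.
#' @export
error_region <- function(kind, target, mask_intervals = NULL,
                         decoy_names = character(),
                         homolog_intervals = NULL, label = NULL) {
  kind <- match.arg(kind, REGION_KINDS)
  target <- as_genomic_intervals(target)
  if (nrow(target) != 1L) {
    stop_validation("error_region: target must be a single interval")
  }
  label <- label %||% target$label
  if (is.na(label) || !nzchar(label)) {
    label <- sprintf("%s:%d-%d", target$contig, target$start, target$end)
  }
  mask_intervals <- if (is.null(mask_intervals)) genomic_intervals() else
    normalize_intervals(mask_intervals)
  decoy_names <- as.character(decoy_names)
  if (kind == "FALSE_DUPLICATION" && nrow(mask_intervals) == 0L) {
    stop_validation("region '", label,
                    "': FALSE_DUPLICATION requires mask intervals")
  }
  if (kind == "COLLAPSED" && nrow(mask_intervals) > 0L) {
    stop_validation("region '", label,
                    "': COLLAPSED regions must not list mask intervals")
  }
  if (kind == "COLLAPSED" && length(decoy_names) == 0L) {
    stop_validation("region '", label, "': COLLAPSED requires decoy names")
  }
  if (kind == "FALSE_DUPLICATION" && length(decoy_names) > 0L) {
    stop_validation("region '", label,
                    "': FALSE_DUPLICATION must not list decoy names")
  }
  hom <- if (is.null(homolog_intervals)) genomic_intervals() else
    as_genomic_intervals(homolog_intervals)
  hom <- normalize_intervals(rbind_intervals(hom, target, mask_intervals))
  structure(
    list(kind = kind, label = label, target = target,
         mask_intervals = mask_intervals, decoy_names = decoy_names,
         homolog_intervals = hom),
    class = "error_region"
  )
}

rbind_intervals <- function(...) {
  parts <- Filter(function(p) nrow(p) > 0L, lapply(list(...), as_genomic_intervals))
  if (length(parts) == 0L) return(genomic_intervals())
  out <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)))
  genomic_intervals(out$contig, out$start, out$end, out$label)
}

#' Bundle error regions into a set
#'
#' @param regions a list of [error_region()] objects.
#' @return an `error_region_set` object (a list with class attribute).
#' @export
error_region_set <- function(regions = list()) {
  if (inherits(regions, "error_region")) regions <- list(regions)
  ok <- vapply(regions, inherits, logical(1), what = "error_region")
  if (!all(ok)) stop_validation("error_region_set: all elements must be error_region")
  labels <- vapply(regions, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop_validation("error_region_set: duplicate region label '",
                    labels[duplicated(labels)][1L], "'")
  }
  structure(regions, names = labels, class = "error_region_set")
}

#' @export
print.error_region_set <- function(x, ...) {
  cat(sprintf("error_region_set with %d region(s)\n", length(x)))
  for (r in x) {
    cat(sprintf("  %-18s %s  target %s:%d-%d  masks:%d decoys:%d homolog bp:%d\n",
                r$kind, r$label, r$target$contig, r$target$start, r$target$end,
                nrow(r$mask_intervals), length(r$decoy_names),
                interval_bases(r$homolog_intervals)))
  }
  invisible(x)
}

#' All target intervals of a region set
#' @param regions an `error_region_set`.
#' @return a `genomic_intervals` object, one row per region, labelled by
#'   region label.
#' @export
region_targets <- function(regions) {
  if (length(regions) == 0L) return(genomic_intervals())
  tg <- do.call(rbind_intervals, lapply(regions, function(r) {
    t <- r$target
    t$label <- r$label
    t
  }))
  tg
}

#' Union of homolog intervals across a region set
#' @param regions an `error_region_set`.
#' @return normalized `genomic_intervals`.
#' @export
homolog_union <- function(regions) {
  if (length(regions) == 0L) return(genomic_intervals())
  normalize_intervals(do.call(rbind_intervals,
                              lapply(regions, `[[`, "homolog_intervals")))
}

#' Union of mask intervals across a region set
#' @param regions an `error_region_set`.
#' @return normalized `genomic_intervals`.
#' @export
mask_union <- function(regions) {
  if (length(regions) == 0L) return(genomic_intervals())
  normalize_intervals(do.call(rbind_intervals,
                              lapply(regions, `[[`, "mask_intervals")))
}

#' Read a region configuration
#'
#' The region config is a BED-derived, tab-separated file with a header line
#' and columns `contig`, `start`, `end`, `label`, `kind`, `decoy_names`
#' (comma-separated list, may be empty). Two companion BED files keyed by
#' region label supply the remaining intervals: `homologs` (read-collection
#' intervals) and `masks` (extra-copy intervals of FALSE_DUPLICATION
#' regions). `#` comment lines are ignored everywhere.
#'
#' @param path path to the region TSV.
#' @param homologs path to the homolog BED (4-column; name = region label).
#'   Defaults to `homologs.bed` next to `path`; missing file means no extra
#'   homolog intervals.
#' @param masks path to the mask BED (4-column; name = region label).
#'   Defaults to `masks.bed` next to `path`.
#' @return an [error_region_set()].
#' @export
read_region_config <- function(path,
                               homologs = file.path(dirname(path), "homologs.bed"),
                               masks = file.path(dirname(path), "masks.bed")) {
  if (!file.exists(path)) stop_validation("region config not found: ", path)
  lines <- readLines(path)
  idx <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(idx) == 0L) return(error_region_set())
  header <- strsplit(lines[idx[1L]], "\t", fixed = TRUE)[[1L]]
  wanted <- c("contig", "start", "end", "label", "kind", "decoy_names")
  if (!all(wanted %in% header)) {
    stop_validation("region config ", path, " line ", idx[1L],
                    ": header must contain columns ",
                    paste(wanted, collapse = ", "))
  }
  body <- idx[-1L]
  hom_all <- if (!is.null(homologs) && file.exists(homologs)) read_bed(homologs)
             else genomic_intervals()
  mask_all <- if (!is.null(masks) && file.exists(masks)) read_bed(masks)
              else genomic_intervals()
  regions <- vector("list", length(body))
  for (i in seq_along(body)) {
    ln <- body[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < length(header) - 1L) {   # decoy_names may be empty+trailing
      stop_validation("region config ", path, " line ", ln,
                      ": expected ", length(header), " tab-separated fields")
    }
    f <- c(f, rep("", length(header) - length(f)))
    rec <- stats::setNames(as.list(f), header)
    start <- suppressWarnings(as.integer(rec$start))
    end <- suppressWarnings(as.integer(rec$end))
    if (is.na(start) || is.na(end)) {
      stop_validation("region config ", path, " line ", ln,
                      ": non-numeric start/end")
    }
    if (!rec$kind %in% REGION_KINDS) {
      stop_validation("region config ", path, " line ", ln,
                      ": unknown kind '", rec$kind, "'")
    }
    decoys <- setdiff(trimws(strsplit(rec$decoy_names, ",", fixed = TRUE)[[1L]]), "")
    lab <- rec$label
    target <- genomic_intervals(rec$contig, start, end, lab)
    hom <- hom_all[!is.na(hom_all$label) & hom_all$label == lab, , drop = FALSE]
    msk <- mask_all[!is.na(mask_all$label) & mask_all$label == lab, , drop = FALSE]
    regions[[i]] <- error_region(
      kind = rec$kind, target = target,
      mask_intervals = if (nrow(msk)) msk else NULL,
      decoy_names = decoys,
      homolog_intervals = if (nrow(hom)) hom else NULL,
      label = lab
    )
  }
  error_region_set(regions)
}

#' Write a region configuration
#'
#' Inverse of [read_region_config()]: writes the region TSV plus the
#' companion homolog and mask BED files.
#'
#' @param regions an [error_region_set()].
#' @param path output TSV path.
#' @param homologs,masks output companion BED paths (defaults next to
#'   `path`).
#' @return `path`, invisibly.
#' @export
write_region_config <- function(regions, path,
                                homologs = file.path(dirname(path), "homologs.bed"),
                                masks = file.path(dirname(path), "masks.bed")) {
  header <- "contig\tstart\tend\tlabel\tkind\tdecoy_names"
  rows <- vapply(regions, function(r) {
    sprintf("%s\t%d\t%d\t%s\t%s\t%s", r$target$contig, r$target$start,
            r$target$end, r$label, r$kind, paste(r$decoy_names, collapse = ","))
  }, character(1))
  writeLines(c(header, rows), path)
  hom <- do.call(rbind_intervals, c(list(genomic_intervals()), lapply(regions, function(r) {
    h <- r$homolog_intervals
    if (nrow(h)) h$label <- r$label
    h
  })))
  msk <- do.call(rbind_intervals, c(list(genomic_intervals()), lapply(regions, function(r) {
    m <- r$mask_intervals
    if (nrow(m)) m$label <- r$label
    m
  })))
  write_bed(hom, homologs)
  write_bed(msk, masks)
  invisible(path)
}
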