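#' Read a multi-contig reference FASTA
#'
#' Sequences are case-folded to uppercase on read; names are truncated at the
#' first whitespace (the FASTA description is kept as an attribute-free
#' comment only).
#'
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet] with unique names.
#' @export
read_ref_fasta <- function(path) {
  if (!file.exists(path)) stop_validation("FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    stop_validation("duplicate contig name in ", path, ": ",
                    names(x)[duplicated(names(x))][1L])
  }
  Biostrings::DNAStringSet(toupper(x))
}

#' Write a reference FASTA (wrapped at 60 columns) with a .fai sidecar
#'
#' @param ref a named [Biostrings::DNAStringSet].
#' @param path output FASTA path; the index is written to `<path>.fai`.
#' @param description optional character vector of per-contig free-text
#'   descriptions (e.g. decoy provenance), appended after the contig name.
#' @return `path`, invisibly.
#' @export
write_ref_fasta <- function(ref, path, description = NULL) {
  stopifnot(!is.null(names(ref)))
  out <- ref
  if (!is.null(description)) {
    stopifnot(length(description) == length(ref))
    nm <- names(ref)
    has <- !is.na(description) & nzchar(description)
    nm[has] <- paste(nm[has], description[has])
    names(out) <- nm
  }
  Biostrings::writeXStringSet(out, path, width = 60L)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Named contig lengths of a reference
#' @param ref a named [Biostrings::DNAStringSet].
#' @return named integer vector.
#' @export
contig_lengths <- function(ref) {
  stats::setNames(Biostrings::width(ref), names(ref))
}

check_masks_in_bounds <- function(ref, masks) {
  len <- contig_lengths(ref)
  missing <- setdiff(unique(masks$contig), names(len))
  if (length(missing)) {
    stop_validation("mask interval names unknown contig: ",
                    paste(missing, collapse = ", "))
  }
  over <- masks$end > len[masks$contig]
  if (any(over)) {
    i <- which(over)[1L]
    stop_validation("mask interval ", masks$contig[i], ":", masks$start[i], "-",
                    masks$end[i], " exceeds contig length ",
                    len[masks$contig[i]])
  }
  invisible(TRUE)
}

#' Hard-mask reference intervals with N
#'
#' Replaces every base inside the mask intervals with uppercase `N`, leaving
#' contig names, order, and lengths unchanged. Hard masking (rather than
#' lowercase soft masking) is used so that aligners cannot place reads on the
#' extra copy at all: reads that were ambiguously split across a false
#' duplication collapse onto the single remaining copy.
#'
#' @param ref a named [Biostrings::DNAStringSet].
#' @param masks a [genomic_intervals()] object (0-based half-open).
#' @return a `DNAStringSet` of identical shape with masked bases.
#' @export
mask_regions <- function(ref, masks) {
  masks <- normalize_intervals(as_genomic_intervals(masks))
  if (nrow(masks) == 0L) return(ref)
  check_masks_in_bounds(ref, masks)
  out <- ref
  for (ctg in unique(masks$contig)) {
    m <- masks[masks$contig == ctg, , drop = FALSE]
    at <- IRanges::IRanges(start = m$start + 1L, end = m$end)
    i <- match(ctg, names(ref))
    out[[i]] <- Biostrings::replaceAt(
      ref[[i]], at,
      as(strrep("N", IRanges::width(at)), "DNAStringSet")
    )
  }
  out
}

#' Append decoy contigs to a reference
#'
#' @param ref a named [Biostrings::DNAStringSet].
#' @param decoys a named `DNAStringSet` (or named character vector) of decoy
#'   sequences; names must be unique and absent from `ref`.
#' @return a `DNAStringSet`: original contigs in original order, then decoys.
#' @export
append_decoys <- function(ref, decoys) {
  if (is.character(decoys)) decoys <- Biostrings::DNAStringSet(decoys)
  if (length(decoys) == 0L) return(ref)
  if (is.null(names(decoys)) || any(!nzchar(names(decoys)))) {
    stop_validation("decoys must be named")
  }
  dup <- names(decoys)[names(decoys) %in% names(ref) | duplicated(names(decoys))]
  if (length(dup)) {
    stop_validation("decoy name collides with existing contig: ", dup[1L])
  }
  c(ref, decoys)
}

#' Declare a reference patch
#'
#' A patch plan is the declarative description of a reference modification:
#' the intervals to hard-mask plus the decoy contigs to append. Mask
#' intervals are normalized (sorted, merged) on construction.
#'
#' @param base_reference_id free-text identifier of the reference the plan
#'   applies to.
#' @param masks a [genomic_intervals()] object.
#' @param decoys a named `DNAStringSet`/character vector of decoy sequences.
#' @param decoy_description optional per-decoy free-text provenance.
#' @return a `patch_plan` object.
#' @export
patch_plan <- function(base_reference_id = "", masks = genomic_intervals(),
                       decoys = Biostrings::DNAStringSet(),
                       decoy_description = NULL) {
  if (is.character(decoys)) decoys <- Biostrings::DNAStringSet(decoys)
  if (length(decoys) && (is.null(names(decoys)) || anyDuplicated(names(decoys)))) {
    stop_validation("patch_plan: decoy names must be present and unique")
  }
  structure(
    list(base_reference_id = base_reference_id,
         masks = normalize_intervals(as_genomic_intervals(masks)),
         decoys = decoys,
         decoy_description = decoy_description),
    class = "patch_plan"
  )
}

#' @export
print.patch_plan <- function(x, ...) {
  cat(sprintf("patch_plan for '%s': %d mask interval(s) (%d bp), %d decoy(s) (%d bp)\n",
              x$base_reference_id, nrow(x$masks), interval_bases(x$masks),
              length(x$decoys), sum(Biostrings::width(x$decoys))))
  invisible(x)
}

#' Apply a patch plan to a reference
#'
#' Masks first, then appends decoys. Deterministic; masking is idempotent
#' (N over N is a no-op), decoy appending is not (duplicate names are
#' rejected).
#'
#' @param ref a named [Biostrings::DNAStringSet].
#' @param plan a [patch_plan()].
#' @return the patched `DNAStringSet`.
#' @export
apply_patch <- function(ref, plan) {
  stopifnot(inherits(plan, "patch_plan"))
  append_decoys(mask_regions(ref, plan$masks), plan$decoys)
}

#' Serialize / restore a patch plan as JSON
#'
#' Decoy sequences are stored inline; plans are desk-scale objects.
#' @param plan a [patch_plan()].
#' @param path JSON path.
#' @return `path` invisibly (write) or a `patch_plan` (read).
#' @export
write_patch_plan <- function(plan, path) {
  obj <- list(
    base_reference_id = plan$base_reference_id,
    masks = as.data.frame(plan$masks),
    decoys = data.frame(
      name = if (length(plan$decoys)) names(plan$decoys) else character(0),
      sequence = as.character(plan$decoys),
      description = plan$decoy_description %||%
        rep(NA_character_, length(plan$decoys)),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_patch_plan
#' @export
read_patch_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  masks <- if (length(obj$masks)) {
    genomic_intervals(obj$masks$contig, obj$masks$start, obj$masks$end,
                      obj$masks$label %||% NA_character_)
  } else genomic_intervals()
  decoys <- if (length(obj$decoys) && length(obj$decoys$name)) {
    stats::setNames(Biostrings::DNAStringSet(obj$decoys$sequence),
                    obj$decoys$name)
  } else Biostrings::DNAStringSet()
  desc <- if (length(decoys)) obj$decoys$description else NULL
  patch_plan(obj$base_reference_id %||% "", masks, decoys, desc)
}
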