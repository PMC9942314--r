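#' Correct a BAM over the configured error regions
#'
#' The core workflow: extract the read pairs overlapping the regions'
#' homolog intervals from the original genome-wide BAM, re-align them to
#' the patched reference, and either return the regional corrected BAM
#' (default -- the fast path) or splice the corrected records back into a
#' genome-wide corrected BAM (`splice = TRUE`).
#'
#' @param bam original coordinate-sorted, indexed BAM.
#' @param regions an [error_region_set()] (or path to a region config TSV).
#' @param ref the patched reference ([Biostrings::DNAStringSet] or FASTA
#'   path) -- masked extra copies plus decoys.
#' @param backend [builtin_aligner()] or [command_aligner()].
#' @param bam_out output BAM path.
#' @param splice emit a genome-wide corrected BAM instead of the regional
#'   one.
#' @param rescue_window mate-rescue window in bp (see [pair_and_dedup()]).
#' @param seed optional integer seed; seeds R's RNG for backends with
#'   random tie-breaking. Without it a fixed default (1) is used -- never
#'   wall-clock seeding.
#' @param manifest_out optional path for a JSON run manifest.
#' @return a run manifest list (invisibly): subcommand, parameters,
#'   counters (reads selected / pairs / rescued / dropped), and output
#'   paths.
#' @export
fix_alignments <- function(bam, regions, ref, backend = builtin_aligner(),
                           bam_out, splice = FALSE, rescue_window = 1000L,
                           seed = NULL, manifest_out = NULL) {
  t0 <- Sys.time()
  set.seed(seed %||% 1L)
  if (is.character(regions)) regions <- read_region_config(regions)
  if (is.character(ref)) ref <- read_ref_fasta(ref)
  ex <- extract_reads(bam, regions, rescue_window)
  rg_lines <- grep("^@RG", bam_header_lines(bam), value = TRUE)
  regional <- if (splice) tempfile(fileext = ".bam") else bam_out
  align_pairs(ex$pairs, ref, backend, bam_out = regional, rg_lines = rg_lines)
  n_spliced <- 0L
  if (splice) {
    splice_back(bam, regional, ex$pairs$name, bam_out)
    n_spliced <- length(ex$pairs$name) * 2L
    unlink(c(regional, paste0(regional, ".bai"),
             sub("\\.bam$", ".bai", regional)))
  }
  manifest <- list(
    tool = "refix", version = as.character(utils::packageVersion("refix")),
    subcommand = "fix",
    parameters = list(bam = bam, splice = splice,
                      rescue_window = as.integer(rescue_window),
                      backend = backend$type, seed = seed %||% 1L),
    counters = c(ex$stats, list(n_records_spliced = n_spliced)),
    outputs = list(bam = bam_out),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(manifest_out)) {
    jsonlite::write_json(manifest, manifest_out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest$outputs$manifest <- manifest_out
  }
  invisible(manifest)
}

#' Patch a reference from files
#'
#' File-level wrapper over [apply_patch()]: reads the base reference, a
#' mask BED and a decoy FASTA, writes the patched FASTA with its index.
#'
#' @param ref_fasta base reference FASTA.
#' @param mask_bed BED of intervals to hard-mask (optional).
#' @param decoy_fasta FASTA of decoy contigs to append (optional).
#' @param out_fasta output path.
#' @return `out_fasta`, invisibly.
#' @export
patch_reference_files <- function(ref_fasta, mask_bed = NULL,
                                  decoy_fasta = NULL, out_fasta) {
  ref <- read_ref_fasta(ref_fasta)
  masks <- if (!is.null(mask_bed)) read_bed(mask_bed) else genomic_intervals()
  decoys <- if (!is.null(decoy_fasta)) read_ref_fasta(decoy_fasta)
            else Biostrings::DNAStringSet()
  plan <- patch_plan(basename(ref_fasta), masks, decoys)
  write_ref_fasta(apply_patch(ref, plan), out_fasta)
  invisible(out_fasta)
}
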