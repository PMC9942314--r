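#' Built-in aligner backend
#'
#' Configures the package's deterministic, test-grade paired-end mapper:
#' exact k-mer seeds (sampled every `seed_step` bases of the read), diagonal
#' candidate loci, ungapped extension scored match `+1` / mismatch `-4`, and
#' `MAPQ = min(60, 6 * (best - second best))` with `MAPQ = 0` for tied best
#' placements -- the one property downstream analysis relies on, since reads
#' split across duplicated sequence are exactly the tied ones.
#'
#' Ambiguous ties are broken deterministically (lowest contig index, then
#' lowest coordinate, then strand) unless `tie_break = "random"`, which
#' breaks each read end's unresolved tie uniformly at random using R's RNG
#' stream (seed it for reproducibility). Random placement models how an
#' aligner spreads reads across near-identical copies and is what produces
#' the characteristic half-depth signature over false duplications.
#'
#' @param k seed length (>= 11).
#' @param seed_step distance between sampled seed offsets along the read.
#' @param max_occ seeds occurring more often than this in the reference are
#'   skipped as repetitive.
#' @param min_score minimum alignment score to report a locus.
#' @param max_cand maximum candidate loci kept per read end.
#' @param insert_min,insert_max template-length window for a proper pair.
#' @param tie_break `"deterministic"` or `"random"`.
#' @return an `aligner_backend` object.
#' @export
builtin_aligner <- function(k = 21L, seed_step = 5L, max_occ = 64L,
                            min_score = 25L, max_cand = 16L,
                            insert_min = 50L, insert_max = 1000L,
                            tie_break = c("deterministic", "random")) {
  if (k < 11L) stop_validation("builtin aligner requires k >= 11")
  structure(
    list(type = "builtin", k = as.integer(k), seed_step = as.integer(seed_step),
         max_occ = as.integer(max_occ), min_score = as.integer(min_score),
         max_cand = as.integer(max_cand), match = 1L, mismatch = -4L,
         insert_min = as.integer(insert_min),
         insert_max = as.integer(insert_max),
         tie_break = match.arg(tie_break)),
    class = "aligner_backend"
  )
}

#' External command aligner backend
#'
#' Wraps any external paired-end aligner that writes SAM to standard output.
#' The template must contain the placeholders `{ref}`, `{fq1}` and `{fq2}`,
#' which are substituted verbatim; the command is executed without a shell.
#'
#' @param template command template, e.g.
#'   `"bwa mem {ref} {fq1} {fq2}"`.
#' @return an `aligner_backend` object.
#' @export
command_aligner <- function(template) {
  for (ph in c("{ref}", "{fq1}", "{fq2}")) {
    if (!grepl(ph, template, fixed = TRUE)) {
      stop_validation("aligner command template must contain placeholder ", ph)
    }
  }
  structure(list(type = "command", template = template),
            class = "aligner_backend")
}

#' Build a reusable k-mer index of a reference
#' @param ref named [Biostrings::DNAStringSet] (or path to a FASTA).
#' @param backend a [builtin_aligner()] backend.
#' @return a `mapper_index` object holding an external pointer.
#' @export
build_mapper_index <- function(ref, backend = builtin_aligner()) {
  if (is.character(ref)) ref <- read_ref_fasta(ref)
  xp <- refix_index_build(names(ref), as.character(ref), backend$k)
  structure(list(ptr = xp, contigs = names(ref),
                 lengths = contig_lengths(ref), backend = backend),
            class = "mapper_index")
}

# Map a character vector of reads; returns the raw candidate table with
# 1-based read index and contig names resolved.
map_read_batch <- function(index, reads) {
  b <- index$backend
  cand <- refix_map_batch(index$ptr, reads, b$seed_step, b$max_occ,
                          b$min_score, b$max_cand, b$match, b$mismatch)
  cand$contig <- index$contigs[cand$cid]
  cand
}

#' Map a single read with the builtin mapper
#'
#' Exposes the per-read contract of the builtin mapper: best locus, CIGAR,
#' score and MAPQ, plus the full candidate table. A read shorter than the
#' seed length is unmapped.
#'
#' @param seq a single read sequence (character).
#' @param ref named [Biostrings::DNAStringSet], FASTA path, or a prebuilt
#'   [build_mapper_index()].
#' @param backend a [builtin_aligner()].
#' @return a list with `mapped` (logical), `contig`, `pos` (0-based),
#'   `strand` (`"+"`/`"-"`), `cigar`, `score`, `mapq`, `nmis`, and
#'   `candidates` (data frame).
#' @export
builtin_map_read <- function(seq, ref, backend = builtin_aligner()) {
  index <- if (inherits(ref, "mapper_index")) ref else
    build_mapper_index(ref, backend)
  cand <- map_read_batch(index, seq)
  if (nrow(cand) == 0L) {
    return(list(mapped = FALSE, contig = NA_character_, pos = NA_integer_,
                strand = NA_character_, cigar = "*", score = NA_integer_,
                mapq = 0L, nmis = NA_integer_, candidates = cand))
  }
  best <- cand[1L, ]
  tied <- sum(cand$score == best$score) > 1L
  second <- if (nrow(cand) > 1L) max(cand$score[-1L]) else 0L
  mapq <- if (tied) 0L else min(60L, 6L * (best$score - second))
  mlen <- nchar(seq) - best$clip_left - best$clip_right
  list(mapped = TRUE, contig = best$contig, pos = as.integer(best$pos),
       strand = c("+", "-")[best$strand + 1L],
       cigar = make_cigar(best$clip_left, mlen, best$clip_right),
       score = best$score, mapq = mapq, nmis = best$nmis, candidates = cand)
}

make_cigar <- function(cl, m, cr) {
  paste0(if (cl > 0) paste0(cl, "S"), m, "M", if (cr > 0) paste0(cr, "S"))
}

# Candidate tables travel through the hot path as plain numeric matrices
# with these columns.
CAND_COLS <- c("cid", "pos", "strand", "score", "cl", "cr")

cand_matrix <- function(cand, len) {
  cbind(cid = cand$cid, pos = cand$pos, strand = cand$strand,
        score = cand$score, cl = cand$clip_left, cr = cand$clip_right)
}

# Which (i, j) candidate combinations form a proper FR pair?
compatible_combos <- function(m1, m2, len1, len2, insert_min, insert_max) {
  n1 <- nrow(m1); n2 <- nrow(m2)
  if (n1 == 0L || n2 == 0L) return(matrix(integer(0), ncol = 2L))
  i <- rep.int(seq_len(n1), n2)
  j <- rep(seq_len(n2), each = n1)
  s1 <- m1[i, 3L]; s2 <- m2[j, 3L]
  same <- m1[i, 1L] == m2[j, 1L] & s1 != s2
  span1 <- len1 - m1[i, 5L] - m1[i, 6L]
  span2 <- len2 - m2[j, 5L] - m2[j, 6L]
  fwd1 <- s1 == 0
  fpos <- ifelse(fwd1, m1[i, 2L], m2[j, 2L])
  rpos <- ifelse(fwd1, m2[j, 2L], m1[i, 2L])
  rspan <- ifelse(fwd1, span2, span1)
  tlen <- (rpos + rspan) - fpos
  ok <- same & fpos <= rpos & tlen >= insert_min & tlen <= insert_max
  cbind(i[ok], j[ok])
}

choose_from <- function(scores, allowed, random_ties) {
  sc <- scores[allowed]
  mx <- max(sc)
  top <- allowed[sc == mx]
  chosen <- if (length(top) > 1L && random_ties) {
    top[sample.int(length(top), 1L)]
  } else top[1L]
  if (length(top) > 1L) {
    mapq <- 0L
  } else {
    others_max <- if (length(allowed) == 1L) 0 else max(sc[allowed != chosen])
    mapq <- min(60L, as.integer(6 * (mx - others_max)))
  }
  list(row = chosen, mapq = mapq)
}

# Core placement logic shared by pair_rescue() and the batch path.
place_pair_core <- function(m1, m2, len1, len2, insert_min, insert_max,
                            move_tol, random_ties) {
  n1 <- nrow(m1); n2 <- nrow(m2)
  combos <- compatible_combos(m1, m2, len1, len2, insert_min, insert_max)
  allowed1 <- seq_len(n1)
  allowed2 <- seq_len(n2)
  if (nrow(combos) > 0L) {
    comp1 <- unique(combos[, 1L])
    comp2 <- unique(combos[, 2L])
    if (max(m1[comp1, 4L]) >= max(m1[, 4L]) - move_tol) allowed1 <- sort(comp1)
    if (max(m2[comp2, 4L]) >= max(m2[, 4L]) - move_tol) allowed2 <- sort(comp2)
  }
  p1 <- if (n1 > 0L) choose_from(m1[, 4L], allowed1, random_ties) else NULL
  p2 <- if (n2 > 0L) choose_from(m2[, 4L], allowed2, random_ties) else NULL
  proper <- FALSE
  if (!is.null(p1) && !is.null(p2) && nrow(combos) > 0L) {
    proper <- any(combos[, 1L] == p1$row & combos[, 2L] == p2$row)
  }
  list(placement1 = p1, placement2 = p2, proper = proper)
}

#' Resolve the paired placement of two mapped read ends
#'
#' Among each end's candidate loci, only candidates that can participate in
#' a proper pair (same contig, opposite strands, template length inside the
#' insert window) are retained, provided the end has such a candidate within
#' one mismatch of its individual best score -- an end whose best placement
#' is incompatible but which has a near-best compatible candidate is moved
#' to it. Each end is then placed at its highest-scoring retained candidate;
#' MAPQ is recomputed over the retained candidates only, so a tie resolved
#' by pair compatibility regains confidence while a tie between two
#' pair-compatible copies keeps MAPQ 0.
#'
#' @param cand1,cand2 candidate tables for mate 1 and mate 2 (as returned in
#'   `builtin_map_read()$candidates`, canonical order).
#' @param len1,len2 read lengths.
#' @param backend a [builtin_aligner()] (supplies insert window, tie rule).
#' @param random_ties override the backend tie rule (logical).
#' @return a list with `placement1`, `placement2` (row index into the
#'   candidate tables, `NA` if unmapped, plus `mapq`) and `proper`
#'   (logical).
#' @export
pair_rescue <- function(cand1, cand2, len1, len2,
                        backend = builtin_aligner(),
                        random_ties = identical(backend$tie_break, "random")) {
  move_tol <- backend$match - backend$mismatch # one mismatch worth of score
  if (nrow(cand1) == 0L && nrow(cand2) == 0L) {
    return(list(placement1 = NULL, placement2 = NULL, proper = FALSE))
  }
  place_pair_core(cand_matrix(cand1), cand_matrix(cand2), len1, len2,
                  backend$insert_min, backend$insert_max, move_tol,
                  random_ties)
}

#' Re-align read pairs to a (patched) reference
#'
#' Maps every pair with the configured backend and writes a
#' coordinate-sorted, indexed BAM whose header lists the full patched
#' reference (including decoys) and the supplied read groups. Every input
#' pair appears in the output, mapped or unmapped.
#'
#' @param pairs a read-pair data frame (`name, seq1, qual1, seq2, qual2,
#'   rg`), e.g. from [extract_reads()] or [read_fastq_pairs()].
#' @param ref named [Biostrings::DNAStringSet] or FASTA path -- the patched
#'   reference.
#' @param backend [builtin_aligner()] or [command_aligner()].
#' @param bam_out output BAM path.
#' @param rg_lines optional character vector of `@RG` header lines to carry
#'   over from the original alignment file.
#' @return `bam_out`, invisibly.
#' @export
align_pairs <- function(pairs, ref, backend = builtin_aligner(),
                        bam_out = tempfile(fileext = ".bam"),
                        rg_lines = NULL) {
  if (is.character(ref)) ref <- read_ref_fasta(ref)
  if (is.null(rg_lines)) {
    ids <- unique(pairs$rg[!is.na(pairs$rg) & nzchar(pairs$rg)])
    rg_lines <- if (length(ids)) sprintf("@RG\tID:%s", ids) else character(0)
  }
  header <- c(sam_header_for_ref(ref, rg_lines),
              "@PG\tID:refix\tPN:refix")
  if (identical(backend$type, "command")) {
    return(align_pairs_command(pairs, ref, backend, bam_out, header))
  }
  index <- build_mapper_index(ref, backend)
  aln <- map_pairs_frame(pairs, index, backend)
  write_bam(aln, header, bam_out)
  invisible(bam_out)
}

# Core batch mapping: returns an alignment data frame for all pairs.
map_pairs_frame <- function(pairs, index, backend) {
  n <- nrow(pairs)
  if (n == 0L) return(empty_alignments())
  random_ties <- identical(backend$tie_break, "random")
  move_tol <- backend$match - backend$mismatch
  cand1 <- map_read_batch(index, pairs$seq1)
  cand2 <- map_read_batch(index, pairs$seq2)
  m1_all <- cand_matrix(cand1)
  m2_all <- cand_matrix(cand2)
  by1 <- split(seq_len(nrow(cand1)), factor(cand1$read, levels = seq_len(n)))
  by2 <- split(seq_len(nrow(cand2)), factor(cand2$read, levels = seq_len(n)))
  len1 <- nchar(pairs$seq1)
  len2 <- nchar(pairs$seq2)

  # chosen global candidate row (NA = unmapped), mapq, proper flag per pair
  pick1 <- rep(NA_integer_, n); mapq1 <- integer(n)
  pick2 <- rep(NA_integer_, n); mapq2 <- integer(n)
  proper <- logical(n)
  for (i in seq_len(n)) {
    r1 <- by1[[i]]; r2 <- by2[[i]]
    if (length(r1) == 0L && length(r2) == 0L) next
    res <- place_pair_core(m1_all[r1, , drop = FALSE],
                           m2_all[r2, , drop = FALSE],
                           len1[i], len2[i], backend$insert_min,
                           backend$insert_max, move_tol, random_ties)
    if (!is.null(res$placement1)) {
      pick1[i] <- r1[res$placement1$row]
      mapq1[i] <- res$placement1$mapq
    }
    if (!is.null(res$placement2)) {
      pick2[i] <- r2[res$placement2$row]
      mapq2[i] <- res$placement2$mapq
    }
    proper[i] <- res$proper
  }
  rec1 <- assemble_mate(pairs$name, pairs$seq1, pairs$qual1, cand1, pick1,
                        mapq1, len1, first = TRUE)
  rec2 <- assemble_mate(pairs$name, pairs$seq2, pairs$qual2, cand2, pick2,
                        mapq2, len2, first = FALSE)
  cross_link_mates(rec1, rec2, proper, pairs$rg)
}

# Vectorised construction of one mate's records for all pairs.
assemble_mate <- function(name, seq, qual, cand, pick, mapq, len, first) {
  n <- length(name)
  mapped <- !is.na(pick)
  flag <- rep(FLAG_PAIRED + if (first) FLAG_FIRST else FLAG_SECOND, n)
  rname <- rep(NA_character_, n)
  pos <- rep(NA_integer_, n)
  cigar <- rep("*", n)
  span <- rep(NA_integer_, n)
  nm <- rep(NA_integer_, n)
  oseq <- seq
  oqual <- qual
  if (any(mapped)) {
    cc <- cand[pick[mapped], , drop = FALSE]
    rev <- cc$strand == 1L
    rname[mapped] <- cc$contig
    pos[mapped] <- as.integer(cc$pos + cc$clip_left)
    mlen <- len[mapped] - cc$clip_left - cc$clip_right
    cigar[mapped] <- paste0(ifelse(cc$clip_left > 0,
                                   paste0(cc$clip_left, "S"), ""),
                            mlen, "M",
                            ifelse(cc$clip_right > 0,
                                   paste0(cc$clip_right, "S"), ""))
    span[mapped] <- mlen
    nm[mapped] <- cc$nmis
    idx <- which(mapped)[rev]
    if (length(idx)) {
      oseq[idx] <- revcomp_chr(seq[idx])
      oqual[idx] <- vapply(qual[idx], function(q) {
        paste(rev(strsplit(q, "", fixed = TRUE)[[1L]]), collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    flag[mapped] <- flag[mapped] + ifelse(rev, FLAG_REVERSE, 0L)
  }
  flag[!mapped] <- flag[!mapped] + FLAG_UNMAPPED
  mapq[!mapped] <- 0L
  list(qname = name, flag = flag, rname = rname, pos = pos, mapq = mapq,
       cigar = cigar, seq = oseq, qual = oqual, span = span, nm = nm,
       mapped = mapped)
}

cross_link_mates <- function(r1, r2, proper, rg) {
  n <- length(r1$qname)
  f1 <- r1$flag; f2 <- r2$flag
  f1 <- f1 + ifelse(!r2$mapped, FLAG_MATE_UNMAPPED, 0L) +
    ifelse(r2$mapped & flag_test(r2$flag, FLAG_REVERSE), FLAG_MATE_REVERSE, 0L) +
    ifelse(proper, FLAG_PROPER, 0L)
  f2 <- f2 + ifelse(!r1$mapped, FLAG_MATE_UNMAPPED, 0L) +
    ifelse(r1$mapped & flag_test(r1$flag, FLAG_REVERSE), FLAG_MATE_REVERSE, 0L) +
    ifelse(proper, FLAG_PROPER, 0L)
  # SAM convention: an unmapped mate sits at its partner's coordinate
  o1 <- !r1$mapped & r2$mapped
  r1$rname[o1] <- r2$rname[o1]; r1$pos[o1] <- r2$pos[o1]
  o2 <- !r2$mapped & r1$mapped
  r2$rname[o2] <- r1$rname[o2]; r2$pos[o2] <- r1$pos[o2]
  both <- r1$mapped & r2$mapped & r1$rname == r2$rname
  tl <- rep(0L, n)
  tl[both] <- pmax(r1$pos[both] + r1$span[both], r2$pos[both] + r2$span[both]) -
    pmin(r1$pos[both], r2$pos[both])
  first_left <- both & (r1$pos <= r2$pos)
  isize1 <- ifelse(both, ifelse(first_left, tl, -tl), 0L)
  isize2 <- ifelse(both, ifelse(first_left, -tl, tl), 0L)
  out <- data.frame(
    qname = c(r1$qname, r2$qname), flag = c(f1, f2),
    rname = c(r1$rname, r2$rname), pos = c(r1$pos, r2$pos),
    mapq = c(r1$mapq, r2$mapq), cigar = c(r1$cigar, r2$cigar),
    mrnm = c(r2$rname, r1$rname), mpos = c(r2$pos, r1$pos),
    isize = c(isize1, isize2), seq = c(r1$seq, r2$seq),
    qual = c(r1$qual, r2$qual), rg = c(rg, rg), nm = c(r1$nm, r2$nm),
    stringsAsFactors = FALSE
  )
  # interleave mate1/mate2 per pair for readability of the SAM
  ord <- as.vector(rbind(seq_len(n), seq_len(n) + n))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

align_pairs_command <- function(pairs, ref, backend, bam_out, header) {
  tmp <- tempfile()
  fq1 <- paste0(tmp, "_R1.fastq")
  fq2 <- paste0(tmp, "_R2.fastq")
  fa <- paste0(tmp, "_ref.fasta")
  on.exit(unlink(c(fq1, fq2, fa, paste0(fa, ".fai"))), add = TRUE)
  pairs_to_fastq(pairs, fq1, fq2)
  write_ref_fasta(ref, fa)
  words <- strsplit(backend$template, " +")[[1L]]
  words[words == "{ref}"] <- fa
  words[words == "{fq1}"] <- fq1
  words[words == "{fq2}"] <- fq2
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  status <- suppressWarnings(
    system2(words[1L], words[-1L], stdout = sam, stderr = TRUE)
  )
  err <- attr(status, "status")
  if (!is.null(err) && err != 0L) {
    stop_backend("aligner command failed (exit ", err, "): ",
                 paste(utils::tail(status, 5L), collapse = " | "))
  }
  lines <- readLines(sam)
  body <- lines[!sam_is_header(lines)]
  sq <- lines[startsWith(lines, "@SQ")]
  # header/reference consistency check
  got <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  if (!all(got %in% names(ref))) {
    stop_backend("aligner header lists contigs absent from the reference: ",
                 paste(setdiff(got, names(ref)), collapse = ", "))
  }
  sam2 <- tempfile(fileext = ".sam")
  on.exit(unlink(sam2), add = TRUE)
  writeLines(c(header, body), sam2)
  Rsamtools::asBam(sam2, sub("\\.bam$", "", bam_out), overwrite = TRUE,
                   indexDestination = TRUE)
  invisible(bam_out)
}

#' Splice corrected regional alignments back into a genome-wide BAM
#'
#' Removes every record -- primary, secondary or supplementary -- whose read
#' name belongs to the extracted set, then adds all corrected records and
#' re-sorts. Removal is by read name across the whole file (not by region)
#' so no orphaned supplementary records survive. The output header is the
#' corrected file's (patched-reference) header with the original `@RG`
#' lines merged in. Record tags are preserved verbatim.
#'
#' @param original_bam genome-wide input BAM.
#' @param corrected_bam regional corrected BAM (from [align_pairs()]).
#' @param extracted_names character vector of read names that were
#'   extracted.
#' @param bam_out output BAM path.
#' @return `bam_out`, invisibly.
#' @export
splice_back <- function(original_bam, corrected_bam, extracted_names, bam_out) {
  olen <- bam_seqlengths(original_bam)
  clen <- bam_seqlengths(corrected_bam)
  common <- intersect(names(olen), names(clen))
  bad <- common[olen[common] != clen[common]]
  if (length(bad)) {
    stop_validation("contig length mismatch between original and corrected: ",
                    paste(bad, collapse = ", "))
  }
  if (!all(names(olen) %in% names(clen))) {
    stop_validation("corrected header is missing contigs present in the ",
                    "original: ",
                    paste(setdiff(names(olen), names(clen)), collapse = ", "))
  }
  olines <- bam_to_sam_lines(original_bam)
  clines <- bam_to_sam_lines(corrected_bam)
  ohead <- olines[sam_is_header(olines)]
  obody <- olines[!sam_is_header(olines)]
  chead <- clines[sam_is_header(clines)]
  cbody <- clines[!sam_is_header(clines)]
  qn <- sub("\t.*$", "", obody)
  keep <- !(qn %in% extracted_names)
  org <- ohead[startsWith(ohead, "@RG")]
  crg <- chead[startsWith(chead, "@RG")]
  rg <- c(crg, setdiff(org, crg))
  header <- c(chead[!startsWith(chead, "@RG")], rg)
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  writeLines(c(header, obody[keep], cbody), sam)
  Rsamtools::asBam(sam, sub("\\.bam$", "", bam_out), overwrite = TRUE,
                   indexDestination = TRUE)
  invisible(bam_out)
}
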