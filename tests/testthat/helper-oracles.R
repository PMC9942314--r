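# Brute-force oracles and toy-data builders shared across the suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Per-base boolean-array oracle: the set of covered "contig:pos" strings.
cover_bases <- function(iv) {
  if (nrow(iv) == 0L) return(character(0))
  unique(unlist(lapply(seq_len(nrow(iv)), function(i) {
    paste0(iv$contig[i], ":", seq.int(iv$start[i], iv$end[i] - 1L))
  })))
}

random_interval_set <- function(n, contigs = c("chrA", "chrB"), max_end = 10000L) {
  start <- sample.int(max_end - 2L, n, replace = TRUE) - 1L
  width <- sample.int(200L, n, replace = TRUE)
  genomic_intervals(sample(contigs, n, replace = TRUE), start,
                    pmin(start + width, max_end))
}

# Build an indexed BAM from a record data frame (pos 0-based) against
# named contig lengths.
toy_bam <- function(records, seqlengths, path = tempfile(fileext = ".bam")) {
  defaults <- list(mapq = 60L, cigar = NA_character_, mrnm = NA_character_,
                   mpos = NA_integer_, isize = 0L, seq = NA_character_,
                   qual = NA_character_, rg = NA_character_)
  for (col in names(defaults)) {
    if (is.null(records[[col]])) {
      records[[col]] <- rep_len(defaults[[col]], nrow(records))
    }
  }
  no_seq <- is.na(records$seq)
  len <- ifelse(no_seq, 100L, nchar(records$seq))
  records$seq[no_seq] <- strrep("A", 100L)
  records$qual[is.na(records$qual)] <- strrep("I", len[is.na(records$qual)])
  records$cigar[is.na(records$cigar)] <- paste0(len[is.na(records$cigar)], "M")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                      as.integer(seqlengths)))
  refix::write_bam(records, header, path)
  path
}

# Reference-span of simple CIGARs for oracle-side overlap tests.
oracle_ref_span <- function(cigar, default = 100L) {
  ifelse(is.na(cigar), default,
         vapply(cigar, function(cg) {
           ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
           if (ops[1] == -1) return(default)
           toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
           sum(vapply(toks, function(t) {
             n <- as.integer(sub("[A-Z=]$", "", t))
             op <- sub("^[0-9]+", "", t)
             if (op %in% c("M", "D", "N", "=", "X")) n else 0L
           }, integer(1)))
         }, integer(1), USE.NAMES = FALSE))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, pos0, base = NULL) {
  x <- strsplit(seq, "")[[1]]
  if (is.null(base)) {
    base <- vapply(x[pos0 + 1], function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                   character(1))
  }
  x[pos0 + 1] <- base
  paste(x, collapse = "")
}

revcomp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# Brute-force oracle: best ungapped placement of a read over every offset
# and strand of every contig (match +1 / mismatch -4, full overlap only).
oracle_best <- function(read, ref) {
  best <- list(score = -Inf, n = 0L)
  for (ctg in names(ref)) {
    s <- as.character(ref[[ctg]])
    L <- nchar(s); rl <- nchar(read)
    for (strand in 0:1) {
      q <- if (strand == 0) read else revcomp(read)
      qc <- strsplit(q, "")[[1]]
      for (off in 0:(L - rl)) {
        rc <- strsplit(substr(s, off + 1, off + rl), "")[[1]]
        mis <- sum(qc != rc)
        sc <- (rl - mis) - 4 * mis
        if (sc > best$score) {
          best <- list(score = sc, n = 1L, contig = ctg, pos = off,
                       strand = strand, nmis = mis)
        } else if (sc == best$score) {
          best$n <- best$n + 1L
        }
      }
    }
  }
  best
}
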