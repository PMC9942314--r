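`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a validation error
#'
#' Validation failures (malformed configs, violated invariants) carry the
#' condition class `refix_validation_error` so callers -- in particular the
#' command-line driver -- can map them to a dedicated exit status.
#'
#' @param ... message parts passed to [sprintf()]-free concatenation.
#' @keywords internal
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("refix_validation_error", "error")))
}

#' @rdname stop_validation
#' @keywords internal
stop_backend <- function(...) {
  stop(errorCondition(paste0(...), class = c("refix_backend_error", "error")))
}

#' Reverse-complement a character vector of DNA sequences
#' @param x character vector over A,C,G,T,N.
#' @return character vector of the same length.
#' @keywords internal
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA string(s) drawn from the current RNG stream
#' @keywords internal
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitute a base with a uniformly chosen different base. Vectorised.
other_base <- function(base) {
  alt <- c("A", "C", "G", "T")
  vapply(base, function(b) sample(setdiff(alt, b), 1L), character(1), USE.NAMES = FALSE)
}
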