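# Shared sequence helpers. All user-visible coordinates in the package are
# 1-based inclusive; any half-open arithmetic is kept local to a function.

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

is_dna <- function(x) {
  !is.na(x) & nzchar(x) & !grepl("[^ACGT]", x)
}

assert_dna <- function(x, what = "sequence") {
  bad <- which(!is_dna(x))
  if (length(bad) > 0) {
    stop(sprintf("%s %d is not a non-empty string over {A,C,G,T}: %s",
                 what, bad[1], x[bad[1]]), call. = FALSE)
  }
  invisible(x)
}

# All substrings of `seq` with lengths in [kmin, kmax], as a tibble of
# (start, length, kmer). Vectorised; returns zero rows if seq shorter
# than kmin.
substrings_in_range <- function(seq, kmin, kmax) {
  n <- nchar(seq)
  ks <- seq.int(kmin, min(kmax, n))
  if (n < kmin) {
    return(tibble(start = integer(), length = integer(), kmer = character()))
  }
  out <- lapply(ks, function(k) {
    starts <- seq_len(n - k + 1L)
    tibble(start = starts, length = k,
           kmer = substring(seq, starts, starts + k - 1L))
  })
  dplyr::bind_rows(out)
}
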