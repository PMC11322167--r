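# k-mer machinery. k-mers are encoded as base-4 integer codes (A=0, C=1,
# G=2, T=3) so set operations run on integer vectors; k <= 15 keeps codes
# below 2^31. Windows containing non-ACGT characters are dropped.

#' Encode the k-mers of a sequence as integers
#'
#' Every length-`k` window (stride `step`) of `seq` is encoded as a base-4
#' integer. Sequences are used in the orientation supplied by the caller:
#' the pipeline feeds reads and contigs in their reference-aligned
#' orientation, and no canonicalisation is applied, because haplotype
#' fingerprints are orientation-specific.
#'
#' @param seq a single character string (ACGT alphabet; other characters
#'   invalidate the windows that contain them).
#' @param k k-mer length (default 12).
#' @param step stride between consecutive windows (default 1).
#' @return integer vector of k-mer codes (possibly with duplicates);
#'   zero-length if the sequence is shorter than `k`.
#' @export
kmer_codes <- function(seq, k = 12L, step = 1L) {
  stopifnot(length(seq) == 1L, k >= 1L, k <= 15L, step >= 1L)
  n <- nchar(seq)
  if (is.na(n) || n < k) return(integer(0))
  code <- .base_codes(seq)
  n_win <- n - k + 1L
  val <- numeric(n_win)
  ok <- rep(TRUE, n_win)
  for (j in seq_len(k)) {
    cj <- code[j:(j + n_win - 1L)]
    ok <- ok & !is.na(cj)
    cj[is.na(cj)] <- 0
    val <- val * 4 + cj
  }
  pos <- seq(1L, n_win, by = step)
  as.integer(val[pos][ok[pos]])
}

.base_lookup <- local({
  x <- rep(NA_integer_, 256)
  x[utf8ToInt("A")] <- 0L; x[utf8ToInt("a")] <- 0L
  x[utf8ToInt("C")] <- 1L; x[utf8ToInt("c")] <- 1L
  x[utf8ToInt("G")] <- 2L; x[utf8ToInt("g")] <- 2L
  x[utf8ToInt("T")] <- 3L; x[utf8ToInt("t")] <- 3L
  x
})

.base_codes <- function(seq) .base_lookup[utf8ToInt(seq)]

#' Unique k-mer set of a sequence
#'
#' Convenience wrapper: [kmer_codes()] followed by `unique()`.
#' @inheritParams kmer_codes
#' @return integer vector of distinct k-mer codes.
#' @export
kmer_set <- function(seq, k = 12L, step = 1L) unique(kmer_codes(seq, k, step))

# Reverse complement for plain character strings.
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
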