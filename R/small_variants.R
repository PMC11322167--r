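# Small (2-49 bp) indel collection from contig CIGARs and the k-mer content
# filter against read evidence.

#' Collect small indels from contig alignments
#'
#' Every I/D CIGAR operation of 2-49 bp yields a left-anchored VCF-style
#' record (anchor base + inserted/deleted sequence). The indel context
#' sequence is taken from the contig: the inserted allele plus 20 bp flanks
#' for insertions, the 40 bp junction flank for deletions (whose bases are
#' absent from the contig). Context windows truncated at a contig end are
#' flagged `SHORT_CONTEXT`.
#'
#' @param segments contig alignment segment tibble (with `cigar`, `seq`).
#' @param reference named character vector (or `DNAStringSet`) of reference
#'   chromosomes, for deleted/anchor bases.
#' @param size_range inclusive indel size range (default `c(2, 49)`).
#' @param flank context flank width (default 20 bp).
#' @return tibble: `chrom`, `pos` (0-based anchor), `ref_allele`,
#'   `alt_allele`, `svtype`, `svlen`, `haplotype`, `block_id`,
#'   `source_name`, `context_seq`, `flag`.
#' @export
collect_small_indels <- function(segments, reference, size_range = c(2, 49),
                                 flank = 20) {
  if (nrow(segments) == 0L) return(empty_small_indels())
  ops <- c("I", "D")
  rref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    segments$cigar, pos = as.integer(segments$ref_s + 1), ops = ops, with.ops = TRUE)
  rqry <- GenomicAlignments::cigarRangesAlongQuerySpace(
    segments$cigar, ops = ops, with.ops = TRUE)
  out <- list()
  for (i in seq_len(nrow(segments))) {
    rr <- rref[[i]]
    if (length(rr) == 0L) next
    rq <- rqry[[i]]
    op <- names(rr)
    len <- pmax(IRanges::width(rr), IRanges::width(rq))
    keep <- len >= size_range[1] & len <= size_range[2]
    if (!any(keep)) next
    seg <- segments[i, ]
    chr <- as.character(reference[[seg$chrom]])
    for (j in which(keep)) {
      qs <- IRanges::start(rq[j]); qe <- IRanges::end(rq[j])  # 1-based in SEQ
      if (op[j] == "I") {
        pos0 <- IRanges::start(rr[j]) - 2          # anchor base, 0-based
        anchor <- str_sub(chr, pos0 + 1, pos0 + 1)
        ins <- str_sub(seg$seq, qs, qe)
        ctx_s <- qs - flank; ctx_e <- qe + flank
        flag <- if (ctx_s < 1 || ctx_e > nchar(seg$seq)) "SHORT_CONTEXT" else ""
        ctx <- str_sub(seg$seq, max(ctx_s, 1), min(ctx_e, nchar(seg$seq)))
        out[[length(out) + 1L]] <- tibble(
          chrom = seg$chrom, pos = pos0, ref_allele = anchor,
          alt_allele = paste0(anchor, ins), svtype = "INS", svlen = len[j],
          haplotype = seg$haplotype, block_id = seg$block_id,
          source_name = seg$source_name, context_seq = ctx, flag = flag)
      } else {
        rs <- IRanges::start(rr[j]); re <- IRanges::end(rr[j])  # deleted, 1-based
        pos0 <- rs - 2
        anchor <- str_sub(chr, pos0 + 1, pos0 + 1)
        deleted <- str_sub(chr, rs, re)
        # junction position in query: base after the deletion starts at qs
        ctx_s <- qs - flank; ctx_e <- qs + flank - 1
        flag <- if (ctx_s < 1 || ctx_e > nchar(seg$seq)) "SHORT_CONTEXT" else ""
        ctx <- str_sub(seg$seq, max(ctx_s, 1), min(ctx_e, nchar(seg$seq)))
        out[[length(out) + 1L]] <- tibble(
          chrom = seg$chrom, pos = pos0, ref_allele = paste0(anchor, deleted),
          alt_allele = anchor, svtype = "DEL", svlen = len[j],
          haplotype = seg$haplotype, block_id = seg$block_id,
          source_name = seg$source_name, context_seq = ctx, flag = flag)
      }
    }
  }
  if (!length(out)) return(empty_small_indels())
  bind_rows(out)
}

empty_small_indels <- function() {
  tibble(chrom = character(0), pos = numeric(0), ref_allele = character(0),
         alt_allele = character(0), svtype = character(0), svlen = numeric(0),
         haplotype = integer(0), block_id = character(0),
         source_name = character(0), context_seq = character(0), flag = character(0))
}

#' Filter small indels by read k-mer content
#'
#' For each indel, the k-mers of its contig context sequence are compared
#' with the pooled k-mer set of all reads whose alignments overlap the
#' 100 bp window centred on the indel anchor; the indel is kept iff strictly
#' more than `kmer_content_min` (70%) of its context k-mers are present in
#' the read k-mer set, otherwise it is removed as an assembly or alignment
#' artifact. Indels with no overlapping reads are removed with status
#' `NO_COVERAGE`.
#'
#' @param indels a [collect_small_indels()] tibble.
#' @param read_segments read alignment segment tibble (with `seq` in aligned
#'   orientation; soft-clipped bases included).
#' @param thresholds an [sv_thresholds()] list (`k`, `step`,
#'   `kmer_content_min`).
#' @param window read-evidence window width (default 100 bp).
#' @return kept indels with `kmer_content` fraction column.
#' @export
kmer_content_filter <- function(indels, read_segments,
                                thresholds = sv_thresholds(), window = 100) {
  if (nrow(indels) == 0L) return(dplyr::mutate(indels, kmer_content = numeric(0)))
  w <- window / 2
  indels$kmer_content <- NA_real_
  pad <- 100  # margin absorbing query/reference drift across small indels
  keep <- vapply(seq_len(nrow(indels)), function(i) {
    ind <- indels[i, ]
    win <- read_segments[read_segments$chrom == ind$chrom &
                           read_segments$ref_e > ind$pos - w &
                           read_segments$ref_s < ind$pos + w, , drop = FALSE]
    if (nrow(win) == 0L) return(FALSE)
    # k-mer content of the reads within the window: trim each read to the
    # query span facing the window (approximate colinear projection)
    read_k <- unique(unlist(lapply(seq_len(nrow(win)), function(j) {
      qs <- max(1, ind$pos - w - pad - win$ref_s[j])
      qe <- min(nchar(win$seq[j]), ind$pos + w + pad - win$ref_s[j])
      if (is.na(win$seq[j]) || qe <= qs) return(integer(0))
      kmer_codes(str_sub(win$seq[j], qs, qe), k = thresholds$k, step = thresholds$step)
    })))
    ctx_k <- kmer_set(ind$context_seq, thresholds$k, thresholds$step)
    if (!length(ctx_k)) return(FALSE)
    frac <- mean(ctx_k %in% read_k)
    indels$kmer_content[i] <<- frac
    frac > thresholds$kmer_content_min
  }, logical(1))
  indels[keep, , drop = FALSE]
}
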