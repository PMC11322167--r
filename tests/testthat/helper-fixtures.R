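# Shared helpers: hand-built alignment segment rows and small cached
# fixtures. Everything is generated in code; heavyweight aligner-backed
# objects are built once per session and memoised.

make_segment <- function(source_name = "ctg1", chrom = "chr1",
                         ref_s, ref_e, contig_s, contig_e, strand = "+",
                         qlen = NA, seq = NA_character_, cigar = NA_character_,
                         haplotype = NA_integer_, block_id = NA_character_,
                         is_supplementary = FALSE, mapq = 60L) {
  n <- max(lengths(list(source_name, ref_s, ref_e, contig_s, contig_e, strand)))
  contig_s <- rep_len(contig_s, n); contig_e <- rep_len(contig_e, n)
  strand <- rep_len(strand, n); qlen <- rep_len(qlen, n)
  qlen <- ifelse(is.na(qlen), contig_e, qlen)
  ori_s <- ifelse(strand == "+", contig_s, qlen - contig_e)
  ori_e <- ifelse(strand == "+", contig_e, qlen - contig_s)
  tibble::tibble(source_name, haplotype, block_id, chrom, ref_s, ref_e,
                 contig_s, contig_e, ori_s, ori_e, strand, qlen,
                 is_supplementary, mapq, cigar, seq)
}

# A split pair of one forward-strand query: contig intervals [c1s,c1e) and
# [c2s,c2e) aligned to reference intervals [r1s,r1e) and [r2s,r2e).
make_split_pair <- function(c1s, c1e, r1s, r1e, c2s, c2e, r2s, r2e,
                            chrom = "chr1", seq = NA_character_, name = "ctg1") {
  dplyr::bind_rows(
    make_segment(name, chrom, r1s, r1e, c1s, c1e, qlen = max(c1e, c2e), seq = seq),
    make_segment(name, chrom, r2s, r2e, c2s, c2e, qlen = max(c1e, c2e), seq = seq,
                 is_supplementary = TRUE))
}

make_signature <- function(chrom = "chr1", start, end = start, svtype, svlen,
                           alt_seq = "", haplotype = 1L, block_id = "1",
                           source_name = "ctg1", origin = "split") {
  tibble::tibble(chrom, start, end, svtype, svlen, alt_seq, haplotype,
                 block_id, source_name, origin)
}

has_aligner <- function() Sys.which("minimap2") != "" && Sys.which("samtools") != ""

# Session-level cache so expensive fixtures are built once.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}
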