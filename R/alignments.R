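# Alignment interface. minimap2 is the pluggable external aligner; BAM
# records are loaded once into a tidy segment table (one row per aligned
# segment, primary or supplementary) on which all downstream operations and
# window queries run.

#' Align FASTA queries to a reference with minimap2
#'
#' Thin wrapper over the external `minimap2` and `samtools` executables.
#' Supplementary alignments keep the full query sequence (`-Y`) so split
#' signatures can extract inserted sequence; a single worker thread keeps
#' output byte-deterministic.
#'
#' @param query_fa,ref_fa FASTA paths.
#' @param out_bam output BAM path (coordinate-sorted).
#' @param preset minimap2 preset (`asm5` for contigs, `map-hifi`/`map-ont`/
#'   `map-pb` for reads).
#' @return `out_bam`, invisibly.
#' @export
align_minimap2 <- function(query_fa, ref_fa, out_bam, preset = "asm5") {
  if (Sys.which("minimap2") == "" || Sys.which("samtools") == "")
    stop_input("minimap2/samtools not found on PATH")
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  status <- system2("minimap2",
                    c("-a", "-x", preset, "-Y", "-t", "1", "--secondary=no",
                      shQuote(ref_fa), shQuote(query_fa)),
                    stdout = sam, stderr = FALSE)
  if (status != 0L) stop_input("minimap2 failed with status %d", status)
  status <- system2("samtools", c("sort", "-o", shQuote(out_bam), shQuote(sam)),
                    stderr = FALSE)
  if (status != 0L) stop_input("samtools sort failed with status %d", status)
  invisible(out_bam)
}

#' Load aligned segments from a BAM file
#'
#' One row per primary or supplementary alignment record (secondary records
#' are dropped; supplementary records below the MAPQ floor are dropped).
#' Coordinates are 0-based half-open. Query coordinates `contig_s`/
#' `contig_e` are reported in the original query orientation; the
#' strand-oriented coordinates `ori_s`/`ori_e` (orientation in which query
#' position increases with reference position) drive split-pair arithmetic.
#' Contig names matching `PS<block>_hp<1|2>_<n>` have haplotype and phase
#' block parsed out.
#'
#' @param bam path to a BAM file.
#' @param min_mapq MAPQ floor applied to supplementary alignments.
#' @return tibble: `source_name`, `haplotype`, `block_id`, `chrom`, `ref_s`,
#'   `ref_e`, `contig_s`, `contig_e`, `ori_s`, `ori_e`, `strand`, `qlen`,
#'   `is_supplementary`, `mapq`, `cigar`, `seq` (query sequence in aligned,
#'   i.e. SEQ, orientation).
#' @export
read_alignment_segments <- function(bam, min_mapq = 20) {
  if (!file.exists(bam)) stop_input("BAM file not found: %s", bam)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE, isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (length(x$qname) == 0L) return(empty_segments())
  cig <- x$cigar
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  q_aln <- GenomicAlignments::cigarWidthAlongQuerySpace(cig, after.soft.clipping = TRUE)
  q_tot <- GenomicAlignments::cigarWidthAlongQuerySpace(cig, before.hard.clipping = TRUE)
  # leading clip length (soft + hard) in SEQ orientation
  lead <- stringr::str_match(cig, "^(?:(\\d+)H)?(?:(\\d+)S)?")
  lead_clip <- rowSums(cbind(as.numeric(lead[, 2]), as.numeric(lead[, 3])), na.rm = TRUE)
  strand <- as.character(x$strand)
  # aligned-orientation query interval [aln_s, aln_e) within full query
  aln_s <- lead_clip
  aln_e <- lead_clip + q_aln
  # original-orientation coordinates
  contig_s <- ifelse(strand == "+", aln_s, q_tot - aln_e)
  contig_e <- ifelse(strand == "+", aln_e, q_tot - aln_s)
  seg <- tibble(
    source_name = x$qname,
    chrom = as.character(x$rname),
    ref_s = x$pos - 1, ref_e = x$pos - 1 + ref_w,
    contig_s = contig_s, contig_e = contig_e,
    ori_s = aln_s, ori_e = aln_e,
    strand = strand, qlen = q_tot,
    is_supplementary = bitwAnd(x$flag, 2048L) > 0L,
    mapq = x$mapq, cigar = cig,
    seq = as.character(x$seq)
  )
  seg <- seg[!(seg$is_supplementary & seg$mapq < min_mapq), , drop = FALSE]
  m <- stringr::str_match(seg$source_name, "^PS([^_]+)_hp([12])_\\d+$")
  seg$block_id <- m[, 2]
  seg$haplotype <- as.integer(m[, 3])
  seg[, c("source_name", "haplotype", "block_id", "chrom", "ref_s", "ref_e",
          "contig_s", "contig_e", "ori_s", "ori_e", "strand", "qlen",
          "is_supplementary", "mapq", "cigar", "seq")]
}

empty_segments <- function() {
  tibble(source_name = character(0), haplotype = integer(0),
         block_id = character(0), chrom = character(0),
         ref_s = numeric(0), ref_e = numeric(0),
         contig_s = numeric(0), contig_e = numeric(0),
         ori_s = numeric(0), ori_e = numeric(0),
         strand = character(0), qlen = numeric(0),
         is_supplementary = logical(0), mapq = integer(0),
         cigar = character(0), seq = character(0))
}
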