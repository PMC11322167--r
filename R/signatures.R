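# Large-indel signature extraction from contig/read alignments: split-pair
# arithmetic (Diff_dis / Diff_olp decision rules) and CIGAR scanning, then
# nearest-neighbour chain clustering within each haplotype.

#' Collect INS/DEL signatures from split alignments
#'
#' Adjacent same-strand, same-chromosome segment pairs of each query
#' (consecutive in query coordinates, primary + supplementary) are tested
#' with `Diff_dis = (Contig_2s - Contig_1e) - (Ref_2s - Ref_1e)` and
#' `Diff_olp = Ref_1e - Ref_2s` (INS) or `Contig_1e - Contig_2s` (DEL).
#' `Diff_dis >= th_dis` with `Diff_olp < th_olp` emits an INS at
#' `floor((Ref_1e + Ref_2s)/2)` with `svlen = |Contig_2s - Contig_1e +
#' Diff_olp|`; `Diff_dis <= -th_dis` with `Diff_olp < th_olp` emits a DEL at
#' `[Ref_1e, Ref_1e + |Diff_dis|)`. Opposite-strand or cross-chromosome
#' pairs are complex-SV material and are not handled here (see
#' [collect_complex_signatures()]), never silently inspected as indels.
#'
#' @param segments a [read_alignment_segments()] tibble (any number of
#'   queries; grouped internally).
#' @param thresholds an [sv_thresholds()] list.
#' @return signature tibble: `chrom`, `start`, `end`, `svtype`, `svlen`,
#'   `alt_seq`, `haplotype`, `block_id`, `source_name`, `origin`.
#' @export
collect_split_signatures <- function(segments, thresholds = sv_thresholds()) {
  n <- nrow(segments)
  if (n < 2L) return(empty_signatures())
  # adjacent pairs within each query, consecutive in contig coordinates
  ord <- order(segments$source_name, segments$contig_s)
  i1 <- ord[-length(ord)]
  i2 <- ord[-1]
  same <- segments$source_name[i1] == segments$source_name[i2] &
    segments$strand[i1] == segments$strand[i2] &
    segments$chrom[i1] == segments$chrom[i2]
  i1 <- i1[same]; i2 <- i2[same]
  if (!length(i1)) return(empty_signatures())
  # within a pair, `a` precedes `b` in strand-oriented query coordinates
  swap <- segments$ori_s[i1] > segments$ori_s[i2]
  a <- ifelse(swap, i2, i1); b <- ifelse(swap, i1, i2)
  c1e <- segments$ori_e[a]; c2s <- segments$ori_s[b]
  r1e <- segments$ref_e[a]; r2s <- segments$ref_s[b]
  diff_dis <- (c2s - c1e) - (r2s - r1e)
  olp_ins <- r1e - r2s
  olp_del <- c1e - c2s
  is_ins <- diff_dis >= thresholds$th_dis & olp_ins < thresholds$th_olp &
    abs(c2s - c1e + olp_ins) >= thresholds$min_sv_size
  is_del <- diff_dis <= -thresholds$th_dis & olp_del < thresholds$th_olp &
    abs(diff_dis) >= thresholds$min_sv_size
  out <- list()
  if (any(is_ins)) {
    ai <- a[is_ins]
    svlen <- abs(c2s - c1e + olp_ins)[is_ins]
    alt <- character(sum(is_ins))
    seqs <- segments$seq[ai]
    from <- c1e[is_ins]
    ok <- !is.na(seqs) & nchar(seqs) >= from + svlen
    alt[ok] <- str_sub(seqs[ok], from[ok] + 1, from[ok] + svlen[ok])
    out[[1L]] <- tibble(
      chrom = segments$chrom[ai],
      start = floor((r1e[is_ins] + r2s[is_ins]) / 2),
      end = floor((r1e[is_ins] + r2s[is_ins]) / 2),
      svtype = "INS", svlen = svlen, alt_seq = alt,
      haplotype = segments$haplotype[ai], block_id = segments$block_id[ai],
      source_name = segments$source_name[ai], origin = "split")
  }
  if (any(is_del)) {
    ad <- a[is_del]
    out[[length(out) + 1L]] <- tibble(
      chrom = segments$chrom[ad],
      start = r1e[is_del], end = r1e[is_del] + abs(diff_dis)[is_del],
      svtype = "DEL", svlen = abs(diff_dis)[is_del], alt_seq = "",
      haplotype = segments$haplotype[ad], block_id = segments$block_id[ad],
      source_name = segments$source_name[ad], origin = "split")
  }
  if (!length(out)) return(empty_signatures())
  res <- bind_rows(out)
  res[order(res$source_name, res$start), , drop = FALSE]
}

#' Collect INS/DEL signatures from CIGAR operations
#'
#' Every I/D CIGAR operation of at least `min_size` bp yields a signature at
#' its exact reference position; inserted query substrings become `alt_seq`.
#'
#' @param segments a [read_alignment_segments()] tibble.
#' @param min_size minimum operation length (bp).
#' @return signature tibble as in [collect_split_signatures()] with
#'   `origin = "cigar"`.
#' @export
collect_cigar_signatures <- function(segments, min_size = 50) {
  if (nrow(segments) == 0L) return(empty_signatures())
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
    keep <- len >= min_size
    if (!any(keep)) next
    seg <- segments[i, ]
    for (j in which(keep)) {
      if (op[j] == "I") {
        alt <- if (!is.na(seg$seq) && nchar(seg$seq) > 1)
          str_sub(seg$seq, IRanges::start(rq[j]), IRanges::end(rq[j])) else ""
        start <- IRanges::start(rr[j]) - 1  # 0-based gap position
        out[[length(out) + 1L]] <- tibble(
          chrom = seg$chrom, start = start, end = start,
          svtype = "INS", svlen = len[j], alt_seq = alt,
          haplotype = seg$haplotype, block_id = seg$block_id,
          source_name = seg$source_name, origin = "cigar")
      } else {
        start <- IRanges::start(rr[j]) - 1
        out[[length(out) + 1L]] <- tibble(
          chrom = seg$chrom, start = start, end = start + len[j],
          svtype = "DEL", svlen = len[j], alt_seq = "",
          haplotype = seg$haplotype, block_id = seg$block_id,
          source_name = seg$source_name, origin = "cigar")
      }
    }
  }
  if (!length(out)) return(empty_signatures())
  bind_rows(out)
}

#' Collect all large-indel signatures of an alignment set
#'
#' Pools split-pair and CIGAR-derived signatures (both routes are common
#' with modern aligners); the pooling of CIGAR-derived large indels can be
#' disabled.
#'
#' @inheritParams collect_split_signatures
#' @param include_cigar pool large CIGAR I/D operations as well (default
#'   TRUE).
#' @return signature tibble.
#' @export
collect_indel_signatures <- function(segments, thresholds = sv_thresholds(),
                                     include_cigar = TRUE) {
  sp <- collect_split_signatures(segments, thresholds)
  if (!include_cigar) return(sp)
  bind_rows(sp, collect_cigar_signatures(segments, thresholds$min_sv_size))
}

empty_signatures <- function() {
  tibble(chrom = character(0), start = numeric(0), end = numeric(0),
         svtype = character(0), svlen = numeric(0), alt_seq = character(0),
         haplotype = integer(0), block_id = character(0),
         source_name = character(0), origin = character(0))
}

# Chain clustering shared by intra-haplotype refinement and inter-haplotype
# pairing: signatures sorted by breakpoint, an edge joins *adjacent* rows
# that pass the similarity test, connected components become clusters.
chain_clusters <- function(sig, shift_cap, th_sim, use_overlap) {
  n <- nrow(sig)
  if (n == 0L) return(integer(0))
  comp <- numeric(n)
  grp <- 1
  comp[1] <- 1
  for (i in seq_len(n - 1L)) {
    a <- sig[i, ]; b <- sig[i + 1L, ]
    edge <- FALSE
    if (a$chrom == b$chrom) {
      shift <- abs(b$start - a$start)
      ssim <- svlen_sim(a$svlen, b$svlen)
      edge <- shift < shift_cap && ssim > th_sim
      if (edge && use_overlap) {
        ovl <- (min(a$end, b$end) - max(a$start, b$start)) / min(a$svlen, b$svlen)
        edge <- ovl > th_sim
      }
    }
    if (!edge) grp <- grp + 1
    comp[i + 1L] <- grp
  }
  comp
}

# Representative of a cluster: largest svlen, leftmost on ties.
cluster_representative <- function(sig) {
  sig[order(-sig$svlen, sig$start), , drop = FALSE][1, , drop = FALSE]
}

#' Cluster signatures within one haplotype
#'
#' Signatures are split by type and sorted by breakpoint; adjacent
#' signatures are chained when `|breakpoint_shift| < th_shift_intrahap` and
#' `svlen_sim > th_sim` (DELs additionally need reciprocal-overlap ratio
#' `> th_sim`). Each connected component is represented by its
#' largest-length signature.
#'
#' @param signatures a signature tibble (one haplotype; the function groups
#'   by `haplotype`/`block_id` if several are present).
#' @param thresholds an [sv_thresholds()] list.
#' @return tibble of representative signatures with `n_signatures` support
#'   counts.
#' @export
cluster_intrahap <- function(signatures, thresholds = sv_thresholds()) {
  if (nrow(signatures) == 0L) return(dplyr::mutate(empty_signatures(), n_signatures = integer(0)))
  out <- list()
  groups <- split(seq_len(nrow(signatures)),
                  list(signatures$svtype,
                       ifelse(is.na(signatures$haplotype), 0L, signatures$haplotype)),
                  drop = TRUE)
  for (grp in groups) {
    sig <- signatures[grp, , drop = FALSE]
    sig <- sig[order(sig$chrom, sig$start, sig$end), , drop = FALSE]
    comp <- chain_clusters(sig, thresholds$th_shift_intrahap, thresholds$th_sim,
                           use_overlap = sig$svtype[1] == "DEL")
    for (cl in split(seq_len(nrow(sig)), comp)) {
      rep <- cluster_representative(sig[cl, , drop = FALSE])
      rep$n_signatures <- length(cl)
      out[[length(out) + 1L]] <- rep
    }
  }
  res <- bind_rows(out)
  res[order(res$chrom, res$start, res$svtype), , drop = FALSE]
}
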