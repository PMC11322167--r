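# Inversions, translocations and duplication recovery. INV/TRA come from
# strand- or chromosome-discordant adjacent split segments; DUPs are mostly
# recovered from insertion calls by re-aligning the inserted sequence near
# its breakpoint.

#' Collect complex-SV signatures from split contig alignments
#'
#' For each query, segments are ordered along the contig. An adjacent
#' same-chromosome pair with opposite strands yields an INV spanning the
#' reference interval of the minority-strand (inverted) segment; an
#' adjacent cross-chromosome pair yields a TRA junction between the two
#' facing breakends; an adjacent same-strand pair whose reference intervals
#' overlap by at least 50 bp yields a tandem-DUP candidate over the
#' overlapped interval.
#'
#' When a `reference` is supplied, an adjacent same-strand pair bracketing
#' similar-sized unaligned gaps on both the contig and the reference is
#' probed for a skipped inversion: aligners sometimes leave an inverted
#' segment entirely unaligned instead of emitting a reverse-strand
#' supplementary record, and the gap betrays it. The unaligned contig piece
#' is compared against the reverse-complemented reference gap; identity
#' above 80% emits an INV over the gap.
#'
#' @param segments a [read_alignment_segments()] tibble.
#' @param thresholds an [sv_thresholds()] list.
#' @param reference optional named character vector or `DNAStringSet` used
#'   for the unaligned-gap inversion probe.
#' @return breakend tibble: `svtype` (INV/TRA/DUP), `chrom`, `pos`, `end`,
#'   `chrom2`, `pos2`, `svlen`, `haplotype`, `block_id`, `source_name`.
#' @export
collect_complex_signatures <- function(segments, thresholds = sv_thresholds(),
                                       reference = NULL) {
  out <- list()
  for (grp in split(seq_len(nrow(segments)), segments$source_name)) {
    if (length(grp) < 2L) next
    seg <- segments[grp, , drop = FALSE]
    seg <- seg[order(seg$contig_s), , drop = FALSE]
    # majority strand by aligned length decides which segment is "inverted"
    len_by_strand <- tapply(seg$ref_e - seg$ref_s, seg$strand, sum)
    major <- names(len_by_strand)[which.max(len_by_strand)]
    for (i in seq_len(nrow(seg) - 1L)) {
      a <- seg[i, ]; b <- seg[i + 1L, ]
      if (a$chrom != b$chrom) {
        # facing breakends: end of a in its direction of travel, start of b
        pos1 <- if (a$strand == "+") a$ref_e else a$ref_s
        pos2 <- if (b$strand == "+") b$ref_s else b$ref_e
        out[[length(out) + 1L]] <- tibble(
          svtype = "TRA", chrom = a$chrom, pos = pos1, end = pos1,
          chrom2 = b$chrom, pos2 = pos2, svlen = 0,
          haplotype = a$haplotype, block_id = a$block_id, source_name = a$source_name)
      } else if (a$strand != b$strand) {
        inv <- if (a$strand == major) b else a
        out[[length(out) + 1L]] <- tibble(
          svtype = "INV", chrom = inv$chrom, pos = inv$ref_s, end = inv$ref_e,
          chrom2 = NA_character_, pos2 = NA_real_, svlen = inv$ref_e - inv$ref_s,
          haplotype = a$haplotype, block_id = a$block_id, source_name = a$source_name)
      } else {
        # same strand, same chromosome: reference overlap => duplicated unit
        lo <- max(a$ref_s, b$ref_s); hi <- min(a$ref_e, b$ref_e)
        if (hi - lo >= 50) {
          out[[length(out) + 1L]] <- tibble(
            svtype = "DUP", chrom = a$chrom, pos = lo, end = hi,
            chrom2 = NA_character_, pos2 = NA_real_, svlen = hi - lo,
            haplotype = a$haplotype, block_id = a$block_id, source_name = a$source_name)
        } else if (!is.null(reference)) {
          inv <- probe_unaligned_inversion(a, b, reference, thresholds)
          if (!is.null(inv)) out[[length(out) + 1L]] <- inv
        }
      }
    }
  }
  if (!length(out)) return(empty_breakends())
  bind_rows(out)
}

# Test whether the unaligned piece between two collinear segments is the
# reverse complement of the bracketed reference gap (an inversion the
# aligner skipped instead of splitting).
probe_unaligned_inversion <- function(a, b, reference, thresholds,
                                      max_gap = 20000) {
  if (a$ori_s > b$ori_s) { tmp <- a; a <- b; b <- tmp }
  gc <- b$ori_s - a$ori_e      # unaligned contig gap
  gr <- b$ref_s - a$ref_e      # unaligned reference gap
  if (gc < thresholds$min_sv_size || gr < thresholds$min_sv_size) return(NULL)
  if (gc > max_gap || gr > max_gap) return(NULL)
  if (svlen_sim(gc, gr) <= thresholds$th_sim) return(NULL)
  if (is.na(a$seq) || nchar(a$seq) < b$ori_s) return(NULL)
  piece <- str_sub(a$seq, a$ori_e + 1, b$ori_s)
  chr <- as.character(reference[[a$chrom]])
  refgap <- str_sub(chr, a$ref_e + 1, b$ref_s)
  sim <- seq_similarity(revcomp(piece), refgap)
  if (is.na(sim) || sim < 0.8) return(NULL)
  tibble(svtype = "INV", chrom = a$chrom, pos = a$ref_e, end = b$ref_s,
         chrom2 = NA_character_, pos2 = NA_real_, svlen = gr,
         haplotype = a$haplotype, block_id = a$block_id,
         source_name = a$source_name)
}

empty_breakends <- function() {
  tibble(svtype = character(0), chrom = character(0), pos = numeric(0),
         end = numeric(0), chrom2 = character(0), pos2 = numeric(0),
         svlen = numeric(0), haplotype = integer(0), block_id = character(0),
         source_name = character(0))
}

#' Merge complex signatures into genotyped calls
#'
#' Signatures of the same rearrangement (two junctions of one inversion,
#' the same junction seen on both haplotypes) are merged: INV/DUP by
#' reciprocal interval overlap > 0.5, TRA by both breakends within 1 kb.
#' The genotype is the per-haplotype presence (`1|0`, `0|1`, `1|1`).
#'
#' @param bnds a [collect_complex_signatures()] tibble.
#' @return call tibble with `gt` added and one row per merged event.
#' @export
merge_complex_calls <- function(bnds) {
  if (nrow(bnds) == 0L) return(dplyr::mutate(empty_breakends(), gt = character(0)))
  # a reciprocal exchange is seen from both derived chromosomes with the
  # same breakend pair; canonicalise junction orientation before merging
  tra <- which(bnds$svtype == "TRA")
  flip <- tra[bnds$chrom2[tra] < bnds$chrom[tra] |
                (bnds$chrom2[tra] == bnds$chrom[tra] & bnds$pos2[tra] < bnds$pos[tra])]
  if (length(flip)) {
    tmp_c <- bnds$chrom[flip]; tmp_p <- bnds$pos[flip]
    bnds$chrom[flip] <- bnds$chrom2[flip]; bnds$pos[flip] <- bnds$pos2[flip]
    bnds$chrom2[flip] <- tmp_c; bnds$pos2[flip] <- tmp_p
    bnds$end[flip] <- bnds$pos[flip]
  }
  out <- list()
  for (grp in split(seq_len(nrow(bnds)), bnds$svtype)) {
    sub <- bnds[grp, , drop = FALSE]
    sub <- sub[order(sub$chrom, sub$pos), , drop = FALSE]
    n <- nrow(sub)
    from <- integer(0); to <- integer(0)
    for (i in seq_len(max(n - 1L, 0L))) for (j in (i + 1L):n) {
      same <- if (sub$svtype[1] == "TRA") {
        sub$chrom[i] == sub$chrom[j] && sub$chrom2[i] == sub$chrom2[j] &&
          abs(sub$pos[i] - sub$pos[j]) <= 1000 && abs(sub$pos2[i] - sub$pos2[j]) <= 1000
      } else {
        ovl <- min(sub$end[i], sub$end[j]) - max(sub$pos[i], sub$pos[j])
        sub$chrom[i] == sub$chrom[j] && ovl > 0 &&
          ovl / max(sub$end[i] - sub$pos[i], sub$end[j] - sub$pos[j]) > 0.5
      }
      if (isTRUE(same)) { from <- c(from, i); to <- c(to, j) }
    }
    comp <- components_from_edges(n, from, to)
    for (cl in split(seq_len(n), comp)) {
      s <- sub[cl, , drop = FALSE]
      rep <- s[order(-s$svlen, s$pos), , drop = FALSE][1, , drop = FALSE]
      haps <- unique(s$haplotype[!is.na(s$haplotype)])
      # members that already carry a paired genotype (e.g. recovered DUPs)
      # contribute their implied haplotypes
      if ("gt" %in% names(s)) {
        gts <- s$gt[!is.na(s$gt)]
        if (any(substr(gts, 1, 1) == "1")) haps <- union(haps, 1L)
        if (any(substr(gts, 3, 3) == "1")) haps <- union(haps, 2L)
      }
      rep$gt <- if (length(haps) >= 2L) "1|1" else if (identical(haps, 1L)) "1|0" else "0|1"
      out[[length(out) + 1L]] <- rep
    }
  }
  res <- bind_rows(out)
  res[order(res$svtype, res$chrom, res$pos), , drop = FALSE]
}

#' Filter inversion calls with read orientation evidence
#'
#' An inversion is kept iff, in the 1 kb flanking window around either
#' breakpoint, at least one read aligns to the reference in two distinct
#' orientations (a split read straddling the inverted junction).
#'
#' @param inv_calls INV call tibble (`chrom`, `pos`, `end`).
#' @param read_segments read alignment segment tibble.
#' @return the kept INV calls (subset of input).
#' @export
filter_inversions <- function(inv_calls, read_segments) {
  if (nrow(inv_calls) == 0L) return(inv_calls)
  keep <- vapply(seq_len(nrow(inv_calls)), function(i) {
    call <- inv_calls[i, ]
    chr_seg <- read_segments[read_segments$chrom == call$chrom, , drop = FALSE]
    for (bp in c(call$pos, call$end)) {
      hit <- chr_seg$source_name[chr_seg$ref_e > bp - 1000 & chr_seg$ref_s < bp + 1000]
      if (!length(hit)) next
      # a junction-crossing read's inverted piece maps near the *other*
      # breakpoint, so orientations are judged over all of the read's
      # alignments on the chromosome, not only the in-window ones
      seg <- chr_seg[chr_seg$source_name %in% hit, , drop = FALSE]
      strands <- tapply(seg$strand, seg$source_name, function(s) length(unique(s)))
      if (any(strands >= 2L)) return(TRUE)
    }
    FALSE
  }, logical(1))
  inv_calls[keep, , drop = FALSE]
}

#' Filter translocation calls with dual-breakend read evidence
#'
#' A junction is kept iff the number of reads having alignments in both
#' breakend windows (+/-1 kb) is at least a quarter of the local read depth
#' (mean of the two windows). Junctions without coverage at a breakend are
#' removed with status `NO_COVERAGE`.
#'
#' @param tra_calls TRA call tibble (`chrom`, `pos`, `chrom2`, `pos2`).
#' @param read_segments read alignment segment tibble.
#' @param min_frac required fraction of the local depth (default 0.25).
#' @return kept TRA calls with `n_spanning` and `local_depth` columns.
#' @export
filter_translocations <- function(tra_calls, read_segments, min_frac = 0.25) {
  if (nrow(tra_calls) == 0L) return(tra_calls)
  tra_calls$n_spanning <- NA_real_
  tra_calls$local_depth <- NA_real_
  keep <- vapply(seq_len(nrow(tra_calls)), function(i) {
    call <- tra_calls[i, ]
    w1 <- read_segments[read_segments$chrom == call$chrom &
                          read_segments$ref_e > call$pos - 1000 &
                          read_segments$ref_s < call$pos + 1000, , drop = FALSE]
    w2 <- read_segments[read_segments$chrom == call$chrom2 &
                          read_segments$ref_e > call$pos2 - 1000 &
                          read_segments$ref_s < call$pos2 + 1000, , drop = FALSE]
    d1 <- window_depth(read_segments, call$chrom, call$pos - 1000, call$pos + 1000)
    d2 <- window_depth(read_segments, call$chrom2, call$pos2 - 1000, call$pos2 + 1000)
    if (d1 == 0 || d2 == 0) return(FALSE)
    spanning <- length(intersect(unique(w1$source_name), unique(w2$source_name)))
    tra_calls$n_spanning[i] <<- spanning
    tra_calls$local_depth[i] <<- (d1 + d2) / 2
    spanning >= min_frac * (d1 + d2) / 2
  }, logical(1))
  tra_calls[keep, , drop = FALSE]
}

#' Recover duplications from insertion calls
#'
#' The alternate sequence of every INS call is re-aligned to the reference
#' around its breakpoint (window `max(1 kb, 2 x svlen)` each side) with a
#' banded edit-distance scan; a hit with at most `dup_max_edit` (default
#' 20%) edits — i.e. at least 80% query agreement — reclassifies the call as
#' a DUP whose duplicated unit is the matched reference interval. Calls with
#' empty or distal-matching alternate sequences stay INS. The output
#' partitions the input: `|DUP| + |INS| == |input|`.
#'
#' @param ins_calls INS call tibble with `alt_seq`.
#' @param reference named character vector (or `DNAStringSet`) of reference
#'   chromosomes.
#' @param thresholds an [sv_thresholds()] list.
#' @param window optional fixed proximity window (bp); default
#'   `max(1000, 2 * svlen)` per call.
#' @return list with `dup_calls` (reclassified, `svtype = "DUP"`, `pos`/
#'   `end` the duplicated unit) and `ins_calls` (the remainder).
#' @export
recover_duplications <- function(ins_calls, reference, thresholds = sv_thresholds(),
                                 window = NULL) {
  if (nrow(ins_calls) == 0L)
    return(list(dup_calls = dplyr::mutate(empty_breakends(), gt = character(0)),
                ins_calls = ins_calls))
  is_dup <- logical(nrow(ins_calls))
  unit_s <- numeric(nrow(ins_calls)); unit_e <- numeric(nrow(ins_calls))
  for (i in seq_len(nrow(ins_calls))) {
    call <- ins_calls[i, ]
    alt <- call$alt_seq
    if (is.na(alt) || nchar(alt) < 30) next
    w <- window %||% max(1000, 2 * nchar(alt))
    chr <- as.character(reference[[call$chrom]])
    lo <- max(0, call$start - w); hi <- min(nchar(chr), call$start + w)
    subject <- Biostrings::DNAString(str_sub(chr, lo + 1, hi))
    # banded edit-distance scan; the band is halved when it exceeds the
    # matcher's internal limit (exact and near-exact copies always match)
    max_edit <- floor(thresholds$dup_max_edit * nchar(alt))
    hit <- NULL
    while (is.null(hit) && max_edit >= 0) {
      hit <- tryCatch(
        Biostrings::matchPattern(Biostrings::DNAString(alt), subject,
                                 max.mismatch = max_edit, with.indels = max_edit > 0),
        error = function(e) NULL)
      if (is.null(hit)) max_edit <- if (max_edit == 0) -1 else floor(max_edit / 2)
    }
    if (!is.null(hit) && length(hit) > 0L) {
      is_dup[i] <- TRUE
      unit_s[i] <- lo + IRanges::start(hit)[1] - 1
      unit_e[i] <- lo + IRanges::end(hit)[1]
    }
  }
  dup <- ins_calls[is_dup, , drop = FALSE]
  if (nrow(dup)) {
    dup$svtype <- "DUP"
    dup$end <- unit_e[is_dup]
    dup$start <- unit_s[is_dup]
    dup$svlen <- dup$end - dup$start
  }
  list(dup_calls = dup, ins_calls = ins_calls[!is_dup, , drop = FALSE])
}
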