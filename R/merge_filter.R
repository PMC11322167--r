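# Pairing of per-haplotype SV calls into genotyped variants, read-evidence
# filtering, deletion depth-band filtering, one-to-K redundancy removal and
# decision-tree genotype refinement.

#' Pair per-haplotype calls and assign genotypes
#'
#' Per phase block, the clustered representatives of both haplotypes are
#' merged, sorted, and chained with the inter-haplotype thresholds
#' (`|shift| < th_shift_interhap`, `svlen_sim > th_sim`, DELs additionally
#' reciprocal overlap `> th_sim`). A component spanning both haplotypes
#' becomes a homozygous call (`1|1`); single-haplotype components keep their
#' phase (`1|0` / `0|1`). The largest-length member represents the call.
#'
#' @param hap_calls tibble of clustered per-haplotype representatives (both
#'   haplotypes, `haplotype` column set; paired within `block_id`).
#' @param thresholds an [sv_thresholds()] list.
#' @return call tibble: signature columns plus `gt` and `n_signatures`.
#' @export
pair_haplotypes <- function(hap_calls, thresholds = sv_thresholds()) {
  if (nrow(hap_calls) == 0L)
    return(dplyr::mutate(empty_signatures(), gt = character(0), n_signatures = integer(0)))
  out <- list()
  groups <- split(seq_len(nrow(hap_calls)),
                  list(hap_calls$svtype,
                       ifelse(is.na(hap_calls$block_id), "", hap_calls$block_id)),
                  drop = TRUE)
  for (grp in groups) {
    sig <- hap_calls[grp, , drop = FALSE]
    sig <- sig[order(sig$chrom, sig$start, sig$end), , drop = FALSE]
    comp <- chain_clusters(sig, thresholds$th_shift_interhap, thresholds$th_sim,
                           use_overlap = sig$svtype[1] == "DEL")
    for (cl in split(seq_len(nrow(sig)), comp)) {
      sub <- sig[cl, , drop = FALSE]
      rep <- cluster_representative(sub)
      haps <- unique(sub$haplotype[!is.na(sub$haplotype)])
      rep$gt <- if (length(haps) >= 2L) "1|1" else if (identical(haps, 1L)) "1|0" else "0|1"
      rep$n_signatures <- nrow(sub)
      out[[length(out) + 1L]] <- rep
    }
  }
  res <- bind_rows(out)
  res[order(res$chrom, res$start, res$svtype), , drop = FALSE]
}

# Read signatures of matching type within the 1 kb window centred on a
# call's breakpoint whose size ratio clears th_sim.
supporting_signatures <- function(call, read_sigs, th_sim = 0.5, window = 1000) {
  w <- window / 2
  hit <- read_sigs[read_sigs$svtype == call$svtype &
                     read_sigs$chrom == call$chrom &
                     read_sigs$start >= call$start - w &
                     read_sigs$start <= call$start + w, , drop = FALSE]
  hit[svlen_sim(hit$svlen, call$svlen) > th_sim, , drop = FALSE]
}

#' Filter calls by read-based signature support
#'
#' Calls in the 50-250 bp size range need at least one same-type read
#' signature within the 1 kb window centred on the breakpoint whose size
#' ratio `min/max` exceeds `th_sim`; calls outside the range pass untouched
#' (read alignment evidence is only reliable for small SVs).
#'
#' @param calls call tibble.
#' @param read_sigs read-derived signature tibble (from
#'   [collect_indel_signatures()] on the read alignments, collected down to
#'   `min_read_sig` bp).
#' @param thresholds an [sv_thresholds()] list.
#' @return calls with the zero-supporter rows removed and an `n_support`
#'   column added for all rows.
#' @export
filter_by_read_support <- function(calls, read_sigs, thresholds = sv_thresholds()) {
  if (nrow(calls) == 0L) return(dplyr::mutate(calls, n_support = integer(0)))
  if (is.null(read_sigs)) {
    warn("no read signatures supplied; read-support filter skipped")
    calls$n_support <- NA_integer_
    return(calls)
  }
  rng <- thresholds$read_filter_range
  calls$n_support <- vapply(seq_len(nrow(calls)), function(i) {
    nrow(supporting_signatures(calls[i, ], read_sigs, thresholds$th_sim))
  }, integer(1))
  in_range <- calls$svlen >= rng[1] & calls$svlen <= rng[2]
  calls[!in_range | calls$n_support >= 1L, , drop = FALSE]
}

#' Filter deletion calls by supporting-signature depth
#'
#' For each candidate DEL, `sig_depth` is the summed length of DEL read
#' signatures within the 1 kb flanking window around the breakpoint divided
#' by the candidate's length. Pooling `sig_depth` over all candidates gives
#' the vector R; a candidate is kept iff
#' `lb * median(R) <= sig_depth <= rb * median(R)` (inclusive bounds), with
#' `(lb, rb)` set by sequencing technology.
#'
#' @param calls call tibble (non-DEL rows pass through untouched).
#' @param read_sigs read-derived signature tibble.
#' @param tech `"hifi"`, `"clr"` or `"ont"`.
#' @param thresholds an [sv_thresholds()] list.
#' @return filtered calls with a `sig_depth` column on DEL rows.
#' @export
filter_del_by_depth <- function(calls, read_sigs, tech = "hifi",
                                thresholds = sv_thresholds()) {
  if (nrow(calls) == 0L) return(calls)
  lb <- thresholds$lb[[tech]]; rb <- thresholds$rb[[tech]]
  is_del <- calls$svtype == "DEL"
  calls$sig_depth <- NA_real_
  if (!any(is_del)) return(calls)
  dels <- which(is_del)
  sd_vec <- vapply(dels, function(i) {
    call <- calls[i, ]
    hit <- read_sigs[read_sigs$svtype == "DEL" &
                       read_sigs$chrom == call$chrom &
                       read_sigs$start >= call$start - 1000 &
                       read_sigs$start <= call$start + 1000, , drop = FALSE]
    sum(hit$svlen) / call$svlen
  }, numeric(1))
  calls$sig_depth[dels] <- sd_vec
  med <- median(sd_vec)
  keep_del <- sd_vec >= lb * med & sd_vec <= rb * med
  if (length(dels) == 1L) keep_del <- TRUE  # median is the candidate itself
  drop <- dels[!keep_del]
  if (length(drop)) calls <- calls[-drop, , drop = FALSE]
  calls
}

#' Remove redundant calls by one-to-K clustering
#'
#' Unlike the chain steps, every pair of same-type calls within the 500 bp
#' positional neighbourhood is compared: an edge joins two INS when
#' `|shift| < th_shift_redun_ins`, `svlen_sim > th_sim` and sequence
#' similarity (1 - edit distance / max length) `> th_sim`; two DELs when
#' `|shift| < th_shift_redun_del`, `svlen_sim > th_sim_relax` and sequence
#' similarity `> th_sim`. The largest call of each connected component
#' survives, so a dissimilar false call sitting between two copies of the
#' same variant no longer breaks the chain.
#'
#' @param calls call tibble; DEL sequence similarity is computed on the
#'   deleted reference spans, which requires `reference` when DEL `alt_seq`
#'   is empty.
#' @param thresholds an [sv_thresholds()] list.
#' @param reference optional named character vector (or `DNAStringSet`) of
#'   reference chromosomes used to fetch deleted spans.
#' @return deduplicated calls (a subset of the input rows).
#' @export
dedupe_one_to_k <- function(calls, thresholds = sv_thresholds(), reference = NULL) {
  if (nrow(calls) <= 1L) return(calls)
  seq_of <- function(row) {
    if (row$svtype == "INS") return(row$alt_seq)
    if (!is.null(reference)) {
      chr <- as.character(reference[[row$chrom]])
      return(str_sub(chr, row$start + 1, row$end))
    }
    row$alt_seq
  }
  keep_rows <- list()
  for (grp in split(seq_len(nrow(calls)), list(calls$svtype, calls$chrom), drop = TRUE)) {
    sub <- calls[grp, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    n <- nrow(sub)
    shift_cap <- if (sub$svtype[1] == "DEL") thresholds$th_shift_redun_del else thresholds$th_shift_redun_ins
    size_floor <- if (sub$svtype[1] == "DEL") thresholds$th_sim_relax else thresholds$th_sim
    seqs <- vapply(seq_len(n), function(i) seq_of(sub[i, ]), character(1))
    from <- integer(0); to <- integer(0)
    for (i in seq_len(max(n - 1L, 0L))) {
      j <- i + 1L
      while (j <= n && sub$start[j] - sub$start[i] <= thresholds$neighborhood) {
        shift <- abs(sub$start[j] - sub$start[i])
        if (shift < shift_cap &&
            svlen_sim(sub$svlen[i], sub$svlen[j]) > size_floor) {
          ss <- seq_similarity(seqs[i], seqs[j])
          if (!is.na(ss) && ss > thresholds$th_sim) {
            from <- c(from, i); to <- c(to, j)
          }
        }
        j <- j + 1L
      }
    }
    comp <- components_from_edges(n, from, to)
    for (cl in split(seq_len(n), comp)) {
      keep_rows[[length(keep_rows) + 1L]] <- cluster_representative(sub[cl, , drop = FALSE])
    }
  }
  res <- bind_rows(keep_rows)
  res[order(res$chrom, res$start, res$svtype), , drop = FALSE]
}

#' Refine genotypes with the decision-tree model
#'
#' For each large indel the leaf of the 24-leaf decision tree is selected by
#' contig-derived genotype (het/hom), size bin (>1 kb or not), SV type and
#' technology; the relative support ratio (supporting read signatures /
#' local read depth over the breakpoint +/-500 bp) above the leaf threshold
#' predicts `1|1`, below predicts a heterozygote. A downgraded homozygote
#' keeps the haplotype with more read-signature support (haplotype labels on
#' read signatures, when available); an upgraded heterozygote becomes
#' `1|1`. Calls with zero local depth keep the contig-derived genotype and
#' are flagged `LOW_DEPTH`.
#'
#' @param calls genotyped call tibble.
#' @param read_sigs read-derived signature tibble (with optional `haplotype`
#'   column).
#' @param read_segments read alignment segment tibble (local depth).
#' @param tech `"hifi"`, `"clr"` or `"ont"`.
#' @param table decision table, defaults to [genotype_decision_table()].
#' @param thresholds an [sv_thresholds()] list.
#' @return calls with refined `gt`, plus `rel_support`, `local_depth` and
#'   `gt_flag` columns.
#' @export
refine_genotype <- function(calls, read_sigs, read_segments, tech = "hifi",
                            table = genotype_decision_table(),
                            thresholds = sv_thresholds()) {
  if (nrow(calls) == 0L) {
    calls$rel_support <- numeric(0); calls$local_depth <- numeric(0)
    calls$gt_flag <- character(0)
    return(calls)
  }
  calls$rel_support <- NA_real_
  calls$local_depth <- NA_real_
  calls$gt_flag <- ""
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, ]
    sup <- supporting_signatures(call, read_sigs, thresholds$th_sim)
    depth <- window_depth(read_segments, call$chrom, call$start - 500, call$start + 500)
    calls$local_depth[i] <- depth
    if (depth == 0) { calls$gt_flag[i] <- "LOW_DEPTH"; next }
    ratio <- nrow(sup) / depth
    calls$rel_support[i] <- ratio
    leaf <- table[table$contig_gt == ifelse(call$gt == "1|1", "hom", "het") &
                    table$size_bin == ifelse(call$svlen > 1000, "gt1kb", "le1kb") &
                    table$svtype == call$svtype & table$tech == tech, , drop = FALSE]
    if (nrow(leaf) != 1L) stop_input("decision table has no unique leaf for call %d", i)
    predict_hom <- ratio >= leaf$threshold
    if (predict_hom && call$gt != "1|1") {
      calls$gt[i] <- "1|1"; calls$gt_flag[i] <- "GT_UPGRADED"
    } else if (!predict_hom && call$gt == "1|1") {
      hap <- 1L
      if ("haplotype" %in% names(sup) && any(!is.na(sup$haplotype))) {
        n2 <- sum(sup$haplotype == 2L, na.rm = TRUE)
        if (n2 > sum(sup$haplotype == 1L, na.rm = TRUE)) hap <- 2L
      }
      calls$gt[i] <- if (hap == 2L) "0|1" else "1|0"
      calls$gt_flag[i] <- "GT_DOWNGRADED"
    }
  }
  calls
}
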