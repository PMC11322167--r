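# Attribution of unphased reads to the haplotype of a phase block (PS_HP)
# by unique k-mer fingerprint similarity with an empirical-quantile
# significance test.

#' Candidate phase blocks for a read interval
#'
#' Rule 1: blocks overlapping the read are the candidates. Rule 2: a read in
#' the gap between two consecutive blocks gets both flanking blocks.
#' Rule 3: otherwise (chromosome ends) the single nearest block. Reads
#' spanning more than two blocks are restricted to the two with the largest
#' overlap.
#'
#' @param read_interval list or one-row data frame with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param blocks phase-block tibble (`block_id`, `chrom`, `start`, `end`),
#'   sorted and non-overlapping per chromosome.
#' @return tibble of 1 or 2 candidate block rows; zero rows (with a
#'   `status` attribute `"unassignable"`) when the chromosome has no blocks.
#' @export
assign_candidate_blocks <- function(read_interval, blocks) {
  ri <- as.list(read_interval)
  blk <- blocks[blocks$chrom == ri$chrom, , drop = FALSE]
  blk <- blk[order(blk$start), , drop = FALSE]
  if (nrow(blk) == 0L) {
    out <- blk
    attr(out, "status") <- "unassignable"
    return(out)
  }
  ov <- pmin(blk$end, ri$end) - pmax(blk$start, ri$start)
  if (any(ov > 0)) {
    hit <- blk[ov > 0, , drop = FALSE]
    if (nrow(hit) > 2L) hit <- hit[order(-ov[ov > 0])[1:2], , drop = FALSE]
    return(hit[order(hit$start), , drop = FALSE])
  }
  # gap between two consecutive blocks?
  before <- which(blk$end <= ri$start)
  after <- which(blk$start >= ri$end)
  if (length(before) && length(after))
    return(blk[c(max(before), min(after)), , drop = FALSE])
  # chromosome end: nearest block
  d <- pmax(blk$start - ri$end, ri$start - blk$end)
  blk[which.min(d), , drop = FALSE]
}

#' Build fingerprint (unique) k-mer sets for candidate PS_HPs
#'
#' For candidate raw k-mer sets R_1..R_m (one per haplotype of each
#' candidate block), the symmetric difference Delta keeps the k-mers present
#' in exactly one raw set, and the fingerprint of PS_HP i is
#' `F_i = R_i intersect Delta`. With one candidate block there are two
#' PS_HPs, with two blocks four.
#'
#' @param phased_reads tibble of phased reads with `seq`, `haplotype` and
#'   `block_id` columns; when `ref_start`/`ref_end` are present a read
#'   contributes to every candidate block its alignment overlaps (membership
#'   by interval), otherwise to its labelled block only. Overlap membership
#'   stops boundary-spanning reads from turning shared genomic k-mers into
#'   spurious haplotype fingerprints.
#' @param candidate_blocks tibble of 1 or 2 candidate block rows.
#' @param k,step k-mer length and stride.
#' @param min_reads a k-mer enters the raw set only when seen in at least
#'   this many distinct reads of the PS_HP (default 2, dropped to 1 for
#'   PS_HPs with fewer than 3 reads): sequencing-error k-mers are read
#'   singletons, so this keeps fingerprints to genuine haplotype sequence.
#' @return object of class `fingerprint_index`: list with `ps_hp` (tibble of
#'   block_id/haplotype), `raw` and `fingerprint` (lists of integer k-mer
#'   code sets), `k`, `step`.
#' @export
build_fingerprints <- function(phased_reads, candidate_blocks, k = 12L, step = 1L,
                               min_reads = 2L) {
  stopifnot(k >= 8L)
  # Membership by alignment overlap when read intervals are available:
  # majority-block attribution lets one haplotype's boundary coverage leak
  # shared genomic k-mers into the fingerprints as spurious uniques.
  by_overlap <- all(c("ref_start", "ref_end") %in% names(phased_reads))
  ps <- tidyr::expand_grid(block_id = candidate_blocks$block_id, haplotype = 1:2)
  raw <- purrr::pmap(ps, function(block_id, haplotype) {
    blk <- candidate_blocks[candidate_blocks$block_id == block_id, ]
    sel <- !is.na(phased_reads$haplotype) & phased_reads$haplotype == haplotype
    sel <- sel & if (by_overlap) {
      phased_reads$ref_end > blk$start & phased_reads$ref_start < blk$end
    } else {
      !is.na(phased_reads$block_id) & phased_reads$block_id == block_id
    }
    rd <- phased_reads[sel, , drop = FALSE]
    if (nrow(rd) == 0L) {
      warn(sprintf("PS_HP %s/hp%d has no phased reads; empty fingerprint", block_id, haplotype))
      return(list(raw = integer(0), supported = integer(0)))
    }
    per_read <- lapply(rd$seq, function(s) unique(kmer_codes(s, k = k, step = step)))
    pooled <- sort(unlist(per_read))
    need <- if (nrow(rd) < 3L) 1L else min_reads
    runs <- rle(pooled)
    list(raw = runs$values, supported = runs$values[runs$lengths >= need])
  })
  # Exclusion uses the unfiltered raw sets (one stray observation elsewhere
  # disqualifies a k-mer); the read-support requirement only gates entry
  # into a set's own fingerprint. With two candidate blocks, a read
  # overlapping both contributes the same k-mers to both blocks of its
  # haplotype, so uniqueness is evaluated between the per-haplotype unions
  # (a junction k-mer seen by one haplotype in both blocks is still a
  # haplotype fingerprint); block resolution comes from each set's own
  # members.
  raw_full <- lapply(raw, `[[`, "raw")
  supported <- lapply(raw, `[[`, "supported")
  if (nrow(candidate_blocks) == 2L && by_overlap) {
    u <- lapply(1:2, function(h) unique(unlist(raw_full[ps$haplotype == h])))
    shared <- intersect(u[[1]], u[[2]])
    delta <- setdiff(unique(unlist(u)), shared)
    fp <- lapply(supported, function(r) r[r %in% delta])
    return(structure(list(ps_hp = ps, raw = raw_full, fingerprint = fp,
                          k = k, step = step),
                     class = "fingerprint_index"))
  }
  fingerprint_from_raw(raw_full, ps, k, step, supported = supported)
}

# Core set arithmetic, shared with tests that supply raw sets directly:
# Delta keeps k-mers present in exactly one raw set; the fingerprint of set
# i is its (optionally support-filtered) members intersected with Delta.
fingerprint_from_raw <- function(raw, ps = NULL, k = 12L, step = 1L,
                                 supported = raw) {
  all_k <- unlist(raw)
  if (length(all_k)) {
    srt <- sort(all_k)
    dup <- unique(srt[duplicated(srt)])
    delta <- setdiff(unique(srt), dup)   # present in exactly one raw set
  } else delta <- integer(0)
  fp <- lapply(supported, function(r) r[r %in% delta])
  structure(list(ps_hp = ps, raw = raw, fingerprint = fp, k = k, step = step),
            class = "fingerprint_index")
}

#' Score a read against a fingerprint index
#'
#' `Sim_i = |S intersect F_i|` where S is the read's k-mer set;
#' `NormSim_i = Sim_i / sum(Sim)`. When all similarities are zero (or the
#' read is shorter than k) the normalised vector is undefined.
#'
#' @param read_seq a single read sequence.
#' @param index a [build_fingerprints()] result.
#' @return list with `sim` (integer vector), `norm_sim` (numeric vector or
#'   `NULL` when undefined) and `defined` flag.
#' @export
score_read <- function(read_seq, index) {
  if (nchar(read_seq) < index$k)
    return(list(sim = rep(0L, length(index$fingerprint)), norm_sim = NULL, defined = FALSE))
  s <- kmer_set(read_seq, index$k, index$step)
  sim <- vapply(index$fingerprint, function(f) sum(s %in% f), numeric(1))
  if (sum(sim) == 0)
    return(list(sim = sim, norm_sim = NULL, defined = FALSE))
  list(sim = sim, norm_sim = sim / sum(sim), defined = TRUE)
}

#' Empirical-quantile significance cutoff
#'
#' Linear-interpolation empirical quantile `Q_{1-r}` of the pooled
#' normalised-similarity vector.
#'
#' @param chi numeric vector of pooled normalised similarities.
#' @param level_r significance level r (default 0.1).
#' @return the cutoff value; `NA` for an empty vector.
#' @export
quantile_cutoff <- function(chi, level_r = 0.1) {
  if (!length(chi)) return(NA_real_)
  unname(quantile(chi, probs = 1 - level_r, type = 7, names = FALSE))
}

#' Assign unphased reads to PS_HPs
#'
#' Every unphased read is scored against the fingerprints of its candidate
#' blocks. The significance cutoff is the `(1-r)` empirical quantile of the
#' pooled null vector of normalised similarities: all (read, candidate)
#' values except, for each read, its maximum — the non-best candidates of a
#' diploid read are its chance associations and form the empirical null. A
#' read whose best normalised similarity exceeds the cutoff is assigned to
#' that PS_HP (exact ties are not assigned); any other read is assigned to
#' both haplotypes of its nearest phase block.
#'
#' @param reads read tibble (as from [simulate_reads()] or loaded
#'   externally) with `read_id`, `seq`, `ref_chrom`, `ref_start`, `ref_end`,
#'   `phased`, `haplotype`, `block_id` columns; rows with `phased == FALSE`
#'   are assigned, the others provide the fingerprints.
#' @param blocks phase-block tibble.
#' @param thresholds an [sv_thresholds()] list (`k`, `step`, `level_r`).
#' @return tibble, one row per unphased read: `read_id`, `decision`
#'   (`"assigned"` or `"both_haps"`), `block_id`, `haplotype` (`NA` for
#'   both-haplotype assignments), `best_norm_sim`, `cutoff_used`.
#' @export
assign_unphased_reads <- function(reads, blocks, thresholds = sv_thresholds()) {
  unph <- reads[!reads$phased, , drop = FALSE]
  phased <- reads[reads$phased, , drop = FALSE]
  if (nrow(unph) == 0L)
    return(tibble(read_id = character(0), decision = character(0),
                  block_id = character(0), haplotype = integer(0),
                  best_norm_sim = numeric(0), cutoff_used = numeric(0)))
  idx_cache <- new.env(parent = emptyenv())
  get_index <- function(cand) {
    key <- paste(cand$block_id, collapse = "+")
    if (!is.null(idx_cache[[key]])) return(idx_cache[[key]])
    idx <- suppressWarnings(
      build_fingerprints(phased, cand, k = thresholds$k, step = thresholds$step,
                         min_reads = thresholds$kmer_min_reads))
    idx_cache[[key]] <- idx
    idx
  }
  scored <- vector("list", nrow(unph))
  for (i in seq_len(nrow(unph))) {
    cand <- assign_candidate_blocks(
      list(chrom = unph$ref_chrom[i], start = unph$ref_start[i], end = unph$ref_end[i]),
      blocks)
    if (nrow(cand) == 0L) {
      scored[[i]] <- list(status = "unassignable"); next
    }
    idx <- get_index(cand)
    sc <- score_read(unph$seq[i], idx)
    nearest <- cand$block_id[which.min(pmax(cand$start - unph$ref_end[i],
                                            unph$ref_start[i] - cand$end,
                                            0))]
    scored[[i]] <- list(status = "scored", index = idx, score = sc, nearest = nearest)
  }
  # pooled leave-max-out null: every candidate attaining a read's maximum
  # is a potential true origin (two blocks of one haplotype can tie), so
  # only values strictly below the maximum enter the null
  null_vals <- unlist(lapply(scored, function(s) {
    if (!identical(s$status, "scored") || !s$score$defined) return(numeric(0))
    v <- s$score$norm_sim
    v[v < max(v)]
  }))
  cutoff <- quantile_cutoff(null_vals, thresholds$level_r)
  out <- vector("list", nrow(unph))
  for (i in seq_len(nrow(unph))) {
    s <- scored[[i]]
    if (identical(s$status, "unassignable")) {
      out[[i]] <- tibble(read_id = unph$read_id[i], decision = "unassignable",
                         block_id = NA_character_, haplotype = NA_integer_,
                         best_norm_sim = NA_real_, cutoff_used = cutoff)
      next
    }
    assigned <- FALSE
    best <- NA_real_
    if (s$score$defined) {
      v <- s$score$norm_sim
      best <- max(v)
      top <- which(v == best)
      # a tie between the two blocks of one haplotype still identifies the
      # haplotype (junction k-mers live in both blocks' fingerprints);
      # resolve the block by the larger read overlap. Ties across
      # haplotypes stay unassigned.
      if (length(top) > 1L) {
        hps <- s$index$ps_hp$haplotype[top]
        if (length(unique(hps)) == 1L) {
          ov <- vapply(top, function(tj) {
            blk <- s$index$ps_hp$block_id[tj]
            cb <- blocks[blocks$block_id == blk, ]
            min(cb$end, unph$ref_end[i]) - max(cb$start, unph$ref_start[i])
          }, numeric(1))
          top <- top[which.max(ov)]
        }
      }
      if (length(top) == 1L && !is.na(cutoff) && best > cutoff) {
        ps <- s$index$ps_hp[top, ]
        out[[i]] <- tibble(read_id = unph$read_id[i], decision = "assigned",
                           block_id = ps$block_id, haplotype = ps$haplotype,
                           best_norm_sim = best, cutoff_used = cutoff)
        assigned <- TRUE
      }
    }
    if (!assigned) {
      out[[i]] <- tibble(read_id = unph$read_id[i], decision = "both_haps",
                         block_id = s$nearest, haplotype = NA_integer_,
                         best_norm_sim = best, cutoff_used = cutoff)
    }
  }
  bind_rows(out)
}
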