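# Minimal Truvari-style evaluator for fixture benchmarking: greedy matching
# under refdist / size-ratio / sequence-similarity / reciprocal-overlap
# predicates, plus breakpoint-shift and alternate-sequence similarity
# summaries.

#' Breakpoint shift and sequence similarity of a matched pair
#'
#' DEL shift is `max(|delta start|, |delta end|)`; INS (and other
#' point-like types) use the start difference. Shifts above 200 bp are
#' reported in the `200+` bin. Sequence similarity is
#' `1 - editdist / max(len)` on the alternate (INS) or deleted-span (DEL)
#' sequences when both are available.
#'
#' @param call,truth one-row records with `svtype`, `start`/`pos`, `end`,
#'   `alt_seq`.
#' @return tibble: `svtype`, `breakpoint_shift`, `shift_bin`,
#'   `seq_similarity`.
#' @export
breakpoint_shift_and_seqsim <- function(call, truth) {
  cs <- call[["start"]] %||% call[["pos"]]; ts <- truth[["pos"]] %||% truth[["start"]]
  if (call$svtype != truth$svtype) stop_input("svtype mismatch in evaluation pair")
  shift <- if (call$svtype == "DEL") {
    max(abs(cs - ts), abs(call$end - truth$end))
  } else abs(cs - ts)
  sim <- NA_real_
  if (nzchar(call[["alt_seq"]] %||% "") && nzchar(truth[["alt_seq"]] %||% ""))
    sim <- seq_similarity(call$alt_seq, truth$alt_seq)
  tibble(svtype = call$svtype, breakpoint_shift = shift,
         shift_bin = ifelse(shift > 200, "200+", as.character(shift)),
         seq_similarity = sim)
}

#' Match SV calls against a truth set
#'
#' Greedy matching by ascending breakpoint distance under Truvari-style
#' predicates: same svtype, reference distance `<= refdist`, size ratio
#' `>= pctsize`, alternate-sequence similarity `>= pctsim` (skipped when
#' `pctsim = 0` or either sequence is missing), and reciprocal overlap
#' `>= pctovl` for DELs. Each truth record matches at most one call.
#' Genotype concordance is computed over the matched pairs when both sides
#' carry `gt`.
#'
#' @param calls call tibble (`chrom`, `start`, `end`, `svtype`, `svlen`,
#'   `alt_seq`, optionally `gt`, `chrom2`, `pos2`).
#' @param truth truth tibble ([generate_diploid_genome()] `$truth` layout).
#' @param refdist maximum reference distance r (default 500 bp; TRA
#'   breakends use 1000 bp on both ends).
#' @param pctsize minimum size ratio P (default 0.5).
#' @param pctsim minimum sequence similarity p (default 0.5).
#' @param pctovl minimum DEL reciprocal overlap O (default 0.01).
#' @param svtypes restrict evaluation to these types (default INS/DEL).
#' @return object of class `sv_eval`: list with `matches`, `fp`, `fn`
#'   tibbles, the parameters, and summary `metrics`.
#' @export
match_calls_to_truth <- function(calls, truth, refdist = 500, pctsize = 0.5,
                                 pctsim = 0.5, pctovl = 0.01,
                                 svtypes = c("INS", "DEL")) {
  truth <- truth[truth$svtype %in% svtypes, , drop = FALSE]
  calls <- calls[calls$svtype %in% svtypes, , drop = FALSE]
  if (!"start" %in% names(calls)) calls$start <- calls[["pos"]]
  if (!"end" %in% names(calls)) calls$end <- calls$start
  if (!"pos2" %in% names(calls)) calls$pos2 <- NA_real_
  if (!"chrom2" %in% names(calls)) calls$chrom2 <- NA_character_
  cand <- list()
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, ]
    for (j in seq_len(nrow(truth))) {
      tr <- truth[j, ]
      d <- match_distance(call, tr, refdist)
      if (is.na(d)) next
      if (!match_predicates(call, tr, pctsize, pctsim, pctovl)) next
      cand[[length(cand) + 1L]] <- tibble(call_i = i, truth_j = j, dist = d)
    }
  }
  cand <- if (length(cand)) bind_rows(cand) else tibble(call_i = integer(0), truth_j = integer(0), dist = numeric(0))
  cand <- cand[order(cand$dist, cand$call_i, cand$truth_j), , drop = FALSE]
  used_c <- logical(nrow(calls)); used_t <- logical(nrow(truth))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    ci <- cand$call_i[k]; tj <- cand$truth_j[k]
    if (used_c[ci] || used_t[tj]) next
    used_c[ci] <- TRUE; used_t[tj] <- TRUE
    rec <- breakpoint_shift_and_seqsim(calls[ci, ], truth[tj, ])
    gt_match <- NA
    if ("gt" %in% names(calls) && "gt" %in% names(truth))
      gt_match <- gt_equivalent(calls$gt[ci], truth$gt[tj])
    pairs[[length(pairs) + 1L]] <- dplyr::bind_cols(
      tibble(call_i = ci, truth_j = tj, chrom = calls$chrom[ci],
             call_start = calls$start[ci] %||% NA_real_, truth_pos = truth$pos[tj],
             call_svlen = calls$svlen[ci], truth_svlen = truth$svlen[tj],
             call_gt = if ("gt" %in% names(calls)) calls$gt[ci] else NA_character_,
             truth_gt = truth$gt[tj], gt_match = gt_match),
      rec)
  }
  matches <- if (length(pairs)) bind_rows(pairs) else NULL
  tp <- sum(used_t)
  metrics <- tibble(
    n_calls = nrow(calls), n_truth = nrow(truth), tp = tp,
    fp = nrow(calls) - sum(used_c), fn = nrow(truth) - tp,
    recall = ifelse(nrow(truth) > 0, tp / nrow(truth), NA_real_),
    precision = ifelse(nrow(calls) > 0, sum(used_c) / nrow(calls), NA_real_))
  metrics$f1 <- with(metrics, ifelse(recall + precision > 0,
                                     2 * recall * precision / (recall + precision), 0))
  metrics$gt_concordance <- if (!is.null(matches) && any(!is.na(matches$gt_match)))
    mean(matches$gt_match, na.rm = TRUE) else NA_real_
  metrics$median_shift <- if (!is.null(matches)) median(matches$breakpoint_shift) else NA_real_
  structure(list(matches = matches, fp = calls[!used_c, , drop = FALSE],
                 fn = truth[!used_t, , drop = FALSE], metrics = metrics,
                 params = list(refdist = refdist, pctsize = pctsize,
                               pctsim = pctsim, pctovl = pctovl)),
            class = "sv_eval")
}

# Genotypes are compared as unordered allele pairs: contig haplotype
# numbering within a phase block is arbitrary relative to the truth.
gt_equivalent <- function(a, b) {
  norm <- function(g) paste(sort(strsplit(g, "[|/]")[[1]]), collapse = "/")
  norm(a) == norm(b)
}

match_distance <- function(call, tr, refdist) {
  if (call$svtype != tr$svtype) return(NA_real_)
  if (call$svtype != "TRA" && call$chrom != tr$chrom) return(NA_real_)
  if (call$svtype == "TRA") {
    # junction orientation is arbitrary: compare both breakend pairings
    if (is.na(call$chrom2)) return(NA_real_)
    d_fwd <- if (call$chrom == tr$chrom && call$chrom2 == tr$chrom2)
      max(abs(call$start - tr$pos), abs(call$pos2 - tr$pos2)) else Inf
    d_rev <- if (call$chrom == tr$chrom2 && call$chrom2 == tr$chrom)
      max(abs(call$start - tr$pos2), abs(call$pos2 - tr$pos)) else Inf
    d <- min(d_fwd, d_rev)
    if (d <= 1000) return(d) else return(NA_real_)
  }
  d <- abs(call$start - tr$pos)
  if (d <= refdist) d else NA_real_
}

match_predicates <- function(call, tr, pctsize, pctsim, pctovl) {
  if (call$svtype == "TRA") return(TRUE)
  if (tr$svlen > 0 && svlen_sim(call$svlen, tr$svlen) < pctsize) return(FALSE)
  if (pctsim > 0 && call$svtype == "INS" &&
      nzchar(call[["alt_seq"]] %||% "") && nzchar(tr[["alt_seq"]] %||% "")) {
    if (seq_similarity(call$alt_seq, tr$alt_seq) < pctsim) return(FALSE)
  }
  if (call$svtype %in% c("DEL", "INV", "DUP")) {
    ovl <- min(call$end, tr$end) - max(call$start, tr$pos)
    recip <- ovl / max(call$end - call$start, tr$end - tr$pos)
    if (is.na(recip) || recip < pctovl) return(FALSE)
  }
  TRUE
}

#' @export
print.sv_eval <- function(x, ...) {
  cat("<sv_eval>\n")
  print(x$metrics)
  invisible(x)
}

#' @rdname match_calls_to_truth
#' @param x an `sv_eval` object.
#' @param ... unused.
#' @export
glance.sv_eval <- function(x, ...) x$metrics

#' @rdname match_calls_to_truth
#' @export
tidy.sv_eval <- function(x, ...) {
  if (is.null(x$matches)) return(tibble())
  as_tibble(x$matches)
}

#' @rdname match_calls_to_truth
#' @param object an `sv_eval` object.
#' @export
autoplot.sv_eval <- function(object, ...) {
  m <- tidy(object)
  if (nrow(m) == 0L) stop_input("no matches to plot")
  m$shift_plot <- pmin(m$breakpoint_shift, 200)
  ggplot(m, aes(x = .data$shift_plot)) +
    geom_histogram(binwidth = 10, boundary = 0) +
    facet_wrap(~svtype) +
    labs(x = "breakpoint shift (bp, 200+ binned)", y = "matched calls",
         title = "Breakpoint shift of true-positive calls") +
    theme_minimal()
}
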