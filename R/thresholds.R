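#' Pipeline thresholds
#'
#' The full configurable parameter table of the caller. Defaults follow the
#' method's published settings; per-technology deletion depth-band ratios
#' `(lb, rb)` are hifi (0.2, 2.6), clr (0.19, 3.0), ont (0.24, 2.8).
#'
#' @param ... named overrides of any default, e.g. `sv_thresholds(k = 15)`.
#' @return a list of class `sv_thresholds` with elements:
#' \describe{
#'   \item{th_dis}{minimum absolute `Diff_dis` of a split pair to call a
#'     signature (30 bp).}
#'   \item{th_olp}{maximum alignment overlap `Diff_olp` of a split pair
#'     (3000 bp).}
#'   \item{th_sim}{size/sequence similarity floor for clustering (0.5).}
#'   \item{th_sim_relax}{relaxed DEL size-similarity floor for redundancy
#'     removal (0.1).}
#'   \item{th_shift_intrahap}{breakpoint-shift cap for within-haplotype
#'     chaining (100 bp).}
#'   \item{th_shift_interhap}{breakpoint-shift cap for cross-haplotype
#'     pairing (200 bp).}
#'   \item{th_shift_redun_ins, th_shift_redun_del}{breakpoint-shift caps for
#'     one-to-K redundancy removal (500 / 300 bp).}
#'   \item{k, step}{k-mer length (12) and stride (1) shared by read
#'     partitioning and the small-indel content filter.}
#'   \item{kmer_min_reads}{distinct-read support needed for a k-mer to
#'     enter a haplotype raw set (2; error k-mers are singletons).}
#'   \item{level_r}{significance level of the quantile test (0.1).}
#'   \item{lb, rb}{per-technology deletion depth-band ratios (named vectors
#'     over hifi/clr/ont).}
#'   \item{neighborhood}{one-to-K positional neighbourhood flank (500 bp).}
#'   \item{min_sv_size}{minimum SV length (50 bp).}
#'   \item{read_filter_range}{size range in which the read-support filter
#'     applies (`c(50, 250)`).}
#'   \item{min_read_sig}{minimum read-signature length collected for
#'     filtering (25 bp, so a 50 bp call can still find a >0.5-ratio
#'     supporter).}
#'   \item{min_mapq}{MAPQ floor for supplementary alignments (20).}
#'   \item{kmer_content_min}{small-indel k-mer content fraction that must be
#'     read-backed (0.7, strict >).}
#'   \item{dup_max_edit}{maximum edit-distance fraction for duplication
#'     recovery re-alignment (0.2, i.e. >=80% query agreement).}
#' }
#' @export
sv_thresholds <- function(...) {
  th <- list(
    th_dis = 30, th_olp = 3000,
    th_sim = 0.5, th_sim_relax = 0.1,
    th_shift_intrahap = 100, th_shift_interhap = 200,
    th_shift_redun_ins = 500, th_shift_redun_del = 300,
    k = 12L, step = 1L, level_r = 0.1, kmer_min_reads = 2L,
    lb = c(hifi = 0.2, clr = 0.19, ont = 0.24),
    rb = c(hifi = 2.6, clr = 3.0, ont = 2.8),
    neighborhood = 500, min_sv_size = 50,
    read_filter_range = c(50, 250), min_read_sig = 25,
    min_mapq = 20, kmer_content_min = 0.7, dup_max_edit = 0.2
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(th))
  if (length(bad)) stop_input("unknown threshold(s): %s", paste(bad, collapse = ", "))
  th[names(dots)] <- dots
  structure(th, class = "sv_thresholds")
}

#' Default genotype decision table
#'
#' The genotype-refinement model is a decision tree over four categorical
#' inputs — contig-derived genotype (het/hom), SV size bin (<=1 kb / >1 kb),
#' SV type and sequencing technology — giving 24 leaves, each holding a
#' threshold on the relative read-support ratio (supporting read signatures /
#' local read depth). A ratio above the leaf threshold predicts a homozygote
#' (`1|1`); below, a heterozygote.
#'
#' The shipped thresholds are derived from the expected support ratio of
#' each class under a read-spanning model. A read supports a call only if
#' it spans the event with enough anchor sequence on both sides (about
#' `A ~ 2 kb` in total for a typical long-read aligner), so the expected
#' homozygous ratio is the spanning fraction `f = (L_read - svlen - A) /
#' L_read` for insertions (the whole inserted sequence must sit inside the
#' read) and `f = (L_read - A) / L_read` for deletions (only the junction
#' must be bridged); heterozygotes expect `f/2`. Each leaf threshold sits
#' at the midpoint of the het and hom expectations for its size bin: for
#' insertions above 1 kb the hom expectation collapses towards zero, which
#' is why those leaves are far lower, and lower still for contig-homozygous
#' calls where the question is only whether support is consistent with two
#' carrying haplotypes.
#'
#' @return tibble with columns `contig_gt` (`het`/`hom`), `size_bin`
#'   (`le1kb`/`gt1kb`), `svtype` (`INS`/`DEL`), `tech` (`hifi`/`clr`/`ont`)
#'   and `threshold`; exactly 24 rows.
#' @export
genotype_decision_table <- function() {
  base <- tidyr::expand_grid(
    contig_gt = c("het", "hom"),
    size_bin = c("le1kb", "gt1kb"),
    svtype = c("INS", "DEL"),
    tech = c("hifi", "clr", "ont")
  )
  thr <- function(contig_gt, size_bin, svtype, tech) {
    adj <- if (tech == "hifi") 0 else -0.05  # noisier reads support less
    # DEL support needs only junction-bridging reads, so the het/hom
    # expectations stay near f/2 and f at any size; large DELs keep the
    # whole carrier-haplotype read set as supporters, pushing het ratios up
    if (svtype == "DEL") return((if (size_bin == "le1kb") 0.65 else 0.75) + adj)
    if (size_bin == "le1kb") return(0.60 + adj)
    # INS > 1 kb: the spanning fraction collapses with size; towards the
    # top of the bin no read can contain the insertion, so support cannot
    # justify overriding a contig-homozygous call at all (threshold 0)
    if (contig_gt == "het") 0.55 + adj else 0
  }
  base$threshold <- purrr::pmap_dbl(base, thr)
  base
}
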