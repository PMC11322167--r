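# End-to-end orchestration: signatures -> clustering -> pairing -> filters
# -> dedupe -> genotype refinement -> complex SVs -> small indels, plus the
# file-level runner used by the CLI.

# Read-derived signatures are collected down to min_read_sig bp so that a
# 50 bp call can still find a supporter clearing the 0.5 size ratio.
collect_read_signatures <- function(read_segments, thresholds = sv_thresholds()) {
  th <- thresholds
  th$min_sv_size <- thresholds$min_read_sig
  collect_indel_signatures(read_segments, th)
}

# Per-haplotype genotyping of small indels: identical records seen from the
# contigs of both haplotypes of a block are homozygous.
genotype_small_indels <- function(small_indels) {
  if (nrow(small_indels) == 0L) return(dplyr::mutate(small_indels, gt = character(0)))
  key <- paste(small_indels$chrom, small_indels$pos, small_indels$ref_allele,
               small_indels$alt_allele, small_indels$block_id)
  out <- list()
  for (grp in split(seq_len(nrow(small_indels)), key)) {
    sub <- small_indels[grp, , drop = FALSE]
    haps <- unique(sub$haplotype[!is.na(sub$haplotype)])
    rep <- sub[1, , drop = FALSE]
    rep$gt <- if (length(haps) >= 2L) "1|1" else if (identical(haps, 1L)) "1|0" else "0|1"
    out[[length(out) + 1L]] <- rep
  }
  res <- bind_rows(out)
  res[order(res$chrom, res$pos), , drop = FALSE]
}

#' Call structural variants from contig and read alignments
#'
#' The full variant-calling stage over pre-loaded alignment segment tables:
#' large-indel signature extraction and per-haplotype clustering, cross-
#' haplotype pairing and genotyping, read-support and deletion depth-band
#' filtering, one-to-K redundancy removal, decision-tree genotype
#' refinement, complex-SV collection/filtering/duplication recovery, and
#' small-indel collection with the k-mer content filter.
#'
#' @param contig_segments contig alignment segments
#'   ([read_alignment_segments()]; contig names must encode provenance as
#'   `PS<block>_hp<h>_<n>`).
#' @param read_segments read alignment segments (a `haplotype` column, e.g.
#'   joined from the partitioner's output, enables per-haplotype support
#'   counting).
#' @param reference named character vector or `DNAStringSet`.
#' @param blocks phase-block tibble.
#' @param tech `"hifi"`, `"clr"` or `"ont"`.
#' @param thresholds an [sv_thresholds()] list.
#' @param gt_table genotype decision table.
#' @param regions optional target-region tibble (`chrom`, `start`, `end`):
#'   calls outside the regions are dropped.
#' @return object of class `sv_callset`: list with `calls` (large indels),
#'   `complex` (INV/TRA/DUP), `small_indels`, `read_sigs` and a `log`
#'   tibble of per-stage record counts.
#' @export
sv_call_pipeline <- function(contig_segments, read_segments, reference, blocks,
                             tech = "hifi", thresholds = sv_thresholds(),
                             gt_table = genotype_decision_table(),
                             regions = NULL) {
  log <- list()
  note <- function(stage, n) log[[length(log) + 1L]] <<- tibble(stage = stage, n = n)

  sigs <- collect_indel_signatures(contig_segments, thresholds)
  note("contig_signatures", nrow(sigs))
  clustered <- cluster_intrahap(sigs, thresholds)
  note("intrahap_clusters", nrow(clustered))
  calls <- pair_haplotypes(clustered, thresholds)
  note("paired_calls", nrow(calls))

  read_sigs <- collect_read_signatures(read_segments, thresholds)
  note("read_signatures", nrow(read_sigs))
  calls <- filter_by_read_support(calls, read_sigs, thresholds)
  note("after_support_filter", nrow(calls))
  calls <- filter_del_by_depth(calls, read_sigs, tech, thresholds)
  note("after_del_depth_filter", nrow(calls))
  calls <- dedupe_one_to_k(calls, thresholds, reference)
  note("after_dedupe", nrow(calls))
  calls <- refine_genotype(calls, read_sigs, read_segments, tech, gt_table, thresholds)

  # complex SVs
  bnds <- collect_complex_signatures(contig_segments, thresholds, reference)
  cplx <- merge_complex_calls(bnds)
  note("complex_candidates", nrow(cplx))
  inv <- filter_inversions(cplx[cplx$svtype == "INV", , drop = FALSE], read_segments)
  tra <- filter_translocations(cplx[cplx$svtype == "TRA", , drop = FALSE], read_segments)
  dup_direct <- cplx[cplx$svtype == "DUP", , drop = FALSE]
  rec <- recover_duplications(calls[calls$svtype == "INS", , drop = FALSE],
                              reference, thresholds)
  calls <- bind_rows(rec$ins_calls, calls[calls$svtype != "INS", , drop = FALSE])
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  dup_rec <- rec$dup_calls
  if (nrow(dup_rec)) {
    dup_rec <- tibble(svtype = "DUP", chrom = dup_rec$chrom, pos = dup_rec$start,
                      end = dup_rec$end, chrom2 = NA_character_, pos2 = NA_real_,
                      svlen = dup_rec$svlen, haplotype = dup_rec$haplotype,
                      block_id = dup_rec$block_id, source_name = dup_rec$source_name,
                      gt = dup_rec$gt)
  }
  dups <- merge_complex_calls(bind_rows(dup_direct, dup_rec))
  cplx_final <- bind_rows(inv, tra, dups)
  note("complex_final", nrow(cplx_final))

  # small indels
  small <- collect_small_indels(contig_segments, reference)
  note("small_indel_candidates", nrow(small))
  small <- kmer_content_filter(small, read_segments, thresholds)
  small <- genotype_small_indels(small)
  note("small_indels_final", nrow(small))

  if (!is.null(regions)) {
    in_regions <- function(chrom, pos) {
      vapply(seq_along(chrom), function(i)
        any(regions$chrom == chrom[i] & regions$start <= pos[i] & pos[i] < regions$end),
        logical(1))
    }
    calls <- calls[in_regions(calls$chrom, calls$start), , drop = FALSE]
    if (nrow(cplx_final)) cplx_final <- cplx_final[in_regions(cplx_final$chrom, cplx_final$pos), , drop = FALSE]
    if (nrow(small)) small <- small[in_regions(small$chrom, small$pos), , drop = FALSE]
  }

  structure(list(calls = calls, complex = cplx_final, small_indels = small,
                 read_sigs = read_sigs, log = bind_rows(log)),
            class = "sv_callset")
}

#' @export
print.sv_callset <- function(x, ...) {
  cat("<sv_callset>\n")
  print(x$log)
  invisible(x)
}

#' @rdname sv_call_pipeline
#' @param x,object an `sv_callset`.
#' @param ... unused.
#' @export
tidy.sv_callset <- function(x, ...) {
  large <- if (nrow(x$calls)) dplyr::transmute(
    x$calls, chrom = .data$chrom, pos = .data$start, end = .data$end,
    svtype = .data$svtype, svlen = .data$svlen, gt = .data$gt,
    chrom2 = NA_character_, pos2 = NA_real_) else NULL
  cplx <- if (nrow(x$complex)) dplyr::transmute(
    x$complex, chrom = .data$chrom, pos = .data$pos, end = .data$end,
    svtype = .data$svtype, svlen = .data$svlen, gt = .data$gt,
    chrom2 = .data$chrom2, pos2 = .data$pos2) else NULL
  out <- bind_rows(large, cplx)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' @rdname sv_call_pipeline
#' @export
glance.sv_callset <- function(x, ...) {
  tibble(n_large_indel = nrow(x$calls), n_complex = nrow(x$complex),
         n_small_indel = nrow(x$small_indels))
}

#' @rdname sv_call_pipeline
#' @export
autoplot.sv_callset <- function(object, ...) {
  d <- tidy(object)
  d$size_bin <- cut(pmax(d$svlen, 1), c(0, 100, 250, 500, 1000, 2500, 10000, Inf))
  ggplot(d[d$svlen > 0, ], aes(x = .data$size_bin, fill = .data$gt)) +
    geom_col(aes(y = 1), position = "stack") +
    facet_wrap(~svtype, scales = "free_y") +
    labs(x = "SV size bin (bp)", y = "calls", title = "Call-set size spectrum") +
    theme_minimal()
}

#' Run the whole pipeline on files
#'
#' Loads reference, phase blocks and BAMs, runs [sv_call_pipeline()] and
#' writes a phased VCF plus a per-stage count log. This is the engine behind
#' the command-line `call` subcommand.
#'
#' @param contig_bam,read_bam coordinate-sorted BAM paths.
#' @param ref_fa reference FASTA path.
#' @param blocks_tsv phase-block TSV (block_id, chrom, start, end).
#' @param out_vcf output VCF path.
#' @param tech sequencing technology.
#' @param read_haplotypes optional tibble (`read_id`, `haplotype`) from the
#'   partitioner.
#' @param thresholds an [sv_thresholds()] list.
#' @return the `sv_callset`, invisibly; writes `out_vcf`.
#' @export
run_call_pipeline <- function(contig_bam, read_bam, ref_fa, blocks_tsv, out_vcf,
                              tech = "hifi", read_haplotypes = NULL,
                              thresholds = sv_thresholds()) {
  reference <- Biostrings::readDNAStringSet(ref_fa)
  names(reference) <- sub("\\s.*$", "", names(reference))
  blocks <- as_tibble(utils::read.delim(blocks_tsv, colClasses = c(block_id = "character")))
  contig_segments <- read_alignment_segments(contig_bam, thresholds$min_mapq)
  read_segments <- read_alignment_segments(read_bam, thresholds$min_mapq)
  read_segments$haplotype <- NA_integer_
  if (!is.null(read_haplotypes))
    read_segments$haplotype <- read_haplotypes$haplotype[
      match(read_segments$source_name, read_haplotypes$read_id)]
  cs <- sv_call_pipeline(contig_segments, read_segments, reference, blocks,
                         tech = tech, thresholds = thresholds)
  write_phased_vcf(tidy(cs), reference, out_vcf,
                   small_indels = cs$small_indels, blocks = blocks)
  invisible(cs)
}

#' Simulate, align, call and evaluate in one run
#'
#' Generates a seeded diploid fixture, simulates reads, aligns contigs and
#' reads with minimap2, partitions the hidden-provenance reads, runs the
#' calling pipeline and evaluates the calls against the implanted truth.
#' Identical configuration and seed give a byte-identical VCF.
#'
#' @param outdir output directory.
#' @param ref_length,spec,het_fraction,n_chrom,n_blocks fixture parameters
#'   (see [generate_diploid_genome()]).
#' @param coverage per-haplotype read coverage.
#' @param tech sequencing technology (sets aligner preset and error rates
#'   unless `error_rates` is given).
#' @param error_rates optional named error-rate vector overriding the
#'   technology preset.
#' @param read_length read length distribution `c(mean, sd)`.
#' @param unphased_fraction fraction of reads with hidden provenance.
#' @param seed integer seed for every stochastic step.
#' @param thresholds an [sv_thresholds()] list.
#' @return list with the fixture, reads, assignments, `sv_callset`, the
#'   `sv_eval` against truth, and paths of the written files.
#' @export
run_all <- function(outdir, ref_length = 1e6,
                    spec = variant_spec(c("INS", "DEL"), c(20, 20), 50, 10000),
                    het_fraction = 0.5, n_chrom = 1, n_blocks = 4,
                    coverage = 15, tech = "hifi", error_rates = NULL,
                    read_length = c(12000, 2000), unphased_fraction = 0.25,
                    seed = 1, thresholds = sv_thresholds()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fixture <- generate_diploid_genome(ref_length, spec, het_fraction,
                                     n_chrom, n_blocks, seed = seed)
  reads <- simulate_reads(fixture, coverage, read_length,
                          error_rates %||% tech, unphased_fraction, seed = seed + 1)
  write_fixture(fixture, outdir, reads)
  emit_truth_vcf(fixture, file.path(outdir, "truth.vcf"))

  preset <- switch(tech, hifi = "map-hifi", clr = "map-pb", ont = "map-ont")
  contig_bam <- file.path(outdir, "contigs.bam")
  read_bam <- file.path(outdir, "reads.bam")
  align_minimap2(file.path(outdir, "contigs.fa"), file.path(outdir, "reference.fa"),
                 contig_bam, preset = "asm5")
  align_minimap2(file.path(outdir, "reads.fa"), file.path(outdir, "reference.fa"),
                 read_bam, preset = preset)

  assignments <- assign_unphased_reads(reads, fixture$blocks, thresholds)
  hap_of <- reads$haplotype
  idx <- match(assignments$read_id[assignments$decision == "assigned"], reads$read_id)
  hap_of[idx] <- assignments$haplotype[assignments$decision == "assigned"]
  read_haplotypes <- tibble(read_id = reads$read_id, haplotype = hap_of)

  out_vcf <- file.path(outdir, "variants.vcf")
  cs <- run_call_pipeline(contig_bam, read_bam,
                          file.path(outdir, "reference.fa"),
                          file.path(outdir, "blocks.tsv"), out_vcf,
                          tech = tech, read_haplotypes = read_haplotypes,
                          thresholds = thresholds)
  ev <- match_calls_to_truth(cs$calls, fixture$truth)
  utils::write.table(cs$log, file.path(outdir, "stage_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(glance(ev), file.path(outdir, "eval_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(fixture = fixture, reads = reads, assignments = assignments,
       callset = cs, eval = ev,
       paths = list(vcf = out_vcf, truth = file.path(outdir, "truth.vcf")))
}
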