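# Synthetic diploid fixtures: a base reference with implanted variants on
# one or both haplotypes, phase blocks, per-block haplotype contigs and
# error-bearing simulated reads with known provenance. Everything downstream
# of the external assembler/phaser can be exercised against these fixtures
# with exact ground truth.

#' Describe the variants to implant in a fixture
#'
#' @param svtype character vector over {SNP, INS, DEL, INV, DUP, TRA}.
#' @param n number of variants of each type.
#' @param min_size,max_size inclusive size range in bp (ignored for SNP and
#'   TRA; sizes are drawn uniformly).
#' @return a tibble understood by [generate_diploid_genome()].
#' @export
variant_spec <- function(svtype, n, min_size = 50, max_size = 500) {
  tibble(svtype = svtype, n = as.integer(n),
         min_size = rep_len(min_size, length(svtype)),
         max_size = rep_len(max_size, length(svtype)))
}

#' Generate a synthetic diploid genome with a known truth set
#'
#' Implants the requested variants into a random reference. Heterozygous
#' variants land on exactly one haplotype, homozygous on both. Variants are
#' placed by rejection sampling with a minimum inter-variant gap (default
#' 1 kb) and are kept clear of phase-block boundaries and chromosome ends so
#' that per-variant signatures never interact. Translocations are simulated
#' as a reciprocal exchange of two terminal segments between two
#' chromosomes; each chromosome participates in at most one exchange.
#'
#' @param ref_length total reference length in bp, split evenly over
#'   `n_chrom` chromosomes.
#' @param spec a [variant_spec()] tibble.
#' @param het_fraction proportion of variants that are heterozygous.
#' @param n_chrom number of chromosomes.
#' @param n_blocks number of phase blocks per chromosome.
#' @param min_gap minimum gap between implanted variants (and from block
#'   boundaries), bp.
#' @param seed integer seed; identical inputs and seed give byte-identical
#'   fixtures.
#' @return an object of class `diploid_fixture`: a list with `reference`,
#'   `hap1`, `hap2` (named character vectors per chromosome), `truth`
#'   (tibble: chrom, pos, end, svtype, svlen, gt, alt_seq, chrom2, pos2),
#'   `blocks` (tibble: block_id, chrom, start, end), coordinate shift maps,
#'   and the seed.
#' @export
generate_diploid_genome <- function(ref_length, spec, het_fraction = 0.5,
                                    n_chrom = 1, n_blocks = 4,
                                    min_gap = 1000, seed = 1) {
  stopifnot(ref_length >= 1000, n_chrom >= 1, n_blocks >= 1)
  if (any(spec$n > 0 & spec$svtype == "TRA") && n_chrom < 2)
    stop_input("TRA variants need at least two chromosomes")
  with_seed(seed, {
    chrom_len <- floor(ref_length / n_chrom)
    chroms <- sprintf("chr%d", seq_len(n_chrom))
    reference <- setNames(vapply(chroms, function(x) random_dna(chrom_len), character(1)), chroms)

    # phase blocks: equal partition of every chromosome
    blocks <- purrr::map_dfr(seq_along(chroms), function(ci) {
      bs <- floor(seq(0, chrom_len, length.out = n_blocks + 1))
      tibble(chrom = chroms[ci], start = bs[-length(bs)], end = bs[-1])
    })
    blocks$block_id <- as.character(seq_len(nrow(blocks)))
    blocks <- blocks[, c("block_id", "chrom", "start", "end")]

    boundaries <- lapply(chroms, function(ch) sort(unique(c(0, blocks$end[blocks$chrom == ch], blocks$start[blocks$chrom == ch]))))
    names(boundaries) <- chroms

    # SNPs only need enough isolation to keep k-mer windows distinct; SVs
    # keep the full min_gap so their signatures never interact
    snp_gap <- 150
    placed <- lapply(chroms, function(ch) tibble(s = numeric(0), e = numeric(0), gap = numeric(0)))
    names(placed) <- chroms
    ok_spot <- function(ch, s, e, gap = min_gap) {
      # no crossing of any boundary pad, no overlap with existing footprints
      b <- boundaries[[ch]]
      if (any(s - gap < b & b < e + gap)) return(FALSE)
      p <- placed[[ch]]
      g <- pmax(gap, p$gap)
      !any(s - g < p$e & p$s < e + g)
    }

    truth <- tibble(chrom = character(0), pos = numeric(0), end = numeric(0),
                    svtype = character(0), svlen = numeric(0), gt = character(0),
                    alt_seq = character(0), chrom2 = character(0), pos2 = numeric(0))
    draw_gt <- function() {
      if (runif(1) < het_fraction) {
        if (runif(1) < 0.5) "1|0" else "0|1"
      } else "1|1"
    }
    max_try <- 5000

    # reciprocal translocations first: distinct chromosome pairs
    n_tra <- sum(spec$n[spec$svtype == "TRA"])
    if (n_tra > floor(n_chrom / 2))
      stop_input("capacity error: %d TRA need %d chromosomes, have %d",
                 n_tra, 2 * n_tra, n_chrom)
    tra_chroms <- if (n_tra > 0) matrix(sample(chroms, 2 * n_tra), ncol = 2) else NULL
    for (i in seq_len(n_tra)) {
      c1 <- tra_chroms[i, 1]; c2 <- tra_chroms[i, 2]
      done <- FALSE
      for (t in seq_len(max_try)) {
        p1 <- floor(runif(1, 0.35, 0.65) * chrom_len)
        p2 <- floor(runif(1, 0.35, 0.65) * chrom_len)
        if (ok_spot(c1, p1, p1) && ok_spot(c2, p2, p2)) {
          placed[[c1]] <- bind_rows(placed[[c1]], tibble(s = p1, e = p1, gap = min_gap))
          placed[[c2]] <- bind_rows(placed[[c2]], tibble(s = p2, e = p2, gap = min_gap))
          truth <- bind_rows(truth, tibble(
            chrom = c1, pos = p1, end = p1, svtype = "TRA", svlen = 0,
            gt = draw_gt(), alt_seq = "", chrom2 = c2, pos2 = p2))
          done <- TRUE; break
        }
      }
      if (!done) stop_input("capacity error: could not place TRA junction %d", i)
    }

    # remaining variants, largest first for packing
    other <- spec[spec$svtype != "TRA" & spec$n > 0, , drop = FALSE]
    todo <- purrr::map_dfr(seq_len(nrow(other)), function(i) {
      row <- other[i, ]
      size <- if (row$svtype == "SNP") rep(1, row$n) else
        floor(runif(row$n, row$min_size, row$max_size + 1))
      tibble(svtype = row$svtype, svlen = size)
    })
    if (!"svlen" %in% names(todo)) todo <- tibble(svtype = character(0), svlen = numeric(0))
    todo <- todo[order(-todo$svlen), , drop = FALSE]
    need <- sum(todo$svlen + 2 * ifelse(todo$svtype == "SNP", snp_gap, min_gap))
    if (need > 0.9 * ref_length)
      stop_input("capacity error: requested variants need ~%d bp of %d bp reference", need, ref_length)
    for (i in seq_len(nrow(todo))) {
      vt <- todo$svtype[i]; len <- todo$svlen[i]
      fp <- switch(vt, SNP = 1, INS = 1, len)  # reference footprint
      gap <- if (vt == "SNP") snp_gap else min_gap
      done <- FALSE
      for (t in seq_len(max_try)) {
        ch <- sample(chroms, 1)
        pos <- floor(runif(1, gap + 1, chrom_len - fp - gap - 1))
        if (ok_spot(ch, pos, pos + fp, gap)) {
          placed[[ch]] <- bind_rows(placed[[ch]], tibble(s = pos, e = pos + fp, gap = gap))
          refseq <- reference[[ch]]
          alt <- switch(vt,
            SNP = {
              old <- str_sub(refseq, pos + 1, pos + 1)
              sample(setdiff(c("A", "C", "G", "T"), old), 1)
            },
            INS = random_dna(len),
            DUP = str_sub(refseq, pos + 1, pos + len),
            "")
          truth <- bind_rows(truth, tibble(
            chrom = ch, pos = pos, end = pos + ifelse(vt %in% c("SNP", "INS"), ifelse(vt == "SNP", 1, 0), len),
            svtype = vt, svlen = ifelse(vt == "SNP", 0, len),
            gt = draw_gt(), alt_seq = alt, chrom2 = NA_character_, pos2 = NA_real_))
          done <- TRUE; break
        }
      }
      if (!done) stop_input("capacity error: could not place %s of %d bp", vt, len)
    }
    truth <- truth[order(match(truth$chrom, chroms), truth$pos), , drop = FALSE]

    # build haplotype sequences
    haps <- list(); shifts <- list(); tra_info <- list(`1` = list(), `2` = list())
    for (h in 1:2) {
      carrier <- substr(truth$gt, ifelse(h == 1, 1, 3), ifelse(h == 1, 1, 3)) == "1"
      hs <- list(); sh <- list()
      for (ch in chroms) {
        vars <- truth[carrier & truth$chrom == ch & truth$svtype != "TRA", , drop = FALSE]
        ap <- apply_variants_chrom(reference[[ch]], vars)
        hs[[ch]] <- ap$seq; sh[[ch]] <- ap$shifts
      }
      # reciprocal terminal exchanges
      tras <- truth[carrier & truth$svtype == "TRA", , drop = FALSE]
      for (i in seq_len(nrow(tras))) {
        c1 <- tras$chrom[i]; c2 <- tras$chrom2[i]
        j1 <- ref2hap(tras$pos[i], sh[[c1]]); j2 <- ref2hap(tras$pos2[i], sh[[c2]])
        a <- hs[[c1]]; b <- hs[[c2]]
        hs[[c1]] <- paste0(str_sub(a, 1, j1), str_sub(b, j2 + 1))
        hs[[c2]] <- paste0(str_sub(b, 1, j2), str_sub(a, j1 + 1))
        tra_info[[h]][[c1]] <- list(junction = j1, donor = c2, donor_junction = j2)
        tra_info[[h]][[c2]] <- list(junction = j2, donor = c1, donor_junction = j1)
      }
      haps[[h]] <- unlist(hs); shifts[[h]] <- sh
    }

    structure(list(
      reference = reference, hap1 = haps[[1]], hap2 = haps[[2]],
      truth = truth, blocks = blocks, shifts = shifts, tra_info = tra_info,
      chrom_len = chrom_len, seed = seed
    ), class = "diploid_fixture")
  })
}

#' @export
print.diploid_fixture <- function(x, ...) {
  cat(sprintf("<diploid_fixture> %d chromosome(s) x %d bp, %d truth variants, %d phase blocks, seed %d\n",
              length(x$reference), x$chrom_len, nrow(x$truth), nrow(x$blocks), x$seed))
  print(dplyr::count(x$truth, .data$svtype, .data$gt))
  invisible(x)
}

# Haplotype sequence accessor (h in 1:2).
fixture_hap <- function(fixture, h) if (h == 1) fixture$hap1 else fixture$hap2

#' Emit per-phase-block haplotype contigs
#'
#' Each haplotype chromosome is cut at the haplotype-mapped phase-block
#' boundaries, emulating the per-block local assembly of the production
#' pipeline; by default contigs are error-free copies of the haplotype.
#' When a reciprocal translocation is carried, boundaries beyond the
#' junction are dropped so the junction-spanning contig retains the
#' exchanged tail. Contig names encode provenance as `PS<block>_hp<h>_<n>`.
#'
#' @param fixture a [generate_diploid_genome()] result.
#' @return tibble: `name`, `block_id`, `haplotype`, `chrom`, `seq`.
#' @export
fixture_contigs <- function(fixture) {
  out <- list()
  for (h in 1:2) {
    hapseq <- fixture_hap(fixture, h)
    for (ch in names(fixture$reference)) {
      blk <- fixture$blocks[fixture$blocks$chrom == ch, , drop = FALSE]
      sh <- fixture$shifts[[h]][[ch]]
      cuts <- ref2hap(blk$start[-1], sh)
      L <- nchar(hapseq[[ch]])
      tra <- fixture$tra_info[[h]][[ch]]
      if (!is.null(tra)) cuts <- cuts[cuts < tra$junction]
      cuts <- sort(unique(c(0, cuts, L)))
      for (i in seq_len(length(cuts) - 1)) {
        out[[length(out) + 1]] <- tibble(
          name = sprintf("PS%s_hp%d_%d", blk$block_id[i], h, 1L),
          block_id = blk$block_id[i], haplotype = h, chrom = ch,
          seq = str_sub(hapseq[[ch]], cuts[i] + 1, cuts[i + 1]))
      }
    }
  }
  bind_rows(out)
}

#' Inject artifact indels into contig sequences
#'
#' Adds small indels to contigs only (not to the underlying haplotypes or
#' reads), emulating assembly errors; used to exercise the read-evidence
#' filters. Artifacts are placed uniformly at least 100 bp from contig ends.
#'
#' @param contigs a [fixture_contigs()] tibble.
#' @param n_per_contig artifacts per contig.
#' @param size_range indel size range, bp.
#' @param seed integer seed.
#' @return list with `contigs` (modified tibble) and `artifacts`
#'   (tibble: name, contig_pos, svtype, svlen).
#' @export
inject_contig_artifacts <- function(contigs, n_per_contig = 1,
                                    size_range = c(5, 20), seed = 1) {
  with_seed(seed, {
    arts <- list()
    # an artifact junction with micro-homology to the removed/inserted
    # sequence is formally a genuine variant shifted by the homology, so
    # injected artifacts avoid it (they model *detectable* assembly errors)
    no_homology <- function(left, mid, right) {
      nchar(mid) > 0 && str_sub(mid, 1, 1) != str_sub(right, 1, 1) &&
        str_sub(mid, -1, -1) != str_sub(left, -1, -1)
    }
    for (i in seq_len(nrow(contigs))) {
      s <- contigs$seq[i]
      for (j in seq_len(n_per_contig)) {
        len <- sample(size_range[1]:size_range[2], 1)
        for (try in 1:100) {
          pos <- sample(seq(100, nchar(s) - 100 - len), 1)  # 0-based
          left <- str_sub(s, pos, pos); right <- str_sub(s, pos + len + 1, pos + len + 1)
          if (runif(1) < 0.5) {
            ins <- random_dna(len)
            if (!no_homology(str_sub(s, 1, pos), ins, str_sub(s, pos + 1))) next
            s <- paste0(str_sub(s, 1, pos), ins, str_sub(s, pos + 1))
            arts[[length(arts) + 1]] <- tibble(name = contigs$name[i], contig_pos = pos,
                                               svtype = "INS", svlen = len)
          } else {
            mid <- str_sub(s, pos + 1, pos + len)
            if (!no_homology(str_sub(s, 1, pos), mid, str_sub(s, pos + len + 1))) next
            s <- paste0(str_sub(s, 1, pos), str_sub(s, pos + len + 1))
            arts[[length(arts) + 1]] <- tibble(name = contigs$name[i], contig_pos = pos,
                                               svtype = "DEL", svlen = len)
          }
          break
        }
      }
      contigs$seq[i] <- s
    }
    list(contigs = contigs, artifacts = bind_rows(arts))
  })
}

# Project a haplotype-coordinate interval of a sample chromosome back onto
# the reference (start-point segment decides the chromosome when a
# translocated tail is involved).
project_to_reference <- function(fixture, h, chrom, s, e) {
  tra <- fixture$tra_info[[h]][[chrom]]
  sh <- fixture$shifts[[h]][[chrom]]
  if (!is.null(tra) && s >= tra$junction) {
    dsh <- fixture$shifts[[h]][[tra$donor]]
    dpos <- tra$donor_junction + (c(s, e) - tra$junction)
    return(list(chrom = tra$donor, start = hap2ref(dpos[1], dsh), end = hap2ref(dpos[2], dsh)))
  }
  list(chrom = chrom, start = hap2ref(s, sh), end = hap2ref(min(e, if (!is.null(tra)) tra$junction else e), sh))
}

#' Simulate error-bearing long reads from a fixture
#'
#' Reads are drawn uniformly from each haplotype of each chromosome until
#' the requested per-haplotype coverage is reached (within 5%). A
#' configurable fraction of reads is emitted with provenance hidden
#' ("unphased") to exercise the read partitioner; the remainder carry their
#' phase-block and haplotype labels, emulating the output of an upstream
#' phaser.
#'
#' @param fixture a [generate_diploid_genome()] result.
#' @param coverage fold coverage per haplotype.
#' @param read_length `c(mean, sd)` of the (truncated normal) read length
#'   distribution, bp.
#' @param error_rates either a technology name (`"hifi"`, `"clr"`, `"ont"`)
#'   or a named numeric vector `c(sub=, ins=, del=)`; use `c(0, 0, 0)` for
#'   error-free reads.
#' @param unphased_fraction fraction of reads whose provenance is hidden
#'   (default 0.25: roughly three quarters of real long reads are phased by
#'   an upstream phaser).
#' @param seed integer seed.
#' @return tibble: `read_id`, `seq`, `chrom`, `hap_start`, `hap_end`
#'   (haplotype coordinates), `ref_start`, `ref_end`, `ref_chrom`
#'   (reference projection), `true_hap`, `true_block`, `phased`, `haplotype`
#'   and `block_id` (visible labels; `NA` for unphased reads).
#' @export
simulate_reads <- function(fixture, coverage, read_length = c(12000, 2000),
                           error_rates = c(sub = 0, ins = 0, del = 0),
                           unphased_fraction = 0.25, seed = 1) {
  stopifnot(coverage > 0)
  if (is.character(error_rates)) error_rates <- error_preset(error_rates)
  if (any(error_rates < 0) || sum(error_rates) >= 0.3)
    stop_input("error rates must be in [0, 0.3)")
  with_seed(seed, {
    rows <- list()
    for (h in 1:2) {
      hapseq <- fixture_hap(fixture, h)
      for (ch in names(hapseq)) {
        L <- nchar(hapseq[[ch]])
        if (read_length[1] > L)
          stop_input("mean read length %d exceeds haplotype length %d", read_length[1], L)
        target <- coverage * L
        total <- 0
        min_piece <- min(2000, floor(L / 2))
        while (total < target) {
          len <- round(rnorm(1, read_length[1], read_length[2]))
          len <- max(min(len, L), min_piece)
          if (total + len > 1.03 * target) len <- max(round(target - total), min_piece)
          # starts may overhang the ends (reads are clipped), keeping
          # coverage uniform up to the terminal bases
          start <- floor(runif(1, -(len - min_piece), L - min_piece + 1))
          s <- max(start, 0); e <- min(start + len, L)
          rows[[length(rows) + 1]] <- tibble(chrom = ch, true_hap = h,
                                             hap_start = s, hap_end = e)
          total <- total + (e - s)
        }
      }
    }
    reads <- bind_rows(rows)
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
    reads$read_id <- sprintf("rd%05d", seq_len(nrow(reads)))

    proj <- purrr::pmap(list(reads$true_hap, reads$chrom, reads$hap_start, reads$hap_end),
                        function(h, ch, s, e) project_to_reference(fixture, h, ch, s, e))
    reads$ref_chrom <- purrr::map_chr(proj, "chrom")
    reads$ref_start <- purrr::map_dbl(proj, "start")
    reads$ref_end <- purrr::map_dbl(proj, "end")

    # true block: largest reference overlap on the projected chromosome
    reads$true_block <- purrr::pmap_chr(
      list(reads$ref_chrom, reads$ref_start, reads$ref_end),
      function(ch, s, e) {
        blk <- fixture$blocks[fixture$blocks$chrom == ch, , drop = FALSE]
        ov <- pmin(blk$end, e) - pmax(blk$start, s)
        if (!length(ov) || max(ov) <= 0) NA_character_ else blk$block_id[which.max(ov)]
      })

    seqs <- character(nrow(reads))
    for (i in seq_len(nrow(reads))) {
      s <- str_sub(fixture_hap(fixture, reads$true_hap[i])[[reads$chrom[i]]],
                   reads$hap_start[i] + 1, reads$hap_end[i])
      seqs[i] <- mutate_sequence(s, error_rates[["sub"]], error_rates[["ins"]], error_rates[["del"]])
    }
    reads$seq <- seqs
    reads$phased <- runif(nrow(reads)) >= unphased_fraction
    reads$haplotype <- ifelse(reads$phased, reads$true_hap, NA_integer_)
    reads$block_id <- ifelse(reads$phased, reads$true_block, NA_character_)
    reads[, c("read_id", "seq", "chrom", "true_hap", "hap_start", "hap_end",
              "ref_chrom", "ref_start", "ref_end", "true_block", "phased",
              "haplotype", "block_id")]
  })
}

#' Write fixture sequences to FASTA
#'
#' Writes `reference.fa`, `contigs.fa` and `reads.fa` (plus provenance and
#' phase-block TSVs) under `dir` for the alignment-backed pipeline steps.
#'
#' @param fixture a [generate_diploid_genome()] result.
#' @param dir output directory (created if needed).
#' @param reads optional [simulate_reads()] tibble.
#' @param contigs optional [fixture_contigs()] tibble (defaults to error-free
#'   contigs).
#' @return `dir`, invisibly; files `reference.fa`, `contigs.fa`, `blocks.tsv`
#'   and, when reads are given, `reads.fa`, `read_provenance.tsv`.
#' @export
write_fixture <- function(fixture, dir, reads = NULL, contigs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- Biostrings::DNAStringSet(fixture$reference)
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fa"))
  if (is.null(contigs)) contigs <- fixture_contigs(fixture)
  ctg <- Biostrings::DNAStringSet(setNames(contigs$seq, contigs$name))
  Biostrings::writeXStringSet(ctg, file.path(dir, "contigs.fa"))
  utils::write.table(fixture$blocks, file.path(dir, "blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(reads)) {
    rd <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
    Biostrings::writeXStringSet(rd, file.path(dir, "reads.fa"))
    utils::write.table(reads[, setdiff(names(reads), "seq")],
                       file.path(dir, "read_provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
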