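# Candidate-block rules, fingerprint set algebra, similarity scoring and
# the quantile significance test.

blocks3 <- tibble::tibble(block_id = c("A", "B", "C"),
                          chrom = c("chr1", "chr1", "chr2"),
                          start = c(0, 300, 0), end = c(100, 400, 500))

test_that("candidate phase blocks follow the overlap / gap / nearest rules", {
  ov <- assign_candidate_blocks(list(chrom = "chr1", start = 120, end = 180),
                                tibble::tibble(block_id = "A", chrom = "chr1",
                                               start = 50, end = 500))
  expect_equal(ov$block_id, "A")
  gap <- assign_candidate_blocks(list(chrom = "chr1", start = 150, end = 250), blocks3)
  expect_equal(gap$block_id, c("A", "B"))
  near <- assign_candidate_blocks(list(chrom = "chr1", start = 0, end = 50),
                                  blocks3[blocks3$block_id == "B", ])
  expect_equal(near$block_id, "B")
  none <- assign_candidate_blocks(list(chrom = "chrX", start = 0, end = 50), blocks3)
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "status"), "unassignable")
})

test_that("fingerprint sets follow the exactly-one-raw-set arithmetic", {
  # R1={A,B,C}, R2={B,D}, R3={C,E}, R4={F} with integer codes
  raw <- list(c(1L, 2L, 3L), c(2L, 4L), c(3L, 5L), 6L)
  idx <- diplosv:::fingerprint_from_raw(raw)
  expect_equal(idx$fingerprint, list(1L, 4L, 5L, 6L))
  # identical raw sets share everything: fingerprints empty
  same <- diplosv:::fingerprint_from_raw(list(1:5, 1:5, 1:5, 1:5))
  expect_true(all(lengths(same$fingerprint) == 0L))
})

test_that("fingerprints match a brute-force membership-count oracle", {
  set.seed(7)
  for (rep in 1:100) {
    raw <- lapply(1:4, function(i) sample.int(4000L, 1000L))
    idx <- diplosv:::fingerprint_from_raw(raw)
    pool <- unique(unlist(raw))
    counts <- vapply(pool, function(x) sum(vapply(raw, function(r) x %in% r, logical(1))), numeric(1))
    once <- pool[counts == 1]
    oracle <- lapply(raw, function(r) r[r %in% once])
    expect_equal(idx$fingerprint, oracle)
    # disjointness invariant
    fp <- unlist(idx$fingerprint)
    expect_equal(anyDuplicated(fp), 0L)
  }
})

test_that("similarity scores are intersection sizes, normalised to sum 1", {
  set.seed(1)
  read <- random_dna(30)
  s <- kmer_set(read)
  raw <- list(c(s[1], 9000001L), c(s[2], 9000002L), 9000003L, 9000004L)
  idx <- diplosv:::fingerprint_from_raw(raw)
  sc <- score_read(read, idx)
  expect_equal(sc$sim, c(1, 1, 0, 0))
  expect_equal(sc$norm_sim, c(0.5, 0.5, 0, 0))
  expect_equal(sum(sc$norm_sim), 1, tolerance = 1e-9)
  # disjoint fingerprints: undefined score
  idx2 <- diplosv:::fingerprint_from_raw(list(9000001L, 9000002L, 9000003L, 9000004L))
  sc2 <- score_read(read, idx2)
  expect_equal(sc2$sim, c(0, 0, 0, 0))
  expect_false(sc2$defined)
  # read shorter than k: undefined
  expect_false(score_read("ACGT", idx)$defined)
})

test_that("the significance cutoff is the linear-interpolation (1-r) quantile", {
  chi <- seq(0.01, 1, by = 0.01)
  expect_equal(quantile_cutoff(chi, 0.1), unname(quantile(chi, 0.9, type = 7)))
  expect_gt(0.95, quantile_cutoff(chi, 0.1))  # a 0.95 max clears this cutoff
  expect_true(is.na(quantile_cutoff(numeric(0))))
})

test_that("unscorable reads fall back to both haplotypes of the nearest block", {
  fx <- generate_diploid_genome(6e4, variant_spec("SNP", 40), het_fraction = 1,
                                n_blocks = 2, seed = 3)
  rd <- simulate_reads(fx, coverage = 4, read_length = c(4000, 300),
                       error_rates = c(sub = 0, ins = 0, del = 0),
                       unphased_fraction = 0, seed = 4)
  # one synthetic unphased read that shares no k-mers with the genome
  alien <- rd[1, ]
  alien$read_id <- "alien"
  alien$seq <- strrep("A", 3000)
  alien$phased <- FALSE
  alien$haplotype <- NA_integer_; alien$block_id <- NA_character_
  res <- assign_unphased_reads(dplyr::bind_rows(rd, alien), fx$blocks)
  expect_equal(nrow(res), 1L)
  expect_equal(res$decision, "both_haps")
  expect_false(is.na(res$block_id))
})

test_that("hidden reads recover their haplotype and every read gets one decision", {
  fx <- cached("partition_fx", generate_diploid_genome(
    1.2e5, variant_spec("SNP", 80), het_fraction = 1, n_blocks = 2, seed = 21))
  rd <- simulate_reads(fx, coverage = 6, read_length = c(5000, 500),
                       error_rates = c(sub = 0, ins = 0, del = 0),
                       unphased_fraction = 0.3, seed = 22)
  res <- assign_unphased_reads(rd, fx$blocks)
  expect_equal(sort(res$read_id), sort(rd$read_id[!rd$phased]))  # coverage conservation
  hid <- rd[!rd$phased, ]
  het_pos <- fx$truth$pos[fx$truth$gt != "1|1"]
  hid$has_het <- vapply(seq_len(nrow(hid)), function(i)
    any(het_pos >= hid$ref_start[i] & het_pos < hid$ref_end[i]), logical(1))
  m <- dplyr::inner_join(
    dplyr::select(res, "read_id", "decision", assigned_hap = "haplotype",
                  "best_norm_sim", "cutoff_used"),
    hid[hid$has_het, ], by = "read_id")
  assigned <- m[m$decision == "assigned", ]
  expect_gt(nrow(assigned) / nrow(m), 0.9)
  expect_gt(mean(assigned$assigned_hap == assigned$true_hap), 0.95)
  # defined norm-sim vectors sum to 1 is exercised inside score_read; here
  # check the decision invariant: assigned implies best above cutoff
  expect_true(all(assigned$best_norm_sim > assigned$cutoff_used))
})
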