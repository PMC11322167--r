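# Haplotype pairing, read-evidence filters, redundancy removal and
# genotype refinement.

test_that("pairing merges cross-haplotype calls into genotypes", {
  th <- sv_thresholds()
  hap <- dplyr::bind_rows(
    make_signature(start = 1000, svtype = "INS", svlen = 300, haplotype = 1L),
    make_signature(start = 1100, svtype = "INS", svlen = 280, haplotype = 2L))
  p <- pair_haplotypes(hap, th)
  expect_equal(nrow(p), 1L)
  expect_equal(p$gt, "1|1")
  expect_equal(p$svlen, 300)

  solo <- make_signature(start = 5000, end = 5400, svtype = "DEL", svlen = 400,
                         haplotype = 2L)
  expect_equal(pair_haplotypes(solo, th)$gt, "0|1")

  # DELs with reciprocal overlap at or below th_sim stay separate het calls
  low_ovl <- dplyr::bind_rows(
    make_signature(start = 1000, end = 2000, svtype = "DEL", svlen = 1000, haplotype = 1L),
    make_signature(start = 1040, end = 1440, svtype = "DEL", svlen = 400, haplotype = 2L))
  # shift 40 < 200, svlen_sim 0.4 <= 0.5 -> no edge
  expect_equal(nrow(pair_haplotypes(low_ovl, th)), 2L)
})

test_that("read-support filter removes exactly the zero-supporter calls in 50-250 bp", {
  th <- sv_thresholds()
  calls <- dplyr::bind_rows(
    make_signature(start = 1000, svtype = "INS", svlen = 100),   # supported
    make_signature(start = 9000, svtype = "INS", svlen = 100),   # no signature near
    make_signature(start = 20000, end = 20400, svtype = "DEL", svlen = 400))  # exempt
  calls$gt <- "1|0"
  read_sigs <- make_signature(start = 1150, svtype = "INS", svlen = 60,
                              origin = "cigar", source_name = "rd1")
  out <- filter_by_read_support(calls, read_sigs, th)
  expect_equal(out$start, c(1000, 20000))
  expect_equal(out$n_support, c(1L, 0L))
  # svlen ratio at the boundary: 0.5 is not > 0.5
  boundary <- filter_by_read_support(calls[1, ],
                                     make_signature(start = 1000, svtype = "INS", svlen = 50), th)
  expect_equal(nrow(boundary), 0L)
})

test_that("deletion depth band is inclusive and monotone in rb", {
  th <- sv_thresholds()
  # three candidates; supporters engineered so sig_depth = 2, 2, 6
  calls <- dplyr::bind_rows(
    make_signature(start = 10000, end = 10110, svtype = "DEL", svlen = 110),
    make_signature(start = 50000, end = 50110, svtype = "DEL", svlen = 110),
    make_signature(start = 90000, end = 90110, svtype = "DEL", svlen = 110))
  read_sigs <- dplyr::bind_rows(
    make_signature(start = 10020, end = 10120, svtype = "DEL", svlen = 100),
    make_signature(start = 10040, end = 10160, svtype = "DEL", svlen = 120),
    make_signature(start = 50020, end = 50120, svtype = "DEL", svlen = 100),
    make_signature(start = 50040, end = 50160, svtype = "DEL", svlen = 120),
    make_signature(start = 90000, end = 90660, svtype = "DEL", svlen = 660))
  out <- filter_del_by_depth(calls, read_sigs, "hifi", th)
  expect_equal(out$sig_depth[1], 220 / 110)
  # median(R) = 2 -> hifi band [0.4, 5.2]; the sig_depth 6 candidate is out
  expect_equal(out$start, c(10000, 50000))
  # inclusive lower bound: engineer sig_depth exactly 0.4 against median 2
  calls2 <- dplyr::bind_rows(
    calls[1:2, ],
    make_signature(start = 90000, end = 90250, svtype = "DEL", svlen = 250))
  rs2 <- dplyr::bind_rows(read_sigs[1:4, ],
                          make_signature(start = 90010, end = 90110, svtype = "DEL", svlen = 100))
  out2 <- filter_del_by_depth(calls2, rs2, "hifi", th)
  expect_equal(out2$sig_depth[3], 0.4)
  expect_equal(nrow(out2), 3L)  # kept at the boundary
  # monotone in rb: enlarging rb never removes a kept call
  th_wide <- sv_thresholds(rb = c(hifi = 5.2, clr = 3, ont = 2.8))
  out3 <- filter_del_by_depth(calls, read_sigs, "hifi", th_wide)
  expect_true(all(out$start %in% out3$start))
})

test_that("one-to-K clustering bridges over a dissimilar intervening call and is idempotent", {
  th <- sv_thresholds()
  set.seed(3)
  big <- random_dna(1000)
  big2 <- paste0(big, random_dna(10))
  calls <- dplyr::bind_rows(
    make_signature(start = 10000, svtype = "INS", svlen = 1000, alt_seq = big),
    make_signature(start = 10040, svtype = "INS", svlen = 60, alt_seq = random_dna(60)),
    make_signature(start = 10080, svtype = "INS", svlen = 1010, alt_seq = big2))
  calls$gt <- "1|0"
  out <- dedupe_one_to_k(calls, th)
  # the two large INS merge despite the dissimilar call between them
  expect_equal(sort(out$svlen), c(60, 1010))
  expect_identical(dedupe_one_to_k(out, th), out)

  # DEL shift at the 300 bp threshold does not merge
  set.seed(4)
  ref <- list(chr1 = random_dna(3000))
  dels <- dplyr::bind_rows(
    make_signature(start = 1000, end = 1400, svtype = "DEL", svlen = 400),
    make_signature(start = 1350, end = 1750, svtype = "DEL", svlen = 400))
  expect_equal(nrow(dedupe_one_to_k(dels, th, ref)), 2L)  # shift 350 >= DEL cap 300
})

test_that("dedupe matches a brute-force all-pairs connected-components oracle", {
  th <- sv_thresholds()
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    pos <- sort(sample(seq(1000, 40000, by = 50), n))
    alt_pool <- replicate(3, random_dna(200))
    calls <- make_signature(start = pos, svtype = "INS",
                            svlen = 200 + sample(0:40, n, TRUE),
                            alt_seq = sample(alt_pool, n, TRUE))
    got <- dedupe_one_to_k(calls, th)
    # brute force over all pairs
    edge <- function(i, j) {
      shift <- abs(calls$start[j] - calls$start[i])
      shift <= th$neighborhood && shift < th$th_shift_redun_ins &&
        min(calls$svlen[c(i, j)]) / max(calls$svlen[c(i, j)]) > th$th_sim &&
        seq_similarity(calls$alt_seq[i], calls$alt_seq[j]) > th$th_sim
    }
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) adj[i, j] <- adj[j, i] <- edge(i, j)
    comp <- rep(0L, n); cur <- 0L
    for (s in seq_len(n)) if (comp[s] == 0L) {
      cur <- cur + 1L; q <- s
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        if (comp[v] == 0L) { comp[v] <- cur; q <- c(q, which(adj[v, ] & comp == 0L)) }
      }
    }
    oracle <- dplyr::bind_rows(lapply(split(seq_len(n), comp), function(ix) {
      sub <- calls[ix, ]; sub[order(-sub$svlen, sub$start), ][1, ]
    }))
    expect_setequal(got$start, oracle$start)
  }
})

test_that("genotype refinement follows the decision-table leaves", {
  th <- sv_thresholds()
  tab <- genotype_decision_table()
  expect_equal(nrow(tab), 24L)
  expect_equal(anyDuplicated(tab[, 1:4]), 0L)
  # local depth 20: twenty reads spanning the window
  segs <- make_segment(sprintf("rd%02d", 1:20), "chr1",
                       ref_s = rep(4000, 20), ref_e = rep(6500, 20),
                       contig_s = 0, contig_e = 2500)
  call_hom <- make_signature(start = 5000, end = 5200, svtype = "DEL", svlen = 200)
  call_hom$gt <- "1|1"
  # 9 supporters -> ratio 0.45 below the hom DEL <=1kb leaf (0.65): downgrade
  sup9 <- make_signature(start = seq(4900, 5060, by = 20), svtype = "DEL",
                         svlen = 190, haplotype = 2L, source_name = sprintf("rd%02d", 1:9))
  down <- refine_genotype(call_hom, sup9, segs, "hifi", tab, th)
  expect_equal(down$gt, "0|1")  # better-supported haplotype kept
  expect_equal(down$gt_flag, "GT_DOWNGRADED")
  expect_equal(down$rel_support, 0.45)
  # 19 supporters -> ratio 0.95 above the het leaf: upgrade
  call_het <- call_hom; call_het$gt <- "0|1"
  sup19 <- make_signature(start = seq(4900, 5260, by = 20), svtype = "DEL",
                          svlen = 190, source_name = sprintf("rd%02d", 1:19))
  up <- refine_genotype(call_het, sup19, segs, "hifi", tab, th)
  expect_equal(up$gt, "1|1")
  expect_equal(up$gt_flag, "GT_UPGRADED")
  # consistent ratio: unchanged
  same <- refine_genotype(call_het, sup9, segs, "hifi", tab, th)
  expect_equal(same$gt, "0|1")
  expect_equal(same$gt_flag, "")
  # zero depth: flagged, genotype kept
  nodepth <- refine_genotype(make_signature(start = 5e6, end = 5e6 + 200,
                                            svtype = "DEL", svlen = 200) |>
                               dplyr::mutate(gt = "1|1"),
                             sup9, segs, "hifi", tab, th)
  expect_equal(nodepth$gt, "1|1")
  expect_equal(nodepth$gt_flag, "LOW_DEPTH")
})

test_that("filters only remove or relabel, never invent calls", {
  th <- sv_thresholds()
  set.seed(9)
  calls <- make_signature(start = seq(1000, 20000, by = 1000), svtype = "DEL",
                          svlen = 100, end = seq(1000, 20000, by = 1000) + 100)
  calls$gt <- "1|0"
  rs <- make_signature(start = seq(1000, 20000, by = 2000) + 30, svtype = "DEL",
                       svlen = 90, source_name = "rd")
  out1 <- filter_by_read_support(calls, rs, th)
  expect_true(all(out1$start %in% calls$start))
  out2 <- filter_del_by_depth(out1, rs, "ont", th)
  expect_true(all(out2$start %in% out1$start))
  out3 <- dedupe_one_to_k(out2, th, list(chr1 = random_dna(30000)))
  expect_true(all(out3$start %in% out2$start))
})
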