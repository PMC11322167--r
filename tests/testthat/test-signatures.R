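# Split-pair decision rules, CIGAR scanning and intra-haplotype chaining.

test_that("split-pair arithmetic emits the expected DEL and INS", {
  th <- sv_thresholds()
  del <- collect_split_signatures(
    make_split_pair(0, 1000, 5000, 6000, 1000, 1800, 6200, 7000), th)
  expect_equal(del$svtype, "DEL")
  expect_equal(del$start, 6000)
  expect_equal(del$end, 6200)
  expect_equal(del$svlen, 200)

  ins <- collect_split_signatures(
    make_split_pair(0, 1000, 5000, 6000, 1300, 2000, 6000, 6700), th)
  expect_equal(ins$svtype, "INS")
  expect_equal(ins$start, 6000)
  expect_equal(ins$svlen, 300)

  # Diff_dis passes but the reference overlap trips the 3000 bp gate
  gated <- collect_split_signatures(
    make_split_pair(0, 1000, 5000, 11000, 1100, 2000, 6000, 6900), th)
  expect_equal(nrow(gated), 0L)
})

test_that("reverse-strand split pairs give the same signatures as forward", {
  th <- sv_thresholds()
  fwd <- collect_split_signatures(
    make_split_pair(0, 1000, 5000, 6000, 1000, 1800, 6200, 7000), th)
  # same alignment expressed on the minus strand: contig coordinates in
  # original orientation flip around qlen = 1800
  seg <- dplyr::bind_rows(
    make_segment("ctg1", "chr1", 5000, 6000, 1800 - 1000, 1800 - 0, strand = "-", qlen = 1800),
    make_segment("ctg1", "chr1", 6200, 7000, 1800 - 1800, 1800 - 1000, strand = "-", qlen = 1800))
  rev <- collect_split_signatures(seg, th)
  expect_equal(rev$svtype, fwd$svtype)
  expect_equal(rev$start, fwd$start)
  expect_equal(rev$svlen, fwd$svlen)
})

test_that("split INS records carry the inserted contig substring", {
  set.seed(5)
  seq <- random_dna(2000)
  ins <- collect_split_signatures(
    make_split_pair(0, 1000, 5000, 6000, 1300, 2000, 6000, 6700, seq = seq),
    sv_thresholds())
  expect_equal(ins$alt_seq, substr(seq, 1001, 1300))
})

test_that("CIGAR operations yield exact positions and respect the size floor", {
  set.seed(6)
  seq <- random_dna(260)
  seg <- make_segment("ctg1", "chr1", ref_s = 1000, ref_e = 1200,
                      contig_s = 0, contig_e = 260, qlen = 260,
                      cigar = "100M60I100M", seq = seq)
  ins <- collect_cigar_signatures(seg, 50)
  expect_equal(ins$svtype, "INS")
  expect_equal(ins$start, 1100)
  expect_equal(ins$svlen, 60)
  expect_equal(ins$alt_seq, substr(seq, 101, 160))

  seg2 <- make_segment("ctg1", "chr1", 1000, 1249, 0, 200, qlen = 200,
                       cigar = "100M49D100M")
  expect_equal(nrow(collect_cigar_signatures(seg2, 50)), 0L)

  seg3 <- make_segment("ctg1", "chr1", 0, 300, 0, 100, qlen = 100,
                       cigar = "50M200D50M")
  del <- collect_cigar_signatures(seg3, 50)
  expect_equal(del$start, 50)
  expect_equal(del$end, 250)
  expect_equal(del$svlen, 200)
})

test_that("intra-haplotype chaining merges close similar signatures only", {
  th <- sv_thresholds()
  sig <- dplyr::bind_rows(
    make_signature(start = 100, svtype = "INS", svlen = 100),
    make_signature(start = 150, svtype = "INS", svlen = 90))
  cl <- cluster_intrahap(sig, th)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$svlen, 100)
  expect_equal(cl$n_signatures, 2L)

  far <- dplyr::bind_rows(
    make_signature(start = 100, end = 200, svtype = "DEL", svlen = 100),
    make_signature(start = 500, end = 600, svtype = "DEL", svlen = 100))
  expect_equal(nrow(cluster_intrahap(far, th)), 2L)
})

test_that("chained components equal a brute-force transitive closure and are order invariant", {
  th <- sv_thresholds()
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(5:30, 1)
    base <- cumsum(sample(c(20, 60, 150, 400), n, replace = TRUE))
    svlen <- sample(c(60, 80, 100, 180, 500), n, replace = TRUE)
    sig <- make_signature(start = base, end = base + svlen, svtype = "DEL",
                          svlen = svlen, haplotype = 1L)[sample(n), ]
    got <- cluster_intrahap(sig, th)
    # brute force: adjacency over consecutive sorted signatures, transitive
    # closure, max-length representative
    s <- sig[order(sig$start), ]
    grp <- 1; comp <- c(1, numeric(n - 1))
    if (n > 1) for (i in 1:(n - 1)) {
      shift <- abs(s$start[i + 1] - s$start[i])
      ssim <- min(s$svlen[i], s$svlen[i + 1]) / max(s$svlen[i], s$svlen[i + 1])
      ovl <- (min(s$end[i], s$end[i + 1]) - max(s$start[i], s$start[i + 1])) /
        min(s$svlen[i], s$svlen[i + 1])
      if (!(shift < th$th_shift_intrahap && ssim > th$th_sim && ovl > th$th_sim)) grp <- grp + 1
      comp[i + 1] <- grp
    }
    oracle <- dplyr::bind_rows(lapply(split(seq_len(n), comp), function(ix) {
      sub <- s[ix, ]
      sub[order(-sub$svlen, sub$start), ][1, ]
    }))
    oracle <- oracle[order(oracle$start), ]
    expect_equal(got$start, oracle$start)
    expect_equal(got$svlen, oracle$svlen)
    # containment: representatives are input rows
    expect_true(all(got$start %in% sig$start))
  }
})
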