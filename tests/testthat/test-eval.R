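# Breakpoint-shift arithmetic and the greedy Truvari-style matcher.

test_that("breakpoint shift uses the max of start/end differences for deletions", {
  call <- tibble::tibble(chrom = "chr1", start = 100, end = 200, svtype = "DEL",
                         svlen = 100, alt_seq = "")
  truth <- tibble::tibble(chrom = "chr1", pos = 110, end = 195, svtype = "DEL",
                          svlen = 85, alt_seq = "")
  rec <- breakpoint_shift_and_seqsim(call, truth)
  expect_equal(rec$breakpoint_shift, 10)
  expect_equal(rec$shift_bin, "10")
  # INS: start difference only, large shifts binned at 200+
  ci <- tibble::tibble(chrom = "chr1", start = 1250, end = 1250, svtype = "INS",
                       svlen = 100, alt_seq = "ACGT")
  ti <- tibble::tibble(chrom = "chr1", pos = 1000, end = 1000, svtype = "INS",
                       svlen = 100, alt_seq = "ACGA")
  rec2 <- breakpoint_shift_and_seqsim(ci, ti)
  expect_equal(rec2$breakpoint_shift, 250)
  expect_equal(rec2$shift_bin, "200+")
  expect_equal(rec2$seq_similarity, 0.75)
  expect_error(breakpoint_shift_and_seqsim(call, ti), "mismatch")
})

test_that("identical call sets evaluate to perfect recall/precision with zero shift", {
  fx <- generate_diploid_genome(1e5, variant_spec(c("INS", "DEL"), c(5, 5), 60, 400),
                                seed = 13)
  asc <- dplyr::rename(fx$truth, start = pos)
  ev <- match_calls_to_truth(asc, fx$truth)
  g <- glance(ev)
  expect_equal(g$recall, 1)
  expect_equal(g$precision, 1)
  expect_equal(g$median_shift, 0)
  expect_equal(g$gt_concordance, 1)
  expect_true(all(tidy(ev)$breakpoint_shift == 0))
})

test_that("calls outside refdist are unmatched", {
  truth <- tibble::tibble(chrom = "chr1", pos = 1000, end = 1000, svtype = "INS",
                          svlen = 100, gt = "1|0", alt_seq = strrep("A", 100),
                          chrom2 = NA_character_, pos2 = NA_real_)
  far <- tibble::tibble(chrom = "chr1", start = 1600, end = 1600, svtype = "INS",
                        svlen = 100, gt = "1|0", alt_seq = strrep("A", 100))
  ev <- match_calls_to_truth(far, truth, pctsim = 0)
  expect_equal(glance(ev)$tp, 0L)
  expect_equal(nrow(ev$fp), 1L)
  expect_equal(nrow(ev$fn), 1L)
  near <- dplyr::mutate(far, start = 1400, end = 1400)
  expect_equal(glance(match_calls_to_truth(near, truth, pctsim = 0))$tp, 1L)
})

test_that("greedy matching equals a maximum bipartite matching on separated fixtures", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    pos <- sort(sample(seq(2000, 5e5, by = 2000), n))
    truth <- tibble::tibble(chrom = "chr1", pos = pos, end = pos,
                            svtype = "INS", svlen = sample(60:500, n, TRUE),
                            gt = "1|0", alt_seq = "", chrom2 = NA_character_,
                            pos2 = NA_real_)
    keep <- runif(n) < 0.8
    calls <- tibble::tibble(chrom = "chr1",
                            start = truth$pos[keep] + sample(-550:550, sum(keep), TRUE),
                            svtype = "INS",
                            svlen = round(truth$svlen[keep] * runif(sum(keep), 0.4, 1)),
                            gt = "1|0", alt_seq = "")
    calls$end <- calls$start
    ev <- match_calls_to_truth(calls, truth, pctsim = 0)
    # independent maximum matching via augmenting paths
    ok_pair <- function(i, j) {
      abs(calls$start[i] - truth$pos[j]) <= 500 &&
        min(calls$svlen[i], truth$svlen[j]) / max(calls$svlen[i], truth$svlen[j]) >= 0.5
    }
    adj <- lapply(seq_len(nrow(calls)), function(i)
      which(vapply(seq_len(nrow(truth)), function(j) ok_pair(i, j), logical(1))))
    match_t <- rep(0L, nrow(truth))
    try_aug <- function(i, seen) {
      for (j in adj[[i]]) if (!seen[j]) {
        seen[j] <- TRUE
        if (match_t[j] == 0L || Recall(match_t[j], seen)) {
          match_t[j] <<- i
          return(TRUE)
        }
      }
      FALSE
    }
    max_tp <- 0L
    for (i in seq_len(nrow(calls)))
      if (try_aug(i, rep(FALSE, nrow(truth)))) max_tp <- max_tp + 1L
    expect_equal(glance(ev)$tp, max_tp)
  }
})

test_that("stricter parameters never increase the true-positive count", {
  set.seed(19)
  n <- 40
  pos <- sort(sample(seq(2000, 3e5, by = 1500), n))
  truth <- tibble::tibble(chrom = "chr1", pos = pos, end = pos, svtype = "INS",
                          svlen = sample(60:400, n, TRUE), gt = "1|0",
                          alt_seq = "", chrom2 = NA_character_, pos2 = NA_real_)
  calls <- tibble::tibble(chrom = "chr1", start = pos + sample(-400:400, n, TRUE),
                          end = pos, svtype = "INS",
                          svlen = round(truth$svlen * runif(n, 0.3, 1)),
                          gt = "1|0", alt_seq = "")
  tp <- function(P, r) glance(match_calls_to_truth(calls, truth, refdist = r,
                                                   pctsize = P, pctsim = 0))$tp
  expect_gte(tp(0.3, 500), tp(0.7, 500))
  expect_gte(tp(0.5, 500), tp(0.5, 200))
  expect_gte(tp(0.3, 500), tp(0.7, 200))
})
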