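# The generator's contracts: length conservation, identity, determinism,
# reconstruction, read conservation and provenance honesty.

test_that("deletions shorten both homozygous haplotypes by the same total", {
  fx <- generate_diploid_genome(1e5, variant_spec("DEL", 10, 100, 500),
                                het_fraction = 0, seed = 1)
  expect_equal(nrow(fx$truth), 10L)
  expect_true(all(fx$truth$gt == "1|1"))
  lost <- sum(fx$truth$svlen)
  expect_equal(nchar(fx$hap1[["chr1"]]), nchar(fx$reference[["chr1"]]) - lost)
  expect_equal(nchar(fx$hap2[["chr1"]]), nchar(fx$reference[["chr1"]]) - lost)
})

test_that("zero variants give haplotypes identical to the reference", {
  fx <- generate_diploid_genome(2e4, variant_spec("DEL", 0), seed = 1)
  expect_identical(fx$hap1, fx$reference)
  expect_identical(fx$hap2, fx$reference)
})

test_that("identical seeds reproduce the fixture; different seeds move variants", {
  sp <- variant_spec(c("INS", "DEL"), c(3, 3), 60, 200)
  a <- generate_diploid_genome(1e5, sp, seed = 1)
  b <- generate_diploid_genome(1e5, sp, seed = 1)
  c <- generate_diploid_genome(1e5, sp, seed = 2)
  expect_identical(a$truth, b$truth)
  expect_identical(a$hap1, b$hap1)
  expect_false(identical(a$truth$pos, c$truth$pos))
})

test_that("re-applying the truth set to the reference reconstructs each haplotype", {
  fx <- generate_diploid_genome(2e5, variant_spec(c("SNP", "INS", "DEL", "INV", "DUP"),
                                                  c(20, 3, 3, 2, 2), 100, 1000),
                                het_fraction = 0.5, seed = 9)
  # independent reconstruction: apply sorted variants right-to-left with
  # plain string surgery
  rebuild <- function(ref, vars) {
    vars <- vars[order(-vars$pos), , drop = FALSE]
    for (i in seq_len(nrow(vars))) {
      v <- vars[i, ]
      left <- substr(ref, 1, v$pos)
      if (v$svtype == "SNP") {
        ref <- paste0(left, v$alt_seq, substring(ref, v$pos + 2))
      } else if (v$svtype == "INS") {
        ref <- paste0(left, v$alt_seq, substring(ref, v$pos + 1))
      } else if (v$svtype == "DEL") {
        ref <- paste0(left, substring(ref, v$end + 1))
      } else if (v$svtype == "INV") {
        mid <- substr(ref, v$pos + 1, v$end)
        ref <- paste0(left, as.character(Biostrings::reverseComplement(Biostrings::DNAString(mid))),
                      substring(ref, v$end + 1))
      } else if (v$svtype == "DUP") {
        mid <- substr(ref, v$pos + 1, v$end)
        ref <- paste0(left, mid, mid, substring(ref, v$end + 1))
      }
    }
    ref
  }
  for (h in 1:2) {
    carrier <- substr(fx$truth$gt, ifelse(h == 1, 1, 3), ifelse(h == 1, 1, 3)) == "1"
    vars <- fx$truth[carrier & fx$truth$chrom == "chr1", ]
    expect_identical(rebuild(fx$reference[["chr1"]], vars),
                     (if (h == 1) fx$hap1 else fx$hap2)[["chr1"]],
                     label = sprintf("haplotype %d reconstruction", h))
  }
})

test_that("infeasible packing raises a capacity error, not silent truncation", {
  expect_error(generate_diploid_genome(2e4, variant_spec("DEL", 50, 400, 500), seed = 1),
               "capacity")
  expect_error(generate_diploid_genome(5e4, variant_spec("TRA", 1), n_chrom = 1, seed = 1),
               "two chromosomes")
})

test_that("simulated reads conserve coverage and are exact substrings at zero error", {
  fx <- generate_diploid_genome(5e4, variant_spec(c("INS", "DEL"), c(2, 2), 60, 300),
                                seed = 4)
  rd <- simulate_reads(fx, coverage = 4, read_length = c(5000, 500),
                       error_rates = c(sub = 0, ins = 0, del = 0), seed = 2)
  for (h in 1:2) {
    tot <- sum(nchar(rd$seq[rd$true_hap == h]))
    L <- nchar((if (h == 1) fx$hap1 else fx$hap2)[["chr1"]])
    expect_lt(abs(tot - 4 * L) / (4 * L), 0.05)
  }
  hapseq <- list(fx$hap1, fx$hap2)
  ok <- vapply(seq_len(nrow(rd)), function(i) {
    substr(hapseq[[rd$true_hap[i]]][[rd$chrom[i]]],
           rd$hap_start[i] + 1, rd$hap_end[i]) == rd$seq[i]
  }, logical(1))
  expect_true(all(ok))
})

test_that("a quarter of reads hide their provenance by default", {
  fx <- generate_diploid_genome(2e5, variant_spec("SNP", 50), seed = 5)
  rd <- simulate_reads(fx, coverage = 6, read_length = c(3000, 300), seed = 6)
  frac <- mean(!rd$phased)
  expect_lt(abs(frac - 0.25), 0.02)
  expect_true(all(is.na(rd$haplotype[!rd$phased])))
  expect_true(all(rd$haplotype[rd$phased] == rd$true_hap[rd$phased]))
})

test_that("a read length distribution exceeding the haplotype length errors", {
  fx <- generate_diploid_genome(1e4, variant_spec("DEL", 0), seed = 1)
  expect_error(simulate_reads(fx, coverage = 1, read_length = c(2e4, 100), seed = 1),
               "exceeds")
})
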