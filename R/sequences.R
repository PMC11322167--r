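# Sequence-level primitives for the fixture generator: random genomes,
# variant application with reference<->haplotype coordinate maps, and
# error injection for simulated reads.

#' Random DNA sequence
#' @param n length in bp.
#' @return a single character string over ACGT.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Apply intra-chromosomal variants (SNP/INS/DEL/INV/DUP rows of a truth
# table, already restricted to one chromosome and one haplotype) to a
# reference chromosome. Returns the haplotype sequence and the per-variant
# coordinate shifts needed to map reference offsets into haplotype offsets.
apply_variants_chrom <- function(ref_seq, vars) {
  if (nrow(vars) == 0L) {
    return(list(seq = ref_seq, shifts = tibble(after = numeric(0), shift = numeric(0))))
  }
  vars <- vars[order(vars$pos), , drop = FALSE]
  L <- nchar(ref_seq)
  pieces <- character(0)
  cursor <- 0L  # 0-based offset into ref
  shift_after <- numeric(nrow(vars))
  shift_amt <- numeric(nrow(vars))
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    pieces <- c(pieces, str_sub(ref_seq, cursor + 1L, v$pos))  # ref [cursor, pos)
    if (v$svtype == "SNP") {
      pieces <- c(pieces, v$alt_seq)
      cursor <- v$pos + 1L
      shift_after[i] <- v$pos + 1; shift_amt[i] <- 0
    } else if (v$svtype == "INS") {
      pieces <- c(pieces, v$alt_seq)
      cursor <- v$pos
      shift_after[i] <- v$pos; shift_amt[i] <- nchar(v$alt_seq)
    } else if (v$svtype == "DEL") {
      cursor <- v$end
      shift_after[i] <- v$end; shift_amt[i] <- -(v$end - v$pos)
    } else if (v$svtype == "INV") {
      pieces <- c(pieces, revcomp(str_sub(ref_seq, v$pos + 1L, v$end)))
      cursor <- v$end
      shift_after[i] <- v$end; shift_amt[i] <- 0
    } else if (v$svtype == "DUP") {
      unit <- str_sub(ref_seq, v$pos + 1L, v$end)
      pieces <- c(pieces, unit, unit)
      cursor <- v$end
      shift_after[i] <- v$end; shift_amt[i] <- v$end - v$pos
    } else {
      stop_input("apply_variants_chrom cannot apply svtype %s", v$svtype)
    }
  }
  pieces <- c(pieces, str_sub(ref_seq, cursor + 1L, L))
  list(seq = paste(pieces, collapse = ""),
       shifts = tibble(after = shift_after, shift = shift_amt))
}

# Map reference offsets to haplotype offsets given the shift table of
# apply_variants_chrom. Exact for positions outside modified intervals
# (block boundaries and read endpoints are kept out of them by the
# generator's placement rules).
ref2hap <- function(pos, shifts) {
  if (nrow(shifts) == 0L) return(pos)
  vapply(pos, function(p) p + sum(shifts$shift[shifts$after <= p]), numeric(1))
}

# Inverse map: haplotype offset -> reference offset.
hap2ref <- function(pos, shifts) {
  if (nrow(shifts) == 0L) return(pos)
  hap_after <- shifts$after + cumsum(shifts$shift)
  cum <- cumsum(shifts$shift)
  vapply(pos, function(p) {
    i <- which(hap_after <= p)
    if (length(i) == 0L) p else p - cum[max(i)]
  }, numeric(1))
}

# Inject substitution/insertion/deletion errors at the given per-base rates.
mutate_sequence <- function(seq, sub_rate = 0, ins_rate = 0, del_rate = 0) {
  if (sub_rate + ins_rate + del_rate == 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  r <- runif(n)
  del_mask <- r < del_rate
  sub_mask <- !del_mask & r < del_rate + sub_rate
  ins_mask <- runif(n) < ins_rate
  bases <- c("A", "C", "G", "T")
  if (any(sub_mask)) {
    idx <- match(v[sub_mask], bases)
    v[sub_mask] <- bases[((idx - 1L + sample.int(3L, sum(sub_mask), replace = TRUE)) %% 4L) + 1L]
  }
  parts <- character(2L * n)
  odd <- seq(1L, 2L * n, by = 2L)
  parts[odd][ins_mask] <- sample(bases, sum(ins_mask), replace = TRUE)
  parts[odd + 1L] <- ifelse(del_mask, "", v)
  paste(parts, collapse = "")
}

# Per-technology error-rate presets (substitution, insertion, deletion).
error_preset <- function(tech = c("hifi", "clr", "ont")) {
  tech <- match.arg(tech)
  switch(tech,
    hifi = c(sub = 0.004, ins = 0.003, del = 0.003),
    clr  = c(sub = 0.040, ins = 0.050, del = 0.030),
    ont  = c(sub = 0.030, ins = 0.030, del = 0.020)
  )
}
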