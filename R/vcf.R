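# Phased VCF 4.2 writing and parse-back. Records are emitted with explicit
# alleles for INS/DEL/SNP and small indels, symbolic ALTs for INV/DUP, and
# bracket-notation BND pairs for TRA. Output is canonical (coordinate
# sorted, fixed field order, no timestamps) so identical inputs give
# byte-identical files.

vcf_header <- function(reference, sample = "SAMPLE") {
  lens <- vapply(names(reference), function(ch) nchar(as.character(reference[[ch]])), numeric(1))
  c("##fileformat=VCFv4.2",
    "##source=diplosv",
    sprintf("##contig=<ID=%s,length=%d>", names(reference), lens),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed length difference of ALT versus REF\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant on the reference\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set (phase block)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
}

# One VCF body line per record row; TRA emits two BND lines.
vcf_record_lines <- function(rec, reference, blocks = NULL) {
  chr <- as.character(reference[[rec$chrom]])
  ps <- rec$ps %||% NA_integer_
  fmt <- sprintf("%s:%s", rec$gt, ifelse(is.na(ps), ".", as.character(ps)))
  id <- rec$id
  anchor <- function(p) str_sub(chr, p, p)  # 1-based
  if (rec$svtype == "SNP") {
    return(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tSVTYPE=SNP\tGT:PS\t%s",
                   rec$chrom, rec$pos + 1, id, anchor(rec$pos + 1), rec$alt_seq, fmt))
  }
  if (rec$svtype == "INS") {
    a <- anchor(rec$pos)  # base before the insertion point (1-based == pos)
    return(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tSVTYPE=INS;SVLEN=%d;END=%d\tGT:PS\t%s",
                   rec$chrom, rec$pos, id, a, paste0(a, rec$alt_seq),
                   rec$svlen, rec$pos, fmt))
  }
  if (rec$svtype == "DEL") {
    a <- anchor(rec$pos)
    deleted <- str_sub(chr, rec$pos + 1, rec$end)
    return(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tSVTYPE=DEL;SVLEN=-%d;END=%d\tGT:PS\t%s",
                   rec$chrom, rec$pos, id, paste0(a, deleted), a,
                   rec$svlen, rec$end, fmt))
  }
  if (rec$svtype %in% c("INV", "DUP")) {
    a <- anchor(rec$pos)
    return(sprintf("%s\t%d\t%s\t%s\t<%s>\t.\tPASS\tSVTYPE=%s;SVLEN=%d;END=%d\tGT:PS\t%s",
                   rec$chrom, rec$pos, id, a, rec$svtype, rec$svtype,
                   rec$svlen, rec$end, fmt))
  }
  if (rec$svtype == "TRA") {
    a1 <- anchor(rec$pos); a2 <- anchor(rec$pos2)
    l1 <- sprintf("%s\t%d\t%s_1\t%s\t%s[%s:%d[\t.\tPASS\tSVTYPE=TRA\tGT:PS\t%s",
                  rec$chrom, rec$pos, id, a1, a1, rec$chrom2, rec$pos2 + 1, fmt)
    l2 <- sprintf("%s\t%d\t%s_2\t%s\t]%s:%d]%s\t.\tPASS\tSVTYPE=TRA\tGT:PS\t%s",
                  rec$chrom2, rec$pos2 + 1, id, a2, rec$chrom, rec$pos, a2, fmt)
    return(c(l1, l2))
  }
  stop_input("cannot format svtype %s", rec$svtype)
}

# Normalise heterogeneous call tables into the writer's record layout.
as_vcf_records <- function(x, blocks = NULL) {
  if (is.null(x) || nrow(x) == 0L) return(NULL)
  rec <- tibble(
    chrom = x[["chrom"]],
    pos = as.integer(x[["pos"]] %||% x[["start"]]),
    end = as.integer(x[["end"]] %||% x[["pos"]] %||% x[["start"]]),
    svtype = x[["svtype"]],
    svlen = as.integer(round(x[["svlen"]] %||% 0)),
    alt_seq = x[["alt_seq"]] %||% "",
    gt = x[["gt"]] %||% "1|0",
    chrom2 = x[["chrom2"]] %||% NA_character_,
    pos2 = as.integer(x[["pos2"]] %||% NA_real_),
    block_id = x[["block_id"]] %||% NA_character_
  )
  if (!is.null(blocks)) {
    rec$ps <- blocks$start[match(rec$block_id, blocks$block_id)] + 1
    # fall back to the containing block
    miss <- which(is.na(rec$ps))
    for (i in miss) {
      blk <- blocks[blocks$chrom == rec$chrom[i] &
                      blocks$start <= rec$pos[i] & rec$pos[i] < blocks$end, , drop = FALSE]
      if (nrow(blk)) rec$ps[i] <- blk$start[1] + 1
    }
  } else rec$ps <- NA_real_
  rec$ps <- as.integer(rec$ps)
  rec
}

#' Write a phased VCF
#'
#' Emits a single coordinate-sorted VCF 4.2 with explicit alleles for
#' indels and SNPs, symbolic ALTs for INV/DUP, and two bracket-notation BND
#' lines per TRA junction. Writing is canonical: a write/read/write
#' round-trip is byte-identical.
#'
#' @param calls large-SV call tibble (0-based `start`/`end` internal
#'   coordinates; converted here).
#' @param reference named character vector or `DNAStringSet` of reference
#'   chromosomes.
#' @param path output path.
#' @param small_indels optional small-indel tibble ([collect_small_indels()]
#'   layout, with `gt`).
#' @param snps optional SNP tibble (`chrom`, `pos`, `alt_seq`, `gt`), passed
#'   through from an upstream phaser.
#' @param blocks optional phase-block tibble for PS values.
#' @param sample sample name in the header.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(calls, reference, path, small_indels = NULL,
                             snps = NULL, blocks = NULL, sample = "SAMPLE") {
  recs <- list(as_vcf_records(calls, blocks))
  if (!is.null(small_indels) && nrow(small_indels)) {
    si <- small_indels
    si$alt_seq <- substring(si$alt_allele, 2)
    recs[[length(recs) + 1L]] <- as_vcf_records(si, blocks)
  }
  if (!is.null(snps) && nrow(snps)) recs[[length(recs) + 1L]] <- as_vcf_records(snps, blocks)
  rec <- bind_rows(recs)
  if (is.null(rec) || nrow(rec) == 0L) {
    writeLines(vcf_header(reference, sample), path)
    return(invisible(path))
  }
  if (any(is.na(rec$gt) | rec$gt == ""))
    stop_input("records missing GT at rows: %s",
               paste(which(is.na(rec$gt) | rec$gt == ""), collapse = ", "))
  rec <- rec[order(match(rec$chrom, names(reference)), rec$pos, rec$svtype, rec$svlen), , drop = FALSE]
  rec$id <- sprintf("DSV%05d", seq_len(nrow(rec)))
  body <- unlist(lapply(seq_len(nrow(rec)), function(i)
    vcf_record_lines(rec[i, ], reference)))
  writeLines(c(vcf_header(reference, sample), body), path)
  invisible(path)
}

#' Read a diplosv-style phased VCF
#'
#' Parses a VCF written by [write_phased_vcf()] or [emit_truth_vcf()] back
#' into the internal 0-based call layout; the two BND lines of a TRA
#' junction collapse back into one record.
#'
#' @param path VCF path.
#' @param reference optional reference (named character or `DNAStringSet`);
#'   when given, DUP alternate sequences are reconstructed from the
#'   duplicated interval.
#' @return tibble: `chrom`, `pos`, `end`, `svtype`, `svlen`, `gt`,
#'   `alt_seq`, `chrom2`, `pos2`, `ps`.
#' @export
read_phased_vcf <- function(path, reference = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(tibble(chrom = character(0), pos = numeric(0), end = numeric(0),
                  svtype = character(0), svlen = numeric(0), gt = character(0),
                  alt_seq = character(0), chrom2 = character(0), pos2 = numeric(0),
                  ps = numeric(0)))
  f <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  rows <- purrr::map_dfr(f, function(x) {
    info <- x[8]
    svtype <- info_get(info, "SVTYPE")
    gtps <- strsplit(x[10], ":")[[1]]
    gt <- gtps[1]; ps <- suppressWarnings(as.numeric(gtps[2]))
    pos1 <- as.numeric(x[2]); ref <- x[4]; alt <- x[5]
    endv <- suppressWarnings(as.numeric(info_get(info, "END")))
    svlen <- suppressWarnings(abs(as.numeric(info_get(info, "SVLEN"))))
    if (is.na(svtype)) svtype <- if (nchar(alt) > nchar(ref)) "INS" else if (nchar(alt) < nchar(ref)) "DEL" else "SNP"
    if (svtype == "SNP") {
      tibble(chrom = x[1], pos = pos1 - 1, end = pos1, svtype = "SNP", svlen = 0,
             gt = gt, alt_seq = alt, chrom2 = NA_character_, pos2 = NA_real_,
             ps = ps, id = x[3])
    } else if (svtype == "INS") {
      tibble(chrom = x[1], pos = pos1, end = pos1, svtype = "INS",
             svlen = svlen %||% (nchar(alt) - 1), gt = gt, alt_seq = substring(alt, 2),
             chrom2 = NA_character_, pos2 = NA_real_, ps = ps, id = x[3])
    } else if (svtype == "DEL") {
      tibble(chrom = x[1], pos = pos1, end = endv, svtype = "DEL", svlen = svlen,
             gt = gt, alt_seq = "", chrom2 = NA_character_, pos2 = NA_real_,
             ps = ps, id = x[3])
    } else if (svtype %in% c("INV", "DUP")) {
      tibble(chrom = x[1], pos = pos1, end = endv, svtype = svtype, svlen = svlen,
             gt = gt, alt_seq = "", chrom2 = NA_character_, pos2 = NA_real_,
             ps = ps, id = x[3])
    } else {  # TRA / BND
      m <- str_match(alt, "[\\[\\]]([^:]+):(\\d+)[\\[\\]]")
      tibble(chrom = x[1], pos = pos1, end = pos1, svtype = "TRA", svlen = 0,
             gt = gt, alt_seq = "", chrom2 = m[2], pos2 = as.numeric(m[3]),
             ps = ps, id = x[3])
    }
  })
  # collapse BND mates: keep the "_1" line of each junction
  is_mate2 <- rows$svtype == "TRA" & grepl("_2$", rows$id)
  rows <- rows[!is_mate2, , drop = FALSE]
  rows$pos2 <- ifelse(rows$svtype == "TRA", rows$pos2 - 1, rows$pos2)
  if (!is.null(reference)) {
    i <- which(rows$svtype == "DUP")
    for (j in i) {
      chr <- as.character(reference[[rows$chrom[j]]])
      rows$alt_seq[j] <- str_sub(chr, rows$pos[j] + 1, rows$end[j])
    }
  }
  rows$id <- NULL
  rows
}

#' Write a fixture truth set as VCF
#'
#' @param fixture a [generate_diploid_genome()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
emit_truth_vcf <- function(fixture, path) {
  tr <- fixture$truth
  write_phased_vcf(tr, fixture$reference, path, blocks = fixture$blocks,
                   sample = "TRUTH")
}

#' Read a truth VCF back into a truth tibble
#'
#' Inverse of [emit_truth_vcf()]: the parsed records reproduce the
#' fixture's truth table (given the reference, so DUP unit sequences can be
#' reconstructed).
#'
#' @param path VCF path.
#' @param reference the fixture reference.
#' @return truth tibble (`chrom`, `pos`, `end`, `svtype`, `svlen`, `gt`,
#'   `alt_seq`, `chrom2`, `pos2`).
#' @export
read_truth_vcf <- function(path, reference = NULL) {
  rows <- read_phased_vcf(path, reference)
  rows$ps <- NULL
  rows[, c("chrom", "pos", "end", "svtype", "svlen", "gt", "alt_seq", "chrom2", "pos2")]
}
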