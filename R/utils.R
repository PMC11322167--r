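# Shared internal helpers: RNG scoping, graph components, edit-distance
# similarity, window depth.

# Run code with a private RNG stream so package functions are deterministic
# under an explicit seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Connected components from an edge list over nodes 1..n (union-find).
components_from_edges <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(from)) {
    a <- find(from[i]); b <- find(to[i])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Sequence similarity from edit distance
#'
#' `1 - editdist / max(nchar)`, the alternate-allele similarity used for
#' redundancy removal and evaluation. Vectorised over pairs.
#'
#' @param a,b character vectors of sequences (recycled to common length).
#' @return numeric vector in `[0, 1]`; `NA` where either sequence is empty.
#' @export
seq_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    la <- nchar(a[i]); lb <- nchar(b[i])
    if (is.na(la) || is.na(lb) || la == 0L || lb == 0L) next
    d <- as.integer(adist(a[i], b[i]))
    out[i] <- 1 - d / max(la, lb)
  }
  out
}

# Mean read depth over a reference window [start, end) from an alignment
# segment table (sum of overlapping bases / window width).
window_depth <- function(segments, chrom, start, end) {
  seg <- segments[segments$chrom == chrom &
                    segments$ref_e > start & segments$ref_s < end, , drop = FALSE]
  if (nrow(seg) == 0L) return(0)
  sum(pmin(seg$ref_e, end) - pmax(seg$ref_s, start)) / (end - start)
}

# svlen size-ratio similarity min/max, vectorised.
svlen_sim <- function(l1, l2) pmin(l1, l2) / pmax(l1, l2)

stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "diplosv_error")
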