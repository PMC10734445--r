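# Average nucleotide identity from MinHash bottom sketches of canonical
# k-mers, and the >97.5% re-occurrence matching rule.
#
# This is a desk-scale sketch estimator: the Jaccard similarity j of two
# genomes' bottom-sketched canonical k-mer sets is inverted to a per-site
# identity through the shared-k-mer model w = 2j/(1+j), ANI =
# 100 * w^(1/k) (the exact inversion of the k-mer survival probability
# (ANI/100)^k; the familiar Mash formula 100*(1 + ln(2j/(1+j))/k) is its
# first-order expansion). Full-alignment ANI output from dedicated tools
# can be supplied instead via a precomputed matrix.

BASE_CODE <- c(A = 0, C = 1, G = 2, T = 3)

# 2-bit encode a DNA string; non-ACGT characters become NA and any k-mer
# covering them is dropped.
encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  unname(BASE_CODE[chars])
}

# All canonical (strand-collapsed) k-mer values of a sequence, as exact
# doubles in [0, 4^k); requires k <= 26 for exact integer arithmetic.
canonical_kmers <- function(seq, k) {
  code <- encode_dna(seq)
  n <- length(code) - k + 1L
  if (n < 1L) return(numeric(0))
  fwd <- numeric(n)
  for (j in 0:(k - 1L))
    fwd <- fwd + code[(1L + j):(n + j)] * 4^(k - 1L - j)
  rc_code <- rev(3 - code)
  rc <- numeric(n)
  for (j in 0:(k - 1L))
    rc <- rc + rc_code[(1L + j):(n + j)] * 4^(k - 1L - j)
  canon <- pmin(fwd, rev(rc))
  unique(canon[!is.na(canon)])
}

# Seeded universal-style hash onto [0, 2^31-2]; the multiplier and offset
# are derived arithmetically from the seed so the global RNG stream is
# left untouched.
hash_kmers <- function(x, seed) {
  p <- 2147483647
  s <- abs(as.numeric(seed)) %% p
  a <- (s * 40503 + 25173) %% 1048573 + 1
  b <- (s * 97531 + 13849) %% p
  (a * (x %% p) + b) %% p
}

bottom_sketch <- function(seq, k, sketch_size, seed) {
  h <- hash_kmers(canonical_kmers(seq, k), seed)
  h <- sort(unique(h))
  h[seq_len(min(sketch_size, length(h)))]
}

#' Estimate average nucleotide identity between two sequences
#'
#' MinHash bottom-sketch estimator on canonical k-mers (strand-collapsed,
#' since contig orientation of assembled genomes is arbitrary).
#' Deterministic given `seed`, symmetric in its arguments; identical
#' sequences give 100.
#'
#' @param seq_a,seq_b DNA sequences (single strings, ACGT alphabet).
#' @param k k-mer size in [11, 26] (default 16).
#' @param sketch_size Bottom-sketch size (default 5000).
#' @param seed Hash seed (integer).
#' @return Estimated ANI as a percentage in [0, 100].
#' @export
estimate_ani <- function(seq_a, seq_b, k = 16, sketch_size = 5000, seed = 1) {
  if (k < 11 || k > 26) stop_fmt("k must lie in [11, 26]")
  if (nchar(seq_a) < 10 * k || nchar(seq_b) < 10 * k)
    stop_fmt("sequences must be at least 10*k = %d bases long", 10 * k)
  sa <- bottom_sketch(seq_a, k, sketch_size, seed)
  sb <- bottom_sketch(seq_b, k, sketch_size, seed)
  s <- min(sketch_size, length(sa), length(sb))
  merged <- sort(unique(c(sa, sb)))[seq_len(s)]
  shared <- sum(merged %in% sa & merged %in% sb)
  j <- shared / s
  if (j <= 0) return(0)
  w <- 2 * j / (1 + j)
  100 * w^(1 / k)
}

#' Pairwise ANI matrix between two genome collections
#'
#' @param set_a,set_b Named character vectors (or named lists) of DNA
#'   sequences.
#' @inheritParams estimate_ani
#' @return Numeric matrix (|set_a| x |set_b|) of ANI percentages.
#' @export
ani_matrix <- function(set_a, set_b, k = 16, sketch_size = 5000, seed = 1) {
  set_a <- as.list(set_a); set_b <- as.list(set_b)
  sk_a <- lapply(set_a, bottom_sketch, k = k, sketch_size = sketch_size,
                 seed = seed)
  sk_b <- lapply(set_b, bottom_sketch, k = k, sketch_size = sketch_size,
                 seed = seed)
  out <- matrix(0, length(set_a), length(set_b),
                dimnames = list(names(set_a), names(set_b)))
  for (i in seq_along(sk_a)) for (j2 in seq_along(sk_b)) {
    sa <- sk_a[[i]]; sb <- sk_b[[j2]]
    s <- min(sketch_size, length(sa), length(sb))
    merged <- sort(unique(c(sa, sb)))[seq_len(s)]
    shared <- sum(merged %in% sa & merged %in% sb)
    j <- shared / s
    out[i, j2] <- if (j <= 0) 0 else 100 * (2 * j / (1 + j))^(1 / k)
  }
  out
}

#' Match re-occurring genomes between two collections
#'
#' Greedy best-hit one-to-one matching by descending ANI: each genome of
#' `set_a` is paired with its maximum-ANI partner in `set_b`, no genome is
#' assigned twice, and ties (several pairs at the maximal ANI of a round)
#' are broken by input order and flagged. A match re-occurs iff its ANI
#' strictly exceeds the threshold (the printed bound is ">97.5%", so a
#' pair at exactly 97.5 does not re-occur).
#'
#' @param set_a,set_b Named character vectors of genome sequences; may be
#'   omitted when `ani` is supplied.
#' @param threshold Re-occurrence threshold in percent (default 97.5,
#'   strict).
#' @param ani Optional precomputed ANI matrix (rows = set_a, columns =
#'   set_b), e.g. from a full-alignment ANI tool.
#' @inheritParams estimate_ani
#' @return data.frame with `genome_a`, `genome_b`, `ani_pct`,
#'   `reoccurring`, `tie`, ordered by descending ANI.
#' @export
find_reoccurring <- function(set_a = NULL, set_b = NULL, threshold = 97.5,
                             k = 16, sketch_size = 5000, seed = 1,
                             ani = NULL) {
  if (is.null(ani)) {
    if (length(set_a) == 0 || length(set_b) == 0)
      return(data.frame(genome_a = character(0), genome_b = character(0),
                        ani_pct = numeric(0), reoccurring = logical(0),
                        tie = logical(0)))
    ani <- ani_matrix(set_a, set_b, k, sketch_size, seed)
  }
  m <- ani
  out <- list()
  while (nrow(m) > 0 && ncol(m) > 0) {
    best <- max(m)
    hits <- which(m == best, arr.ind = TRUE)
    tie <- nrow(hits) > 1
    i <- hits[1, 1]; j <- hits[1, 2]
    out[[length(out) + 1L]] <- data.frame(
      genome_a = rownames(m)[i], genome_b = colnames(m)[j],
      ani_pct = best, reoccurring = best > threshold, tie = tie,
      stringsAsFactors = FALSE)
    m <- m[-i, -j, drop = FALSE]
  }
  do.call(rbind, out)
}
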