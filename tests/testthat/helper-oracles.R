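# Independent brute-force oracles used across the suite.  These are
# deliberately naive re-derivations (position-by-position scans, full
# enumerations, per-base depth counts) kept separate from the package's
# own algorithms.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

gr <- function(chrom, start, end = NULL, width = NULL, ...) {
  r <- if (is.null(end)) IRanges(start, width = width) else
    IRanges(start, end)
  GRanges(chrom, r, ...)
}

# Write BED/narrowPeak lines to a tempfile scoped to the calling test.
local_bed <- function(..., env = parent.frame()) {
  tf <- withr::local_tempfile(fileext = ".bed", .local_envir = env)
  writeLines(c(...), tf)
  tf
}

# --- naive motif-category scanner ----------------------------------

rc <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}

# All (start, end, strand) occurrences of pattern in s, by direct
# substring comparison at every position.
naive_matches <- function(s, pattern, strand) {
  k <- nchar(pattern)
  L <- nchar(s)
  if (L < k) return(NULL)
  starts <- which(substring(s, 1:(L - k + 1), k:L) == pattern)
  if (!length(starts)) return(NULL)
  data.frame(start = starts, end = starts + k - 1, strand = strand)
}

# Category presence by exhaustive position-wise scanning with the
# same-strand containment exclusion rule.
naive_scan <- function(s, categories = kmer_categories(),
                       both_strands = TRUE) {
  s <- toupper(s)
  labs <- categories$label
  all_hits <- lapply(seq_along(labs), function(ci) {
    out <- NULL
    for (kmer in categories$kmers[[ci]]) {
      out <- rbind(out, naive_matches(s, kmer, "+"))
      if (both_strands)
        out <- rbind(out, naive_matches(s, rc(kmer), "-"))
    }
    out
  })
  pres <- logical(length(labs))
  names(pres) <- labs
  for (ci in seq_along(labs)) {
    h <- all_hits[[ci]]
    if (is.null(h)) next
    parents <- categories$excludes[[ci]]
    keep <- rep(TRUE, nrow(h))
    if (length(parents)) {
      pm <- do.call(rbind, all_hits[match(parents, labs)])
      if (!is.null(pm)) {
        for (i in seq_len(nrow(h))) {
          inside <- any(pm$strand == h$strand[i] &
                          pm$start <= h$start[i] & h$end[i] <= pm$end)
          if (inside) keep[i] <- FALSE
        }
      }
    }
    pres[ci] <- any(keep)
  }
  pres
}

# --- exhaustive mHG ------------------------------------------------

# Hypergeometric prefix tails of a binary vector (direct formula).
mhg_stat_oracle <- function(v) {
  N <- length(v)
  K <- sum(v)
  n <- seq_len(N - 1)
  min(phyper(cumsum(v)[n] - 1, K, N - K, n, lower.tail = FALSE))
}

# All C(N, K) binary vectors with K ones.
all_binary_vectors <- function(N, K) {
  combs <- combn(N, K)
  lapply(seq_len(ncol(combs)), function(j) {
    v <- integer(N)
    v[combs[, j]] <- 1L
    v
  })
}

# Exact p by enumeration: fraction of arrangements whose statistic is
# at most the observed one (relative tolerance for float ties).
mhg_p_oracle <- function(v) {
  stats <- vapply(all_binary_vectors(length(v), sum(v)),
                  mhg_stat_oracle, numeric(1))
  obs <- mhg_stat_oracle(v)
  mean(stats <= obs * (1 + 1e-9))
}

# --- Fisher / hypergeometric ---------------------------------------

# One-tailed (greater) Fisher p for rbind(c(a,b),(c,d)) by explicit
# hypergeometric summation over the upper tail.
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b            # row 1 total
  n <- c_ + d           # row 2 total
  k <- a + c_           # first-column margin
  hi <- min(m, k)
  x <- a:hi
  sum(choose(m, x) * choose(n, k - x)) / choose(m + n, k)
}

# --- BH step-up ----------------------------------------------------

bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

# --- average linkage, O(n^3) ---------------------------------------

# Returns the merge heights of naive average-linkage clustering on a
# distance matrix (UPGMA on dissimilarities).
brute_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA)
    bestval <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (j <= i) next
      val <- mean(d[active[[i]], active[[j]]])
      if (val < bestval) { bestval <- val; best <- c(i, j) }
    }
    heights <- c(heights, bestval)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1]] <- merged
  }
  heights
}

# --- per-base depth merge ------------------------------------------

# Regions with >= min_sets distinct sets covering, by counting depth at
# every base on [1, L] (single chromosome).
brute_depth_merge <- function(sets, min_sets, L) {
  depth <- integer(L)
  for (s in sets) {
    covered <- logical(L)
    for (i in seq_along(s))
      covered[start(s)[i]:min(end(s)[i], L)] <- TRUE
    depth <- depth + covered
  }
  keep <- depth >= min_sets
  if (!any(keep)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

# --- tiny synthetic configs ----------------------------------------

tiny_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_chroms = 1, chrom_length = 60000,
               n_genes = 40, n_peaks_shared = 30,
               n_peaks_hetero_specific = 15, n_peaks_homo_specific = 15,
               peak_width = 300, n_controls = 6, n_artifact_regions = 3,
               n_noise_peaks = 10)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

random_dna <- function(n, len, gc = 0.4) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = ""), character(1))
}

# Plant a k-mer into each of a fraction of sequences at random offsets.
plant_kmer <- function(seqs, kmer, rate) {
  n <- length(seqs)
  hit <- runif(n) < rate
  for (i in which(hit)) {
    pos <- sample(nchar(seqs[i]) - nchar(kmer) + 1, 1)
    substr(seqs[i], pos, pos + nchar(kmer) - 1) <- kmer
  }
  seqs
}
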