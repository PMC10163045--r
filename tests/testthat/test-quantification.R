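frag <- function(chrom, pos, strand = "+", mapq = 60) {
  f <- gr(chrom, pos, pos, strand = strand)
  f$mapq <- mapq
  f
}

test_that("fragment counting extends from the 5' end and filters MAPQ", {
  peak <- gr("chr1", 251, 400)  # [250,400) in file coordinates
  peak$name <- "p1"
  # 5' at 100 on + extends to [100,300) -> overlaps
  bc <- count_fragments_in_intervals(list(s = frag("chr1", 101)), peak,
                                     fragment_size = 200)
  expect_equal(unname(bc$counts[1, 1]), 1L)
  # 5' at 100 with only 50 bp extension does not reach the peak
  bc2 <- count_fragments_in_intervals(list(s = frag("chr1", 101)), peak,
                                      fragment_size = 50)
  expect_equal(unname(bc2$counts[1, 1]), 0L)
  # minus-strand fragment extends leftwards
  bc3 <- count_fragments_in_intervals(list(s = frag("chr1", 500, "-")),
                                      peak, fragment_size = 200)
  expect_equal(unname(bc3$counts[1, 1]), 1L)
  # MAPQ 29 is excluded at the default cutoff of 30
  bc4 <- count_fragments_in_intervals(
    list(s = c(frag("chr1", 300, mapq = 29), frag("chr1", 300, mapq = 30))),
    peak)
  expect_equal(unname(bc4$counts[1, 1]), 1L)
  expect_equal(unname(bc4$library_sizes), 1)
  # unknown chromosomes are skipped with a warning
  expect_warning(
    count_fragments_in_intervals(list(s = frag("chrX", 100)), peak),
    "without peaks")
})

test_that("fragment counting is additive over a partition of fragments", {
  set.seed(21)
  peaks <- gr("chr1", seq(1000, 20000, by = 1000),
              seq(1000, 20000, by = 1000) + 400)
  peaks$name <- paste0("p", seq_along(peaks))
  pos <- sample(1:21000, 300)
  all_fr <- frag("chr1", pos)
  part1 <- all_fr[1:120]
  part2 <- all_fr[121:300]
  full <- count_fragments_in_intervals(list(s = all_fr), peaks)
  split2 <- count_fragments_in_intervals(list(a = part1, b = part2),
                                         peaks)
  expect_equal(unname(full$counts[, 1]),
               unname(split2$counts[, 1] + split2$counts[, 2]))
})

test_that("normalization follows the documented formulas", {
  m <- matrix(c(10, 20), nrow = 1,
              dimnames = list("p1", c("a", "b")))
  bc <- binding_counts(m, library_sizes = c(1e6, 1e6),
                       peak_lengths = 500)
  # RPKM: 10 reads / (0.5 kb * 1 M reads) = 20
  expect_equal(unname(normalize_matrix(bc, "rpkm")$counts[1, ]),
               c(20, 40))
  # equal library sizes: library_size normalization is the identity
  expect_equal(normalize_matrix(bc, "library_size")$counts, bc$counts)
  # doubling counts and library size of one sample changes nothing
  bc2 <- binding_counts(matrix(c(10, 40), nrow = 1,
                               dimnames = list("p1", c("a", "b"))),
                        library_sizes = c(1e6, 2e6))
  n1 <- normalize_matrix(bc2, "library_size")$counts
  bc3 <- binding_counts(matrix(c(10, 20), nrow = 1,
                               dimnames = list("p1", c("a", "b"))),
                        library_sizes = c(1e6, 1e6))
  n2 <- normalize_matrix(bc3, "library_size")$counts
  expect_equal(unname(n1[1, 2] / n1[1, 1]), unname(n2[1, 2] / n2[1, 1]))
  expect_error(
    normalize_matrix(binding_counts(m, library_sizes = c(1e6, 1e6)),
                     "rpkm"),
    "lengths")
})

test_that("replicate correlation behaves at the extremes", {
  set.seed(31)
  x <- rnbinom(10000, mu = 100, size = 10)
  bc <- binding_counts(cbind(a = x, b = x))
  expect_equal(replicate_correlation(bc, "a", "b"), 1.0)
  bc2 <- binding_counts(cbind(a = x, b = sample(x)))
  expect_lt(abs(replicate_correlation(bc2, "a", "b")), 0.05)
  expect_error(replicate_correlation(binding_counts(cbind(a = 1:2,
                                                          b = 1:2)),
                                     "a", "b"), "3 peaks")
  # synthetic NB replicates at dispersion 0.1 correlate highly
  mu <- exp(runif(5000, log(20), log(500)))
  r1 <- rnbinom(5000, mu = mu, size = 10)
  r2 <- rnbinom(5000, mu = mu, size = 10)
  bc3 <- binding_counts(cbind(a = r1, b = r2))
  expect_gt(replicate_correlation(bc3, "a", "b"), 0.7)
})

test_that("binding correlation clustering matches brute-force linkage", {
  set.seed(41)
  n <- 400
  base1 <- rnorm(n, 8, 2)
  base2 <- rnorm(n, 8, 2)
  mk <- function(base, noise) 2^(base + rnorm(n, 0, noise))
  counts <- cbind(s1_r1 = mk(base1, 0.2), s1_r2 = mk(base1, 0.2),
                  s2_r1 = mk(base1, 0.6), s2_r2 = mk(base1, 0.6),
                  s3_r1 = mk(base2, 0.2), s3_r2 = mk(base2, 0.2))
  cons <- gr("chr1", seq(1, by = 1000, length.out = n),
             seq(1, by = 1000, length.out = n) + 200)
  bc <- binding_counts(round(counts))
  sample_of <- setNames(rep(c("s1", "s2", "s3"), each = 2),
                        colnames(counts))
  res <- binding_correlation_clustering(bc, cons, sample_of = sample_of)
  # correlation matrix structure
  expect_true(isSymmetric(res$correlation))
  expect_equal(unname(diag(res$correlation)), rep(1, 3))
  # correlated pair joins before the independent sample
  merged_first <- rownames(res$correlation)[res$hclust$merge[1, ] < 0]
  expect_setequal(sort(-res$hclust$merge[1, ]),
                  which(rownames(res$correlation) %in% c("s1", "s2")))
  # identical samples merge at height 0
  bc_id <- binding_counts(cbind(a = round(counts[, 1]),
                                b = round(counts[, 1])))
  res_id <- binding_correlation_clustering(bc_id, cons)
  expect_equal(res_id$hclust$height, 0)
  expect_match(res_id$newick, "^\\(")
  # average-linkage heights equal the O(n^3) oracle
  res6 <- binding_correlation_clustering(bc, cons)
  d <- as.dist(1 - res6$correlation)
  expect_equal(sort(res6$hclust$height),
               sort(brute_average_linkage(d)),
               tolerance = 1e-12)
})

test_that("top-n enrichment filter keeps regions from any replicate's top peaks", {
  n <- 50
  cons <- gr("chr1", seq(1, by = 1000, length.out = n),
             seq(1, by = 1000, length.out = n) + 200)
  counts <- matrix(rpois(2 * n, 50), ncol = 2,
                   dimnames = list(NULL, c("a", "b")))
  bc <- binding_counts(counts)
  # replicate peaks: a's top peak covers region 1, b's covers region 2
  mk_rp <- function(i, q) {
    p <- gr("chr1", start(cons)[i], end(cons)[i])
    p$neg_log10_q <- q
    p$name <- "x"
    p
  }
  rp <- list(a = c(mk_rp(1, 10), mk_rp(3, 1)),
             b = c(mk_rp(2, 9), mk_rp(4, 1)))
  res <- binding_correlation_clustering(bc, cons, replicate_peaks = rp,
                                        top_n = 1)
  expect_length(res$consensus, 2)
  expect_equal(start(res$consensus), start(cons)[1:2])
  expect_error(
    binding_correlation_clustering(bc, cons,
                                   replicate_peaks = list(a = gr("chr2", 1, 2)),
                                   top_n = 1),
    "no consensus regions")
})

test_that("window peak caller finds planted enrichment and stays quiet on null", {
  set.seed(51)
  L <- 200000
  chrom_lengths <- c(chr1 = L)
  # null: sample and control both uniform
  null_s <- frag("chr1", sort(sample(1:L, 3000, TRUE)))
  null_c <- frag("chr1", sort(sample(1:L, 3000, TRUE)))
  called_null <- call_peaks_window(null_s, null_c, chrom_lengths,
                                   window = 200)
  expect_lte(length(called_null), 1)
  # planted: 10x density in 5 regions of 1 kb
  regions <- seq(20000, 180000, length.out = 5)
  enriched <- unlist(lapply(regions, function(r)
    sample(r:(r + 999), 200, TRUE)))
  s <- frag("chr1", sort(c(sample(1:L, 2000, TRUE), enriched)))
  called <- call_peaks_window(s, null_c, chrom_lengths, window = 200)
  hits <- countOverlaps(gr("chr1", regions, regions + 999), called)
  expect_gte(mean(hits > 0), 0.95)
  # summit and q-value columns are populated
  expect_true(all(called$neg_log10_q > 0))
  expect_true(all(!is.na(called$summit)))
  expect_error(call_peaks_window(null_s, NULL, chrom_lengths,
                                 window = -5), "positive")
})
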