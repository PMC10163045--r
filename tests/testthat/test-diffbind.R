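# Build a binding_counts object for a hetero/homo pair from matrices.
pair_counts <- function(het, hom) {
  m <- cbind(het, hom)
  colnames(m) <- c(paste0("hetero_rep", seq_len(ncol(het))),
                   paste0("homo_rep", seq_len(ncol(hom))))
  rownames(m) <- sprintf("p%05d", seq_len(nrow(m)))
  binding_counts(m, samples = data.frame(
    sample = colnames(m),
    condition = rep(c("hetero", "homo"), c(ncol(het), ncol(hom))),
    replicate = c(seq_len(ncol(het)), seq_len(ncol(hom))),
    stringsAsFactors = FALSE))
}

nb_matrix <- function(n, reps, mu, size = 10) {
  matrix(rnbinom(n * reps, mu = mu, size = size), ncol = reps)
}

test_that("normalization removes a global scale factor", {
  set.seed(61)
  n <- 2000
  mu <- exp(runif(n, log(20), log(500)))
  het <- nb_matrix(n, 2, mu)
  hom <- het * 2L  # condition B is a scaled copy
  np <- normalize_pair(pair_counts(het, hom))
  cond <- np$condition
  m_ratio <- rowMeans(np$log2[np$occupied, cond == "hetero"]) -
    rowMeans(np$log2[np$occupied, cond == "homo"])
  expect_lt(abs(median(m_ratio)), 0.05)
  # identical matrices: the two condition blocks come out identical and
  # every M is zero
  np_id <- normalize_pair(pair_counts(het, het))
  expect_equal(np_id$log2[, 1:2], np_id$log2[, 3:4],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("unchanged peaks stay centred when 30% of peaks shift", {
  set.seed(62)
  n <- 3000
  up <- seq_len(n) <= 0.15 * n
  down <- seq_len(n) > 0.15 * n & seq_len(n) <= 0.3 * n
  unchanged <- !(up | down)
  mu <- exp(runif(n, log(50), log(500)))
  het <- nb_matrix(n, 3, mu * ifelse(up, 4, ifelse(down, 0.25, 1)))
  hom <- nb_matrix(n, 3, mu)
  np <- normalize_pair(pair_counts(het, hom))
  cond <- np$condition
  M <- rowMeans(np$log2[, cond == "hetero"]) -
    rowMeans(np$log2[, cond == "homo"])
  expect_lt(abs(median(M[unchanged & np$occupied])), 0.05)
  # all-low counts: nothing is occupied
  ones <- matrix(1L, n, 3)
  expect_error(normalize_pair(pair_counts(ones, ones)), "occupied")
})

test_that("mean-variance curve recovers homoscedastic variance", {
  set.seed(63)
  n <- 5000
  mu <- runif(n, 4, 10)
  sigma <- 0.4
  m <- matrix(rnorm(n * 6, mean = mu, sd = sigma), ncol = 6)
  np <- structure(list(log2 = `rownames<-`(m, paste0("p", 1:n)),
                       condition = rep(c("hetero", "homo"), each = 3),
                       occupied = rep(TRUE, n), pseudocount = 1),
                  class = "normalized_pair")
  curve <- fit_mean_variance(np)
  grid <- seq(quantile(mu, 0.05), quantile(mu, 0.95), length.out = 20)
  expect_true(all(abs(curve$predict(grid) / sigma^2 - 1) < 0.15))
  expect_gt(curve$prior_df, 0)
})

test_that("log-count variance decreases with NB mean and degenerate input errors", {
  set.seed(64)
  n <- 4000
  mu <- exp(seq(log(10), log(1000), length.out = n))
  het <- nb_matrix(n, 3, mu)
  hom <- nb_matrix(n, 3, mu)
  np <- normalize_pair(pair_counts(het, hom))
  curve <- fit_mean_variance(np)
  lo <- curve$predict(log2(15))
  hi <- curve$predict(log2(800))
  expect_gt(lo, hi)  # delta method: var of log falls as mean rises
  # identical replicates -> all variances zero -> degenerate
  x <- matrix(rep(rnbinom(100, mu = 100, size = 5), 4), ncol = 4)
  np0 <- structure(list(log2 = `rownames<-`(log2(x + 1),
                                            paste0("p", 1:100)),
                        condition = rep(c("hetero", "homo"), each = 2),
                        occupied = rep(TRUE, 100), pseudocount = 1),
                   class = "normalized_pair")
  expect_error(fit_mean_variance(np0), "degenerate")
})

test_that("differential test calls planted fold changes and nulls correctly", {
  set.seed(65)
  n <- 4000
  shifted <- seq_len(n) <= 500
  mu_h <- ifelse(shifted, 200, 100)
  mu_o <- ifelse(shifted, 50, 100)
  het <- nb_matrix(n, 3, mu_h)
  hom <- nb_matrix(n, 3, mu_o)
  np <- normalize_pair(pair_counts(het, hom))
  res <- test_differential(np, fit_mean_variance(np))
  # planted hetero-up peaks called heterodimer-specific
  expect_gt(mean(res$class[shifted] == "heterodimer_specific"), 0.9)
  # null peaks largely unchanged
  expect_lt(mean(res$class[!shifted] != "unchanged"), 0.05)
  # invariant: class definition matches p/fc thresholds
  expect_true(all((res$class == "heterodimer_specific") ==
                    (res$padj < 0.05 & res$log2fc > 0)))
  expect_true(all((res$class == "homodimer_specific") ==
                    (res$padj < 0.05 & res$log2fc < 0)))
})

test_that("identical condition means give p near 1 and class unchanged", {
  set.seed(66)
  n <- 500
  x <- nb_matrix(n, 2, 200)
  m <- log2(cbind(x, x) + 1)
  rownames(m) <- paste0("p", 1:n)
  np <- structure(list(log2 = m,
                       condition = rep(c("hetero", "homo"), each = 2),
                       occupied = rep(TRUE, n), pseudocount = 1),
                  class = "normalized_pair")
  # add tiny independent noise so variances are not exactly zero
  np$log2 <- np$log2 + matrix(rnorm(n * 4, 0, 1e-3), ncol = 4)
  res <- test_differential(np, fit_mean_variance(np))
  expect_true(all(abs(res$log2fc) < 0.01))
  expect_true(all(res$class == "unchanged"))
})

test_that("swapping condition labels negates fold changes, keeps p", {
  set.seed(67)
  n <- 1000
  het <- nb_matrix(n, 3, exp(runif(n, log(30), log(300))))
  hom <- nb_matrix(n, 3, exp(runif(n, log(30), log(300))))
  bc1 <- pair_counts(het, hom)
  # swap: homo columns first, relabelled
  m2 <- cbind(hom, het)
  colnames(m2) <- c(paste0("hetero_rep", 1:3), paste0("homo_rep", 1:3))
  rownames(m2) <- rownames(bc1$counts)
  bc2 <- binding_counts(m2, samples = data.frame(
    sample = colnames(m2), condition = rep(c("hetero", "homo"), each = 3),
    replicate = rep(1:3, 2), stringsAsFactors = FALSE))
  np1 <- normalize_pair(bc1)
  np2 <- normalize_pair(bc2)
  r1 <- test_differential(np1, fit_mean_variance(np1))
  r2 <- test_differential(np2, fit_mean_variance(np2))
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-9)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-9)
  swap <- c(heterodimer_specific = "homodimer_specific",
            homodimer_specific = "heterodimer_specific",
            unchanged = "unchanged")
  expect_equal(unname(swap[r1$class]), r2$class)
})

test_that("raising one heterodimer count never lowers that peak's log2FC", {
  set.seed(68)
  n <- 200
  het <- nb_matrix(n, 3, 100)
  hom <- nb_matrix(n, 3, 100)
  m <- log2(cbind(het, hom) + 1)
  rownames(m) <- paste0("p", 1:n)
  np <- structure(list(log2 = m,
                       condition = rep(c("hetero", "homo"), each = 3),
                       occupied = rep(TRUE, n), pseudocount = 1),
                  class = "normalized_pair")
  curve <- fit_mean_variance(np)
  base <- test_differential(np, curve)
  for (delta in c(0.5, 1, 2)) {
    np2 <- np
    np2$log2[7, 1] <- np2$log2[7, 1] + delta
    bumped <- test_differential(np2, curve)
    expect_gte(bumped$log2fc[7], base$log2fc[7])
  }
})

test_that("BH adjustment equals the textbook step-up procedure", {
  set.seed(69)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # hand-checked case
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
})

test_that("top differential selection orders and ties deterministically", {
  res <- data.frame(
    peak_id = c("a", "b", "c", "d", "e"),
    log2fc = c(3, -2, 3, 1, 0.5),
    padj = c(0.01, 0.01, 0.001, 0.2, 0.04),
    stringsAsFactors = FALSE)
  sel <- select_top_differential(res, n = 10, direction = "hetero")
  # equal |fc|: smaller padj first
  expect_equal(sel$peak_id, c("c", "a", "e"))
  sel2 <- select_top_differential(res, n = 1, direction = "homo")
  expect_equal(sel2$peak_id, "b")
  expect_warning(
    empty <- select_top_differential(res[res$padj > 0.5, , drop = FALSE],
                                     direction = "hetero"),
    "no peaks qualify")
  expect_equal(nrow(empty), 0)
  # 1500 qualifying peaks with n = 2000 returns all 1500
  big <- data.frame(peak_id = sprintf("p%04d", 1:1500),
                    log2fc = runif(1500, 0.1, 5),
                    padj = runif(1500, 0, 0.05),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(select_top_differential(big, n = 2000,
                                            direction = "hetero")), 1500)
})
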