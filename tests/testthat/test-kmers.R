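test_that("built-in category table matches the published definitions", {
  tab <- kmer_categories()
  expect_equal(tab$label,
               c("CRE_like", "TRE_like", "AACGTG", "CACGTG", "GACGTG",
                 "TACGTG", "TGAC_half", "TGAG_half", "TGAT"))
  expect_equal(tab$kmers[[match("CRE_like", tab$label)]], "TGACGTCA")
  expect_equal(tab$kmers[[match("TRE_like", tab$label)]], "TGACTCA")
  expect_equal(tab$excludes[[match("TGAC_half", tab$label)]], "CRE_like")
  expect_equal(tab$excludes[[match("TGAG_half", tab$label)]], "TRE_like")
  ext <- kmer_categories("extended")
  expect_setequal(ext$excludes[[match("TGAC_half", ext$label)]],
                  c("CRE_like", "TRE_like"))
})

test_that("scanner applies the CRE exclusion and strand collapse", {
  # the only TGAC sits inside TGACGTCA -> half-site suppressed
  s <- scan_sequence_categories("ATGACGTCAT")
  expect_true(s$presence[1, "CRE_like"])
  expect_false(s$presence[1, "TGAC_half"])
  # a bare TGAC is a half-site and nothing else
  s2 <- scan_sequence_categories("AATGACAAA")
  expect_true(s2$presence[1, "TGAC_half"])
  expect_equal(sum(s2$presence), 1)
  # palindromic G-box: one binary presence despite both-strand matches
  s3 <- scan_sequence_categories("GCACGTGC")
  expect_true(s3$presence[1, "CACGTG"])
  expect_equal(sum(s3$presence[1, ] == 1), 1)
  # TGAC inside TRE-like counts under the literal rule...
  s4 <- scan_sequence_categories("ATGACTCAT")
  expect_true(s4$presence[1, "TRE_like"])
  expect_true(s4$presence[1, "TGAC_half"])
  # ...but is masked under the extended hierarchy
  s5 <- scan_sequence_categories("ATGACTCAT", kmer_categories("extended"))
  expect_false(s5$presence[1, "TGAC_half"])
  # N never matches (TRE-like broken by N, no other k-mer on either
  # strand); invalid characters are rejected
  expect_equal(sum(scan_sequence_categories("TGANTCA")$presence), 0)
  expect_error(scan_sequence_categories("TGAX"), "A, C, G, T, N")
})

test_that("scanner equals the naive position-wise oracle on random 150-mers", {
  set.seed(71)
  seqs <- random_dna(400, 150)
  # enrich the collection with planted elements so all branches fire
  seqs[1:80] <- plant_kmer(seqs[1:80], "TGACGTCA", 1)
  seqs[81:160] <- plant_kmer(seqs[81:160], "TGACTCA", 1)
  got <- scan_sequence_categories(seqs)$presence
  want <- t(vapply(seqs, naive_scan, logical(9), USE.NAMES = FALSE))
  expect_identical(unname(got), unname(want))
})

test_that("reverse-complementing inputs leaves presences unchanged", {
  set.seed(72)
  seqs <- plant_kmer(random_dna(150, 150), "TGACGTCA", 0.3)
  seqs <- plant_kmer(seqs, "CACGTG", 0.3)
  fwd <- scan_sequence_categories(seqs)$presence
  rev <- scan_sequence_categories(rc(seqs))$presence
  expect_identical(fwd, rev)
})

test_that("a present half-site implies an occurrence outside its parent", {
  set.seed(73)
  seqs <- plant_kmer(random_dna(300, 80), "TGACGTCA", 0.5)
  scan <- scan_sequence_categories(seqs)
  for (i in which(scan$presence[, "TGAC_half"])) {
    m <- scan$matches
    halves <- m[m$seq == i & m$category == "TGAC_half", ]
    parents <- m[m$seq == i & m$category == "CRE_like", ]
    # retained half matches must not sit inside same-strand CRE matches
    for (j in seq_len(nrow(halves))) {
      inside <- nrow(parents) > 0 &&
        any(parents$strand == halves$strand[j] &
              parents$start <= halves$start[j] &
              halves$end[j] <= parents$end)
      expect_false(inside)
    }
  }
})

test_that("per-peak matrix scans the 150 bp midpoint window", {
  # peak [1000,1400) in file coordinates -> scan [1125,1275)
  genome <- c(chr1 = paste(rep("A", 2000), collapse = ""))
  g <- genome[["chr1"]]
  substr(g, 1126, 1132) <- "TGACTCA"  # 1-based window start = 1126
  genome_in <- c(chr1 = g)
  peak <- gr("chr1", 1001, 1400)
  peak$name <- "p1"
  mmt <- peak_category_matrix(peak, genome_in, window = 150)
  expect_equal(unname(mmt$presence[1, "TRE_like"]), 1L)
  # one base earlier falls outside the window
  g2 <- genome[["chr1"]]
  substr(g2, 1119, 1125) <- "TGACTCA"
  mmt2 <- peak_category_matrix(peak, c(chr1 = g2), window = 150)
  expect_equal(unname(mmt2$presence[1, "TRE_like"]), 0L)
  expect_error(peak_category_matrix(gr("chrZ", 1, 100), genome_in),
               "missing from genome")
})

test_that("combination counts enumerate presence sets exactly", {
  set.seed(74)
  seqs <- c(plant_kmer(random_dna(6, 40, gc = 0.2), "TGACGTCA", 1),
            plant_kmer(random_dna(7, 40, gc = 0.2), "CACGTG", 1),
            random_dna(7, 40, gc = 0.2))
  pres <- scan_sequence_categories(seqs)$presence * 1L
  rownames(pres) <- paste0("p", 1:20)
  mmt <- structure(list(presence = pres,
                        peak_class = rep(c("heterodimer_specific",
                                           "homodimer_specific"), 10),
                        peak_id = rownames(pres)),
                   class = "motif_match_table")
  out <- combination_counts(mmt)
  # exhaustive re-count
  labs <- colnames(pres)
  want <- table(apply(pres, 1, function(r)
    if (!any(r == 1)) "none" else paste(labs[r == 1], collapse = "+")))
  expect_equal(sum(out$heterodimer_specific) +
                 sum(out$homodimer_specific), 20)
  for (i in seq_len(nrow(out))) {
    expect_equal(out$heterodimer_specific[i] + out$homodimer_specific[i],
                 unname(want[[out$combination[i]]]))
  }
})

test_that("category enrichment reproduces closed-form Fisher results", {
  mk_mmt <- function(h_with, h_without, o_with, o_without) {
    pres <- matrix(c(rep(1, h_with), rep(0, h_without),
                     rep(1, o_with), rep(0, o_without)), ncol = 1,
                   dimnames = list(NULL, "CACGTG"))
    structure(list(presence = pres,
                   peak_class = rep(c("heterodimer_specific",
                                      "homodimer_specific"),
                                    c(h_with + h_without,
                                      o_with + o_without)),
                   peak_id = paste0("p", seq_len(nrow(pres)))),
              class = "motif_match_table")
  }
  # [[5,0],[0,5]]: one-tailed p = 1/252
  r <- category_enrichment(mk_mmt(5, 0, 0, 5))
  expect_equal(r$p_hetero, 1 / 252, tolerance = 1e-12)
  expect_gt(r$log2_odds_ratio, 0)  # Haldane-corrected, finite
  expect_true(is.finite(r$log2_odds_ratio))
  # equal proportions: OR = 1, one-tailed p >= 0.5
  r2 <- category_enrichment(mk_mmt(10, 90, 10, 90))
  expect_equal(r2$log2_odds_ratio, 0)
  expect_gte(r2$p_hetero, 0.5)
  expect_gte(r2$p_homo, 0.5)
  expect_error(category_enrichment(structure(list(
    presence = matrix(1, 1, 1, dimnames = list(NULL, "x")),
    peak_class = "heterodimer_specific", peak_id = "p"),
    class = "motif_match_table")), "required")
})

test_that("one-tailed Fisher p equals hypergeometric summation", {
  set.seed(75)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    expect_equal(fisher_one_tailed(cells[1], cells[2], cells[3],
                                   cells[4]),
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("planted rate contrast is recovered with the right direction", {
  set.seed(76)
  n <- 500
  het <- plant_kmer(random_dna(n, 150), "TGACTCA", 0.6)
  hom <- plant_kmer(random_dna(n, 150), "TGACTCA", 0.1)
  pres <- scan_sequence_categories(c(het, hom))$presence * 1L
  mmt <- structure(list(presence = pres,
                        peak_class = rep(c("heterodimer_specific",
                                           "homodimer_specific"),
                                         each = n),
                        peak_id = paste0("p", 1:(2 * n))),
                   class = "motif_match_table")
  enr <- category_enrichment(mmt)
  tre <- enr[enr$category == "TRE_like", ]
  expect_gt(tre$log2_odds_ratio, 0)
  expect_lt(tre$padj_hetero, 1e-10)
  expect_equal(tre$direction, "hetero")
})

test_that("dinucleotide shuffle preserves dinucleotide counts exactly", {
  set.seed(77)
  dinuc_counts <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  for (s in c(random_dna(20, 60), "ACGTACGTACGT", "AAAAAT")) {
    sh <- dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(as.list(dinuc_counts(sh)), as.list(dinuc_counts(s)))
  }
  # shuffles differ from the original often enough to be a background
  long <- random_dna(1, 200)
  expect_false(all(vapply(1:5, function(i)
    dinucleotide_shuffle(long) == long, logical(1))))
})

test_that("k-mer discovery ranks a planted motif first and controls the null", {
  set.seed(78)
  pos <- plant_kmer(random_dna(300, 100), "TGACTCA", 0.5)
  res <- ksm_lite_discover(pos, k_min = 6, k_max = 8)
  expect_true(grepl("TGACTCA|TGAGTCA", res$kmer[1]) ||
                grepl(res$kmer[1], "TGACTCA") ||
                grepl(res$kmer[1], rc("TGACTCA")))
  expect_lt(res$padj[1], 1e-6)
  # null: no planting -> no k-mer survives BH in most runs
  hits <- vapply(1:10, function(i) {
    nullres <- ksm_lite_discover(random_dna(150, 80), k_min = 6,
                                 k_max = 7)
    min(nullres$padj)
  }, numeric(1))
  expect_gte(mean(hits >= 0.05), 0.9)
  expect_warning(ksm_lite_discover(c("ACG", random_dna(60, 100)),
                                   k_min = 5, k_max = 6), "shorter")
})
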