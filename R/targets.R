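# Peak-to-gene target scoring (closest-gene style) and flat gene-set
# enrichment.

#' Closest-gene target scores
#'
#' Scores every gene by the distance from its TSS to the nearest peak
#' summit on the same chromosome, converted through the empirical
#' distribution of those distances over all genes:
#' `score(g) = 1 - ECDF(d(g))`, with tied distances sharing the mid-rank
#' value, so the score decreases monotonically with distance.  Genes on
#' chromosomes without peaks get score 0.  Per-gene q-values come from a
#' permutation null in which summits are re-placed uniformly per
#' chromosome `B` times; the one-sided p-value is the fraction of
#' permutations giving a distance at most the observed one
#' (with an add-one correction), BH-adjusted.
#'
#' @param peaks peak GRanges (summit offsets used when present,
#'   midpoints otherwise).
#' @param genes gene-model GRanges with `gene_id`.
#' @param chrom_lengths named vector of chromosome lengths; defaults to
#'   the maxima seen in `peaks` and `genes`.
#' @param B number of permutations (default 200; below 100 q-values are
#'   unstable and a warning is given).
#' @param seed optional integer seed for the permutation null.
#' @return data.frame of class `target_scores`: `gene_id`, `distance`,
#'   `score`, `pvalue`, `qvalue`.
#' @export
closest_gene_scores <- function(peaks, genes, chrom_lengths = NULL,
                                B = 200, seed = NULL) {
  assert_granges(peaks, "peaks")
  assert_granges(genes, "genes")
  if (length(peaks) == 0L || length(genes) == 0L)
    stopf("need at least one peak and one gene")
  if (B < 100) warnf("B = %d permutations; q-values may be unstable", B)
  tss <- gene_tss(genes)
  if (is.null(chrom_lengths)) {
    all_chr <- union(as.character(seqnames(peaks)),
                     as.character(seqnames(genes)))
    chrom_lengths <- vapply(all_chr, function(ch)
      max(c(end(peaks)[as.character(seqnames(peaks)) == ch],
            end(genes)[as.character(seqnames(genes)) == ch], 1L)),
      numeric(1))
  }
  tss_chrom <- as.character(seqnames(tss))
  tss_pos <- split(start(tss), tss_chrom)
  summit_chrom <- as.character(seqnames(peaks))
  summit_pos <- split(peak_summits(peaks), summit_chrom)
  n_per_chrom <- lengths(summit_pos)
  dist_all <- function(summits_by_chrom) {
    d <- rep(Inf, length(tss))
    for (ch in names(tss_pos)) {
      idx <- which(tss_chrom == ch)
      d[idx] <- nearest_abs_dist(tss_pos[[ch]],
                                 summits_by_chrom[[ch]])
    }
    d
  }
  d_obs <- dist_all(summit_pos)
  score <- distance_to_score(d_obs)
  run_perm <- function() {
    le <- rep(0, length(tss))
    for (b in seq_len(B)) {
      perm <- lapply(names(n_per_chrom), function(ch)
        floor(runif(n_per_chrom[[ch]], 1, chrom_lengths[[ch]] + 1)))
      names(perm) <- names(n_per_chrom)
      le <- le + (dist_all(perm) <= d_obs)
    }
    le
  }
  le <- if (is.null(seed)) run_perm() else with_seed(seed, run_perm())
  pval <- (1 + le) / (B + 1)
  out <- data.frame(gene_id = tss$gene_id, distance = d_obs,
                    score = score, pvalue = pval,
                    qvalue = bh_adjust(pval),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("target_scores", "data.frame")
  out
}

# For each query position, the absolute distance to the nearest subject
# position (Inf when there are no subjects).
nearest_abs_dist <- function(q, s) {
  if (is.null(s) || length(s) == 0L) return(rep(Inf, length(q)))
  s <- sort(s)
  i <- findInterval(q, s)
  left <- ifelse(i >= 1L, q - s[pmax(i, 1L)], Inf)
  right <- ifelse(i < length(s), s[pmin(i + 1L, length(s))] - q, Inf)
  pmin(left, right)
}

# 1 - mid-rank ECDF of the distances; Inf distances (peak-less
# chromosomes) are forced to score 0.
distance_to_score <- function(d) {
  n <- length(d)
  score <- 1 - rank(d, ties.method = "average") / n
  score[is.infinite(d)] <- 0
  score
}

#' Flat gene-set (GO-style) enrichment of top target genes
#'
#' One-sided hypergeometric test of the overlap between the top-scored
#' genes and each annotation term within the gene universe, BH-adjusted
#' across terms; the 5 most enriched terms are flagged.
#'
#' @param top_genes character vector of selected genes (e.g. the 2000
#'   highest-scoring genes of a sample).
#' @param annotation data.frame with columns `gene` and `term`, or a
#'   named list of term -> gene vectors.
#' @param universe character vector of all genes; must contain
#'   `top_genes`.
#' @param n_flag number of top terms to flag (default 5).
#' @return data.frame `term`, `n_term`, `overlap`, `p`, `padj`,
#'   `top_flag`, sorted by p.
#' @export
gene_set_enrichment <- function(top_genes, annotation, universe,
                                n_flag = 5) {
  if (is.data.frame(annotation)) {
    if (!all(c("gene", "term") %in% names(annotation)))
      stopf("'annotation' needs columns gene and term")
    annotation <- split(annotation$gene, annotation$term)
  }
  if (length(annotation) == 0L) stopf("empty annotation")
  if (!all(top_genes %in% universe))
    stopf("'universe' must contain all top genes")
  N <- length(unique(universe))
  n <- length(unique(top_genes))
  res <- lapply(names(annotation), function(term) {
    tg <- intersect(annotation[[term]], universe)
    K <- length(tg)
    k <- length(intersect(tg, top_genes))
    p <- if (K == 0L) 1 else
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, n_term = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  out$top_flag <- seq_len(nrow(out)) <= n_flag
  rownames(out) <- NULL
  out
}
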