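# Fragment counting, normalization, replicate reproducibility, and the
# genome-wide binding correlation / clustering analysis; plus a window
# Poisson peak caller for control samples.

#' Construct a binding-counts object
#'
#' A light container for a peak x sample matrix of non-negative integer
#' counts with sample metadata, per-sample library sizes, and (after
#' [normalize_matrix()]) normalization factors.
#'
#' @param counts integer matrix, rows = peak ids, columns = sample ids.
#' @param samples data.frame with at least columns `sample`, `condition`,
#'   `replicate`; rows match the count columns.
#' @param library_sizes per-sample totals; default column sums.
#' @param peak_lengths optional per-peak lengths in bp (needed for RPKM).
#' @return object of class `binding_counts`.
#' @export
binding_counts <- function(counts, samples = NULL, library_sizes = NULL,
                           peak_lengths = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(is.na(counts)))
    stopf("'counts' must be non-negative and complete")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("peak", seq_len(nrow(counts)))
  if (is.null(samples))
    samples <- data.frame(sample = colnames(counts),
                          condition = NA_character_,
                          replicate = NA_integer_,
                          stringsAsFactors = FALSE)
  if (nrow(samples) != ncol(counts))
    stopf("'samples' rows (%d) must match count columns (%d)",
          nrow(samples), ncol(counts))
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes < colSums(counts)))
    stopf("'library_sizes' cannot be smaller than in-peak column sums")
  if (any(library_sizes <= 0)) stopf("'library_sizes' must be positive")
  structure(list(counts = counts, samples = samples,
                 library_sizes = setNames(as.numeric(library_sizes),
                                          colnames(counts)),
                 norm_factors = NULL,
                 peak_lengths = peak_lengths),
            class = "binding_counts")
}

#' @export
print.binding_counts <- function(x, ...) {
  cat(sprintf("binding_counts: %d peaks x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("samples:", paste(colnames(x$counts), collapse = ", "), "\n")
  if (!is.null(x$norm_factors))
    cat("normalized (factors:",
        paste(signif(x$norm_factors, 3), collapse = ", "), ")\n")
  invisible(x)
}

#' Write / read a counts TSV (rows = peak ids, columns = sample ids)
#'
#' @param bc a [binding_counts()] object.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(bc, path) {
  df <- data.frame(peak_id = rownames(bc$counts), bc$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param samples optional sample sheet data.frame to attach on read.
#' @export
read_counts <- function(path, samples = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  binding_counts(m, samples = samples)
}

#' Count fragments in peak intervals
#'
#' Each fragment is represented by its 5' position and strand, extended
#' to `fragment_size` bp, and counted for every peak its extension
#' overlaps.  Fragments below the mapping-quality cutoff are excluded
#' before counting.
#'
#' @param fragments named list (one element per sample) of GRanges of 5'
#'   positions (width 1, strand set) with a `mapq` metadata column, or
#'   BED6-style GRanges where `score` holds MAPQ.
#' @param peaks peak GRanges.
#' @param min_mapq minimum mapping quality (default 30).
#' @param fragment_size extension length in bp (default 200).
#' @return a [binding_counts()]; library sizes are the per-sample counts
#'   of MAPQ-passing fragments (in or out of peaks).
#' @export
count_fragments_in_intervals <- function(fragments, peaks, min_mapq = 30,
                                         fragment_size = 200) {
  assert_granges(peaks, "peaks")
  if (!is.list(fragments) || length(fragments) == 0L)
    stopf("'fragments' must be a non-empty named list of GRanges")
  if (is.null(names(fragments)))
    names(fragments) <- paste0("sample", seq_along(fragments))
  peak_chroms <- unique(as.character(seqnames(peaks)))
  counts <- vapply(fragments, function(fr) {
    assert_granges(fr, "fragments[[i]]")
    mapq <- if (!is.null(fr$mapq)) fr$mapq else fr$score
    if (is.null(mapq)) mapq <- rep(Inf, length(fr))
    fr <- fr[mapq >= min_mapq]
    unknown <- !(as.character(seqnames(fr)) %in% peak_chroms)
    if (any(unknown))
      warnf("skipping %d fragment(s) on chromosomes without peaks",
            sum(unknown))
    ext <- suppressWarnings(resize(fr, fragment_size, fix = "start"))
    suppressWarnings(countOverlaps(unstrand(peaks), unstrand(ext)))
  }, integer(length(peaks)))
  counts <- matrix(counts, nrow = length(peaks),
                   dimnames = list(peaks$name, names(fragments)))
  libs <- vapply(fragments, function(fr) {
    mapq <- if (!is.null(fr$mapq)) fr$mapq else fr$score
    if (is.null(mapq)) mapq <- rep(Inf, length(fr))
    sum(mapq >= min_mapq)
  }, numeric(1))
  binding_counts(counts, library_sizes = pmax(libs, colSums(counts)),
                 peak_lengths = width(peaks))
}

#' Normalize a count matrix
#'
#' `library_size` rescales each sample to the mean library size
#' (`count * mean(lib) / lib_j`); `rpkm` converts to reads per kilobase
#' of peak per million library reads.
#'
#' @param bc a [binding_counts()].
#' @param method `"library_size"` or `"rpkm"`.
#' @return a `binding_counts` whose `counts` hold normalized values and
#'   whose `norm_factors` record the per-sample multipliers.
#' @export
normalize_matrix <- function(bc, method = c("library_size", "rpkm")) {
  stopifnot(inherits(bc, "binding_counts"))
  method <- match.arg(method)
  libs <- bc$library_sizes
  if (any(libs <= 0)) stopf("library sizes must be positive")
  if (method == "library_size") {
    f <- mean(libs) / libs
    norm <- sweep(bc$counts, 2, f, "*")
  } else {
    if (is.null(bc$peak_lengths))
      stopf("RPKM normalization requires peak lengths")
    f <- 1 / (libs / 1e6)
    norm <- sweep(bc$counts / (bc$peak_lengths / 1000), 2, f, "*")
  }
  out <- bc
  out$counts <- norm
  out$norm_factors <- setNames(as.numeric(f), colnames(bc$counts))
  out
}

#' Pearson correlation between two replicates
#'
#' Computed on `log10(count + 1)` over the shared peak universe.
#'
#' @param bc a [binding_counts()].
#' @param rep_a,rep_b column names or indices.
#' @return Pearson r.
#' @export
replicate_correlation <- function(bc, rep_a, rep_b) {
  stopifnot(inherits(bc, "binding_counts"))
  if (nrow(bc$counts) < 3L)
    stopf("need at least 3 peaks to compute a correlation")
  a <- log10(bc$counts[, rep_a] + 1)
  b <- log10(bc$counts[, rep_b] + 1)
  cor(a, b)
}

#' Genome-wide binding correlation and clustering
#'
#' Filters a consensus peak set to the regions overlapping any
#' replicate's `top_n` most enriched peaks, builds one
#' `log2(normalized count + 1)` vector per sample by averaging its
#' replicates, computes the pairwise Pearson correlation matrix, and
#' clusters samples hierarchically with `1 - r` distances and average
#' linkage.
#'
#' "Most enriched" ranks peaks by `neg_log10_q` descending, breaking
#' ties by `fold_enrichment` and then by coordinate.
#'
#' @param bc a normalized [binding_counts()] on the consensus peak set
#'   (one column per replicate).
#' @param consensus consensus GRanges, rows of `bc` in the same order.
#' @param replicate_peaks named list of per-replicate peak GRanges
#'   (names matching `bc` columns) used for the top-`n` filter; `NULL`
#'   skips filtering.
#' @param sample_of named character vector mapping replicate (column)
#'   names to sample labels; default maps each column to itself.
#' @param top_n number of most-enriched peaks kept per replicate
#'   (default 3000); replicates with fewer peaks contribute all of them.
#' @param pseudocount added before `log2` (default 1).
#' @return list of class `binding_correlation` with `correlation`
#'   (symmetric matrix, unit diagonal), `hclust`, `newick` and the
#'   filtered `consensus`.
#' @export
binding_correlation_clustering <- function(bc, consensus,
                                           replicate_peaks = NULL,
                                           sample_of = NULL,
                                           top_n = 3000,
                                           pseudocount = 1) {
  stopifnot(inherits(bc, "binding_counts"))
  assert_granges(consensus, "consensus")
  if (length(consensus) != nrow(bc$counts))
    stopf("consensus length must match count rows")
  keep <- rep(TRUE, length(consensus))
  if (!is.null(replicate_peaks)) {
    keep <- rep(FALSE, length(consensus))
    for (rp in replicate_peaks) {
      top <- top_enriched(rp, top_n)
      keep <- keep |
        suppressWarnings(overlapsAny(consensus, unstrand(top)))
    }
  }
  if (!any(keep))
    stopf("no consensus regions left after the top-%d filter", top_n)
  m <- log2(bc$counts[keep, , drop = FALSE] + pseudocount)
  if (is.null(sample_of))
    sample_of <- setNames(colnames(m), colnames(m))
  samples <- unique(unname(sample_of[colnames(m)]))
  prof <- vapply(samples, function(s) {
    cols <- colnames(m)[sample_of[colnames(m)] == s]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(sum(keep)))
  cormat <- cor(prof)
  cormat[is.na(cormat)] <- 0
  diag(cormat) <- 1
  hc <- hclust(as.dist(1 - cormat), method = "average")
  structure(list(correlation = cormat, hclust = hc,
                 newick = hclust_to_newick(hc),
                 consensus = consensus[keep]),
            class = "binding_correlation")
}

# Rank peaks by enrichment: q descending, fold enrichment, coordinate.
top_enriched <- function(peaks, n) {
  q <- if (!is.null(peaks$neg_log10_q)) peaks$neg_log10_q else
    rep(0, length(peaks))
  fe <- if (!is.null(peaks$fold_enrichment)) peaks$fold_enrichment else
    rep(0, length(peaks))
  q[is.na(q)] <- 0
  fe[is.na(fe)] <- 0
  ord <- order(-q, -fe, as.character(seqnames(peaks)), start(peaks))
  peaks[head(ord, n)]
}

hclust_to_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Window-based Poisson peak caller
#'
#' A desk-scale point-source peak caller for control or test samples:
#' the genome is tiled into `window`-bp windows, each window's fragment
#' count is tested against a control-scaled local Poisson rate (upper
#' tail), p-values are BH-adjusted across windows, significant adjacent
#' windows are merged, and each merged peak reports its maximum-coverage
#' summit, fold enrichment and `-log10` q-value.
#'
#' @param sample_frags GRanges of sample fragment 5' positions (width 1,
#'   strand set; optional `mapq`).
#' @param control_frags GRanges of control fragments, or `NULL`; with no
#'   control (or zero control coverage) a global background rate is used
#'   with a warning.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window window size in bp (default 200).
#' @param q_threshold q-value cutoff (default 0.01).
#' @param fragment_size extension length in bp (default 200).
#' @param min_mapq MAPQ cutoff (default 30).
#' @return peak GRanges with `name`, `score`, `fold_enrichment`,
#'   `neg_log10_q` and `summit` columns.
#' @export
call_peaks_window <- function(sample_frags, control_frags = NULL,
                              chrom_lengths, window = 200,
                              q_threshold = 0.01, fragment_size = 200,
                              min_mapq = 30) {
  if (window <= 0) stopf("'window' must be positive")
  prep <- function(fr) {
    mapq <- if (!is.null(fr$mapq)) fr$mapq else rep(Inf, length(fr))
    fr <- fr[mapq >= min_mapq]
    suppressWarnings(resize(fr, fragment_size, fix = "start"))
  }
  sf <- prep(sample_frags)
  tiles <- tile_genome(chrom_lengths, window)
  obs <- countOverlaps(tiles, unstrand(sf))
  n_sample <- length(sf)
  if (!is.null(control_frags)) {
    cf <- prep(control_frags)
    ctl <- countOverlaps(tiles, unstrand(cf))
    n_control <- length(cf)
  } else {
    ctl <- NULL
    n_control <- 0
  }
  if (n_control == 0 || sum(ctl) == 0) {
    if (!is.null(control_frags))
      warnf("zero control coverage; falling back to global background")
    lambda <- rep(max(mean(obs), 1e-9), length(tiles))
  } else {
    scale <- n_sample / n_control
    global <- max(mean(ctl) * scale, 1e-9)
    lambda <- pmax(ctl * scale, global)
  }
  p <- ppois(obs - 1, lambda, lower.tail = FALSE)
  q <- bh_adjust(p)
  sig <- q <= q_threshold & obs > 0
  if (!any(sig)) return(empty_peaks())
  sig_tiles <- tiles[sig]
  sig_tiles$q <- q[sig]
  sig_tiles$fe <- obs[sig] / lambda[sig]
  merged <- reduce(sig_tiles, with.revmap = TRUE)
  cov <- coverage(unstrand(sf))
  res <- lapply(seq_along(merged), function(i) {
    idx <- merged$revmap[[i]]
    chrom <- as.character(seqnames(merged)[i])
    lo <- start(merged)[i]
    hi <- min(end(merged)[i], length(cov[[chrom]]))
    seg <- as.numeric(cov[[chrom]][lo:hi])
    c(summit = which.max(seg) - 1L,
      q = min(sig_tiles$q[idx]),
      fe = max(sig_tiles$fe[idx]))
  })
  res <- do.call(rbind, res)
  out <- granges(merged)
  out$name <- sprintf("window_peak%04d", seq_along(out))
  out$score <- round(pmin(1000, -10 * log10(pmax(res[, "q"], 1e-100))))
  out$fold_enrichment <- res[, "fe"]
  out$neg_log10_q <- -log10(pmax(res[, "q"], 1e-300))
  out$summit <- as.integer(res[, "summit"])
  sort_peaks(out)
}

tile_genome <- function(chrom_lengths, window) {
  grs <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(1L, L, by = window)
    GRanges(ch, IRanges(starts, width = pmin(window, L - starts + 1L)))
  })
  unlist(GRangesList(grs))
}
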