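# Interval procedures: coverage-threshold merging, blacklist
# construction, consensus peak building, genomic-feature annotation and
# peak-set overlap combinations.

#' Merge peak sets by coverage threshold
#'
#' Returns the maximal regions covered by at least `min_sets` of the
#' input peak sets.  Each set's peaks are collapsed first, so one set
#' contributes at most depth 1 at any base.  With `min_sets = 1` this is
#' the plain union of the sets.
#'
#' @param sets a list of peak GRanges.
#' @param min_sets minimum number of distinct sets that must cover a base
#'   for it to be kept.
#' @return a sorted, non-overlapping GRanges.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(41, 100))
#' merge_intervals(list(a, b), min_sets = 2)  # chr1:41-50
#' @export
merge_intervals <- function(sets, min_sets = 1) {
  if (!is.list(sets) || length(sets) == 0L)
    stopf("'sets' must be a non-empty list of GRanges")
  lapply(sets, assert_granges, name = "sets[[i]]")
  min_sets <- assert_count(min_sets, "min_sets", min = 1)
  # depth capped at 1 per set by reducing each set before pooling
  pooled <- unlist(GRangesList(lapply(sets, function(g)
    granges(reduce(unstrand(g))))))
  if (length(pooled) == 0L) return(granges(pooled))
  cov <- coverage(pooled)
  sliced <- slice(cov, lower = min_sets, rangesOnly = TRUE)
  gr <- GRanges(rep(names(sliced), lengths(sliced)),
                unlist(sliced, use.names = FALSE))
  sort_peaks(granges(gr))
}

#' Build a blacklist from control peak sets
#'
#' Regions covered by peaks of at least `min_shared` distinct control
#' sets are flagged as artifact ("blacklist") regions.  Overlapping peaks
#' within one control are collapsed first so a single control can only
#' contribute once at any base.
#'
#' @param control_sets list of control peak GRanges (one per control
#'   sample).
#' @param min_shared minimum number of controls sharing a region
#'   (default 5).
#' @return sorted, non-overlapping blacklist GRanges.
#' @export
build_blacklist <- function(control_sets, min_shared = 5) {
  min_shared <- assert_count(min_shared, "min_shared", min = 1)
  if (!is.list(control_sets) || length(control_sets) < min_shared)
    stopf("need at least min_shared (%d) control sets, got %d",
          min_shared, length(control_sets))
  merge_intervals(control_sets, min_sets = min_shared)
}

#' Remove peaks overlapping a blacklist
#'
#' Whole-peak removal: any peak with at least 1 bp of overlap with any
#' blacklist region is dropped (peaks are never trimmed).  Idempotent.
#'
#' @param peaks peak GRanges.
#' @param blacklist blacklist GRanges (may be empty).
#' @return the retained peaks.
#' @export
subtract_blacklist <- function(peaks, blacklist) {
  assert_granges(peaks, "peaks")
  assert_granges(blacklist, "blacklist")
  if (length(blacklist) == 0L) return(peaks)
  peaks[!overlapsAny(unstrand(peaks), unstrand(blacklist))]
}

#' Build a summit-centered consensus peak set
#'
#' Peaks present (>= 1 bp overlap) in at least `min_overlap` of the input
#' sets are re-centered on their summit and expanded by `summit_pad`
#' bases up- and downstream (width exactly `2 * summit_pad`); overlapping
#' consensus intervals are then merged.  Peaks without a summit offset
#' fall back to the interval midpoint.
#'
#' @param peak_sets list of peak GRanges.
#' @param min_overlap minimum number of sets a region must appear in
#'   (default 2).
#' @param summit_pad half-width of a consensus interval in bp
#'   (default 100).
#' @return sorted, non-overlapping consensus GRanges.
#' @export
consensus_peaks <- function(peak_sets, min_overlap = 2, summit_pad = 100) {
  if (!is.list(peak_sets) || length(peak_sets) == 0L)
    stopf("'peak_sets' must be a non-empty list of GRanges")
  if (!is.numeric(summit_pad) || summit_pad <= 0)
    stopf("'summit_pad' must be positive")
  min_overlap <- assert_count(min_overlap, "min_overlap", min = 1)
  supported <- merge_intervals(peak_sets, min_sets = min_overlap)
  pooled <- unlist(GRangesList(lapply(peak_sets, function(g) {
    g <- unstrand(g)
    s <- peak_summits(g)
    gr <- granges(g)
    gr$summit_pos <- s
    gr
  })))
  keep <- overlapsAny(pooled, supported)
  pooled <- pooled[keep]
  if (length(pooled) == 0L) return(granges(GRanges()))
  centered <- GRanges(seqnames(pooled),
                      IRanges(start = pooled$summit_pos - summit_pad + 1L,
                              width = 2L * summit_pad))
  start(centered) <- pmax(start(centered), 1L)
  sort_peaks(granges(reduce(centered)))
}

# Absolute summit positions (1-based); midpoint fallback when the summit
# offset is absent.
peak_summits <- function(peaks) {
  mid <- as.integer(floor((start(peaks) + end(peaks)) / 2))
  if (is.null(peaks$summit)) return(mid)
  off <- peaks$summit
  ifelse(is.na(off), mid, start(peaks) + as.integer(off))
}

#' Annotate peaks by genomic location
#'
#' Assigns each peak to a feature category by its summit position, with
#' precedence promoter > genic > intergenic.  Promoters are the regions
#' within `promoter_halfwidth` bp of a TSS (default +/- 1 kb).  Peaks on
#' chromosomes absent from the gene annotation are labelled
#' `"unplaced"` with a warning.
#'
#' @param peaks peak GRanges.
#' @param genes gene-model GRanges with strand (see
#'   [read_gene_models()]).
#' @param promoter_halfwidth promoter half-width in bp around the TSS.
#' @return factor of categories, one per peak, levels
#'   `c("promoter", "genic", "intergenic", "unplaced")`.
#' @export
annotate_genomic_location <- function(peaks, genes,
                                      promoter_halfwidth = 1000) {
  assert_granges(peaks, "peaks")
  assert_granges(genes, "genes")
  promoter_halfwidth <- assert_count(promoter_halfwidth,
                                     "promoter_halfwidth", min = 1)
  pos <- GRanges(seqnames(peaks), IRanges(peak_summits(peaks), width = 1L))
  tss <- gene_tss(genes)
  prom <- suppressWarnings(trim(resize(tss, width = 2L * promoter_halfwidth + 1L,
                                       fix = "center")))
  cat <- rep("intergenic", length(peaks))
  known <- as.character(seqnames(pos)) %in%
    unique(as.character(seqnames(genes)))
  if (any(!known)) {
    warnf("%d peak(s) on chromosomes absent from the gene annotation",
          sum(!known))
    cat[!known] <- "unplaced"
  }
  in_gene <- overlapsAny(unstrand(pos), unstrand(genes))
  in_prom <- overlapsAny(unstrand(pos), unstrand(prom))
  cat[known & in_gene] <- "genic"
  cat[known & in_prom] <- "promoter"
  factor(cat, levels = c("promoter", "genic", "intergenic", "unplaced"))
}

#' Peak overlap combinations across groups
#'
#' On the merged universe of all groups' peaks, assigns each merged
#' region the subset of groups with at least 1 bp of overlap, and counts
#' regions per combination (the numbers behind an UpSet plot).  The
#' combination counts sum to the size of the merged universe.
#'
#' @param groups named list of peak GRanges, one per group label.
#' @return data.frame with columns `combination` (labels joined by
#'   `"+"` in input order) and `count`.
#' @export
overlap_combinations <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("'groups' must be a named list of >= 2 peak sets")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stopf("'groups' must be named")
  universe <- merge_intervals(groups, min_sets = 1)
  member <- vapply(groups, function(g)
    overlapsAny(universe, unstrand(g)), logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(groups)))
  combo <- apply(member, 1L, function(m)
    paste(names(groups)[m], collapse = "+"))
  tab <- table(combo)
  out <- data.frame(combination = names(tab),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$combination), , drop = FALSE]
}
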