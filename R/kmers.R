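# k-mer motif categories: the built-in category table, sequence
# scanning with half-site exclusion rules, per-peak presence calls,
# combination counts, Fisher enrichment between peak classes, and a
# light k-mer discovery against a dinucleotide-shuffled background.

revcomp_string <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}

#' The built-in k-mer motif-category table
#'
#' Categories, in order: the CRE-like element `TGACGTCA`; the TRE-like
#' element `TGACTCA`; the four ACGTG elements (`AACGTG`, `CACGTG`,
#' `GACGTG`, `TACGTG`, varying at the position before the ACGT); the
#' `TGAC` half-site, excluded when it lies inside a CRE-like match; the
#' `TGAG` half-site, excluded when it lies inside a TRE-like match; and
#' `TGAT`.
#'
#' @param exclusion_hierarchy `"literal"` (default) excludes the TGAC
#'   half-site from CRE-like contexts only; `"extended"` additionally
#'   masks TGAC half-sites inside TRE-like matches.
#' @return list of class `kmer_categories` with parallel fields `label`,
#'   `kmers` (list of k-mer vectors) and `excludes` (list of parent
#'   category labels).
#' @export
kmer_categories <- function(exclusion_hierarchy = c("literal",
                                                    "extended")) {
  exclusion_hierarchy <- match.arg(exclusion_hierarchy)
  tgac_parents <- if (exclusion_hierarchy == "extended")
    c("CRE_like", "TRE_like") else "CRE_like"
  structure(list(
    label = c("CRE_like", "TRE_like", "AACGTG", "CACGTG", "GACGTG",
              "TACGTG", "TGAC_half", "TGAG_half", "TGAT"),
    kmers = list("TGACGTCA", "TGACTCA", "AACGTG", "CACGTG", "GACGTG",
                 "TACGTG", "TGAC", "TGAG", "TGAT"),
    excludes = list(character(0), character(0), character(0),
                    character(0), character(0), character(0),
                    tgac_parents, "TRE_like", character(0))),
    class = "kmer_categories")
}

#' Read a category table from TSV
#'
#' Columns: `label`, `kmer`, `excludes` (comma-separated parent labels,
#' may be empty).  Multiple rows with the same label pool their k-mers.
#'
#' @param path TSV file.
#' @return a `kmer_categories` object.
#' @export
read_kmer_categories <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, fill = TRUE)
  if (!all(c("label", "kmer") %in% names(df)))
    stopf("category TSV needs columns 'label' and 'kmer'")
  labels <- unique(df$label)
  kmers <- lapply(labels, function(l) toupper(df$kmer[df$label == l]))
  excl <- lapply(labels, function(l) {
    e <- df$excludes[df$label == l]
    e <- e[!is.na(e) & nzchar(e)]
    unique(unlist(strsplit(e, ",", fixed = TRUE)))
  })
  bad <- unlist(kmers)[grepl("[^ACGT]", unlist(kmers))]
  if (length(bad)) stopf("k-mers must be over ACGT: %s", bad[1])
  structure(list(label = labels, kmers = kmers, excludes = excl),
            class = "kmer_categories")
}

#' Scan sequences for motif-category matches
#'
#' A category is present in a sequence when any of its k-mers (or, with
#' `both_strands`, a k-mer's reverse complement) occurs, except that a
#' match of a category with exclusion parents is suppressed when its
#' footprint lies entirely within a same-strand match of a parent
#' category (e.g. TGAC inside TGACGTCA does not count as a half-site).
#' Presence is binary per category per sequence; `N` bases never match.
#'
#' @param seqs character vector or [Biostrings::DNAStringSet] over
#'   `A,C,G,T,N`.
#' @param categories a [kmer_categories()] table.
#' @param both_strands scan the reverse complement too (default `TRUE`).
#' @return list with `presence` (logical matrix, sequences x categories)
#'   and `matches` (data.frame of retained matches: `seq`, `category`,
#'   `kmer`, `start`, `end`, `strand`).
#' @export
scan_sequence_categories <- function(seqs, categories = kmer_categories(),
                                     both_strands = TRUE) {
  stopifnot(inherits(categories, "kmer_categories"))
  if (is.character(seqs)) {
    if (any(grepl("[^ACGTN]", toupper(seqs))))
      stopf("sequences may only contain A, C, G, T, N")
    seqs <- DNAStringSet(toupper(seqs))
  }
  n <- length(seqs)
  labs <- categories$label
  hits <- vector("list", length(labs))
  names(hits) <- labs
  for (ci in seq_along(labs)) {
    rows <- list()
    for (kmer in categories$kmers[[ci]]) {
      pats <- list(c(kmer, "+"))
      if (both_strands) {
        rc <- revcomp_string(kmer)
        # a palindrome on the minus strand is the same footprint
        if (rc != kmer) pats <- c(pats, list(c(rc, "-")))
        else pats <- c(pats, list(c(rc, "-")))
      }
      for (p in pats) {
        mi <- vmatchPattern(p[1], seqs, fixed = TRUE)
        cnt <- elementNROWS(mi)
        if (sum(cnt) == 0L) next
        ir <- unlist(mi, use.names = FALSE)
        rows[[length(rows) + 1L]] <-
          data.frame(seq = rep(seq_len(n), cnt), kmer = kmer,
                     start = start(ir), end = end(ir), strand = p[2],
                     stringsAsFactors = FALSE)
      }
    }
    hits[[ci]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(seq = integer(0), kmer = character(0),
                 start = integer(0), end = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
  }
  # exclusion: drop matches fully inside a same-strand parent match
  for (ci in seq_along(labs)) {
    parents <- categories$excludes[[ci]]
    h <- hits[[ci]]
    if (length(parents) == 0L || nrow(h) == 0L) next
    pm <- do.call(rbind, hits[match(parents, labs)])
    if (is.null(pm) || nrow(pm) == 0L) next
    child <- GRanges(paste0(h$seq, h$strand), IRanges(h$start, h$end))
    parent <- GRanges(paste0(pm$seq, pm$strand),
                      IRanges(pm$start, pm$end))
    suppressWarnings({
      inside <- overlapsAny(child, parent, type = "within")
    })
    hits[[ci]] <- h[!inside, , drop = FALSE]
  }
  presence <- vapply(hits, function(h)
    seq_len(n) %in% h$seq, logical(n))
  presence <- matrix(presence, nrow = n,
                     dimnames = list(names(seqs), labs))
  matches <- do.call(rbind, lapply(seq_along(labs), function(ci) {
    h <- hits[[ci]]
    if (nrow(h) == 0L) return(NULL)
    cbind(data.frame(category = labs[ci], stringsAsFactors = FALSE), h)
  }))
  if (is.null(matches))
    matches <- data.frame(category = character(0), seq = integer(0),
                          kmer = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          stringsAsFactors = FALSE)
  list(presence = presence, matches = matches)
}

#' Per-peak motif-category presence matrix
#'
#' Scans the `window`-bp region centered on each peak midpoint (clipped
#' at chromosome ends) and records binary presence per category;
#' multiple matches of a category in one peak count once.
#'
#' @param peaks peak GRanges; an optional `class` metadata column (e.g.
#'   from [test_differential()]) is carried through.
#' @param genome named character vector or
#'   [Biostrings::DNAStringSet] of chromosome sequences.
#' @param categories a [kmer_categories()] table.
#' @param window scan window width in bp (default 150).
#' @param both_strands scan both strands (default `TRUE`).
#' @return list of class `motif_match_table`: `presence` (binary matrix
#'   peaks x categories), `peak_class` (character), `peak_id`.
#' @export
peak_category_matrix <- function(peaks, genome,
                                 categories = kmer_categories(),
                                 window = 150, both_strands = TRUE) {
  assert_granges(peaks, "peaks")
  if (is.character(genome)) genome <- DNAStringSet(genome)
  miss <- setdiff(unique(as.character(seqnames(peaks))), names(genome))
  if (length(miss))
    stopf("peak chromosome(s) missing from genome: %s",
          paste(miss, collapse = ", "))
  half <- window %/% 2L
  mid <- (start(peaks) + end(peaks)) %/% 2L
  lo <- pmax(1L, mid - half + 1L)
  hi <- pmin(nchar(genome)[match(as.character(seqnames(peaks)),
                                 names(genome))], mid + half)
  seqs <- subseq(genome[as.character(seqnames(peaks))], lo, hi)
  scan <- scan_sequence_categories(seqs, categories, both_strands)
  ids <- if (!is.null(peaks$name)) peaks$name else
    paste0("peak_", seq_along(peaks))
  rownames(scan$presence) <- ids
  structure(list(presence = scan$presence * 1L,
                 peak_class = if (!is.null(peaks$class)) peaks$class else
                   rep(NA_character_, length(peaks)),
                 peak_id = ids),
            class = "motif_match_table")
}

#' Count peaks per category combination
#'
#' Maps each peak to the exact set of categories present in it and
#' counts peaks per distinct combination, split by peak class (the
#' numbers behind an UpSet-style plot of motif co-occurrence).
#'
#' @param mmt a [peak_category_matrix()] result.
#' @return data.frame with `combination` (`"none"` for the empty set)
#'   and one count column per peak class.
#' @export
combination_counts <- function(mmt) {
  stopifnot(inherits(mmt, "motif_match_table"))
  pres <- mmt$presence
  if (nrow(pres) == 0L) stopf("empty match table")
  labs <- colnames(pres)
  combo <- apply(pres, 1L, function(r)
    if (!any(r == 1)) "none" else paste(labs[r == 1], collapse = "+"))
  cls <- mmt$peak_class
  cls[is.na(cls)] <- "all"
  tab <- table(combo, cls)
  out <- data.frame(combination = rownames(tab),
                    stringsAsFactors = FALSE)
  for (cl in colnames(tab)) out[[cl]] <- as.integer(tab[, cl])
  tot <- rowSums(out[, -1, drop = FALSE])
  out[order(-tot, out$combination), , drop = FALSE]
}

#' Category enrichment between heterodimer- and homodimer-specific peaks
#'
#' For every category, builds the 2x2 table of peak class
#' (heterodimer-specific vs homodimer-specific) by category presence and
#' computes one-tailed Fisher exact p-values in each direction
#' (heterodimer-enriched and homodimer-enriched), BH-adjusted across
#' categories within each direction.  The log2 odds ratio uses a
#' Haldane continuity correction (+0.5 to every cell) when any cell is
#' zero.
#'
#' @param mmt a [peak_category_matrix()] result whose `peak_class`
#'   contains `"heterodimer_specific"` and `"homodimer_specific"`.
#' @param alpha significance threshold recorded in the output
#'   (default 0.05).
#' @return data.frame with per-category counts, `log2_odds_ratio`,
#'   `p_hetero`, `padj_hetero`, `p_homo`, `padj_homo`, and
#'   `direction` (`"hetero"`, `"homo"` or `"none"` at `alpha`).
#' @export
category_enrichment <- function(mmt, alpha = 0.05) {
  stopifnot(inherits(mmt, "motif_match_table"))
  cls <- mmt$peak_class
  is_h <- cls == "heterodimer_specific"
  is_o <- cls == "homodimer_specific"
  if (!any(is_h) || !any(is_o))
    stopf("both heterodimer_specific and homodimer_specific peaks are required")
  pres <- mmt$presence
  res <- lapply(colnames(pres), function(cat) {
    hw <- sum(pres[is_h, cat] == 1)
    ho <- sum(is_h) - hw
    ow <- sum(pres[is_o, cat] == 1)
    oo <- sum(is_o) - ow
    p_het <- fisher_one_tailed(hw, ho, ow, oo)
    p_hom <- fisher_one_tailed(ow, oo, hw, ho)
    cells <- c(hw, ho, ow, oo)
    if (any(cells == 0)) cells <- cells + 0.5
    l2or <- log2((cells[1] * cells[4]) / (cells[2] * cells[3]))
    data.frame(category = cat, hetero_with = hw, hetero_without = ho,
               homo_with = ow, homo_without = oo,
               log2_odds_ratio = l2or, p_hetero = p_het, p_homo = p_hom,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj_hetero <- bh_adjust(out$p_hetero)
  out$padj_homo <- bh_adjust(out$p_homo)
  out$direction <- ifelse(out$padj_hetero < alpha, "hetero",
                          ifelse(out$padj_homo < alpha, "homo", "none"))
  out
}

#' One-tailed Fisher exact p-value for a 2x2 table
#'
#' Tests whether the first row's success proportion exceeds the
#' second's (`alternative = "greater"` on the table
#' `rbind(c(a, b), c(c, d))`).  This is the primitive behind
#' [category_enrichment()].
#'
#' @param a,b first-row cells (with / without).
#' @param c_,d second-row cells (with / without).
#' @return the one-tailed p-value.
#' @export
fisher_one_tailed <- function(a, b, c_, d) {
  stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                     alternative = "greater")$p.value
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Eulerian-path shuffle: the returned sequence has
#' exactly the same dinucleotide counts (and hence mononucleotide
#' counts, first and last base) as the input.
#'
#' @param seq a single character string.
#' @return shuffled string.
#' @export
dinucleotide_shuffle <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  L <- length(s)
  if (L < 3L) return(seq)
  verts <- unique(s)
  last <- s[L]
  # multiset of outgoing edges per vertex
  edges <- split(s[-1], s[-L])
  repeat {
    # pick a random terminal ("last exit") edge for every vertex except
    # the walk's final vertex, and keep only choices whose last-edge
    # graph reaches the final vertex from everywhere (Altschul-Erickson)
    lastedge <- list()
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.null(edges[[v]])) next
      lastedge[[v]] <- sample(edges[[v]], 1)
    }
    reach <- function(v) {
      seen <- character(0)
      while (v != last) {
        if (v %in% seen || is.null(lastedge[[v]])) return(FALSE)
        seen <- c(seen, v)
        v <- lastedge[[v]]
      }
      TRUE
    }
    for (v in names(lastedge)) if (!reach(v)) { ok <- FALSE; break }
    if (ok) break
  }
  ordered <- list()
  for (v in verts) {
    e <- edges[[v]]
    if (is.null(e)) next
    if (!is.null(lastedge[[v]])) {
      # remove one instance of the terminal edge, shuffle, re-append
      i <- match(lastedge[[v]], e)
      rest <- e[-i]
      ordered[[v]] <- c(if (length(rest)) sample(rest, length(rest)),
                        lastedge[[v]])
    } else {
      ordered[[v]] <- if (length(e) > 1) sample(e, length(e)) else e
    }
  }
  ptr <- setNames(rep(1L, length(ordered)), names(ordered))
  out <- character(L)
  out[1] <- s[1]
  v <- s[1]
  for (i in 2:L) {
    nxt <- ordered[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[i] <- nxt
    v <- nxt
  }
  paste(out, collapse = "")
}

#' Light k-mer discovery against a dinucleotide-shuffled background
#'
#' For every k-mer (strand-collapsed to its lexicographically smaller
#' form) occurring in the positive sequences, tests sequence-level
#' presence in positives vs a background of per-sequence dinucleotide
#' shuffles with a one-sided hypergeometric p-value, and ranks k-mers by
#' p with BH adjustment.
#'
#' @param positives character vector or DNAStringSet (>= 50 sequences
#'   recommended).
#' @param k_min,k_max k-mer length range (defaults 5 and 14).
#' @param n_background_shuffles shuffles per positive sequence
#'   (default 1).
#' @return data.frame `kmer`, `k`, `n_pos`, `n_bg`, `p`, `padj`, sorted
#'   by p ascending.
#' @export
ksm_lite_discover <- function(positives, k_min = 5, k_max = 14,
                              n_background_shuffles = 1) {
  if (!is.character(positives)) positives <- as.character(positives)
  positives <- toupper(positives)
  short <- nchar(positives) < k_min
  if (any(short)) {
    warnf("skipping %d sequence(s) shorter than k_min", sum(short))
    positives <- positives[!short]
  }
  if (length(positives) == 0L) stopf("no usable positive sequences")
  background <- unlist(lapply(seq_len(n_background_shuffles), function(i)
    vapply(positives, dinucleotide_shuffle, character(1),
           USE.NAMES = FALSE)))
  n_pos <- length(positives)
  n_bg <- length(background)
  seq_kmer_set <- function(s, k) {
    L <- nchar(s)
    if (L < k) return(character(0))
    km <- substring(s, 1:(L - k + 1), k:L)
    km <- km[!grepl("N", km, fixed = TRUE)]
    rc <- revcomp_string(km)
    unique(pmin(km, rc))
  }
  rows <- list()
  for (k in seq(k_min, k_max)) {
    pos_sets <- lapply(positives, seq_kmer_set, k = k)
    bg_sets <- lapply(background, seq_kmer_set, k = k)
    pos_tab <- table(unlist(pos_sets))
    bg_tab <- table(unlist(bg_sets))
    kmers <- names(pos_tab)
    a <- as.integer(pos_tab)
    b <- as.integer(bg_tab[kmers])
    b[is.na(b)] <- 0L
    # one-sided hypergeometric: presence in positives among all
    # sequences carrying the k-mer
    p <- phyper(a - 1L, a + b, n_pos + n_bg - a - b, n_pos,
                lower.tail = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(kmer = kmers, k = k, n_pos = a, n_bg = b, p = p,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out <- out[order(out$p, -out$n_pos, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}
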