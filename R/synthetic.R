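# Seeded synthetic-data generator.
#
# Produces a small genome, gene models, homodimer/heterodimer peak sets
# with planted motif-category k-mers, negative-binomial replicate count
# matrices, control samples carrying shared artifact regions, and a
# DEG-like gene set enriched for true target genes.  Every quantity is
# recorded in a ground-truth ledger so downstream stages can be checked
# against what was planted.

#' Configuration for the synthetic-data generator
#'
#' All downstream defaults describe a small Arabidopsis-like study: two
#' dimer conditions (heterodimer vs homodimer) with replicated
#' negative-binomial peak counts, condition-dependent motif-category
#' planting, and a set of negative-control samples sharing artifact
#' regions.
#'
#' @param seed integer seed; identical seed and configuration give
#'   byte-identical outputs.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param gc_content background GC fraction in (0, 1); default 0.36,
#'   Arabidopsis-like.
#' @param n_genes number of genes.
#' @param n_peaks_shared,n_peaks_hetero_specific,n_peaks_homo_specific
#'   peak counts per condition class.
#' @param peak_width peak width in bp.
#' @param category_rates named list with elements `hetero`, `homo` and
#'   `shared`, each a named numeric vector of planting probabilities per
#'   motif-category label (see [kmer_categories()]).  Rates apply to the
#'   150 bp window around the peak midpoint.
#' @param nb_mean expected fragment count of a bound peak.
#' @param nb_dispersion negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param fold_change true bound/unbound mean ratio for condition-specific
#'   peaks (>= 1).
#' @param n_replicates replicates per condition.
#' @param n_controls number of negative-control samples.
#' @param n_artifact_regions number of shared artifact regions planted in
#'   the controls.
#' @param n_noise_peaks private noise peaks per control sample.
#' @param frac_peaks_near_tss fraction of peaks anchored near a gene TSS;
#'   those genes are the true targets.
#' @param deg_target_fraction fraction of true-target genes placed in the
#'   DEG-like gene set.
#' @param deg_n_random number of random non-target genes added to the DEG
#'   set; `NULL` (default) matches the number of included targets.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_chroms = 2,
                             chrom_length = 500000,
                             gc_content = 0.36,
                             n_genes = 600,
                             n_peaks_shared = 300,
                             n_peaks_hetero_specific = 150,
                             n_peaks_homo_specific = 150,
                             peak_width = 400,
                             category_rates = NULL,
                             nb_mean = 100,
                             nb_dispersion = 0.1,
                             fold_change = 4,
                             n_replicates = 2,
                             n_controls = 6,
                             n_artifact_regions = 5,
                             n_noise_peaks = 20,
                             frac_peaks_near_tss = 0.3,
                             deg_target_fraction = 0.8,
                             deg_n_random = NULL) {
  if (is.null(category_rates)) {
    # heterodimers prefer the GCN4-like elements, homodimers the classic
    # ACGTG elements (the "type II" pattern)
    category_rates <- list(
      hetero = c(TRE_like = 0.6, TGAC_half = 0.6),
      homo = c(CACGTG = 0.6, GACGTG = 0.3),
      shared = c(CACGTG = 0.3, TGAC_half = 0.3))
  }
  cfg <- list(seed = assert_count(seed, "seed", min = 0),
              n_chroms = assert_count(n_chroms, "n_chroms", min = 1),
              chrom_length = assert_count(chrom_length, "chrom_length",
                                          min = 1000),
              gc_content = gc_content,
              n_genes = assert_count(n_genes, "n_genes", min = 1),
              n_peaks_shared = assert_count(n_peaks_shared,
                                            "n_peaks_shared"),
              n_peaks_hetero_specific =
                assert_count(n_peaks_hetero_specific,
                             "n_peaks_hetero_specific"),
              n_peaks_homo_specific =
                assert_count(n_peaks_homo_specific,
                             "n_peaks_homo_specific"),
              peak_width = assert_count(peak_width, "peak_width",
                                        min = 50),
              category_rates = category_rates,
              nb_mean = assert_positive(nb_mean, "nb_mean"),
              nb_dispersion = assert_positive(nb_dispersion,
                                              "nb_dispersion"),
              fold_change = fold_change,
              n_replicates = assert_count(n_replicates, "n_replicates",
                                          min = 1),
              n_controls = assert_count(n_controls, "n_controls"),
              n_artifact_regions = assert_count(n_artifact_regions,
                                                "n_artifact_regions"),
              n_noise_peaks = assert_count(n_noise_peaks,
                                           "n_noise_peaks"),
              frac_peaks_near_tss = assert_fraction(frac_peaks_near_tss,
                                                    "frac_peaks_near_tss"),
              deg_target_fraction = assert_fraction(deg_target_fraction,
                                                    "deg_target_fraction"),
              deg_n_random = deg_n_random)
  if (!is.numeric(gc_content) || gc_content <= 0 || gc_content > 1)
    stopf("'gc_content' must be in (0, 1]")
  if (!is.numeric(fold_change) || fold_change < 1)
    stopf("'fold_change' must be >= 1")
  if (!is.list(category_rates) ||
      !all(c("hetero", "homo", "shared") %in% names(category_rates)))
    stopf("'category_rates' must be a list with hetero, homo, shared")
  for (cls in names(category_rates)) {
    r <- category_rates[[cls]]
    if (length(r) && (any(r < 0) || any(r > 1)))
      stopf("'category_rates$%s' must lie in [0, 1]", cls)
  }
  if (!is.null(deg_n_random))
    assert_count(deg_n_random, "deg_n_random")
  structure(cfg, class = "synthetic_config")
}

#' Simulate a background genome and gene models
#'
#' Bases are drawn i.i.d. at the configured GC content; genes receive
#' non-overlapping bodies and random strands.
#'
#' @param config a [synthetic_config()].
#' @return list with `genome` (named character vector of chromosome
#'   sequences) and `genes` (GRanges with `gene_id`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$chrom_length < 10 * config$peak_width)
    stopf("'chrom_length' must be >= 10 * peak_width")
  with_seed(child_seed(config$seed, 1), {
    gc <- config$gc_content
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    genome <- vapply(seq_len(config$n_chroms), function(i) {
      paste(sample(names(probs), config$chrom_length, replace = TRUE,
                   prob = probs), collapse = "")
    }, character(1))
    names(genome) <- paste0("chr", seq_len(config$n_chroms))
    genes <- place_genes(config)
    list(genome = genome, genes = genes)
  })
}

# Non-overlapping gene placement by stick-breaking the free space on
# each chromosome between consecutive gene bodies.
place_genes <- function(config) {
  per_chrom <- table(factor(sample(config$n_chroms, config$n_genes,
                                   replace = TRUE),
                            levels = seq_len(config$n_chroms)))
  out <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chroms)) {
    n <- as.integer(per_chrom[ci])
    if (n == 0L) next
    lens <- sample(500:2000, n, replace = TRUE)
    free <- config$chrom_length - sum(lens)
    if (free < n)
      stopf("chromosome %d too short for %d genes", ci, n)
    cuts <- sort(runif(n, 0, free))
    gaps <- diff(c(0, cuts))
    starts <- cumsum(gaps + c(0, lens[-n])) + 1
    starts <- floor(starts)
    gr <- GRanges(paste0("chr", ci),
                  IRanges(starts, width = lens),
                  strand = sample(c("+", "-"), n, replace = TRUE))
    gr$gene_id <- sprintf("gene%04d", gi + seq_len(n))
    gi <- gi + n
    out[[ci]] <- gr
  }
  sort_peaks(unlist(GRangesList(out[!vapply(out, is.null, logical(1))])))
}

#' Plant peaks and motif-category k-mers into a genome
#'
#' Lays out non-overlapping peaks of the three condition classes
#' (shared, heterodimer-specific, homodimer-specific), anchors a fraction
#' near gene TSSs (those genes become the true targets), and writes
#' category k-mers into the 150 bp window around each peak midpoint at
#' the class-dependent rates of the configuration.  Planted k-mers never
#' overlap one another, and a planted half-site is re-drawn if its
#' context would accidentally complete its exclusion-parent element.
#'
#' @param sim output of [simulate_genome()].
#' @param config the same [synthetic_config()].
#' @param categories a [kmer_categories()] table.
#' @return list with `genome` (mutated sequences), `truth` (a
#'   `synthetic_truth` list: `peaks` GRanges with `class`, `mean_hetero`,
#'   `mean_homo`, `target_gene`; `plantings` data.frame; `true_targets`
#'   character vector).
#' @export
plant_peaks_and_motifs <- function(sim, config,
                                   categories = kmer_categories()) {
  stopifnot(inherits(config, "synthetic_config"))
  genome <- sim$genome
  genes <- sim$genes
  with_seed(child_seed(config$seed, 2), {
    classes <- c(rep("shared", config$n_peaks_shared),
                 rep("hetero_specific", config$n_peaks_hetero_specific),
                 rep("homo_specific", config$n_peaks_homo_specific))
    n_peaks <- length(classes)
    if (n_peaks == 0L) stopf("no peaks requested")
    classes <- sample(classes)
    w <- config$peak_width
    capacity <- sum(nchar(genome)) %/% (2L * w)
    if (n_peaks > capacity)
      stopf("cannot place %d non-overlapping peaks; achievable maximum is about %d",
            n_peaks, capacity)
    tss <- gene_tss(genes)
    tss_chrom <- as.character(seqnames(tss))
    unused_genes <- sample(length(tss))
    occ_start <- lapply(genome, function(s) numeric(0))
    occ_end <- lapply(genome, function(s) numeric(0))
    chrom_len <- nchar(genome)
    p_chrom <- character(n_peaks)
    p_start <- integer(n_peaks)
    target_gene <- rep(NA_character_, n_peaks)
    for (i in seq_len(n_peaks)) {
      anchored <- runif(1) < config$frac_peaks_near_tss &&
        length(unused_genes) > 0L
      ok <- FALSE
      for (try in seq_len(200L)) {
        if (anchored) {
          gidx <- unused_genes[1]
          chrom <- tss_chrom[gidx]
          mid <- start(tss)[gidx] + round(runif(1, -300, 300))
        } else {
          chrom <- names(genome)[sample.int(length(genome), 1)]
          mid <- round(runif(1, w, chrom_len[[chrom]] - w))
        }
        s <- as.integer(mid - w %/% 2)
        e <- s + w - 1L
        if (s < 1L || e > chrom_len[[chrom]]) next
        if (!any(occ_start[[chrom]] <= e & occ_end[[chrom]] >= s)) {
          occ_start[[chrom]] <- c(occ_start[[chrom]], s)
          occ_end[[chrom]] <- c(occ_end[[chrom]], e)
          p_chrom[i] <- chrom
          p_start[i] <- s
          if (anchored) {
            target_gene[i] <- tss$gene_id[gidx]
            unused_genes <- unused_genes[-1]
          }
          ok <- TRUE
          break
        }
        anchored <- FALSE  # fall back to free placement on collision
      }
      if (!ok)
        stopf("could not place peak %d of %d without overlap; reduce peak counts or widths",
              i, n_peaks)
    }
    peaks <- GRanges(p_chrom, IRanges(p_start, width = w))
    peaks$name <- sprintf("peak%05d", seq_len(n_peaks))
    peaks$score <- 0
    peaks$class <- classes
    peaks$target_gene <- target_gene
    peaks$mean_hetero <- ifelse(classes == "homo_specific",
                                config$nb_mean / config$fold_change,
                                config$nb_mean)
    peaks$mean_homo <- ifelse(classes == "hetero_specific",
                              config$nb_mean / config$fold_change,
                              config$nb_mean)
    peaks$summit <- as.integer(w %/% 2)
    peaks$fold_enrichment <- NA_real_
    peaks$neg_log10_q <- NA_real_

    planted <- plant_category_kmers(genome, peaks, config, categories)
    truth <- structure(list(peaks = sort_peaks(peaks),
                            plantings = planted$ledger,
                            true_targets =
                              sort(unique(stats::na.omit(target_gene))),
                            config = config),
                       class = "synthetic_truth")
    list(genome = planted$genome, truth = truth)
  })
}

# Write category k-mers into the 150 bp window around each peak
# midpoint.  Planted k-mers never overlap; a k-mer with an exclusion
# parent is re-drawn if the flanking sequence would embed it in a parent
# match on either strand.
plant_category_kmers <- function(genome, peaks, config, categories) {
  chars <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  rates_by_class <- list(shared = config$category_rates$shared,
                         hetero_specific = config$category_rates$hetero,
                         homo_specific = config$category_rates$homo)
  half <- 75L
  led_peak <- character(0); led_cat <- character(0)
  led_kmer <- character(0); led_chrom <- character(0)
  led_start <- integer(0)
  chrom_len <- nchar(genome)
  peak_chrom <- as.character(seqnames(peaks))
  for (i in seq_along(peaks)) {
    rates <- rates_by_class[[peaks$class[i]]]
    if (is.null(rates) || length(rates) == 0L) next
    chrom <- peak_chrom[i]
    mid <- (start(peaks)[i] + end(peaks)[i]) %/% 2L
    win_lo <- max(1L, mid - half)
    win_hi <- min(chrom_len[[chrom]], mid + half)
    used_s <- integer(0); used_e <- integer(0)
    for (cat in names(rates)) {
      if (runif(1) >= rates[[cat]]) next
      idx <- match(cat, categories$label)
      if (is.na(idx)) stopf("unknown category '%s' in category_rates", cat)
      kmer <- sample(categories$kmers[[idx]], 1)
      if (runif(1) < 0.5) kmer <- revcomp_string(kmer)
      k <- nchar(kmer)
      kchars <- strsplit(kmer, "", fixed = TRUE)[[1]]
      parents <- categories$excludes[[idx]]
      parent_kmers <- unlist(categories$kmers[match(parents,
                                                    categories$label)])
      done <- FALSE
      for (try in seq_len(100L)) {
        pos <- floor(runif(1, win_lo, win_hi - k + 1))
        if (any(used_s <= pos + k - 1L & used_e >= pos)) next
        # context check: would the insertion sit inside a parent element?
        if (length(parent_kmers)) {
          ctx_lo <- max(1L, pos - 8L)
          ctx_hi <- min(chrom_len[[chrom]], pos + k - 1L + 8L)
          ctx <- chars[[chrom]][ctx_lo:ctx_hi]
          ctx[(pos - ctx_lo + 1L):(pos - ctx_lo + k)] <- kchars
          ctx <- paste(ctx, collapse = "")
          hit <- any(vapply(parent_kmers, function(p) {
            grepl(p, ctx, fixed = TRUE) ||
              grepl(revcomp_string(p), ctx, fixed = TRUE)
          }, logical(1)))
          if (hit) next
        }
        chars[[chrom]][pos:(pos + k - 1L)] <- kchars
        used_s <- c(used_s, pos); used_e <- c(used_e, pos + k - 1L)
        led_peak <- c(led_peak, peaks$name[i])
        led_cat <- c(led_cat, cat)
        led_kmer <- c(led_kmer, kmer)
        led_chrom <- c(led_chrom, chrom)
        led_start <- c(led_start, pos)
        done <- TRUE
        break
      }
      if (!done)
        warnf("could not plant %s in peak %s without overlap", cat,
              peaks$name[i])
    }
  }
  genome_out <- vapply(chars, paste, character(1), collapse = "")
  names(genome_out) <- names(genome)
  ledger <- data.frame(peak_id = led_peak, category = led_cat,
                       kmer = led_kmer, chrom = led_chrom,
                       start = led_start, stringsAsFactors = FALSE)
  list(genome = genome_out, ledger = ledger)
}

#' Simulate replicate count matrices from the ground truth
#'
#' Per-peak counts are negative binomial with the class- and
#' condition-dependent true means recorded in the truth ledger, scaled by
#' per-replicate depth factors drawn log-uniform in [0.7, 1.4].
#'
#' @param truth a `synthetic_truth` from [plant_peaks_and_motifs()].
#' @param config the same [synthetic_config()].
#' @return a [binding_counts()] object with samples
#'   `hetero_rep*` and `homo_rep*`.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "synthetic_config"))
  with_seed(child_seed(config$seed, 3), {
    peaks <- truth$peaks
    n <- length(peaks)
    nr <- config$n_replicates
    size <- 1 / config$nb_dispersion
    depth <- exp(runif(2 * nr, log(0.7), log(1.4)))
    cols <- c(paste0("hetero_rep", seq_len(nr)),
              paste0("homo_rep", seq_len(nr)))
    mu <- cbind(matrix(rep(peaks$mean_hetero, nr), ncol = nr),
                matrix(rep(peaks$mean_homo, nr), ncol = nr))
    mu <- sweep(mu, 2, depth, "*")
    counts <- matrix(rnbinom(n * 2 * nr, mu = as.vector(mu), size = size),
                     nrow = n, dimnames = list(peaks$name, cols))
    samples <- data.frame(sample = cols,
                          condition = rep(c("hetero", "homo"), each = nr),
                          replicate = rep(seq_len(nr), 2),
                          depth_factor = depth,
                          stringsAsFactors = FALSE)
    binding_counts(counts, samples,
                   library_sizes = pmax(colSums(counts), 1) * 10)
  })
}

#' Simulate negative-control peak sets with shared artifact regions
#'
#' Each artifact region is planted at identical coordinates in at least
#' `max(5, n_controls - 1)` of the controls, so the blacklist rule
#' (shared by >= 5 controls) can recover it exactly.  Every control also
#' carries private uniform noise peaks.
#'
#' @param config a [synthetic_config()].
#' @return list with `controls` (list of peak GRanges) and
#'   `artifact_regions` (GRanges).
#' @export
simulate_controls <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_controls < 1) stopf("'n_controls' must be >= 1")
  with_seed(child_seed(config$seed, 4), {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    L <- config$chrom_length
    artifacts <- random_intervals(config$n_artifact_regions, chroms, L,
                                  width = 1000L, disjoint = TRUE)
    if (length(artifacts))
      artifacts$name <- sprintf("artifact%02d", seq_along(artifacts))
    n_present <- min(config$n_controls, max(5L, config$n_controls - 1L))
    controls <- vector("list", config$n_controls)
    presence <- lapply(seq_along(artifacts), function(i)
      sample(config$n_controls, n_present))
    for (ci in seq_len(config$n_controls)) {
      art <- artifacts[vapply(presence, function(p) ci %in% p, logical(1))]
      noise <- random_intervals(config$n_noise_peaks, chroms, L,
                                width = 300L, disjoint = FALSE)
      gr <- sort_peaks(suppressWarnings(c(granges(art), granges(noise))))
      gr$name <- sprintf("ctrl%d_peak%03d", ci, seq_along(gr))
      gr$score <- 0
      gr$fold_enrichment <- NA_real_
      gr$neg_log10_q <- NA_real_
      gr$summit <- NA_integer_
      controls[[ci]] <- gr
    }
    names(controls) <- sprintf("control%d", seq_len(config$n_controls))
    list(controls = controls, artifact_regions = artifacts)
  })
}

random_intervals <- function(n, chroms, chrom_length, width,
                             disjoint = FALSE) {
  if (n == 0L)
    return(GRanges())
  out <- GRanges()
  tries <- 0L
  while (length(out) < n && tries < 50L * n) {
    tries <- tries + 1L
    chrom <- chroms[sample.int(length(chroms), 1)]
    s <- floor(runif(1, 1, chrom_length - width))
    cand <- GRanges(chrom, IRanges(s, width = width))
    if (disjoint && length(out) &&
        suppressWarnings(overlapsAny(cand, out))) next
    out <- suppressWarnings(c(out, cand))
  }
  if (length(out) < n)
    stopf("could not place %d disjoint intervals", n)
  out
}

#' Simulate a DEG-like gene set enriched for true targets
#'
#' The set contains `deg_target_fraction` of the true-target genes plus
#' random non-target genes (by default as many as the included targets).
#'
#' @param truth a `synthetic_truth`.
#' @param genes gene models from [simulate_genome()].
#' @param config the same [synthetic_config()].
#' @return character vector of gene ids.
#' @export
simulate_deg_set <- function(truth, genes, config) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "synthetic_config"))
  with_seed(child_seed(config$seed, 5), {
    targets <- truth$true_targets
    n_in <- round(config$deg_target_fraction * length(targets))
    included <- if (n_in > 0) sort(sample(targets, n_in)) else character(0)
    non_targets <- setdiff(genes$gene_id, targets)
    n_rand <- if (is.null(config$deg_n_random)) length(included) else
      config$deg_n_random
    n_rand <- min(n_rand, length(non_targets))
    fill <- if (n_rand > 0) sort(sample(non_targets, n_rand)) else
      character(0)
    sort(unique(c(included, fill)))
  })
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining [simulate_genome()],
#' [plant_peaks_and_motifs()], [simulate_counts()],
#' [simulate_controls()] and [simulate_deg_set()].
#'
#' @param config a [synthetic_config()].
#' @return list with `config`, `genome` (named character vector),
#'   `genes`, `truth`, `counts`, `controls`, `artifact_regions`,
#'   `deg_set`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  sim <- simulate_genome(config)
  planted <- plant_peaks_and_motifs(sim, config)
  counts <- simulate_counts(planted$truth, config)
  ctl <- simulate_controls(config)
  deg <- simulate_deg_set(planted$truth, sim$genes, config)
  list(config = config, genome = planted$genome, genes = sim$genes,
       truth = planted$truth, counts = counts,
       controls = ctl$controls, artifact_regions = ctl$artifact_regions,
       deg_set = deg)
}

#' Write a synthetic dataset to disk
#'
#' Emits the genome as 60-column FASTA, gene models as BED6 and GFF3,
#' peaks and controls as narrowPeak, counts as TSV, the ground-truth
#' ledger as TSV plus JSON, and the DEG set as a one-column TSV.
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  writeXStringSet(DNAStringSet(sim$genome), p("genome.fa"), width = 60)
  write_gene_models(sim$genes, p("genes.bed"))
  write_gene_models(sim$genes, p("genes.gff3"))
  write_peaks(sim$truth$peaks, p("peaks.narrowPeak"))
  for (nm in names(sim$controls))
    write_peaks(sim$controls[[nm]], p(paste0(nm, ".narrowPeak")))
  write_counts(sim$counts, p("counts.tsv"))
  ledger <- as.data.frame(sim$truth$peaks)
  write.table(ledger, p("truth_peaks.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$plantings, p("truth_plantings.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(true_targets = sim$truth$true_targets,
                            deg_set = sim$deg_set),
                       p("truth.json"), auto_unbox = FALSE)
  write.table(data.frame(gene = sim$deg_set), p("deg_set.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
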