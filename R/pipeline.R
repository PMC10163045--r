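# End-to-end orchestration: synthetic data -> blacklist -> consensus /
# correlation -> differential binding -> motif categories -> targets and
# gene-set association, with TSV outputs and a checksummed JSON manifest
# per run.

#' Pipeline parameters
#'
#' Numeric knobs of the analysis stages with their standard defaults:
#' peak q-value threshold 0.01, MAPQ cutoff 30, fragment size 200 bp,
#' blacklist sharing threshold 5 controls, consensus summit pad 100 bp
#' and minimum overlap 2 samples, per-replicate top-3000 enrichment
#' filter for the correlation stage, differential-binding alpha 0.05,
#' top-2000 differential peaks, 150 bp motif scan window, top-2000
#' target genes, and a promoter half-width of 1 kb.
#'
#' @param ... overrides of the defaults listed above.
#' @return a validated named list of class `pipeline_params`.
#' @export
pipeline_params <- function(...) {
  defaults <- list(q_threshold = 0.01,
                   min_mapq = 30,
                   fragment_size = 200,
                   blacklist_min_shared = 5,
                   consensus_min_overlap = 2,
                   summit_pad = 100,
                   correlation_top_n = 3000,
                   diff_alpha = 0.05,
                   top_differential_n = 2000,
                   motif_window = 150,
                   top_target_genes = 2000,
                   promoter_halfwidth = 1000,
                   occupancy_min = 10,
                   target_permutations = 200,
                   seed = 42)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stopf("unknown pipeline parameter(s): %s",
          paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, over)
  for (nm in names(params)) {
    if (!is.numeric(params[[nm]]) || length(params[[nm]]) != 1L ||
        is.na(params[[nm]]) || params[[nm]] <= 0)
      stopf("pipeline parameter '%s' must be a single positive number", nm)
  }
  structure(params, class = "pipeline_params")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates a seeded synthetic dataset, then runs every downstream
#' stage: blacklist construction and peak filtering, consensus peaks and
#' binding correlation clustering, differential binding classification,
#' motif-category scanning and enrichment, closest-gene target scoring
#' and mHG association with the simulated DEG set.  Each stage writes
#' TSV outputs under `outdir` and the run finishes with a
#' `manifest.json` recording parameters, seed and MD5 checksums of every
#' artifact; rerunning with the same configuration is byte-identical.
#'
#' @param config path to a YAML file, or a list, with optional blocks
#'   `params` (see [pipeline_params()]) and `synthetic` (see
#'   [synthetic_config()]).
#' @param outdir output directory.
#' @param seed overrides the seed in the config when given.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), outdir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("'config' must be a list or a YAML path")
  params <- do.call(pipeline_params, config$params %||% list())
  if (!is.null(seed)) params$seed <- seed
  syn_args <- config$synthetic %||% list()
  syn_args$seed <- params$seed
  scfg <- do.call(synthetic_config, syn_args)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  artifacts <- character(0)
  note <- function(...) artifacts <<- c(artifacts, c(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- simulate -------------------------------------------------------
  sim <- stage("simulate", {
    s <- simulate_dataset(scfg)
    write_synthetic_dataset(s, p("synthetic"))
    note(list.files(p("synthetic"), full.names = TRUE))
    s
  })

  # --- blacklist ------------------------------------------------------
  bl <- stage("blacklist", {
    blacklist <- build_blacklist(sim$controls,
                                 min_shared = params$blacklist_min_shared)
    filtered <- subtract_blacklist(sim$truth$peaks, blacklist)
    write_peaks(as_peakset(blacklist), p("blacklist.narrowPeak"))
    write_peaks(filtered, p("peaks_filtered.narrowPeak"))
    note(p("blacklist.narrowPeak"), p("peaks_filtered.narrowPeak"))
    list(blacklist = blacklist, filtered = filtered)
  })

  # --- consensus + correlation ---------------------------------------
  corr <- stage("correlate", {
    counts <- sim$counts
    rep_sets <- lapply(colnames(counts$counts), function(s) {
      rp <- sim$truth$peaks
      rp$neg_log10_q <- log10(counts$counts[rp$name, s] + 1)
      rp$fold_enrichment <- counts$counts[rp$name, s]
      rp
    })
    names(rep_sets) <- colnames(counts$counts)
    cons <- consensus_peaks(rep_sets,
                            min_overlap = params$consensus_min_overlap,
                            summit_pad = params$summit_pad)
    cons <- subtract_blacklist(cons, bl$blacklist)
    ov <- findOverlaps(cons, sim$truth$peaks)
    cmat <- matrix(0, nrow = length(cons), ncol = ncol(counts$counts),
                   dimnames = list(sprintf("consensus%05d",
                                           seq_along(cons)),
                                   colnames(counts$counts)))
    if (length(ov)) {
      agg <- rowsum(counts$counts[subjectHits(ov), , drop = FALSE],
                    group = queryHits(ov))
      cmat[as.integer(rownames(agg)), ] <- agg
    }
    cbc <- binding_counts(cmat, samples = counts$samples,
                          library_sizes = counts$library_sizes)
    cbc <- normalize_matrix(cbc, "library_size")
    sample_of <- setNames(counts$samples$condition,
                          counts$samples$sample)
    bcc <- binding_correlation_clustering(
      cbc, cons, replicate_peaks = rep_sets, sample_of = sample_of,
      top_n = params$correlation_top_n)
    write_matrix_tsv(bcc$correlation, p("correlation.tsv"))
    writeLines(bcc$newick, p("dendrogram.nwk"))
    write_peaks(as_peakset(cons), p("consensus.narrowPeak"))
    note(p("correlation.tsv"), p("dendrogram.nwk"),
         p("consensus.narrowPeak"))
    bcc
  })

  # --- differential binding ------------------------------------------
  db <- stage("diffbind", {
    keep <- bl$filtered$name
    cc <- sim$counts
    cc$counts <- cc$counts[keep, , drop = FALSE]
    np <- normalize_pair(cc, occupancy_min = params$occupancy_min)
    curve <- fit_mean_variance(np)
    res <- test_differential(np, curve, alpha = params$diff_alpha)
    write.table(res, p("differential_binding.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note(p("differential_binding.tsv"))
    res
  })

  # --- motif categories ----------------------------------------------
  mot <- stage("motifs", {
    peaks <- bl$filtered
    idx <- match(peaks$name, db$peak_id)
    peaks$class <- db$class[idx]
    spec <- peaks[peaks$class %in% c("heterodimer_specific",
                                     "homodimer_specific")]
    mmt <- peak_category_matrix(spec, sim$genome,
                                window = params$motif_window)
    enr <- category_enrichment(mmt, alpha = params$diff_alpha)
    comb <- combination_counts(mmt)
    write.table(enr, p("category_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(comb, p("combination_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note(p("category_enrichment.tsv"), p("combination_counts.tsv"))
    list(match_table = mmt, enrichment = enr, combinations = comb)
  })

  # --- targets + gene-set association --------------------------------
  tg <- stage("targets", {
    scores <- closest_gene_scores(
      bl$filtered, sim$genes,
      chrom_lengths = setNames(rep(scfg$chrom_length, scfg$n_chroms),
                               paste0("chr", seq_len(scfg$n_chroms))),
      B = params$target_permutations,
      seed = child_seed(params$seed, 6))
    mhg <- rank_and_test(scores, sim$deg_set)
    anno <- annotate_genomic_location(
      bl$filtered, sim$genes,
      promoter_halfwidth = params$promoter_halfwidth)
    write.table(scores, p("target_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(table(location = anno)),
                p("peak_locations.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(
      list(N = mhg$N, K = mhg$K, n_star = mhg$n_star,
           mhg_statistic = mhg$mhg_statistic, p_value = mhg$p_value),
      p("mhg_deg_association.json"), auto_unbox = TRUE, digits = NA)
    note(p("target_scores.tsv"), p("peak_locations.tsv"),
         p("mhg_deg_association.json"))
    list(scores = scores, mhg = mhg, locations = anno)
  })

  files <- sort(unique(artifacts))
  sums <- tools::md5sum(files)
  names(sums) <- sub(paste0("^", normalizePath(outdir), "/?"), "",
                     normalizePath(files))
  manifest <- list(
    params = unclass(params),
    synthetic = unclass(scfg)[!vapply(unclass(scfg), is.list,
                                      logical(1))],
    seed = params$seed,
    files = as.list(sums))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(sim = sim, blacklist = bl, correlation = corr,
                 differential = db, motifs = mot, targets = tg,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Give a bare GRanges the peak metadata columns expected by
# write_peaks().
as_peakset <- function(gr) {
  if (is.null(gr$name)) gr$name <- sprintf("region%05d", seq_along(gr))
  if (is.null(gr$score)) gr$score <- 0
  if (is.null(gr$fold_enrichment)) gr$fold_enrichment <- NA_real_
  if (is.null(gr$neg_log10_q)) gr$neg_log10_q <- NA_real_
  if (is.null(gr$summit)) gr$summit <- NA_integer_
  gr
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
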