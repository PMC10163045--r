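# Reading and writing peak sets and gene models.
#
# On disk, BED / narrowPeak / BED6 gene files follow their native 0-based
# half-open convention; in memory everything is a GRanges (1-based,
# closed).  Peak GRanges carry the metadata columns
#   name            peak identifier (unique within a set)
#   score           integer display score (0 when absent)
#   fold_enrichment enrichment over background (NA when absent)
#   neg_log10_q     -log10 q-value of the peak call (NA when absent)
#   summit          0-based offset of the summit from the peak start
#                   (NA when absent; narrowPeak column 10, -1 = absent)

.NARROWPEAK_COLS <- c("chrom", "start", "end", "name", "score", "strand",
                      "signalValue", "pValue", "qValue", "peak")

#' Read a peak file into a GRanges
#'
#' Supports 3- or 6-column BED and 10-column ENCODE narrowPeak, optionally
#' gzip-compressed.  narrowPeak column 10 (summit offset from peak start)
#' is stored in the `summit` metadata column, with -1 mapped to `NA`.
#'
#' @param path file path (plain or `.gz`).
#' @param format `"narrowPeak"` or `"BED"`.  Default guesses from the file
#'   extension, falling back to BED.
#' @return a sorted [GenomicRanges::GRanges] with the peak metadata
#'   columns described above.
#' @examples
#' tf <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t200\tp1\t0\t.\t8.0\t5.0\t3.2\t50", tf)
#' p <- read_peaks(tf)
#' start(p)  # 101 (1-based)
#' p$summit  # 50
#' @export
read_peaks <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(format)) {
    format <- if (grepl("narrowpeak(\\.gz)?$", tolower(path)))
      "narrowPeak" else "BED"
  }
  format <- match.arg(format, c("narrowPeak", "BED"))
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) return(empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (format == "narrowPeak") 10L else 3L
  bad <- which(nf < need)
  if (length(bad))
    stopf("malformed %s line %d in %s: expected >= %d fields, got %d",
          format, bad[1], path, need, nf[bad[1]])
  n <- length(fields)
  get <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  chrom <- get(1)
  start0 <- suppressWarnings(as.numeric(get(2)))
  end0 <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stopf("malformed coordinate on line %d of %s", bad[1], path)
  bad <- which(start0 >= end0)
  if (length(bad))
    stopf("start >= end on line %d of %s", bad[1], path)
  name <- get(4)
  name[is.na(name) | name == "."] <- paste0("peak_", seq_len(n))[
    is.na(name) | name == "."]
  score <- suppressWarnings(as.numeric(get(5)))
  score[is.na(score)] <- 0
  strand <- get(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), strand = strand,
                name = name, score = score)
  if (format == "narrowPeak") {
    gr$fold_enrichment <- suppressWarnings(as.numeric(get(7)))
    gr$neg_log10_q <- suppressWarnings(as.numeric(get(9)))
    summit <- suppressWarnings(as.numeric(get(10)))
    summit[!is.na(summit) & summit < 0] <- NA
    gr$summit <- as.integer(summit)
  } else {
    gr$fold_enrichment <- NA_real_
    gr$neg_log10_q <- NA_real_
    gr$summit <- NA_integer_
  }
  sort_peaks(gr)
}

#' Write a peak GRanges to BED or narrowPeak
#'
#' @param peaks a peak GRanges (see [read_peaks()] for metadata columns).
#' @param path destination path; a `.gz` suffix writes gzip output.
#' @param format `"narrowPeak"` or `"BED"` (BED6).
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("narrowPeak", "BED")) {
  assert_granges(peaks, "peaks")
  format <- match.arg(format)
  n <- length(peaks)
  name <- if (!is.null(peaks$name)) peaks$name else paste0("peak_", seq_len(n))
  score <- if (!is.null(peaks$score)) peaks$score else rep(0, n)
  strand <- as.character(strand(peaks))
  strand[strand == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = name, score = score, strand = strand,
                   stringsAsFactors = FALSE)
  if (format == "narrowPeak") {
    fe <- if (!is.null(peaks$fold_enrichment)) peaks$fold_enrichment else
      rep(NA_real_, n)
    q <- if (!is.null(peaks$neg_log10_q)) peaks$neg_log10_q else
      rep(NA_real_, n)
    summit <- if (!is.null(peaks$summit)) peaks$summit else
      rep(NA_integer_, n)
    df$signalValue <- ifelse(is.na(fe), 0, fe)
    df$pValue <- -1
    df$qValue <- ifelse(is.na(q), -1, q)
    df$peak <- ifelse(is.na(summit), -1L, as.integer(summit))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

empty_peaks <- function() {
  gr <- GRanges()
  gr$name <- character(0)
  gr$score <- numeric(0)
  gr$fold_enrichment <- numeric(0)
  gr$neg_log10_q <- numeric(0)
  gr$summit <- integer(0)
  gr
}

#' Read gene models from a BED6 or GFF3 file
#'
#' Returns a GRanges of gene bodies with a `gene_id` metadata column.  The
#' transcription start site of each gene is the interval start on the
#' plus strand and the interval end on the minus strand; use [gene_tss()]
#' to materialize it.
#'
#' @param path BED6 (`.bed`) or GFF3 (`.gff`/`.gff3`) file, optionally
#'   gzipped.  GFF3 input keeps records of type `gene` only.
#' @return GRanges with `gene_id`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.gff3?(\\.gz)?$", tolower(path))) {
    lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 9L)
    if (length(bad)) stopf("malformed GFF3 line %d in %s", bad[1], path)
    m <- do.call(rbind, fields)
    keep <- m[, 3] == "gene"
    m <- m[keep, , drop = FALSE]
    ids <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
    gr <- GRanges(m[, 1],
                  IRanges(as.numeric(m[, 4]), as.numeric(m[, 5])),
                  strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "*"))
    gr$gene_id <- ids
  } else {
    gr <- read_peaks(path, format = "BED")
    gr$gene_id <- gr$name
    mcols(gr) <- mcols(gr)["gene_id"]
  }
  sort_peaks(gr)
}

#' Write gene models
#'
#' @param genes GRanges with `gene_id`.
#' @param path destination; format chosen by extension (`.gff3` vs BED6).
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  assert_granges(genes, "genes")
  if (grepl("\\.gff3?$", tolower(path))) {
    lines <- c("##gff-version 3",
               sprintf("%s\tdimerspec\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       as.character(seqnames(genes)), start(genes),
                       end(genes), as.character(strand(genes)),
                       genes$gene_id))
    writeLines(lines, path)
  } else {
    g <- genes
    g$name <- g$gene_id
    g$score <- 0
    write_peaks(g, path, format = "BED")
  }
  invisible(path)
}

#' Transcription start sites of gene models
#'
#' @param genes GRanges of gene bodies with strand.
#' @return GRanges of width-1 TSS positions, metadata preserved.
#' @export
gene_tss <- function(genes) {
  assert_granges(genes, "genes")
  resize(genes, width = 1L, fix = "start")
}
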