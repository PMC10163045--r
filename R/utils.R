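# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded generator
#' calls do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream-specific child seed from a base seed; keeps independent
# stages reproducible regardless of call order.  Kept below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1009 + stream * 9176) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single number in [0, 1]", name)
  invisible(as.numeric(x))
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stopf("'%s' must be a single positive number", name)
  invisible(as.numeric(x))
}

assert_granges <- function(x, name) {
  if (!methods::is(x, "GRanges"))
    stopf("'%s' must be a GRanges object", name)
  invisible(x)
}

# Sort a GRanges by (chrom, start, end) without depending on seqlevel
# bookkeeping of the input.
sort_peaks <- function(gr) {
  gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] used everywhere a
#' false-discovery-rate correction is applied, so the choice of procedure
#' lives in one place.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @keywords internal
#' @noRd
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
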