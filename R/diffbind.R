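# Differential binding between heterodimer and homodimer samples:
# within- and between-condition normalization of log2 counts, a
# mean-variance curve fit, and a moderated t-test with curve-based
# variance shrinkage.  This is a deliberately compact re-statement of
# the hierarchical-normalization / local-fit approach used for
# ChIP-seq-style count matrices, not a line-for-line port.

#' Normalize a heterodimer/homodimer count pair
#'
#' Works on `log2(count + pseudocount)`.  Within each condition, every
#' replicate is linearly rescaled (matching mean and standard deviation
#' on commonly occupied peaks) to the condition's first replicate; the
#' two conditions are then rescaled symmetrically to their common
#' location and scale, so that the median log ratio (M) of occupied
#' peaks is centred at zero and the M-A trend is removed.  The symmetric
#' between-condition step makes the procedure exactly invariant to
#' swapping the condition labels.
#'
#' @param bc a [binding_counts()] whose `samples$condition` takes exactly
#'   two values (conventionally `"hetero"` and `"homo"`).
#' @param occupancy_min a peak is "occupied" when its raw count is at
#'   least this in every sample (default 10); normalization statistics
#'   are computed on occupied peaks only.
#' @param pseudocount added before `log2` (default 1).
#' @return list of class `normalized_pair`: `log2` matrix, `condition`
#'   per column, `occupied` logical per peak, `pseudocount`.
#' @export
normalize_pair <- function(bc, occupancy_min = 10, pseudocount = 1) {
  stopifnot(inherits(bc, "binding_counts"))
  cond <- bc$samples$condition
  lev <- unique(cond)
  if (length(lev) != 2L)
    stopf("'bc' must contain exactly two conditions, got %d", length(lev))
  counts <- bc$counts
  occupied <- rowSums(counts >= occupancy_min) == ncol(counts)
  if (!any(occupied))
    stopf("no peaks occupied (count >= %d) in every sample", occupancy_min)
  m <- log2(counts + pseudocount)
  # within-condition: match each replicate to the condition's first,
  # by median and MAD on occupied peaks (robust to a minority of
  # truly differential peaks)
  loc <- function(x) median(x)
  scl <- function(x) stats::mad(x)
  for (cl in lev) {
    cols <- which(cond == cl)
    ref <- m[occupied, cols[1]]
    for (j in cols[-1]) {
      y <- m[occupied, j]
      s <- if (scl(y) > 0) scl(ref) / scl(y) else 1
      m[, j] <- loc(ref) + (m[, j] - loc(y)) * s
    }
  }
  # between-condition: rescale both condition profiles to the common
  # location/scale (symmetric in the two labels, so that swapping them
  # is an exact mirror); centres the median M of occupied peaks at 0
  prof <- vapply(lev, function(cl)
    rowMeans(m[occupied, cond == cl, drop = FALSE]), numeric(sum(occupied)))
  mu <- apply(prof, 2, loc)
  sg <- apply(prof, 2, scl)
  mu0 <- mean(mu)
  sg0 <- if (all(sg > 0)) exp(mean(log(sg))) else mean(sg)
  for (k in seq_along(lev)) {
    cols <- which(cond == lev[k])
    scale_k <- if (sg[k] > 0) sg0 / sg[k] else 1
    m[, cols] <- mu0 + (m[, cols] - mu[k]) * scale_k
  }
  structure(list(log2 = m, condition = cond, occupied = occupied,
                 pseudocount = pseudocount),
            class = "normalized_pair")
}

#' Fit a mean-variance curve to normalized log2 counts
#'
#' Per-peak means (over all samples) and pooled within-condition
#' variances are related by a local regression (`lowess` on the log
#' variance), with a parametric fallback `log var = a + b * mean` when
#' the local fit degenerates.  The prior degrees of freedom of the
#' variance distribution are estimated from the spread of
#' `log(observed / fitted)` variance ratios on occupied peaks, using the
#' fact that for chi-squared-distributed variances this spread is
#' `trigamma(d1/2) + trigamma(d0/2)`.
#'
#' @param np a [normalize_pair()] result.
#' @param span `lowess` smoother span (default 0.3).
#' @return list of class `mean_variance_curve`: `predict(mean)` returning
#'   strictly positive variances, `method`, `prior_df`, `residual_df`.
#' @export
fit_mean_variance <- function(np, span = 0.3) {
  stopifnot(inherits(np, "normalized_pair"))
  if (nrow(np$log2) < 50L)
    stopf("need >= 50 peaks to fit a mean-variance curve")
  mv <- pooled_moments(np)
  if (all(mv$s2 < 1e-12))
    stopf("all per-peak variances are zero; degenerate input")
  pos <- mv$s2 > 0
  eps <- 1e-8
  method <- "local"
  # E[log s2] = log(sigma^2) + digamma(d/2) - log(d/2) for chi-square
  # variances: correct the log-scale fit for this bias
  log_bias <- digamma(mv$df / 2) - log(mv$df / 2)
  lo <- try(lowess(mv$mean[pos], log(mv$s2[pos] + eps), f = span),
            silent = TRUE)
  if (!inherits(lo, "try-error") && all(is.finite(lo$y))) {
    pred_fun <- function(x) {
      y <- approx(lo$x, lo$y, xout = x, rule = 2, ties = mean)$y
      pmax(exp(y - log_bias), eps)
    }
  } else {
    method <- "parametric"
    fit <- stats::lm(log(mv$s2[pos] + eps) ~ mv$mean[pos])
    a <- coef(fit)[1]; b <- coef(fit)[2]
    pred_fun <- function(x) pmax(exp(a + b * x - log_bias), eps)
  }
  d1 <- mv$df
  idx <- np$occupied & pos
  ratio <- mv$s2[idx] / pred_fun(mv$mean[idx])
  v <- var(log(ratio))
  excess <- v - trigamma(d1 / 2)
  prior_df <- if (is.na(excess) || excess <= 1e-6) Inf else
    2 * trigamma_inverse(excess)
  structure(list(predict = pred_fun, method = method,
                 prior_df = prior_df, residual_df = d1),
            class = "mean_variance_curve")
}

# Per-peak overall mean and pooled within-condition variance.
pooled_moments <- function(np) {
  m <- np$log2
  cond <- np$condition
  lev <- unique(cond)
  ss <- 0
  df <- 0
  for (cl in lev) {
    cols <- which(cond == cl)
    if (length(cols) >= 2L) {
      mu <- rowMeans(m[, cols, drop = FALSE])
      ss <- ss + rowSums((m[, cols, drop = FALSE] - mu)^2)
      df <- df + length(cols) - 1L
    }
  }
  if (df == 0L)
    stopf("at least one condition needs >= 2 replicates for a variance")
  list(mean = rowMeans(m), s2 = ss / df, df = df)
}

# Inverse of the trigamma function by monotone bisection; used for the
# moment estimator of the prior degrees of freedom.
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  lo <- 1e-4; hi <- 1e7
  if (trigamma(lo) < x) return(lo)
  if (trigamma(hi) > x) return(hi)
  uniroot(function(y) trigamma(y) - x, c(lo, hi), tol = 1e-10)$root
}

#' Moderated differential-binding test
#'
#' Per peak, the pooled within-condition variance is shrunk toward the
#' fitted mean-variance curve with the estimated prior degrees of
#' freedom, and a two-sided moderated t-test compares the heterodimer
#' and homodimer condition means.  P-values are BH-adjusted over all
#' peaks, and peaks are classified `heterodimer_specific` (adjusted
#' p < alpha and positive log2 fold change), `homodimer_specific`
#' (adjusted p < alpha and negative log2 fold change) or `unchanged`.
#'
#' @param np a [normalize_pair()] result.
#' @param curve a [fit_mean_variance()] curve fitted on the same matrix.
#' @param alpha significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param hetero label of the heterodimer condition (default
#'   `"hetero"`); the fold change is heterodimer minus homodimer.
#' @return data.frame of class `diff_bind_result` with columns
#'   `peak_id`, `mean_hetero`, `mean_homo`, `log2fc`, `stat`, `pvalue`,
#'   `padj`, `class`.
#' @export
test_differential <- function(np, curve, alpha = 0.05,
                              hetero = "hetero") {
  stopifnot(inherits(np, "normalized_pair"),
            inherits(curve, "mean_variance_curve"))
  cond <- np$condition
  lev <- unique(cond)
  if (!hetero %in% lev)
    stopf("condition '%s' not present", hetero)
  homo <- setdiff(lev, hetero)
  m <- np$log2
  ha <- which(cond == hetero)
  hb <- which(cond == homo)
  mean_h <- rowMeans(m[, ha, drop = FALSE])
  mean_o <- rowMeans(m[, hb, drop = FALSE])
  fc <- mean_h - mean_o
  mv <- pooled_moments(np)
  fitted <- curve$predict(mv$mean)
  d0 <- curve$prior_df
  d1 <- mv$df
  if (is.finite(d0)) {
    s2 <- (d0 * fitted + d1 * mv$s2) / (d0 + d1)
    df_total <- d0 + d1
  } else {
    s2 <- fitted
    df_total <- 1e6
  }
  se <- sqrt(s2 * (1 / length(ha) + 1 / length(hb)))
  stat <- fc / se
  p <- 2 * pt(-abs(stat), df = df_total)
  padj <- bh_adjust(p)
  cls <- rep("unchanged", length(fc))
  cls[padj < alpha & fc > 0] <- "heterodimer_specific"
  cls[padj < alpha & fc < 0] <- "homodimer_specific"
  out <- data.frame(peak_id = rownames(m), mean_hetero = mean_h,
                    mean_homo = mean_o, log2fc = fc, stat = stat,
                    pvalue = p, padj = padj, class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("diff_bind_result", "data.frame")
  out
}

#' Select the strongest differential peaks in one direction
#'
#' Filters to adjusted p <= `alpha` and the requested fold-change sign,
#' sorts by absolute log2 fold change descending (ties: smaller adjusted
#' p first, then peak id), and returns up to `n` peaks.
#'
#' @param results a [test_differential()] result.
#' @param n maximum number of peaks (default 2000).
#' @param direction `"hetero"` (positive fold change) or `"homo"`.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param peaks optional peak GRanges (matched by `name`); when given the
#'   return value is the subsetted GRanges in selection order.
#' @return data.frame of selected rows, or GRanges when `peaks` is given;
#'   empty with a warning when nothing qualifies.
#' @export
select_top_differential <- function(results, n = 2000,
                                    direction = c("hetero", "homo"),
                                    alpha = 0.05, peaks = NULL) {
  direction <- match.arg(direction)
  sgn <- if (direction == "hetero") 1 else -1
  keep <- results$padj <= alpha & sign(results$log2fc) == sgn
  sel <- results[keep, , drop = FALSE]
  if (nrow(sel) == 0L) {
    warnf("no peaks qualify (adjusted p <= %g, direction %s)", alpha,
          direction)
  }
  ord <- order(-abs(sel$log2fc), sel$padj, sel$peak_id)
  sel <- head(sel[ord, , drop = FALSE], n)
  if (!is.null(peaks)) {
    idx <- match(sel$peak_id, peaks$name)
    if (anyNA(idx)) stopf("peak ids missing from 'peaks'")
    return(peaks[idx])
  }
  sel
}
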