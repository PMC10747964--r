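#' Storey q-values
#'
#' Estimates the null proportion pi0 from the p-value histogram,
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`, smooths the estimates
#' with a cubic smoothing spline (3 df) over the lambda grid, evaluates the
#' smoother at the largest lambda and clips to (0, 1].  Q-values follow by
#' the usual cumulative minimum from the largest p:
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`.  Tied p-values share a
#' q-value.  With `pi0 = 1` the result is exactly the Benjamini-Hochberg
#' adjusted p-value.
#'
#' @param pvalues numeric vector with values in (0, 1].
#' @param lambda grid for pi0 estimation (default 0.05 to 0.90 by 0.05).
#' @param pi0 optionally force pi0 (e.g. 1 for plain BH) instead of
#'   estimating it.
#' @return list of class `"qvalue_result"`: `qvalues` (aligned with input),
#'   `pi0`, `lambda`, `pi0_lambda` (the raw grid estimates).
#' @export
storey_qvalues <- function(pvalues, lambda = seq(0.05, 0.90, by = 0.05),
                           pi0 = NULL) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("input error: p-values must lie in (0, 1]")
  m <- length(p)
  pi0_lambda <- NULL
  if (is.null(pi0)) {
    if (m < 20L) {
      warning("fewer than 20 p-values; pi0 fixed to 1")
      pi0 <- 1
    } else {
      pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / (m:1)))[ro]
  structure(list(qvalues = q, pi0 = pi0, lambda = lambda,
                 pi0_lambda = pi0_lambda),
            class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat(sprintf("Storey q-values: m = %d, pi0 = %.4f, min q = %.4g\n",
              length(x$qvalues), x$pi0, min(x$qvalues)))
  invisible(x)
}

#' Add genome-wide and chromosome-wise q-value columns to an association table
#'
#' Genome-wide q-values use all p-values; chromosome-wise q-values rerun the
#' Storey procedure independently within each chromosome.  Chromosomes with
#' fewer than 20 SNPs get pi0 fixed to 1 (the spline is unstable there),
#' with a warning.
#'
#' @param assoc an `"assoc_table"` with `chrom` and `p` columns.
#' @return the table with `q_genome` and `q_chrom` columns filled.
#' @export
add_qvalues <- function(assoc) {
  ok <- !is.na(assoc$p)
  assoc$q_genome <- assoc$q_chrom <- NA_real_
  assoc$q_genome[ok] <- storey_qvalues(assoc$p[ok])$qvalues
  for (ch in unique(assoc$chrom)) {
    sel <- ok & assoc$chrom == ch
    if (!any(sel)) next
    if (sum(sel) < 20L) {
      warning("chromosome ", ch, " has < 20 SNPs; pi0 fixed to 1")
      assoc$q_chrom[sel] <- storey_qvalues(assoc$p[sel], pi0 = 1)$qvalues
    } else {
      assoc$q_chrom[sel] <- storey_qvalues(assoc$p[sel])$qvalues
    }
  }
  assoc
}
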