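#' Per-SNP Weir & Cockerham Fst between two cohorts
#'
#' Two-population theta estimator from allele counts (the 1984
#' variance-components form with the finite-sample nc correction).  Negative
#' estimates are retained -- the composite score uses only ranks.  SNPs
#' monomorphic for the same allele in both cohorts are flagged invalid
#' (`NA`).
#'
#' @param target,reference [genotype_matrix()] objects on the same SNP map.
#' @return numeric vector of theta values, `NA` where undefined.
#' @export
fst_per_snp <- function(target, reference) {
  check_shared_map(target, reference)
  stats1 <- pop_stats(target$doses)
  stats2 <- pop_stats(reference$doses)
  n1 <- stats1$n; n2 <- stats2$n
  if (any(n1 < 2 | n2 < 2)) stop("need >= 2 genotyped samples per population at every SNP")
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * stats1$p + n2 * stats2$p) / (r * nbar)
  s2 <- (n1 * (stats1$p - pbar)^2 + n2 * (stats2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * stats1$h + n2 * stats2$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(abs(denom) < 1e-300, NA_real_, a / denom)
  theta[pbar %in% c(0, 1)] <- NA_real_   # monomorphic in both
  unname(theta)
}

pop_stats <- function(X) {
  n <- colSums(!is.na(X))
  p <- colMeans(X, na.rm = TRUE) / 2
  h <- colMeans(X == 1L, na.rm = TRUE)
  list(n = n, p = p, h = h)
}

check_shared_map <- function(a, b) {
  if (nrow(a$snp_table) != nrow(b$snp_table) ||
      !all(a$snp_table$snp_id == b$snp_table$snp_id))
    stop("the two cohorts must share the same SNP map")
  invisible(TRUE)
}

#' Signed difference in derived allele frequency
#'
#' `ddaf = derived-frequency(target) - derived-frequency(reference)`.  The
#' ancestral allele must match one of the two mapped alleles; otherwise the
#' SNP is flagged invalid.
#'
#' @param target_freq,reference_freq per-SNP frequencies of allele B.
#' @param ancestral per-SNP ancestral allele labels.
#' @param snp_table SNP map supplying `allele_A`/`allele_B`.
#' @return numeric vector in [-1, 1], `NA` where the ancestral call matches
#'   neither allele.
#' @export
delta_daf <- function(target_freq, reference_freq, ancestral, snp_table) {
  isA <- ancestral == snp_table$allele_A
  isB <- ancestral == snp_table$allele_B
  out <- rep(NA_real_, length(target_freq))
  out[isA] <- target_freq[isA] - reference_freq[isA]
  out[isB] <- (1 - target_freq[isB]) - (1 - reference_freq[isB])
  out
}

# ---- extended haplotype homozygosity ---------------------------------------

# EHH of a haplotype matrix at one additional column given current grouping.
# Returns list(groups, ehh).
ehh_step <- function(groups, alleles) {
  key <- groups * 2L + alleles
  g <- match(key, unique(key))
  cnt <- tabulate(g)
  n <- length(g)
  list(groups = g, ehh = sum(cnt * (cnt - 1)) / (n * (n - 1)))
}

#' Extended haplotype homozygosity decay curve
#'
#' `EHH(x) = sum_h choose(c_h, 2) / choose(n_hap, 2)` where `c_h` counts
#' haplotypes identical from the core SNP out to x.  EHH is 1 at the core and
#' non-increasing outward.  The curve is truncated once EHH falls below
#' `min_ehh` (the first sub-threshold SNP is included as the end point) or at
#' the chromosome end.
#'
#' @param haplotypes haplotype matrix (rows = haplotypes, 0/1 alleles) for
#'   one chromosome.
#' @param positions bp positions of the columns.
#' @param core_snp column index of the core SNP.
#' @param direction `"left"` or `"right"`.
#' @param min_ehh truncation threshold (default 0.05).
#' @return data.frame with `snp` (column index), `distance_bp` (from core)
#'   and `ehh`.
#' @export
ehh_curve <- function(haplotypes, positions, core_snp,
                      direction = c("right", "left"), min_ehh = 0.05) {
  direction <- match.arg(direction)
  H <- as.matrix(haplotypes)
  if (nrow(H) < 2L) stop("need at least 2 haplotypes")
  m <- ncol(H)
  step <- if (direction == "right") 1L else -1L
  snps <- core_snp
  ehh <- 1
  st <- ehh_step(rep(1L, nrow(H)), H[, core_snp])
  g <- st$groups
  j <- core_snp
  while (TRUE) {
    j <- j + step
    if (j < 1L || j > m) break
    st <- ehh_step(g, H[, j])
    g <- st$groups
    snps <- c(snps, j)
    ehh <- c(ehh, st$ehh)
    if (st$ehh < min_ehh) break
  }
  data.frame(snp = snps, distance_bp = abs(positions[snps] - positions[core_snp]),
             ehh = ehh)
}

# trapezoid integral of y over x
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Cross-population extended haplotype homozygosity at one core SNP
#'
#' Walks outward from the core in both directions simultaneously in the two
#' populations, stopping in each direction at the outermost SNP where both
#' populations still have EHH >= `min_ehh` (the same truncation point applies
#' to both).  iHH is the trapezoid integral of EHH against physical distance
#' summed over both directions (physical bp is used as the map proxy), and
#' the raw statistic is `ln(iHH_target / iHH_reference)`.
#'
#' @param target_haps,ref_haps haplotype matrices on the same SNP columns.
#' @param positions bp positions of the columns.
#' @param core_snp core column index.
#' @param min_ehh truncation threshold (default 0.05).
#' @return list with `raw` (`NA` when either integral is zero), `ihh_target`,
#'   `ihh_reference`.
#' @export
xpehh_core <- function(target_haps, ref_haps, positions, core_snp,
                       min_ehh = 0.05) {
  m <- length(positions)
  walk <- function(step) {
    gt <- ehh_step(rep(1L, nrow(target_haps)), target_haps[, core_snp])$groups
    gr <- ehh_step(rep(1L, nrow(ref_haps)), ref_haps[, core_snp])$groups
    xs <- positions[core_snp]; et <- 1; er <- 1
    j <- core_snp
    while (TRUE) {
      j <- j + step
      if (j < 1L || j > m) break
      st <- ehh_step(gt, target_haps[, j])
      sr <- ehh_step(gr, ref_haps[, j])
      if (st$ehh < min_ehh || sr$ehh < min_ehh) break
      gt <- st$groups; gr <- sr$groups
      xs <- c(xs, positions[j]); et <- c(et, st$ehh); er <- c(er, sr$ehh)
    }
    x <- abs(xs - positions[core_snp])
    c(trapz(x, et), trapz(x, er))
  }
  lr <- walk(-1L) + walk(1L)
  raw <- if (lr[1] <= 0 || lr[2] <= 0) NA_real_ else log(lr[1] / lr[2])
  list(raw = raw, ihh_target = lr[1], ihh_reference = lr[2])
}

#' Genome-wide XP-EHH scan
#'
#' Computes the raw cross-population statistic at every SNP (per chromosome)
#' and standardizes the valid values to mean 0, sd 1.
#'
#' @param target,reference phased [genotype_matrix()] objects sharing a map.
#' @param min_ehh truncation threshold.
#' @return data.frame with `xpehh_raw` and `xpehh_std` per SNP.
#' @export
xpehh_scan <- function(target, reference, min_ehh = 0.05) {
  check_shared_map(target, reference)
  if (is.null(target$haplotypes) || is.null(reference$haplotypes))
    stop("XP-EHH requires phased haplotypes in both populations")
  snp <- target$snp_table
  raw <- rep(NA_real_, nrow(snp))
  Ht_all <- rbind(target$haplotypes$h1, target$haplotypes$h2)
  Hr_all <- rbind(reference$haplotypes$h1, reference$haplotypes$h2)
  for (ch in unique(snp$chrom)) {
    cols <- which(snp$chrom == ch)
    Ht <- Ht_all[, cols, drop = FALSE]
    Hr <- Hr_all[, cols, drop = FALSE]
    ok_rows_t <- stats::complete.cases(Ht)
    ok_rows_r <- stats::complete.cases(Hr)
    Ht <- Ht[ok_rows_t, , drop = FALSE]; Hr <- Hr[ok_rows_r, , drop = FALSE]
    pos <- snp$pos_bp[cols]
    for (k in seq_along(cols)) {
      raw[cols[k]] <- xpehh_core(Ht, Hr, pos, k, min_ehh)$raw
    }
  }
  mu <- mean(raw, na.rm = TRUE); s <- stats::sd(raw, na.rm = TRUE)
  std <- if (is.na(s) || s == 0) rep(NA_real_, length(raw)) else (raw - mu) / s
  data.frame(xpehh_raw = raw, xpehh_std = std)
}

# ---- composite score --------------------------------------------------------

#' Combine component statistics into composite selection signals
#'
#' Each component is converted to fractional ranks `1/(n+1) ... n/(n+1)` over
#' its valid SNPs (average ranks for ties), mapped to z-scores by the inverse
#' normal CDF, and averaged per SNP.  Under the null the mean of m
#' independent such z-scores is N(0, 1/m), so the one-sided p-value is
#' `1 - Phi(zbar * sqrt(m))` and `CSS = -log10(p)`.  SNPs invalid in a
#' component are ranked only in the others, with m reduced accordingly; SNPs
#' invalid in all components get `NA`.
#'
#' @param components data.frame with columns `snp_id`, `chrom`, `pos_bp` and
#'   the component statistics named in `stats`.
#' @param stats component column names
#'   (default `c("fst", "ddaf", "xpehh_std")`).
#' @return data.frame of class `"css_table"` with per-component fractional
#'   ranks (`rank_*`), `zbar`, `m`, `p`, `css`.
#' @export
composite_css <- function(components, stats = c("fst", "ddaf", "xpehh_std")) {
  stopifnot(all(stats %in% names(components)))
  Z <- matrix(NA_real_, nrow(components), length(stats),
              dimnames = list(NULL, stats))
  R <- Z
  for (s in stats) {
    x <- components[[s]]
    ok <- !is.na(x)
    r <- rank(x[ok], ties.method = "average") / (sum(ok) + 1)
    R[ok, s] <- r
    Z[ok, s] <- qnorm(r)
  }
  mm <- rowSums(!is.na(Z))
  zbar <- ifelse(mm > 0, rowMeans(Z, na.rm = TRUE), NA_real_)
  p <- 1 - pnorm(zbar * sqrt(mm))
  # guard against p underflow at extreme ranks
  p <- pmax(p, .Machine$double.xmin)
  p[mm == 0] <- NA_real_
  out <- components[, c("snp_id", "chrom", "pos_bp")]
  colnames(R) <- paste0("rank_", stats)
  out <- cbind(out, components[stats], R, zbar = zbar, m = mm,
               p = p, css = -log10(p))
  class(out) <- c("css_table", "data.frame")
  out
}

#' Window-smooth composite selection signals
#'
#' Smoothed CSS at a SNP is the mean raw CSS over all SNPs of the same
#' chromosome within half a window on either side (inclusive); an isolated
#' SNP keeps its own value.  The default 1 Mb window averages over 0.5 Mb on
#' either side.
#'
#' @param css a `"css_table"` from [composite_css()].
#' @param window_bp full window width in bp (default 1e6).
#' @return the table with a `css_smoothed` column added.
#' @export
smooth_css <- function(css, window_bp = 1e6) {
  hw <- window_bp / 2
  out <- rep(NA_real_, nrow(css))
  for (ch in unique(css$chrom)) {
    sel <- which(css$chrom == ch)
    pos <- css$pos_bp[sel]
    val <- css$css[sel]
    ok <- !is.na(val)
    v0 <- ifelse(ok, val, 0)
    cs <- c(0, cumsum(v0)); cn <- c(0, cumsum(ok))
    lo <- findInterval(pos - hw - 0.5, pos) + 1L
    hi <- findInterval(pos + hw + 0.5, pos)
    tot <- cs[hi + 1L] - cs[lo]
    cnt <- cn[hi + 1L] - cn[lo]
    out[sel] <- ifelse(cnt > 0, tot / cnt, NA_real_)
  }
  css$css_smoothed <- out
  css
}

#' Threshold smoothed CSS into significant regions
#'
#' The significance threshold is the empirical `quantile` (order-statistic
#' definition, quantile type 1) of smoothed CSS over all SNPs; SNPs strictly
#' above it are significant, which caps the flagged fraction at
#' `1 - quantile`.  Significant SNPs are grouped into maximal runs of
#' consecutive SNPs per chromosome and each region is summarised by the mean
#' smoothed CSS of its members.
#'
#' @param css a smoothed `"css_table"` (see [smooth_css()]).
#' @param quantile empirical quantile for the threshold (default 0.995).
#' @return list: `css` (table with `significant` flag and `region_id`),
#'   `regions` (one row per region), `threshold`.
#' @export
significant_regions <- function(css, quantile = 0.995) {
  if (is.null(css$css_smoothed)) stop("run smooth_css() first")
  thr <- stats::quantile(css$css_smoothed, quantile, na.rm = TRUE,
                         type = 1, names = FALSE)
  sig <- !is.na(css$css_smoothed) & css$css_smoothed > thr
  region_id <- rep(NA_integer_, nrow(css))
  regions <- list()
  rid <- 0L
  for (ch in unique(css$chrom)) {
    sel <- which(css$chrom == ch)
    r <- rle(sig[sel])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      rid <- rid + 1L
      mem <- sel[starts[k]:ends[k]]
      region_id[mem] <- rid
      regions[[rid]] <- data.frame(
        region_id = rid, chrom = ch,
        start_bp = css$pos_bp[mem[1]], end_bp = css$pos_bp[mem[length(mem)]],
        n_snps = length(mem),
        regional_css = mean(css$css_smoothed[mem]))
    }
  }
  css$significant <- sig
  css$region_id <- region_id
  list(css = css,
       regions = if (rid > 0) do.call(rbind, regions) else
         data.frame(region_id = integer(0), chrom = integer(0),
                    start_bp = numeric(0), end_bp = numeric(0),
                    n_snps = integer(0), regional_css = numeric(0)),
       threshold = thr)
}

#' Composite selection signal scan
#'
#' Full contrast of a target cohort against a reference panel: per-SNP Weir &
#' Cockerham Fst, signed delta-DAF and standardized XP-EHH are rank-combined
#' into CSS, window-smoothed and thresholded into significant regions.
#'
#' @param target phased [genotype_matrix()] of the target cohort (e.g. the
#'   case dogs).
#' @param reference phased [genotype_matrix()] of the low-risk reference
#'   panel, on the same SNP map.
#' @param ancestral optional per-SNP ancestral allele labels; by default the
#'   major allele of the reference panel is used as the ancestral call (a
#'   fallback worth remembering when interpreting delta-DAF signs).
#' @param window_bp smoothing window (default 1 Mb).
#' @param quantile significance quantile of smoothed CSS (default 0.995).
#' @param min_ehh EHH truncation threshold for XP-EHH (default 0.05).
#' @return list of class `"css_scan"`: `css` (per-SNP table), `regions`,
#'   `threshold`, and the parameters used.
#' @export
css_scan <- function(target, reference, ancestral = NULL,
                     window_bp = 1e6, quantile = 0.995, min_ehh = 0.05) {
  check_shared_map(target, reference)
  snp <- target$snp_table
  tf <- allele_freq(target); rf <- allele_freq(reference)
  if (is.null(ancestral)) {
    message("css_scan: ancestral alleles not supplied; using the reference-panel major allele")
    ancestral <- ifelse(rf <= 0.5, snp$allele_A, snp$allele_B)
  }
  comp <- data.frame(snp_id = snp$snp_id, chrom = snp$chrom,
                     pos_bp = snp$pos_bp,
                     fst = fst_per_snp(target, reference),
                     ddaf = delta_daf(tf, rf, ancestral, snp),
                     stringsAsFactors = FALSE)
  comp <- cbind(comp, xpehh_scan(target, reference, min_ehh))
  tbl <- smooth_css(composite_css(comp), window_bp)
  sr <- significant_regions(tbl, quantile)
  structure(list(css = sr$css, regions = sr$regions, threshold = sr$threshold,
                 window_bp = window_bp, quantile = quantile),
            class = "css_scan")
}

#' @export
print.css_scan <- function(x, ...) {
  cat(sprintf("CSS scan: %d SNPs, smoothing window %g bp, %.1f%% threshold = %.3f\n",
              nrow(x$css), x$window_bp, 100 * x$quantile, x$threshold))
  cat(sprintf("  significant SNPs: %d in %d region(s)\n",
              sum(x$css$significant, na.rm = TRUE), nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a CSS scan
#' @param x a `"css_scan"`.
#' @param ... passed to `plot`.
#' @export
plot.css_scan <- function(x, ...) {
  tb <- x$css
  cum <- cumsum(c(0, tapply(tb$pos_bp, tb$chrom, max)))
  cf <- as.integer(factor(tb$chrom, levels = unique(tb$chrom)))
  xpos <- tb$pos_bp + cum[cf]
  graphics::plot(xpos, tb$css_smoothed, pch = 20, cex = 0.4,
                 col = c("grey40", "darkorange")[cf %% 2 + 1],
                 xlab = "genome position", ylab = "smoothed CSS", ...)
  graphics::abline(h = x$threshold, col = "red", lty = 2)
  invisible(x)
}
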