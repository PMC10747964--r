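#' Enumerate sliding haplotype windows
#'
#' All (start, width) pairs with width between `min_width` and `max_width`,
#' sliding one SNP at a time, that fit inside `n_snps` markers.
#'
#' @param n_snps number of SNPs available.
#' @param min_width,max_width window sizes in SNPs (defaults 2 and 8).
#' @param step slide step in SNPs (default 1).
#' @return data.frame with `start` and `width`; empty (with a warning) when
#'   fewer than `min_width` SNPs are available.
#' @export
sliding_windows <- function(n_snps, min_width = 2L, max_width = 8L, step = 1L) {
  if (n_snps < min_width) {
    warning("fewer SNPs than the minimum window width; no windows")
    return(data.frame(start = integer(0), width = integer(0)))
  }
  out <- do.call(rbind, lapply(min_width:min(max_width, n_snps), function(w) {
    data.frame(start = seq(1L, n_snps - w + 1L, by = step), width = w)
  }))
  rownames(out) <- NULL
  out
}

#' Haplotype frequencies in a window, by cohort
#'
#' With phased input the haplotype strings are tallied directly.  With
#' unphased doses the phase within the (at most 8 SNP) window is resolved by
#' an expectation-maximization estimate of haplotype frequencies under
#' Hardy-Weinberg; expected haplotype counts at the final iterate are
#' reported.  EM stops when no frequency moves by more than `tol` (default
#' 1e-6) or after `max_iter` iterations (non-convergence is flagged and the
#' last iterate used).  Samples with missing data in the window are excluded,
#' so counts sum to twice the complete-data sample count per cohort.
#' Haplotypes are written in the allele alphabet of the SNP map.
#'
#' @param genotypes a [genotype_matrix()].
#' @param window a `(start, width)` pair of SNP indices (global column index).
#' @param cohorts per-sample cohort labels (e.g. status), or a phenotype
#'   table.
#' @param use_phase use phased haplotypes when present (default TRUE).
#' @param tol,max_iter EM controls.
#' @return data.frame of class `"haplotype_window"`: `haplotype`, one count
#'   column per cohort, plus attributes `window`, `converged`.
#' @export
window_haplotype_freqs <- function(genotypes, window, cohorts,
                                   use_phase = TRUE, tol = 1e-6,
                                   max_iter = 200L) {
  start <- window[1]; width <- window[2]
  cols <- start:(start + width - 1L)
  if (max(cols) > nrow(genotypes$snp_table)) stop("window outside the SNP map")
  if (is.data.frame(cohorts))
    cohorts <- cohorts$status[match(genotypes$sample_ids, cohorts$sample_id)]
  cohorts <- as.character(cohorts)
  snp <- genotypes$snp_table[cols, ]
  to_string <- function(M)
    apply(M, 1, function(r) paste(ifelse(r == 1L, snp$allele_B, snp$allele_A),
                                  collapse = ""))
  converged <- TRUE
  if (use_phase && !is.null(genotypes$haplotypes)) {
    h1 <- genotypes$haplotypes$h1[, cols, drop = FALSE]
    h2 <- genotypes$haplotypes$h2[, cols, drop = FALSE]
    keep <- stats::complete.cases(h1) & stats::complete.cases(h2)
    labs <- rep(cohorts[keep], 2L)
    strs <- c(to_string(h1[keep, , drop = FALSE]),
              to_string(h2[keep, , drop = FALSE]))
    counts <- table(haplotype = strs, cohort = labs)
  } else {
    if (width > 8L) stop("EM phasing is limited to windows of at most 8 SNPs")
    D <- genotypes$doses[, cols, drop = FALSE]
    keep <- stats::complete.cases(D)
    D <- D[keep, , drop = FALSE]
    labs <- cohorts[keep]
    em <- em_window(D, tol = tol, max_iter = max_iter)
    converged <- em$converged
    if (!converged)
      warning("EM did not converge in ", max_iter, " iterations; using last iterate")
    # expected haplotype counts per cohort from posterior pair weights
    haps <- to_string(em$haplotypes)
    cohs <- sort(unique(labs))
    counts <- matrix(0, length(haps), length(cohs),
                     dimnames = list(haplotype = haps, cohort = cohs))
    for (i in seq_len(nrow(D))) {
      pr <- em$posterior[[em$pattern_of[i]]]
      ci <- match(labs[i], cohs)
      for (k in seq_len(nrow(pr))) {
        counts[pr[k, 1], ci] <- counts[pr[k, 1], ci] + pr[k, 3]
        counts[pr[k, 2], ci] <- counts[pr[k, 2], ci] + pr[k, 3]
      }
    }
    counts <- as.table(counts)
  }
  out <- as.data.frame.matrix(unclass(counts))
  out <- cbind(haplotype = rownames(counts), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "window") <- c(start = start, width = width)
  attr(out, "converged") <- converged
  class(out) <- c("haplotype_window", "data.frame")
  out
}

# EM for haplotype frequencies within a small window of unphased doses.
# Returns the haplotype configuration matrix, per-genotype-pattern posterior
# pair weights and the frequency vector.
em_window <- function(D, tol = 1e-6, max_iter = 200L) {
  w <- ncol(D)
  pat_str <- apply(D, 1, paste, collapse = "/")
  upat <- unique(pat_str)
  pattern_of <- match(pat_str, upat)
  n_pat <- as.vector(table(factor(pat_str, levels = upat)))
  # enumerate haplotypes compatible with any observed pattern
  pairs_for <- function(p) {
    g <- as.integer(strsplit(p, "/")[[1]])
    het <- which(g == 1L)
    base <- ifelse(g == 2L, 1L, 0L)
    if (length(het) == 0L) return(list(list(base, base)))
    k <- length(het)
    combos <- as.matrix(expand.grid(rep(list(0:1), k)))
    lapply(seq_len(max(1L, 2L^(k - 1L))), function(i) {
      h1 <- base; h1[het] <- combos[i, ]
      h2 <- base; h2[het] <- 1L - combos[i, ]
      list(h1, h2)
    })
  }
  all_pairs <- lapply(upat, pairs_for)
  hap_key <- new.env()
  haps <- list()
  hap_id <- function(h) {
    k <- paste(h, collapse = "")
    v <- hap_key[[k]]
    if (is.null(v)) {
      v <- length(haps) + 1L
      haps[[v]] <<- h
      hap_key[[k]] <- v
    }
    v
  }
  pair_idx <- lapply(all_pairs, function(pl)
    t(vapply(pl, function(pp) c(hap_id(pp[[1]]), hap_id(pp[[2]])), integer(2))))
  H <- do.call(rbind, haps)
  nh <- nrow(H)
  f <- rep(1 / nh, nh)
  n2 <- 2 * sum(n_pat)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    newf <- numeric(nh)
    for (u in seq_along(upat)) {
      pi_ <- pair_idx[[u]]
      wgt <- f[pi_[, 1]] * f[pi_[, 2]] * ifelse(pi_[, 1] == pi_[, 2], 1, 2)
      s <- sum(wgt)
      wgt <- if (s > 0) wgt / s else rep(1 / nrow(pi_), nrow(pi_))
      contrib <- wgt * n_pat[u]
      for (k in seq_len(nrow(pi_))) {
        newf[pi_[k, 1]] <- newf[pi_[k, 1]] + contrib[k]
        newf[pi_[k, 2]] <- newf[pi_[k, 2]] + contrib[k]
      }
    }
    newf <- newf / n2
    delta <- max(abs(newf - f))
    f <- newf
    if (delta < tol) { converged <- TRUE; break }
  }
  posterior <- lapply(seq_along(upat), function(u) {
    pi_ <- pair_idx[[u]]
    wgt <- f[pi_[, 1]] * f[pi_[, 2]] * ifelse(pi_[, 1] == pi_[, 2], 1, 2)
    s <- sum(wgt)
    wgt <- if (s > 0) wgt / s else rep(1 / nrow(pi_), nrow(pi_))
    cbind(pi_, wgt)
  })
  list(haplotypes = H, freq = f, posterior = posterior,
       pattern_of = pattern_of, converged = converged)
}

# ---- haplotype blocks (Gabriel-style) --------------------------------------

# Likelihood-based confidence interval on |D'| for a SNP pair, from unphased
# two-locus genotype counts under HWE.  Returns c(low, high) on a 0..1 grid,
# or NULL when a locus is monomorphic.
dprime_ci <- function(g1, g2, grid = seq(0, 1, by = 0.01)) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NULL)
  # sign of association from the composite (Burrows) disequilibrium
  dhat <- mean(g1 * g2) / 2 - 2 * pA * pB
  s <- if (dhat >= 0) 1 else -1
  dmax <- if (s > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(NULL)
  n9 <- table(factor(g1, 0:2), factor(g2, 0:2))
  ll <- vapply(grid, function(dp) {
    D <- s * dp * dmax
    p11 <- pA * pB + D; p10 <- pA * (1 - pB) - D
    p01 <- (1 - pA) * pB - D; p00 <- (1 - pA) * (1 - pB) + D
    h <- pmax(c(p00, p01, p10, p11), 1e-12)
    # genotype-pair probabilities under HWE (double het sums both phasings)
    P <- matrix(0, 3, 3)
    P[1, 1] <- h[1]^2;       P[1, 2] <- 2 * h[1] * h[2];       P[1, 3] <- h[2]^2
    P[2, 1] <- 2 * h[1] * h[3]; P[2, 2] <- 2 * (h[1] * h[4] + h[2] * h[3])
    P[2, 3] <- 2 * h[2] * h[4]
    P[3, 1] <- h[3]^2;       P[3, 2] <- 2 * h[3] * h[4];       P[3, 3] <- h[4]^2
    sum(n9 * log(pmax(P, 1e-300)))
  }, numeric(1))
  w <- exp(ll - max(ll))
  cw <- cumsum(w) / sum(w)
  low <- grid[which(cw >= 0.05)[1]]
  high <- grid[which(cw >= 0.95)[1]]
  c(low = low, high = high)
}

#' Gabriel-style haplotype blocks
#'
#' For every SNP pair in the region a likelihood-based confidence interval on
#' |D'| is computed from unphased genotypes.  A pair is in strong LD when the
#' CI lower bound is at least 0.70 and the upper bound at least 0.98; it
#' shows strong recombination when the upper bound is below 0.90; otherwise
#' it is uninformative (as are pairs involving a monomorphic SNP).  A
#' candidate interval is a block when at least `strong_frac` (default 95%) of
#' its informative pairs are strong LD and it has at least one informative
#' pair; overlapping candidates are resolved longest-span-first.
#'
#' @param genotypes a [genotype_matrix()].
#' @param snps integer indices (global) of the region's SNPs; default all.
#' @param strong_frac required fraction of strong-LD informative pairs.
#' @return data.frame with `start_idx`, `end_idx` (into `snps`), `start_bp`,
#'   `end_bp`, `n_snps`.
#' @export
haplotype_blocks <- function(genotypes, snps = NULL, strong_frac = 0.95) {
  if (is.null(snps)) snps <- seq_len(nrow(genotypes$snp_table))
  L <- length(snps)
  empty <- data.frame(start_idx = integer(0), end_idx = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0))
  if (L < 2L) return(empty)
  D <- genotypes$doses[, snps, drop = FALSE]
  status <- matrix(NA_character_, L, L)  # "strong" / "recomb" / NA
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      ci <- dprime_ci(D[, i], D[, j])
      if (is.null(ci)) next
      status[i, j] <- if (ci["low"] >= 0.70 && ci["high"] >= 0.98) "strong"
                      else if (ci["high"] < 0.90) "recomb"
                      else NA_character_
    }
  }
  cand <- list()
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      st <- status[i:j, i:j][upper.tri(diag(j - i + 1L))]
      inf <- st[!is.na(st)]
      if (length(inf) == 0L) next
      if (mean(inf == "strong") >= strong_frac)
        cand[[length(cand) + 1L]] <- c(i, j)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  span <- genotypes$snp_table$pos_bp[snps[cand[, 2]]] -
          genotypes$snp_table$pos_bp[snps[cand[, 1]]]
  cand <- cand[order(-span), , drop = FALSE]
  used <- logical(L)
  blocks <- list()
  for (k in seq_len(nrow(cand))) {
    rng <- cand[k, 1]:cand[k, 2]
    if (any(used[rng])) next
    used[rng] <- TRUE
    blocks[[length(blocks) + 1L]] <- data.frame(
      start_idx = cand[k, 1], end_idx = cand[k, 2],
      start_bp = genotypes$snp_table$pos_bp[snps[cand[k, 1]]],
      end_bp = genotypes$snp_table$pos_bp[snps[cand[k, 2]]],
      n_snps = length(rng))
  }
  out <- do.call(rbind, blocks)
  out[order(out$start_idx), , drop = FALSE]
}

#' Runs of homozygosity within a region
#'
#' Maximal runs of consecutive homozygous SNPs (dose 0 or 2) per sample,
#' reported when at least `min_run_snps` long.  Missing calls break runs.
#'
#' @param genotypes a [genotype_matrix()].
#' @param snps region SNP indices (default all).
#' @param min_run_snps minimum run length in SNPs (default 2).
#' @return data.frame: `sample_id`, `start_idx`, `end_idx` (within `snps`),
#'   `n_snps`, `start_bp`, `end_bp`.
#' @export
roh_in_region <- function(genotypes, snps = NULL, min_run_snps = 2L) {
  if (is.null(snps)) snps <- seq_len(nrow(genotypes$snp_table))
  D <- genotypes$doses[, snps, drop = FALSE]
  pos <- genotypes$snp_table$pos_bp[snps]
  res <- list()
  for (i in seq_len(nrow(D))) {
    hom <- !is.na(D[i, ]) & D[i, ] != 1L
    r <- rle(hom)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run_snps)) {
      res[[length(res) + 1L]] <- data.frame(
        sample_id = genotypes$sample_ids[i],
        start_idx = starts[k], end_idx = ends[k], n_snps = r$lengths[k],
        start_bp = pos[starts[k]], end_bp = pos[ends[k]])
    }
  }
  if (!length(res))
    return(data.frame(sample_id = character(0), start_idx = integer(0),
                      end_idx = integer(0), n_snps = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0)))
  do.call(rbind, res)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact p by the minimum-likelihood rule: with margins fixed, sum the
#' hypergeometric probabilities of all tables whose probability does not
#' exceed that of the observed table (within a 1e-7 relative tolerance).
#'
#' @param tbl 2x2 matrix of counts `rbind(c(a, b), c(c, d))`.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tbl) {
  tbl <- as.matrix(tbl)
  stopifnot(all(dim(tbl) == c(2L, 2L)), all(tbl >= 0))
  a <- tbl[1, 1]
  m1 <- sum(tbl[1, ]); m2 <- sum(tbl[2, ]); k <- sum(tbl[, 1])
  lo <- max(0, k - m2); hi <- min(k, m1)
  pr <- dhyper(lo:hi, m1, m2, k)
  p0 <- dhyper(a, m1, m2, k)
  min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
}

#' Case/control homozygosity contingency test
#'
#' A sample counts as homozygous when it is homozygous (dose 0 or 2) at
#' every SNP of `snp_set`; samples with a missing call there are excluded.
#' The 2x2 homozygous-by-status table is tested with the two-sided Fisher
#' exact test.
#'
#' @param genotypes a [genotype_matrix()].
#' @param snp_set SNP indices defining the homozygosity requirement.
#' @param phenotypes phenotype table for the genotyped samples.
#' @return list of class `"hom_test"`: `table` (cases/controls x hom/not),
#'   `odds_ratio`, `p`, and the per-cohort homozygosity proportions.
#' @export
homozygosity_test <- function(genotypes, snp_set, phenotypes) {
  D <- genotypes$doses[, snp_set, drop = FALSE]
  st <- phenotypes$status[match(genotypes$sample_ids, phenotypes$sample_id)]
  ok <- stats::complete.cases(D) & !is.na(st)
  if (!any(ok & st == "case") || !any(ok & st == "control"))
    stop("empty case or control cohort")
  hom <- rowSums(D[ok, , drop = FALSE] == 1L) == 0L
  stk <- st[ok]
  tbl <- rbind(cases = c(hom = sum(hom & stk == "case"),
                         not_hom = sum(!hom & stk == "case")),
               controls = c(hom = sum(hom & stk == "control"),
                            not_hom = sum(!hom & stk == "control")))
  or <- (tbl[1, 1] * tbl[2, 2]) / (tbl[1, 2] * tbl[2, 1])
  structure(list(table = tbl,
                 odds_ratio = or,
                 p = fisher_exact_2x2(tbl),
                 prop_cases = tbl[1, 1] / sum(tbl[1, ]),
                 prop_controls = tbl[2, 1] / sum(tbl[2, ])),
            class = "hom_test")
}

#' @export
print.hom_test <- function(x, ...) {
  print(x$table)
  cat(sprintf("homozygous: cases %.1f%% vs controls %.1f%%; OR = %.3f; Fisher two-sided p = %.4g\n",
              100 * x$prop_cases, 100 * x$prop_controls, x$odds_ratio, x$p))
  invisible(x)
}
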