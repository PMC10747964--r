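#' Minor-allele-frequency filter
#'
#' Removes SNPs whose minor allele frequency is strictly below the threshold
#' (so MAF exactly at the threshold is retained); monomorphic SNPs always
#' fall below any positive threshold.
#'
#' @param genotypes a [genotype_matrix()].
#' @param threshold MAF cutoff (default 0.02).
#' @return the filtered [genotype_matrix()]; the number of removed SNPs is
#'   reported and kept in attribute `"n_removed"`.
#' @export
filter_maf <- function(genotypes, threshold = 0.02) {
  f <- allele_freq(genotypes)
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf >= threshold
  if (!any(keep)) stop("all SNPs removed by the MAF filter")
  message(sprintf("filter_maf: removed %d of %d SNPs (MAF < %g)",
                  sum(!keep), length(keep), threshold))
  out <- subset_genotypes(genotypes, snps = keep)
  risk <- attr(genotypes, "risk")
  if (!is.null(risk)) {
    # re-map planted-risk indices onto the filtered SNP set
    new_pos <- match(risk$snp_idx, which(keep))
    risk$snp_idx <- new_pos[!is.na(new_pos)]
    risk$pattern <- risk$pattern[!is.na(new_pos)]
    attr(out, "risk") <- risk
  }
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Genetic relationship matrix from standardized doses
#'
#' `A[j,k] = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' with `p_i` the observed frequency of the counted allele; missing doses are
#' mean-imputed per SNP before standardization.
#'
#' @param genotypes post-MAF-filter [genotype_matrix()].
#' @return list of class `"grm"`: `A`, `sample_ids`, `p`, `m`.
#' @export
compute_grm <- function(genotypes) {
  X <- genotypes$doses
  p <- colMeans(X, na.rm = TRUE) / 2
  v <- 2 * p * (1 - p)
  if (any(v == 0 | is.na(v)))
    stop("zero-variance SNP reached the GRM; run filter_maf() first")
  if (anyNA(X)) {
    for (j in which(colSums(is.na(X)) > 0))
      X[is.na(X[, j]), j] <- 2 * p[j]
  }
  Z <- sweep(sweep(X, 2, 2 * p), 2, sqrt(v), "/")
  A <- tcrossprod(Z) / ncol(X)
  structure(list(A = A, sample_ids = genotypes$sample_ids,
                 p = p, m = ncol(X)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d samples from %d SNPs; mean diagonal %.3f\n",
              nrow(x$A), x$m, mean(diag(x$A))))
  invisible(x)
}

#' REML variance components under the null polygenic model
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sigma_g^2 A)`, `e ~ N(0, sigma_e^2 I)`
#' by restricted maximum likelihood.  The GRM is eigendecomposed once and the
#' restricted log-likelihood is profiled over the ratio
#' `delta = sigma_e^2 / sigma_g^2` on a log-spaced grid followed by
#' golden-section refinement.  A case/control phenotype is analysed on the
#' observed 0/1 scale.  When the likelihood is flat in `delta` (e.g. `A`
#' numerically proportional to the identity) the boundary convention
#' `sigma_g^2 = 0` is returned.  Negative GRM eigenvalues are floored at zero
#' with a warning.
#'
#' @param phenotype numeric vector (0/1 control/case, or quantitative).
#' @param grm a [compute_grm()] result (or a plain symmetric matrix).
#' @param covariates optional covariate matrix; an intercept is always added.
#' @return list of class `"varcomp"`: `sigma_g2`, `sigma_e2`, `delta`, `h2`,
#'   `loglik`, plus the eigendecomposition for reuse by [mlma_scan()].
#' @export
reml_null <- function(phenotype, grm, covariates = NULL) {
  A <- if (inherits(grm, "grm")) grm$A else as.matrix(grm)
  y <- as.numeric(phenotype)
  n <- length(y)
  stopifnot(nrow(A) == n)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  p <- ncol(X)
  eig <- eigen(A, symmetric = TRUE)
  if (any(eig$values < -1e-8))
    warning("GRM has negative eigenvalues; floored at 0")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  ldXX <- determinant(crossprod(X), logarithm = TRUE)$modulus

  restricted_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xs * w, Xs)
    XtWy <- crossprod(Xs * w, ys)
    bhat <- solve(XtWX, XtWy)
    r <- ys - Xs %*% bhat
    rss <- sum(w * r^2)
    sg2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * sg2) + sum(log(d + delta)) +
            determinant(XtWX, logarithm = TRUE)$modulus - ldXX + (n - p))
  }

  grid <- seq(log(1e-5), log(1e5), length.out = 80)
  ll <- vapply(grid, restricted_ll, numeric(1))
  flat <- (max(ll) - min(ll)) < 1e-6
  if (flat || which.max(ll) == length(grid)) {
    # unidentifiable or boundary: no genetic variance
    r <- stats::lm.fit(X, y)$residuals
    out <- list(sigma_g2 = 0, sigma_e2 = sum(r^2) / (n - p), delta = Inf,
                h2 = 0, loglik = max(ll),
                eigen = list(values = d, vectors = U), X = X,
                boundary = TRUE)
    class(out) <- "varcomp"
    return(out)
  }
  i0 <- which.max(ll)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(restricted_ll, c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  delta <- exp(opt$maximum)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xs * w, Xs)
  bhat <- solve(XtWX, crossprod(Xs * w, ys))
  r <- ys - Xs %*% bhat
  sg2 <- sum(w * r^2) / (n - p)
  out <- list(sigma_g2 = sg2, sigma_e2 = delta * sg2, delta = delta,
              h2 = sg2 / (sg2 + delta * sg2),
              loglik = opt$objective,
              eigen = list(values = d, vectors = U), X = X,
              boundary = FALSE)
  class(out) <- "varcomp"
  out
}

#' @export
print.varcomp <- function(x, ...) {
  cat("REML polygenic null model\n")
  cat(sprintf("  sigma_g^2 = %.5f  sigma_e^2 = %.5f  h2 = %.3f%s\n",
              x$sigma_g2, x$sigma_e2, x$h2,
              if (isTRUE(x$boundary)) "  [boundary: no genetic variance]" else ""))
  cat(sprintf("  restricted log-likelihood %.3f\n", x$loglik))
  invisible(x)
}

#' Mixed-linear-model association scan
#'
#' EMMAX-style scan: variance components are fixed from the null model and
#' each SNP is tested by generalized least squares against
#' `V = sigma_g^2 A + sigma_e^2 I`, computed in the eigenbasis of the GRM so
#' each SNP costs O(n) after one rotation.  The candidate SNP remains in the
#' GRM (no leave-one-chromosome-out).  The effect allele is the minor allele
#' in the analysed sample (doses are flipped where needed and the counted
#' allele recorded).  The Wald chi-square(1) test is two-sided.  SNPs
#' collinear with the covariates get `NA` statistics with a message.
#'
#' @param genotypes filtered [genotype_matrix()].
#' @param phenotype numeric vector aligned with the samples.
#' @param grm the [compute_grm()] result used for the null model.
#' @param vc the [reml_null()] fit.
#' @param covariates optional covariate matrix (intercept always included).
#' @return data.frame of class `"assoc_table"`: `snp_id`, `chrom`, `pos_bp`,
#'   `counted_allele`, `freq`, `b`, `se`, `wald`, `p` (q-value columns are
#'   added by [add_qvalues()]).
#' @export
mlma_scan <- function(genotypes, phenotype, grm, vc, covariates = NULL) {
  stopifnot(inherits(vc, "varcomp"))
  y <- as.numeric(phenotype)
  X <- cbind(rep(1, length(y)), covariates)
  n <- length(y)
  G <- genotypes$doses
  if (anyNA(G)) {
    pm <- colMeans(G, na.rm = TRUE)
    for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- pm[j]
  }
  freq <- colMeans(G) / 2
  flip <- freq > 0.5
  G[, flip] <- 2 - G[, flip]
  freq[flip] <- 1 - freq[flip]
  counted <- ifelse(flip, genotypes$snp_table$allele_A, genotypes$snp_table$allele_B)

  U <- vc$eigen$vectors; dvals <- vc$eigen$values
  v <- vc$sigma_g2 * dvals + vc$sigma_e2
  w <- 1 / v
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  Gs <- crossprod(U, G)
  # residualize y and G on covariates under weights w
  sw <- sqrt(w)
  qrX <- qr(Xs * sw)
  ry <- qr.resid(qrX, ys * sw)          # in the whitened basis
  RG <- qr.resid(qrX, Gs * sw)
  sxx <- colSums(RG^2)
  sxy <- colSums(RG * as.vector(ry))
  ok <- sxx > 1e-10
  if (any(!ok))
    message("mlma_scan: ", sum(!ok), " SNP(s) collinear with covariates; p set missing")
  b <- se <- rep(NA_real_, ncol(G))
  b[ok] <- sxy[ok] / sxx[ok]
  se[ok] <- sqrt(1 / sxx[ok])
  wald <- (b / se)^2
  pval <- pchisq(wald, df = 1, lower.tail = FALSE)
  out <- data.frame(snp_id = genotypes$snp_table$snp_id,
                    chrom = genotypes$snp_table$chrom,
                    pos_bp = genotypes$snp_table$pos_bp,
                    counted_allele = counted, freq = freq,
                    b = b, se = se, wald = wald, p = pval,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' One-call mixed-model GWAS
#'
#' MAF filter, GRM, null REML, EMMAX scan and Storey q-values (genome-wide
#' and chromosome-wise) in one step.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes phenotype table aligned with (a superset of) the
#'   samples; status is analysed as 0/1.
#' @param maf MAF threshold (default 0.02).
#' @param covariates optional covariate matrix.
#' @param samples optional subset of sample ids (e.g. from
#'   [subset_young_onset()]).
#' @return list of class `"mlma_gwas"`: `assoc` (with q-value columns),
#'   `vc`, `grm`, `n_samples`.
#' @export
mlma_gwas <- function(genotypes, phenotypes, maf = 0.02, covariates = NULL,
                      samples = NULL) {
  if (!is.null(samples)) genotypes <- subset_genotypes(genotypes, samples = samples)
  keep <- match(genotypes$sample_ids, phenotypes$sample_id)
  if (anyNA(keep)) stop("phenotypes missing for some genotyped samples")
  y <- as.integer(phenotypes$status[keep] == "case")
  g <- filter_maf(genotypes, maf)
  grm <- compute_grm(g)
  vc <- reml_null(y, grm, covariates)
  assoc <- mlma_scan(g, y, grm, vc, covariates)
  assoc <- add_qvalues(assoc)
  structure(list(assoc = assoc, vc = vc, grm = grm,
                 n_samples = length(y), n_cases = sum(y)),
            class = "mlma_gwas")
}

#' @export
print.mlma_gwas <- function(x, ...) {
  cat(sprintf("Mixed-model GWAS: %d samples (%d cases), %d SNPs\n",
              x$n_samples, x$n_cases, nrow(x$assoc)))
  print(x$vc)
  top <- x$assoc[order(x$assoc$p), ][1:min(5, nrow(x$assoc)), ]
  cat("top SNPs:\n")
  print(top[, c("snp_id", "chrom", "pos_bp", "b", "se", "p", "q_genome", "q_chrom")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.mlma_gwas <- function(object, q_threshold = 0.05, ...) {
  a <- object$assoc
  cat(sprintf("SNPs with genome-wide q < %g: %d; chromosome-wise q < %g: %d\n",
              q_threshold, sum(a$q_genome < q_threshold, na.rm = TRUE),
              q_threshold, sum(a$q_chrom < q_threshold, na.rm = TRUE)))
  invisible(a[which(a$q_chrom < q_threshold), ])
}

#' Manhattan-plot data export
#'
#' @param assoc an `"assoc_table"`.
#' @return data.frame with `chrom`, `pos_bp`, cumulative genome position and
#'   `neglog10p`, ready for plotting.
#' @export
manhattan_data <- function(assoc) {
  a <- assoc[order(assoc$chrom, assoc$pos_bp), ]
  offs <- c(0, cumsum(tapply(a$pos_bp, a$chrom, max)))
  names(offs) <- NULL
  chrom_f <- as.integer(factor(a$chrom, levels = unique(a$chrom)))
  data.frame(chrom = a$chrom, pos_bp = a$pos_bp,
             cum_pos = a$pos_bp + offs[chrom_f],
             neglog10p = -log10(a$p))
}

#' Plot an association scan
#' @param x an `"assoc_table"`.
#' @param q_lines draw -log10 thresholds at the p corresponding to these
#'   genome-wide q cutoffs (default 0.01 and 0.05).
#' @param ... passed to `plot`.
#' @export
plot.assoc_table <- function(x, q_lines = c(0.01, 0.05), ...) {
  md <- manhattan_data(x)
  cf <- as.integer(factor(md$chrom, levels = unique(md$chrom)))
  graphics::plot(md$cum_pos, md$neglog10p, pch = 20, cex = 0.5,
                 col = c("grey30", "steelblue")[cf %% 2 + 1],
                 xlab = "genome position", ylab = expression(-log[10](p)), ...)
  if (!is.null(x$q_genome) && length(q_lines)) {
    for (i in seq_along(q_lines)) {
      sig <- x$p[x$q_genome <= q_lines[i]]
      if (length(sig))
        graphics::abline(h = -log10(max(sig)), col = c("blue", "red")[i], lty = 2)
    }
  }
  invisible(md)
}

#' Select the young-onset sub-study samples
#'
#' Retains cases diagnosed at `case_max_age` years or less and controls
#' strictly older than `control_min_age` years.  Samples with missing age are
#' dropped (reported); an empty case or control set is an error.
#'
#' @param phenotypes a phenotype table with `age_years`.
#' @param case_max_age inclusive case age cutoff (default 6).
#' @param control_min_age exclusive control age floor (default 7).
#' @return character vector of retained sample ids, with counts reported.
#' @export
subset_young_onset <- function(phenotypes, case_max_age = 6, control_min_age = 7) {
  ph <- as.data.frame(phenotypes)
  has_age <- !is.na(ph$age_years)
  if (!any(has_age)) stop("no samples with recorded age")
  if (any(!has_age))
    message("subset_young_onset: dropped ", sum(!has_age), " samples with missing age")
  ph <- ph[has_age, ]
  cases <- ph$sample_id[ph$status == "case" & ph$age_years <= case_max_age]
  controls <- ph$sample_id[ph$status == "control" & ph$age_years > control_min_age]
  if (length(cases) == 0L) stop("young-onset subset has no cases")
  if (length(controls) == 0L) stop("young-onset subset has no controls")
  message(sprintf("subset_young_onset: %d cases (age <= %g), %d controls (age > %g)",
                  length(cases), case_max_age, length(controls), control_min_age))
  c(cases, controls)
}
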