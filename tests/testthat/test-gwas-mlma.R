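test_that("MAF filter applies a strict less-than rule", {
  # 50 samples; SNP1 has 5/100 = 0.05 counted alleles, SNP2 has 4/100 = 0.04
  d <- matrix(0L, 50, 3)
  d[1:5, 1] <- 1L
  d[1:4, 2] <- 1L
  d[1:25, 3] <- 2L   # freq 0.5
  g <- make_geno(d)
  out <- suppressMessages(filter_maf(g, threshold = 0.05))
  expect_identical(out$snp_table$snp_id, c("s001", "s003"))
  # monomorphic SNPs always drop for positive thresholds
  gm <- make_geno(cbind(rep(0L, 10), rep(1L, 10)))
  out2 <- suppressMessages(filter_maf(gm, 0.02))
  expect_equal(ncol(out2$doses), 1L)
  # threshold 0 is the identity
  expect_equal(ncol(suppressMessages(filter_maf(g, 0))$doses), 3L)
  expect_error(suppressMessages(filter_maf(make_geno(cbind(rep(0L, 10))), 0.02)),
               "all SNPs removed")
})

test_that("GRM matches the standardized-dose formula", {
  g <- make_geno(rbind(2L, 0L))        # one SNP, p = 0.5
  A <- compute_grm(g)$A
  expect_equal(A[1, 2], -2)            # (2-1)(0-1)/(2*0.25)
  expect_equal(A[1, 1], 2)
  g2 <- make_geno(rbind(1L, 1L))       # dose 1, p = 0.5 -> standardized 0
  expect_equal(unname(compute_grm(g2)$A), matrix(0, 2, 2))
  expect_error(compute_grm(make_geno(rbind(2L, 2L))), "zero-variance")
  # HWE panel: mean diagonal near 1
  set.seed(4)
  p <- runif(3000, 0.1, 0.9)
  d <- vapply(p, function(pp) rbinom(60, 2, pp), integer(60))
  A2 <- compute_grm(make_geno(d))$A
  expect_lt(abs(mean(diag(A2)) - 1), 0.05)
  # permutation equivariance
  g3 <- make_geno(d[, 1:300])
  perm <- sample(60)
  A3 <- compute_grm(g3)$A
  A3p <- compute_grm(subset_genotypes(g3, samples = perm))$A
  expect_equal(unname(A3p), unname(A3[perm, perm]))
})

test_that("null REML recovers heritability extremes and boundary cases", {
  cfg <- nold_config(seed = 17)
  g <- gene_drop(simulate_pedigree(cfg), cfg)
  grm <- compute_grm(suppressMessages(filter_maf(g)))
  n <- nrow(grm$A)
  # permuted phenotype: no genetic signal
  set.seed(2)
  y <- rbinom(n, 1, 0.15)
  h2 <- replicate(20, reml_null(sample(y), grm)$h2)
  expect_lt(median(h2), 0.1)
  # phenotype built from the lead eigenvector: h2 near 1
  eg <- eigen(grm$A, symmetric = TRUE)
  set.seed(3)
  y1 <- sqrt(eg$values[1]) * eg$vectors[, 1] + rnorm(n, sd = 0.01)
  expect_gt(reml_null(y1, grm)$h2, 0.9)
  # identity GRM: unidentifiable, documented sigma_g2 = 0 convention
  vc_id <- reml_null(y, diag(n))
  expect_equal(vc_id$sigma_g2, 0)
  expect_true(vc_id$boundary)
})

test_that("MLMA reduces to ordinary least squares when sigma_g2 = 0", {
  cfg <- nold_config(seed = 19)
  g <- gene_drop(simulate_pedigree(cfg), cfg)
  gf <- suppressMessages(filter_maf(g))
  grm <- compute_grm(gf)
  set.seed(5)
  y <- rbinom(nrow(grm$A), 1, 0.2)
  vc <- reml_null(y, grm)
  vc0 <- vc; vc0$sigma_g2 <- 0; vc0$sigma_e2 <- stats::var(y)
  a <- mlma_scan(gf, y, grm, vc0)
  # independent OLS route: lm() effects + known-variance Wald
  X <- gf$doses
  f <- colMeans(X) / 2; X[, f > 0.5] <- 2L - X[, f > 0.5]
  for (j in seq(1, ncol(X), by = 37)) {
    fit <- lm(y ~ X[, j])
    b_ols <- unname(coef(fit)[2])
    se_ols <- sqrt(vc0$sigma_e2 * solve(crossprod(cbind(1, X[, j])))[2, 2])
    p_ols <- pchisq((b_ols / se_ols)^2, 1, lower.tail = FALSE)
    expect_equal(a$b[j], b_ols, tolerance = 1e-8)
    expect_equal(a$p[j], p_ols, tolerance = 1e-8)
  }
})

test_that("association p-values are calibrated under the null", {
  cfg <- nold_config(seed = 23)
  g <- gene_drop(simulate_pedigree(cfg), cfg)
  # uniformity under the model's own polygenic null, common variants, and no
  # more test SNPs than samples (keeps the KS resolution above the shared
  # REML-scale jitter; rare-variant conservatism is a documented feature)
  gfc <- suppressMessages(filter_maf(g, 0.1))
  gfc <- subset_genotypes(gfc, snps = seq_len(min(300L, ncol(gfc$doses))))
  grmc <- compute_grm(gfc)
  eg <- eigen(grmc$A, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(0.3 * pmax(eg$values, 0) + 0.7))
  set.seed(11)
  ks <- replicate(20, {
    yn <- as.vector(L %*% rnorm(nrow(grmc$A)))
    a <- mlma_scan(gfc, yn, grmc, reml_null(yn, grmc))
    suppressWarnings(stats::ks.test(a$p, "punif")$p.value)
  })
  expect_gte(mean(ks > 0.01), 0.95)
  # permutation type-I error of the binary-trait scan at nominal 0.05,
  # over the full MAF spectrum
  gf <- suppressMessages(filter_maf(g))
  grm <- compute_grm(gf)
  set.seed(12)
  y <- rbinom(nrow(grm$A), 1, 0.15)
  rej <- replicate(10, {
    yp <- sample(y)
    vc <- reml_null(yp, grm)
    mean(mlma_scan(gf, yp, grm, vc)$p < 0.05, na.rm = TRUE)
  })
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
})

test_that("association statistics are invariant to affine phenotype rescaling", {
  cfg <- tiny_config(seed = 29)
  g <- gene_drop(simulate_pedigree(cfg), cfg)
  gf <- suppressMessages(filter_maf(g))
  grm <- compute_grm(gf)
  set.seed(7)
  y <- rnorm(nrow(grm$A)) + 0.3 * grm$A[, 1]
  a1 <- mlma_scan(gf, y, grm, reml_null(y, grm))
  y2 <- 3 * y + 5
  a2 <- mlma_scan(gf, y2, grm, reml_null(y2, grm))
  expect_equal(a2$p, a1$p, tolerance = 1e-6)
  expect_equal(a2$b, 3 * a1$b, tolerance = 1e-6)
})

test_that("planted recessive locus is the top association signal", {
  b <- simulate_cohort(sim_config(seed = 101))
  gw <- suppressMessages(mlma_gwas(b$genotypes, b$phenotypes))
  top <- gw$assoc[which.min(gw$assoc$p), ]
  risk <- attr(b$genotypes, "risk")
  span <- b$genotypes$snp_table$pos_bp[risk$snp_idx]
  expect_equal(top$chrom, risk$chrom)
  expect_gte(top$pos_bp, min(span) - 250000)
  expect_lte(top$pos_bp, max(span) + 250000)
  # and it reaches chromosome-wise significance
  expect_lt(top$q_chrom, 0.01)
})

test_that("young-onset subset applies the age cutoffs exactly", {
  ph <- data.frame(sample_id = sprintf("S%d", 1:6),
                   status = c("case", "case", "case", "control", "control", "control"),
                   age_years = c(6.0, 6.5, NA, 7.0, 7.5, 9))
  ids <- suppressMessages(subset_young_onset(ph))
  expect_true("S1" %in% ids)    # case aged exactly 6 retained
  expect_false("S2" %in% ids)   # case older than 6 dropped
  expect_false("S3" %in% ids)   # missing age dropped
  expect_false("S4" %in% ids)   # control aged exactly 7 excluded (strictly above)
  expect_true(all(c("S5", "S6") %in% ids))
  ph$age_years <- NA_real_
  expect_error(subset_young_onset(ph), "no samples with recorded age")
  ph2 <- data.frame(sample_id = "S1", status = "case", age_years = 5)
  expect_error(suppressMessages(subset_young_onset(ph2)), "no controls")
})
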