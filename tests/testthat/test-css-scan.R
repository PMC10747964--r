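test_that("Weir-Cockerham theta behaves at the calibration points", {
  set.seed(2)
  # identical frequencies, large n: theta near 0
  d1 <- vapply(runif(300, 0.3, 0.7), function(p) rbinom(150, 2, p), integer(150))
  d2 <- vapply(colMeans(d1) / 2, function(p) rbinom(150, 2, p), integer(150))
  th <- fst_per_snp(make_geno(d1), make_geno(d2))
  expect_lt(abs(mean(th, na.rm = TRUE)), 0.01)
  # fixed difference: theta = 1
  gA <- make_geno(matrix(2L, 20, 1)); gB <- make_geno(matrix(0L, 20, 1))
  expect_equal(fst_per_snp(gA, gB), 1)
  # monomorphic in both for the same allele: invalid
  expect_true(is.na(fst_per_snp(gA, make_geno(matrix(2L, 20, 1)))))
  # pooling and random splitting: mean theta about 0
  pool <- rbind(d1, d2)
  idx <- sample(nrow(pool))
  thp <- fst_per_snp(make_geno(pool[idx[1:150], ]), make_geno(pool[idx[151:300], ]))
  expect_lt(abs(mean(thp, na.rm = TRUE)), 0.01)
})

test_that("delta-DAF is signed, bounded and flips with the ancestral call", {
  snp <- make_geno(matrix(0L, 2, 3))$snp_table
  tf <- c(0.9, 0.4, 0.5); rf <- c(0.1, 0.4, 0.5)
  anc <- c("A", "A", "B")
  dd <- delta_daf(tf, rf, anc, snp)
  expect_equal(dd, c(0.8, 0, 0))
  # flipping the ancestral allele negates the statistic
  dd2 <- delta_daf(tf, rf, c("B", "B", "A"), snp)
  expect_equal(dd2, -dd)
  # ancestral matching neither allele -> invalid
  expect_true(is.na(delta_daf(0.5, 0.2, "T", snp[1, ])))
})

test_that("EHH equals the exhaustive pair-counting oracle", {
  set.seed(6)
  H <- matrix(rbinom(30 * 15, 1, 0.5), 30, 15)
  pos <- seq(1000, by = 1000, length.out = 15)
  for (core in c(4L, 8L)) {
    for (dir in c("left", "right")) {
      curve <- ehh_curve(H, pos, core, dir, min_ehh = 0)
      expect_equal(curve$ehh[1], 1)           # defined as 1 at the core
      for (r in seq_len(nrow(curve))[-1]) {
        expect_equal(curve$ehh[r], ehh_oracle(H, core, curve$snp[r]),
                     tolerance = 1e-12)
      }
    }
  }
  # identical haplotypes: EHH stays 1 to the chromosome end
  H1 <- matrix(rep(c(0, 1, 0, 1, 1), each = 10), 10, 5)
  c1 <- ehh_curve(H1, pos[1:5], 3, "right")
  expect_true(all(c1$ehh == 1))
  # the two haplotypes differ at the adjacent SNP: EHH drops to 0 there
  H2 <- rbind(c(0L, 0L, 1L), c(0L, 1L, 1L))
  c2 <- ehh_curve(H2, pos[1:3], 1, "right")
  expect_equal(c2$ehh[c2$snp == 2], 0)
  expect_error(ehh_curve(H[1, , drop = FALSE], pos, 1, "right"), "2 haplotypes")
})

test_that("XP-EHH is zero for identical populations and positive under a sweep", {
  set.seed(9)
  H <- matrix(rbinom(40 * 21, 1, 0.5), 40, 21)
  pos <- seq(1e4, by = 1e4, length.out = 21)
  r0 <- xpehh_core(H, H, pos, 11)
  expect_equal(r0$raw, 0)
  # target fixed for one long haplotype around the core: raw > 0
  sweep_hap <- rbinom(21, 1, 0.5)
  Ht <- matrix(rep(sweep_hap, each = 30), 30, 21)
  Ht[1:5, ] <- H[1:5, ]                      # a little diversity
  r1 <- xpehh_core(Ht, H, pos, 11)
  expect_gt(r1$raw, 0)
})

test_that("standardized XP-EHH has mean 0 and unit sd over valid SNPs", {
  cfg <- sim_config(n_chromosomes = 4, snps_per_chromosome = 300,
                    risk_chromosome = 1, risk_span = c(47, 54), seed = 33,
                    n_ref_breeds = 5, n_ref_per_breed = 30)
  b <- simulate_cohort(cfg)
  sub <- subset_genotypes(b$genotypes, samples = 1:60)
  sc <- xpehh_scan(sub, b$panel)
  valid <- !is.na(sc$xpehh_std)
  expect_gt(sum(valid), 1000)
  expect_lt(abs(mean(sc$xpehh_std[valid])), 0.05)
  expect_lt(abs(sd(sc$xpehh_std[valid]) - 1), 0.05)
})

test_that("composite CSS reproduces its closed forms", {
  n <- 999
  set.seed(10)
  comp <- data.frame(snp_id = sprintf("s%d", 1:n), chrom = 1, pos_bp = 1:n,
                     fst = runif(n), ddaf = runif(n), xpehh_std = runif(n))
  # plant a SNP at the top of every component
  comp[n, c("fst", "ddaf", "xpehh_std")] <- 2
  tb <- composite_css(comp)
  expect_equal(tb$css[n], -log10(1 - pnorm(sqrt(3) * qnorm(0.999))),
               tolerance = 1e-10)
  # median rank in all components: p = 0.5
  comp3 <- data.frame(snp_id = c("a", "b", "c"), chrom = 1, pos_bp = 1:3,
                      fst = c(1, 2, 3), ddaf = c(1, 2, 3), xpehh_std = c(1, 2, 3))
  tb3 <- composite_css(comp3)
  expect_equal(tb3$rank_fst, c(0.25, 0.5, 0.75))
  expect_equal(tb3$p[2], 0.5)
  expect_equal(tb3$css[2], -log10(0.5), tolerance = 1e-12)
})

test_that("components missing at a SNP reduce m instead of killing the score", {
  comp <- data.frame(snp_id = c("a", "b", "c", "d"), chrom = 1, pos_bp = 1:4,
                     fst = c(0.1, 0.2, 0.3, 0.4),
                     ddaf = c(NA, 0.1, 0.2, 0.3),
                     xpehh_std = NA_real_)
  tb <- composite_css(comp)
  expect_equal(tb$m, c(1, 2, 2, 2))
  expect_false(any(is.na(tb$css)))
  tb_none <- composite_css(data.frame(snp_id = "a", chrom = 1, pos_bp = 1,
                                      fst = NA_real_, ddaf = NA_real_,
                                      xpehh_std = NA_real_))
  expect_true(is.na(tb_none$css))
})

test_that("CSS is invariant under monotone transformation of components", {
  set.seed(12)
  n <- 200
  comp <- data.frame(snp_id = sprintf("s%d", 1:n), chrom = 1, pos_bp = 1:n,
                     fst = rnorm(n), ddaf = rnorm(n), xpehh_std = rnorm(n))
  t1 <- composite_css(comp)
  comp2 <- comp
  comp2$fst <- exp(comp$fst)
  comp2$ddaf <- comp$ddaf^3
  comp2$xpehh_std <- atan(comp$xpehh_std)
  t2 <- composite_css(comp2)
  expect_equal(t2$css, t1$css, tolerance = 1e-12)
})

test_that("composite p-values are uniform under the independent-component null", {
  set.seed(14)
  ks <- replicate(20, {
    n <- 1000
    comp <- data.frame(snp_id = sprintf("s%d", 1:n), chrom = 1, pos_bp = 1:n,
                       fst = rnorm(n), ddaf = rnorm(n), xpehh_std = rnorm(n))
    suppressWarnings(stats::ks.test(composite_css(comp)$p, "punif")$p.value)
  })
  expect_gte(mean(ks > 0.01), 0.95)
})

test_that("window smoothing equals the brute-force window mean", {
  set.seed(15)
  n <- 400
  tb <- data.frame(snp_id = sprintf("s%d", 1:n), chrom = rep(1:2, each = n / 2),
                   pos_bp = rep(sort(sample(1:5e6, n / 2)), 2),
                   css = runif(n))
  class(tb) <- c("css_table", "data.frame")
  sm <- smooth_css(tb, window_bp = 1e6)
  for (i in sample(n, 60)) {
    sel <- tb$chrom == tb$chrom[i] & abs(tb$pos_bp - tb$pos_bp[i]) <= 5e5
    expect_equal(sm$css_smoothed[i], mean(tb$css[sel]), tolerance = 1e-12)
  }
  # constant input is unchanged; isolated SNP keeps its own value
  tb2 <- data.frame(snp_id = c("a", "b"), chrom = c(1, 1),
                    pos_bp = c(1, 5e6), css = c(0.7, 0.2))
  sm2 <- smooth_css(tb2, 1e6)
  expect_equal(sm2$css_smoothed, c(0.7, 0.2))
})

test_that("significant regions respect the quantile bound and grouping rules", {
  set.seed(16)
  n <- 10000
  tb <- data.frame(snp_id = sprintf("s%d", 1:n), chrom = rep(1:10, each = n / 10),
                   pos_bp = rep(seq(1e4, by = 1e4, length.out = n / 10), 10),
                   css = runif(n))
  tb$css_smoothed <- tb$css       # test the thresholding in isolation
  class(tb) <- c("css_table", "data.frame")
  sr <- significant_regions(tb, 0.995)
  expect_lte(mean(sr$css$significant), 0.005)
  # two runs separated by a gap give two regions
  tb2 <- data.frame(snp_id = sprintf("s%d", 1:5), chrom = 1,
                    pos_bp = (1:5) * 1000, css = 0,
                    css_smoothed = c(9, 9, 0, 9, 0))
  sr2 <- significant_regions(structure(tb2, class = c("css_table", "data.frame")),
                             quantile = 0.4)
  expect_equal(nrow(sr2$regions), 2)
  expect_equal(sr2$regions$n_snps, c(2, 1))
  expect_equal(sr2$regions$regional_css, c(9, 9))
})

test_that("the full scan flags the planted sweep region", {
  b <- simulate_cohort(sim_config(seed = 77))
  cases <- b$phenotypes$sample_id[b$phenotypes$status == "case"]
  sc <- suppressMessages(css_scan(subset_genotypes(b$genotypes, samples = cases),
                                  b$panel))
  risk <- attr(b$genotypes, "risk")
  expect_true(any(sc$css$significant[risk$snp_idx]))
  expect_lte(mean(sc$css$significant, na.rm = TRUE), 0.005)
  expect_true(all(sc$regions$n_snps >= 1))
})
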