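test_that("sliding window enumeration matches the closed form", {
  w8 <- sliding_windows(8)
  expect_equal(nrow(w8), sum(8 - (2:8) + 1))       # 28
  expect_equal(nrow(sliding_windows(10)), 42)
  w2 <- sliding_windows(2)
  expect_equal(nrow(w2), 1)
  expect_equal(w2$width, 2)
  expect_warning(out <- sliding_windows(1), "no windows")
  expect_equal(nrow(out), 0)
  # all widths within [2, 8] and windows inside the map
  expect_true(all(w8$width >= 2 & w8$width <= 8))
  expect_true(all(w8$start + w8$width - 1 <= 8))
})

test_that("phased haplotype window counts are direct string tallies", {
  h1 <- rbind(c(0L, 0L), c(1L, 1L), c(0L, 1L))
  h2 <- rbind(c(0L, 1L), c(1L, 1L), c(0L, 1L))
  g <- make_phased(h1, h2)
  ph <- make_pheno(g, c("case", "control", "control"))
  hw <- window_haplotype_freqs(g, c(1, 2), ph)
  expect_setequal(hw$haplotype, c("AA", "AB", "BB"))
  expect_equal(sum(hw$case), 2)            # counts conserve 2N per cohort
  expect_equal(sum(hw$control), 4)
  expect_equal(hw$control[hw$haplotype == "BB"], 2)
  expect_equal(hw$case[hw$haplotype == "AA"], 1)
})

test_that("EM phasing splits the unidentifiable double heterozygote evenly", {
  g <- make_geno(matrix(c(1L, 1L), 1, 2))
  ph <- make_pheno(g, "case")
  hw <- window_haplotype_freqs(g, c(1, 2), ph, use_phase = FALSE)
  expect_equal(sort(hw$case), c(0.5, 0.5, 0.5, 0.5))
})

test_that("EM recovers known haplotype frequencies from unphased doses", {
  set.seed(19)
  haps <- rbind(c(0, 0, 0), c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  freq <- c(0.4, 0.3, 0.2, 0.1)
  n <- 200
  pick <- function() haps[sample.int(4, 1, prob = freq), ]
  h1 <- t(replicate(n, pick())); h2 <- t(replicate(n, pick()))
  g <- make_geno(h1 + h2)
  ph <- make_pheno(g, rep("control", n))
  hw <- window_haplotype_freqs(g, c(1, 3), ph, use_phase = FALSE)
  est <- hw$control / (2 * n)
  names(est) <- hw$haplotype
  truth <- setNames(freq, apply(haps, 1, function(r)
    paste(ifelse(r == 1, "B", "A"), collapse = "")))
  for (h in names(truth))
    expect_lt(abs(est[[h]] - truth[[h]]), 0.05)
})

test_that("Gabriel-style blocks find perfect LD and reject independence", {
  set.seed(23)
  # two complementary haplotypes: every pair in perfect LD
  hap <- rbind(rep(0L, 5), rep(1L, 5))
  h1 <- hap[sample(1:2, 60, replace = TRUE), ]
  h2 <- hap[sample(1:2, 60, replace = TRUE), ]
  g <- make_geno(h1 + h2)
  blocks <- haplotype_blocks(g)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$start_idx, 1)
  expect_equal(blocks$end_idx, 5)
  # independent SNPs: no blocks
  d <- vapply(rep(0.5, 5), function(p) rbinom(80, 2, p), integer(80))
  expect_equal(nrow(haplotype_blocks(make_geno(d))), 0)
  # single SNP: no blocks
  expect_equal(nrow(haplotype_blocks(make_geno(d[, 1, drop = FALSE]))), 0)
})

test_that("ROH scanning matches a brute-force re-scan", {
  set.seed(29)
  d <- matrix(sample(c(0L, 1L, 2L, NA), 25 * 40, replace = TRUE,
                     prob = c(0.4, 0.25, 0.3, 0.05)), 25, 40)
  g <- make_geno(d)
  roh <- roh_in_region(g, min_run_snps = 3)
  brute <- list()
  for (i in 1:25) {
    run <- 0L
    for (j in 1:41) {
      hom <- j <= 40 && !is.na(d[i, j]) && d[i, j] != 1L
      if (hom) run <- run + 1L
      else {
        if (run >= 3L)
          brute[[length(brute) + 1L]] <- c(i, j - run, j - 1L, run)
        run <- 0L
      }
    }
  }
  brute <- do.call(rbind, brute)
  expect_equal(nrow(roh), nrow(brute))
  expect_equal(match(roh$sample_id, g$sample_ids), brute[, 1])
  expect_equal(roh$start_idx, brute[, 2])
  expect_equal(roh$end_idx, brute[, 3])
  # degenerate samples
  expect_equal(nrow(roh_in_region(make_geno(matrix(1L, 1, 10)), min_run_snps = 1)), 0)
  all_hom <- roh_in_region(make_geno(matrix(2L, 1, 10)), min_run_snps = 1)
  expect_equal(all_hom$n_snps, 10)
})

test_that("Fisher exact p matches the hypergeometric enumeration oracle", {
  tables <- list(rbind(c(3, 20), c(52, 36)),
                 rbind(c(5, 5), c(5, 5)),
                 rbind(c(0, 10), c(10, 0)),
                 rbind(c(2, 1), c(3, 9)),
                 rbind(c(7, 0), c(1, 4)))
  for (tb in tables) {
    expect_equal(fisher_exact_2x2(tb), fisher_oracle(tb), tolerance = 1e-12)
    # symmetry under swapping the cohort rows
    expect_equal(fisher_exact_2x2(tb[2:1, ]), fisher_exact_2x2(tb),
                 tolerance = 1e-12)
    # agreement with the reference implementation
    expect_equal(fisher_exact_2x2(tb), fisher.test(tb)$p.value,
                 tolerance = 1e-9)
  }
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5))), 1)
})

test_that("homozygosity test counts joint homozygotes and applies Fisher", {
  # 4 cases: 1 homozygous at both SNPs; 5 controls: 4 homozygous
  d <- rbind(c(0L, 2L),  # case hom
             c(1L, 2L), c(0L, 1L), c(1L, 1L),          # cases not hom
             c(2L, 2L), c(0L, 0L), c(2L, 0L), c(0L, 2L),  # controls hom
             c(NA, 2L))                                 # control, missing -> excluded
  g <- make_geno(d)
  ph <- make_pheno(g, c(rep("case", 4), rep("control", 5)))
  ht <- homozygosity_test(g, 1:2, ph)
  expect_equal(unname(ht$table["cases", ]), c(1, 3))
  expect_equal(unname(ht$table["controls", ]), c(4, 0))
  expect_equal(ht$p, fisher_oracle(ht$table), tolerance = 1e-12)
  expect_error(homozygosity_test(g, 1:2, make_pheno(g, rep("case", 9))),
               "empty case or control")
})
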