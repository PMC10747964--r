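test_that("pedigree simulation produces a valid multi-generation structure", {
  cfg <- tiny_config(seed = 7)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 10 + 2 * 20)
  expect_true(all(is.na(ped$sire[ped$generation == 0])))
  # every parent appears in an earlier generation (topological oracle)
  gen <- setNames(ped$generation, ped$id)
  for (i in which(ped$generation > 0)) {
    expect_lt(gen[[ped$sire[i]]], ped$generation[i])
    expect_lt(gen[[ped$dam[i]]], ped$generation[i])
  }
  # two founders, one generation: all offspring are full sibs of the pair
  ped2 <- simulate_pedigree(sim_config(n_founders = 2, n_generations = 1,
                                       n_offspring_per_generation = 8))
  off <- ped2[ped2$generation == 1, ]
  expect_true(all(off$sire == "D0001") && all(off$dam == "D0002"))
  # shared ancestors exist once generations >= 2
  expect_true(any(duplicated(ped$sire[ped$generation > 0])))
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- tiny_config(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$genotypes$doses, b$genotypes$doses)
  expect_identical(a$genotypes$haplotypes, b$genotypes$haplotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$panel$doses, b$panel$doses)
})

test_that("gene dropping is Mendelian-consistent and phase-consistent", {
  cfg <- tiny_config(seed = 3)
  ped <- simulate_pedigree(cfg)
  g <- gene_drop(ped, cfg)
  h <- g$haplotypes
  expect_identical(h$h1 + h$h2, unname(g$doses) + 0L)
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  for (i in which(ped$generation > 0)) {
    s <- idx[[ped$sire[i]]]; d <- idx[[ped$dam[i]]]
    # child haplotype 1 is a mosaic of the sire's two haplotypes
    expect_true(all(h$h1[i, ] == h$h1[s, ] | h$h1[i, ] == h$h2[s, ]))
    expect_true(all(h$h2[i, ] == h$h1[d, ] | h$h2[i, ] == h$h2[d, ]))
    # forced Mendelian cases
    both2 <- g$doses[s, ] == 2L & g$doses[d, ] == 2L
    both0 <- g$doses[s, ] == 0L & g$doses[d, ] == 0L
    expect_true(all(g$doses[i, both2] == 2L))
    expect_true(all(g$doses[i, both0] == 0L))
  }
  expect_error(gene_drop(data.frame(id = "X", sire = "nope", dam = NA), cfg),
               "unknown parent")
})

test_that("founder haplotype pool frequencies are recovered in a large founder cohort", {
  cfg <- sim_config(n_founders = 250, n_generations = 1,
                    n_offspring_per_generation = 2,
                    n_chromosomes = 2, snps_per_chromosome = 40,
                    risk_chromosome = 1, risk_span = c(21, 28),
                    block_size_snps = 20, seed = 5)
  ped <- simulate_pedigree(cfg)
  g <- gene_drop(ped, cfg)
  founders <- ped$id[ped$generation == 0]
  gf <- subset_genotypes(g, samples = founders)
  pool <- lymphscan:::founder_pool(cfg)
  expected <- unlist(lapply(pool, function(blocks)
    unlist(lapply(blocks, function(b) colSums(b$patterns * b$freq)))))
  observed <- allele_freq(gf)
  n_hap <- 2 * length(founders)
  tol <- 4 * sqrt(pmax(expected * (1 - expected), 0.002) / n_hap)
  expect_true(all(abs(observed - expected) < tol))
})

test_that("penetrance model links phenotype to the planted risk genotype", {
  cfg <- tiny_config(f0 = 0, f1 = 0, f2 = 1, seed = 2)
  ped <- simulate_pedigree(cfg)
  g <- gene_drop(ped, cfg)
  ph <- assign_phenotypes(g, cfg)
  expect_identical(ph$status == "case", ph$risk_genotype == 2L)
  expect_true(all(ph$age_years[ph$status == "case"] > 0 &
                  ph$age_years[ph$status == "case"] <= 14))
  expect_true(all(ph$age_years[ph$status == "control"] >= 7 &
                  ph$age_years[ph$status == "control"] <= 12))
  # flat penetrance: status independent of genotype
  cfg0 <- tiny_config(f0 = 0.3, f1 = 0.3, f2 = 0.3, seed = 8)
  ph0 <- assign_phenotypes(gene_drop(simulate_pedigree(cfg0), cfg0), cfg0)
  tab <- table(ph0$status, ph0$risk_genotype)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("default configuration emulates the cohort's case fraction", {
  b <- simulate_cohort(sim_config())
  expect_equal(nrow(b$phenotypes), 330)
  frac <- mean(b$phenotypes$status == "case")
  expect_lt(abs(frac - 49 / 330), 0.05)
})

test_that("reference panel follows the Balding-Nichols construction", {
  cfg <- tiny_config(n_ref_breeds = 4, n_ref_per_breed = 40, seed = 4)
  p <- runif(80, 0.1, 0.9)
  p[1] <- 0   # fixed ancestral allele stays fixed
  panel <- simulate_reference_panel(p, cfg)
  expect_equal(dim(panel), c(160L, 80L))
  expect_true(all(panel$doses[, 1] == 0L))
  # F -> 0 limit: breed frequencies hug the ancestral values
  cfg_low <- tiny_config(n_ref_breeds = 4, n_ref_per_breed = 60,
                         breed_divergence = 0.002, seed = 4)
  low <- simulate_reference_panel(p, cfg_low)
  b1 <- subset_genotypes(low, samples = which(attr(low, "breed") == "breed01"))
  expect_lt(mean(abs(allele_freq(b1)[-1] - p[-1])), 0.06)
  # Fst between two breeds grows with F (monotonicity over many SNPs)
  mean_fst <- function(F) {
    cfgF <- sim_config(n_chromosomes = 2, snps_per_chromosome = 250,
                       risk_chromosome = 1, risk_span = c(47, 54),
                       n_ref_breeds = 2, n_ref_per_breed = 60,
                       breed_divergence = F, seed = 9)
    pf <- runif(500, 0.2, 0.8)
    pan <- simulate_reference_panel(pf, cfgF)
    br <- attr(pan, "breed")
    mean(fst_per_snp(subset_genotypes(pan, samples = which(br == "breed01")),
                     subset_genotypes(pan, samples = which(br == "breed02"))),
         na.rm = TRUE)
  }
  set.seed(1)
  expect_lt(mean_fst(0.02), mean_fst(0.15))
  expect_lt(mean_fst(0.15), mean_fst(0.45))
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(f0 = 0.5, f1 = 0.2), "penetrance")
  expect_error(sim_config(n_founders = 1), "founders")
  expect_error(sim_config(breed_divergence = 1.2), "F must lie")
  expect_error(sim_config(risk_span = c(70, 90)), "risk_span")
  expect_error(sim_config(risk_span = c(15, 25)), "one haplotype block")
})

test_that("optional missingness masks doses and phase together", {
  cfg <- tiny_config(missing_rate = 0.1, seed = 6)
  g <- gene_drop(simulate_pedigree(cfg), cfg)
  na_d <- is.na(g$doses)
  expect_gt(mean(na_d), 0.05)
  expect_lt(mean(na_d), 0.15)
  expect_identical(unname(na_d), is.na(g$haplotypes$h1))
})
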