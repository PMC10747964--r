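#' Simulation configuration for a breed cohort with a planted recessive locus
#'
#' Bundles and validates all knobs of the synthetic-cohort generator.  The
#' defaults emulate the study conditions the package is designed around: a
#' cohort of about 330 dogs in a multi-generation pedigree with shared
#' ancestors, roughly 15% lymphoma cases, 38 autosomes of SNPs arranged in
#' linkage-disequilibrium blocks, a recessive risk haplotype planted on one
#' chromosome, and a 26-breed low-risk reference panel for the selection
#' contrast.  Chromosome lengths are scaled down (2.4 Mb, 80 SNPs each, 30 kb
#' spacing) so that a full pipeline run stays desk-sized while keeping the
#' marker density of a high-density canine array.
#'
#' @param n_founders number of pedigree founders (generation 0).
#' @param n_generations number of bred generations after the founders.
#' @param n_offspring_per_generation litter total added per generation.
#' @param n_chromosomes number of autosomes.
#' @param snps_per_chromosome markers per autosome.
#' @param chromosome_length_bp physical length of each autosome in bp.
#' @param block_size_snps SNPs per founder haplotype block (LD unit).
#' @param risk_chromosome chromosome carrying the planted risk haplotype.
#' @param risk_span two SNP indices (within-chromosome, inclusive) delimiting
#'   the risk haplotype.  Must fall inside a single haplotype block so the
#'   risk pattern segregates as one founder haplotype.
#' @param risk_hap_freq founder frequency of the risk haplotype.
#' @param f0,f1,f2 penetrance (probability of disease) for carriers of 0, 1
#'   and 2 copies of the risk haplotype; must satisfy `0 <= f0 <= f1 <= f2 <= 1`.
#' @param case_age_mean,case_age_sd mean/sd (years) of the truncated-normal
#'   age-at-diagnosis distribution for cases, truncated to (0, 14].
#' @param control_age_min,control_age_max uniform age range (years) for
#'   controls, chosen to support a young-onset sub-study design in which
#'   controls must be older than 7 years.
#' @param breed_divergence Balding-Nichols F in (0,1): drift of each reference
#'   breed's allele frequencies around the ancestral frequency.
#' @param n_ref_breeds,n_ref_per_breed reference-panel composition.
#' @param missing_rate probability a genotype call is masked as missing.
#' @param seed master seed; all stages derive their own stream from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_chromosomes = 4, snps_per_chromosome = 40)
#' cfg$risk_chromosome
#' @export
sim_config <- function(n_founders = 60L,
                       n_generations = 3L,
                       n_offspring_per_generation = 90L,
                       n_chromosomes = 38L,
                       snps_per_chromosome = 80L,
                       chromosome_length_bp = 2.4e6,
                       block_size_snps = 20L,
                       risk_chromosome = 13L,
                       risk_span = c(47L, 54L),
                       risk_hap_freq = 0.35,
                       f0 = 0.05, f1 = 0.08, f2 = 0.80,
                       case_age_mean = 5.7, case_age_sd = 2.5,
                       control_age_min = 7, control_age_max = 12,
                       breed_divergence = 0.10,
                       n_ref_breeds = 26L, n_ref_per_breed = 19L,
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_offspring_per_generation = as.integer(n_offspring_per_generation),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    chromosome_length_bp = as.numeric(chromosome_length_bp),
    block_size_snps = as.integer(block_size_snps),
    risk_chromosome = as.integer(risk_chromosome),
    risk_span = as.integer(risk_span),
    risk_hap_freq = as.numeric(risk_hap_freq),
    f0 = f0, f1 = f1, f2 = f2,
    case_age_mean = case_age_mean, case_age_sd = case_age_sd,
    control_age_min = control_age_min, control_age_max = control_age_max,
    breed_divergence = as.numeric(breed_divergence),
    n_ref_breeds = as.integer(n_ref_breeds),
    n_ref_per_breed = as.integer(n_ref_per_breed),
    missing_rate = as.numeric(missing_rate),
    seed = as.integer(seed)
  )
  counts <- c("n_founders", "n_generations", "n_offspring_per_generation",
              "n_chromosomes", "snps_per_chromosome", "block_size_snps",
              "n_ref_breeds", "n_ref_per_breed")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("configuration error: '", nm, "' must be a positive count")
  if (cfg$n_founders < 2L)
    stop("configuration error: need at least 2 founders to form matings")
  if (!(cfg$f0 >= 0 && cfg$f0 <= cfg$f1 && cfg$f1 <= cfg$f2 && cfg$f2 <= 1))
    stop("configuration error: penetrances must satisfy 0 <= f0 <= f1 <= f2 <= 1")
  if (cfg$breed_divergence <= 0 || cfg$breed_divergence >= 1)
    stop("configuration error: breed_divergence F must lie in (0, 1)")
  if (length(cfg$risk_span) != 2L || cfg$risk_span[1] > cfg$risk_span[2])
    stop("configuration error: risk_span must be an increasing index pair")
  if (cfg$risk_chromosome < 1L || cfg$risk_chromosome > cfg$n_chromosomes)
    stop("configuration error: risk_chromosome outside the genome")
  if (cfg$risk_span[2] > cfg$snps_per_chromosome)
    stop("configuration error: risk_span outside its chromosome")
  blk <- (cfg$risk_span - 1L) %/% cfg$block_size_snps
  if (blk[1] != blk[2])
    stop("configuration error: risk_span must lie within one haplotype block")
  if (cfg$risk_hap_freq <= 0 || cfg$risk_hap_freq >= 1)
    stop("configuration error: risk_hap_freq must lie in (0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("configuration error: missing_rate must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Cohort simulation configuration\n")
  cat(sprintf("  pedigree: %d founders + %d x %d offspring\n",
              x$n_founders, x$n_generations, x$n_offspring_per_generation))
  cat(sprintf("  genome:   %d chromosomes x %d SNPs (%.1f Mb each), blocks of %d\n",
              x$n_chromosomes, x$snps_per_chromosome,
              x$chromosome_length_bp / 1e6, x$block_size_snps))
  cat(sprintf("  risk:     chr %d SNPs %d-%d, founder freq %.2f, penetrance %.2f/%.2f/%.2f\n",
              x$risk_chromosome, x$risk_span[1], x$risk_span[2],
              x$risk_hap_freq, x$f0, x$f1, x$f2))
  cat(sprintf("  panel:    %d breeds x %d dogs, F = %.2f   seed %d\n",
              x$n_ref_breeds, x$n_ref_per_breed, x$breed_divergence, x$seed))
  invisible(x)
}

# ---- genotype container -----------------------------------------------------

#' Construct a genotype matrix object
#'
#' Container used throughout the package: an allele-dose matrix (copies of
#' allele B, `NA` = missing) with its SNP map and, when available, the pair of
#' phased haplotype matrices (0 = allele A, 1 = allele B) whose sum equals the
#' dose matrix.
#'
#' @param doses samples x SNPs integer matrix with values 0/1/2 or `NA`.
#' @param snp_table data.frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `allele_A`, `allele_B`; positions must be strictly increasing within a
#'   chromosome.
#' @param sample_ids character vector, one per dose row.
#' @param haplotypes optional list of two 0/1 matrices (`h1`, `h2`).
#' @return An object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(doses, snp_table, sample_ids, haplotypes = NULL) {
  doses <- as.matrix(doses)
  stopifnot(nrow(doses) == length(sample_ids), ncol(doses) == nrow(snp_table))
  need <- c("snp_id", "chrom", "pos_bp", "allele_A", "allele_B")
  if (!all(need %in% names(snp_table)))
    stop("snp_table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids")
  for (ch in unique(snp_table$chrom)) {
    p <- snp_table$pos_bp[snp_table$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing within chromosome ", ch)
  }
  ok <- doses %in% c(0L, 1L, 2L) | is.na(doses)
  if (!all(ok)) stop("doses must be 0, 1, 2 or NA")
  if (!is.null(haplotypes)) {
    stopifnot(length(haplotypes) == 2L)
    s <- haplotypes[[1]] + haplotypes[[2]]
    mism <- !is.na(doses) & s != doses
    if (any(mism)) stop("phase/dose inconsistency: haplotypes do not sum to doses")
    names(haplotypes) <- c("h1", "h2")
  }
  dimnames(doses) <- list(sample_ids, snp_table$snp_id)
  structure(list(sample_ids = as.character(sample_ids),
                 snp_table = as.data.frame(snp_table),
                 doses = doses,
                 haplotypes = haplotypes),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s)%s\n",
              length(x$sample_ids), nrow(x$snp_table),
              length(unique(x$snp_table$chrom)),
              if (is.null(x$haplotypes)) "" else " (phased)"))
  nm <- sum(is.na(x$doses))
  if (nm > 0) cat(sprintf("  %d missing calls (%.2f%%)\n", nm,
                          100 * nm / length(x$doses)))
  invisible(x)
}

#' Dimensions of a genotype matrix
#' @param x a `genotype_matrix`.
#' @export
dim.genotype_matrix <- function(x) dim(x$doses)

#' Frequency of allele B at each SNP
#' @param genotypes a `genotype_matrix`.
#' @return numeric vector of allele-B frequencies (missing calls excluded).
#' @export
allele_freq <- function(genotypes) {
  colMeans(genotypes$doses, na.rm = TRUE) / 2
}

#' Subset a genotype matrix by samples and/or SNPs
#' @param genotypes a `genotype_matrix`.
#' @param samples sample ids or indices (default all).
#' @param snps SNP indices or logical mask (default all).
#' @export
subset_genotypes <- function(genotypes, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_along(genotypes$sample_ids)
        else if (is.character(samples)) match(samples, genotypes$sample_ids)
        else samples
  if (anyNA(si)) stop("unknown sample id(s)")
  vi <- if (is.null(snps)) seq_len(nrow(genotypes$snp_table)) else which_idx(snps, nrow(genotypes$snp_table))
  haps <- genotypes$haplotypes
  if (!is.null(haps))
    haps <- list(h1 = haps$h1[si, vi, drop = FALSE], h2 = haps$h2[si, vi, drop = FALSE])
  genotype_matrix(genotypes$doses[si, vi, drop = FALSE],
                  genotypes$snp_table[vi, , drop = FALSE],
                  genotypes$sample_ids[si], haps)
}

which_idx <- function(i, n) {
  if (is.logical(i)) { stopifnot(length(i) == n); which(i) } else as.integer(i)
}

# ---- pedigree simulation ----------------------------------------------------

#' Simulate a multi-generation pedigree with shared ancestors
#'
#' Founders form generation 0 (alternating sexes); each later generation adds
#' offspring whose sire and dam are drawn at random from all earlier males and
#' females.  Sampling with replacement from a small parent pool yields the
#' overlapping sib-groups and repeatedly used ancestors typical of a closed
#' breed registry.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `"pedigree"` with columns `id`, `sire`, `dam`
#'   (`NA` for founders), `sex` (`"M"`/`"F"`) and `generation`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "pedigree"))
  nf <- config$n_founders
  id <- sprintf("D%04d", seq_len(nf))
  ped <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                    sex = rep(c("M", "F"), length.out = nf),
                    generation = 0L, stringsAsFactors = FALSE)
  counter <- nf
  for (g in seq_len(config$n_generations)) {
    males <- ped$id[ped$sex == "M"]
    females <- ped$id[ped$sex == "F"]
    if (length(males) == 0L || length(females) == 0L)
      stop("configuration error: impossible mating structure (missing a sex)")
    n_off <- config$n_offspring_per_generation
    off_id <- sprintf("D%04d", counter + seq_len(n_off))
    counter <- counter + n_off
    ped <- rbind(ped, data.frame(
      id = off_id,
      sire = sample(males, n_off, replace = TRUE),
      dam = sample(females, n_off, replace = TRUE),
      sex = sample(c("M", "F"), n_off, replace = TRUE),
      generation = g, stringsAsFactors = FALSE))
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Founder haplotype pool: per chromosome, per block, 4 block haplotypes with
# Dirichlet(1,1,1,1) frequencies; the risk block gets the risk haplotype as
# pattern 1 at the configured frequency.
founder_pool <- function(config) {
  set.seed(derive_seed(config$seed, "founders"))
  m <- config$snps_per_chromosome
  bs <- config$block_size_snps
  pool <- vector("list", config$n_chromosomes)
  rdirichlet1 <- function(k) { g <- stats::rgamma(k, 1); g / sum(g) }
  for (ch in seq_len(config$n_chromosomes)) {
    starts <- seq(1L, m, by = bs)
    blocks <- lapply(starts, function(s) {
      w <- min(bs, m - s + 1L)
      pat <- matrix(rbinom(4L * w, 1L, 0.5), nrow = 4L)
      # keep the 4 block haplotypes distinct so block identity is well defined
      tries <- 0L
      while (anyDuplicated(apply(pat, 1, paste, collapse = "")) && tries < 50L) {
        pat <- matrix(rbinom(4L * w, 1L, 0.5), nrow = 4L); tries <- tries + 1L
      }
      list(start = s, width = w, patterns = pat, freq = rdirichlet1(4L))
    })
    pool[[ch]] <- blocks
  }
  # plant the risk haplotype: pattern 1 of the block containing the span
  span <- config$risk_span
  rc <- config$risk_chromosome
  bi <- (span[1] - 1L) %/% bs + 1L
  blk <- pool[[rc]][[bi]]
  blk$freq <- c(config$risk_hap_freq, (1 - config$risk_hap_freq) * rdirichlet1(3L))
  rel <- (span[1]:span[2]) - blk$start + 1L
  # the planted risk haplotype is a distinct tag haplotype: over the span it
  # differs from every other block haplotype at every SNP, so the span SNPs
  # jointly identify it (an 8-SNP tag of the risk haplotype)
  for (r in 2:4) blk$patterns[r, rel] <- 1L - blk$patterns[1, rel]
  pool[[rc]][[bi]] <- blk
  attr(pool, "risk_pattern") <- blk$patterns[1, rel]
  pool
}

sim_snp_table <- function(config) {
  m <- config$snps_per_chromosome
  spacing <- config$chromosome_length_bp / m
  do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ch) {
    pos <- round((seq_len(m) - 0.5) * spacing)
    data.frame(snp_id = sprintf("chr%d_%d", ch, pos),
               chrom = ch, pos_bp = pos,
               allele_A = "A", allele_B = "B", stringsAsFactors = FALSE)
  }))
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotypes are drawn from a block-haplotype pool (four haplotypes
#' per block, Dirichlet frequencies, independent between blocks); each meiosis
#' recombines the parental pair with exactly one uniformly placed crossover
#' per chromosome.  Offspring haplotypes are therefore mosaics of their
#' parents' haplotypes and Mendelian consistency holds by construction.
#'
#' @param pedigree a [simulate_pedigree()] result (or compatible data.frame).
#' @param config the same [sim_config()] used for the pedigree.
#' @return A phased [genotype_matrix()].  The planted risk locus is recorded
#'   in attribute `"risk"` (chromosome, global SNP indices, 0/1 pattern).
#' @export
gene_drop <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  ped <- as.data.frame(pedigree)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  for (col in c("sire", "dam")) {
    known <- !is.na(ped[[col]])
    if (any(known & !(ped[[col]] %in% ped$id)))
      stop("input error: pedigree references unknown parent '",
           ped[[col]][known & !(ped[[col]] %in% ped$id)][1], "'")
  }
  pool <- founder_pool(config)
  set.seed(derive_seed(config$seed, "genedrop"))
  snp <- sim_snp_table(config)
  m_tot <- nrow(snp)
  mpc <- config$snps_per_chromosome
  h1 <- matrix(0L, n, m_tot); h2 <- matrix(0L, n, m_tot)
  chrom_cols <- lapply(seq_len(config$n_chromosomes),
                       function(ch) ((ch - 1L) * mpc + 1L):(ch * mpc))
  draw_founder_hap <- function() {
    out <- integer(m_tot)
    for (ch in seq_len(config$n_chromosomes)) {
      cols <- chrom_cols[[ch]]
      hap <- unlist(lapply(pool[[ch]], function(b) {
        b$patterns[sample.int(4L, 1L, prob = b$freq), ]
      }), use.names = FALSE)
      out[cols] <- hap
    }
    out
  }
  gamete <- function(pi) {
    g <- integer(m_tot)
    for (ch in seq_len(config$n_chromosomes)) {
      cols <- chrom_cols[[ch]]
      xo <- runif(1, 0, config$chromosome_length_bp)
      first <- sample.int(2L, 1L)
      left <- snp$pos_bp[cols] <= xo
      a <- if (first == 1L) h1[pi, cols] else h2[pi, cols]
      b <- if (first == 1L) h2[pi, cols] else h1[pi, cols]
      g[cols] <- ifelse(left, a, b)
    }
    g
  }
  ord <- order(ped$generation)
  for (i in ord) {
    if (is.na(ped$sire[i]) && is.na(ped$dam[i])) {
      h1[i, ] <- draw_founder_hap()
      h2[i, ] <- draw_founder_hap()
    } else {
      h1[i, ] <- if (is.na(ped$sire[i])) draw_founder_hap() else gamete(idx[[ped$sire[i]]])
      h2[i, ] <- if (is.na(ped$dam[i]))  draw_founder_hap() else gamete(idx[[ped$dam[i]]])
    }
  }
  doses <- h1 + h2
  haps <- list(h1 = h1, h2 = h2)
  span_global <- (config$risk_chromosome - 1L) * mpc +
    (config$risk_span[1]:config$risk_span[2])
  risk_pattern <- attr(pool, "risk_pattern")
  # latent risk dose is computed before any missingness masking
  match_risk <- function(h) {
    sub <- h[, span_global, drop = FALSE]
    as.integer(rowSums(sub == matrix(risk_pattern, nrow(sub),
                                     length(risk_pattern), byrow = TRUE)) ==
               length(risk_pattern))
  }
  latent_dose <- match_risk(h1) + match_risk(h2)
  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(doses)) < config$missing_rate, n, m_tot)
    doses[mask] <- NA_integer_
    haps$h1[mask] <- NA_integer_; haps$h2[mask] <- NA_integer_
  }
  g <- genotype_matrix(doses, snp, ped$id, haps)
  attr(g, "risk") <- list(chrom = config$risk_chromosome,
                          snp_idx = span_global,
                          pattern = risk_pattern,
                          dose = latent_dose)
  g
}

# number of haplotypes per sample exactly matching the risk pattern; uses the
# latent (pre-masking) dose recorded by gene_drop when available
risk_dose <- function(genotypes) {
  risk <- attr(genotypes, "risk")
  if (is.null(risk)) stop("genotypes carry no planted-risk annotation")
  if (!is.null(risk$dose)) return(risk$dose)
  if (is.null(genotypes$haplotypes)) stop("risk dose requires phased genotypes")
  hit <- function(h) {
    sub <- h[, risk$snp_idx, drop = FALSE]
    as.integer(rowSums(sub == matrix(risk$pattern, nrow(sub),
                                     length(risk$pattern), byrow = TRUE),
                       na.rm = FALSE) == length(risk$pattern))
  }
  hit(genotypes$haplotypes$h1) + hit(genotypes$haplotypes$h2)
}

#' Assign case/control phenotypes from the planted risk genotype
#'
#' Disease status is drawn with penetrance `f0`/`f1`/`f2` according to the
#' number of haplotypes (0/1/2) exactly matching the planted risk haplotype
#' over its span.  Cases receive an age at diagnosis from a normal
#' distribution truncated to (0, 14]; controls an age uniform on the
#' configured control range.
#'
#' @param genotypes phased output of [gene_drop()].
#' @param config the matching [sim_config()].
#' @return data.frame of class `"phenotype_table"`: `sample_id`, `status`
#'   (`"case"`/`"control"`), `age_years`, and the latent `risk_genotype`.
#' @export
assign_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "phenotypes"))
  rd <- risk_dose(genotypes)
  pen <- c(config$f0, config$f1, config$f2)[rd + 1L]
  is_case <- runif(length(pen)) < pen
  age <- numeric(length(pen))
  # truncated normal by rejection; (0, 14] window
  nc <- sum(is_case)
  if (nc > 0) {
    draws <- numeric(0)
    while (length(draws) < nc) {
      x <- rnorm(2L * nc, config$case_age_mean, config$case_age_sd)
      draws <- c(draws, x[x > 0 & x <= 14])
    }
    age[is_case] <- draws[seq_len(nc)]
  }
  age[!is_case] <- runif(sum(!is_case), config$control_age_min, config$control_age_max)
  out <- data.frame(sample_id = genotypes$sample_ids,
                    status = ifelse(is_case, "case", "control"),
                    age_years = age,
                    risk_genotype = rd,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Simulate a multi-breed low-risk reference panel
#'
#' Each breed's per-SNP allele frequencies are drawn around the supplied
#' ancestral frequencies by the Balding-Nichols construction
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`; panel haplotypes are then sampled site-wise
#' so genotypes are in Hardy-Weinberg proportions within each breed.
#'
#' @param cohort_frequencies per-SNP ancestral allele-B frequencies (typically
#'   [allele_freq()] of the study cohort).
#' @param config a [sim_config()]; uses `breed_divergence`, `n_ref_breeds`,
#'   `n_ref_per_breed` and the SNP map settings.
#' @return A phased [genotype_matrix()] with a `breed` attribute (one label
#'   per sample).
#' @export
simulate_reference_panel <- function(cohort_frequencies, config) {
  stopifnot(inherits(config, "sim_config"))
  FST <- config$breed_divergence
  if (FST <= 0 || FST >= 1) stop("configuration error: F must lie in (0, 1)")
  set.seed(derive_seed(config$seed, "panel"))
  snp <- sim_snp_table(config)
  m <- nrow(snp)
  if (length(cohort_frequencies) != m)
    stop("cohort_frequencies length does not match the configured SNP map")
  p <- pmin(pmax(cohort_frequencies, 0), 1)
  nb <- config$n_ref_breeds; npb <- config$n_ref_per_breed
  n <- nb * npb
  h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
  breed <- rep(sprintf("breed%02d", seq_len(nb)), each = npb)
  shape1 <- p * (1 - FST) / FST
  shape2 <- (1 - p) * (1 - FST) / FST
  for (b in seq_len(nb)) {
    pb <- numeric(m)
    poly <- p > 0 & p < 1
    pb[poly] <- rbeta(sum(poly), shape1[poly], shape2[poly])
    pb[p == 1] <- 1
    rows <- ((b - 1L) * npb + 1L):(b * npb)
    h1[rows, ] <- matrix(rbinom(npb * m, 1L, rep(pb, each = npb)), npb, m)
    h2[rows, ] <- matrix(rbinom(npb * m, 1L, rep(pb, each = npb)), npb, m)
  }
  ids <- sprintf("R%s_%02d", breed, sequence(rep(npb, nb)))
  g <- genotype_matrix(h1 + h2, snp, ids, list(h1 = h1, h2 = h2))
  attr(g, "breed") <- breed
  g
}

#' Simulate a complete study bundle
#'
#' Convenience wrapper running [simulate_pedigree()], [gene_drop()],
#' [assign_phenotypes()] and [simulate_reference_panel()] with one
#' configuration.
#'
#' @param config a [sim_config()].
#' @return list with `pedigree`, `genotypes`, `phenotypes`, `panel`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  geno <- gene_drop(ped, config)
  pheno <- assign_phenotypes(geno, config)
  panel <- simulate_reference_panel(allele_freq(geno), config)
  list(pedigree = ped, genotypes = geno, phenotypes = pheno,
       panel = panel, config = config)
}
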