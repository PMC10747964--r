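# Shared builders for the test suite.  Everything is generated in code; no
# binary fixtures.

# A small cohort configuration that keeps simulation-heavy tests fast.
tiny_config <- function(...) {
  sim_config(n_founders = 10L, n_generations = 2L,
             n_offspring_per_generation = 20L,
             n_chromosomes = 2L, snps_per_chromosome = 40L,
             chromosome_length_bp = 1.2e6, block_size_snps = 10L,
             risk_chromosome = 1L, risk_span = c(12L, 19L), ...)
}

# LD-free configuration for calibration checks (KS-type tests assume
# independent markers).
nold_config <- function(...) {
  sim_config(n_chromosomes = 10L, risk_chromosome = 5L,
             block_size_snps = 1L, risk_span = c(47L, 47L), ...)
}

# Build a genotype_matrix straight from a dose matrix.
make_geno <- function(doses, chrom = NULL, pos = NULL, phased = FALSE) {
  doses <- as.matrix(doses)
  m <- ncol(doses)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- ave(seq_len(m), chrom, FUN = seq_along) * 1000
  snp <- data.frame(snp_id = sprintf("s%03d", seq_len(m)), chrom = chrom,
                    pos_bp = pos, allele_A = "A", allele_B = "B",
                    stringsAsFactors = FALSE)
  haps <- NULL
  if (phased) {
    h1 <- (doses == 2L) + 0L
    h2 <- (doses >= 1L) + 0L
    haps <- list(h1 = h1, h2 = h2)
  }
  genotype_matrix(doses, snp, sprintf("S%03d", seq_len(nrow(doses))), haps)
}

# Build a phased genotype_matrix from explicit haplotype matrices.
make_phased <- function(h1, h2, chrom = NULL, pos = NULL) {
  g <- make_geno(h1 + h2, chrom, pos)
  genotype_matrix(g$doses, g$snp_table, g$sample_ids,
                  list(h1 = as.matrix(h1), h2 = as.matrix(h2)))
}

# Phenotype table from a status vector aligned with a genotype matrix.
make_pheno <- function(geno, status, age = NA_real_) {
  data.frame(sample_id = geno$sample_ids, status = status,
             age_years = age, stringsAsFactors = FALSE)
}

fixture_path <- function(f) system.file("extdata", f, package = "lymphscan")

# Exhaustive-ancestry oracle used by the kinship tests.
ancestor_closure <- function(ped, id) {
  out <- character(0)
  frontier <- id
  while (length(frontier)) {
    i <- match(frontier[1], ped$id); frontier <- frontier[-1]
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(p) && !(p %in% out)) {
        out <- c(out, p); frontier <- c(frontier, p)
      }
    }
  }
  out
}

# O(n^2) pair-counting EHH oracle.
ehh_oracle <- function(H, core, j) {
  lo <- min(core, j); hi <- max(core, j)
  s <- apply(H[, lo:hi, drop = FALSE], 1, paste, collapse = "")
  n <- length(s)
  same <- outer(s, s, "==")
  (sum(same) - n) / (n * (n - 1))
}

# Direct hypergeometric enumeration oracle for the two-sided Fisher test,
# written from choose() so it is independent of dhyper().
fisher_oracle <- function(tbl) {
  a <- tbl[1, 1]; m1 <- sum(tbl[1, ]); m2 <- sum(tbl[2, ]); k <- sum(tbl[, 1])
  lo <- max(0, k - m2); hi <- min(k, m1)
  pr <- vapply(lo:hi, function(x)
    choose(m1, x) * choose(m2, k - x) / choose(m1 + m2, k), numeric(1))
  p0 <- pr[a - lo + 1]
  sum(pr[pr <= p0 * (1 + 1e-7)])
}
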