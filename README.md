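# lymphscan

Mapping inherited cancer-risk loci in closed dog-breed populations.

Lymphoma is the most common haematological cancer of dogs and is strongly
breed-associated: in breeds such as the Bullmastiff it appears young and
segregates through an extended pedigree, suggesting risk loci on a shared,
inbred genetic background. `lymphscan` implements the full computational
workflow of a breed-cohort risk-locus study as reusable, tested R functions:

* **Pedigree kinship** — the recursive kinship matrix
  (phi(i,i) = (1 + phi(s,d))/2, phi(i,j) = (phi(s,j) + phi(d,j))/2), its
  positive-semidefinite numerator-relationship form, and case-descendant
  counting for putative common ancestors.
* **Relationship networks** — NetView-style mutual k-nearest-neighbour graphs
  (default k = 10) from 1−IBS genotype distances or kinship-derived
  distances, with connected components and case/control overlay.
* **Mixed-linear-model GWAS** — MAF filter (strict `MAF < 0.02` removal), a
  GCTA-style genetic relationship matrix
  `A_jk = (1/m) Σ_i (x_ij − 2p_i)(x_ik − 2p_i)/(2p_i(1−p_i))`, one REML fit
  of `y = Xb + g + e`, `g ~ N(0, σ_g²A)` profiled over δ = σ_e²/σ_g² in the
  eigenbasis of A, then an EMMAX-style scan (variance components fixed from
  the null model; two-sided Wald χ²(1) per SNP at O(n) after one rotation).
  A young-onset sub-study selector (cases ≤ 6 y, controls > 7 y) mirrors the
  early-onset design.
* **Storey q-values** — π₀ from the p-value histogram smoothed with a 3-df
  spline, `q_(i) = min_{j≥i} π₀ m p_(j)/j`, applied genome-wide and
  chromosome-wise.
* **Composite selection signals (CSS)** — per-SNP Weir–Cockerham Fst, signed
  ΔDAF and standardized XP-EHH against a multi-breed low-risk reference
  panel; each statistic is converted to fractional ranks `1/(n+1) … n/(n+1)`,
  z-scored by the inverse normal CDF and averaged; `p = 1 − Φ(z̄√m)`,
  `CSS = −log10 p`, smoothed in 1 Mb windows; SNPs above the 99.5% empirical
  quantile of smoothed CSS form significant regions.
* **Regional haplotype analysis** — sliding 2–8-SNP haplotype windows
  (EM-phased when genotypes are unphased), Gabriel-style haplotype blocks
  from likelihood-based D′ confidence intervals, runs of homozygosity, and a
  two-sided Fisher exact test on case/control joint-homozygosity tables.
* **Recessive variant triage** — trio filtering (affected hom-alt, carrier
  het, control hom-ref), region filtering on 1-based coordinates, and an
  interval-based consequence classifier (UTRs, codon-table missense calls).
* **Synthetic cohorts** — a pedigree simulator with gene dropping through
  block-structured founder haplotypes, a planted recessive risk haplotype
  with configurable penetrance (f0/f1/f2), phenotype ages, and a
  Balding–Nichols multi-breed reference panel, so the entire pipeline runs
  and is tested without any external data.

## Worked example

Simulate the default cohort (330 dogs, 38 scaled-down autosomes, a recessive
risk haplotype on chromosome 13 at SNPs 47–54) and scan it:

```r
library(lymphscan)
cfg <- sim_config(seed = 1)
bundle <- simulate_cohort(cfg)
table(bundle$phenotypes$status)
#>    case control
#>      50     280

gw <- mlma_gwas(bundle$genotypes, bundle$phenotypes)
#> filter_maf: removed 500 of 3040 SNPs (MAF < 0.02)
print(gw)
#> Mixed-model GWAS: 330 samples (50 cases), 2540 SNPs
#> REML polygenic null model
#>   sigma_g^2 = 0.04589  sigma_e^2 = 0.08148  h2 = 0.360
#> top SNPs:
#>         snp_id chrom  pos_bp      b      se         p  q_genome   q_chrom
#>  chr13_1545000    13 1545000 0.2672 0.03789 1.764e-12 1.895e-09 2.736e-11
#>  chr13_1575000    13 1575000 0.2680 0.03802 1.803e-12 1.895e-09 2.736e-11
#>  ...
```

The top SNPs sit inside the planted span (chr13: 1.395–1.605 Mb) and reach
chromosome-wise significance (q < 0.01). The selection contrast against the
simulated 26-breed panel recovers the same region:

```r
cases <- bundle$phenotypes$sample_id[bundle$phenotypes$status == "case"]
scan <- css_scan(subset_genotypes(bundle$genotypes, samples = cases), bundle$panel)
print(scan)
#> CSS scan: 3040 SNPs, smoothing window 1e+06 bp, 99.5% threshold = 2.590
#>   significant SNPs: 15 in 1 region(s)
#>  region_id chrom start_bp  end_bp n_snps regional_css
#>          1    13  1275000 1695000     15        2.679
```

Interpretation: `h2` is the variance fraction attributed to the GRM on the
observed 0/1 disease scale; `b` is the per-allele effect of the counted
(minor) allele; the CSS region is the maximal run of SNPs whose smoothed
composite score exceeds the genome-wide 99.5% quantile (threshold 2.590
here), and `regional_css` is the mean smoothed score of its members.

A packaged worked example reproduces the published risk-region variant
table: `read_variant_table()` yields 8 exonic records (7 substitutions, 1
insertion), and `region_filter(v, "13", 25200000, 26400000)` isolates the
single gene-coding variant in the 1.2 Mb fine-mapped region (the MYC 3'UTR
insertion).

One-call orchestration with a manifest of md5-hashed outputs:

```r
run_pipeline(run_config(out_dir = "run1", seed = 1))
```

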