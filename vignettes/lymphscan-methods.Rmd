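---
title: "Methods and modelling choices in lymphscan"
author: "lymphscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in lymphscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lymphscan)
```

`lymphscan` reimplements, as one coherent and fully tested toolchain, the
analysis workflow used to map recessive cancer-risk loci in a closed dog
breed: pedigree relatedness, fine-scale population networks, a
mixed-linear-model association scan with Storey q-values, a composite
selection-signal contrast against low-risk breeds, regional haplotype and
homozygosity dissection, and recessive variant triage. This vignette records
the models, the parameters that matter, and the design decisions taken where
the methods literature leaves choices open.

## The synthetic cohort: what it emulates and what it does not

No genotype or sequence data are distributed with the study design this
package addresses, so the simulator is a first-class module: it generates
cohorts with the structural features the downstream methods rely on, at a
desk scale.

**Pedigree.** Generation 0 holds `n_founders` unrelated dogs (alternating
sexes); each later generation adds offspring whose sire and dam are sampled
with replacement from all earlier males and females. Repeated use of a small
parent pool produces the overlapping sibships and popular-sire structure of
a breed registry. Defaults: 60 founders + 3 × 90 offspring = 330 dogs. We
chose 60 founders after observing that very small founder pools let
founder-frequency drift dominate the cohort composition; with 60 the
realized case fraction is stable across seeds while substantial kinship
structure remains.

**Genome and linkage disequilibrium.** 38 autosomes of 80 SNPs each (2.4 Mb
per chromosome, 30 kb spacing). Founder haplotypes follow a haplotype-block
model: within each block of `block_size_snps` (default 20 SNPs = 600 kb,
matching the long within-breed LD of dogs) four block haplotypes segregate
with Dirichlet(1,1,1,1) frequencies; blocks are independent. Meioses place
exactly one uniformly positioned crossover per chromosome — there is no
genetic map in the emulated design, and one crossover per chromosome per
meiosis keeps multi-generation LD realistic at this scale. Gene dropping
makes Mendelian consistency exact by construction, and the tests assert it.

**The planted risk locus.** One block haplotype on chromosome 13 is the risk
haplotype; over its 8-SNP span (SNPs 47–54) it differs from every other
block haplotype at every SNP, i.e. the span is a perfect 8-SNP tag of the
risk haplotype, in the way an observed homozygous core haplotype tags a risk
region. Its founder frequency is 0.35. Disease is penetrance-based, not
liability-threshold — the filtering language of the emulated design is
recessive-genotype-based — with f0/f1/f2 = 0.05/0.08/0.80 for 0/1/2 copies.
These values were calibrated once so the expected case fraction matches the
emulated cohort (~15%, 49/330); they encode strong but incomplete recessive
penetrance over a background rate. Cases draw an age at diagnosis from
N(5.7, 2.5²) truncated to (0, 14]; controls draw uniform(7, 12) years, a
stated convention (the emulated cohort reports no control age distribution)
chosen so the young-onset sub-design — cases ≤ 6, controls strictly > 7 —
is exercised.

**Reference panel.** 26 breeds × 19 dogs (494 total; the emulated 498 is not
divisible by 26). Per breed, allele frequencies are drawn around the cohort
ancestral frequencies by the Balding–Nichols construction
Beta(p(1−F)/F, (1−p)(1−F)/F) with F = 0.10, and haplotypes are sampled
site-wise, so panel genotypes are in Hardy–Weinberg proportions within
breeds. The panel has no within-breed LD; this is deliberate — the CSS
statistics only require the reference's frequency spectrum and a baseline
haplotype-homozygosity level — but it means panel-side EHH decays faster
than in real breeds, which slightly inflates target-side XP-EHH everywhere
and washes out in the genome-wide standardization.

**What passing tests do not show.** The simulator has no genotyping error,
no imputation uncertainty, no X chromosome, no breed-specific demography,
and its genome is length-compressed ~25×. Power and calibration results on
it demonstrate correctness of the machinery under the stated model, not
field performance on array data.

## Mixed-linear-model association

The scan is EMMAX-style. The GRM uses standardized doses of the counted
allele with per-SNP observed frequencies; missing doses are mean-imputed
per SNP. One REML fit of the null model `y = Xb + g + e`,
`g ~ N(0, σ_g²A)`, profiles the restricted likelihood over
δ = σ_e²/σ_g² on an 80-point log grid (1e−5 to 1e5) refined by
`optimize()`; everything is computed in the eigenbasis of A, so the
subsequent per-SNP generalized-least-squares Wald tests cost O(n) each. The
case/control phenotype is analysed on the observed 0/1 scale, the candidate
SNP stays in the GRM (no leave-one-chromosome-out), the Wald χ²(1) test is
two-sided, and the effect allele is the minor allele in the analysed sample,
recorded per SNP. When the restricted likelihood is flat in δ (e.g. A
numerically proportional to the identity, where the model is
unidentifiable) the fit returns the boundary convention σ_g² = 0, and the
scan then reproduces ordinary least squares exactly — a tested reduction.

Two calibration facts are worth stating because they shaped the test
design. First, with a binary phenotype the permutation distribution of the
per-SNP statistic is discrete, so permuted-phenotype p-values carry atoms
and can never be Kolmogorov–Smirnov-uniform per replicate; binary-trait
calibration is therefore checked as a type-I-error band (empirical rejection
at nominal 0.05 within [0.035, 0.065]) over the full MAF spectrum. Second,
all m SNPs of a scan share one REML variance estimate, whose O(√(2/n))
sampling error shifts the whole p-vector of a replicate together; a KS test
resolves this artefact once m greatly exceeds n. Distributional uniformity
is therefore verified on phenotypes drawn from the model's own polygenic
null, restricted to common variants (MAF ≥ 0.1) and with at most as many
test SNPs as samples. With the true variance plugged in, the scan is exactly
calibrated; the residual rare-variant conservatism of the χ² reference is a
known property of this class of estimator.

## Storey q-values

π₀(λ) = #{p > λ}/(m(1−λ)) on λ = 0.05, …, 0.90 is smoothed with
`smooth.spline(df = 3)` and read off at λ = 0.90, clipped to (0, 1] —
the spline was chosen over bootstrap π₀ for determinism. Q-values follow by
the cumulative minimum from the largest p; ties share a q-value, the result
is order-invariant, and forcing π₀ = 1 reproduces Benjamini–Hochberg
exactly (a tested identity). Chromosome-wise q-values rerun the procedure
within each chromosome; chromosomes with fewer than 20 SNPs pin π₀ to 1
with a warning because the spline is unstable there.

## Composite selection signals

Per SNP, three statistics contrast the case cohort with the reference
panel: Weir–Cockerham's two-population θ (1984 variance-components form
with the n_c correction; negative estimates are retained since only ranks
enter the composite), signed ΔDAF (derived-allele frequency difference;
ancestral alleles default to the reference-panel major allele, with the
fallback announced), and XP-EHH (EHH integrated over physical bp by the
trapezoid rule in both directions; the same truncation point — the
outermost SNP where both populations hold EHH ≥ 0.05 — applies to both
populations; physical distance stands proxy for the genetic map). EHH is
defined as 1 at the core SNP. Components are converted to fractional ranks
r ∈ {1/(n+1), …, n/(n+1)} (average ranks for ties), z-scored by Φ⁻¹, and
averaged; p = 1 − Φ(z̄√m) and CSS = −log10 p. A SNP invalid in one
component keeps the others with m reduced.

Two wording ambiguities in the CSS literature were resolved as follows. The
smoothing window is 1 Mb total, i.e. 0.5 **Mb** on either side (the
parenthetical "0.5 Kb" in the source description contradicts its own
leading "1 Mb"); the window is configurable. The 99.5% significance
threshold is applied genome-wide (not per chromosome), and the empirical
quantile uses the order-statistic definition (`type = 1`): interpolating
quantile definitions can leave strictly more than 0.5% of SNPs above the
"top 0.005" threshold, while the order statistic honours the bound exactly.
Whether ΔDAF should be ranked signed or absolute is not specified in the
source method; signed (target-directional) is the default here.

One honest caveat: the N(0, 1/m) null for z̄ assumes the three component
ranks are independent. They are not — Fst and ΔDAF are both functions of
the same per-SNP frequency difference — so composite p-values from real
two-cohort data are not exactly uniform under a fully null contrast (we
verified this empirically; even a random split of one population rejects
KS uniformity). The method is used, as designed, for *ranking* and
empirical-quantile thresholding, both of which are unaffected; the
uniformity property is asserted where it genuinely holds, namely for
independently distributed component statistics.

## Regional haplotype analysis

Sliding windows enumerate all widths 2–8 sliding one SNP at a time. With
phased input, window haplotype counts are direct tallies; with unphased
doses, an EM estimate of window haplotype frequencies under Hardy–Weinberg
(convergence 1e−6 on the max frequency change, cap 200 iterations,
non-convergence flagged) supplies expected counts; the unidentifiable
double-heterozygote splits its mass evenly, as it must. Haplotype blocks
follow the Gabriel construction: likelihood-based confidence intervals on
|D′| from a 0.01 grid (posterior mass 5%/95% bounds under a flat prior,
genotype likelihood under HWE), strong LD = CI within [0.70, 1] with upper
≥ 0.98, strong recombination = upper < 0.90, and a block requires ≥ 95% of
informative pairs strong, resolved longest-span-first. Runs of homozygosity
are maximal runs of non-heterozygous doses; missing calls break runs. The
case/control homozygosity test counts a sample as homozygous only if
homozygous at *every* SNP of the query set and applies a two-sided Fisher
exact test by the minimum-likelihood enumeration rule, verified against a
`choose()`-based oracle to 1e−12. The emulated report does not name the
test behind its printed contingency p-value, so the packaged check treats
that value as an upper bound, not an equality.

## Variant triage

The recessive trio rule retains a variant only when the affected dog
(risk-haplotype homozygote) is hom-alt, the carrier parent het, and the
unrelated control hom-ref; a relaxation admitting hom-alt carriers
(incomplete penetrance) exists behind a flag, off by default. Coordinates
are 1-based inclusive throughout; BED-like annotation is converted on read
and the conversion reported. The consequence classifier is interval-based:
intergenic without a gene overlap, UTR classes from UTR intervals, missense
when a CDS substitution changes the annotated codon under the standard
genetic code (`Biostrings::GENETIC_CODE`), everything else "gene-coding
other"; splice-site handling is reduced to exon-boundary proximity and
full impact prediction is out of scope. The packaged risk-region variant
table reproduces its source verbatim, including the gene-symbol spellings
("LDH", "TMEM71") as printed.

## Problem sizes and reproducibility

Default analyses run at 330 samples × 3,040 SNPs; the acceptance script's
selection scan uses 38 × 264 ≈ 10,000 SNPs; calibration suites use LD-free
genomes of ~800 SNPs (KS-type checks assume independent markers) and
replicate counts of 20. These sizes were chosen so the full pipeline is
interactive on a laptop while every statistical property remains testable.
All randomness flows from one master seed per run through stage-name-hashed
sub-seeds, so stages can be rerun in isolation and complete pipeline runs
are hash-identical (`run_pipeline()` writes an md5 manifest; rerunning with
the same configuration reproduces it, a tested contract).

## Known limitations

* The scan treats the 0/1 phenotype linearly; no liability transformation
  or exact logistic mixed model is provided.
* XP-EHH uses physical distance as a map proxy and requires phased input;
  phasing itself (beyond 8-SNP EM windows) is out of scope.
* The consequence classifier does not model splice donors/acceptors beyond
  exon-boundary proximity, nor protein-impact scores.
* Reference-panel realism is limited to frequency drift (no within-breed
  LD, no demography), which is sufficient for the rank-based CSS but not
  for haplotype-sharing analyses across the contrast.
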