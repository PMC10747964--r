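#' Assemble a pipeline run configuration
#'
#' Collects every stage's parameters (defaults match the package's standard
#' analysis: MAF 0.02, network k 10, 1 Mb CSS window, 99.5% CSS quantile,
#' q-value report thresholds 0.01/0.05, haplotype windows 2-8 SNPs) together
#' with output paths, stage toggles and the master seed from which each
#' stage derives its own stream.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param stages character vector of stages to run, in dependency order.
#' @param maf,network_k,css_window_bp,css_quantile,q_thresholds,hap_widths,roh_min_snps
#'   stage parameters.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(out_dir = tempfile("lymphscan_run_"),
                       seed = 1L,
                       sim = sim_config(seed = seed),
                       stages = c("simulate", "kinship", "network", "gwas",
                                  "css", "haplo", "variants"),
                       maf = 0.02, network_k = 10L,
                       css_window_bp = 1e6, css_quantile = 0.995,
                       q_thresholds = c(0.01, 0.05),
                       hap_widths = c(2L, 8L), roh_min_snps = 3L) {
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 stages = stages, maf = maf, network_k = network_k,
                 css_window_bp = css_window_bp, css_quantile = css_quantile,
                 q_thresholds = q_thresholds, hap_widths = hap_widths,
                 roh_min_snps = roh_min_snps),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order on a simulated cohort:
#' simulate (PED/MAP, haplotype sidecar, pedigree and phenotype TSVs),
#' kinship matrix, mutual-kNN network, mixed-model GWAS with genome-wide and
#' chromosome-wise q-values, CSS contrast against the simulated reference
#' panel, haplotype/ROH/homozygosity analysis of the top GWAS region, and a
#' recessive trio variant filter demonstration on the risk region.  Every
#' output file is listed in a manifest with its md5 hash, so a rerun with
#' the same configuration and seed reproduces identical hashes.  A failing
#' stage aborts with the stage named; outputs of completed stages are kept.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the manifest path, per-stage outputs and
#'   the parameter list.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  results <- list()
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  bundle <- NULL

  if ("simulate" %in% config$stages) {
    bundle <- stage("simulate", function() simulate_cohort(config$sim))
    stage("simulate", function() {
      write_ped_map(bundle$genotypes, path("cohort.ped"), path("cohort.map"),
                    bundle$phenotypes, bundle$pedigree)
      write_haplotypes(bundle$genotypes, path("cohort.haps.tsv"))
      write_tsv_table(bundle$pedigree, path("pedigree.tsv"))
      write_tsv_table(bundle$phenotypes, path("phenotypes.tsv"))
      write_ped_map(bundle$panel, path("panel.ped"), path("panel.map"))
    })
    files <- c(files, path(c("cohort.ped", "cohort.map", "cohort.haps.tsv",
                             "pedigree.tsv", "phenotypes.tsv",
                             "panel.ped", "panel.map")))
    results$simulate <- bundle
  }
  if (is.null(bundle)) stop("pipeline currently requires the simulate stage")

  if ("kinship" %in% config$stages) {
    K <- stage("kinship", function() kinship_matrix(bundle$pedigree))
    write.table(round(K, 6), path("kinship.tsv"), sep = "\t", quote = FALSE)
    files <- c(files, path("kinship.tsv"))
    results$kinship <- K
  }

  if ("network" %in% config$stages) {
    net <- stage("network", function() {
      D <- ibs_distance(bundle$genotypes)
      mutual_knn_network(D, k = config$network_k, labels = bundle$phenotypes)
    })
    write_network(net, path("network_edges.tsv"), path("network_nodes.tsv"))
    files <- c(files, path(c("network_edges.tsv", "network_nodes.tsv")))
    results$network <- net
  }

  gwas <- NULL
  if ("gwas" %in% config$stages) {
    gwas <- stage("gwas", function()
      mlma_gwas(bundle$genotypes, bundle$phenotypes, maf = config$maf))
    write.table(gwas$assoc, path("assoc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(manhattan_data(gwas$assoc), path("manhattan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, path(c("assoc.tsv", "manhattan.tsv")))
    results$gwas <- gwas
  }

  if ("css" %in% config$stages) {
    cases <- bundle$phenotypes$sample_id[bundle$phenotypes$status == "case"]
    scan <- stage("css", function()
      css_scan(subset_genotypes(bundle$genotypes, samples = cases),
               bundle$panel, window_bp = config$css_window_bp,
               quantile = config$css_quantile))
    write.table(scan$css, path("css.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(scan$regions, path("css_regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, path(c("css.tsv", "css_regions.tsv")))
    results$css <- scan
  }

  if ("haplo" %in% config$stages) {
    hp <- stage("haplo", function() {
      top <- if (!is.null(gwas)) gwas$assoc[which.min(gwas$assoc$p), ]
             else NULL
      risk <- attr(bundle$genotypes, "risk")
      region_chrom <- if (!is.null(top)) top$chrom else risk$chrom
      snp <- bundle$genotypes$snp_table
      reg <- which(snp$chrom == region_chrom)
      # centre a window of ~30 SNPs on the top hit
      if (!is.null(top)) {
        ci <- which(snp$chrom == region_chrom & snp$pos_bp == top$pos_bp)
        reg <- reg[abs(reg - ci) <= 15]
      }
      wins <- sliding_windows(length(reg), config$hap_widths[1],
                              config$hap_widths[2])
      top_win <- window_haplotype_freqs(bundle$genotypes,
                                        c(reg[1], config$hap_widths[2]),
                                        bundle$phenotypes)
      blocks <- haplotype_blocks(bundle$genotypes, reg)
      roh <- roh_in_region(bundle$genotypes, reg, config$roh_min_snps)
      core <- reg[seq(max(1, (length(reg) - 2) %/% 2), length.out = 3)]
      ht <- homozygosity_test(bundle$genotypes, core, bundle$phenotypes)
      list(windows = wins, top_window = top_win, blocks = blocks,
           roh = roh, hom_test = ht, region = reg)
    })
    write.table(hp$blocks, path("hap_blocks.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(hp$roh, path("roh.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(cohort = rownames(hp$hom_test$table),
                           hp$hom_test$table,
                           p = hp$hom_test$p),
                path("homozygosity_test.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, path(c("hap_blocks.tsv", "roh.tsv",
                             "homozygosity_test.tsv")))
    results$haplo <- hp
  }

  if ("variants" %in% config$stages) {
    vr <- stage("variants", function() {
      # demonstrate the trio filter on the planted risk region: take one
      # affected risk homozygote, one heterozygous parent-like carrier and
      # one non-risk control, typed at the risk-span SNPs
      risk <- attr(bundle$genotypes, "risk")
      rd <- risk_dose(bundle$genotypes)
      aff <- which(rd == 2L)[1]; car <- which(rd == 1L)[1]
      ctl <- which(rd == 0L)[1]
      if (anyNA(c(aff, car, ctl))) stop("no complete trio in the simulated cohort")
      snp <- bundle$genotypes$snp_table[risk$snp_idx, ]
      # express doses relative to the risk allele at each span SNP
      orient <- function(i) {
        d <- bundle$genotypes$doses[i, risk$snp_idx]
        ifelse(risk$pattern == 1L, d, 2L - d)
      }
      variants <- data.frame(chromosome = as.character(snp$chrom),
                             position_bp = snp$pos_bp,
                             ref_allele = ifelse(risk$pattern == 1L,
                                                 snp$allele_A, snp$allele_B),
                             alt_allele = ifelse(risk$pattern == 1L,
                                                 snp$allele_B, snp$allele_A),
                             var_type = "SNP", type = "SNP", gene = "",
                             exon = "", consequence = "", aa_change = "-",
                             stringsAsFactors = FALSE)
      trio <- data.frame(affected = orient(aff), carrier = orient(car),
                         control = orient(ctl))
      recessive_filter(variants, trio)
    })
    write_variant_table(vr, path("variants_recessive.tsv"))
    files <- c(files, path("variants_recessive.tsv"))
    results$variants <- vr
  }

  params <- list(seed = config$seed, stages = paste(config$stages, collapse = ","),
                 maf = config$maf, network_k = config$network_k,
                 css_window_bp = config$css_window_bp,
                 css_quantile = config$css_quantile,
                 q_thresholds = paste(config$q_thresholds, collapse = ","),
                 hap_widths = paste(config$hap_widths, collapse = "-"),
                 n_founders = config$sim$n_founders,
                 n_chromosomes = config$sim$n_chromosomes,
                 snps_per_chromosome = config$sim$snps_per_chromosome)
  manifest <- path("run_manifest.txt")
  write_run_manifest(manifest, params, files)
  invisible(list(manifest = manifest, files = files, params = params,
                 results = results))
}
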