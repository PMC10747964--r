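#' Read genotypes from PLINK-style PED/MAP text files
#'
#' The PED dialect has six leading columns (family, id, sire, dam, sex,
#' phenotype coded 1 = control / 2 = case / other = missing) followed by two
#' allele columns per SNP; `0 0` is a missing genotype.  The MAP file has
#' columns chromosome, SNP id, genetic position (ignored) and bp position,
#' optionally followed by the two allele codes (A then counted allele B) as
#' written by [write_ped_map()].  When the MAP declares alleles, doses count
#' the declared B allele; otherwise the minor allele in the file is counted
#' (ties broken by first appearance) and recorded in the returned SNP table.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return list with `genotypes` (a [genotype_matrix()], unphased) and
#'   `phenotypes` (a phenotype table; `age_years` is `NA`, PED carries none).
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  ncols <- lengths(map_tok)
  if (length(unique(ncols)) != 1L || !(ncols[1] %in% c(4L, 6L)))
    stop("parse error in ", map_path, ": MAP rows must all have 4 or 6 columns (line ",
         which(ncols != ncols[1])[1] %||% 1L, ")")
  mm <- do.call(rbind, map_tok)
  m <- nrow(mm)
  snp <- data.frame(snp_id = mm[, 2], chrom = type_chrom(mm[, 1]),
                    pos_bp = as.numeric(mm[, 4]),
                    allele_A = if (ncols[1] == 6L) mm[, 5] else NA_character_,
                    allele_B = if (ncols[1] == 6L) mm[, 6] else NA_character_,
                    stringsAsFactors = FALSE)
  if (anyNA(snp$pos_bp)) stop("parse error in ", map_path, ": non-numeric bp position")

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  tok <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  bad <- which(lengths(tok) != want)
  if (length(bad))
    stop("parse error in ", ped_path, ": line ", bad[1], " has ",
         lengths(tok)[bad[1]], " fields, expected ", want,
         " (6 + 2 x ", m, " SNPs)")
  pm <- do.call(rbind, tok)
  ids <- pm[, 2]
  if (anyDuplicated(ids))
    stop("parse error in ", ped_path, ": duplicated sample id '",
         ids[duplicated(ids)][1], "' (line ", which(duplicated(ids))[1], ")")
  n <- nrow(pm)
  a1 <- pm[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- pm[, 6L + 2L * seq_len(m), drop = FALSE]
  valid <- c("A", "C", "G", "T", "1", "2", "0", "B")
  if (!all(a1 %in% valid) || !all(a2 %in% valid))
    stop("parse error in ", ped_path, ": allele codes must be A/C/G/T/1/2/0")
  miss <- a1 == "0" | a2 == "0"
  doses <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- c(a1[!miss[, j], j], a2[!miss[, j], j])
    seen <- unique(obs)
    if (length(seen) > 2L)
      stop("parse error: SNP ", snp$snp_id[j], " has >2 alleles")
    if (!is.na(snp$allele_B[j])) {
      counted <- snp$allele_B[j]
      other <- snp$allele_A[j]
    } else if (length(seen) == 0L) {
      counted <- "B"; other <- "A"
    } else {
      # minor allele, first-seen order breaking ties
      cnt <- vapply(seen, function(a) sum(obs == a), numeric(1))
      counted <- seen[order(cnt, seq_along(seen))][1]
      other <- setdiff(seen, counted)[1] %||% NA_character_
      snp$allele_B[j] <- counted
      snp$allele_A[j] <- if (is.na(other)) "?" else other
    }
    dj <- (a1[, j] == counted) + (a2[, j] == counted)
    dj[miss[, j]] <- NA_integer_
    doses[, j] <- as.integer(dj)
  }
  pheno_code <- pm[, 6]
  status <- ifelse(pheno_code == "2", "case",
                   ifelse(pheno_code == "1", "control", NA_character_))
  pheno <- data.frame(sample_id = ids, status = status,
                      age_years = NA_real_, stringsAsFactors = FALSE)
  class(pheno) <- c("phenotype_table", "data.frame")
  list(genotypes = genotype_matrix(doses, snp, ids), phenotypes = pheno)
}

type_chrom <- function(x) {
  xi <- suppressWarnings(as.integer(x))
  if (anyNA(xi)) x else xi
}

#' Write genotypes (and phenotypes) as PED/MAP text files
#'
#' Writes the extended 6-column MAP (chromosome, id, 0, bp, allele A, allele
#' B) so that [read_ped_map()] round-trips the dose matrix bit-exactly.
#' Phase, when present, is preserved in the allele order of each genotype
#' pair; otherwise heterozygotes are written `A B`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @param phenotypes optional phenotype table supplying status (case -> 2,
#'   control -> 1) for PED column 6.
#' @param pedigree optional pedigree supplying sire/dam/sex columns.
#' @return invisibly, the two paths.
#' @export
write_ped_map <- function(genotypes, ped_path, map_path,
                          phenotypes = NULL, pedigree = NULL) {
  snp <- genotypes$snp_table
  map <- data.frame(snp$chrom, snp$snp_id, 0L, snp$pos_bp,
                    snp$allele_A, snp$allele_B)
  write.table(map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- length(genotypes$sample_ids); m <- nrow(snp)
  A <- matrix(rep(snp$allele_A, each = n), n, m)
  B <- matrix(rep(snp$allele_B, each = n), n, m)
  if (!is.null(genotypes$haplotypes)) {
    g1 <- ifelse(genotypes$haplotypes$h1 == 1L, B, A)
    g2 <- ifelse(genotypes$haplotypes$h2 == 1L, B, A)
  } else {
    d <- genotypes$doses
    g1 <- ifelse(d >= 1L, B, A)
    g2 <- ifelse(d == 2L, B, A)
  }
  na <- is.na(genotypes$doses)
  g1[na] <- "0"; g2[na] <- "0"
  inter <- matrix("", n, 2L * m)
  inter[, seq(1L, 2L * m, 2L)] <- g1
  inter[, seq(2L, 2L * m, 2L)] <- g2
  ids <- genotypes$sample_ids
  sire <- dam <- rep("0", n); sex <- rep("0", n)
  if (!is.null(pedigree)) {
    pi <- match(ids, pedigree$id)
    sire <- ifelse(is.na(pedigree$sire[pi]), "0", pedigree$sire[pi])
    dam <- ifelse(is.na(pedigree$dam[pi]), "0", pedigree$dam[pi])
    sex <- ifelse(pedigree$sex[pi] == "M", "1", "2")
  }
  phe <- rep("0", n)
  if (!is.null(phenotypes)) {
    si <- match(ids, phenotypes$sample_id)
    phe <- ifelse(phenotypes$status[si] == "case", "2",
                  ifelse(phenotypes$status[si] == "control", "1", "0"))
  }
  ped <- cbind("FAM1", ids, sire, dam, sex, phe, inter)
  write.table(ped, ped_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Write/read a phased haplotype sidecar
#'
#' One row per haplotype (two per sample, suffixes `_1`/`_2`), alleles as a
#' 0/1 string in SNP-map order.
#' @param genotypes phased [genotype_matrix()].
#' @param path output path.
#' @export
write_haplotypes <- function(genotypes, path) {
  if (is.null(genotypes$haplotypes)) stop("genotypes are not phased")
  h1 <- apply(genotypes$haplotypes$h1, 1, paste, collapse = "")
  h2 <- apply(genotypes$haplotypes$h2, 1, paste, collapse = "")
  out <- data.frame(hap_id = c(paste0(genotypes$sample_ids, "_1"),
                               paste0(genotypes$sample_ids, "_2")),
                    alleles = c(h1, h2))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotypes
#' @param genotypes_unphased the matching unphased genotype matrix whose
#'   doses/map the sidecar completes.
#' @export
read_haplotypes <- function(path, genotypes_unphased) {
  tb <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  ids <- genotypes_unphased$sample_ids
  pick <- function(sfx) {
    r <- match(paste0(ids, sfx), tb$hap_id)
    if (anyNA(r)) stop("parse error: haplotype sidecar missing samples")
    do.call(rbind, lapply(strsplit(tb$alleles[r], ""), as.integer))
  }
  genotype_matrix(genotypes_unphased$doses, genotypes_unphased$snp_table,
                  ids, list(h1 = pick("_1"), h2 = pick("_2")))
}

#' Write a pedigree or phenotype table as TSV
#' @param x pedigree or phenotype data.frame.
#' @param path output path.
#' @export
write_tsv_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pedigree TSV (id, sire, dam, optional sex/generation/case columns)
#' @param path input path.
#' @export
read_pedigree <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(tb)))
    stop("parse error: pedigree TSV needs columns id, sire, dam")
  for (col in c("sire", "dam"))
    tb[[col]][tb[[col]] %in% c("", "0", "NA")] <- NA_character_
  class(tb) <- c("pedigree", "data.frame")
  tb
}

#' Read a phenotype TSV (sample_id, status, age_years)
#' @param path input path.
#' @export
read_phenotypes <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(tb)))
    stop("parse error: phenotype TSV needs sample_id and status columns")
  if (!all(tb$status %in% c("case", "control", NA)))
    stop("parse error: status must be 'case' or 'control'")
  if (is.null(tb$age_years)) tb$age_years <- NA_real_
  class(tb) <- c("phenotype_table", "data.frame")
  tb
}

# ---- variant tables ---------------------------------------------------------

#' Read a variant summary table (risk-region variant list)
#'
#' Parses the tab-separated variant summary shipped with the package (and any
#' table with the same columns: Location, Type, Ref, Allele, Gene, Exon
#' Number, Consequence, A.A.Change).  Insertion locations written `a^b` mean
#' "inserted between positions a and b" and are parsed to position `a` with
#' the insertion flag set.  `SNV` is treated as a synonym of `SNP` when
#' counting single-nucleotide substitutions.
#'
#' @param path path to the TSV.
#' @param chromosome chromosome label to attach (the table itself is
#'   region-scoped and carries none).
#' @return data.frame of variant records: `chromosome`, `position_bp`,
#'   `ref_allele`, `alt_allele`, `var_type` (as written), `type`
#'   (canonicalised `"SNP"`/`"Ins"`), `gene`, `exon`, `consequence`,
#'   `aa_change`.
#' @export
read_variant_table <- function(path, chromosome = "13") {
  tb <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("Location", "Type", "Ref", "Allele", "Gene",
            "Exon Number", "Consequence", "A.A.Change")
  if (!all(need %in% names(tb)))
    stop("parse error: variant table needs columns: ",
         paste(setdiff(need, names(tb)), collapse = ", "))
  if (nrow(tb) == 0L) return(empty_variants(chromosome))
  loc <- tb$Location
  ins <- grepl("^[0-9]+\\^[0-9]+$", loc)
  plain <- grepl("^[0-9]+$", loc)
  if (any(!ins & !plain))
    stop("parse error: unparseable location '", loc[!ins & !plain][1], "'")
  pos <- numeric(length(loc))
  pos[ins] <- as.numeric(sub("\\^.*$", "", loc[ins]))
  pos[!ins] <- as.numeric(loc[!ins])
  vt <- tb$Type
  canon <- ifelse(vt %in% c("SNP", "SNV"), "SNP",
                  ifelse(vt == "Ins", "Ins", NA_character_))
  if (anyNA(canon)) stop("parse error: unknown variant type '", vt[is.na(canon)][1], "'")
  if (any((canon == "Ins") != (tb$Ref == "-")))
    stop("parse error: insertion records must (and only they may) have Ref '-'")
  out <- data.frame(chromosome = chromosome, position_bp = pos,
                    ref_allele = tb$Ref, alt_allele = tb$Allele,
                    var_type = vt, type = canon,
                    gene = tb$Gene, exon = tb[["Exon Number"]],
                    consequence = tb$Consequence, aa_change = tb[["A.A.Change"]],
                    stringsAsFactors = FALSE)
  out
}

empty_variants <- function(chromosome = character(0)) {
  data.frame(chromosome = character(0), position_bp = numeric(0),
             ref_allele = character(0), alt_allele = character(0),
             var_type = character(0), type = character(0), gene = character(0),
             exon = character(0), consequence = character(0),
             aa_change = character(0), stringsAsFactors = FALSE)
}

#' Write a variant table in the summary-table layout
#' @param variants a variant record data.frame (see [read_variant_table()]).
#' @param path output path.
#' @export
write_variant_table <- function(variants, path) {
  loc <- ifelse(variants$type == "Ins",
                sprintf("%d^%d", as.integer(variants$position_bp),
                        as.integer(variants$position_bp) + 1L),
                as.character(as.integer(variants$position_bp)))
  out <- data.frame(Location = loc, Type = variants$var_type,
                    Ref = variants$ref_allele, Allele = variants$alt_allele,
                    Gene = variants$gene, `Exon Number` = variants$exon,
                    Consequence = variants$consequence,
                    A.A.Change = variants$aa_change, check.names = FALSE)
  names(out)[8] <- "A.A.Change"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a minimal VCF-like TSV
#'
#' Columns CHROM, POS, REF, ALT then one column per sample with genotypes
#' `0/0`, `0/1`, `1/1` or `./.`.  Returns variant records plus an alt-allele
#' dose matrix (samples x variants).
#' @param path input path.
#' @export
read_vcf_like <- function(path) {
  tb <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("CHROM", "POS", "REF", "ALT")
  if (!all(need %in% names(tb)))
    stop("parse error: VCF-like file needs CHROM, POS, REF, ALT columns")
  samples <- setdiff(names(tb), need)
  gt_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA_integer_)
  doses <- matrix(NA_integer_, length(samples), nrow(tb),
                  dimnames = list(samples, NULL))
  for (s in samples) {
    g <- tb[[s]]
    if (!all(g %in% names(gt_map)))
      stop("parse error: bad genotype '", g[!(g %in% names(gt_map))][1],
           "' for sample ", s)
    doses[s, ] <- unname(gt_map[g])
  }
  pos <- as.numeric(tb$POS)
  if (anyNA(pos)) stop("parse error: non-numeric POS")
  variants <- data.frame(chromosome = tb$CHROM, position_bp = pos,
                         ref_allele = tb$REF, alt_allele = tb$ALT,
                         var_type = ifelse(tb$REF == "-", "Ins", "SNP"),
                         type = ifelse(tb$REF == "-", "Ins", "SNP"),
                         gene = "", exon = "", consequence = "",
                         aa_change = "-", stringsAsFactors = FALSE)
  list(variants = variants, doses = doses, samples = samples)
}

#' Read a BED-like annotation of gene features
#'
#' Columns: chrom, start, end, feature, gene, then optional `key=value;...`
#' attributes (e.g. `frame=0;cds_seq=ATG...` on CDS rows).  Intervals are
#' 0-based half-open on disk (BED convention) and converted to 1-based
#' inclusive on read; the conversion is reported once per call.
#' @param path input path.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive), `feature`,
#'   `gene`, `attrs` (named list column).
#' @export
read_bed_annotation <- function(path) {
  tb <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", comment.char = "#")
  if (ncol(tb) < 5L)
    stop("parse error: annotation needs >= 5 columns (chrom, start, end, feature, gene)")
  names(tb)[1:5] <- c("chrom", "start", "end", "feature", "gene")
  start0 <- as.numeric(tb$start); end0 <- as.numeric(tb$end)
  if (anyNA(start0) || anyNA(end0)) stop("parse error: non-numeric interval bounds")
  message("read_bed_annotation: converted ", nrow(tb),
          " intervals from 0-based half-open to 1-based inclusive")
  attrs <- rep(list(list()), nrow(tb))
  if (ncol(tb) >= 6L) {
    attrs <- lapply(tb[[6]], function(s) {
      if (is.na(s) || !nzchar(s)) return(list())
      kv <- strsplit(strsplit(s, ";")[[1]], "=")
      stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
    })
  }
  out <- data.frame(chrom = tb$chrom, start = start0 + 1, end = end0,
                    feature = tb$feature, gene = tb$gene,
                    stringsAsFactors = FALSE)
  out$attrs <- attrs
  out
}

#' Read / write the structured run configuration (YAML `key: value` text)
#' @param path config path.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param config a named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a run manifest: parameters, seed and md5 hash of every output file
#' @param path manifest path.
#' @param params named list of scalar parameters (seeds included).
#' @param files character vector of output file paths to hash.
#' @export
write_run_manifest <- function(path, params, files) {
  lines <- c(sprintf("generated: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             vapply(names(params), function(k)
               sprintf("param %s: %s", k, paste(format(params[[k]]), collapse = ",")),
               ""))
  ex <- files[file.exists(files)]
  if (length(ex))
    lines <- c(lines, sprintf("file %s: md5=%s", basename(ex), tools::md5sum(ex)))
  writeLines(lines, path)
  invisible(path)
}
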