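#' Recessive-pattern trio filter
#'
#' Keeps variants consistent with a fully recessive disease model in the
#' sequencing trio: the affected dog (a risk-haplotype homozygote) must be
#' homozygous for the alternate allele, the carrier parent (risk-haplotype
#' heterozygote) heterozygous, and the unrelated control (non-risk
#' homozygote) homozygous reference.  Variants with a missing call in any
#' role are dropped and counted separately.  The optional relaxation admits
#' a hom-alt carrier (incomplete penetrance); it is off by default.
#'
#' @param variants variant record data.frame.
#' @param trio data.frame (one row per variant) with columns `affected`,
#'   `carrier`, `control` holding alt-allele doses 0/1/2 or `NA`.
#' @param allow_carrier_homalt relax the carrier requirement to dose >= 1.
#' @return the retained variants; attributes `n_removed` (pattern failures)
#'   and `n_missing` (dropped for missing calls).
#' @export
recessive_filter <- function(variants, trio, allow_carrier_homalt = FALSE) {
  stopifnot(nrow(variants) == nrow(trio),
            all(c("affected", "carrier", "control") %in% names(trio)))
  miss <- is.na(trio$affected) | is.na(trio$carrier) | is.na(trio$control)
  carrier_ok <- if (allow_carrier_homalt) trio$carrier >= 1L
                else trio$carrier == 1L
  keep <- !miss & trio$affected == 2L & carrier_ok & trio$control == 0L
  out <- variants[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep & !miss)
  attr(out, "n_missing") <- sum(miss)
  out
}

#' Restrict variants to a chromosomal region
#'
#' @param variants variant record data.frame.
#' @param chromosome chromosome label.
#' @param start_bp,end_bp 1-based inclusive interval bounds.
#' @return the variants with `start_bp <= position_bp <= end_bp` on the
#'   chromosome.
#' @export
region_filter <- function(variants, chromosome, start_bp, end_bp) {
  if (!is.numeric(start_bp) || !is.numeric(end_bp) || is.na(start_bp) ||
      is.na(end_bp) || start_bp > end_bp)
    stop("malformed region: need numeric start_bp <= end_bp")
  keep <- variants$chromosome == as.character(chromosome) &
    variants$position_bp >= start_bp & variants$position_bp <= end_bp
  variants[keep, , drop = FALSE]
}

#' Classify the consequence of a variant against gene annotation
#'
#' Interval-based classifier: a variant overlapping no gene interval is
#' `"intergenic"`; inside a UTR interval it is `"5 prime UTR"` or
#' `"3 prime UTR"`; a substitution inside a CDS whose annotated codon changes
#' amino acid (standard genetic code) is `"missense"`; everything else in a
#' gene is `"gene-coding other"` (including CDS substitutions without frame
#' or sequence annotation, which also raise a warning, insertions, and
#' synonymous changes).  CDS rows of the annotation may carry
#' `frame=<0|1|2>;cds_seq=<sequence>` attributes giving the reading frame at
#' the interval start and the interval's coding sequence on the forward
#' strand.
#'
#' @param variant one variant record (single-row data.frame or list with
#'   `chromosome`, `position_bp`, `ref_allele`, `alt_allele`, `type`).
#' @param annotation a [read_bed_annotation()] table (1-based inclusive).
#' @return one of `"intergenic"`, `"5 prime UTR"`, `"3 prime UTR"`,
#'   `"missense"`, `"gene-coding other"`.
#' @export
classify_consequence <- function(variant, annotation) {
  pos <- variant$position_bp
  chrom <- as.character(variant$chromosome)
  hit <- annotation$chrom == chrom & annotation$start <= pos & annotation$end >= pos
  genes <- annotation[hit & annotation$feature == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) return("intergenic")
  feats <- annotation[hit, , drop = FALSE]
  if (any(feats$feature == "UTR5")) return("5 prime UTR")
  if (any(feats$feature == "UTR3")) return("3 prime UTR")
  cds <- feats[feats$feature == "CDS", , drop = FALSE]
  if (nrow(cds) >= 1L && identical(variant$type, "SNP")) {
    at <- cds$attrs[[1]]
    if (is.null(at$frame) || is.null(at$cds_seq)) {
      warning("CDS without frame/sequence annotation at ", chrom, ":", pos,
              "; classified as gene-coding other")
      return("gene-coding other")
    }
    frame <- as.integer(at$frame)
    seq <- toupper(at$cds_seq)
    off <- pos - cds$start[1]                # 0-based offset into the interval
    idx <- off + frame                       # 0-based position in codon frame
    cstart <- idx - idx %% 3 - frame + 1     # 1-based codon start in seq
    if (cstart < 1 || cstart + 2 > nchar(seq)) return("gene-coding other")
    codon <- substr(seq, cstart, cstart + 2)
    within <- off - (cstart - 1) + 1         # 1..3 position inside the codon
    if (substr(codon, within, within) != toupper(variant$ref_allele))
      warning("reference allele does not match annotated codon at ",
              chrom, ":", pos)
    alt_codon <- codon
    substr(alt_codon, within, within) <- toupper(variant$alt_allele)
    aa_ref <- unname(GENETIC_CODE[codon])
    aa_alt <- unname(GENETIC_CODE[alt_codon])
    if (!is.na(aa_ref) && !is.na(aa_alt) && aa_ref != aa_alt)
      return("missense")
    return("gene-coding other")
  }
  "gene-coding other"
}

#' Classify many variants at once
#'
#' @param variants variant record data.frame.
#' @param annotation a [read_bed_annotation()] table.
#' @return the variants with the `consequence` column (re)filled.
#' @export
classify_variants <- function(variants, annotation) {
  variants$consequence <- vapply(seq_len(nrow(variants)), function(i)
    classify_consequence(variants[i, ], annotation), character(1))
  variants
}
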