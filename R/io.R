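# Text-format I/O: TSV tables with '#' metadata headers, FAM-style
# pedigrees, PLINK-style transposed genotypes, and VCF v4.2 with dosages.
# All genomic coordinates are 1-based inclusive.

#' Write a data.frame as TSV with '#'-prefixed metadata header lines
#'
#' @param x data.frame.
#' @param path output file.
#' @param meta named character vector written as `# key: value` lines.
#' @export
write_tsv_meta <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path input file.
#' @return data.frame; '#' lines are skipped.
#' @export
read_tsv_meta <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a pedigree as 6-column FAM-style TSV
#'
#' Columns: family, individual, father, mother, sex (1 = male, 2 = female),
#' phenotype (0 = missing). Missing parents are coded 0.
#'
#' @param pedigree data.frame from [gen_pedigrees()].
#' @param path output file.
#' @export
write_fam <- function(pedigree, path) {
  fam <- data.frame(
    fid = pedigree$fid, iid = pedigree$iid,
    father = ifelse(is.na(pedigree$father), "0", pedigree$father),
    mother = ifelse(is.na(pedigree$mother), "0", pedigree$mother),
    sex = ifelse(pedigree$sex == "male", 1L, 2L), phe = 0L)
  utils::write.table(fam, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column FAM-style pedigree
#'
#' @param path input file.
#' @param cohort cohort label to attach to every row.
#' @return pedigree data.frame (fid, iid, father, mother, sex, cohort).
#' @export
read_fam <- function(path, cohort = "cohort1") {
  fam <- utils::read.table(path, stringsAsFactors = FALSE)
  data.frame(fid = as.character(fam[[1]]), iid = as.character(fam[[2]]),
             father = ifelse(fam[[3]] == "0", NA_character_,
                             as.character(fam[[3]])),
             mother = ifelse(fam[[4]] == "0", NA_character_,
                             as.character(fam[[4]])),
             sex = ifelse(fam[[5]] == 1, "male", "female"),
             cohort = cohort, stringsAsFactors = FALSE)
}

#' Write genotypes as PLINK-style transposed text
#'
#' One row per SNP: snp, chrom, pos, ref, alt, then one dosage column per
#' sample (header row carries sample ids).
#'
#' @param genotypes genotype_matrix.
#' @param path output file.
#' @export
write_plink_t <- function(genotypes, path) {
  tab <- cbind(genotypes$snps[, c("snp", "chrom", "pos", "ref", "alt")],
               as.data.frame(t(genotypes$dosage)))
  write_tsv_meta(tab, path,
                 meta = c(format = "plink-transposed-dosage",
                          coordinates = "1-based"))
}

#' Write genotypes as VCF v4.2 with GT and DS fields
#'
#' Hard calls are written as GT (0/0, 0/1, 1/1 from rounded dosage) and the
#' dosage itself as DS.
#'
#' @param genotypes genotype_matrix.
#' @param path output file.
#' @export
write_vcf <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", genotypes$samples),
                     collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes$dosage))) {
    d <- genotypes$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[pmin(pmax(round(d), 0), 2) + 1])
    ds <- ifelse(is.na(d), ".", format(d, trim = TRUE))
    s <- genotypes$snps[j, ]
    writeLines(paste(c(s$chrom, s$pos, s$snp, s$ref, s$alt, ".", "PASS",
                       ".", "GT:DS", paste(gt, ds, sep = ":")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype_matrix (DS field honored)
#'
#' Uses vcfR when available; expects an uncompressed or bgzipped VCF with
#' GT and optionally DS in FORMAT. DS takes precedence over GT.
#'
#' @param path VCF file.
#' @return genotype_matrix.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
  }
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dosage <- t(ds)
  snps <- data.frame(snp = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF,
                     alt = fix$ALT,
                     maf = pmin(colMeans(dosage, na.rm = TRUE) / 2,
                                1 - colMeans(dosage, na.rm = TRUE) / 2),
                     genotyped = TRUE, info = 1, stringsAsFactors = FALSE)
  colnames(dosage) <- snps$snp
  structure(list(dosage = dosage, snps = snps,
                 samples = rownames(dosage)),
            class = "genotype_matrix")
}
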