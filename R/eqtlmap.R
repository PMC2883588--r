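# Stage III: cis-candidate gene selection around associated SNPs, LD
# surrogate SNPs, eQTL association (linear or Kruskal-Wallis), and
# allele-direction harmonization between eQTL and GWAS effects.

#' Candidate genes in cis of a SNP
#'
#' A gene is a cis candidate when the SNP lies within the gene body or
#' within `window` bases 5'-upstream of the strand-aware transcription
#' start (upstream of `start` for + genes, downstream of `end` for -
#' genes). The window bound is inclusive at exactly `window` bases.
#'
#' @param snp list or one-row data.frame with chrom and pos (1-based).
#' @param annotations data.frame(gene, chrom, start, end, strand) with
#'   1-based inclusive coordinates.
#' @param window upstream window in bases (default 500000).
#' @return data.frame(gene, location, distance_kb): location is "intragenic"
#'   or "upstream"; distance_kb is 0 inside the gene, else the distance to
#'   the TSS in kb (1 decimal).
#' @export
cis_candidates <- function(snp, annotations, window = 500000) {
  ann <- annotations[annotations$chrom == snp$chrom, , drop = FALSE]
  if (!nrow(ann))
    return(data.frame(gene = character(), location = character(),
                      distance_kb = numeric(), stringsAsFactors = FALSE))
  pos <- snp$pos
  inside <- pos >= ann$start & pos <= ann$end
  tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  updist <- ifelse(ann$strand == "+", tss - pos, pos - tss)
  upstream <- !inside & updist > 0 & updist <= window
  keep <- inside | upstream
  data.frame(gene = ann$gene[keep],
             location = ifelse(inside[keep], "intragenic", "upstream"),
             distance_kb = ifelse(inside[keep], 0,
                                  round(updist[keep] / 1000, 1)),
             stringsAsFactors = FALSE)
}

#' LD between two SNPs as squared dosage correlation
#'
#' The composite-LD convention for unphased data: the squared Pearson
#' correlation of the two dosage vectors. Monomorphic input gives NA.
#'
#' @param dosages_a,dosages_b aligned numeric dosage vectors.
#' @return r-squared in [0, 1], or NA.
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  if (stats::sd(dosages_a, na.rm = TRUE) == 0 ||
      stats::sd(dosages_b, na.rm = TRUE) == 0) return(NA_real_)
  stats::cor(dosages_a, dosages_b, use = "complete.obs")^2
}

#' Pick an LD surrogate for a SNP absent from an expression panel
#'
#' Returns the panel SNP with the highest r-squared to the target subject
#' to the minimum (default 0.5); ties are broken by smallest genomic
#' distance to the target, then lexicographic id.
#'
#' @param target_dosages dosage vector of the target SNP in a reference
#'   sample aligned with `panel`.
#' @param panel genotype_matrix of candidate surrogates (same samples).
#' @param target_pos target SNP position (for the distance tie-break).
#' @param r2_min minimum r-squared (default 0.5).
#' @return NULL if none qualifies, else list(snp, r2, phase) where phase is
#'   the sign of the dosage correlation (allele orientation of the
#'   surrogate relative to the target).
#' @export
pick_surrogate <- function(target_dosages, panel, target_pos = NA,
                           r2_min = 0.5) {
  r <- suppressWarnings(
    stats::cor(target_dosages, panel$dosage, use = "pairwise.complete.obs"))
  r2 <- drop(r)^2
  r2[is.na(r2)] <- -Inf
  ok <- which(r2 >= r2_min)
  if (!length(ok)) return(NULL)
  best <- r2[ok]
  top <- ok[best == max(best)]
  if (length(top) > 1 && !is.na(target_pos)) {
    d <- abs(panel$snps$pos[top] - target_pos)
    top <- top[d == min(d)]
  }
  if (length(top) > 1) top <- top[order(panel$snps$snp[top])][1]
  list(snp = panel$snps$snp[top], r2 = unname(r2[top]),
       phase = unname(sign(drop(r)[top])))
}

#' Single-gene cis-eQTL association test
#'
#' Linear mode regresses (pre-adjusted) expression on additive dosage and
#' tests the slope; kruskal_wallis mode rank-tests expression across the
#' hard-call genotype groups. Significance is called at the FDR-derived
#' cutoff `p_sig` (default 0.005).
#'
#' @param dosages numeric dosage vector.
#' @param expression aligned expression vector (covariate-adjusted
#'   upstream).
#' @param method "linear" or "kruskal_wallis".
#' @param p_sig significance cutoff (default 0.005).
#' @return data.frame(method, p, direction, significant). Direction is the
#'   slope sign (NA for the rank test).
#' @export
eqtl_test <- function(dosages, expression, method = c("linear",
                      "kruskal_wallis"), p_sig = 0.005) {
  method <- match.arg(method)
  ok <- stats::complete.cases(dosages, expression)
  x <- dosages[ok]; y <- expression[ok]
  if (method == "linear") {
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)$coefficients
    p <- sm["x", "Pr(>|t|)"]
    dir <- sign(sm["x", "Estimate"])
  } else {
    g <- factor(round(x), levels = 0:2)
    g <- droplevels(g)
    if (nlevels(g) < 2) stop("fewer than 2 genotype groups")
    p <- stats::kruskal.test(y, g)$p.value
    dir <- NA_real_
  }
  data.frame(method = method, p = p, direction = dir,
             significant = p < p_sig, stringsAsFactors = FALSE)
}

#' Express an eQTL effect on the GWAS-coded allele
#'
#' When the eQTL was measured on a surrogate SNP, the surrogate's allele
#' orientation relative to the GWAS target is the sign of their dosage
#' correlation (`ld_phase`); a negative phase flips the eQTL direction.
#' The joint statement describes what the trait-increasing allele does to
#' the transcript.
#'
#' @param gwas_direction GWAS effect sign (+1/-1) for the coded allele.
#' @param eqtl_direction eQTL effect sign on the surrogate's coded allele.
#' @param ld_phase +1/-1 (or NA when unknown).
#' @return data.frame(eqtl_on_gwas_allele, concordant, statement).
#' @export
harmonize_direction <- function(gwas_direction, eqtl_direction, ld_phase) {
  if (is.na(ld_phase) || ld_phase == 0)
    return(data.frame(eqtl_on_gwas_allele = NA_real_, concordant = NA,
                      statement = "indeterminate phase",
                      stringsAsFactors = FALSE))
  e <- eqtl_direction * ld_phase
  concordant <- e == gwas_direction
  updown <- if (e * gwas_direction > 0) "increases" else "decreases"
  statement <- sprintf("trait-increasing allele %s expression", updown)
  data.frame(eqtl_on_gwas_allele = e, concordant = concordant,
             statement = statement, stringsAsFactors = FALSE)
}
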