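# Stage IV synthesis: significance tiering with the four suggestive-SNP
# criteria, nearest-gene assignment, the two-route candidate-gene
# prioritization rule, and hypergeometric term enrichment with BH
# correction.

#' Tier meta-analysis results and apply the suggestive-SNP criteria
#'
#' Genome-wide tier: meta p below `genome_wide_p`. Suggestive candidates
#' must meet all four criteria: (1) meta p in (genome_wide_p, suggestive_p],
#' (2) discovery p strictly below `discovery_p`, (3) replication p at or
#' below `replication_p`, and (4) the same direction of effect in discovery
#' and replication. One lead SNP (smallest meta p) is kept per locus window.
#'
#' @param meta data.frame with snp, chrom, pos, p (meta), beta.
#' @param discovery data.frame with snp, p, direction.
#' @param replication data.frame with snp, p, direction (replication meta
#'   or single cohort); missing SNPs fail criterion 3 only if no cohort is
#'   available.
#' @param genome_wide_p,suggestive_p,discovery_p,replication_p thresholds
#'   (defaults 4.3e-7, 5e-5, 1e-3, 0.05).
#' @param locus_window bp window for collapsing to lead SNPs (default
#'   500000).
#' @return data.frame of candidate loci with a `tier` column
#'   ("genome_wide"/"suggestive") and the per-criterion logicals.
#' @export
tier_and_filter_suggestive <- function(meta, discovery, replication,
                                       genome_wide_p = 4.3e-7,
                                       suggestive_p = 5e-5,
                                       discovery_p = 1e-3,
                                       replication_p = 0.05,
                                       locus_window = 500000) {
  di <- match(meta$snp, discovery$snp)
  ri <- match(meta$snp, replication$snp)
  c1 <- meta$p > genome_wide_p & meta$p <= suggestive_p
  c2 <- !is.na(di) & discovery$p[di] < discovery_p
  c3 <- !is.na(ri) & replication$p[ri] <= replication_p
  c4 <- !is.na(di) & !is.na(ri) &
    sign(discovery$direction[di]) == sign(replication$direction[ri])
  tier <- ifelse(meta$p < genome_wide_p, "genome_wide",
                 ifelse(c1 & c2 & c3 & c4, "suggestive", "none"))
  out <- cbind(meta,
               data.frame(in_band = c1, discovery_ok = c2,
                          replication_ok = c3, direction_ok = c4,
                          tier = tier, stringsAsFactors = FALSE))
  out <- out[out$tier != "none", , drop = FALSE]
  if (!nrow(out)) return(out)
  # collapse to lead SNPs per locus window, most significant first
  out <- out[order(out$p), , drop = FALSE]
  lead <- logical(nrow(out))
  taken <- list()
  for (i in seq_len(nrow(out))) {
    ch <- out$chrom[i]; pos <- out$pos[i]
    hit <- FALSE
    for (t in taken)
      if (t$chrom == ch && abs(t$pos - pos) <= locus_window) {
        hit <- TRUE; break
      }
    if (!hit) {
      lead[i] <- TRUE
      taken[[length(taken) + 1L]] <- list(chrom = ch, pos = pos)
    }
  }
  out <- out[lead, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nearest gene and location descriptor for a SNP
#'
#' A SNP inside a gene body reports that gene as "intragenic"; an
#' intergenic SNP reports the gene whose nearer edge is closest, with the
#' distance in kb to one decimal. Equidistant genes are all reported.
#'
#' @param snp list/one-row data.frame with chrom and pos.
#' @param annotations data.frame(gene, chrom, start, end, strand).
#' @return data.frame(gene, location, distance_kb); zero rows when the
#'   chromosome has no annotation.
#' @export
assign_nearest_gene <- function(snp, annotations) {
  ann <- annotations[annotations$chrom == snp$chrom, , drop = FALSE]
  if (!nrow(ann)) {
    warning("no annotation on chromosome ", snp$chrom)
    return(data.frame(gene = character(), location = character(),
                      distance_kb = numeric(), stringsAsFactors = FALSE))
  }
  pos <- snp$pos
  inside <- pos >= ann$start & pos <= ann$end
  if (any(inside))
    return(data.frame(gene = ann$gene[inside], location = "intragenic",
                      distance_kb = 0, stringsAsFactors = FALSE))
  d <- pmin(abs(pos - ann$start), abs(pos - ann$end))
  best <- which(d == min(d))
  data.frame(gene = ann$gene[best], location = "intergenic",
             distance_kb = round(d[best] / 1000, 1),
             stringsAsFactors = FALSE)
}

#' Two-route candidate-gene prioritization
#'
#' Route "expression_2of3" fires when at least two of the three expression
#' signatures support the gene: PTH-regulated class ("+++up"/"+++down"),
#' maturation ANOVA significant at the screen's Bonferroni alpha, and
#' skeletal evidence in the embryo atlas. Route "lcms_pairs" fires when the
#' gene has at least `pairs_min` significant pleiotropic QTL/eQTL pairs.
#' Missing evidence counts as non-significant.
#'
#' @param evidence data.frame with columns gene, pth_class, maturation_sig
#'   (logical), atlas_skeletal (logical), lcms_pairs (integer); NAs
#'   allowed.
#' @param pairs_min LCMS pair threshold (default 2).
#' @return the evidence with columns n_expression_signatures, route
#'   ("expression_2of3", "lcms_pairs" — the first that fires — or "none")
#'   and prioritized.
#' @export
prioritize_genes <- function(evidence, pairs_min = 2) {
  pth <- !is.na(evidence$pth_class) &
    evidence$pth_class %in% c("+++up", "+++down")
  mat <- !is.na(evidence$maturation_sig) & evidence$maturation_sig
  atl <- !is.na(evidence$atlas_skeletal) & evidence$atlas_skeletal
  n_sig <- pth + mat + atl
  lcms <- !is.na(evidence$lcms_pairs) & evidence$lcms_pairs >= pairs_min
  route <- ifelse(n_sig >= 2, "expression_2of3",
                  ifelse(lcms, "lcms_pairs", "none"))
  evidence$n_expression_signatures <- n_sig
  evidence$route <- route
  evidence$prioritized <- route != "none"
  evidence
}

#' Hypergeometric term enrichment with Benjamini-Hochberg correction
#'
#' For each term, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap when sampling the gene set from the universe.
#'
#' @param gene_set character vector (must be a subset of `universe`).
#' @param term_annotations data.frame(gene, term).
#' @param universe character vector of all genes considered.
#' @return data.frame(term, overlap, set_size, term_size, universe_size,
#'   p, p_adjusted) sorted by p.
#' @export
enrich_hypergeom <- function(gene_set, term_annotations, universe) {
  if (!all(gene_set %in% universe))
    stop("gene_set must be contained in the universe")
  ann <- term_annotations[term_annotations$gene %in% universe, ,
                          drop = FALSE]
  dropped <- setdiff(unique(term_annotations$term), unique(ann$term))
  if (length(dropped))
    warning("terms with no gene in the universe skipped: ",
            paste(dropped, collapse = ", "))
  terms <- unique(ann$term)
  N <- length(universe); n <- length(gene_set)
  rows <- lapply(terms, function(tm) {
    members <- unique(ann$gene[ann$term == tm])
    K <- length(members)
    k <- length(intersect(members, gene_set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, set_size = n, term_size = K,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
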