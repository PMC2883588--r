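# Expression-signature evidence: PTH regulation classes, osteoblast
# maturation ANOVA, embryo-atlas ordinal scoring, and EST tag abundance
# over/under-representation.

#' Classify a gene's PTH response from triplicate arrays
#'
#' A gene is PTH-regulated ("+++" up or down) when all three criteria hold:
#' (i) expression is detectable (above `detect_threshold`) in all 3 PTH- or
#' all 3 vehicle-treated samples; (ii) the mean PTH/vehicle ratio is at
#' least `fold_min` in either direction; (iii) at least `min_pairs` of the
#' 9 PTH-vs-vehicle replicate comparisons differ by at least `fold_min` in
#' the direction of the mean ratio. Otherwise the gene is "++" (detectable
#' in all replicates of at least one arm), "+" (detectable in some sample
#' but not all of an arm), or "0" (never detectable).
#'
#' @param pth,vehicle numeric length-3 intensity vectors.
#' @param detect_threshold detection level (default 100, strict ">").
#' @param fold_min fold-change rule (default 1.5, on raw intensity ratios).
#' @param min_pairs qualifying pairwise comparisons needed (default 7 of 9).
#' @param detect_both require detectability in all replicates of both arms
#'   for criterion (i) instead of at least one arm (default FALSE).
#' @return data.frame(class, mean_ratio, n_pairs): class in
#'   \{"0", "+", "++", "+++up", "+++down"\}.
#' @export
classify_pth <- function(pth, vehicle, detect_threshold = 100,
                         fold_min = 1.5, min_pairs = 7,
                         detect_both = FALSE) {
  stopifnot(length(pth) == 3, length(vehicle) == 3)
  if (any(c(pth, vehicle) < 0)) stop("negative intensities")
  det_p <- all(pth > detect_threshold)
  det_v <- all(vehicle > detect_threshold)
  detectable <- if (detect_both) det_p && det_v else det_p || det_v
  mean_ratio <- mean(pth) / mean(vehicle)
  up <- mean_ratio >= 1
  ratios <- outer(pth, vehicle, "/")
  qualifying <- if (up) ratios >= fold_min else ratios <= 1 / fold_min
  n_pairs <- sum(qualifying)
  regulated <- detectable &&
    (mean_ratio >= fold_min || mean_ratio <= 1 / fold_min) &&
    n_pairs >= min_pairs
  cls <- if (regulated) {
    if (up) "+++up" else "+++down"
  } else if (detectable) {
    "++"
  } else if (any(c(pth, vehicle) > detect_threshold)) {
    "+"
  } else "0"
  data.frame(class = cls, mean_ratio = mean_ratio, n_pairs = n_pairs,
             stringsAsFactors = FALSE)
}

#' One-way ANOVA across a maturation time course
#'
#' Fixed-effects F test of expression differences across 7 time points with
#' 3 replicates each (6 and 14 df); the significance flag is taken at the
#' caller's Bonferroni-corrected alpha.
#'
#' @param values numeric vector of 21 intensities.
#' @param timepoint factor/vector of 21 time labels (7 levels x 3).
#' @param alpha flag threshold (e.g. 0.05/6 or 0.05/109).
#' @return data.frame(f, p, significant).
#' @export
maturation_anova <- function(values, timepoint, alpha = 0.05 / 109) {
  tp <- factor(timepoint)
  if (anyNA(values)) stop("missing cells in the time-course design")
  tab <- table(tp)
  if (length(tab) < 2 || any(tab < 2)) stop("incomplete design")
  gm <- mean(values)
  mu <- tapply(values, tp, mean)
  ssb <- sum(tab * (mu - gm)^2)
  ssw <- sum((values - mu[tp])^2)
  df1 <- length(tab) - 1L
  df2 <- length(values) - length(tab)
  if (ssw == 0 && ssb == 0)
    return(data.frame(f = 0, p = 1, significant = FALSE))
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  data.frame(f = f, p = p, significant = p < alpha)
}

.atlas_levels <- c(not_detectable = 0, weak = 1, medium = 2, strong = 3)

#' Ordinal expression score over embryo-atlas organ subsets
#'
#' Assay-level ordinal calls (not_detectable < weak < medium < strong) are
#' averaged per organ subset with round-half-up to the nearest level; the
#' skeletal-evidence flag is true when the skeleton-related subsets average
#' at least "medium" (the atlas reading of "moderate").
#'
#' @param calls data.frame(subset, level) of assay annotations.
#' @param skeletal_subsets subset names counted as skeleton-related.
#' @return list: `subsets` data.frame(subset, mean_code, level),
#'   `skeletal_evidence` logical.
#' @export
atlas_score <- function(calls, skeletal_subsets = "skeleton") {
  if (!all(calls$level %in% names(.atlas_levels)))
    stop("unknown expression level label")
  code <- .atlas_levels[calls$level]
  mean_code <- tapply(code, calls$subset, mean)
  rounded <- floor(mean_code + 0.5)  # round half up
  subsets <- data.frame(subset = names(mean_code),
                        mean_code = as.numeric(mean_code),
                        level = names(.atlas_levels)[rounded + 1],
                        stringsAsFactors = FALSE)
  sk <- subsets$subset %in% skeletal_subsets
  skeletal <- any(sk) && any(subsets$mean_code[sk] >= 2)
  list(subsets = subsets, skeletal_evidence = skeletal)
}

#' EST tag over/under-representation of a gene in a tissue
#'
#' Hypergeometric test of the gene's tag count in one tissue against its
#' expectation from the tissue's share of the full library; abundances are
#' also reported per 200,000 tags.
#'
#' @param gene_counts named integer vector: the gene's tag count per tissue.
#' @param tissue_totals named integer vector: total tags per tissue
#'   (same tissues).
#' @param tissue tissue to test.
#' @return data.frame(observed, expected, per200k, p_over, p_under, p,
#'   label): label is "over", "under" or "neither" by the smaller tail at
#'   0.05 (two-sided doubling, capped at 1).
#' @export
est_abundance_test <- function(gene_counts, tissue_totals, tissue) {
  stopifnot(all(names(gene_counts) %in% names(tissue_totals)))
  N <- sum(tissue_totals)
  if (N == 0) stop("empty EST library")
  K <- sum(gene_counts)                    # gene's tags overall
  n <- tissue_totals[[tissue]]             # tags in the tissue
  k <- if (tissue %in% names(gene_counts)) gene_counts[[tissue]] else 0L
  expected <- K * n / N
  p_over <- stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
  p_under <- stats::phyper(k, n, N - n, K)
  p <- min(1, 2 * min(p_over, p_under))
  label <- if (p >= 0.05) "neither" else if (p_over < p_under) "over"
           else "under"
  data.frame(observed = k, expected = expected,
             per200k = 200000 * k / n, p_over = p_over, p_under = p_under,
             p = p, label = label, stringsAsFactors = FALSE)
}
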