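# Stage II: replication selection, inverse-variance fixed-effect
# meta-analysis with Cochran's Q, Storey q-values, FDR-derived genome-wide
# thresholds, Bonferroni helpers, and the chi-square power calculation.

#' Select discovery SNPs for replication
#'
#' SNPs pass to the replication stage when their discovery p-value is
#' strictly below `p_max`; imputed SNPs can be excluded.
#'
#' @param results association data.frame (columns snp, p and, when
#'   `genotyped_only`, a logical `genotyped`).
#' @param p_max selection threshold (default 1e-3, strict "<").
#' @param genotyped_only drop imputed SNPs (default TRUE).
#' @return character vector of SNP ids.
#' @export
select_for_replication <- function(results, p_max = 1e-3,
                                   genotyped_only = TRUE) {
  keep <- results$p < p_max
  if (genotyped_only && !is.null(results$genotyped))
    keep <- keep & results$genotyped
  unique(results$snp[keep])
}

#' Harmonize cohort effect alleles before meta-analysis
#'
#' Aligns every cohort's effect to the first cohort's (ref, alt) coding:
#' matching alleles pass through, swapped alleles flip the beta sign, and
#' strand flips (A<->T, C<->G complements) are resolved for non-ambiguous
#' pairs. Ambiguous A/T and C/G SNPs that need a strand decision are
#' dropped with a warning unless allele frequencies are supplied to
#' disambiguate.
#'
#' @param cohorts list of data.frames with columns beta, se and optionally
#'   ref, alt, eaf.
#' @return the list with betas aligned; dropped entries are NULL.
#' @export
harmonize_alleles <- function(cohorts) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  refc <- cohorts[[1]]
  if (is.null(refc$ref)) return(cohorts)  # no allele info: assume aligned
  ambiguous <- identical(unname(comp[refc$ref]), refc$alt)
  for (i in seq_along(cohorts)[-1]) {
    x <- cohorts[[i]]
    if (is.null(x$ref)) next
    if (ambiguous) {
      # swap and strand flip are indistinguishable from allele labels;
      # the alt-allele frequency decides the orientation
      if (is.null(x$eaf) || is.null(refc$eaf)) {
        if (x$ref == refc$ref && x$alt == refc$alt) {
          cohorts[[i]] <- x  # same labels: assume same strand
          next
        }
        warning("ambiguous A/T or C/G SNP without frequencies; dropped ",
                "cohort ", i)
        cohorts[i] <- list(NULL)
        next
      }
      if ((x$eaf - 0.5) * (refc$eaf - 0.5) < 0) x$beta <- -x$beta
    } else if (x$ref == refc$ref && x$alt == refc$alt) {
      # aligned
    } else if (x$ref == refc$alt && x$alt == refc$ref) {
      x$beta <- -x$beta
    } else if (identical(unname(comp[x$ref]), refc$ref) &&
               identical(unname(comp[x$alt]), refc$alt)) {
      # pure strand flip, same orientation
    } else if (identical(unname(comp[x$ref]), refc$alt) &&
               identical(unname(comp[x$alt]), refc$ref)) {
      x$beta <- -x$beta
    } else {
      warning("unresolvable alleles for cohort ", i, "; dropped")
      cohorts[i] <- list(NULL)
      next
    }
    cohorts[[i]] <- x
  }
  cohorts
}

#' Inverse-variance fixed-effect meta-analysis of one SNP
#'
#' Weights w_i = 1/SE_i^2; the combined beta is the weighted mean, combined
#' SE is (sum w)^(-1/2), and Cochran's Q = sum w_i (beta_i - beta_hat)^2 is
#' tested against chi-square with k - 1 df. The direction string records
#' per-cohort beta signs in the supplied cohort order. With a single cohort
#' Q is undefined (NA).
#'
#' @param betas per-cohort effect estimates.
#' @param ses per-cohort standard errors (> 0).
#' @param cohort_names optional cohort labels (order fixes the direction
#'   string).
#' @param genome_wide_p genome-wide tier threshold (default 4.3e-7).
#' @param suggestive_p suggestive tier upper bound (default 5e-5).
#' @return one-row data.frame: beta, se, z, p, q_stat, q_p, direction,
#'   n_cohorts, tier.
#' @export
meta_fixed <- function(betas, ses, cohort_names = NULL,
                       genome_wide_p = 4.3e-7, suggestive_p = 5e-5) {
  stopifnot(length(betas) == length(ses), length(betas) >= 1)
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- beta / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  k <- length(betas)
  if (k > 1) {
    q_stat <- sum(w * (betas - beta)^2)
    q_p <- stats::pchisq(q_stat, df = k - 1, lower.tail = FALSE)
    if (k == 2) attr(q_p, "low_reliability") <- TRUE
  } else {
    q_stat <- NA_real_; q_p <- NA_real_
  }
  dirs <- ifelse(betas > 0, "+", ifelse(betas < 0, "-", "0"))
  tier <- if (p < genome_wide_p) "genome_wide"
          else if (p <= suggestive_p) "suggestive" else "none"
  out <- data.frame(beta = beta, se = se, z = z, p = p, q_stat = q_stat,
                    q_p = as.numeric(q_p),
                    direction = paste(dirs, collapse = " "),
                    n_cohorts = k, tier = tier, stringsAsFactors = FALSE)
  if (!is.null(cohort_names))
    attr(out, "cohort_order") <- cohort_names
  out
}

#' Storey q-values (positive false-discovery rate)
#'
#' pi0 is estimated as #\{p > lambda\} / (m (1 - lambda)) capped at 1
#' (default lambda = 0.5); q(p_(i)) = min over j >= i of
#' pi0 m p_(j) / j, which is monotone non-decreasing in p. Forcing pi0 = 1
#' reduces the procedure exactly to Benjamini-Hochberg.
#'
#' @param p_values numeric vector in (0, 1].
#' @param lambda pi0 tuning parameter in (0, 1).
#' @param pi0 optional fixed pi0 (e.g. 1 for plain BH).
#' @return list(qvalues, pi0).
#' @export
qvalues <- function(p_values, lambda = 0.5, pi0 = NULL) {
  m <- length(p_values)
  if (!m) stop("empty p-value vector")
  if (is.null(pi0))
    pi0 <- min(1, sum(p_values > lambda) / (m * (1 - lambda)))
  o <- order(p_values)
  q <- pi0 * m * p_values[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  list(qvalues = out, pi0 = pi0)
}

#' FDR-derived genome-wide significance threshold
#'
#' Finds the largest p-value threshold t whose expected number of false
#' discoveries, pi0 * m * t, stays within the budget — equivalently the
#' largest observed p with q-value times discovery count within the budget.
#'
#' @param p_values numeric vector in (0, 1].
#' @param max_expected_false false-discovery budget (default 1).
#' @param lambda passed to [qvalues()].
#' @return list of class "fdr_summary": m, pi0, threshold, q_at_threshold,
#'   expected_false, n_significant.
#' @export
fdr_threshold <- function(p_values, max_expected_false = 1, lambda = 0.5) {
  m <- length(p_values)
  if (!m) stop("empty p-value vector")
  qv <- qvalues(p_values, lambda = lambda)
  ps <- sort(p_values)
  efd <- qv$pi0 * m * ps
  ok <- which(efd <= max_expected_false)
  if (!length(ok)) {
    warning("no threshold meets the budget; reporting the smallest p")
    t <- ps[1]; i <- 1L
  } else {
    i <- max(ok); t <- ps[i]
  }
  structure(list(m = m, pi0 = qv$pi0, threshold = t,
                 q_at_threshold = sort(qv$qvalues)[i],
                 expected_false = qv$pi0 * m * t,
                 n_significant = sum(p_values <= t)),
            class = "fdr_summary")
}

#' @export
print.fdr_summary <- function(x, ...) {
  cat(sprintf(
    "FDR threshold over m = %d tests (pi0 = %.3f):\n  p <= %.3g (q = %.3g), %d significant, %.3g expected false\n",
    x$m, x$pi0, x$threshold, x$q_at_threshold, x$n_significant,
    x$expected_false))
  invisible(x)
}

#' Bonferroni-corrected significance cutoff
#'
#' @param alpha family-wise error level.
#' @param m number of tests (>= 1).
#' @return alpha / m; the "display" attribute holds the value rounded to
#'   2 significant figures as printed in summary tables.
#' @export
bonferroni <- function(alpha = 0.05, m = 1) {
  if (m < 1) stop("m must be >= 1")
  structure(alpha / m, display = signif(alpha / m, 2))
}

#' Power of a single-SNP association test
#'
#' For a SNP explaining a fraction h2 of the phenotypic variance in a
#' sample of n, the association chi-square is noncentral with
#' ncp = n h2 / (1 - h2); power is the upper tail beyond the 1-df
#' chi-square critical value at alpha.
#'
#' @param n sample size.
#' @param h2 variance fraction in [0, 1).
#' @param alpha significance level.
#' @return detection probability.
#' @export
compute_power <- function(n, h2, alpha) {
  stopifnot(h2 >= 0, h2 < 1, alpha > 0, alpha < 1)
  ncp <- n * h2 / (1 - h2)
  crit <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}
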