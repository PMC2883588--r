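# Stage I: genotype/sample QC, pedigree kinship, covariate residualization,
# PCA projection for substructure, kinship-aware mixed-model association,
# and the genomic-control inflation factor.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against HWE expectations at the sample allele frequency. Monomorphic
#' SNPs return p = 1.
#'
#' @param counts integer vector (n_AA, n_Aa, n_aa).
#' @return the HWE p-value.
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("no genotypes")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((counts - expd)^2 / expd)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Imputation-quality variance ratio of a dosage vector
#'
#' Ratio of the observed dosage variance to the binomial expectation
#' 2 p (1 - p) at the stated MAF; well-imputed SNPs have ratio near 1,
#' poorly imputed ones shrink toward the mean. Ratios below `flag_below`
#' are flagged for exclusion.
#'
#' @param dosages numeric vector in [0, 2] (NA allowed).
#' @param maf minor allele frequency in (0, 0.5].
#' @param flag_below exclusion flag threshold (default 0.3).
#' @return list(ratio, flagged).
#' @export
dosage_variance_ratio <- function(dosages, maf, flag_below = 0.3) {
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  obs <- stats::var(dosages, na.rm = TRUE)
  if (is.na(obs)) obs <- 0
  ratio <- obs / (2 * maf * (1 - maf))
  list(ratio = ratio, flagged = ratio < flag_below)
}

#' QC bookkeeping: retained count and per-rule percentages
#'
#' @param total starting SNP count.
#' @param exclusions named integer vector of per-rule exclusion counts.
#' @return data.frame(rule, excluded, pct of the starting total, 1 decimal)
#'   plus a "retained" attribute.
#' @export
qc_bookkeeping <- function(total, exclusions) {
  out <- data.frame(rule = names(exclusions),
                    excluded = as.integer(exclusions),
                    pct = round(100 * exclusions / total, 1),
                    stringsAsFactors = FALSE)
  attr(out, "retained") <- total - sum(exclusions)
  out
}

#' Genotype and sample quality-control filter
#'
#' Samples with call rate below `sample_call_rate_min` are removed first;
#' SNPs are then excluded, in order, for call rate, HWE departure, low MAF,
#' and missing annotation. Exclusion percentages are reported against the
#' starting SNP total. Thresholds are inclusive on the retention side
#' (a SNP exactly at the threshold is kept).
#'
#' @param genotypes a genotype_matrix (see [gen_genotypes()]); `snps` may
#'   carry an `annotated` logical column.
#' @param snp_call_rate_min minimum SNP call rate (default 0.95).
#' @param hwe_p_min minimum HWE p-value (default 1e-6).
#' @param maf_min minimum MAF (default 0.01).
#' @param sample_call_rate_min minimum per-sample call rate (default 0.97).
#' @return list(genotypes = filtered genotype_matrix, report = qc_report).
#' @export
qc_filter <- function(genotypes, snp_call_rate_min = 0.95,
                      hwe_p_min = 1e-6, maf_min = 0.01,
                      sample_call_rate_min = 0.97) {
  d <- genotypes$dosage
  if (!nrow(d) || !ncol(d)) stop("empty genotype matrix")
  total <- ncol(d)
  samp_cr <- rowMeans(!is.na(d))
  keep_s <- samp_cr >= sample_call_rate_min
  d <- d[keep_s, , drop = FALSE]

  reason <- rep(NA_character_, total)
  cr <- colMeans(!is.na(d))
  reason[is.na(reason) & cr < snp_call_rate_min] <- "call_rate"
  hwe_p <- vapply(seq_len(total), function(j) {
    if (!is.na(reason[j])) return(1)
    g <- round(d[, j]); g <- g[!is.na(g)]
    hwe_test(c(sum(g == 0), sum(g == 1), sum(g == 2)))
  }, numeric(1))
  reason[is.na(reason) & hwe_p < hwe_p_min] <- "hwe"
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  reason[is.na(reason) & maf < maf_min] <- "maf"
  if (!is.null(genotypes$snps$annotated))
    reason[is.na(reason) & !genotypes$snps$annotated] <- "no_annotation"

  keep <- is.na(reason)
  counts <- c(call_rate = sum(reason == "call_rate", na.rm = TRUE),
              hwe = sum(reason == "hwe", na.rm = TRUE),
              maf = sum(reason == "maf", na.rm = TRUE),
              no_annotation = sum(reason == "no_annotation", na.rm = TRUE))
  report <- structure(list(
    total_snps = total,
    samples_removed = sum(!keep_s),
    table = qc_bookkeeping(total, counts),
    retained = sum(keep),
    reason = reason), class = "qc_report")
  out <- genotypes
  out$dosage <- d[, keep, drop = FALSE]
  out$snps <- genotypes$snps[keep, , drop = FALSE]
  out$snps$maf <- maf[keep]
  out$samples <- rownames(d)
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC report: ", x$total_snps, " SNPs in, ", x$retained,
      " retained; ", x$samples_removed, " samples removed\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Pedigree kinship matrix
#'
#' Standard recursive kinship coefficients: Phi(i,i) = 0.5 (1 + Phi(fa, mo)),
#' Phi(i,j) = 0.5 (Phi(fa, j) + Phi(mo, j)) evaluated with parents before
#' children. 2 Phi scales the additive genetic covariance in the mixed model.
#'
#' @param pedigree data.frame with iid, father, mother (NA for founders).
#' @return symmetric kinship matrix with sample ids as dimnames.
#' @export
compute_kinship <- function(pedigree) {
  n <- nrow(pedigree)
  if (all(is.na(pedigree$father) & is.na(pedigree$mother))) {
    K <- diag(0.5, n)
    dimnames(K) <- list(pedigree$iid, pedigree$iid)
    return(K)
  }
  ord <- pedigree_order(pedigree)
  idx <- seq_len(n); names(idx) <- pedigree$iid
  K <- matrix(0, n, n, dimnames = list(pedigree$iid, pedigree$iid))
  for (i in ord) {
    fa <- pedigree$father[i]; mo <- pedigree$mother[i]
    fi <- if (is.na(fa)) NA_integer_ else idx[[fa]]
    mi <- if (is.na(mo)) NA_integer_ else idx[[mo]]
    for (j in ord) {
      if (j == i) break  # ord processed up to i; fill row i vs earlier j
      kij <- 0
      if (!is.na(fi)) kij <- kij + 0.5 * K[fi, j]
      if (!is.na(mi)) kij <- kij + 0.5 * K[mi, j]
      K[i, j] <- K[j, i] <- kij
    }
    K[i, i] <- if (!is.na(fi) && !is.na(mi)) 0.5 * (1 + K[fi, mi]) else 0.5
  }
  K
}

#' Sex- and cohort-specific standardized phenotype residuals
#'
#' Within each sex-by-cohort group, the trait is regressed on the covariate
#' set by ordinary least squares and the residuals are standardized to mean
#' 0, SD 1. Principal components enter simply as covariate columns.
#'
#' @param phenotypes data.frame with iid, sex, cohort, the trait and
#'   covariate columns.
#' @param trait trait column name.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param group_by columns defining the standardization groups
#'   (default c("sex", "cohort")).
#' @return data.frame(iid, sex, cohort, residual).
#' @export
compute_residuals <- function(phenotypes, trait, covariates = character(),
                              group_by = c("sex", "cohort")) {
  stopifnot(trait %in% names(phenotypes),
            all(covariates %in% names(phenotypes)))
  grp <- interaction(phenotypes[group_by], drop = TRUE)
  res <- numeric(nrow(phenotypes))
  for (g in levels(grp)) {
    i <- which(grp == g)
    y <- phenotypes[[trait]][i]
    if (length(i) <= length(covariates) + 2)
      stop("group ", g, " too small for the covariate set")
    if (stats::sd(y) == 0) stop("constant trait in group ", g)
    if (length(covariates)) {
      X <- as.matrix(phenotypes[i, covariates, drop = FALSE])
      r <- stats::lm.fit(cbind(1, X), y)$residuals
    } else {
      r <- y - mean(y)
    }
    res[i] <- r / stats::sd(r)
  }
  data.frame(iid = phenotypes$iid, sex = phenotypes$sex,
             cohort = phenotypes$cohort, residual = res,
             stringsAsFactors = FALSE)
}

#' Principal components on an unrelated subset, projected to all samples
#'
#' SNPs are centered at 2p and scaled by sqrt(2 p (1 - p)) using allele
#' frequencies estimated in the unrelated subset; the component axes are
#' computed on the subset and every sample is projected onto them.
#'
#' @param genotypes a genotype_matrix.
#' @param unrelated_subset character vector of sample ids.
#' @param n_components number of components (<= subset size).
#' @return list: `scores` (all samples x components), `loadings`
#'   (SNPs x components, orthonormal), `subset` the ids used.
#' @export
pca_project <- function(genotypes, unrelated_subset, n_components = 10) {
  if (!length(unrelated_subset)) stop("empty unrelated subset")
  if (n_components > length(unrelated_subset))
    stop("n_components exceeds subset size")
  d <- genotypes$dosage
  sub <- d[unrelated_subset, , drop = FALSE]
  p <- colMeans(sub, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  scale <- sqrt(2 * p[keep] * (1 - p[keep]))
  std <- function(m) sweep(sweep(m[, keep, drop = FALSE], 2, 2 * p[keep]),
                           2, scale, "/")
  Zs <- std(sub)
  sv <- svd(Zs, nu = 0, nv = n_components)
  loadings <- sv$v
  scores <- std(d) %*% loadings
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(scores = scores, loadings = loadings, subset = unrelated_subset)
}

#' Precompute the kinship eigendecomposition for mixed-model association
#'
#' The eigendecomposition of 2 Phi is done once per kinship matrix and
#' reused across all SNPs.
#'
#' @param kinship kinship matrix Phi.
#' @return list(U, lambda, samples) of class "kinship_eigen"; U is NULL
#'   for a diagonal kinship (the rotation is the identity).
#' @export
kinship_eigen <- function(kinship) {
  if (all(kinship[upper.tri(kinship)] == 0)) {
    return(structure(list(U = NULL, lambda = 2 * diag(kinship),
                          samples = rownames(kinship)),
                     class = "kinship_eigen"))
  }
  e <- eigen(2 * kinship, symmetric = TRUE)
  structure(list(U = e$vectors, lambda = pmax(e$values, 0),
                 samples = rownames(kinship)),
            class = "kinship_eigen")
}

# Profile log-likelihood of the variance ratio h = sigma2_A / total variance,
# on rotated data (ys = U'y, Xs = U'X), up to constants.
.lmm_profile_ll <- function(h, ys, Xs, lambda) {
  v <- h * lambda + (1 - h)
  w <- 1 / v
  fit <- stats::lm.wfit(Xs, ys, w)
  n <- length(ys)
  rss <- sum(w * fit$residuals^2)
  -0.5 * (n * log(rss / n) + sum(log(v)))
}

#' Kinship-aware mixed-model single-SNP association
#'
#' Fits y = b0 + b * dosage + g + e with cov(g) = sigma2_A * 2 Phi and
#' cov(e) = sigma2_E * I. The variance ratio is estimated by maximum
#' likelihood on the spectral transform of 2 Phi (profiled over the scale);
#' the SNP effect is then tested by a Wald t-test on the generalized
#' least-squares fit with the residual scale estimated on n - p degrees of
#' freedom, so with an identity kinship the result reduces exactly to
#' ordinary least squares. Missing dosages are mean-imputed per SNP.
#'
#' @param residuals data.frame from [compute_residuals()] (column
#'   `residual`), or a plain numeric vector named by sample.
#' @param dosages numeric vector (one SNP) or samples x SNPs matrix.
#' @param kinship kinship matrix Phi, or a precomputed [kinship_eigen()].
#' @param snp_info optional data.frame with snp metadata (snp, maf) aligned
#'   to the dosage columns.
#' @param trait trait label stored in the output.
#' @param stratum stratum label ("combined" by default).
#' @return data.frame with snp, trait, stratum, beta, se, p, direction, n,
#'   maf, h2_ratio (the fitted variance ratio).
#' @export
assoc_lme <- function(residuals, dosages, kinship, snp_info = NULL,
                      trait = "trait", stratum = "combined") {
  y <- if (is.data.frame(residuals)) {
    stats::setNames(residuals$residual, residuals$iid)
  } else residuals
  if (is.null(dim(dosages))) dosages <- matrix(dosages, ncol = 1,
    dimnames = list(names(y), "snp1"))
  ke <- if (inherits(kinship, "kinship_eigen")) kinship
        else kinship_eigen(kinship)
  lambda <- ke$lambda
  n <- length(y)
  if (is.null(ke$U)) {  # diagonal kinship: identity rotation
    U <- NULL
    if (!is.null(ke$samples) && !is.null(names(y)))
      lambda <- lambda[match(names(y), ke$samples)]
    ys <- unname(y)
    ones_s <- rep(1, n)
  } else {
    if (!is.null(ke$samples) && !is.null(names(y))) {
      stopifnot(all(names(y) %in% ke$samples))
      ord <- match(names(y), ke$samples)
      U <- ke$U[ord, , drop = FALSE]
    } else U <- ke$U
    ys <- drop(crossprod(U, y))
    ones_s <- drop(crossprod(U, rep(1, n)))
  }
  m <- ncol(dosages)
  # mean-impute missing dosages, then rotate all SNPs at once
  D <- dosages
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  Ds <- if (is.null(U)) unname(D) else crossprod(U, D)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    x <- D[, j]
    vj <- stats::var(x)
    id <- if (!is.null(snp_info)) snp_info$snp[j] else colnames(dosages)[j]
    maf <- if (!is.null(snp_info) && !is.null(snp_info$maf))
      snp_info$maf[j] else min(mean(x) / 2, 1 - mean(x) / 2)
    if (is.na(vj) || vj == 0) {
      warning("monomorphic SNP: ", id)
      out[[j]] <- data.frame(snp = id, trait = trait, stratum = stratum,
                             beta = 0, se = NA_real_, p = 1, direction = 0L,
                             n = n, maf = maf, h2_ratio = NA_real_,
                             stringsAsFactors = FALSE)
      next
    }
    Xs <- cbind(ones_s, Ds[, j])
    opt <- stats::optimize(.lmm_profile_ll, c(0, 0.999), ys = ys, Xs = Xs,
                           lambda = lambda, maximum = TRUE, tol = 1e-6)
    h <- opt$maximum
    # boundary polish: accept h = 0 if it is not worse
    if (.lmm_profile_ll(0, ys, Xs, lambda) >= opt$objective) h <- 0
    v <- h * lambda + (1 - h)
    w <- 1 / v
    fit <- stats::lm.wfit(Xs, ys, w)
    p_fixed <- 2L
    sigma2 <- sum(w * fit$residuals^2) / (n - p_fixed)
    XtWX <- crossprod(Xs * sqrt(w))
    covb <- sigma2 * solve(XtWX)
    beta <- fit$coefficients[2]
    se <- sqrt(covb[2, 2])
    tval <- beta / se
    pval <- 2 * stats::pt(abs(tval), df = n - p_fixed, lower.tail = FALSE)
    out[[j]] <- data.frame(snp = id, trait = trait, stratum = stratum,
                           beta = beta, se = se, p = pval,
                           direction = as.integer(sign(beta)), n = n,
                           maf = maf, h2_ratio = h, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genomic-control inflation factor
#'
#' Lambda_GC is the median association chi-square divided by the null
#' median of the 1-df chi-square distribution (0.4549364).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return the inflation factor.
#' @export
genomic_lambda <- function(p_values) {
  if (!length(p_values)) stop("empty p-value vector")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}
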