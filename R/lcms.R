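# Likelihood-based causality model selection over (locus L, transcript G,
# trait T) triples: causal L -> G -> T, reactive L -> T -> G, and
# independent L -> G, L -> T with correlated residuals. Models are
# conditional-Gaussian factorizations compared by BIC; P(L) is common to
# all three and omitted.

# Gaussian ML log-likelihood of a simple linear regression y ~ x.
.reg_ll <- function(y, x) {
  n <- length(y)
  fit <- stats::lm.fit(cbind(1, x), y)
  s2 <- sum(fit$residuals^2) / n
  list(ll = -n / 2 * (log(2 * pi * s2) + 1),
       coef = fit$coefficients, s2 = s2, resid = fit$residuals)
}

#' Fit the three causality models to one (L, G, T) triple
#'
#' Each model is a product of linear-Gaussian conditionals with the locus
#' coded additively: causal P(G|L) P(T|G); reactive P(T|L) P(G|T);
#' independent P(G, T | L) with means linear in L and a free residual
#' correlation (one extra parameter, so correlated transcript and trait
#' can still favor independence when neither mediates the other).
#' BIC = -2 logL + k log(n) over complete cases.
#'
#' @param L genotype dosage vector (polymorphic).
#' @param G expression vector.
#' @param T_ trait vector.
#' @return object of class "lcms_fit": per-model logLik, k, BIC, and the
#'   selected label (see [select_model()]).
#' @export
fit_models <- function(L, G, T_) {
  ok <- stats::complete.cases(L, G, T_)
  L <- L[ok]; G <- G[ok]; T_ <- T_[ok]
  n <- length(L)
  if (n < 30) stop("need at least 30 complete cases")
  if (stats::sd(L) == 0) stop("monomorphic locus")
  if (stats::sd(G) == 0 || stats::sd(T_) == 0)
    stop("constant transcript or trait")
  gl <- .reg_ll(G, L)   # G | L
  tg <- .reg_ll(T_, G)  # T | G
  tl <- .reg_ll(T_, L)  # T | L
  gt <- .reg_ll(G, T_)  # G | T
  ll_causal <- gl$ll + tg$ll
  ll_reactive <- tl$ll + gt$ll
  # independent: bivariate Gaussian residuals of (G, T) on L
  R <- cbind(gl$resid, tl$resid)
  S <- crossprod(R) / n
  det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
  ll_indep <- -n / 2 * (2 * log(2 * pi) + log(det_s) + 2)
  k <- c(causal = 6, reactive = 6, independent = 7)
  ll <- c(causal = ll_causal, reactive = ll_reactive,
          independent = ll_indep)
  bic <- -2 * ll + k * log(n)
  fit <- structure(list(logLik = ll, k = k, bic = bic, n = n,
                        coef = list(causal = list(G_on_L = gl$coef,
                                                  T_on_G = tg$coef),
                                    reactive = list(T_on_L = tl$coef,
                                                    G_on_T = gt$coef),
                                    independent = list(
                                      G_on_L = gl$coef, T_on_L = tl$coef,
                                      resid_cor = S[1, 2] /
                                        sqrt(S[1, 1] * S[2, 2])))),
                   class = "lcms_fit")
  fit$selected <- select_model(fit)
  fit
}

#' Select the best-fitting causality model by BIC
#'
#' The model with the lowest BIC wins; an exact tie for the minimum is
#' reported as "ambiguous" (the conservative contract: a tie never asserts
#' causality).
#'
#' @param fit an "lcms_fit".
#' @return one of "causal", "reactive", "independent", "ambiguous".
#' @export
select_model <- function(fit) {
  b <- fit$bic
  i <- which(b == min(b))
  if (length(i) > 1) "ambiguous" else names(b)[i]
}

#' @export
print.lcms_fit <- function(x, ...) {
  cat("Causality model selection (n =", x$n, ")\n")
  tab <- data.frame(model = names(x$bic), logLik = round(x$logLik, 3),
                    k = x$k, BIC = round(x$bic, 3))
  print(tab, row.names = FALSE)
  cat("selected:", x$selected, "\n")
  invisible(x)
}

#' @export
summary.lcms_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Bootstrap reliability of a causality model call
#'
#' Cases are resampled with replacement B times; the reliability is the
#' fraction of resamples whose selected model matches the full-data
#' selection. Degenerate resamples (a constant column) are skipped and not
#' counted in the denominator.
#'
#' @param L,G,T_ the triple, see [fit_models()].
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return reliability in [0, 1]; attribute "B_used" records the effective
#'   denominator.
#' @export
bootstrap_reliability <- function(L, G, T_, B = 1000, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  full <- fit_models(L, G, T_)$selected
  set.seed(child_seed(seed, 7L))
  n <- length(L)
  agree <- 0L; used <- 0L
  for (b in seq_len(B)) {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::sd(L[i]) == 0 || stats::sd(G[i]) == 0 ||
        stats::sd(T_[i]) == 0) next
    used <- used + 1L
    if (fit_models(L[i], G[i], T_[i])$selected == full)
      agree <- agree + 1L
  }
  structure(if (used) agree / used else NA_real_, B_used = used)
}

#' Count significant pleiotropic eQTL / trait-QTL pairs at a locus
#'
#' A pair qualifies when both the eQTL and the trait-QTL p-values at the
#' locus are below `p_threshold`; when the underlying data are supplied,
#' a shared-effect likelihood screen additionally requires that a single
#' locus effect for both outcomes is not rejected against separate linked
#' effects (see [pleiotropy_screen()]). At least `pairs_min` qualifying
#' pairs constitute causal evidence.
#'
#' @param eqtl_p named vector of eQTL p-values at the locus (per
#'   transcript or tissue).
#' @param trait_p named vector of trait-QTL p-values at the locus (per
#'   trait).
#' @param p_threshold joint significance cutoff (default 0.05).
#' @param pairs_min pairs needed for causal evidence (default 2).
#' @param screen optional logical matrix (length(eqtl_p) x length(trait_p))
#'   of pleiotropy-screen passes; NULL means all pass.
#' @return list(count, causal_evidence, pairs data.frame).
#' @export
pleiotropy_pairs <- function(eqtl_p, trait_p, p_threshold = 0.05,
                             pairs_min = 2, screen = NULL) {
  sig_e <- which(eqtl_p < p_threshold)
  sig_t <- which(trait_p < p_threshold)
  pairs <- expand.grid(eqtl = sig_e, trait = sig_t)
  if (!is.null(screen) && nrow(pairs))
    pairs <- pairs[screen[cbind(pairs$eqtl, pairs$trait)], , drop = FALSE]
  count <- nrow(pairs)
  list(count = count, causal_evidence = count >= pairs_min,
       pairs = data.frame(
         eqtl = if (count) names(eqtl_p)[pairs$eqtl] else character(),
         trait = if (count) names(trait_p)[pairs$trait] else character(),
         stringsAsFactors = FALSE))
}

#' Pleiotropy-versus-close-linkage screen for one (G, T) pair
#'
#' Compares a shared-QTL model (both outcomes driven by the same marker
#' L1) against a two-locus linkage model (G on L1, T on a linked marker
#' L2) by BIC on their Gaussian likelihoods. With no second marker the
#' screen reduces to joint single-marker support and passes.
#'
#' @param G expression vector.
#' @param T_ trait vector.
#' @param L1 shared candidate marker dosages.
#' @param L2 optional linked alternative marker for the trait.
#' @return list(pass, bic_pleiotropy, bic_linkage): pass is TRUE when the
#'   shared-marker model's BIC is no worse.
#' @export
pleiotropy_screen <- function(G, T_, L1, L2 = NULL) {
  n <- length(G)
  b_pleio <- -2 * (.reg_ll(G, L1)$ll + .reg_ll(T_, L1)$ll) + 6 * log(n)
  if (is.null(L2))
    return(list(pass = TRUE, bic_pleiotropy = b_pleio,
                bic_linkage = NA_real_))
  b_link <- -2 * (.reg_ll(G, L1)$ll + .reg_ll(T_, L2)$ll) + 6 * log(n)
  list(pass = b_pleio <= b_link, bic_pleiotropy = b_pleio,
       bic_linkage = b_link)
}
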