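# Stage I: QC, kinship, residualization, PCA projection, mixed-model
# association, genomic control.

test_that("HWE chi-square test matches hand-computed cases", {
  expect_equal(hwe_test(c(25, 50, 25)), 1)
  # (50,0,50): chi-square = 25^2/25 + 50^2/50 + 25^2/25 = 100
  expect_equal(hwe_test(c(50, 0, 50)),
               pchisq(100, 1, lower.tail = FALSE))
  expect_lt(hwe_test(c(50, 0, 50)), 1e-6)
  expect_equal(hwe_test(c(100, 0, 0)), 1)  # monomorphic
})

test_that("dosage variance ratio flags shrunken imputations", {
  # hard calls at exact HWE proportions, maf 0.5
  d <- rep(c(0, 1, 2), times = c(25, 50, 25))
  r <- dosage_variance_ratio(d, 0.5)
  expect_equal(r$ratio, var(d) / 0.5)
  expect_equal(r$ratio, 1, tolerance = 0.02)  # sample-variance n/(n-1)
  expect_false(dosage_variance_ratio(d, 0.5)$flagged)
  expect_true(dosage_variance_ratio(rep(0.6, 50), 0.3)$flagged)
  expect_equal(dosage_variance_ratio(rep(0.6, 50), 0.3)$ratio, 0)
  # shrinking halfway toward the mean scales the variance by 0.25
  ds <- mean(d) + 0.5 * (d - mean(d))
  expect_equal(dosage_variance_ratio(ds, 0.5)$ratio, 0.25,
               tolerance = 0.02)
  expect_error(dosage_variance_ratio(d, 0), "maf")
})

test_that("QC filter excludes by rule in order and partitions the total", {
  set.seed(21)
  n <- 1000
  ped <- gen_pedigrees(0, 0, n, seed = 21)
  g <- gen_genotypes(ped, 50, c(0.2, 0.4), seed = 22)
  # SNP 1: poor call rate; SNP 2: HWE failure; SNP 3: rare; SNP 4: no
  # annotation; SNP 5: boundary MAF exactly at threshold (kept); one
  # sample missing 3 of 50 SNPs (call rate 0.94) is removed first
  g$dosage[seq_len(80), 1] <- NA                      # call rate 0.92
  g$dosage[, 2] <- rep(c(0, 2), length.out = n)       # no hets
  g$dosage[, 3] <- c(rep(1, 18), rep(0, n - 18))      # maf ~0.009
  g$dosage[, 5] <- c(rep(1, 20), rep(0, n - 20))      # maf ~0.010
  g$snps$annotated <- rep(TRUE, 50); g$snps$annotated[4] <- FALSE
  g$dosage[n, 6:8] <- NA                              # bad sample
  out <- qc_filter(g)
  expect_equal(out$report$samples_removed, 1)
  rep_tab <- out$report$table
  expect_equal(rep_tab$excluded[rep_tab$rule == "call_rate"], 1)
  expect_equal(rep_tab$excluded[rep_tab$rule == "hwe"], 1)
  expect_equal(rep_tab$excluded[rep_tab$rule == "maf"], 1)
  expect_equal(rep_tab$excluded[rep_tab$rule == "no_annotation"], 1)
  expect_equal(out$report$reason[1], "call_rate")
  expect_true("snp000005" %in% out$genotypes$snps$snp)  # inclusive at 0.01
  # partition invariant
  expect_equal(out$report$retained + sum(rep_tab$excluded),
               out$report$total_snps)
  expect_error(qc_filter(list(dosage = matrix(numeric(), 0, 0))), "empty")
})

test_that("pedigree kinship reproduces textbook and gene-dropping values", {
  ped <- gen_pedigrees(2, 2, 3, seed = 23)
  K <- compute_kinship(ped)
  i <- match(c("F0001_01", "F0001_02", "F0001_03", "F0001_04", "U00001"),
             ped$iid)
  expect_equal(2 * K[i[1], i[3]], 0.5)   # parent-offspring
  expect_equal(2 * K[i[3], i[4]], 0.5)   # full sibs
  expect_equal(2 * K[i[1], i[2]], 0)     # unrelated founders
  expect_equal(2 * K[i[1], i[5]], 0)
  expect_true(all(eigen(K, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  expect_error(compute_kinship(data.frame(
    iid = c("a", "b"), father = c("b", "a"), mother = c(NA, NA))),
    "cycle")
})

test_that("three-generation kinship agrees with the gene-dropping oracle", {
  ped3 <- data.frame(
    fid = "F1",
    iid = c("gf", "gm", "fa2", "mo", "kid1", "kid2"),
    father = c(NA, NA, "gf", NA, "fa2", "fa2"),
    mother = c(NA, NA, "gm", NA, "mo", "mo"),
    sex = c("male", "female", "male", "female", "male", "female"),
    cohort = "c", stringsAsFactors = FALSE)
  K <- compute_kinship(ped3)
  for (pair in list(c("gf", "kid1"), c("kid1", "kid2"), c("fa2", "kid2"))) {
    mc <- oracle_kinship2_mc(ped3, pair[1], pair[2], n_drops = 1e5)
    expect_equal(2 * K[pair[1], pair[2]], mc, tolerance = 0.02)
  }
})

test_that("standardized residuals are groupwise mean-0/SD-1 and orthogonal", {
  set.seed(24)
  n <- 240
  phe <- data.frame(
    iid = sprintf("s%03d", 1:n),
    sex = rep(c("male", "female"), n / 2),
    cohort = rep(c("orig", "offs"), each = n / 2),
    age = runif(n, 30, 80))
  phe$age2 <- phe$age^2
  phe$trait <- 2 + 0.05 * phe$age + rnorm(n)
  r <- compute_residuals(phe, "trait", c("age", "age2"))
  grp <- interaction(r$sex, r$cohort)
  expect_true(all(abs(tapply(r$residual, grp, mean)) < 1e-10))
  expect_true(all(abs(tapply(r$residual, grp, sd) - 1) < 1e-10))
  # exact linear function of age leaves pure noise orthogonal to age
  phe$trait <- 3 * phe$age
  expect_error(compute_residuals(phe, "trait", c("age")), NA)
  phe$trait <- 3 * phe$age + rnorm(n)
  r2 <- compute_residuals(phe, "trait", c("age"))
  for (g in levels(grp)) {
    i <- grp == g
    expect_lt(summary(lm(r2$residual[i] ~ phe$age[i]))$r.squared, 1e-10)
  }
})

test_that("PCA projection separates simulated subpopulations", {
  set.seed(25)
  n <- 200; m <- 2000
  pop <- rep(0:1, each = n / 2)
  p0 <- runif(m, 0.2, 0.8)
  shift <- rnorm(m, 0, sqrt(0.05 * p0 * (1 - p0)))  # Fst-like divergence
  p1 <- pmin(pmax(p0 + shift, 0.01), 0.99)
  d <- t(vapply(seq_len(n), function(i) {
    rbinom(m, 2, if (pop[i] == 0) p0 else p1)
  }, numeric(m)))
  rownames(d) <- sprintf("s%03d", 1:n)
  colnames(d) <- sprintf("snp%04d", 1:m)
  g <- list(dosage = d,
            snps = data.frame(snp = colnames(d), chrom = "1",
                              pos = seq_len(m)),
            samples = rownames(d))
  pc <- pca_project(g, rownames(d), 4)
  expect_equal(crossprod(pc$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_gt(abs(cor(pc$scores[, 1], pop)), 0.9)
  # projecting onto a subset-derived basis reproduces subset scores
  sub <- rownames(d)[seq(1, n, 2)]
  pcs <- pca_project(g, sub, 4)
  expect_equal(pcs$scores[sub, ],
               pca_project(list(dosage = d[sub, ], snps = g$snps,
                                samples = sub), sub, 4)$scores,
               tolerance = 1e-8)
  expect_error(pca_project(g, rownames(d)[1:3], 10), "exceeds")
})

test_that("mixed-model association reduces to OLS under identity kinship", {
  set.seed(26)
  n <- 150
  y <- rnorm(n); names(y) <- sprintf("s%03d", 1:n)
  x <- rbinom(n, 2, 0.3)
  K <- diag(0.5, n); dimnames(K) <- list(names(y), names(y))
  a <- assoc_lme(y, stats::setNames(x, names(y)), K)
  ols <- summary(lm(y ~ x))$coefficients
  expect_equal(a$beta, ols[2, 1], tolerance = 1e-8)
  expect_equal(a$se, ols[2, 2], tolerance = 1e-8)
  expect_equal(a$p, ols[2, 4], tolerance = 1e-8)
})

test_that("association p-values are invariant to affine dosage recoding", {
  set.seed(27)
  ped <- gen_pedigrees(40, 2, 0, seed = 27)
  g <- gen_genotypes(ped, 3, c(0.3, 0.5), seed = 28)
  K <- compute_kinship(ped)
  phe <- gen_phenotypes(g, ped, K, "snp000001", 0.05,
                        sigma2_A = 0.4, sigma2_E = 0.6, seed = 29)
  res <- compute_residuals(phe, "trait", group_by = "sex")
  x <- g$dosage[res$iid, 1]
  a1 <- assoc_lme(res, x, K[res$iid, res$iid])
  a2 <- assoc_lme(res, 2 - x, K[res$iid, res$iid])     # allele flip
  a3 <- assoc_lme(res, 10 * x + 3, K[res$iid, res$iid])  # affine recode
  expect_equal(a1$p, a2$p, tolerance = 1e-8)
  expect_equal(a1$beta, -a2$beta, tolerance = 1e-8)
  expect_equal(a1$p, a3$p, tolerance = 1e-8)
  expect_equal(a1$beta, 10 * a3$beta, tolerance = 1e-8)
  # monomorphic SNP degrades gracefully
  expect_warning(a0 <- assoc_lme(res, rep(1, nrow(res)),
                                 K[res$iid, res$iid]), "monomorphic")
  expect_equal(a0$p, 1)
  expect_equal(a0$beta, 0)
})

test_that("planted-SNP detection frequency matches the power calculation", {
  # h2 = 5%, n = 400 unrelated, alpha = 1e-4: analytic power ~ 0.994
  alpha <- 1e-4
  pow <- compute_power(400, 0.05, alpha)
  hits <- vapply(1:40, function(s) {
    ped <- gen_pedigrees(0, 0, 400, seed = s)
    g <- gen_genotypes(ped, 2, c(0.3, 0.5), seed = s + 100)
    K <- compute_kinship(ped)
    phe <- gen_phenotypes(g, ped, K, "snp000001", 0.05,
                          sigma2_A = 0, sigma2_E = 1, seed = s + 200)
    res <- compute_residuals(phe, "trait", group_by = "sex")
    a <- assoc_lme(res, g$dosage[res$iid, 1], kinship_eigen(K))
    a$p < alpha
  }, logical(1))
  expect_equal(mean(hits), pow, tolerance = 0.06)
})

test_that("genomic lambda is calibrated and scale-equivariant", {
  p_grid <- (1:10000 - 0.5) / 10000
  expect_equal(genomic_lambda(p_grid), 1, tolerance = 0.01)
  chi <- qchisq(p_grid, 1, lower.tail = FALSE)
  p_doubled <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p_doubled), 2 * genomic_lambda(p_grid),
               tolerance = 0.01)
  expect_error(genomic_lambda(numeric()), "empty")
})
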