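# Generators: pedigrees, gene-dropped genotypes, phenotypes, triples,
# designed expression experiments.

test_that("pedigree generator produces the requested family structure", {
  singles <- gen_pedigrees(0, 0, 100, seed = 1)
  expect_equal(nrow(singles), 100)
  expect_true(all(is.na(singles$father)))

  fams <- gen_pedigrees(10, 2, 0, seed = 1)
  expect_equal(nrow(fams), 40)
  expect_equal(length(unique(fams$fid)), 10)
  expect_equal(sum(is.na(fams$father)), 20)  # 2 founders per family

  expect_identical(gen_pedigrees(5, 3, 7, seed = 7),
                   gen_pedigrees(5, 3, 7, seed = 7))
  expect_error(gen_pedigrees(-1, 0, 0), "non-negative")
})

test_that("founder genotypes sit at Hardy-Weinberg proportions", {
  ped <- gen_pedigrees(0, 0, 400, seed = 2)
  g <- gen_genotypes(ped, 2000, c(0.5, 0.5), seed = 3)
  freq <- rowMeans(apply(g$dosage, 2, tabulate, nbins = 3))
  # genotype frequencies pooled over 2000 SNPs x 400 samples
  counts <- c(sum(g$dosage == 0), sum(g$dosage == 1), sum(g$dosage == 2))
  props <- counts / sum(counts)
  expect_equal(props, c(0.25, 0.5, 0.25), tolerance = 0.02)
})

test_that("transmission is Mendelian and sib dosages correlate at 2*Phi", {
  ped <- gen_pedigrees(150, 2, 0, seed = 4)
  g <- gen_genotypes(ped, 400, c(0.3, 0.5), seed = 5)
  d <- g$dosage
  fa <- d[match(paste0(unique(ped$fid), "_01"), rownames(d)), ]
  mo <- d[match(paste0(unique(ped$fid), "_02"), rownames(d)), ]
  k1 <- d[match(paste0(unique(ped$fid), "_03"), rownames(d)), ]
  k2 <- d[match(paste0(unique(ped$fid), "_04"), rownames(d)), ]
  # forcing cross: hom-ref x hom-alt parents give heterozygous offspring
  force <- (fa == 0 & mo == 2) | (fa == 2 & mo == 0)
  expect_true(all(k1[force] == 1))
  # offspring allele counts bounded by what parents can transmit
  expect_true(all(k1 <= (fa >= 1) + (mo >= 1)))
  expect_true(all(k1 >= (fa == 2) + (mo == 2)))
  # full-sib dosage correlation approximates 2*Phi = 0.5
  sib_cor <- mean(vapply(seq_len(ncol(d)), function(j) {
    if (stats::sd(k1[, j]) == 0 || stats::sd(k2[, j]) == 0) return(NA_real_)
    cor(k1[, j], k2[, j])
  }, numeric(1)), na.rm = TRUE)
  expect_equal(sib_cor, 0.5, tolerance = 0.05)
})

test_that("LD blocks reach their target r-squared", {
  ped <- gen_pedigrees(0, 0, 3000, seed = 6)
  ld <- data.frame(source = 1L, target = 2L, r2 = 0.61)
  g <- gen_genotypes(ped, 4, c(0.4, 0.4), seed = 7, ld_blocks = ld)
  r2 <- ld_r2(g$dosage[, 1], g$dosage[, 2])
  expect_equal(r2, 0.61, tolerance = 0.05)
  # untouched SNPs stay independent
  expect_lt(ld_r2(g$dosage[, 3], g$dosage[, 4]), 0.01)
})

test_that("phenotype generator realizes the stated variance structure", {
  ped <- gen_pedigrees(400, 2, 0, seed = 8)
  g <- gen_genotypes(ped, 10, c(0.3, 0.5), seed = 9)
  K <- compute_kinship(ped)
  expect_error(gen_phenotypes(g, ped, K, c("snp000001", "snp000002"),
                              c(0.6, 0.5)), "< 1")
  # sib-pair phenotype correlation ~ 0.5 * sigma2_A / total
  phe <- gen_phenotypes(g, ped, K, character(), numeric(),
                        sigma2_A = 0.6, sigma2_E = 0.4, seed = 10)
  y <- phe$trait; names(y) <- phe$iid
  fid <- unique(ped$fid)
  s1 <- y[paste0(fid, "_03")]; s2 <- y[paste0(fid, "_04")]
  expect_lt(abs(cor(s1, s2) - 0.5 * 0.6), 0.09)  # ~2 SE at 400 pairs
  # a planted SNP explains its stated share of variance
  phe2 <- gen_phenotypes(g, ped, K, "snp000001", 0.2,
                         sigma2_A = 0, sigma2_E = 1, seed = 11)
  b <- attr(phe2, "beta")
  v_snp <- unname(b^2 * var(g$dosage[, "snp000001"]))
  expect_equal(v_snp / var(phe2$trait), 0.2, tolerance = 0.1)
})

test_that("architecture triples satisfy their conditional independences", {
  set.seed(12)
  L <- rbinom(4000, 2, 0.5)
  pcor <- function(x, y, z) {
    rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
    cor(rx, ry)
  }
  ca <- gen_expression_triple(L, "causal", a = 1, b = 1, noise_sd = 0.1,
                              seed = 13)
  expect_lt(abs(pcor(L, ca$T, ca$G)), 0.05)  # L indep T given G
  ind <- gen_expression_triple(L, "independent", a = 1, noise_sd = 0.1,
                               seed = 14)
  expect_lt(abs(pcor(ind$G, ind$T, L)), 0.05)  # G indep T given L
  expect_error(gen_expression_triple(L, "spurious"), "arg")
  tri <- gen_expression_triples(
    gen_genotypes(gen_pedigrees(0, 0, 50, seed = 1), 5, c(0.5, 0.5),
                  seed = 2),
    c("causal", "null"), seed = 15)
  expect_equal(tri$truth$architecture, c("causal", "null"))
})

test_that("PTH experiment truth labels are recovered by the classifier", {
  ex <- gen_pth_experiment(300, regulated_fraction = 0.2, fold = 3,
                           seed = 16, noise_cv = 0.05)
  calls <- vapply(seq_len(300), function(i)
    classify_pth(ex$pth[i, ], ex$vehicle[i, ])$class, character(1))
  reg <- calls %in% c("+++up", "+++down")
  expect_true(all(reg[ex$truth$regulated]))
  # null experiment: regulated calls at most a small false-positive rate
  nul <- gen_pth_experiment(300, regulated_fraction = 0, seed = 17)
  calls0 <- vapply(seq_len(300), function(i)
    classify_pth(nul$pth[i, ], nul$vehicle[i, ])$class, character(1))
  expect_lt(mean(calls0 %in% c("+++up", "+++down")), 0.02)
  expect_error(gen_pth_experiment(10, regulated_fraction = 1.2), "\\[0, 1\\]")
})

test_that("maturation time course has the 7x3 design and seeded determinism", {
  ex <- gen_maturation_experiment(50, affected_fraction = 0.3, seed = 18)
  expect_equal(dim(ex$intensity), c(50, 21))
  expect_equal(sort(unique(ex$design$day)), c(4, 5, 6, 8, 16, 25, 30))
  expect_equal(unname(table(ex$design$day)), rep(3L, 7),
               ignore_attr = TRUE)
  expect_identical(ex$intensity,
                   gen_maturation_experiment(50, affected_fraction = 0.3,
                                             seed = 18)$intensity)
})
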