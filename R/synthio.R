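# Synthetic-data generators: pedigrees, gene-dropped genotypes, polygenic
# phenotypes, architecture-labelled (locus, transcript, trait) triples, and
# designed expression experiments. Every generator is deterministic for a
# fixed seed; all child seeds derive from one master seed.

#' Derive a deterministic child seed from a master seed
#'
#' Child seeds keep independent generators reproducible under one master
#' seed. Kept below 2^31 so they are valid R integer seeds.
#'
#' @param seed master seed (integer).
#' @param stage integer stage index (>= 1).
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 104729) %% 2147483647L)
}

#' Generate a pedigree of nuclear families plus unrelated singletons
#'
#' Emulates a family-based cohort design: each family has two founders and
#' a stated number of full-sib offspring; singletons are unrelated founders.
#'
#' @param n_families number of nuclear families.
#' @param offspring_per_family offspring per family.
#' @param n_unrelated number of unrelated singletons.
#' @param seed integer seed (controls sex assignment of offspring/singletons).
#' @param cohort cohort label stored on every row.
#' @return a data.frame with columns fid, iid, father, mother, sex
#'   ("male"/"female"), cohort. Founders have NA parents; parents precede
#'   children.
#' @export
gen_pedigrees <- function(n_families, offspring_per_family, n_unrelated,
                          seed = 1L, cohort = "cohort1") {
  if (n_families < 0 || offspring_per_family < 0 || n_unrelated < 0)
    stop("counts must be non-negative")
  set.seed(child_seed(seed, 1L))
  rows <- list()
  if (n_families > 0) {
    for (f in seq_len(n_families)) {
      fid <- sprintf("F%04d", f)
      fa <- sprintf("%s_01", fid); mo <- sprintf("%s_02", fid)
      rows[[length(rows) + 1L]] <- data.frame(
        fid = fid, iid = c(fa, mo), father = NA_character_,
        mother = NA_character_, sex = c("male", "female"),
        cohort = cohort, stringsAsFactors = FALSE)
      if (offspring_per_family > 0) {
        kid <- sprintf("%s_%02d", fid, 2L + seq_len(offspring_per_family))
        rows[[length(rows) + 1L]] <- data.frame(
          fid = fid, iid = kid, father = fa, mother = mo,
          sex = sample(c("male", "female"), offspring_per_family, TRUE),
          cohort = cohort, stringsAsFactors = FALSE)
      }
    }
  }
  if (n_unrelated > 0) {
    iid <- sprintf("U%05d", seq_len(n_unrelated))
    rows[[length(rows) + 1L]] <- data.frame(
      fid = iid, iid = iid, father = NA_character_, mother = NA_character_,
      sex = sample(c("male", "female"), n_unrelated, TRUE),
      cohort = cohort, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(fid = character(), iid = character(),
                      father = character(), mother = character(),
                      sex = character(), cohort = character(),
                      stringsAsFactors = FALSE))
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  ped
}

#' Generate genotypes on a pedigree by gene dropping
#'
#' Founder haplotypes are drawn at Hardy-Weinberg equilibrium at a MAF
#' sampled uniformly from `maf_range`; offspring inherit one haplotype from
#' each parent. SNPs are grouped into non-recombining blocks (default block
#' size 1, i.e. independent SNPs); within a block a single parental
#' haplotype is transmitted, which preserves any founder LD built into the
#' block.
#'
#' @param pedigree data.frame from [gen_pedigrees()].
#' @param n_snps number of SNPs.
#' @param maf_range length-2 numeric in (0, 0.5]; per-SNP MAF drawn
#'   uniformly in this interval (a single value fixes the MAF).
#' @param seed integer seed.
#' @param ld_blocks optional data.frame(source, target, r2) requesting that
#'   SNP `target`'s founder alleles be copies of SNP `source`'s with flips
#'   calibrated to reach squared correlation `r2`; source and target are
#'   placed in the same transmission block.
#' @param chrom chromosome label for all SNPs.
#' @param pos_start first SNP position; SNPs are spaced `pos_step` apart.
#' @param pos_step base-pair spacing between consecutive SNPs.
#' @return list of class "genotype_matrix": `dosage` (samples x SNPs matrix,
#'   values 0/1/2), `snps` data.frame (snp, chrom, pos, ref, alt, maf,
#'   genotyped, info), `samples` character vector.
#' @export
gen_genotypes <- function(pedigree, n_snps, maf_range = c(0.05, 0.5),
                          seed = 1L, ld_blocks = NULL, chrom = "1",
                          pos_start = 1e5, pos_step = 5e3) {
  if (nrow(pedigree) == 0) stop("empty pedigree")
  if (length(maf_range) == 1) maf_range <- rep(maf_range, 2)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  set.seed(child_seed(seed, 2L))
  n <- nrow(pedigree)
  ord <- pedigree_order(pedigree)
  idx <- match(pedigree$iid, pedigree$iid)
  names(idx) <- pedigree$iid

  maf <- runif(n_snps, maf_range[1], maf_range[2])
  block <- seq_len(n_snps)  # default: every SNP its own block
  if (!is.null(ld_blocks)) {
    for (r in seq_len(nrow(ld_blocks)))
      block[ld_blocks$target[r]] <- block[ld_blocks$source[r]]
  }
  ublock <- unique(block)
  block_id <- match(block, ublock)
  n_blocks <- length(ublock)

  h1 <- matrix(0L, n, n_snps)  # paternal-transmitted haplotype
  h2 <- matrix(0L, n, n_snps)
  for (i in ord) {
    fa <- pedigree$father[i]; mo <- pedigree$mother[i]
    if (is.na(fa)) {  # founder: HWE draw, then overlay LD copies
      a1 <- rbinom(n_snps, 1L, maf)
      a2 <- rbinom(n_snps, 1L, maf)
      if (!is.null(ld_blocks)) {
        for (r in seq_len(nrow(ld_blocks))) {
          s <- ld_blocks$source[r]; t <- ld_blocks$target[r]
          eps <- ld_flip_prob(maf[s], ld_blocks$r2[r])
          a1[t] <- flip_allele(a1[s], eps)
          a2[t] <- flip_allele(a2[s], eps)
          maf[t] <- maf[s]
        }
      }
      h1[i, ] <- a1; h2[i, ] <- a2
    } else {
      fi <- idx[[fa]]; mi <- idx[[mo]]
      pick_f <- rbinom(n_blocks, 1L, 0.5)[block_id]  # one pick per block
      pick_m <- rbinom(n_blocks, 1L, 0.5)[block_id]
      h1[i, ] <- ifelse(pick_f == 1L, h1[fi, ], h2[fi, ])
      h2[i, ] <- ifelse(pick_m == 1L, h1[mi, ], h2[mi, ])
    }
  }
  dosage <- h1 + h2
  rownames(dosage) <- pedigree$iid
  snp_id <- sprintf("snp%06d", seq_len(n_snps))
  colnames(dosage) <- snp_id
  snps <- data.frame(
    snp = snp_id, chrom = chrom,
    pos = as.integer(pos_start + (seq_len(n_snps) - 1L) * pos_step),
    ref = "A", alt = "B", maf = maf, genotyped = TRUE, info = 1,
    stringsAsFactors = FALSE)
  structure(list(dosage = dosage, snps = snps, samples = pedigree$iid),
            class = "genotype_matrix")
}

# Flip each allele with probability eps (independent of allele state).
flip_allele <- function(a, eps) {
  f <- rbinom(length(a), 1L, eps)
  as.integer(xor(a, f))
}

#' Flip probability giving a target allelic r-squared
#'
#' For a copied allele flipped with probability eps independent of state,
#' the correlation with the source allele (frequency p) is
#' p(1-p)(1-2 eps) / sqrt(p(1-p) q(1-q)) with q = p(1-eps) + (1-p) eps.
#' Solved numerically for the eps whose squared correlation equals `r2`.
#'
#' @param p source minor-allele frequency in (0, 0.5].
#' @param r2 target squared correlation in (0, 1].
#' @return flip probability in [0, 0.5).
#' @export
ld_flip_prob <- function(p, r2) {
  if (r2 >= 1) return(0)
  f <- function(eps) {
    q <- p * (1 - eps) + (1 - p) * eps
    (p * (1 - p) * (1 - 2 * eps))^2 / (p * (1 - p) * q * (1 - q)) - r2
  }
  uniroot(f, c(0, 0.499999), tol = 1e-10)$root
}

# Topological order of a pedigree (parents before children); cycles rejected.
pedigree_order <- function(pedigree) {
  n <- nrow(pedigree)
  idx <- seq_len(n); names(idx) <- pedigree$iid
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(pedigree$father) | placed[idx[pedigree$father]]) &
      (is.na(pedigree$mother) | placed[idx[pedigree$mother]])
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) stop("pedigree contains a cycle or a missing parent")
  ord
}

#' Simulate polygenic phenotypes with planted SNP effects
#'
#' y = sum_j beta_j dosage_j + covariates + g + e, with additive polygenic
#' g ~ MVN(0, sigma2_A * 2 Phi) and residual e ~ N(0, sigma2_E). Each
#' planted SNP's beta is scaled so the SNP explains its stated h2 fraction
#' of the total phenotypic variance.
#'
#' @param genotypes a genotype_matrix.
#' @param pedigree pedigree data.frame.
#' @param kinship kinship matrix Phi over the same samples (from
#'   [compute_kinship()]).
#' @param causal_snps character vector of SNP ids with planted effects.
#' @param h2 numeric vector, per-SNP variance fraction in [0, 1); sum < 1.
#' @param sigma2_A additive polygenic variance.
#' @param sigma2_E residual variance.
#' @param seed integer seed.
#' @param covariates optional data.frame of covariates (numeric columns);
#'   each gets a N(0,1)-drawn coefficient unless `covariate_beta` given.
#' @param covariate_beta optional named numeric coefficients.
#' @return data.frame with iid, sex, cohort, the covariates, and column
#'   `trait`; attribute "beta" records the planted per-SNP effects.
#' @export
gen_phenotypes <- function(genotypes, pedigree, kinship,
                           causal_snps = character(), h2 = numeric(),
                           sigma2_A = 0, sigma2_E = 1, seed = 1L,
                           covariates = NULL, covariate_beta = NULL) {
  stopifnot(length(causal_snps) == length(h2))
  if (sum(h2) >= 1) stop("total SNP h2 must be < 1")
  if (length(causal_snps) && !all(causal_snps %in% genotypes$snps$snp))
    stop("causal SNPs missing from genotype matrix")
  set.seed(child_seed(seed, 3L))
  n <- length(genotypes$samples)
  v_total <- (sigma2_A + sigma2_E) / (1 - sum(h2))
  y <- numeric(n)
  beta <- numeric(length(causal_snps)); names(beta) <- causal_snps
  for (j in seq_along(causal_snps)) {
    d <- genotypes$dosage[, causal_snps[j]]
    vj <- stats::var(d)
    if (vj <= 0) stop("monomorphic causal SNP: ", causal_snps[j])
    beta[j] <- sqrt(h2[j] * v_total / vj)
    y <- y + beta[j] * (d - mean(d))
  }
  if (sigma2_A > 0) {
    K2 <- 2 * kinship[genotypes$samples, genotypes$samples]
    L <- chol(K2 + diag(1e-8, n))
    y <- y + sqrt(sigma2_A) * drop(crossprod(L, rnorm(n)))
  }
  y <- y + rnorm(n, sd = sqrt(sigma2_E))
  out <- data.frame(iid = genotypes$samples,
                    sex = pedigree$sex[match(genotypes$samples, pedigree$iid)],
                    cohort = pedigree$cohort[match(genotypes$samples,
                                                   pedigree$iid)],
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    cb <- covariate_beta
    if (is.null(cb)) {
      cb <- rnorm(ncol(covariates)); names(cb) <- colnames(covariates)
    }
    for (cn in colnames(covariates)) {
      out[[cn]] <- covariates[[cn]]
      y <- y + cb[[cn]] * covariates[[cn]]
    }
  }
  out$trait <- y
  attr(out, "beta") <- beta
  out
}

#' Generate (locus, transcript, trait) triples under a named architecture
#'
#' Linear-Gaussian structural models on an additive locus dosage L:
#' causal L -> G -> T; reactive L -> T -> G; independent L -> G and L -> T
#' with independent errors; null: neither G nor T depends on L (G and T
#' share no edge in any architecture beyond what the structure implies).
#'
#' @param L numeric dosage vector for the locus.
#' @param architecture one of "causal", "reactive", "independent", "null".
#' @param a effect of L on its direct child (G for causal/independent,
#'   T for reactive; also the L -> T effect under independent).
#' @param b downstream effect (G -> T for causal, T -> G for reactive).
#' @param noise_sd error SD for both structural equations.
#' @param seed integer seed.
#' @return list(G, T, architecture).
#' @export
gen_expression_triple <- function(L, architecture, a = 0.8, b = 0.8,
                                  noise_sd = 0.5, seed = 1L) {
  arch <- match.arg(architecture,
                    c("causal", "reactive", "independent", "null"))
  set.seed(child_seed(seed, 4L))
  n <- length(L)
  e1 <- rnorm(n, sd = noise_sd); e2 <- rnorm(n, sd = noise_sd)
  if (arch == "causal") {
    G <- a * L + e1; T <- b * G + e2
  } else if (arch == "reactive") {
    T <- a * L + e1; G <- b * T + e2
  } else if (arch == "independent") {
    G <- a * L + e1; T <- a * L + e2
  } else {
    G <- e1; T <- e2
  }
  list(G = G, T = T, architecture = arch)
}

#' Generate a panel of architecture-labelled expression/trait pairs
#'
#' One triple per gene on a shared or per-gene locus; used for model-recovery
#' studies of the causality model selection.
#'
#' @param genotypes genotype_matrix supplying locus dosages (one SNP per gene,
#'   recycled if fewer SNPs than genes).
#' @param architectures character vector, one label per gene.
#' @param a,b,noise_sd structural parameters, see [gen_expression_triple()].
#' @param seed integer seed.
#' @return list with `expression` (genes x samples matrix), `trait`
#'   (genes x samples matrix of the paired trait), `truth` data.frame
#'   (gene, snp, architecture).
#' @export
gen_expression_triples <- function(genotypes, architectures, a = 0.8,
                                   b = 0.8, noise_sd = 0.5, seed = 1L) {
  bad <- setdiff(architectures,
                 c("causal", "reactive", "independent", "null"))
  if (length(bad)) stop("unknown architecture label: ", bad[1])
  n_genes <- length(architectures)
  snp_ids <- rep_len(genotypes$snps$snp, n_genes)
  G <- matrix(0, n_genes, length(genotypes$samples))
  T <- matrix(0, n_genes, length(genotypes$samples))
  for (g in seq_len(n_genes)) {
    tri <- gen_expression_triple(genotypes$dosage[, snp_ids[g]],
                                 architectures[g], a, b, noise_sd,
                                 seed = child_seed(seed, 100L + g))
    G[g, ] <- tri$G; T[g, ] <- tri$T
  }
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  rownames(G) <- rownames(T) <- gene_ids
  colnames(G) <- colnames(T) <- genotypes$samples
  list(expression = G, trait = T,
       truth = data.frame(gene = gene_ids, snp = snp_ids,
                          architecture = architectures,
                          stringsAsFactors = FALSE))
}

#' Simulate a triplicate PTH-vs-vehicle expression experiment
#'
#' Intensities are log-normal around gene-specific baselines; a stated
#' fraction of genes is regulated with the stated fold change (direction
#' random), emulating triplicate arrays per treatment arm.
#'
#' @param n_genes number of genes.
#' @param regulated_fraction fraction of genes regulated by PTH, in [0, 1].
#' @param fold fold change (>= 1) applied to regulated genes.
#' @param seed integer seed.
#' @param base_log_mean,base_log_sd log-scale baseline intensity parameters.
#' @param noise_cv log-scale replicate noise SD.
#' @param frac_unexpressed fraction of genes with baseline below detection.
#' @param detect_threshold detection threshold used to place unexpressed
#'   baselines.
#' @return list: `pth` and `vehicle` (genes x 3 matrices), `truth`
#'   data.frame (gene, regulated, direction).
#' @export
gen_pth_experiment <- function(n_genes, regulated_fraction = 0.1, fold = 3,
                               seed = 1L, base_log_mean = log(400),
                               base_log_sd = 0.5, noise_cv = 0.1,
                               frac_unexpressed = 0.1,
                               detect_threshold = 100) {
  if (regulated_fraction < 0 || regulated_fraction > 1)
    stop("regulated_fraction must lie in [0, 1]")
  if (fold < 1) stop("fold must be >= 1")
  set.seed(child_seed(seed, 5L))
  base <- exp(rnorm(n_genes, base_log_mean, base_log_sd))
  unexpr <- runif(n_genes) < frac_unexpressed
  base[unexpr] <- runif(sum(unexpr), 5, detect_threshold * 0.5)
  regulated <- runif(n_genes) < regulated_fraction & !unexpr
  direction <- ifelse(regulated, sample(c(1, -1), n_genes, TRUE), 0)
  mult <- ifelse(direction == 1, fold, ifelse(direction == -1, 1 / fold, 1))
  pth <- base * mult * exp(matrix(rnorm(n_genes * 3, 0, noise_cv), n_genes))
  veh <- base * exp(matrix(rnorm(n_genes * 3, 0, noise_cv), n_genes))
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  rownames(pth) <- rownames(veh) <- gene_ids
  colnames(pth) <- paste0("PTH_", 1:3); colnames(veh) <- paste0("VEH_", 1:3)
  list(pth = pth, vehicle = veh,
       truth = data.frame(gene = gene_ids, regulated = regulated,
                          direction = c("0", "up", "down")[
                            match(direction, c(0, 1, -1))],
                          stringsAsFactors = FALSE))
}

#' Simulate a 7-timepoint x 3-replicate osteoblast maturation time course
#'
#' Emulates directed osteoblast differentiation sampled at days 4, 5, 6, 8,
#' 16, 25 and 30 post-induction, three arrays per time point. Affected genes
#' get a smooth time trend of the stated amplitude (in within-group SD units).
#'
#' @param n_genes number of genes.
#' @param affected_fraction fraction with a real time effect.
#' @param effect_size amplitude of the time trend in units of replicate SD.
#' @param seed integer seed.
#' @param noise_sd replicate SD on the log scale.
#' @return list: `intensity` genes x 21 matrix (columns day x replicate),
#'   `design` data.frame (sample, day, replicate), `truth` data.frame
#'   (gene, affected).
#' @export
gen_maturation_experiment <- function(n_genes, affected_fraction = 0.1,
                                      effect_size = 3, seed = 1L,
                                      noise_sd = 1) {
  set.seed(child_seed(seed, 6L))
  days <- c(4, 5, 6, 8, 16, 25, 30)
  design <- data.frame(
    sample = sprintf("D%02d_r%d", rep(days, each = 3), rep(1:3, 7)),
    day = rep(days, each = 3), replicate = rep(1:3, 7))
  affected <- runif(n_genes) < affected_fraction
  m <- matrix(rnorm(n_genes * 21, 0, noise_sd), n_genes)
  # smooth per-gene trend: random phase sinusoid over the day index
  for (g in which(affected)) {
    phase <- runif(1, 0, 2 * pi)
    trend <- effect_size * noise_sd * sin(seq(0, pi, length.out = 7) + phase)
    m[g, ] <- m[g, ] + rep(trend, each = 3)
  }
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  rownames(m) <- gene_ids
  colnames(m) <- design$sample
  list(intensity = m, design = design,
       truth = data.frame(gene = gene_ids, affected = affected,
                          stringsAsFactors = FALSE))
}
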