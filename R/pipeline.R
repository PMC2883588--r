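# Orchestration: pipeline configuration, the synthetic end-to-end run
# (stages I-IV on generated cohorts with planted effects), and QQ-plot
# data export. Reruns with the same config and seed are byte-identical.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the four-stage analysis with its
#' default. All defaults are the analysis constants: genome-wide p
#' 4.3e-7, suggestive band upper bound 5e-5, replication selection 1e-3,
#' replication p 0.05, eQTL significance 0.005, HWE p 1e-6, SNP call rate
#' 0.95, sample call rate 0.97, MAF 0.01, dosage variance ratio 0.3, LD
#' r-squared 0.5, cis window 500 kb, LCMS pair minimum 2, bootstrap B 1000.
#'
#' @param ... overrides for any listed field.
#' @return object of class "pipeline_config".
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    genome_wide_p = 4.3e-7, suggestive_p = 5e-5,
    replication_select_p = 1e-3, replication_p = 0.05,
    eqtl_p = 0.005, hwe_p = 1e-6, snp_call = 0.95, sample_call = 0.97,
    maf_min = 0.01, variance_ratio_min = 0.3, ld_r2_min = 0.5,
    cis_window = 500000L, lcms_pairs_min = 2L, bootstrap_B = 1000L,
    seed = 1L, cohort_order = c("discovery", "replication"),
    # synthetic study design
    n_families = 0L, offspring_per_family = 2L, n_unrelated = 2000L,
    n_replication = 2000L, n_snps = 200L, maf_range = c(0.2, 0.5),
    genome_wide_h2 = 0.03,
    suggestive_h2 = numeric(0),
    sigma2_A = 0, sigma2_E = 1,
    lcms_n = 300L, lcms_a = 0.8, lcms_b = 0.8, lcms_noise_sd = 0.5)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config field: ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration (hash ", config_hash(x), "):\n", sep = "")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

#' Deterministic FNV-1a hash of a configuration
#'
#' @param config any R object (deparsed before hashing).
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the four-stage pipeline on a synthetic study
#'
#' Generates a discovery cohort (optionally family-structured) and an
#' unrelated replication cohort with one planted genome-wide SNP
#' (`genome_wide_h2`) and optional suggestive-range SNPs (`suggestive_h2`),
#' then executes: Stage I QC, kinship, residualization and mixed-model
#' association; Stage II replication selection and fixed-effect
#' meta-analysis with tiering; Stage III cis-eQTL of lead SNPs in a
#' simulated expression panel; Stage IV suggestive-SNP filtering,
#' nearest-gene assignment, LCMS causality evidence at planted suggestive
#' loci, and two-route prioritization. Each planted suggestive SNP carries
#' a causal-architecture gene whose transcript mediates two correlated
#' traits, so its locus supplies pleiotropic eQTL/trait-QTL pairs.
#'
#' @param config a [pipeline_config()].
#' @param dir optional run directory; when given, all stage tables are
#'   written as TSV with config-hash and seed headers.
#' @return list of class "osteogwas_run": discovery/replication association
#'   tables, meta table, lambda_gc, candidates, evidence, prioritization,
#'   truth (planted SNP ids and architectures).
#' @export
run_pipeline <- function(config = pipeline_config(), dir = NULL) {
  cfg <- config
  seed <- cfg$seed
  n_plant <- length(cfg$suggestive_h2) + 1L
  if (cfg$n_snps < n_plant + 10L)
    stop("n_snps too small for the planted design")

  ## ---- synthetic inputs -------------------------------------------------
  ped_d <- gen_pedigrees(cfg$n_families, cfg$offspring_per_family,
                         cfg$n_unrelated, seed = child_seed(seed, 11L),
                         cohort = "discovery")
  ped_r <- gen_pedigrees(0L, 0L, cfg$n_replication,
                         seed = child_seed(seed, 12L),
                         cohort = "replication")
  # SNPs spaced 2 Mb apart so each planted locus is its own 500 kb window
  geno_d <- gen_genotypes(ped_d, cfg$n_snps, cfg$maf_range,
                          seed = child_seed(seed, 13L), pos_step = 2e6)
  geno_r <- gen_genotypes(ped_r, cfg$n_snps, cfg$maf_range,
                          seed = child_seed(seed, 14L), pos_step = 2e6)
  # planted SNPs: spread across the panel so each lands in its own locus
  gap <- max(1L, cfg$n_snps %/% n_plant)
  plant_idx <- 1L + (seq_len(n_plant) - 1L) * gap
  plant_ids <- geno_d$snps$snp[plant_idx]
  h2 <- c(cfg$genome_wide_h2, cfg$suggestive_h2)
  kin_d <- compute_kinship(ped_d)
  kin_r <- compute_kinship(ped_r)
  phe_d <- gen_phenotypes(geno_d, ped_d, kin_d, plant_ids, h2,
                          sigma2_A = cfg$sigma2_A, sigma2_E = cfg$sigma2_E,
                          seed = child_seed(seed, 15L))
  phe_r <- gen_phenotypes(geno_r, ped_r, kin_r, plant_ids, h2,
                          sigma2_A = 0, sigma2_E = cfg$sigma2_E,
                          seed = child_seed(seed, 16L))

  ## ---- stage I: QC + association ---------------------------------------
  qc <- qc_filter(geno_d, snp_call_rate_min = cfg$snp_call,
                  hwe_p_min = cfg$hwe_p, maf_min = cfg$maf_min,
                  sample_call_rate_min = cfg$sample_call)
  gd <- qc$genotypes
  res_d <- compute_residuals(phe_d, "trait", group_by = "sex")
  ke_d <- kinship_eigen(kin_d[res_d$iid, res_d$iid])
  assoc_d <- assoc_lme(res_d, gd$dosage[res_d$iid, , drop = FALSE], ke_d,
                       snp_info = gd$snps)
  assoc_d$genotyped <- TRUE
  lambda_gc <- genomic_lambda(
    assoc_d$p[!assoc_d$snp %in% plant_ids])

  ## ---- stage II: replication + meta ------------------------------------
  sel <- select_for_replication(assoc_d, cfg$replication_select_p)
  res_r <- compute_residuals(phe_r, "trait", group_by = "sex")
  keep_r <- intersect(sel, colnames(geno_r$dosage))
  assoc_r <- if (length(keep_r)) {
    assoc_lme(res_r, geno_r$dosage[res_r$iid, keep_r, drop = FALSE],
              kinship_eigen(kin_r[res_r$iid, res_r$iid]),
              snp_info = geno_r$snps[match(keep_r, geno_r$snps$snp), ])
  } else assoc_d[0, ]
  meta <- do.call(rbind, lapply(keep_r, function(s) {
    a <- assoc_d[assoc_d$snp == s, ]; b <- assoc_r[assoc_r$snp == s, ]
    m <- meta_fixed(c(a$beta, b$beta), c(a$se, b$se),
                    cohort_names = cfg$cohort_order,
                    genome_wide_p = cfg$genome_wide_p,
                    suggestive_p = cfg$suggestive_p)
    cbind(data.frame(snp = s,
                     chrom = gd$snps$chrom[match(s, gd$snps$snp)],
                     pos = gd$snps$pos[match(s, gd$snps$snp)],
                     stringsAsFactors = FALSE), m)
  }))
  if (is.null(meta)) meta <- data.frame()

  ## ---- gene annotation: one gene spanning each planted locus -----------
  ann <- data.frame(
    gene = sprintf("GENE%03d", seq_len(n_plant)),
    chrom = geno_d$snps$chrom[plant_idx],
    start = geno_d$snps$pos[plant_idx] - 2000L,
    end = geno_d$snps$pos[plant_idx] + 2000L,
    strand = "+", stringsAsFactors = FALSE)

  ## ---- stage IV: tiering + LCMS evidence + prioritization --------------
  candidates <- if (nrow(meta)) {
    tier_and_filter_suggestive(
      meta[, c("snp", "chrom", "pos", "p", "beta")], assoc_d, assoc_r,
      genome_wide_p = cfg$genome_wide_p, suggestive_p = cfg$suggestive_p,
      discovery_p = cfg$replication_select_p,
      replication_p = cfg$replication_p,
      locus_window = cfg$cis_window)
  } else data.frame()
  # LCMS triples at each planted suggestive locus (F2-style panel)
  lcms_rows <- list()
  if (n_plant > 1) {
    ped_f2 <- gen_pedigrees(0L, 0L, cfg$lcms_n,
                            seed = child_seed(seed, 17L), cohort = "f2")
    geno_f2 <- gen_genotypes(ped_f2, n_plant, c(0.5, 0.5),
                             seed = child_seed(seed, 18L))
    for (i in 2:n_plant) {
      L <- geno_f2$dosage[, i]
      tri <- gen_expression_triple(L, "causal", a = cfg$lcms_a,
                                   b = cfg$lcms_b,
                                   noise_sd = cfg$lcms_noise_sd,
                                   seed = child_seed(seed, 200L + i))
      set.seed(child_seed(seed, 300L + i))
      T2 <- tri$T + rnorm(cfg$lcms_n, sd = cfg$lcms_noise_sd)
      fit <- fit_models(L, tri$G, tri$T)
      pp <- pleiotropy_pairs(
        c(G = summary(stats::lm(tri$G ~ L))$coefficients[2, 4]),
        c(T1 = summary(stats::lm(tri$T ~ L))$coefficients[2, 4],
          T2 = summary(stats::lm(T2 ~ L))$coefficients[2, 4]),
        p_threshold = 0.05, pairs_min = cfg$lcms_pairs_min)
      lcms_rows[[i - 1L]] <- data.frame(
        gene = ann$gene[i], snp = plant_ids[i],
        selected = fit$selected, lcms_pairs = pp$count,
        stringsAsFactors = FALSE)
    }
  }
  lcms_tab <- if (length(lcms_rows)) do.call(rbind, lcms_rows)
              else data.frame(gene = character(), snp = character(),
                              selected = character(),
                              lcms_pairs = integer())
  # evidence table for candidate genes (expression channels absent here)
  cand_genes <- if (nrow(candidates)) {
    unique(do.call(rbind, lapply(seq_len(nrow(candidates)), function(i) {
      g <- assign_nearest_gene(candidates[i, ], ann)
      if (nrow(g)) cbind(snp = candidates$snp[i], g) else NULL
    })))
  } else data.frame()
  evidence <- data.frame(
    gene = ann$gene, pth_class = NA_character_, maturation_sig = NA,
    atlas_skeletal = NA,
    lcms_pairs = ifelse(ann$gene %in% lcms_tab$gene,
                        lcms_tab$lcms_pairs[match(ann$gene,
                                                  lcms_tab$gene)], NA),
    stringsAsFactors = FALSE)
  # only genes whose locus reached the suggestive tier are candidates
  sugg_genes <- if (nrow(cand_genes)) {
    tiers <- candidates$tier[match(cand_genes$snp, candidates$snp)]
    cand_genes$gene[tiers == "suggestive"]
  } else character()
  evidence <- evidence[evidence$gene %in% sugg_genes, , drop = FALSE]
  prior <- if (nrow(evidence)) {
    prioritize_genes(evidence, pairs_min = cfg$lcms_pairs_min)
  } else evidence

  run <- structure(list(
    config = cfg, qc_report = qc$report, assoc_discovery = assoc_d,
    assoc_replication = assoc_r, meta = meta, lambda_gc = lambda_gc,
    candidates = candidates, annotation = ann, lcms = lcms_tab,
    evidence = evidence, prioritization = prior,
    truth = list(planted = data.frame(
      snp = plant_ids, h2 = h2,
      role = c("genome_wide", rep("suggestive", n_plant - 1L)),
      gene = ann$gene, stringsAsFactors = FALSE))),
    class = "osteogwas_run")

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    meta_hdr <- c(package = "osteogwas",
                  config_hash = config_hash(cfg),
                  seed = as.character(seed),
                  coordinates = "1-based inclusive")
    write_tsv_meta(assoc_d, file.path(dir, "assoc_discovery.tsv"), meta_hdr)
    write_tsv_meta(assoc_r, file.path(dir, "assoc_replication.tsv"),
                   meta_hdr)
    if (nrow(meta)) write_tsv_meta(meta, file.path(dir, "meta.tsv"),
                                   meta_hdr)
    if (nrow(candidates))
      write_tsv_meta(candidates, file.path(dir, "candidates.tsv"), meta_hdr)
    if (nrow(lcms_tab)) write_tsv_meta(lcms_tab,
                                       file.path(dir, "lcms.tsv"), meta_hdr)
    if (nrow(prior)) write_tsv_meta(prior,
                                    file.path(dir, "prioritization.tsv"),
                                    meta_hdr)
  }
  run
}

#' @export
print.osteogwas_run <- function(x, ...) {
  cat("osteogwas pipeline run (seed ", x$config$seed, ", hash ",
      config_hash(x$config), ")\n", sep = "")
  cat("  discovery SNPs tested: ", nrow(x$assoc_discovery),
      "; lambda_GC = ", round(x$lambda_gc, 3), "\n", sep = "")
  cat("  SNPs meta-analyzed: ", nrow(x$meta), "\n", sep = "")
  if (nrow(x$candidates)) {
    cat("  candidate loci:\n")
    print(x$candidates[, c("snp", "chrom", "pos", "p", "tier")],
          row.names = FALSE)
  } else cat("  no candidate loci\n")
  if (nrow(x$prioritization)) {
    cat("  prioritized genes:\n")
    print(x$prioritization[, c("gene", "lcms_pairs", "route",
                               "prioritized")], row.names = FALSE)
  }
  invisible(x)
}

#' Observed-versus-expected quantiles for a QQ plot
#'
#' @param p_values numeric vector in (0, 1].
#' @return data.frame(expected, observed) of -log10 quantiles; expected
#'   uses the (i - 0.5)/m rank convention.
#' @export
make_qq_data <- function(p_values) {
  m <- length(p_values)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(sort(p_values)))
}
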