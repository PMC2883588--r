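# Stage IV: tiering with the four suggestive criteria, nearest gene,
# two-route prioritization, term enrichment.

make_tier_fixture <- function() {
  meta <- data.frame(
    snp = c("gw", "sugg", "toobig", "s2"),
    chrom = "1", pos = c(1e6, 5e6, 9e6, 13e6),
    p = c(2.68e-11, 4.87e-6, 6e-5, 2e-5),
    beta = c(0.3, 0.2, 0.1, -0.15), stringsAsFactors = FALSE)
  discovery <- data.frame(
    snp = meta$snp, p = c(1e-12, 4.87e-6, 1e-4, 5e-4),
    direction = c(1, 1, 1, -1), stringsAsFactors = FALSE)
  replication <- data.frame(
    snp = meta$snp, p = c(1e-4, 0.03, 0.04, 0.02),
    direction = c(1, 1, 1, -1), stringsAsFactors = FALSE)
  list(meta = meta, discovery = discovery, replication = replication)
}

test_that("tiering applies all four suggestive criteria", {
  fx <- make_tier_fixture()
  out <- tier_and_filter_suggestive(fx$meta, fx$discovery, fx$replication)
  expect_equal(out$tier[out$snp == "gw"], "genome_wide")
  expect_equal(out$tier[out$snp == "sugg"], "suggestive")
  expect_false("toobig" %in% out$snp)  # meta p 6e-5 > 5e-5
  expect_equal(out$tier[out$snp == "s2"], "suggestive")
})

test_that("each suggestive criterion is individually necessary", {
  fx <- make_tier_fixture()
  # flip criterion 2: discovery p at the boundary (strict <)
  d2 <- fx$discovery; d2$p[d2$snp == "sugg"] <- 1e-3
  o2 <- tier_and_filter_suggestive(fx$meta, d2, fx$replication)
  expect_false("sugg" %in% o2$snp)
  # flip criterion 3: replication p just above 0.05
  r3 <- fx$replication; r3$p[r3$snp == "sugg"] <- 0.051
  o3 <- tier_and_filter_suggestive(fx$meta, fx$discovery, r3)
  expect_false("sugg" %in% o3$snp)
  # boundary: replication p exactly 0.05 passes (<=)
  r3b <- fx$replication; r3b$p[r3b$snp == "sugg"] <- 0.05
  expect_true("sugg" %in%
    tier_and_filter_suggestive(fx$meta, fx$discovery, r3b)$snp)
  # flip criterion 4: discordant directions
  r4 <- fx$replication; r4$direction[r4$snp == "sugg"] <- -1
  o4 <- tier_and_filter_suggestive(fx$meta, fx$discovery, r4)
  expect_false("sugg" %in% o4$snp)
  # flip criterion 1: meta p into the genome-wide range changes tier
  m1 <- fx$meta; m1$p[m1$snp == "sugg"] <- 1e-8
  o1 <- tier_and_filter_suggestive(m1, fx$discovery, fx$replication)
  expect_equal(o1$tier[o1$snp == "sugg"], "genome_wide")
})

test_that("locus collapsing keeps one lead SNP per window", {
  fx <- make_tier_fixture()
  fx$meta$pos <- c(1e6, 5e6, 9e6, 5e6 + 3e5)  # s2 within 500 kb of sugg
  out <- tier_and_filter_suggestive(fx$meta, fx$discovery, fx$replication)
  # s2 (p 2e-5) beats sugg (4.87e-6)? No: sugg has the smaller p, wins
  expect_true("sugg" %in% out$snp)
  expect_false("s2" %in% out$snp)
})

test_that("nearest-gene assignment reports distances in kb", {
  ann <- data.frame(gene = c("NEAR", "FAR"), chrom = "8",
                    start = c(100000L, 900000L), end = c(120000L, 950000L),
                    strand = "+", stringsAsFactors = FALSE)
  inside <- assign_nearest_gene(list(chrom = "8", pos = 110000), ann)
  expect_equal(inside$gene, "NEAR")
  expect_equal(inside$location, "intragenic")
  near <- assign_nearest_gene(list(chrom = "8", pos = 133400), ann)
  expect_equal(near$gene, "NEAR")
  expect_equal(near$distance_kb, 13.4)
  # equidistant genes are both reported
  mid <- assign_nearest_gene(list(chrom = "8", pos = 510000), ann)
  expect_setequal(mid$gene, c("NEAR", "FAR"))
  expect_warning(assign_nearest_gene(list(chrom = "X", pos = 1), ann),
                 "no annotation")
})

test_that("two-route prioritization mirrors the published evidence patterns", {
  ev <- data.frame(
    gene = c("GPR177like", "HECW2like", "single", "nothing"),
    pth_class = c("+++down", NA, "+++up", "++"),
    maturation_sig = c(TRUE, FALSE, FALSE, FALSE),
    atlas_skeletal = c(FALSE, NA, FALSE, FALSE),
    lcms_pairs = c(NA, 3L, 0L, 0L), stringsAsFactors = FALSE)
  out <- prioritize_genes(ev)
  expect_equal(out$route,
               c("expression_2of3", "lcms_pairs", "none", "none"))
  expect_equal(out$prioritized, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$n_expression_signatures, c(2, 0, 1, 0))
})

test_that("prioritization is monotone in added evidence", {
  set.seed(71)
  classes <- c(NA, "0", "+", "++", "+++up", "+++down")
  for (i in 1:40) {
    base <- data.frame(
      gene = "g",
      pth_class = sample(classes, 1),
      maturation_sig = sample(c(NA, TRUE, FALSE), 1),
      atlas_skeletal = sample(c(NA, TRUE, FALSE), 1),
      lcms_pairs = sample(c(NA, 0:3), 1), stringsAsFactors = FALSE)
    more <- base
    more$pth_class <- "+++up"; more$maturation_sig <- TRUE
    more$lcms_pairs <- max(2L, base$lcms_pairs, na.rm = TRUE)
    expect_true(prioritize_genes(more)$prioritized >=
                prioritize_genes(base)$prioritized)
  }
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # universe 20, term size 5, set size 4, overlap 3: p = 155/4845
  universe <- sprintf("g%02d", 1:20)
  term <- data.frame(gene = universe[1:5], term = "adhesion")
  gene_set <- c(universe[1:3], universe[10])
  out <- enrich_hypergeom(gene_set, term, universe)
  expect_equal(out$overlap, 3)
  expect_equal(out$p, 155 / 4845, tolerance = 1e-12)
  expect_equal(out$p, oracle_hyper_upper(3, 5, 20, 4), tolerance = 1e-12)

  # the full universe as gene set gives p = 1 everywhere
  all_out <- enrich_hypergeom(universe, term, universe)
  expect_true(all(all_out$p == 1))

  # random small universes against the enumeration oracle; BH monotone
  set.seed(72)
  for (i in 1:10) {
    N <- sample(20:200, 1)
    uni <- sprintf("u%03d", 1:N)
    terms <- do.call(rbind, lapply(1:4, function(t)
      data.frame(gene = sample(uni, sample(3:N, 1)),
                 term = paste0("t", t))))
    gs <- sample(uni, sample(3:15, 1))
    out <- enrich_hypergeom(gs, terms, uni)
    for (j in seq_len(nrow(out)))
      expect_equal(out$p[j],
                   oracle_hyper_upper(out$overlap[j], out$term_size[j],
                                      N, out$set_size[j]),
                   tolerance = 1e-10)
    expect_true(all(out$p_adjusted >= out$p - 1e-15))
    expect_true(all(out$p_adjusted <= 1))
    expect_true(all(diff(out$p_adjusted) >= -1e-15))  # sorted by p
  }
  expect_error(enrich_hypergeom("zzz", term, universe), "universe")
})
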