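test_that("genotype simulation is deterministic and respects LD settings", {
  scn <- simulation_scenario(n_individuals = 300, n_markers = 200,
                             ld_block_size = 10, rho_ld = 0, seed = 71)
  g1 <- simulate_genotypes(scn)
  g2 <- simulate_genotypes(scn)
  expect_identical(g1$dosages, g2$dosages)
  # rho = 0: adjacent markers essentially uncorrelated
  r_adj <- sapply(seq_len(199), function(j)
    cor(g1$dosages[, j], g1$dosages[, j + 1]))
  expect_lt(mean(abs(r_adj)), 0.06)

  scn9 <- simulation_scenario(n_individuals = 300, n_markers = 200,
                              ld_block_size = 10, rho_ld = 0.9, seed = 71)
  g9 <- simulate_genotypes(scn9)
  block <- rep(seq_len(20), each = 10)
  cm <- cor(g9$dosages)
  same <- outer(block, block, "==") & upper.tri(cm)
  diff_b <- outer(block, block, "!=") & upper.tri(cm)
  expect_gt(mean(cm[same]), mean(cm[diff_b]) + 0.2)
})

test_that("annotation simulation hits the coverage target and scatters pathways", {
  scn <- simulation_scenario(n_individuals = 50, n_markers = 3000,
                             n_genes = 200, gene_coverage = 0.4,
                             n_chromosomes = 4, seed = 72)
  g <- simulate_genotypes(scn)
  ann <- simulate_annotation(scn, g)
  idx <- map_markers_to_genes(g, ann$genes)
  frac <- mean(lengths(idx$marker_genes) > 0)
  expect_lt(abs(frac - 0.4), 0.05)
  # identical under the same seed
  ann2 <- simulate_annotation(scn, g)
  expect_identical(ann$genes, ann2$genes)
  expect_identical(ann$pathways, ann2$pathways)
  # pathways with >= 4 genes span at least 2 chromosomes
  chr_of <- ann$genes$chrom[match(ann$pathways$gene_id, ann$genes$gene_id)]
  by_pw <- split(chr_of, ann$pathways$pathway_id)
  for (pw in by_pw)
    if (length(pw) >= 4) expect_gte(length(unique(pw)), 2)
})

test_that("genetic-value variance matches the configured heritability", {
  scn <- simulation_scenario(n_individuals = 1000, n_markers = 1500,
                             h2_total = 0.3, seed = 73)
  g <- simulate_genotypes(scn)
  sim <- simulate_phenotypes(scn, g)
  expect_lt(abs(var(sim$truth$genetic_values) / 0.3 - 1), 0.1)
})

test_that("pathway enrichment concentrates variance in the target set", {
  scn <- simulation_scenario(n_individuals = 200, n_markers = 1000,
                             trait_model = "pathway_enriched",
                             rho_set = 0.5, seed = 74)
  g <- simulate_genotypes(scn)
  set.seed(74)
  target <- feature_set("target", sample(1000, 100), 1000)
  sim <- simulate_phenotypes(scn, g, target_set = target)
  a <- sim$truth$effects
  v_set <- sum(a[target$markers]^2)
  v_rest <- sum(a[-target$markers]^2)
  expect_lt(abs(v_set / (v_set + v_rest) - 0.5), 0.15)
  expect_error(simulate_phenotypes(scn, g), "target_set")
})

test_that("setting the enrichment to the marker share recovers the null", {
  # rho_set = m_S/m makes per-marker effect variances equal across strata
  scn <- simulation_scenario(n_individuals = 50, n_markers = 400,
                             trait_model = "pathway_enriched",
                             rho_set = 0.25, seed = 75)
  g <- simulate_genotypes(scn)
  target <- feature_set("t", 1:100, 400)
  sim <- simulate_phenotypes(scn, g, target_set = target)
  a <- sim$truth$effects
  # variances equal across strata: ratio of mean squares near 1
  expect_lt(abs(log(mean(a[1:100]^2) / mean(a[101:400]^2))), log(2.5))
})

test_that("focal-locus traits carry one large effect inside the focal gene", {
  scn <- simulation_scenario(n_individuals = 100, n_markers = 800,
                             trait_model = "focal_locus",
                             focal_share = 0.3, seed = 76)
  g <- simulate_genotypes(scn)
  ann <- simulate_annotation(scn, g)
  sim <- simulate_phenotypes(scn, g, ann)
  fm <- sim$truth$focal_marker
  expect_false(is.na(fm))
  focal_row <- ann$genes[ann$genes$gene_id == ann$focal_gene, ]
  expect_true(g$markers$pos[fm] >= focal_row$start &&
                g$markers$pos[fm] <= focal_row$stop)
  expect_equal(which.max(abs(sim$truth$effects)), fm)
})

test_that("simulated reliabilities stay inside the configured bounds", {
  scn <- simulation_scenario(n_individuals = 400, n_markers = 100, seed = 77)
  g <- simulate_genotypes(scn)
  sim <- simulate_phenotypes(scn, g)
  r <- sim$phenotypes$reliability
  expect_true(all(r >= 0.05 & r <= 0.99))
  expect_gt(mean(r), 0.8)   # proven-bull scale
})

test_that("simulation files round-trip through the standard readers", {
  scn <- simulation_scenario(n_individuals = 30, n_markers = 150,
                             n_genes = 20, n_pathways = 4, seed = 78)
  g <- simulate_genotypes(scn)
  ann <- simulate_annotation(scn, g)
  sim <- simulate_phenotypes(scn, g, ann)
  dir <- withr::local_tempdir()
  paths <- write_simulation(g, ann, sim$phenotypes, dir)
  g2 <- read_genotypes(paths[["genotypes"]], format = "dosage")
  expect_equal(g2$dosages, g$dosages)
  genes2 <- read_gene_annotation(paths[["genes"]], "tsv")
  expect_equal(genes2, ann$genes)
  pm2 <- read_pathway_map(paths[["pathways"]], "tsv")
  expect_setequal(pm2$pathway_id, ann$pathways$pathway_id)
  ph2 <- read_phenotypes(paths[["phenotypes"]])
  expect_equal(ph2$value, sim$phenotypes$value)
})
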