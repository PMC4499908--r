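make_map_fixture <- function() {
  # markers at 100, 200, ..., 1000 on chr1 and chr2
  dos <- matrix(rep(c(0L, 1L, 2L), length.out = 3 * 20), nrow = 3)
  g <- toy_genotypes(dos, chrom = rep(c("chr1", "chr2"), each = 10),
                     pos = rep(seq(100L, 1000L, by = 100L), 2))
  genes <- tibble::tibble(
    gene_id = c("G1", "G2", "G3", "G4"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(100L, 250L, 150L, 901L),
    stop = c(300L, 450L, 350L, 1000L))
  list(g = g, genes = genes)
}

test_that("marker-in-gene rule uses inclusive closed intervals and flank", {
  fx <- make_map_fixture()
  idx <- map_markers_to_genes(fx$g, fx$genes, flank = 0)
  # G1 spans [100,300]: markers at 100, 200, 300 (inclusive boundaries)
  expect_equal(idx$gene_markers$G1, c(1L, 2L, 3L))
  # marker at 99 would be outside; with flank 10 the gene grows
  genes99 <- tibble::tibble(gene_id = "Gx", chrom = "chr1",
                            start = 201L, stop = 250L)
  expect_length(map_markers_to_genes(fx$g, genes99)$gene_markers$Gx, 0)
  expect_equal(map_markers_to_genes(fx$g, genes99,
                                    flank = 1)$gene_markers$Gx, 2L)
})

test_that("a marker inside overlapping genes is listed under both", {
  fx <- make_map_fixture()
  idx <- map_markers_to_genes(fx$g, fx$genes)
  # marker 3 (chr1:300) is in G1 [100,300] and G2 [250,450]
  expect_setequal(idx$marker_genes[[3]], c("G1", "G2"))
  # index is symmetric between the two views
  for (gid in names(idx$gene_markers))
    for (mk in idx$gene_markers[[gid]])
      expect_true(gid %in% idx$marker_genes[[mk]])
})

test_that("genes on chromosomes absent from the genotypes map to nothing", {
  fx <- make_map_fixture()
  genes <- rbind(fx$genes, tibble::tibble(gene_id = "G9", chrom = "chrX",
                                          start = 1L, stop = 500L))
  expect_warning(idx <- map_markers_to_genes(fx$g, genes), "absent")
  expect_length(idx$gene_markers$G9, 0)
})

test_that("pathway marker sets union gene markers once per pathway", {
  fx <- make_map_fixture()
  idx <- map_markers_to_genes(fx$g, fx$genes)
  pm <- tibble::tibble(pathway_id = c("P1", "P1"), gene_id = c("G1", "G2"))
  s <- pathway_marker_set("P1", pm, idx)
  # G1 -> {1,2,3}, G2 -> {3,4}; marker 3 counted once
  expect_equal(s$markers, 1:4)
  expect_equal(s$m_set, 4L)
  # single-gene pathway with one marker is allowed (m_S = 1)
  pm1 <- tibble::tibble(pathway_id = "P2", gene_id = "G4")
  expect_equal(pathway_marker_set("P2", pm1, idx)$m_set, 1L)
  # pathway whose genes have no markers errors
  genes_empty <- rbind(fx$genes, tibble::tibble(gene_id = "G8",
                                                chrom = "chr1",
                                                start = 451L, stop = 460L))
  idx2 <- map_markers_to_genes(fx$g, genes_empty)
  pm0 <- tibble::tibble(pathway_id = "P0", gene_id = "G8")
  expect_error(pathway_marker_set("P0", pm0, idx2), "zero mapped markers")
})

test_that("focal-region genes are selected by padded-interval overlap", {
  genes <- tibble::tibble(
    gene_id = c("F", "near", "far", "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000000L, 600000L, 100000L, 1000000L),
    stop = c(1100000L, 620000L, 300000L, 1100000L))
  fg <- focal_region_genes("F", genes, window = 5e5)
  expect_true(all(c("F", "near") %in% fg))    # 380 kb gap: inside window
  expect_false("far" %in% fg)                 # 700 kb gap: outside
  expect_false("other_chrom" %in% fg)
  expect_error(focal_region_genes("missing", genes), "unknown focal gene")
})

test_that("complement sets form exact partitions", {
  s <- feature_set("S", c(1, 2, 3), m = 10)
  cs <- complement_set(s)
  expect_equal(cs$m_set, 7L)
  expect_setequal(c(s$markers, cs$markers), 1:10)
  expect_length(intersect(s$markers, cs$markers), 0)
  full <- feature_set("full", 1:10, m = 10)
  expect_error(complement_set(full), "covers all markers")
  # property over random sets
  set.seed(1)
  for (k in 1:20) {
    m <- sample(5:50, 1)
    sz <- sample(m - 1, 1)
    s <- feature_set("r", sample(m, sz), m)
    cs <- complement_set(s)
    expect_equal(s$m_set + cs$m_set, m)
    expect_setequal(c(s$markers, cs$markers), seq_len(m))
  }
})

test_that("feature sets round-trip through TSV", {
  sets <- list(feature_set("A", c(2, 5, 9), 12, contains_focal = TRUE),
               feature_set("B", c(1, 12), 12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_sets(sets, path)
  back <- read_feature_sets(path)
  expect_equal(back$A$markers, c(2L, 5L, 9L))
  expect_true(back$A$contains_focal)
  expect_false(back$B$contains_focal)
})

test_that("mapped-marker fraction matches the generator's coverage setting", {
  fx <- small_sim()
  frac <- mean(lengths(fx$idx$marker_genes) > 0)
  expect_lt(abs(frac - fx$scn$gene_coverage), 0.05)
})

test_that("focal flag reflects intersection with the focal region", {
  fx <- small_sim()
  focal_genes <- focal_region_genes(fx$ann$focal_gene, fx$ann$genes,
                                    window = 5e4)
  s_focal <- gene_set_markers("with", fx$ann$focal_gene, fx$idx, focal_genes)
  expect_true(s_focal$contains_focal)
  non_focal_gene <- setdiff(names(fx$idx$gene_markers)[
    lengths(fx$idx$gene_markers) > 0], focal_genes)[1]
  s_non <- gene_set_markers("without", non_focal_gene, fx$idx, focal_genes)
  expect_false(s_non$contains_focal)
})
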