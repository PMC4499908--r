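test_that("dosage TSV round-trips dosages, ids and coordinates exactly", {
  g <- toy_genotypes(matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
                            dimnames = list(c("a", "b", "c"), c("m1", "m2"))),
                     chrom = c("chr1", "chr2"), pos = c(100L, 250L))
  expect_equal(g$markers$freq, c(mean(c(0, 1, 2)) / 2, mean(c(2, 1, 0)) / 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(g, path)
  g2 <- read_genotypes(path, format = "dosage")
  expect_identical(dimnames(g2$dosages), dimnames(g$dosages))
  expect_equal(g2$dosages, g$dosages, ignore_attr = FALSE)
  expect_equal(g2$markers, g$markers)
})

test_that("VCF genotype calls are converted to alternate-allele dosages", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  recs <- data.frame(chrom = c("chr1", "chr1"), pos = c(100, 200),
                     id = c("s1", "s2"))
  gts <- rbind(c("0/1", "1/1", "0/0"), c("0|0", "0/1", "1|1"))
  write_vcf_fixture(path, recs, c("A1", "A2", "A3"), gts)
  g <- read_genotypes(path, format = "vcf")
  expect_equal(unname(g$dosages[, "s1"]), c(1, 2, 0))
  expect_equal(unname(g$dosages[, "s2"]), c(0, 1, 2))
})

test_that("VCF missing calls follow the reject/impute policy", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  recs <- data.frame(chrom = "chr1", pos = 100, id = "s1")
  gts <- matrix(c("0/1", "./.", "1/1"), nrow = 1)
  write_vcf_fixture(path, recs, c("A1", "A2", "A3"), gts)
  expect_error(read_genotypes(path, format = "vcf"), "missing")
  expect_warning(g <- read_genotypes(path, format = "vcf",
                                     missing = "impute"), "imputing")
  expect_equal(unname(g$dosages[, 1]), c(1, 1.5, 2))
})

test_that("duplicate marker and individual ids are rejected", {
  dos <- matrix(c(0, 1, 1, 2), nrow = 2,
                dimnames = list(c("a", "b"), c("m1", "m1")))
  expect_error(new_genotypes(dos, tibble::tibble(
    marker_id = c("m1", "m1"), chrom = "chr1", pos = c(1L, 2L))),
    "duplicate marker")
  dos2 <- matrix(c(0, 1, 1, 2), nrow = 2,
                 dimnames = list(c("a", "a"), c("m1", "m2")))
  expect_error(new_genotypes(dos2, tibble::tibble(
    marker_id = c("m1", "m2"), chrom = "chr1", pos = c(1L, 2L))),
    "duplicate individual")
})

test_that("markers are sorted by position and duplicates in position fail", {
  g <- toy_genotypes(matrix(c(0, 1, 2, 0, 1, 1), nrow = 3), pos = c(300L, 100L))
  expect_equal(g$markers$pos, c(100L, 300L))
  expect_false(is.unsorted(g$markers$pos))
  expect_error(toy_genotypes(matrix(0:1, 1), pos = c(100L, 100L)),
               "duplicate marker positions")
})

test_that("MAF filter keeps strictly above-threshold markers, preserves order, idempotent", {
  # freqs: 0.125 (kept), 0 (monomorphic, dropped), exactly at threshold (dropped)
  dos <- cbind(c(0, 0, 0, 1), c(0, 0, 0, 0), c(0, 0, 0, 2), c(1, 1, 2, 0))
  g <- toy_genotypes(dos)
  f <- filter_maf(g, 0.01)
  expect_equal(f$markers$marker_id, c("m1", "m3", "m4"))
  expect_equal(filter_maf(g, 0.25)$markers$marker_id, "m4")
  # marker at exactly the threshold is removed (strict inequality)
  g2 <- toy_genotypes(cbind(rep(c(0L, 1L), c(49, 1)), rep(0:2, length.out = 50)))
  expect_equal(min(g2$markers$freq), 0.01)
  expect_false("m1" %in% filter_maf(g2, 0.01)$markers$marker_id)
  # idempotence
  expect_equal(filter_maf(f, 0.01)$dosages, f$dosages)
  # retained frequencies bounded away from the threshold
  set.seed(3)
  gr <- random_genotypes(40, 60, seed = 3, pmin = 0.0, pmax = 1.0)
  fr <- filter_maf(gr, 0.01)
  expect_true(all(fr$markers$freq > 0.01 & fr$markers$freq < 0.99))
})

test_that("PLINK bed/bim/fam round-trips dosages and coordinates", {
  g <- random_genotypes(13, 7, seed = 5)
  prefix <- withr::local_tempfile()
  write_plink_fixture(g, prefix)
  g2 <- read_genotypes(paste0(prefix, ".bed"), format = "plink")
  expect_equal(g2$dosages, g$dosages)
  expect_equal(g2$markers$pos, g$markers$pos)
})

test_that("phenotype reader validates structure and reliability range", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(id = c("a", "b"), trait = "t1",
                                  value = c(1.2, -0.5),
                                  reliability = c(0.9, 0.8)), path)
  ph <- read_phenotypes(path)
  expect_equal(ph$value, c(1.2, -0.5))
  readr::write_tsv(tibble::tibble(id = c("a", "a"), trait = "t1",
                                  value = 1:2), path)
  expect_error(read_phenotypes(path), "duplicate")
  readr::write_tsv(tibble::tibble(id = "a", trait = "t1", value = 1,
                                  reliability = 1.0), path)
  expect_error(read_phenotypes(path), "reliabilities")
})
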