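# Fixture builders and file writers used across tests. Heavier shared
# datasets are memoized for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small genotype object built directly from a dosage matrix.
toy_genotypes <- function(dos, chrom = NULL, pos = NULL) {
  n <- nrow(dos); m <- ncol(dos)
  if (is.null(rownames(dos))) rownames(dos) <- paste0("i", seq_len(n))
  if (is.null(colnames(dos))) colnames(dos) <- paste0("m", seq_len(m))
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  new_genotypes(dos, tibble::tibble(marker_id = colnames(dos),
                                    chrom = chrom, pos = pos))
}

# Random polymorphic genotypes (independent markers, HWE).
random_genotypes <- function(n, m, seed = 1, pmin = 0.1, pmax = 0.9) {
  set.seed(seed)
  repeat {
    p <- runif(m, pmin, pmax)
    dos <- sapply(p, function(pp) rbinom(n, 2, pp))
    if (all(colSums(dos) > 0 & colSums(dos) < 2 * n)) break
  }
  toy_genotypes(dos)
}

# Small mid-scale dataset shared by several files: 150 individuals,
# 1200 markers, genes covering ~40% of markers.
small_sim <- function() cached("small_sim", function() {
  scn <- simulation_scenario(n_individuals = 150, n_markers = 1200,
                             n_genes = 90, n_chromosomes = 3, seed = 42)
  g <- simulate_genotypes(scn)
  ann <- simulate_annotation(scn, g)
  sim <- simulate_phenotypes(scn, g, ann)
  idx <- map_markers_to_genes(g, ann$genes)
  ph <- align_phenotypes(sim$phenotypes, "sim_trait", individual_ids(g))
  w <- center_scale(g)
  list(scn = scn, geno = g, ann = ann, sim = sim, idx = idx,
       y = ph$y, weights = residual_weights(ph$reliability),
       w = w, G = build_grm(w))
})

# PLINK bed/bim/fam writer (SNP-major) for round-trip tests.
write_plink_fixture <- function(g, prefix) {
  n <- nrow(g$dosages); m <- ncol(g$dosages)
  bim <- data.frame(g$markers$chrom, g$markers$marker_id, 0,
                    g$markers$pos, "A", "B")
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(rownames(g$dosages), rownames(g$dosages), 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  code <- c(`0` = 3L, `1` = 2L, `2` = 0L)   # 2-bit codes per dosage
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bpm <- ceiling(n / 4)
  for (j in seq_len(m)) {
    cj <- code[as.character(g$dosages[, j])]
    cj <- c(cj, rep(0L, 4 * bpm - n))
    byte <- cj[c(TRUE, FALSE, FALSE, FALSE)] +
      4L * cj[c(FALSE, TRUE, FALSE, FALSE)] +
      16L * cj[c(FALSE, FALSE, TRUE, FALSE)] +
      64L * cj[c(FALSE, FALSE, FALSE, TRUE)]
    writeBin(as.raw(byte), con)
  }
  prefix
}

# Minimal single-sample VCF writer.
write_vcf_fixture <- function(path, records, samples, gts) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$chrom[i], records$pos[i], records$id[i], "A", "C",
            ".", "PASS", ".", "GT", gts[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}

# Minimal GFF3 writer for gene rows.
write_gff_fixture <- function(path, genes) {
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(genes)), function(i)
               sprintf("%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       genes$chrom[i], genes$start[i], genes$stop[i],
                       genes$gene_id[i]), ""))
  writeLines(lines, path)
  path
}
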