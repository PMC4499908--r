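#' Define a simulation scenario
#'
#' Captures the statistical structure the variance-partitioning method
#' assumes: biallelic dosages in LD blocks over several chromosomes, gene
#' intervals covering a set fraction of markers, pathways of heterogeneous
#' size scattered across chromosomes, and phenotypes built from marker
#' effects plus heteroskedastic residuals with DRP-style reliability
#' weights. Defaults emulate a proven-bull dairy panel at desk scale:
#' 500 individuals, 5000 markers on 5 chromosomes (LD blocks of 10 markers,
#' latent correlation 0.5), ~300 genes covering 40 percent of markers,
#' 20 pathways, total heritability 0.3, reliabilities around 0.9.
#'
#' @param n_individuals,n_markers,n_chromosomes panel dimensions.
#' @param ld_block_size markers per LD block.
#' @param rho_ld within-block latent correlation in `[0, 1)`.
#' @param freq_range alternate-allele frequency bounds.
#' @param n_genes,gene_coverage gene count and fraction of markers inside
#'   genes.
#' @param n_pathways,pathway_size_range pathway count and gene-count bounds
#'   (sizes drawn log-uniformly).
#' @param trait_model `"infinitesimal_null"` (every marker the same
#'   expected contribution), `"pathway_enriched"` (a designated set carries
#'   `rho_set` of the genetic variance) or `"focal_locus"` (one large-effect
#'   marker in a focal gene on top of an infinitesimal background).
#' @param h2_total total heritability in `(0, 1)`.
#' @param rho_set genetic-variance share of the enriched set.
#' @param focal_share genetic-variance share of the focal marker.
#' @param reliability_beta Beta(a, b) parameters for simulated
#'   reliabilities, or NULL for unit-weight phenotypes (EBV-like).
#' @param reliability_range floor/ceiling keeping DRP weights finite.
#' @param mu trait mean.
#' @param seed master seed; all generators are pure functions of
#'   (scenario, seed).
#' @return A `sim_scenario` list.
#' @export
simulation_scenario <- function(n_individuals = 500, n_markers = 5000,
                                n_chromosomes = 5, ld_block_size = 10,
                                rho_ld = 0.5, freq_range = c(0.05, 0.95),
                                n_genes = 300, gene_coverage = 0.4,
                                n_pathways = 20,
                                pathway_size_range = c(3, 60),
                                trait_model = c("infinitesimal_null",
                                                "pathway_enriched",
                                                "focal_locus"),
                                h2_total = 0.3, rho_set = 0.5,
                                focal_share = 0.3,
                                reliability_beta = c(9, 1),
                                reliability_range = c(0.05, 0.99),
                                mu = 0, seed = 1) {
  trait_model <- match.arg(trait_model)
  stopifnot(n_individuals > 0, n_markers > 0, n_chromosomes > 0,
            ld_block_size > 0, rho_ld >= 0, rho_ld < 1,
            h2_total > 0, h2_total < 1, rho_set >= 0, rho_set <= 1,
            focal_share >= 0, focal_share < 1,
            gene_coverage > 0, gene_coverage < 1, n_genes > 0,
            n_pathways > 0)
  structure(list(n_individuals = n_individuals, n_markers = n_markers,
                 n_chromosomes = n_chromosomes,
                 ld_block_size = ld_block_size, rho_ld = rho_ld,
                 freq_range = freq_range, n_genes = n_genes,
                 gene_coverage = gene_coverage, n_pathways = n_pathways,
                 pathway_size_range = pathway_size_range,
                 trait_model = trait_model, h2_total = h2_total,
                 rho_set = rho_set, focal_share = focal_share,
                 reliability_beta = reliability_beta,
                 reliability_range = reliability_range, mu = mu,
                 seed = seed),
            class = "sim_scenario")
}

# Markers per chromosome, as even as possible.
chrom_sizes <- function(m, n_chr) {
  base <- m %/% n_chr
  sz <- rep(base, n_chr)
  extra <- m - base * n_chr
  if (extra > 0) sz[seq_len(extra)] <- sz[seq_len(extra)] + 1L
  sz
}

#' Simulate genotypes with block LD
#'
#' Allele frequencies are drawn uniformly within the configured bounds;
#' each of the two haplotypes per individual comes from a block-equicorrelated
#' latent Gaussian (correlation `rho_ld` within a block, independence across
#' blocks) thresholded at the allele-frequency quantile, so genotypes are in
#' Hardy-Weinberg proportions marginally and correlated within blocks.
#' Markers are spaced 1 kb apart. A marker that comes out monomorphic in a
#' small sample is nudged by one heterozygous call so downstream scaling is
#' defined.
#'
#' @param scn a [simulation_scenario()].
#' @param seed RNG seed; defaults to the scenario master seed.
#' @return A [new_genotypes()] object.
#' @export
simulate_genotypes <- function(scn, seed = scn$seed) {
  stopifnot(inherits(scn, "sim_scenario"))
  set.seed(seed)
  n <- scn$n_individuals
  m <- scn$n_markers
  p <- runif(m, scn$freq_range[1], scn$freq_range[2])
  sizes <- chrom_sizes(m, scn$n_chromosomes)
  chrom <- rep(paste0("chr", seq_len(scn$n_chromosomes)), sizes)
  pos <- unlist(lapply(sizes, function(s) seq_len(s) * 1000L))
  dos <- matrix(0L, n, m)
  col0 <- 0L
  rho <- scn$rho_ld
  for (c_i in seq_len(scn$n_chromosomes)) {
    mc <- sizes[c_i]
    starts <- seq(1L, mc, by = scn$ld_block_size)
    for (b in starts) {
      k <- min(scn$ld_block_size, mc - b + 1L)
      cols <- col0 + b - 1L + seq_len(k)
      thr <- matrix(qnorm(p[cols]), n, k, byrow = TRUE)
      hap <- function() {
        z0 <- rnorm(n)
        lat <- sqrt(rho) * z0 + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
        (lat < thr) + 0L
      }
      dos[, cols] <- hap() + hap()
    }
    col0 <- col0 + mc
  }
  # guard against monomorphic columns in small samples
  mono <- which(colSums(dos) %in% c(0L, 2L * n))
  for (j in mono) dos[sample.int(n, 1L), j] <- 1L
  dimnames(dos) <- list(sprintf("ind%04d", seq_len(n)),
                        sprintf("M%05d", seq_len(m)))
  new_genotypes(dos, tibble(marker_id = colnames(dos), chrom = chrom,
                            pos = pos))
}

#' Simulate gene annotation and pathway map
#'
#' Genes are non-overlapping marker runs placed with random intergenic
#' gaps; their total marker content matches the configured genome coverage
#' up to Poisson noise in the drawn gene lengths. Pathway sizes are drawn
#' log-uniformly within the configured bounds and genes are sampled from
#' the whole genome, so pathways are scattered; any pathway of four or more
#' genes is guaranteed to span at least two chromosomes (when there are
#' two). One gene near the middle of chromosome 1 is designated as the
#' focal (large-effect) gene.
#'
#' @param scn a [simulation_scenario()].
#' @param geno genotypes from [simulate_genotypes()].
#' @param seed RNG seed; defaults to master seed + 1.
#' @return list with `genes` (tibble: gene_id, chrom, start, stop),
#'   `pathways` (tibble: pathway_id, gene_id), `focal_gene` (id).
#' @export
simulate_annotation <- function(scn, geno, seed = scn$seed + 1) {
  stopifnot(inherits(scn, "sim_scenario"), inherits(geno, "genotypes"))
  set.seed(seed)
  m <- n_markers(geno)
  sizes <- chrom_sizes(m, scn$n_chromosomes)
  chroms <- paste0("chr", seq_len(scn$n_chromosomes))
  mean_len <- scn$gene_coverage * m / scn$n_genes
  if (mean_len < 1) abort("infeasible coverage: genes shorter than 1 marker")
  genes_per_chr <- pmax(1L, round(scn$n_genes * sizes / m))
  rows <- list()
  gid <- 0L
  for (c_i in seq_along(chroms)) {
    gc <- genes_per_chr[c_i]
    mc <- sizes[c_i]
    lens <- 1L + rpois(gc, mean_len - 1)
    while (sum(lens) > mc)   # infeasible draw; shrink the longest gene
      lens[which.max(lens)] <- max(1L, lens[which.max(lens)] - 1L)
    gaps <- as.vector(stats::rmultinom(1, mc - sum(lens), rep(1, gc + 1)))
    at <- 0L
    mk <- geno$markers[geno$markers$chrom == chroms[c_i], ]
    for (j in seq_len(gc)) {
      at <- at + gaps[j]
      first <- at + 1L
      last <- at + lens[j]
      at <- last
      gid <- gid + 1L
      rows[[gid]] <- tibble(gene_id = sprintf("G%04d", gid),
                            chrom = chroms[c_i],
                            start = mk$pos[first], stop = mk$pos[last])
    }
  }
  genes <- dplyr::bind_rows(rows)

  sz_rng <- scn$pathway_size_range
  pw <- lapply(seq_len(scn$n_pathways), function(k) {
    size <- min(nrow(genes),
                round(exp(runif(1, log(sz_rng[1]), log(sz_rng[2])))))
    picked <- sample(genes$gene_id, size)
    if (size >= 4 && scn$n_chromosomes >= 2) {
      chr <- genes$chrom[match(picked, genes$gene_id)]
      if (length(unique(chr)) == 1) {
        other <- genes$gene_id[genes$chrom != chr[1]]
        if (length(other)) picked[1] <- sample(other, 1)
      }
    }
    tibble(pathway_id = sprintf("P%02d", k), gene_id = picked)
  })
  pathways <- dplyr::bind_rows(pw)

  chr1 <- genes[genes$chrom == chroms[1], ]
  mid <- (min(chr1$start) + max(chr1$stop)) / 2
  focal <- chr1$gene_id[which.min(abs((chr1$start + chr1$stop) / 2 - mid))]
  list(genes = genes, pathways = pathways, focal_gene = focal)
}

#' Simulate phenotypes under a trait architecture
#'
#' Genetic values are `W a` on the centered/scaled markers. Under
#' `infinitesimal_null` every marker effect has variance `sigma2_g / m`;
#' under `pathway_enriched` the target set carries `rho_set` of the genetic
#' variance and the rest share the remainder; under `focal_locus` one
#' marker in the focal gene carries `focal_share` of the genetic variance
#' on top of an infinitesimal background. Residuals are Gaussian with
#' per-record variance `sigma2_e / w_i`, the weights coming from simulated
#' Beta reliabilities through [residual_weights()] (unit weights when
#' `reliability_beta` is NULL). On the unit-weight scale
#' `sigma2_g = h2_total` and `sigma2_e = 1 - h2_total`.
#'
#' @param scn a [simulation_scenario()].
#' @param geno genotypes.
#' @param annotation result of [simulate_annotation()] (needed for
#'   `focal_locus`).
#' @param target_set [feature_set()] carrying the enrichment
#'   (required for `pathway_enriched`).
#' @param seed RNG seed; defaults to master seed + 2.
#' @return list with `phenotypes` (tibble: id, trait, value, reliability)
#'   and `truth` (sigma2_g, sigma2_e, effects, genetic values, focal
#'   marker index if any).
#' @export
simulate_phenotypes <- function(scn, geno, annotation = NULL,
                                target_set = NULL, seed = scn$seed + 2) {
  stopifnot(inherits(scn, "sim_scenario"), inherits(geno, "genotypes"))
  set.seed(seed)
  W <- center_scale(geno)$W
  n <- nrow(W); m <- ncol(W)
  sigma2_g <- scn$h2_total
  sigma2_e <- 1 - scn$h2_total
  focal_marker <- NA_integer_
  a <- switch(scn$trait_model,
    infinitesimal_null = rnorm(m, 0, sqrt(sigma2_g / m)),
    pathway_enriched = {
      if (is.null(target_set)) abort("pathway_enriched needs a `target_set`")
      if (target_set$m_set == 0) abort("empty target set")
      av <- numeric(m)
      ms <- target_set$m_set
      av[target_set$markers] <- rnorm(ms, 0, sqrt(scn$rho_set * sigma2_g / ms))
      rest <- setdiff(seq_len(m), target_set$markers)
      av[rest] <- rnorm(length(rest),
                        0, sqrt((1 - scn$rho_set) * sigma2_g / length(rest)))
      av
    },
    focal_locus = {
      if (is.null(annotation)) abort("focal_locus needs `annotation`")
      g <- annotation$genes[annotation$genes$gene_id == annotation$focal_gene, ]
      inside <- which(geno$markers$chrom == g$chrom &
                        geno$markers$pos >= g$start &
                        geno$markers$pos <= g$stop)
      if (length(inside) == 0) abort("focal gene has no markers")
      focal_marker <- inside[ceiling(length(inside) / 2)]
      av <- rnorm(m, 0, sqrt((1 - scn$focal_share) * sigma2_g / m))
      av[focal_marker] <- av[focal_marker] +
        sample(c(-1, 1), 1) * sqrt(scn$focal_share * sigma2_g)
      av
    }
  )
  gval <- drop(W %*% a)
  if (is.null(scn$reliability_beta)) {
    rel <- NULL
    wts <- rep(1, n)
  } else {
    rel <- pmin(pmax(rbeta(n, scn$reliability_beta[1], scn$reliability_beta[2]),
                     scn$reliability_range[1]), scn$reliability_range[2])
    wts <- residual_weights(rel)$weights
  }
  e <- rnorm(n, 0, sqrt(sigma2_e / wts))
  y <- scn$mu + gval + e
  list(
    phenotypes = tibble(id = individual_ids(geno), trait = "sim_trait",
                        value = unname(y),
                        reliability = if (is.null(rel)) NA_real_ else rel),
    truth = list(sigma2_g = sigma2_g, sigma2_e = sigma2_e, effects = a,
                 genetic_values = gval, focal_marker = focal_marker,
                 trait_model = scn$trait_model,
                 h2_set = if (scn$trait_model == "pathway_enriched")
                   scn$rho_set else NA_real_)
  )
}

#' Write a simulated dataset in the standard file formats
#'
#' Emits the dosage TSV, gene TSV, pathway TSV and phenotype TSV consumed
#' by the readers, so the full pipeline can be exercised end-to-end from
#' files.
#'
#' @param geno genotypes.
#' @param annotation [simulate_annotation()] result.
#' @param phenotypes phenotype tibble.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_simulation <- function(geno, annotation, phenotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             genes = file.path(dir, "genes.tsv"),
             pathways = file.path(dir, "pathways.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  write_dosage_tsv(geno, paths[["genotypes"]])
  readr::write_tsv(annotation$genes, paths[["genes"]], progress = FALSE)
  readr::write_tsv(annotation$pathways, paths[["pathways"]], progress = FALSE)
  readr::write_tsv(phenotypes, paths[["phenotypes"]], progress = FALSE)
  invisible(paths)
}
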