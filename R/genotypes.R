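#' Genotype container
#'
#' A `genotypes` object holds an individuals-by-markers allele-dosage matrix
#' (counts of the alternate allele, 0/1/2) together with a marker table
#' carrying chromosome, 1-based position and the observed alternate-allele
#' frequency. Dosages may be non-integer only for markers that were
#' mean-imputed on read.
#'
#' @param dosages numeric matrix, individuals in rows, markers in columns;
#'   rownames are individual ids, colnames marker ids.
#' @param markers tibble with columns `marker_id`, `chrom`, `pos`.
#' @return A `genotypes` object: list with elements `dosages` (matrix) and
#'   `markers` (tibble with `marker_id`, `chrom`, `pos`, `freq`).
#' @export
new_genotypes <- function(dosages, markers) {
  if (!is.matrix(dosages)) abort("`dosages` must be a matrix")
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    abort("`dosages` must carry individual ids (rownames) and marker ids (colnames)")
  if (anyDuplicated(rownames(dosages)))
    abort("duplicate individual ids in genotype data")
  if (anyDuplicated(colnames(dosages)))
    abort("duplicate marker ids in genotype data")
  if (anyNA(dosages))
    abort("missing dosages present; use missing = \"impute\" or clean the input")
  if (any(dosages < 0 | dosages > 2))
    abort("dosages must lie in [0, 2] (alternate-allele counts)")
  storage.mode(dosages) <- "double"
  markers <- as_tibble(markers)[, c("marker_id", "chrom", "pos")]
  if (!identical(markers$marker_id, colnames(dosages)))
    abort("marker table and dosage columns disagree")
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)

  # sort by (chrom, pos); positions must then be strictly increasing
  ord <- order(match(markers$chrom, unique(markers$chrom)), markers$pos)
  markers <- markers[ord, ]
  dosages <- dosages[, ord, drop = FALSE]
  dup <- unlist(tapply(markers$pos, markers$chrom, function(p) duplicated(p)))
  if (any(dup))
    abort("duplicate marker positions within a chromosome")

  markers$freq <- unname(colMeans(dosages) / 2)
  structure(list(dosages = dosages, markers = markers), class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf(
    "<genotypes> %d individuals x %d markers on %d chromosome(s)\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$markers$chrom))
  ))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$dosages)

n_markers <- function(g) ncol(g$dosages)
n_individuals <- function(g) nrow(g$dosages)
individual_ids <- function(g) rownames(g$dosages)

#' Read genotypes into the internal dosage representation
#'
#' Supported dialects: a dosage TSV (first column `id`, one column per marker
#' named `marker_id:chrom:pos`), VCF (plain or bgzipped, biallelic sites,
#' GT field), and PLINK bed/bim/fam (SNP-major bed; dosage counts the bim A1
#' allele). Multiallelic sites are always rejected; missing calls are
#' rejected by default or mean-imputed per marker.
#'
#' @param path file path; for PLINK either the `.bed` file or the prefix.
#' @param format one of `"dosage"`, `"vcf"`, `"plink"`.
#' @param missing policy for missing calls: `"reject"` (default) or `"impute"`
#'   (per-marker mean dosage, with a warning).
#' @return A [new_genotypes()] object.
#' @export
read_genotypes <- function(path, format = c("dosage", "vcf", "plink"),
                           missing = c("reject", "impute")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  switch(format,
    dosage = read_dosage_tsv(path, missing),
    vcf = read_vcf_genotypes(path, missing),
    plink = read_plink_genotypes(path, missing)
  )
}

resolve_missing <- function(dosages, missing) {
  if (!anyNA(dosages)) return(dosages)
  if (missing == "reject")
    abort("missing genotype calls present and missing = \"reject\"")
  warn(sprintf("mean-imputing %d missing genotype call(s)", sum(is.na(dosages))))
  for (j in which(colSums(is.na(dosages)) > 0)) {
    mj <- mean(dosages[, j], na.rm = TRUE)
    if (is.nan(mj)) abort("marker with all calls missing cannot be imputed")
    dosages[is.na(dosages[, j]), j] <- mj
  }
  dosages
}

read_dosage_tsv <- function(path, missing = "reject") {
  dat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(dat)[1] != "id") abort("dosage TSV must have first column `id`")
  ids <- as.character(dat$id)
  mk_cols <- names(dat)[-1]
  parts <- strsplit(mk_cols, ":", fixed = TRUE)
  if (any(lengths(parts) < 3))
    abort("dosage TSV marker columns must be named marker_id:chrom:pos")
  pos <- vapply(parts, function(p) p[[length(p)]], "")
  chrom <- vapply(parts, function(p) p[[length(p) - 1L]], "")
  mid <- vapply(parts, function(p) paste(p[-c(length(p) - 1L, length(p))],
                                         collapse = ":"), "")
  dosages <- as.matrix(dat[, -1, drop = FALSE])
  dimnames(dosages) <- list(ids, mid)
  dosages <- resolve_missing(dosages, missing)
  new_genotypes(dosages,
                tibble(marker_id = mid, chrom = chrom, pos = as.integer(pos)))
}

#' Write genotypes as a dosage TSV
#'
#' Inverse of `read_genotypes(format = "dosage")`: round-trips dosages, ids
#' and marker coordinates exactly.
#'
#' @param g a [new_genotypes()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  hdr <- paste(g$markers$marker_id, g$markers$chrom, g$markers$pos, sep = ":")
  dat <- as.data.frame(g$dosages)
  names(dat) <- hdr
  dat <- cbind(id = rownames(g$dosages), dat)
  readr::write_tsv(as_tibble(dat), path, progress = FALSE)
  invisible(path)
}

read_vcf_genotypes <- function(path, missing = "reject") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("package `vcfR` is required to read VCF")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))   # single-site VCF
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE) | is.na(alt) | alt == ""
  if (any(multi)) abort(sprintf("%d non-biallelic site(s) in VCF", sum(multi)))
  gt <- vcfR::extract.gt(v, element = "GT")
  # count '1' alleles; tolerate phased separators
  count_alt <- function(cell) {
    if (is.na(cell) || cell %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(cell, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  dosages <- t(matrix(vapply(gt, count_alt, 0), nrow = nrow(gt)))
  mid <- fix[, "ID"]
  noid <- is.na(mid) | mid == "."
  mid[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  rn <- colnames(gt)
  dimnames(dosages) <- list(rn, mid)
  dosages <- resolve_missing(dosages, missing)
  new_genotypes(dosages, tibble(marker_id = mid, chrom = fix[, "CHROM"],
                                pos = as.integer(fix[, "POS"])))
}

read_plink_genotypes <- function(path, missing = "reject") {
  prefix <- sub("\\.bed$", "", path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) abort(sprintf("PLINK file not found: %s", f))
  bim_t <- readr::read_table(bim, col_names = c("chrom", "marker_id", "cm",
                                                "pos", "a1", "a2"),
                             col_types = "ccdicc", progress = FALSE)
  fam_t <- readr::read_table(fam, col_names = c("fid", "iid", "pat", "mat",
                                                "sex", "phe"),
                             col_types = "cccccc", progress = FALSE)
  n <- nrow(fam_t); m <- nrow(bim_t)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    abort("not a PLINK .bed file (bad magic)")
  if (raw[3] != as.raw(0x01))
    abort("only SNP-major .bed files are supported")
  bpm <- ceiling(n / 4)
  if (length(raw) != 3 + bpm * m) abort("truncated .bed file")
  body <- raw[-(1:3)]
  # unpack 2-bit codes: 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  codes <- matrix(0L, nrow = 4 * bpm, ncol = m)
  ints <- as.integer(body)
  dim(ints) <- c(bpm, m)
  lut <- matrix(0L, nrow = 256, ncol = 4)
  for (b in 0:255)
    lut[b + 1, ] <- bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L)
  decode <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  dosages <- matrix(NA_real_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    two_bit <- as.vector(t(lut[ints[, j] + 1L, , drop = FALSE]))[seq_len(n)]
    dosages[, j] <- decode[as.character(two_bit)]
  }
  dimnames(dosages) <- list(fam_t$iid, bim_t$marker_id)
  dosages <- resolve_missing(dosages, missing)
  new_genotypes(dosages, tibble(marker_id = bim_t$marker_id,
                                chrom = bim_t$chrom, pos = bim_t$pos))
}

#' Filter markers on minor allele frequency
#'
#' Retains markers whose minor allele frequency strictly exceeds `threshold`
#' (a marker at exactly the threshold is removed); marker order is preserved.
#' Idempotent.
#'
#' @param g a [new_genotypes()] object.
#' @param threshold MAF threshold in `[0, 0.5)`; default 0.01.
#' @return A filtered [new_genotypes()] object.
#' @export
filter_maf <- function(g, threshold = 0.01) {
  stopifnot(inherits(g, "genotypes"))
  if (threshold < 0 || threshold >= 0.5) abort("`threshold` must be in [0, 0.5)")
  maf <- pmin(g$markers$freq, 1 - g$markers$freq)
  keep <- maf > threshold
  if (!any(keep)) abort("no markers pass the MAF filter")
  new_genotypes(g$dosages[, keep, drop = FALSE], g$markers[keep, ])
}

#' Read a phenotype table
#'
#' TSV with columns `id`, `trait`, `value` and optional `reliability`
#' (in `[0, 1)`); one record per (individual, trait). Absent reliabilities
#' imply unit residual weights downstream.
#'
#' @param path TSV path.
#' @return tibble with columns `id`, `trait`, `value`, `reliability`
#'   (NA when not supplied).
#' @export
read_phenotypes <- function(path) {
  dat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "trait", "value")
  if (!all(need %in% names(dat)))
    abort("phenotype TSV needs columns id, trait, value")
  if (!"reliability" %in% names(dat)) dat$reliability <- NA_real_
  dat$id <- as.character(dat$id)
  if (anyDuplicated(dat[, c("id", "trait")]))
    abort("duplicate (individual, trait) phenotype records")
  ok <- is.na(dat$reliability) | (dat$reliability >= 0 & dat$reliability < 1)
  if (!all(ok)) abort("reliabilities must lie in [0, 1)")
  as_tibble(dat[, c("id", "trait", "value", "reliability")])
}
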