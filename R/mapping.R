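#' Associate markers with genes by position
#'
#' A marker belongs to a gene when its position lies inside the gene's
#' closed interval, optionally padded by `flank` bp on both sides, on the
#' same chromosome. Strand is ignored; a marker may belong to several
#' overlapping genes. The default `flank = 0` keeps only markers inside
#' genes.
#'
#' @param g a [new_genotypes()] object.
#' @param genes gene table from [read_gene_annotation()].
#' @param flank symmetric padding in bp, `>= 0`.
#' @return A `marker_gene_index`: list with `gene_markers` (named list of
#'   sorted marker indices per gene), `marker_genes` (list of gene ids per
#'   marker), `flank`, and `genes` (the gene table used).
#' @export
map_markers_to_genes <- function(g, genes, flank = 0) {
  stopifnot(inherits(g, "genotypes"))
  if (flank < 0) abort("`flank` must be >= 0")
  genes <- validate_gene_table(genes)
  off_chrom <- !genes$chrom %in% unique(g$markers$chrom)
  if (any(off_chrom))
    warn(sprintf("%d gene(s) on chromosomes absent from the genotypes",
                 sum(off_chrom)))
  mk <- GenomicRanges::GRanges(
    g$markers$chrom,
    IRanges::IRanges(g$markers$pos, width = 1L)
  )
  gn <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start - as.integer(flank)),
                     genes$stop + as.integer(flank))
  )
  hits <- GenomicRanges::findOverlaps(mk, gn)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  gene_markers <- setNames(vector("list", nrow(genes)), genes$gene_id)
  split_q <- split(qh, sh)
  for (k in names(split_q))
    gene_markers[[as.integer(k)]] <- sort(unique(split_q[[k]]))
  gene_markers[vapply(gene_markers, is.null, TRUE)] <-
    list(integer(0))
  marker_genes <- setNames(vector("list", n_markers(g)), g$markers$marker_id)
  split_s <- split(genes$gene_id[sh], qh)
  for (k in names(split_s))
    marker_genes[[as.integer(k)]] <- unique(split_s[[k]])
  marker_genes[vapply(marker_genes, is.null, TRUE)] <- list(character(0))
  structure(list(gene_markers = gene_markers, marker_genes = marker_genes,
                 flank = flank, genes = genes, n_markers = n_markers(g)),
            class = "marker_gene_index")
}

#' @export
print.marker_gene_index <- function(x, ...) {
  n_in <- sum(lengths(x$marker_genes) > 0)
  cat(sprintf(
    "<marker_gene_index> %d genes, %d/%d markers in genes (flank %d bp)\n",
    length(x$gene_markers), n_in, x$n_markers, x$flank))
  invisible(x)
}

#' Construct a marker feature set
#'
#' @param name set label.
#' @param marker_indices integer marker indices (deduplicated, sorted).
#' @param m total number of markers in the active genotype matrix.
#' @param contains_focal does the set's gene list intersect the focal region?
#' @param genes optional character vector of contributing gene ids.
#' @return A `feature_set` object with fields `name`, `markers`, `m_set`,
#'   `m_total`, `contains_focal`, `genes`.
#' @export
feature_set <- function(name, marker_indices, m, contains_focal = FALSE,
                        genes = character(0)) {
  idx <- sort(unique(as.integer(marker_indices)))
  if (length(idx) < 1) abort(sprintf("feature set `%s` is empty", name))
  if (idx[1] < 1 || idx[length(idx)] > m)
    abort("marker indices outside the genotype matrix")
  structure(list(name = name, markers = idx, m_set = length(idx),
                 m_total = as.integer(m),
                 contains_focal = isTRUE(contains_focal),
                 genes = as.character(genes)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s: %d of %d markers%s\n", x$name, x$m_set,
              x$m_total, if (x$contains_focal) " [focal]" else ""))
  invisible(x)
}

#' Markers of a pathway, once per pathway
#'
#' Union of the marker lists of the pathway's genes, deduplicated so a
#' marker inside several genes of the same pathway counts once. Genes with
#' no mapped markers contribute nothing.
#'
#' @param pathway_id pathway name present in `pmap`.
#' @param pmap pathway map tibble.
#' @param index a `marker_gene_index`.
#' @param focal_genes optional character vector of focal-region gene ids
#'   used to set the `contains_focal` flag.
#' @return A [feature_set()].
#' @export
pathway_marker_set <- function(pathway_id, pmap, index,
                               focal_genes = character(0)) {
  genes <- pathway_genes(pmap, pathway_id)
  gene_set_markers(pathway_id, genes, index, focal_genes)
}

#' Markers of an explicit gene list
#'
#' @param name set label.
#' @param genes character vector of gene ids.
#' @param index a `marker_gene_index`.
#' @param focal_genes focal-region gene ids for the focal flag.
#' @return A [feature_set()].
#' @export
gene_set_markers <- function(name, genes, index, focal_genes = character(0)) {
  known <- intersect(genes, names(index$gene_markers))
  idx <- sort(unique(unlist(index$gene_markers[known], use.names = FALSE)))
  if (length(idx) == 0)
    abort(sprintf("gene group `%s` has zero mapped markers", name))
  feature_set(name, idx, index$n_markers,
              contains_focal = length(intersect(genes, focal_genes)) > 0,
              genes = genes)
}

#' Genes around a focal large-effect locus
#'
#' Returns every gene whose interval overlaps the focal gene's interval
#' padded by `window` bp on each side, on the focal chromosome; the focal
#' gene itself is always included. Emulates defining a known causative
#' gene's neighbourhood (e.g. the 500-kbp window around DGAT1).
#'
#' @param focal_gene_id id of the focal gene, present in `genes`.
#' @param genes gene table.
#' @param window padding in bp, default 500000.
#' @return character vector of gene ids.
#' @export
focal_region_genes <- function(focal_gene_id, genes, window = 5e5) {
  genes <- validate_gene_table(genes)
  k <- match(focal_gene_id, genes$gene_id)
  if (is.na(k)) abort(sprintf("unknown focal gene `%s`", focal_gene_id))
  lo <- genes$start[k] - window
  hi <- genes$stop[k] + window
  hit <- genes$chrom == genes$chrom[k] & genes$start <= hi & genes$stop >= lo
  genes$gene_id[hit]
}

#' Complement of a feature set
#'
#' All markers of the active genotype matrix not in the set; together they
#' partition the markers, `m_set + m_complement = m`.
#'
#' @param s a [feature_set()].
#' @param m total marker count (defaults to the set's recorded total).
#' @return A [feature_set()] named `!<name>`.
#' @export
complement_set <- function(s, m = s$m_total) {
  stopifnot(inherits(s, "feature_set"))
  if (s$m_set >= m)
    abort("feature set covers all markers; complement is empty")
  feature_set(paste0("!", s$name), setdiff(seq_len(m), s$markers), m,
              contains_focal = FALSE)
}

#' Write/read feature sets as TSV (one marker per row)
#'
#' Layout: columns `name`, `contains_focal`, `marker_index`; reproducible
#' serialization of sampled gene groups.
#'
#' @param sets list of [feature_set()] objects.
#' @param path TSV path.
#' @return `path` invisibly (write); list of feature sets (read).
#' @export
write_feature_sets <- function(sets, path) {
  rows <- dplyr::bind_rows(lapply(sets, function(s)
    tibble(name = s$name, contains_focal = s$contains_focal,
           m_total = s$m_total, marker_index = s$markers)))
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_sets
#' @export
read_feature_sets <- function(path) {
  dat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  lapply(split(dat, factor(dat$name, levels = unique(dat$name))), function(d)
    feature_set(d$name[1], d$marker_index, d$m_total[1],
                contains_focal = d$contains_focal[1]))
}
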