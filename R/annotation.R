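#' Read a gene annotation table
#'
#' Accepts GFF3 (rows of type `gene`; the gene id is taken from the `ID`,
#' `gene_id` or `Name` attribute, in that order) or a four-column TSV with
#' header `gene_id`, `chrom`, `start`, `stop`. Intervals are 1-based and
#' fully closed, the GFF3 convention.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gff3"`.
#' @return tibble with columns `gene_id`, `chrom`, `start`, `stop`.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  tab <- switch(format,
    tsv = {
      dat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
      need <- c("gene_id", "chrom", "start", "stop")
      if (!all(need %in% names(dat)))
        abort("gene TSV needs columns gene_id, chrom, start, stop")
      dat[, need]
    },
    gff3 = {
      if (!requireNamespace("rtracklayer", quietly = TRUE))
        abort("package `rtracklayer` is required to read GFF3")
      gff <- rtracklayer::readGFF(path)
      gff <- gff[gff$type == "gene", , drop = FALSE]
      if (nrow(gff) == 0) abort("no `gene` rows in GFF3")
      pick <- function(row, cols) {
        for (cl in cols) {
          v <- row[[cl]]
          if (!is.null(v) && length(v) && !is.na(v[1]) && nzchar(v[1]))
            return(as.character(v[1]))
        }
        NA_character_
      }
      ids <- vapply(seq_len(nrow(gff)), function(i)
        pick(gff[i, , drop = FALSE],
             intersect(c("ID", "gene_id", "Name"), names(gff))), "")
      tibble(gene_id = ids, chrom = as.character(gff$seqid),
             start = as.integer(gff$start), stop = as.integer(gff$end))
    }
  )
  validate_gene_table(tab)
}

validate_gene_table <- function(tab) {
  tab <- as_tibble(tab)
  tab$gene_id <- as.character(tab$gene_id)
  tab$chrom <- as.character(tab$chrom)
  tab$start <- as.integer(tab$start)
  tab$stop <- as.integer(tab$stop)
  if (anyNA(tab$gene_id) || any(!nzchar(tab$gene_id)))
    abort("gene annotation has a missing gene id")
  if (anyDuplicated(tab$gene_id)) abort("duplicate gene ids in annotation")
  bad <- tab$start > tab$stop
  if (any(bad))
    abort(sprintf("gene %s has start > stop", tab$gene_id[which(bad)[1]]))
  tab
}

#' Read a pathway-to-gene map
#'
#' Accepts GMT (one pathway per line: name, description, then gene ids) or a
#' two-column TSV with header `pathway_id`, `gene_id`. Duplicate
#' (pathway, gene) pairs are collapsed; genes missing from a gene table are
#' permitted here and resolved at mapping time.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gmt"`.
#' @return tibble with columns `pathway_id`, `gene_id`, one row per pair.
#' @export
read_pathway_map <- function(path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  pairs <- switch(format,
    tsv = {
      dat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
      if (!all(c("pathway_id", "gene_id") %in% names(dat)))
        abort("pathway TSV needs columns pathway_id, gene_id")
      tibble(pathway_id = as.character(dat$pathway_id),
             gene_id = as.character(dat$gene_id))
    },
    gmt = {
      lines <- readr::read_lines(path, progress = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      rows <- lapply(lines, function(l) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1]]
        f <- f[nzchar(f)]
        if (length(f) < 3)
          abort(sprintf("GMT line for `%s` lists no genes", f[1]))
        tibble(pathway_id = f[1], gene_id = f[-(1:2)])
      })
      dplyr::bind_rows(rows)
    }
  )
  pairs <- dplyr::distinct(pairs)
  if (nrow(pairs) == 0) abort("empty pathway map")
  empty <- setdiff(unique(pairs$pathway_id),
                   unique(pairs$pathway_id[nzchar(pairs$gene_id)]))
  if (length(empty))
    abort(sprintf("pathway %s has zero genes", empty[1]))
  pairs
}

#' Genes of one pathway
#' @param pmap pathway map tibble from [read_pathway_map()].
#' @param pathway_id pathway name.
#' @return character vector of gene ids.
#' @export
pathway_genes <- function(pmap, pathway_id) {
  g <- unique(pmap$gene_id[pmap$pathway_id == pathway_id])
  if (length(g) == 0) abort(sprintf("unknown pathway `%s`", pathway_id))
  g
}
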