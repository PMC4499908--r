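#' Center and scale the marker matrix
#'
#' Each dosage column is transformed to
#' `(x - 2 p) / sqrt(2 p (1 - p))` with `p` the observed alternate-allele
#' frequency, the standard unit-variance GRM scaling. Every column of the
#' result has mean zero; monomorphic markers must be filtered out first.
#'
#' @param g a [new_genotypes()] object with all markers polymorphic.
#' @return A `scaled_markers` object: list with `W` (n x m matrix),
#'   `centers`, `scales`, and the parent `markers` table.
#' @export
center_scale <- function(g) {
  stopifnot(inherits(g, "genotypes"))
  p <- g$markers$freq
  if (any(p <= 0 | p >= 1))
    abort("monomorphic marker present; run filter_maf() first")
  centers <- 2 * p
  scales <- sqrt(2 * p * (1 - p))
  W <- sweep(sweep(g$dosages, 2, centers, "-"), 2, scales, "/")
  structure(list(W = W, centers = centers, scales = scales,
                 markers = g$markers), class = "scaled_markers")
}

#' @export
print.scaled_markers <- function(x, ...) {
  cat(sprintf("<scaled_markers> %d x %d, columns centered/scaled\n",
              nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' Genomic relationship matrix for a marker subset
#'
#' `G = W_S W_S' / m_S` over the columns in the feature set (all markers
#' when `s` is NULL). G is symmetric, has zero row sums (centered columns)
#' and is positive semidefinite.
#'
#' @param w a [center_scale()] result.
#' @param s a [feature_set()] or NULL for all markers.
#' @return A `grm` object: list with `G` (n x n), `m_used`, `name`.
#' @export
build_grm <- function(w, s = NULL) {
  stopifnot(inherits(w, "scaled_markers"))
  if (is.null(s)) {
    idx <- seq_len(ncol(w$W)); name <- "all"
  } else {
    stopifnot(inherits(s, "feature_set"))
    if (s$m_total != ncol(w$W))
      abort("feature set was built for a different marker universe")
    idx <- s$markers; name <- s$name
  }
  if (length(idx) == 0) abort("empty marker subset")
  Ws <- w$W[, idx, drop = FALSE]
  G <- tcrossprod(Ws) / length(idx)
  structure(list(G = G, m_used = length(idx), name = name), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %s: %d x %d from %d markers\n", x$name,
              nrow(x$G), ncol(x$G), x$m_used))
  invisible(x)
}

#' Deviation from the nested-partition identity
#'
#' For a true partition of the scaled markers into a set and its
#' complement, the all-marker GRM decomposes exactly as
#' `G = (m_S G_S + (m - m_S) G_notS) / m`. Returns the maximum absolute
#' deviation from this identity; machine-level values (<= 1e-8) certify
#' that the partitioned and simple models are exactly nested.
#'
#' @param G,G_S,G_notS `grm` objects built from the same scaled markers.
#' @return max absolute elementwise deviation.
#' @export
verify_partition_identity <- function(G, G_S, G_notS) {
  if (!all(dim(G$G) == dim(G_S$G)) || !all(dim(G$G) == dim(G_notS$G)))
    abort("GRM dimension mismatch")
  m <- G$m_used; m_S <- G_S$m_used; m_n <- G_notS$m_used
  if (m_S + m_n != m) abort("marker counts do not form a partition")
  max(abs(G$G - (m_S * G_S$G + m_n * G_notS$G) / m))
}

#' Export/import a GRM as lower-triangle TSV
#'
#' Columns `id1`, `id2`, `value` (row >= column entries only), 12
#' significant digits; `m_used` and the subset name ride in a header
#' comment line.
#'
#' @param grm a `grm` object with dimnames on `G`.
#' @param path TSV path.
#' @return `path` invisibly (write); a `grm` (read).
#' @export
write_grm_tsv <- function(grm, path) {
  ids <- rownames(grm$G)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(grm$G)))
  lt <- which(lower.tri(grm$G, diag = TRUE), arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grm name=%s m_used=%d n=%d", grm$name, grm$m_used,
                     nrow(grm$G)), con)
  writeLines("id1\tid2\tvalue", con)
  writeLines(sprintf("%s\t%s\t%.12g", ids[lt[, 1]], ids[lt[, 2]],
                     grm$G[lt]), con)
  invisible(path)
}

#' @rdname write_grm_tsv
#' @export
read_grm_tsv <- function(path) {
  hdr <- readr::read_lines(path, n_max = 1, progress = FALSE)
  meta <- regmatches(hdr, regexec("name=(\\S+) m_used=(\\d+) n=(\\d+)", hdr))[[1]]
  if (length(meta) != 4) abort("missing GRM header line")
  n <- as.integer(meta[4])
  dat <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  ids <- unique(c(dat$id1, dat$id2))
  if (length(ids) != n) abort("GRM TSV id count disagrees with header")
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(dat$id1, ids); j <- match(dat$id2, ids)
  G[cbind(i, j)] <- dat$value
  G[cbind(j, i)] <- dat$value
  structure(list(G = G, m_used = as.integer(meta[3]), name = meta[2]),
            class = "grm")
}
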