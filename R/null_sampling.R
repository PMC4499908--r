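#' Sample one random gene group
#'
#' Competitive-null sampling: a target marker count is drawn uniformly from
#' `1..max_target`, then genes (restricted to genes with at least one mapped
#' marker) are drawn uniformly without replacement until the union of their
#' unique markers first reaches the target. Uses the current R RNG stream;
#' seed upstream for reproducibility.
#'
#' @param index a `marker_gene_index`.
#' @param max_target upper bound of the uniform target distribution.
#' @param focal_genes focal-region gene ids for the focal flag.
#' @param name set label; default `"random_group"`.
#' @return A [feature_set()]; attribute `target` records the drawn target
#'   and attribute `exhausted` is TRUE when the gene universe ran out
#'   before the target was reached (with a warning).
#' @export
sample_random_gene_group <- function(index, max_target = 50000,
                                     focal_genes = character(0),
                                     name = "random_group") {
  if (max_target < 1) abort("`max_target` must be >= 1")
  sizes <- lengths(index$gene_markers)
  pool <- names(index$gene_markers)[sizes > 0]
  if (length(pool) == 0) abort("no genes with mapped markers")
  target <- sample.int(max_target, 1L)
  perm <- sample(pool)
  seen <- logical(index$n_markers)
  count <- 0L
  k <- 0L
  exhausted <- TRUE
  for (gid in perm) {
    k <- k + 1L
    mk <- index$gene_markers[[gid]]
    new <- mk[!seen[mk]]
    seen[new] <- TRUE
    count <- count + length(new)
    if (count >= target) { exhausted <- FALSE; break }
  }
  if (exhausted)
    warn(sprintf("gene universe exhausted at %d markers (target %d)",
                 count, target))
  genes <- perm[seq_len(k)]
  s <- feature_set(name, which(seen), index$n_markers,
                   contains_focal = length(intersect(genes, focal_genes)) > 0,
                   genes = genes)
  attr(s, "target") <- target
  attr(s, "exhausted") <- exhausted
  s
}

#' Build the empirical null by repeated random gene groups
#'
#' For each of `n_groups` random gene groups: build the set GRM (the
#' complement GRM follows from the exact partition identity with the
#' all-marker GRM), fit the partitioned model starting from the shared
#' simple-model fit, and record group size, explained-variance fraction,
#' likelihood ratio, focal flag and QC status. The simple model is fitted
#' once and reused. Per-group child seeds are derived deterministically
#' from `seed`, so the batch is reproducible bit-for-bit and
#' parallelizable in any order.
#'
#' @param y phenotype vector aligned with the genotype rows.
#' @param w a [center_scale()] result.
#' @param index a `marker_gene_index` on the same markers.
#' @param n_groups number of random groups (>= 50 for curve fitting).
#' @param max_target target-size upper bound, see
#'   [sample_random_gene_group()].
#' @param weights [residual_weights()] or NULL.
#' @param seed master seed (mandatory).
#' @param focal_genes focal-region gene ids; sets per-group focal flags.
#' @param G_all optional precomputed all-marker [build_grm()].
#' @param simple_fit optional precomputed [fit_simple()] result.
#' @return A `null_table`: tibble with one row per group (`group`, `m_set`,
#'   `h2_set`, `lr`, `contains_focal`, `converged`, `qc`, `excluded`,
#'   `error`), with attributes `m_total`, `seed`, `simple_fit`.
#' @export
build_null_distribution <- function(y, w, index, n_groups, max_target,
                                    weights = NULL, seed,
                                    focal_genes = character(0),
                                    G_all = NULL, simple_fit = NULL) {
  stopifnot(inherits(w, "scaled_markers"))
  if (missing(seed)) abort("`seed` is mandatory for null sampling")
  if (n_groups < 1) abort("`n_groups` must be >= 1")
  m <- ncol(w$W)
  if (is.null(G_all)) G_all <- build_grm(w)
  if (is.null(simple_fit)) simple_fit <- fit_simple(y, G_all, weights)
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, n_groups)
  rows <- vector("list", n_groups)
  for (i in seq_len(n_groups)) {
    set.seed(child[i])
    rows[[i]] <- tryCatch({
      s <- withCallingHandlers(
        sample_random_gene_group(index, max_target, focal_genes,
                                 name = sprintf("rg%04d", i)),
        warning = function(wn) invokeRestart("muffleWarning"))
      fit_null_sample(y, w, s, G_all, simple_fit, weights)
    }, error = function(e)
      tibble(group = sprintf("rg%04d", i), m_set = NA_integer_,
             h2_set = NA_real_, lr = NA_real_, contains_focal = NA,
             converged = NA, qc = "", excluded = TRUE,
             error = conditionMessage(e)))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "m_total") <- m
  attr(out, "seed") <- seed
  attr(out, "simple_fit") <- simple_fit
  class(out) <- c("null_table", class(out))
  out
}

# One partitioned fit for a sampled or user-supplied set, returned as a
# null-table row.
fit_null_sample <- function(y, w, s, G_all, simple_fit, weights) {
  m <- ncol(w$W)
  G_S <- build_grm(w, s)
  G_n <- complement_grm(G_all, G_S)
  fit <- fit_partitioned(y, G_S, G_n, weights, null_fit = simple_fit,
                         contains_focal = s$contains_focal)
  lr <- likelihood_ratio(fit, simple_fit)
  fit <- qc_fit(fit, lr = lr)
  tibble(group = s$name, m_set = s$m_set,
         h2_set = h2_set(fit), lr = lr$lr,
         contains_focal = s$contains_focal,
         converged = fit$converged,
         qc = paste(fit$qc_flags, collapse = ";"),
         excluded = length(fit$qc_flags) > 0 || !fit$converged,
         error = NA_character_)
}

# Complement GRM via the exact partition identity,
# G_notS = (m G - m_S G_S) / m_notS.
complement_grm <- function(G_all, G_S) {
  m <- G_all$m_used; m_S <- G_S$m_used
  if (m_S >= m) abort("set covers all markers; complement GRM undefined")
  structure(list(G = (m * G_all$G - m_S * G_S$G) / (m - m_S),
                 m_used = m - m_S, name = paste0("!", G_S$name)),
            class = "grm")
}

#' Write/read a null table as TSV
#' @param tbl a `null_table`.
#' @param path TSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_null_table <- function(tbl, path) {
  readr::write_tsv(as_tibble(tbl), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_null_table
#' @export
read_null_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
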