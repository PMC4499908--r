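#' Subset genotypes to a set of individuals
#' @param g a [new_genotypes()] object.
#' @param ids individual ids to keep (order respected).
#' @return a [new_genotypes()] object (allele frequencies recomputed).
#' @export
subset_individuals <- function(g, ids) {
  stopifnot(inherits(g, "genotypes"))
  k <- match(ids, individual_ids(g))
  if (anyNA(k)) abort("unknown individual id in subset")
  new_genotypes(g$dosages[k, , drop = FALSE], g$markers)
}

prepare_scan_inputs <- function(geno, genes, phenotypes, trait,
                                maf = 0.01, flank = 0,
                                focal_gene = NULL, focal_window = 5e5) {
  geno <- filter_maf(geno, maf)
  ids <- intersect(individual_ids(geno),
                   phenotypes$id[phenotypes$trait == trait])
  if (length(ids) < 3) abort("fewer than 3 individuals with genotype and trait")
  if (length(ids) < n_individuals(geno)) geno <- subset_individuals(geno, ids)
  ph <- align_phenotypes(phenotypes, trait, ids)
  w <- center_scale(geno)
  index <- map_markers_to_genes(geno, genes, flank = flank)
  focal_genes <- if (!is.null(focal_gene))
    focal_region_genes(focal_gene, genes, focal_window) else character(0)
  weights <- residual_weights(ph$reliability, n = length(ids))
  list(geno = geno, w = w, index = index, focal_genes = focal_genes,
       y = ph$y, weights = weights, ids = ids)
}

fit_null_curves <- function(null_tbl, focal_genes, stratify_focal = TRUE,
                            lambda = "cv") {
  strata <- "all"
  if (length(focal_genes) > 0 && stratify_focal) {
    n_foc <- sum(null_tbl$contains_focal & !null_tbl$excluded, na.rm = TRUE)
    n_non <- sum(!null_tbl$contains_focal & !null_tbl$excluded, na.rm = TRUE)
    if (n_foc >= 50 && n_non >= 50) strata <- c("focal", "non_focal")
  }
  curves <- list()
  for (st in strata) for (stat in c("lr", "h2_set"))
    curves[[paste(stat, st, sep = ".")]] <-
      fit_threshold_curve(null_tbl, statistic = stat, tau = 0.95,
                          stratum = st, lambda = lambda)
  curves
}

#' Run the full pathway scan
#'
#' End-to-end pipeline: MAF filter, marker-to-gene mapping, all-marker GRM
#' and simple-model fit (done once per trait), per-pathway partitioned
#' fits, random-gene-group empirical null, monotone 95th-percentile
#' threshold curves (stratified by focal content when a focal gene is
#' configured), chi-square reference selection and Benjamini-Hochberg FDR.
#' Every random draw derives from `seed`; re-running with the same inputs
#' reproduces the results exactly.
#'
#' @param geno [new_genotypes()] object.
#' @param genes gene table ([read_gene_annotation()]).
#' @param pathways pathway map ([read_pathway_map()]).
#' @param phenotypes phenotype tibble ([read_phenotypes()]).
#' @param trait trait name.
#' @param maf MAF threshold (strict), default 0.01.
#' @param flank marker-to-gene padding in bp, default 0.
#' @param focal_gene optional focal large-effect gene id.
#' @param focal_window bp window defining the focal gene neighbourhood.
#' @param n_null_groups random gene groups for the empirical null.
#' @param max_target upper bound of the uniform group-size target; default
#'   20 percent of the mapped (in-gene) markers.
#' @param fdr_level FDR level for significance calls, default 0.10.
#' @param df chi-square reference policy: `"auto"` selects by
#'   Kolmogorov-Smirnov distance on the null LRs (needs >= 100 clean
#'   groups; falls back to 1 df with a warning below that), or a fixed
#'   `"chi2_df1"`, `"chi2_df2"`, `"mixture"`.
#' @param lambda threshold-curve smoothing, see [fit_threshold_curve()].
#' @param stratify_focal stratify threshold curves by focal content when a
#'   focal gene is set (requires >= 50 null groups per stratum).
#' @param seed master seed (mandatory).
#' @return A `pathway_scan` list: `results` (tibble, one row per pathway:
#'   `pathway`, `trait`, `m_set`, `h2_set`, `lr`, `passes_lr95`,
#'   `passes_h95`, `p_value`, `q_value`, `significant`, `qc`), `null`
#'   (null table), `curves`, `df_selection`, `simple_fit`, `config`.
#' @export
run_pathway_scan <- function(geno, genes, pathways, phenotypes, trait,
                             maf = 0.01, flank = 0, focal_gene = NULL,
                             focal_window = 5e5, n_null_groups = 200,
                             max_target = NULL, fdr_level = 0.10,
                             df = c("auto", "chi2_df1", "chi2_df2",
                                    "mixture"),
                             lambda = "cv", stratify_focal = TRUE, seed) {
  df <- match.arg(df)
  if (missing(seed)) abort("`seed` is mandatory")
  inp <- prepare_scan_inputs(geno, genes, phenotypes, trait, maf, flank,
                             focal_gene, focal_window)
  G_all <- build_grm(inp$w)
  simple <- fit_simple(inp$y, G_all, inp$weights)
  simple <- qc_fit(simple)
  if (!simple$converged) warn("simple-model fit did not converge")

  ids_pw <- unique(pathways$pathway_id)
  pw_rows <- lapply(ids_pw, function(pid) {
    tryCatch({
      s <- pathway_marker_set(pid, pathways, inp$index, inp$focal_genes)
      row <- fit_null_sample(inp$y, inp$w, s, G_all, simple, inp$weights)
      row$group <- pid
      row
    }, error = function(e)
      tibble(group = pid, m_set = NA_integer_, h2_set = NA_real_,
             lr = NA_real_, contains_focal = NA, converged = NA, qc = "",
             excluded = TRUE, error = conditionMessage(e)))
  })
  pw_tbl <- dplyr::bind_rows(pw_rows)

  mapped <- sum(lengths(inp$index$marker_genes) > 0)
  if (is.null(max_target)) max_target <- max(1L, round(0.2 * mapped))
  null_tbl <- build_null_distribution(
    inp$y, inp$w, inp$index, n_groups = n_null_groups,
    max_target = max_target, weights = inp$weights, seed = seed,
    focal_genes = inp$focal_genes, G_all = G_all, simple_fit = simple)

  n_excl <- sum(null_tbl$excluded)
  if (n_excl > 0)
    message(sprintf("empirical null: %d of %d groups QC-excluded",
                    n_excl, nrow(null_tbl)))
  curves <- fit_null_curves(null_tbl, inp$focal_genes, stratify_focal, lambda)
  pw_tbl <- evaluate_criteria(pw_tbl, curves)
  sel <- resolve_df_selection(df, null_tbl$lr[!null_tbl$excluded])
  pv <- pathway_pvalues(pw_tbl$lr, sel, fdr_level)

  results <- tibble(pathway = pw_tbl$group, trait = trait,
                    m_set = pw_tbl$m_set, h2_set = pw_tbl$h2_set,
                    lr = pw_tbl$lr, passes_lr95 = pw_tbl$passes_lr95,
                    passes_h95 = pw_tbl$passes_h95,
                    p_value = pv$p_value, q_value = pv$q_value,
                    significant = pv$significant &
                      !is.na(pw_tbl$passes_lr95) & pw_tbl$passes_lr95 &
                      pw_tbl$passes_h95,
                    qc = pw_tbl$qc)
  structure(list(results = results, null = null_tbl, curves = curves,
                 df_selection = sel, simple_fit = simple,
                 config = list(trait = trait, maf = maf, flank = flank,
                               focal_gene = focal_gene,
                               focal_window = focal_window,
                               n_null_groups = n_null_groups,
                               max_target = max_target,
                               fdr_level = fdr_level, seed = seed,
                               n = length(inp$y),
                               m = n_markers(inp$geno))),
            class = "pathway_scan")
}

#' @export
print.pathway_scan <- function(x, ...) {
  cat(sprintf("<pathway_scan> trait %s: %d pathways, %d null groups (seed %d)\n",
              x$config$trait, nrow(x$results), nrow(x$null), x$config$seed))
  cat(sprintf("  chi-square reference: %s; %d significant at FDR %.0f%%\n",
              x$df_selection$selected, sum(x$results$significant, na.rm = TRUE),
              100 * x$config$fdr_level))
  invisible(x)
}

#' Run the empirical-null calibration only
#'
#' Builds the random-gene-group null table, the 50th/95th-percentile
#' monotone threshold curves for LR and H2_set (per focal stratum when
#' configured), and the chi-square reference selection, without scoring
#' any pathway.
#'
#' @inheritParams run_pathway_scan
#' @return list with `null` (null table), `curves`, `df_selection`,
#'   `simple_fit`, `config`.
#' @export
run_null_calibration <- function(geno, genes, phenotypes, trait,
                                 maf = 0.01, flank = 0, focal_gene = NULL,
                                 focal_window = 5e5, n_null_groups = 200,
                                 max_target = NULL, lambda = "cv",
                                 stratify_focal = TRUE, seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (n_null_groups < 100) abort("calibration needs n_null_groups >= 100")
  inp <- prepare_scan_inputs(geno, genes, phenotypes, trait, maf, flank,
                             focal_gene, focal_window)
  G_all <- build_grm(inp$w)
  simple <- fit_simple(inp$y, G_all, inp$weights)
  mapped <- sum(lengths(inp$index$marker_genes) > 0)
  if (is.null(max_target)) max_target <- max(1L, round(0.2 * mapped))
  null_tbl <- build_null_distribution(
    inp$y, inp$w, inp$index, n_groups = n_null_groups,
    max_target = max_target, weights = inp$weights, seed = seed,
    focal_genes = inp$focal_genes, G_all = G_all, simple_fit = simple)
  curves <- c(
    fit_null_curves(null_tbl, inp$focal_genes, stratify_focal, lambda),
    list(lr50.all = fit_threshold_curve(null_tbl, "lr", tau = 0.5,
                                        lambda = lambda),
         h250.all = fit_threshold_curve(null_tbl, "h2_set", tau = 0.5,
                                        lambda = lambda)))
  sel <- select_chi2_df(null_tbl$lr[!null_tbl$excluded])
  list(null = null_tbl, curves = curves, df_selection = sel,
       simple_fit = simple,
       config = list(trait = trait, maf = maf, flank = flank,
                     focal_gene = focal_gene, n_null_groups = n_null_groups,
                     max_target = max_target, seed = seed,
                     n = length(inp$y), m = n_markers(inp$geno)))
}

resolve_df_selection <- function(df, lr) {
  if (df == "auto") {
    if (sum(!is.na(lr)) >= 100) return(select_chi2_df(lr))
    warn("fewer than 100 clean null groups; using the 1-df reference")
    df <- "chi2_df1"
  }
  structure(list(selected = df, ks = NULL, n = sum(!is.na(lr)),
                 mixture_weight = 0.5), class = "df_selection")
}

#' Write scan results as TSV
#' @param scan a `pathway_scan`.
#' @param path TSV path.
#' @return `path` invisibly.
#' @export
write_scan_results <- function(scan, path) {
  readr::write_tsv(scan$results, path, progress = FALSE)
  invisible(path)
}
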