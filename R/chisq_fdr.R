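#' Choose the chi-square reference for the LR statistics
#'
#' Compares the empirical distribution of (zero-truncated) likelihood
#' ratios from the random gene groups against chi-square with 1 df, 2 df,
#' and a mixture of the two (default weights 50:50) by the
#' Kolmogorov-Smirnov statistic; the smallest statistic wins, ties broken
#' toward the lower-df candidate.
#'
#' @param lr numeric LR values (negatives truncated to 0; at least 100
#'   non-degenerate values required).
#' @param mixture_weight weight on the 1-df component of the mixture.
#' @return A `df_selection`: list with `selected` (one of `"chi2_df1"`,
#'   `"chi2_df2"`, `"mixture"`), `ks` (named statistic vector), `n`,
#'   `mixture_weight`.
#' @export
select_chi2_df <- function(lr, mixture_weight = 0.5) {
  lr <- lr[!is.na(lr)]
  lr <- pmax(lr, 0)
  if (length(lr) < 100) abort("need >= 100 LR values to pick a reference")
  if (all(lr == 0)) abort("all LR values are zero; reference undefined")
  cdfs <- list(
    chi2_df1 = function(x) pchisq(x, df = 1),
    chi2_df2 = function(x) pchisq(x, df = 2),
    mixture = function(x) mixture_weight * pchisq(x, df = 1) +
      (1 - mixture_weight) * pchisq(x, df = 2)
  )
  ks <- vapply(cdfs, ks_statistic, 0, x = lr)
  best <- ks <= min(ks) + 1e-12
  selected <- names(cdfs)[which(best)[1]]
  structure(list(selected = selected, ks = ks, n = length(lr),
                 mixture_weight = mixture_weight), class = "df_selection")
}

# Two-sided Kolmogorov-Smirnov distance between a sample and a CDF,
# robust to ties.
ks_statistic <- function(x, cdf) {
  xs <- sort(x)
  n <- length(xs)
  Fx <- cdf(xs)
  max(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n)
}

#' @export
print.df_selection <- function(x, ...) {
  cat(sprintf("<df_selection> %s (n = %d)\n", x$selected, x$n))
  print(round(x$ks, 4))
  invisible(x)
}

# Upper-tail probability under the selected reference.
chi2_sf <- function(lr, selection) {
  w <- selection$mixture_weight
  switch(selection$selected,
    chi2_df1 = pchisq(lr, 1, lower.tail = FALSE),
    chi2_df2 = pchisq(lr, 2, lower.tail = FALSE),
    mixture = w * pchisq(lr, 1, lower.tail = FALSE) +
      (1 - w) * pchisq(lr, 2, lower.tail = FALSE)
  )
}

#' Chi-square p-values and Benjamini-Hochberg q-values for pathways
#'
#' Upper-tail p-values of the (zero-truncated) LR statistics under the
#' selected chi-square reference, adjusted across pathways by the
#' Benjamini-Hochberg step-up procedure. An LR of exactly zero maps to
#' p = 1.
#'
#' @param lr numeric LR values, one per pathway (NA allowed; propagated).
#' @param selection a [select_chi2_df()] result.
#' @param fdr_level FDR control level for the `significant` call,
#'   default 0.10.
#' @return tibble with columns `lr`, `p_value`, `q_value`, `significant`.
#' @export
pathway_pvalues <- function(lr, selection, fdr_level = 0.10) {
  stopifnot(inherits(selection, "df_selection"))
  lr0 <- pmax(lr, 0)
  p <- chi2_sf(lr0, selection)
  q <- p.adjust(p, method = "BH")
  tibble(lr = lr, p_value = p, q_value = q,
         significant = !is.na(q) & q <= fdr_level)
}
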