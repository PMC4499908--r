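#' Plot a null table
#'
#' Scatter of the chosen null statistic against group size, the
#' infinitesimal expectation `m_S / m` (for `h2_set`), and any supplied
#' threshold curves; points are coloured by focal content when focal
#' groups are present.
#'
#' @param object a `null_table`.
#' @param statistic `"h2_set"` or `"lr"`.
#' @param curves optional list of [fit_threshold_curve()] results to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot null_table
#' @export
autoplot.null_table <- function(object, statistic = c("h2_set", "lr"),
                                curves = NULL, ...) {
  statistic <- match.arg(statistic)
  dat <- as_tibble(object)
  dat <- dat[!dat$excluded & !is.na(dat[[statistic]]), ]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$m_set,
                                         y = .data[[statistic]]))
  if (any(dat$contains_focal, na.rm = TRUE)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$contains_focal),
                                 alpha = 0.5, size = 1) +
      ggplot2::labs(colour = "focal group")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.5, size = 1)
  }
  if (statistic == "h2_set" && !is.null(attr(object, "m_total"))) {
    m <- attr(object, "m_total")
    p <- p + ggplot2::geom_abline(slope = 1 / m, intercept = 0,
                                  linetype = "dashed", colour = "grey40")
  }
  if (!is.null(curves)) {
    for (cv in curves) {
      if (cv$statistic != statistic) next
      g <- seq(min(cv$x), max(cv$x), length.out = 200)
      p <- p + ggplot2::geom_line(
        data = tibble(m_set = g, v = predict(cv, g),
                      stratum = cv$stratum, tau = factor(cv$tau)),
        ggplot2::aes(x = .data$m_set, y = .data$v, linetype = .data$tau),
        inherit.aes = FALSE)
    }
  }
  p + ggplot2::labs(x = "group size (markers)",
                    y = if (statistic == "h2_set")
                      "explained genomic variance fraction" else
                        "likelihood ratio")
}

#' Plot a threshold curve
#' @param object a `threshold_curve`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot threshold_curve
#' @export
autoplot.threshold_curve <- function(object, ...) {
  g <- seq(min(object$x), max(object$x), length.out = 200)
  ggplot2::ggplot(tibble(m_set = g, threshold = predict(object, g)),
                  ggplot2::aes(x = .data$m_set, y = .data$threshold)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "group size (markers)",
                  y = sprintf("%s %d%% threshold", object$statistic,
                              round(100 * object$tau)))
}

#' Plot a pathway scan
#'
#' The null cloud with its 95th-percentile curves plus the pathway points,
#' highlighting those meeting both significance criteria.
#'
#' @param object a `pathway_scan`.
#' @param statistic `"h2_set"` or `"lr"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pathway_scan
#' @export
autoplot.pathway_scan <- function(object, statistic = c("h2_set", "lr"),
                                  ...) {
  statistic <- match.arg(statistic)
  p <- autoplot(object$null, statistic = statistic, curves = object$curves)
  res <- object$results[!is.na(object$results[[statistic]]), ]
  p + ggplot2::geom_point(
    data = res,
    ggplot2::aes(x = .data$m_set, y = .data[[statistic]],
                 shape = .data$significant),
    colour = "red", size = 2, inherit.aes = FALSE) +
    ggplot2::labs(shape = "both criteria + FDR")
}
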