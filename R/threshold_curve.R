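# Lower (type-1) sample quantile: smallest value whose ECDF reaches tau.
quantile_type1 <- function(v, tau) {
  vs <- sort(v)
  vs[max(1L, ceiling(tau * length(vs)))]
}

# Isotonic (non-decreasing) quantile regression by generalized PAVA.
# x must be sorted; ties in x are pre-pooled. Each block's fitted value is
# the type-1 tau-quantile of its pooled responses, which minimizes pinball
# loss under the monotonicity constraint. Returns fitted values at the
# unique x positions.
isotonic_quantile <- function(x, y, tau) {
  ux <- unique(x)
  groups <- split(y, match(x, ux))
  blocks <- vector("list", length(groups))
  nb <- 0L
  for (g in groups) {
    nb <- nb + 1L
    blocks[[nb]] <- list(y = g, level = quantile_type1(g, tau), count = 1L)
    while (nb > 1L && blocks[[nb - 1L]]$level > blocks[[nb]]$level) {
      pooled <- c(blocks[[nb - 1L]]$y, blocks[[nb]]$y)
      blocks[[nb - 1L]] <- list(y = pooled,
                                level = quantile_type1(pooled, tau),
                                count = blocks[[nb - 1L]]$count +
                                  blocks[[nb]]$count)
      blocks[nb] <- list(NULL)
      nb <- nb - 1L
    }
  }
  blocks <- blocks[seq_len(nb)]
  rep(vapply(blocks, `[[`, 0, "level"),
      vapply(blocks, `[[`, 0L, "count"))
}

pinball_loss <- function(y, yhat, tau) {
  r <- y - yhat
  sum(ifelse(r >= 0, tau * r, (tau - 1) * r))
}

# Gaussian-kernel smoothing of knot values followed by a running maximum,
# so the smoothed curve stays non-decreasing. h = 0 returns the input.
smooth_monotone <- function(x, v, h) {
  if (h <= 0) return(v)
  sm <- vapply(x, function(x0) {
    wts <- exp(-0.5 * ((x - x0) / h)^2)
    sum(wts * v) / sum(wts)
  }, 0)
  cummax(sm)
}

#' Fit a monotone quantile threshold curve
#'
#' Estimates the `tau`-quantile of a null statistic (`lr` or `h2_set`) as a
#' non-decreasing function of group size by isotonic quantile regression
#' (exact pinball-loss minimizer under the monotonicity constraint, solved
#' by pooled adjacent violators), optionally followed by kernel smoothing
#' with monotonicity restored. The smoothing bandwidth is chosen by 5-fold
#' cross-validated pinball loss by default (`lambda = "cv"`); `lambda = 0`
#' gives the raw isotonic fit and a numeric `lambda` a fixed bandwidth in
#' group-size units. The curve is piecewise linear between fitted knots and
#' clamped to its end values outside the observed size range.
#'
#' @param samples a `null_table` (or any tibble with columns `m_set`, the
#'   statistic, `contains_focal`, `excluded`).
#' @param statistic `"lr"` or `"h2_set"`.
#' @param tau percentile level, e.g. 0.95 or 0.50.
#' @param stratum `"all"`, `"focal"` or `"non_focal"` (QC-excluded rows are
#'   always dropped).
#' @param lambda `"cv"`, 0, or a positive bandwidth.
#' @param min_samples minimum unflagged samples required (default 50).
#' @return A `threshold_curve`: list with `x` (knot sizes), `y` (threshold
#'   values), `tau`, `statistic`, `stratum`, `lambda`, `n_used`.
#' @export
fit_threshold_curve <- function(samples, statistic = c("lr", "h2_set"),
                                tau = 0.95,
                                stratum = c("all", "focal", "non_focal"),
                                lambda = "cv", min_samples = 50) {
  statistic <- match.arg(statistic)
  stratum <- match.arg(stratum)
  dat <- as_tibble(samples)
  dat <- dat[!dat$excluded & !is.na(dat[[statistic]]), ]
  if (stratum == "focal") dat <- dat[dat$contains_focal, ]
  if (stratum == "non_focal") dat <- dat[!dat$contains_focal, ]
  if (nrow(dat) < min_samples)
    abort(sprintf("only %d unflagged samples in stratum `%s` (need >= %d)",
                  nrow(dat), stratum, min_samples))
  ord <- order(dat$m_set)
  x <- as.numeric(dat$m_set[ord])
  y <- dat[[statistic]][ord]

  fit_at <- function(xi, yi, h) {
    fx <- unique(xi)
    fy <- smooth_monotone(fx, isotonic_quantile(xi, yi, tau), h)
    list(x = fx, y = fy)
  }
  eval_curve <- function(cv, xout) {
    if (length(cv$x) == 1L) return(rep(cv$y, length(xout)))
    approx(cv$x, cv$y, xout = xout, rule = 2)$y
  }

  if (identical(lambda, "cv")) {
    r <- diff(range(x))
    grid <- if (r > 0) c(0, r / 50, r / 20, r / 8, r / 3) else 0
    if (length(grid) > 1) {
      fold <- (seq_along(x) - 1L) %% 5L
      loss <- vapply(grid, function(h) {
        sum(vapply(0:4, function(f) {
          tr <- fold != f
          if (sum(tr) < 2L || sum(!tr) == 0L) return(0)
          cv <- fit_at(x[tr], y[tr], h)
          pinball_loss(y[!tr], eval_curve(cv, x[!tr]), tau)
        }, 0))
      }, 0)
      lambda <- grid[which.min(loss)]
    } else lambda <- 0
  }
  cv <- fit_at(x, y, lambda)
  structure(list(x = cv$x, y = cv$y, tau = tau, statistic = statistic,
                 stratum = stratum, lambda = lambda, n_used = nrow(dat)),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf(
    "<threshold_curve> %s %d%%, stratum %s: %d knots over sizes [%g, %g]\n",
    x$statistic, round(100 * x$tau), x$stratum, length(x$x),
    min(x$x), max(x$x)))
  invisible(x)
}

#' Evaluate a threshold curve at group sizes
#'
#' Piecewise-linear interpolation between knots, clamped to the end values
#' outside the fitted range.
#'
#' @param object a `threshold_curve`.
#' @param newdata numeric group sizes.
#' @param ... unused.
#' @return numeric thresholds.
#' @export
predict.threshold_curve <- function(object, newdata, ...) {
  if (length(object$x) == 1L) return(rep(object$y, length(newdata)))
  approx(object$x, object$y, xout = as.numeric(newdata), rule = 2)$y
}

#' Dump a threshold curve on a size grid
#' @param curve a `threshold_curve`.
#' @param path TSV path.
#' @param grid_size number of grid points.
#' @return `path` invisibly.
#' @export
write_threshold_curve <- function(curve, path, grid_size = 200) {
  g <- seq(min(curve$x), max(curve$x), length.out = grid_size)
  readr::write_tsv(tibble(m_set = g, threshold = predict(curve, g),
                          statistic = curve$statistic, tau = curve$tau,
                          stratum = curve$stratum), path, progress = FALSE)
  invisible(path)
}

# Pick the curve matching a statistic and a focal flag from a curve list;
# falls back to the "all" stratum.
match_curve <- function(curves, statistic, focal) {
  strat <- if (isTRUE(focal)) "focal" else "non_focal"
  for (cv in curves)
    if (cv$statistic == statistic && cv$stratum == strat) return(cv)
  for (cv in curves)
    if (cv$statistic == statistic && cv$stratum == "all") return(cv)
  abort(sprintf("no %s threshold curve for stratum %s or all", statistic, strat))
}

#' Apply the dual significance criteria
#'
#' A gene group is called when its likelihood ratio reaches the group-size-
#' adjusted 95th-percentile LR threshold (better model fit than 95 percent
#' of random gene groups) and, separately, when its explained-variance
#' fraction reaches the matching H2 threshold. Both comparisons are
#' inclusive (`>=`); QC-excluded rows get NA. When focal-stratified curves
#' are supplied, each row is compared against the curve of its own focal
#' stratum.
#'
#' @param tbl tibble with columns `m_set`, `lr`, `h2_set`,
#'   `contains_focal`, `excluded`.
#' @param curves list of [fit_threshold_curve()] results containing an LR
#'   curve and an H2 curve at `tau = 0.95` (per stratum or `"all"`).
#' @return `tbl` with logical columns `passes_lr95` and `passes_h95` added.
#' @export
evaluate_criteria <- function(tbl, curves) {
  tbl <- as_tibble(tbl)
  n <- nrow(tbl)
  p_lr <- rep(NA, n); p_h2 <- rep(NA, n)
  for (i in seq_len(n)) {
    if (isTRUE(tbl$excluded[i]) || is.na(tbl$lr[i]) || is.na(tbl$h2_set[i]))
      next
    lr_cv <- match_curve(curves, "lr", tbl$contains_focal[i])
    h2_cv <- match_curve(curves, "h2_set", tbl$contains_focal[i])
    p_lr[i] <- tbl$lr[i] >= predict(lr_cv, tbl$m_set[i])
    p_h2[i] <- tbl$h2_set[i] >= predict(h2_cv, tbl$m_set[i])
  }
  tbl$passes_lr95 <- p_lr
  tbl$passes_h95 <- p_h2
  tbl
}
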