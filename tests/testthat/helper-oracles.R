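# Independent oracles used across the suite.

# Brute-force REML maximizer: coarse grid over variance components followed
# by Nelder-Mead polish on the log scale. Only reml_loglik is shared with
# the implementation under test; the optimization is independent.
oracle_reml_max <- function(y, Gs, weights = NULL) {
  vp <- var(y)
  q <- length(Gs) + 1L
  mk_ll <- function(theta) {
    cmp <- lapply(seq_along(Gs), function(i)
      list(G = Gs[[i]], sigma2 = theta[i]))
    tryCatch(reml_loglik(y, cmp, sigma2_e = theta[q], weights = weights),
             error = function(e) -Inf)
  }
  grid1 <- vp * c(1e-6, 0.02, 0.05, 0.1, 0.2, 0.35, 0.55, 0.8, 1.1, 1.6)
  combos <- as.matrix(do.call(expand.grid, rep(list(grid1), q)))
  vals <- apply(combos, 1, mk_ll)
  best <- combos[which.max(vals), ]
  polish <- optim(log(pmax(best, 1e-12)),
                  function(lt) -mk_ll(exp(lt)),
                  method = "Nelder-Mead",
                  control = list(maxit = 4000, reltol = 1e-12))
  max(max(vals), -polish$value)
}

# Closed-form REML log-likelihood of iid N(mu, s2) with unknown mean.
iid_reml_loglik <- function(y, s2) {
  n <- length(y)
  ss <- sum((y - mean(y))^2)
  -0.5 * ((n - 1) * log(2 * pi * s2) + log(n) + ss / s2)
}

# Dynamic-programming isotonic quantile regression restricted to observed
# response levels (an optimal solution always exists on that lattice).
# Returns the minimal total pinball loss.
dp_isotonic_pinball <- function(x, y, tau) {
  ux <- unique(sort(x))
  levels <- sort(unique(y))
  pin <- function(r) sum(ifelse(r >= 0, tau * r, (tau - 1) * r))
  cost <- sapply(levels, function(l)
    vapply(ux, function(x0) pin(y[x == x0] - l), 0))
  if (is.null(dim(cost))) cost <- matrix(cost, nrow = length(ux))
  best <- cost[1, ]
  if (length(ux) > 1) {
    for (g in 2:length(ux)) best <- cost[g, ] + cummin(best)
  }
  min(best)
}

pinball <- function(y, yhat, tau) {
  r <- y - yhat
  sum(ifelse(r >= 0, tau * r, (tau - 1) * r))
}

# Ten-line Benjamini-Hochberg step-up reference: walk p-values from the
# largest down, scale by n/rank, enforce monotonicity, cap at 1.
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ranks <- n:1
  q <- cummin(n / ranks * p[o])
  q <- pmin(q, 1)
  q[order(o)]
}
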