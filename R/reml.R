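#' Residual weights from DRP reliabilities
#'
#' Deregressed proofs carry a reliability `r` per record; the residual
#' weight is `w = r^2 / (1 - r^2)` and the residual covariance contribution
#' is `sigma2_e * diag(1/w)`, so reliable records get small residual
#' variance. Without reliabilities all weights are 1 (identity residual
#' structure, the EBV case).
#'
#' @param reliability numeric vector of reliabilities in `[0, 1)`, or NULL.
#' @param n number of records (required when `reliability` is NULL).
#' @param min_reliability floor applied to reliabilities so weights stay
#'   positive and finite; default 0.01.
#' @return A `residual_weights` object: list with `weights` (length-n
#'   positive vector) and `unit` (TRUE when no reliabilities were given).
#' @export
residual_weights <- function(reliability = NULL, n = NULL,
                             min_reliability = 0.01) {
  if (is.null(reliability) || all(is.na(reliability))) {
    if (is.null(n)) abort("`n` required when reliabilities are absent")
    return(structure(list(weights = rep(1, n), unit = TRUE),
                     class = "residual_weights"))
  }
  r <- reliability
  if (anyNA(r)) abort("reliabilities must be all present or all absent")
  if (any(r < 0)) abort("negative reliability")
  if (any(r >= 1)) abort("reliability of 1 gives an infinite weight")
  r <- pmax(r, min_reliability)
  if (any(r <= 0)) abort("non-positive weight; raise `min_reliability`")
  structure(list(weights = r^2 / (1 - r^2), unit = FALSE),
            class = "residual_weights")
}

as_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  if (inherits(weights, "residual_weights")) weights <- weights$weights
  if (length(weights) != n) abort("weights length disagrees with y")
  if (any(weights <= 0)) abort("weights must be positive")
  weights
}

grm_matrix <- function(G) {
  if (inherits(G, "grm")) G$G else G
}

#' Restricted log-likelihood of a genomic mixed model
#'
#' REML log-likelihood (intercept-only fixed effects, profiled out) of
#' `y ~ N(1 mu, V)` with
#' `V = sum_i sigma2_i G_i + sigma2_e diag(1/w)`. The additive constant
#' `-(n-1)/2 log(2 pi)` is included so closed-form references match
#' exactly.
#'
#' @param y numeric phenotype vector.
#' @param components list of `list(G = <grm or matrix>, sigma2 = <value>)`.
#' @param sigma2_e residual variance (>= 0; V must stay positive definite).
#' @param weights [residual_weights()], positive vector, or NULL for unit.
#' @return restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(y, components, sigma2_e, weights = NULL) {
  n <- length(y)
  w <- as_weights(weights, n)
  V <- diag(sigma2_e / w, n)
  for (cmp in components) {
    if (cmp$sigma2 < 0) abort("negative variance component")
    if (cmp$sigma2 > 0) V <- V + cmp$sigma2 * grm_matrix(cmp$G)
  }
  st <- reml_core(y, V)
  if (is.null(st)) abort("V is singular or not positive definite")
  st$ll
}

# Core REML quantities at a given V. Returns NULL when chol fails.
reml_core <- function(y, V) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdet <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  u <- rowSums(Vi)              # Vi %*% 1
  s <- sum(u)                   # 1' Vi 1
  if (s <= 0) return(NULL)
  Py <- drop(Vi %*% y) - u * (sum(u * y) / s)
  yPy <- sum(y * Py)
  ll <- -0.5 * (logdet + log(s) + yPy + (n - 1) * log(2 * pi))
  list(ll = ll, Vi = Vi, u = u, s = s, Py = Py, yPy = yPy)
}

# tr(P K) and quadratic forms for one covariance structure K (matrix or
# diagonal given as a vector).
tr_PK <- function(st, K) {
  if (is.matrix(K)) {
    sum(st$Vi * K) - drop(crossprod(st$u, K %*% st$u)) / st$s
  } else {
    sum(diag(st$Vi) * K) - sum(st$u^2 * K) / st$s
  }
}

K_times <- function(K, v) if (is.matrix(K)) drop(K %*% v) else K * v

P_times <- function(st, v) drop(st$Vi %*% v) - st$u * (sum(st$u * v) / st$s)

#' AI-REML variance-component estimation (internal engine)
#'
#' Average-information updates with EM-REML fallback whenever an AI step
#' would leave the admissible region or decrease the restricted likelihood;
#' variance components are clamped at `1e-10 * var(y)`. Convergence when the
#' relative log-likelihood change drops below `tol_ll` or the gradient norm
#' below `tol_grad`.
#'
#' @param y phenotype vector.
#' @param Ks named list of genetic covariance structures (n x n matrices).
#' @param w positive residual weight vector (residual structure `diag(1/w)`).
#' @param start starting values, length `length(Ks) + 1` (residual last).
#' @param max_iter,tol_ll,tol_grad stopping rule.
#' @return list: `theta` (named), `loglik`, `iterations`, `converged`,
#'   `gradient`, `boundary` (logical per component), `vp`.
#' @keywords internal
reml_fit <- function(y, Ks, w, start = NULL, max_iter = 100,
                     tol_ll = 1e-8, tol_grad = 1e-6) {
  n <- length(y)
  vp <- var(y)
  eps <- 1e-10 * vp
  q <- length(Ks) + 1L
  Kall <- c(Ks, list(e = 1 / w))   # residual structure as a diagonal vector
  if (is.null(start)) {
    gshare <- rep(0.5 * vp / length(Ks), length(Ks))
    start <- c(gshare, 0.5 * vp)
  }
  theta <- pmax(start, eps)

  build_V <- function(th) {
    V <- diag(th[q] / w, n)
    for (i in seq_along(Ks)) V <- V + th[i] * Ks[[i]]
    V
  }
  st <- reml_core(y, build_V(theta))
  if (is.null(st)) abort("starting covariance matrix is not positive definite")

  em_step <- function(th, st) {
    tn <- th
    for (i in seq_len(q)) {
      Ki <- Kall[[i]]
      v <- K_times(Ki, st$Py)
      tn[i] <- th[i] + th[i]^2 * (sum(st$Py * v) - tr_PK(st, Ki)) / n
    }
    pmax(tn, eps)
  }

  # A component sitting at the zero boundary is an absorbing state for EM;
  # when its gradient points inward, probe a few interior values and keep
  # the best ascent (never accept a decrease).
  boundary_kick <- function(theta, st, grad) {
    for (i in which(theta <= 2 * eps & grad > tol_grad)) {
      for (cand_val in vp * c(1e-2, 1e-3, 1e-4)) {
        cand <- theta
        cand[i] <- cand_val
        st_try <- reml_core(y, build_V(cand))
        if (!is.null(st_try) && st_try$ll > st$ll + 1e-10)
          return(list(theta = cand, st = st_try))
      }
    }
    NULL
  }

  grad_at <- function(st) {
    vlist <- lapply(Kall, K_times, v = st$Py)
    vapply(seq_len(q), function(i)
      -0.5 * (tr_PK(st, Kall[[i]]) - sum(st$Py * vlist[[i]])), 0)
  }
  # KKT: interior components need a small gradient, boundary components a
  # non-positive one
  kkt_ok <- function(theta, grad)
    all(abs(grad) < tol_grad | (theta <= 2 * eps & grad < 0))

  # Quasi-Newton polish on the log-variance scale with analytic gradients;
  # rescues fits where AI and EM both crawl near a boundary.
  log_polish <- function(theta) {
    res <- tryCatch(optim(
      log(pmax(theta, eps)),
      fn = function(lt) {
        stp <- reml_core(y, build_V(exp(lt)))
        if (is.null(stp)) 1e10 else -stp$ll
      },
      gr = function(lt) {
        th <- exp(lt)
        stp <- reml_core(y, build_V(th))
        if (is.null(stp)) return(rep(0, q))
        -(th * grad_at(stp))
      },
      method = "L-BFGS-B", lower = log(eps), upper = log(1e3 * vp),
      control = list(maxit = 200, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    cand <- pmax(exp(res$par), eps)
    st_new <- reml_core(y, build_V(cand))
    if (is.null(st_new)) NULL else
      list(theta = cand, st = st_new, ok = res$convergence == 0)
  }

  iter <- 0L
  converged <- FALSE
  stalled <- FALSE
  grad <- rep(NA_real_, q)
  repeat {
    iter <- iter + 1L
    grad <- grad_at(st)
    if (kkt_ok(theta, grad)) { converged <- TRUE; break }
    vlist <- lapply(Kall, K_times, v = st$Py)
    AI <- matrix(0, q, q)
    Pv <- lapply(vlist, P_times, st = st)
    for (i in seq_len(q)) for (j in i:q)
      AI[i, j] <- AI[j, i] <- 0.5 * sum(vlist[[i]] * Pv[[j]])
    step <- tryCatch(solve(AI + diag(1e-8 * max(diag(AI), 1e-12), q), grad),
                     error = function(e) NULL)
    # AI update with step halving; EM fallback if no fraction ascends
    cand <- NULL; st_new <- NULL
    if (!is.null(step)) {
      for (frac in c(1, 0.5, 0.25, 0.1)) {
        cand_try <- pmax(theta + frac * step, eps)
        st_try <- reml_core(y, build_V(cand_try))
        if (!is.null(st_try) && st_try$ll >= st$ll - 1e-10) {
          cand <- cand_try; st_new <- st_try; break
        }
      }
    }
    if (is.null(st_new)) {
      cand <- em_step(theta, st)
      st_new <- reml_core(y, build_V(cand))
      if (is.null(st_new) || st_new$ll < st$ll - 1e-8) {
        kick <- boundary_kick(theta, st, grad)
        if (is.null(kick)) { stalled <- TRUE; break }
        cand <- kick$theta; st_new <- kick$st
      }
    }
    dll <- st_new$ll - st$ll
    theta <- cand
    st <- st_new
    if (abs(dll) < tol_ll * (1 + abs(st$ll))) {
      kick <- boundary_kick(theta, st, grad)
      if (is.null(kick)) { stalled <- TRUE; break }
      theta <- kick$theta; st <- kick$st
    }
    if (iter >= max_iter) break
  }
  # stalled or out of iterations without meeting KKT: one polish pass.
  # A stall (no ascent left in AI, EM or boundary kicks) is itself a
  # legitimate stationary state; the polish is a rescue for slow crawls.
  if (!converged) {
    grad <- grad_at(st)
    if (kkt_ok(theta, grad)) {
      converged <- TRUE
    } else {
      pol <- log_polish(theta)
      if (!is.null(pol) && pol$st$ll >= st$ll - 1e-10) {
        theta <- pol$theta
        st <- pol$st
        grad <- grad_at(st)
        converged <- stalled || pol$ok || kkt_ok(theta, grad)
      } else {
        converged <- stalled
      }
    }
  }
  names(theta) <- c(names(Ks), "e")
  list(theta = theta, loglik = st$ll, iterations = iter,
       converged = converged, gradient = grad,
       boundary = theta <= eps * (1 + 1e-6), vp = vp)
}

new_varfit <- function(model, fit, m_set = NA_integer_, m_total, n,
                       set_name = NA_character_, contains_focal = NA) {
  structure(list(model = model, sigma2 = fit$theta, loglik = fit$loglik,
                 iterations = fit$iterations, converged = fit$converged,
                 boundary = fit$boundary, vp = fit$vp, n = n,
                 m_set = m_set, m_total = m_total, set_name = set_name,
                 contains_focal = contains_focal,
                 qc_flags = character(0)),
            class = "varfit")
}

#' Fit the simple (one genetic component) model
#'
#' `y = 1 mu + g + e` with `g ~ N(0, G sigma2_g)` built from all markers and
#' `e ~ N(0, sigma2_e diag(1/w))`: the competitive null that every marker
#' contributes equally to genomic variance.
#'
#' @param y phenotype vector aligned with the GRM order.
#' @param G_all all-marker [build_grm()].
#' @param weights [residual_weights()] or NULL.
#' @param ... passed to the REML engine (`max_iter`, `tol_ll`, `tol_grad`).
#' @return A `varfit` with components `g` and `e`.
#' @export
fit_simple <- function(y, G_all, weights = NULL, ...) {
  n <- length(y)
  if (n < 3) abort("need at least 3 records")
  w <- as_weights(weights, n)
  fit <- reml_fit(y, list(g = grm_matrix(G_all)), w, ...)
  new_varfit("simple", fit, m_total = if (inherits(G_all, "grm"))
    G_all$m_used else NA_integer_, n = n)
}

#' Fit the partitioned (two genetic components) model
#'
#' `y = 1 mu + g_S + g_notS + e` with independent genetic effects whose
#' covariances are the set and complement GRMs times their variance
#' components. When a converged simple-model fit is supplied the estimation
#' starts at its image under the nested identity
#' `(sigma2_g m_S/m, sigma2_g m_notS/m, sigma2_e)`, so with ascent-only
#' steps the likelihood ratio against the simple model is non-negative by
#' construction.
#'
#' @param y phenotype vector aligned with the GRM order.
#' @param G_S,G_notS [build_grm()] of the feature set and its complement.
#' @param weights [residual_weights()] or NULL.
#' @param null_fit optional converged `varfit` from [fit_simple()] on the
#'   same `y` and weights, used for starting values.
#' @param contains_focal focal flag carried into the fit record.
#' @param ... passed to the REML engine.
#' @return A `varfit` with components `set`, `notset` and `e`.
#' @export
fit_partitioned <- function(y, G_S, G_notS, weights = NULL, null_fit = NULL,
                            contains_focal = NA, ...) {
  n <- length(y)
  if (n < 3) abort("need at least 3 records")
  w <- as_weights(weights, n)
  m_S <- G_S$m_used; m_n <- G_notS$m_used; m <- m_S + m_n
  start <- NULL
  if (!is.null(null_fit) && isTRUE(null_fit$converged)) {
    start <- c(null_fit$sigma2[["g"]] * m_S / m,
               null_fit$sigma2[["g"]] * m_n / m,
               null_fit$sigma2[["e"]])
  } else {
    vp <- var(y)
    start <- c(0.5 * vp * m_S / m, 0.5 * vp * m_n / m, 0.5 * vp)
  }
  fit <- reml_fit(y, list(set = grm_matrix(G_S), notset = grm_matrix(G_notS)),
                  w, start = start, ...)
  new_varfit("partitioned", fit, m_set = m_S, m_total = m, n = n,
             set_name = G_S$name, contains_focal = contains_focal)
}

#' @export
print.varfit <- function(x, ...) {
  cat(sprintf("<varfit:%s>%s logLik %.4f (%s, %d iter)\n", x$model,
              if (!is.na(x$set_name)) paste0(" ", x$set_name) else "",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  est <- paste(sprintf("%s=%.4g", names(x$sigma2), x$sigma2), collapse = ", ")
  cat(" ", est, "\n")
  if (length(x$qc_flags)) cat("  qc:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.varfit <- function(object, ...) {
  structure(object$loglik, df = length(object$sigma2), class = "logLik")
}

#' Likelihood ratio between the partitioned and simple models
#'
#' `LR = 2 (logLik_full - logLik_null)` on REML likelihoods sharing the
#' intercept-only fixed structure. Small negatives (> -1e-4), pure numerical
#' noise, are truncated to zero; larger negatives are kept and flagged.
#'
#' @param full partitioned-model `varfit`.
#' @param null simple-model `varfit` on the same data.
#' @return A `likelihood_ratio`: list with `lr`, `negative` (flag),
#'   `df_used` (NA until a reference is selected), `p_value` (NA).
#' @export
likelihood_ratio <- function(full, null) {
  stopifnot(inherits(full, "varfit"), inherits(null, "varfit"))
  if (full$n != null$n) abort("fits are not on the same data")
  lr <- 2 * (full$loglik - null$loglik)
  negative <- lr < -1e-4
  if (lr < 0 && !negative) lr <- 0
  structure(list(lr = lr, negative = negative, df_used = NA,
                 p_value = NA_real_), class = "likelihood_ratio")
}

#' Proportion of genomic variance explained by the set
#'
#' `H2_set = sigma2_S / (sigma2_S + sigma2_notS)` from a partitioned fit.
#'
#' @param fit partitioned `varfit`.
#' @return value in `[0, 1]`; NA with a warning when both genetic
#'   components are zero.
#' @export
h2_set <- function(fit) {
  stopifnot(inherits(fit, "varfit"))
  if (fit$model != "partitioned") abort("h2_set needs a partitioned fit")
  s <- fit$sigma2[["set"]]; ns <- fit$sigma2[["notset"]]
  tot <- s + ns
  if (tot <= 0) {
    warn("both genetic components are zero; H2_set undefined")
    return(NA_real_)
  }
  s / tot
}

#' Null expectation of the explained-variance fraction
#'
#' Under the infinitesimal assumption a set of `m_S` of `m` markers is
#' expected to account for `m_S / m` of the genomic variance.
#'
#' @param m_S set size, `0 < m_S < m`.
#' @param m total marker count.
#' @return `m_S / m`.
#' @export
expected_h2 <- function(m_S, m) {
  if (m_S <= 0 || m_S >= m) abort("`m_S` must satisfy 0 < m_S < m")
  m_S / m
}

#' Quality control of a REML fit
#'
#' Flags fits on which AI-REML converged to a meaningless point:
#' `near_zero_component` when the residual variance or the total genetic
#' variance collapses below `1e-6 * Vp` (a single genetic component at its
#' boundary is an ordinary null outcome and is not flagged),
#' `variance_inflation` when the summed components exceed four times the
#' sample phenotypic variance, and `negative_lr` when a supplied likelihood
#' ratio is materially negative. Non-convergence is tracked on the fit
#' itself. Flagged fits are excluded from empirical-null curve fitting.
#'
#' @param fit a `varfit`.
#' @param sample_phenotypic_variance `Vp`; defaults to the fit's `var(y)`.
#' @param lr optional [likelihood_ratio()].
#' @return the fit with its `qc_flags` field populated.
#' @export
qc_fit <- function(fit, sample_phenotypic_variance = fit$vp, lr = NULL) {
  stopifnot(inherits(fit, "varfit"))
  vp <- sample_phenotypic_variance
  th <- fit$sigma2
  genetic <- sum(th[setdiff(names(th), "e")])
  flags <- character(0)
  if (th[["e"]] < 1e-6 * vp || genetic < 1e-6 * vp)
    flags <- c(flags, "near_zero_component")
  if (sum(th) > 4 * vp)
    flags <- c(flags, "variance_inflation")
  if (!is.null(lr) && isTRUE(lr$negative))
    flags <- c(flags, "negative_lr")
  fit$qc_flags <- flags
  fit
}

#' @rdname tidy_varfit
#' @name tidy_varfit
#' @title Broom-style accessors for REML fits
#' @description `tidy()` returns one row per variance component with its
#'   estimate, boundary status and share of the total variance; `glance()`
#'   returns a one-row model summary (log-likelihood, convergence, H2_set
#'   for partitioned fits).
#' @param x,object a `varfit`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy varfit
#' @export
tidy.varfit <- function(x, ...) {
  tibble(component = names(x$sigma2),
         estimate = unname(x$sigma2),
         share = unname(x$sigma2) / sum(x$sigma2),
         boundary = unname(x$boundary))
}

#' @rdname tidy_varfit
#' @method glance varfit
#' @export
glance.varfit <- function(x, ...) {
  tibble(model = x$model, set_name = x$set_name,
         m_set = x$m_set, m_total = x$m_total, n = x$n,
         loglik = x$loglik,
         h2_set = if (x$model == "partitioned") h2_set(x) else NA_real_,
         converged = x$converged, iterations = x$iterations,
         qc = paste(x$qc_flags, collapse = ";"))
}

#' Align a phenotype table with an individual ordering
#'
#' @param pheno tibble from [read_phenotypes()].
#' @param trait trait name to extract.
#' @param ids individual ids in GRM order.
#' @return list with `y` (numeric) and `reliability` (vector or NULL).
#' @export
align_phenotypes <- function(pheno, trait, ids) {
  ph <- pheno[pheno$trait == trait, ]
  if (nrow(ph) == 0) abort(sprintf("no records for trait `%s`", trait))
  k <- match(ids, ph$id)
  if (anyNA(k))
    abort(sprintf("%d individual(s) lack `%s` records", sum(is.na(k)), trait))
  rel <- ph$reliability[k]
  list(y = ph$value[k],
       reliability = if (all(is.na(rel))) NULL else rel)
}
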