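test_that("DRP reliabilities map to r^2/(1-r^2) residual weights", {
  rw <- residual_weights(c(0.8, 0.5))
  expect_equal(rw$weights, c(0.64 / 0.36, 0.25 / 0.75), tolerance = 1e-12)
  expect_equal(round(rw$weights[1], 4), 1.7778)
  # absent reliabilities give the identity structure
  rw0 <- residual_weights(NULL, n = 4)
  expect_true(rw0$unit)
  expect_equal(rw0$weights, rep(1, 4))
  # r = 1 and r < 0 are invalid; r = 0 hits the configured floor
  expect_error(residual_weights(1), "infinite")
  expect_error(residual_weights(-0.1), "negative")
  expect_error(residual_weights(0, min_reliability = 0), "non-positive")
  expect_gt(residual_weights(0)$weights, 0)
})

test_that("restricted likelihood matches the closed-form iid Gaussian REML", {
  set.seed(31)
  y <- rnorm(5, 10, 2)
  G <- build_grm(center_scale(random_genotypes(5, 20, seed = 31)))
  for (s2 in c(0.5, 2, 7)) {
    ll <- reml_loglik(y, list(list(G = G, sigma2 = 0)), sigma2_e = s2)
    expect_equal(ll, iid_reml_loglik(y, s2), tolerance = 1e-10)
  }
})

test_that("restricted likelihood is invariant to translating y", {
  fx <- small_sim()
  set.seed(32)
  y <- fx$y
  cmp <- list(list(G = fx$G, sigma2 = 0.3))
  expect_equal(reml_loglik(y, cmp, 0.6, fx$weights),
               reml_loglik(y + 57.3, cmp, 0.6, fx$weights),
               tolerance = 1e-8)
  f1 <- fit_simple(y, fx$G, fx$weights)
  f2 <- fit_simple(y + 57.3, fx$G, fx$weights)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-6)
})

test_that("variance estimates scale as c^2 when y is scaled by c", {
  fx <- small_sim()
  f1 <- fit_simple(fx$y, fx$G, fx$weights)
  f2 <- fit_simple(3 * fx$y, fx$G, fx$weights)
  expect_equal(f2$sigma2, 9 * f1$sigma2, tolerance = 1e-5)
})

test_that("constrained partitioned likelihood reproduces the simple model exactly", {
  fx <- small_sim()
  w <- fx$w
  m <- ncol(w$W)
  set.seed(33)
  s <- feature_set("s", sample(m, 150), m)
  G_S <- build_grm(w, s)
  G_n <- build_grm(w, complement_set(s))
  f0 <- fit_simple(fx$y, fx$G, fx$weights)
  s2g <- f0$sigma2[["g"]]
  ll_null <- reml_loglik(fx$y, list(list(G = fx$G, sigma2 = s2g)),
                         f0$sigma2[["e"]], fx$weights)
  ll_mapped <- reml_loglik(
    fx$y,
    list(list(G = G_S, sigma2 = s2g * s$m_set / m),
         list(G = G_n, sigma2 = s2g * (m - s$m_set) / m)),
    f0$sigma2[["e"]], fx$weights)
  expect_equal(ll_mapped, ll_null, tolerance = 1e-10)
})

test_that("small-instance REML fits match the grid+polish oracle", {
  set.seed(34)
  for (k in 1:5) {
    n <- sample(25:35, 1)
    g <- random_genotypes(n, 60, seed = 340 + k)
    w <- center_scale(g)
    G <- build_grm(w)
    y <- drop(chol(G$G * 0.4 + diag(0.6, n) + diag(1e-6, n)) %*% rnorm(n))
    fs <- fit_simple(y, G)
    oracle <- oracle_reml_max(y, list(G$G))
    expect_lt(abs(fs$loglik - oracle) / abs(oracle), 1e-3)
    s <- feature_set("s", sample(60, 20), 60)
    G_S <- build_grm(w, s); G_n <- build_grm(w, complement_set(s))
    fp <- fit_partitioned(y, G_S, G_n, null_fit = fs)
    oracle2 <- oracle_reml_max(y, list(G_S$G, G_n$G))
    expect_lt(abs(fp$loglik - oracle2) / abs(oracle2), 1e-3)
  }
})

test_that("pure-noise phenotypes drive the genetic variance to the boundary", {
  set.seed(35)
  g <- random_genotypes(120, 400, seed = 35)
  G <- build_grm(center_scale(g))
  y <- rnorm(120)
  f <- fit_simple(y, G)
  expect_lt(f$sigma2[["g"]] / var(y), 0.05)
})

test_that("simple-model heritability is recovered on simulated data", {
  scn <- simulation_scenario(n_individuals = 250, n_markers = 1000,
                             h2_total = 0.5, reliability_beta = NULL,
                             seed = 99)
  g <- simulate_genotypes(scn)
  sim <- simulate_phenotypes(scn, g)
  G <- build_grm(center_scale(g))
  f <- fit_simple(sim$phenotypes$value, G)
  h2_hat <- f$sigma2[["g"]] / sum(f$sigma2)
  expect_lt(abs(h2_hat - 0.5), 0.15)
})

test_that("likelihood ratios truncate numerical noise and flag real negatives", {
  fx <- small_sim()
  f0 <- fit_simple(fx$y, fx$G, fx$weights)
  lr_of <- function(full_ll, null_ll) {
    full <- f0; null <- f0
    full$loglik <- full_ll; null$loglik <- null_ll
    likelihood_ratio(full, null)
  }
  expect_equal(lr_of(-100, -102.5)$lr, 5)
  expect_equal(lr_of(-100, -100)$lr, 0)
  tiny <- lr_of(-100.000001, -100)
  expect_equal(tiny$lr, 0)
  expect_false(tiny$negative)
  neg <- lr_of(-103, -102.5)
  expect_equal(neg$lr, -1)
  expect_true(neg$negative)
})

test_that("H2_set arithmetic and degenerate cases", {
  fx <- small_sim()
  set.seed(36)
  s <- feature_set("s", sample(1200, 100), 1200)
  G_S <- build_grm(fx$w, s); G_n <- build_grm(fx$w, complement_set(s))
  f <- fit_partitioned(fx$y, G_S, G_n, fx$weights)
  f$sigma2[c("set", "notset")] <- c(1.5, 4.5)
  expect_equal(h2_set(f), 0.25)
  f$sigma2[c("set", "notset")] <- c(0, 2)
  expect_equal(h2_set(f), 0)
  f$sigma2[c("set", "notset")] <- c(2, 0)
  expect_equal(h2_set(f), 1)
  f$sigma2[c("set", "notset")] <- c(0, 0)
  expect_warning(expect_true(is.na(h2_set(f))), "undefined")
})

test_that("expected explained-variance fraction is the marker share", {
  expect_equal(round(expected_h2(251436, 637951), 3), 0.394)
  expect_equal(expected_h2(50, 100), 0.5)
  expect_equal(expected_h2(1, 637951), 1 / 637951, tolerance = 1e-12)
  expect_error(expected_h2(0, 10), "m_S")
  expect_error(expected_h2(10, 10), "m_S")
})

test_that("fit QC flags inflation and collapsed components", {
  fx <- small_sim()
  f <- fit_simple(fx$y, fx$G, fx$weights)
  vp <- f$vp
  clean <- qc_fit(f)
  expect_length(clean$qc_flags, 0)
  infl <- f; infl$sigma2[c("g", "e")] <- c(3 * vp, 2.5 * vp)
  expect_true("variance_inflation" %in% qc_fit(infl)$qc_flags)
  dead <- f; dead$sigma2[c("g", "e")] <- c(vp, 1e-9 * vp)
  expect_true("near_zero_component" %in% qc_fit(dead)$qc_flags)
  nogen <- f; nogen$sigma2[c("g", "e")] <- c(1e-9 * vp, vp)
  expect_true("near_zero_component" %in% qc_fit(nogen)$qc_flags)
  lr <- structure(list(lr = -1, negative = TRUE), class = "likelihood_ratio")
  expect_true("negative_lr" %in% qc_fit(f, lr = lr)$qc_flags)
})

test_that("tidy and glance summarise fits in broom shape", {
  fx <- small_sim()
  set.seed(37)
  s <- feature_set("s", sample(1200, 200), 1200)
  f <- fit_partitioned(fx$y, build_grm(fx$w, s),
                       build_grm(fx$w, complement_set(s)), fx$weights)
  td <- tidy(f)
  expect_equal(td$component, c("set", "notset", "e"))
  expect_equal(sum(td$share), 1)
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$h2_set, h2_set(f))
  expect_true(gl$converged)
})
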