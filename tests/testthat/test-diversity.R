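test_that("occupancy given abundance matches closed forms and enumeration", {
  expect_identical(occupancy_given_abundance(1, 188), 1)
  expect_equal(occupancy_given_abundance(2, 188), c(1, 187) / 188)
  expect_equal(occupancy_given_abundance(3, 3), c(1 / 9, 2 / 3, 2 / 9))
  # exhaustive enumeration oracle over all W^k allocations (small grid; the
  # full k,W <= 6 grid runs in the acceptance suite)
  for (k in 1:4) for (W in 1:4) {
    expect_equal(occupancy_given_abundance(k, W), enumerate_occupancy(k, W),
                 tolerance = 0, label = sprintf("k=%d W=%d", k, W))
  }
  # large-count log-space path agrees with the exact small-count path and
  # concentrates at j = W
  p_big <- occupancy_given_abundance(500, 6)
  expect_equal(sum(p_big), 1, tolerance = 1e-10)
  expect_gt(p_big[6], 0.999)
  p30 <- occupancy_given_abundance(30, 5)
  p31 <- occupancy_given_abundance(31, 5)   # log-space branch
  expect_equal(sum(p31), 1, tolerance = 1e-10)
  expect_gt(stats::cor(p30, p31), 0.999)
})

test_that("marginal occupancy pmf normalises and matches its oracles", {
  for (par in list(c(1, 2), c(0.3, 0.8), c(5, 0.05))) {
    p <- marginal_occupancy(par[1], par[2], 188)
    expect_lt(abs(sum(p) - 1), 1e-10)
    expect_true(all(p >= 0))
  }
  # analytic and quadrature routes agree where the analytic sum is stable
  pa <- marginal_occupancy(1.5, 0.7, 12, method = "analytic")
  pq <- marginal_occupancy(1.5, 0.7, 12, method = "quadrature")
  expect_lt(max(abs(pa - pq)), 1e-6)
  # degenerate-mixing limit: alpha -> Inf with alpha*theta = lambda0 fixed
  lam0 <- 3
  p_deg <- marginal_occupancy(1e6, lam0 / 1e6, 188)
  expect_lt(max(abs(p_deg - stats::dbinom(0:188, 188,
                                          -expm1(-lam0 / 188)))), 1e-5)
  # Monte-Carlo oracle at the dispersed design point
  p <- marginal_occupancy(1, 2, 188)
  set.seed(HOUSE_SEED)
  lam <- stats::rgamma(2e5, 1, scale = 2)
  occ <- stats::rbinom(2e5, 188, -expm1(-lam / 188))
  emp <- tabulate(occ + 1L, nbins = 189) / 2e5
  j <- which(p > 1e-3)
  z <- (emp[j] - p[j]) / sqrt(p[j] * (1 - p[j]) / 2e5)
  expect_lt(max(abs(z)), 4)
})

test_that("the likelihood peaks near truth and depends only on the spectrum", {
  W <- 188
  hits <- 0L
  for (s in 1:20) {
    sp <- simulate_occupancy_spectrum(1e4, 1, 0.3, W, seed = HOUSE_SEED + s)
    ll <- occupancy_loglik(sp, 1e4, 1, 0.3)
    if (ll >= occupancy_loglik(sp, 5e3, 1, 0.3) &&
        ll >= occupancy_loglik(sp, 2e4, 1, 0.3)) hits <- hits + 1L
  }
  expect_gte(hits, 11L)   # majority over 20 seeds
  sp <- simulate_occupancy_spectrum(5e3, 1, 0.3, W, seed = 1)
  expect_true(is.finite(occupancy_loglik(sp, 5e3, 1, 0.3)))
  empty <- structure(list(n_wells = 10L, n_j = integer(10), n_obs = 0L),
                     class = "occupancy_spectrum")
  expect_error(occupancy_loglik(empty, 10, 1, 1), "undefined")
})

test_that("fit_diversity recovers model parameters and obeys its bounds", {
  theta <- 0.7^(-1 / 2) - 1     # ~30% of clones sampled at alpha = 2
  sp <- simulate_occupancy_spectrum(2e4, 2, theta, 188, seed = HOUSE_SEED)
  fit <- fit_diversity(sp)
  expect_s3_class(fit, "diversity_fit")
  expect_true(fit$converged)
  expect_equal(fit$richness, 2e4, tolerance = 0.1)
  expect_gte(fit$richness, sp$n_obs)
  expect_gte(fit$clonality, 0); expect_lte(fit$clonality, 1)
  # the closed-form richness step: S_hat = n_obs / (1 - P0) at the optimum
  p0 <- marginal_occupancy(fit$mixing_shape, fit$mixing_scale, 188)[1]
  expect_equal(fit$richness, sp$n_obs / (1 - p0), tolerance = 1e-8)
  expect_warning(fit_diversity(simulate_occupancy_spectrum(
    50, 2, 1, 20, seed = 1)), "unreliable")
})

test_that("degenerate-mixing fits reduce to the binomial occupancy estimator", {
  # all clones share one intensity: occupancy is plain Binomial(W, p)
  W <- 100L
  sp <- simulate_occupancy_spectrum(2e4, 1e5, 2 / 1e5, W, seed = HOUSE_SEED)
  fit <- fit_diversity(sp)
  # the known zero-truncated binomial estimator
  j <- seq_len(W)
  mean_occ <- sum(j * sp$n_j) / sp$n_obs
  g <- function(q) W * q / (1 - (1 - q)^W) - mean_occ
  q_hat <- stats::uniroot(g, c(1e-6, 0.5))$root
  S_bin <- sp$n_obs / (1 - (1 - q_hat)^W)
  expect_equal(fit$richness, S_bin, tolerance = 0.05)
})

test_that("diversity_fit behaves like a standard fitted-model object", {
  sp <- simulate_occupancy_spectrum(5e3, 1, 0.5, 96, seed = HOUSE_SEED)
  fit <- fit_diversity(sp)
  co <- coef(fit)
  expect_named(co, c("richness", "mixing_shape", "mixing_scale",
                     "clonality"))
  expect_s3_class(logLik(fit), "logLik")
  expect_identical(attr(logLik(fit), "df"), 3L)
  pred <- predict(fit)
  expect_identical(nrow(pred), 96L)
  expect_equal(sum(pred$expected_clones), fit$richness *
                 (1 - marginal_occupancy(fit$mixing_shape,
                                         fit$mixing_scale, 96)[1]),
               tolerance = 1e-6)
  r <- residuals(fit)
  expect_length(r, 96L)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2L)
  expect_s3_class(sim[[1]], "occupancy_spectrum")
  expect_output(print(fit), "richness")
  expect_output(summary(fit), "sampled fraction")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("clonality is 0 for uniform, ~1 for dominated, exact on vectors", {
  # hand-computed two-clone vector
  expect_equal(clonality(c(0.9, 0.1)), 0.531, tolerance = 1e-3)
  expect_identical(clonality(rep(1 / 64, 64)), 0)
  # single dominant clone among 1e4
  eps <- 1e-9
  f <- c(1 - eps, rep(eps / 9999, 9999))
  expect_gt(clonality(f), 0.99)
  # model-based: uniform limit alpha -> Inf gives 0
  expect_lt(model_clonality(1e4, 1e6, 1), 1e-4)
  expect_identical(model_clonality(1, 2, 1), 0)
  # closed form vs independent Gauss-Laguerre quadrature route: the
  # quadrature converges slowly for near-flat weights (small shapes), so
  # the agreement band is shape-dependent
  expect_lt(abs(model_clonality(1e5, 0.5, 0.7) -
                  model_clonality(1e5, 0.5, 0.7, method = "quadrature")),
            2e-4)
  expect_lt(abs(model_clonality(1e5, 2, 0.7) -
                  model_clonality(1e5, 2, 0.7, method = "quadrature")),
            1e-6)
  expect_lt(abs(model_clonality(1e5, 20, 0.7) -
                  model_clonality(1e5, 20, 0.7, method = "quadrature")),
            1e-8)
  # model clonality agrees with empirical entropy of gamma frequencies
  set.seed(HOUSE_SEED)
  f <- sample_clone_frequencies(2e4, 0.2, 1)
  expect_equal(clonality(f), model_clonality(2e4, 0.2, 1), tolerance = 0.02)
  expect_error(clonality(c(0.5, 0.4)), "sum to 1")
})
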