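#' Occupancy distribution of a clone conditioned on its sampled cell count
#'
#' For a clone represented by exactly `k` cells thrown independently and
#' uniformly into `W` wells, the probability that the clone occupies exactly
#' j wells is `C(W, j) * surj(k, j) / W^k`, where `surj(k, j) =
#' j! * Stirling2(k, j)` counts the surjections of k labelled cells onto j
#' labelled wells. Small `k` uses exact integer-valued double arithmetic;
#' large `k` evaluates the Stirling recurrence in log space.
#'
#' @param k Sampled cell count (>= 1).
#' @param W Number of wells (>= 1).
#' @return Numeric probability vector over j = 1..min(k, W), summing to 1.
#' @export
#' @examples
#' occupancy_given_abundance(3, 3)  # 1/9, 2/3, 2/9
occupancy_given_abundance <- function(k, W) {
  if (!is_count(k) || !is_count(W))
    stop("`k` and `W` must be positive integers", call. = FALSE)
  jmax <- min(k, W)
  if (k <= 30L) {
    # exact: Stirling numbers by recurrence, integer-valued doubles
    S2 <- matrix(0, nrow = k + 1L, ncol = jmax + 1L)
    S2[1L, 1L] <- 1
    for (kk in seq_len(k)) {
      for (jj in seq_len(min(kk, jmax))) {
        S2[kk + 1L, jj + 1L] <- jj * S2[kk, jj + 1L] + S2[kk, jj]
      }
    }
    j <- seq_len(jmax)
    p <- choose(W, j) * factorial(j) * S2[k + 1L, j + 1L] / W^k
    return(p)
  }
  # log-space DP on the same (all-positive) recurrence
  logadd <- function(a, b) {
    m <- pmax(a, b)
    ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(-abs(a - b))))
  }
  prev <- c(0, rep(-Inf, jmax))       # log S2(0, 0..jmax)
  for (kk in seq_len(k)) {
    cur <- rep(-Inf, jmax + 1L)
    jj <- seq_len(min(kk, jmax))
    cur[jj + 1L] <- logadd(log(jj) + prev[jj + 1L], prev[jj])
    prev <- cur
  }
  j <- seq_len(jmax)
  logp <- lchoose(W, j) + lfactorial(j) + prev[j + 1L] - k * log(W)
  exp(logp - max(logp)) * exp(max(logp))
}

#' Marginal occupancy distribution under the gamma-mixed Poisson model
#'
#' Under the abundance model, a clone's intensity lambda is
#' Gamma(`mixing_shape`, scale = `mixing_scale`); conditional on lambda the
#' per-well cell counts are independent Poisson(lambda/W), so the clone's
#' occupancy is Binomial(W, 1 - exp(-lambda/W)). Marginalising analytically
#' over lambda with the gamma Laplace transform gives
#' `P(j) = C(W,j) * sum_m C(j,m) (-1)^m (1 + theta (W - j + m)/W)^(-alpha)`.
#' The alternating sum cancels catastrophically for mid-range j at large W,
#' so each entry carries a floating-point error estimate and unstable
#' entries are replaced by deterministic quadrature over the mixing density
#' (composite Gauss-Legendre on the probability scale of lambda, with
#' panels refined towards the distribution tails), the numerically safe
#' route whose total probability is exactly 1 by construction.
#'
#' @param mixing_shape,mixing_scale Gamma parameters (alpha, theta), > 0.
#' @param W Number of wells (>= 1).
#' @param method `"auto"` (analytic with per-entry quadrature fallback),
#'   `"analytic"`, or `"quadrature"`.
#' @param nodes Quadrature nodes per panel (7 panels).
#' @return Probability vector over j = 0..W (length W + 1), summing to 1
#'   within 1e-10.
#' @export
marginal_occupancy <- function(mixing_shape, mixing_scale, W,
                               method = c("auto", "analytic", "quadrature"),
                               nodes = 72L) {
  method <- match.arg(method)
  if (mixing_shape <= 0 || mixing_scale <= 0)
    stop("mixing parameters must be positive", call. = FALSE)
  if (!is_count(W)) stop("`W` must be a positive integer", call. = FALSE)
  alpha <- mixing_shape
  theta <- mixing_scale

  analytic <- function() {
    p <- numeric(W + 1L)
    err <- numeric(W + 1L)
    for (j in 0:W) {
      m <- 0:j
      terms <- choose(j, m) * (-1)^m * (1 + theta * (W - j + m) / W)^(-alpha)
      cwj <- choose(W, j)
      p[j + 1L] <- cwj * sum(terms)
      err[j + 1L] <- cwj * sum(abs(terms)) * .Machine$double.eps * (j + 2)
    }
    list(p = p, err = err)
  }
  quadrature <- function() {
    gl <- gauss_legendre_unit(nodes)
    lam <- stats::qgamma(gl$x, shape = alpha, scale = theta)
    pw <- -expm1(-lam / W)            # per-well occupancy probability
    # (W+1) x nodes matrix of binomial pmfs, weighted column-sum
    db <- stats::dbinom(rep(0:W, times = length(pw)), W,
                        rep(pw, each = W + 1L))
    as.numeric(matrix(db, nrow = W + 1L) %*% gl$w)
  }

  if (method == "quadrature") return(quadrature())
  an <- analytic()
  if (method == "analytic") return(an$p)
  bad <- an$p < -1e-12 | an$err > 1e-12 | !is.finite(an$p)
  # any unstable entry: switch the whole vector to the quadrature route,
  # whose entries share one rule and sum to 1 exactly
  if (any(bad)) return(quadrature())
  pmax(an$p, 0)
}

#' Log-likelihood of an occupancy spectrum under the abundance model
#'
#' Large-richness (Poissonized) form: the spectrum counts n_j, j = 1..W,
#' are treated as independent Poisson with means S * P(j), where P is the
#' marginal occupancy pmf; the occupancy-0 class is unobserved and enters
#' only through the means. Up to an additive constant free of the
#' parameters, `loglik = sum_j [n_j log(S P_j) - S P_j]`.
#'
#' @param spectrum An `"occupancy_spectrum"`.
#' @param richness Repertoire richness S (> 0).
#' @param mixing_shape,mixing_scale Gamma mixing parameters.
#' @return Log-likelihood value (finite for all valid parameters).
#' @export
occupancy_loglik <- function(spectrum, richness, mixing_shape,
                             mixing_scale) {
  stopifnot(inherits(spectrum, "occupancy_spectrum"))
  if (spectrum$n_obs == 0L)
    stop("log-likelihood is undefined for an empty spectrum", call. = FALSE)
  if (richness <= 0) stop("`richness` must be positive", call. = FALSE)
  W <- spectrum$n_wells
  p <- marginal_occupancy(mixing_shape, mixing_scale, W)
  pj <- pmax(p[-1L], 1e-300)
  mu <- richness * pj
  sum(spectrum$n_j * log(mu)) - sum(mu)
}

# profile log-likelihood over (alpha, theta): S is maximised analytically,
# S_hat = n_obs / (1 - P0)
profile_loglik <- function(spectrum, mixing_shape, mixing_scale) {
  W <- spectrum$n_wells
  p <- marginal_occupancy(mixing_shape, mixing_scale, W)
  p0 <- min(p[1L], 1 - 1e-12)
  S_hat <- spectrum$n_obs / (1 - p0)
  pj <- pmax(p[-1L], 1e-300)
  ll <- sum(spectrum$n_j * log(S_hat * pj)) - S_hat * (1 - p0)
  list(loglik = ll, S_hat = S_hat, p = p)
}

#' Fit the replicate-occupancy abundance model by maximum likelihood
#'
#' The estimator behind the repertoire diversity indices: given the
#' occupancy spectrum of a sample over W replicate wells, fits richness S
#' and the gamma abundance mixing parameters (alpha, theta) by a tandem
#' scheme. For fixed (alpha, theta) the richness maximising the Poissonized
#' likelihood has the closed form `S_hat = n_obs / (1 - P0)` (the analytic
#' step); the mixing parameters are then optimised numerically on the
#' (log alpha, log theta) scale over the profile likelihood with
#' Nelder-Mead from four fixed starts, guarding against the alpha-theta
#' ridge (the numeric step). Clonality is evaluated on the fitted model via
#' [model_clonality()].
#'
#' @param spectrum An `"occupancy_spectrum"` (from [occupancy_spectrum()]
#'   or [read_occupancy_spectrum()]).
#' @param starts Optional 2-column matrix of (alpha, theta) starts.
#' @param control Passed to [stats::optim()] (Nelder-Mead); the default
#'   convergence tolerance on the profile likelihood is 1e-8.
#' @return An object of class `"diversity_fit"` with components `richness`
#'   (S_hat), `mixing_shape`, `mixing_scale`, `clonality`, `loglik`,
#'   `converged`, `n_obs`, `reliable` (FALSE below 100 observed clones,
#'   with a warning), `spectrum` and `fitted` (expected n_j). Supports
#'   `print`, `summary`, `coef`, `logLik`, `predict`, `simulate`,
#'   `residuals` and `plot`.
#' @seealso [occupancy_loglik()], [marginal_occupancy()],
#'   [model_clonality()]
#' @export
#' @examples
#' sp <- simulate_occupancy_spectrum(5000, 2, 0.4, W = 50, seed = 1)
#' fit <- fit_diversity(sp)
#' coef(fit)
fit_diversity <- function(spectrum, starts = NULL, control = list()) {
  stopifnot(inherits(spectrum, "occupancy_spectrum"))
  if (spectrum$n_obs == 0L)
    stop("cannot fit an empty spectrum", call. = FALSE)
  reliable <- spectrum$n_obs >= 100L
  if (!reliable)
    warning("fewer than 100 observed clones: estimate flagged unreliable")
  if (is.null(starts))
    starts <- cbind(alpha = c(0.1, 0.5, 2, 10),
                    theta = c(1, 0.3, 0.1, 0.03))
  control <- utils::modifyList(list(reltol = 1e-10, maxit = 2000L), control)

  negpll <- function(par) {
    a <- exp(par[1L]); t <- exp(par[2L])
    if (!is.finite(a) || !is.finite(t) || a > 1e8 || t > 1e8) return(1e12)
    -profile_loglik(spectrum, a, t)$loglik
  }
  best <- NULL
  conv <- FALSE
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(log(starts[s, ]), negpll, method = "Nelder-Mead",
                      control = control)
    if (is.null(best) || o$value < best$value) {
      best <- o
      conv <- o$convergence == 0L
    }
  }
  alpha <- unname(exp(best$par[1L]))
  theta <- unname(exp(best$par[2L]))
  pro <- profile_loglik(spectrum, alpha, theta)
  S_hat <- max(pro$S_hat, spectrum$n_obs)
  clon <- model_clonality(S_hat, alpha, theta)
  fitted_nj <- S_hat * pro$p[-1L]
  structure(list(richness = S_hat, mixing_shape = alpha,
                 mixing_scale = theta, clonality = clon,
                 loglik = pro$loglik, converged = conv, reliable = reliable,
                 n_obs = spectrum$n_obs, n_wells = spectrum$n_wells,
                 spectrum = spectrum, fitted = fitted_nj),
            class = "diversity_fit")
}

#' @export
print.diversity_fit <- function(x, ...) {
  cat("Replicate-occupancy abundance model fit\n")
  cat(sprintf("  wells W = %d, observed clones = %d\n", x$n_wells, x$n_obs))
  cat(sprintf("  richness  S-hat     = %.0f\n", x$richness))
  cat(sprintf("  clonality           = %.4f\n", x$clonality))
  cat(sprintf("  mixing    gamma(shape = %.4g, scale = %.4g)\n",
              x$mixing_shape, x$mixing_scale))
  cat(sprintf("  log-likelihood %.2f%s%s\n", x$loglik,
              if (x$converged) "" else "  [not converged]",
              if (x$reliable) "" else "  [unreliable: n_obs < 100]"))
  invisible(x)
}

#' @export
summary.diversity_fit <- function(object, ...) {
  sampled_frac <- object$n_obs / object$richness
  cat("Replicate-occupancy abundance model\n\n")
  print(object)
  cat(sprintf("\n  implied sampled fraction of repertoire: %.1f%%\n",
              100 * sampled_frac))
  j <- which(object$spectrum$n_j > 0)
  df <- data.frame(occupancy = j, observed = object$spectrum$n_j[j],
                   expected = round(object$fitted[j], 1))
  print(utils::head(df, 12), row.names = FALSE)
  invisible(object)
}

#' @export
coef.diversity_fit <- function(object, ...) {
  c(richness = object$richness, mixing_shape = object$mixing_shape,
    mixing_scale = object$mixing_scale, clonality = object$clonality)
}

#' @export
logLik.diversity_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n_obs, class = "logLik")
}

#' @export
#' @method predict diversity_fit
predict.diversity_fit <- function(object, ...) {
  data.frame(occupancy = seq_len(object$n_wells),
             expected_clones = object$fitted)
}

#' @export
#' @method residuals diversity_fit
residuals.diversity_fit <- function(object, type = c("pearson", "raw"),
                                    ...) {
  type <- match.arg(type)
  r <- object$spectrum$n_j - object$fitted
  if (type == "pearson") r <- r / sqrt(pmax(object$fitted, 1e-12))
  r
}

#' @export
#' @method simulate diversity_fit
simulate.diversity_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(i)
      simulate_occupancy_spectrum(round(object$richness),
                                  object$mixing_shape, object$mixing_scale,
                                  W = object$n_wells))
  })
}

#' @export
#' @method plot diversity_fit
plot.diversity_fit <- function(x, ...) {
  j <- which(x$spectrum$n_j > 0 | x$fitted > 0.5)
  graphics::plot(j, x$spectrum$n_j[j], log = "y", pch = 16,
                 xlab = "occupancy (wells)",
                 ylab = "unique sequences",
                 main = "Observed vs fitted occupancy spectrum", ...)
  graphics::lines(j, pmax(x$fitted[j], 1e-2), col = "red3", lwd = 2)
  graphics::legend("topright", legend = c("observed", "fitted"),
                   pch = c(16, NA), lty = c(NA, 1), col = c("black", "red3"))
  invisible(x)
}

#' Simulate an occupancy spectrum directly from the abundance model
#'
#' Draws clone intensities from the gamma mixing distribution and each
#' clone's occupancy from Binomial(W, 1 - exp(-lambda/W)) (exact under
#' independent Poisson per-well counts). Used for model-level parameter
#' recovery studies and by [simulate.diversity_fit()].
#'
#' @param richness Number of clones S.
#' @param mixing_shape,mixing_scale Gamma parameters.
#' @param W Number of wells.
#' @param seed Optional integer seed.
#' @return An `"occupancy_spectrum"`.
#' @export
simulate_occupancy_spectrum <- function(richness, mixing_shape,
                                        mixing_scale, W, seed = NULL) {
  with_seed(seed, {
    lam <- stats::rgamma(richness, shape = mixing_shape,
                         scale = mixing_scale)
    occ <- stats::rbinom(richness, W, -expm1(-lam / W))
    occ <- occ[occ > 0L]
    structure(list(n_wells = as.integer(W),
                   n_j = tabulate(occ, nbins = W),
                   n_obs = length(occ)),
              class = "occupancy_spectrum")
  })
}

#' Clonality of a fitted or explicit abundance model
#'
#' Clonality is `1 - H / log(S)`, clipped to \[0, 1\], where H is the
#' Shannon entropy of the clone frequency vector: 0 for a maximally uniform
#' repertoire, approaching 1 under clonal domination. For the gamma model
#' the expected entropy of S i.i.d. Gamma(alpha, theta) intensities,
#' normalised to frequencies, follows the large-S identity
#' `H = log(S alpha theta) - E[lambda log lambda]/(alpha theta)`; since
#' `E[lambda log lambda] = alpha theta (digamma(alpha + 1) + log theta)` in
#' closed form, this reduces exactly (and scale-free) to
#' `H = log S + log alpha - digamma(alpha + 1)`, which is what the default
#' evaluates. `method = "quadrature"` computes the same expectation by
#' 64-node generalised Gauss-Laguerre quadrature over the gamma density
#' instead, as an independent numerical route to the closed form.
#'
#' @param richness Model richness S.
#' @param mixing_shape,mixing_scale Gamma parameters.
#' @param method `"closed-form"` (exact, default) or `"quadrature"`
#'   (shapes <= 100 only).
#' @return Clonality in \[0, 1\]; defined as 0 when `richness <= 1`.
#' @export
#' @examples
#' model_clonality(1e4, 0.5, 1) > model_clonality(1e4, 5, 1)
model_clonality <- function(richness, mixing_shape, mixing_scale = 1,
                            method = c("closed-form", "quadrature")) {
  method <- match.arg(method)
  if (mixing_shape <= 0 || mixing_scale <= 0)
    stop("mixing parameters must be positive", call. = FALSE)
  if (richness <= 1) return(0)
  alpha <- mixing_shape
  theta <- mixing_scale
  if (method == "quadrature") {
    if (alpha > 100)
      stop("quadrature method supports shapes <= 100 only", call. = FALSE)
    # lambda * f_alpha(lambda) = alpha theta f_{alpha+1}(lambda), so
    # E[lambda log lambda] = alpha theta E_{alpha+1}[log lambda]; weight
    # x^alpha e^-x is valid for every alpha > 0
    gq <- pracma::gaussLaguerre(64L, alpha)
    e_log_shift <- sum(gq$w * log(theta * gq$x)) / gamma(alpha + 1)
    H <- log(richness * alpha * theta) - e_log_shift
  } else {
    H <- log(richness) + log(alpha) - digamma(alpha + 1)
  }
  min(max(1 - H / log(richness), 0), 1)
}

#' Empirical clonality of a frequency vector
#'
#' `clonality(p)` for an explicit clone-frequency vector is
#' `1 - H(p)/log(length(p))` with H the Shannon entropy (natural log);
#' for a `"diversity_fit"` it returns the model-based value stored in the
#' fit.
#'
#' @param x Frequency vector (nonnegative, summing to 1) or a
#'   `"diversity_fit"`.
#' @param ... Unused.
#' @return Clonality in \[0, 1\].
#' @export
#' @examples
#' clonality(c(0.9, 0.1))  # 0.531
clonality <- function(x, ...) UseMethod("clonality")

#' @export
clonality.numeric <- function(x, ...) {
  if (any(x < 0) || abs(sum(x) - 1) > 1e-6)
    stop("frequencies must be nonnegative and sum to 1", call. = FALSE)
  if (length(x) <= 1L) return(0)
  p <- x[x > 0]
  H <- -sum(p * log(p))
  min(max(1 - H / log(length(x)), 0), 1)
}

#' @export
clonality.diversity_fit <- function(x, ...) x$clonality

#' Write a diversity estimate as JSON
#'
#' @param fit A `"diversity_fit"`.
#' @param path Output path.
#' @export
write_diversity_json <- function(fit, path) {
  jsonlite::write_json(
    list(richness = fit$richness, clonality = fit$clonality,
         alpha = fit$mixing_shape, theta = fit$mixing_scale,
         loglik = fit$loglik, converged = fit$converged,
         n_obs = fit$n_obs, n_wells = fit$n_wells),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
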