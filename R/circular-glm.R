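#' MCMC configuration for the circular GLM
#'
#' Defaults follow the analysis design: four chains, 200 burn-in
#' iterations, 2500 retained iterations per chain.
#'
#' @param n_chains number of chains.
#' @param burnin burn-in iterations per chain (discarded; proposal scales
#'   adapt only during this phase).
#' @param iterations retained iterations per chain.
#' @param seed integer seed; chain `c` uses `seed + c`.
#' @param beta1_prior_sd SD of an optional mean-zero Gaussian prior on the
#'   slope; `Inf` (default) gives the flat prior.
#' @param proposal_scales optional `list(beta1=, log_kappa=)` random-walk
#'   SDs; when `NULL` they are set from approximate Fisher information at
#'   the initial estimates.
#' @return object of class `circglm_config`.
#' @export
circglm_config <- function(n_chains = 4L, burnin = 200L, iterations = 2500L,
                           seed = 1L, beta1_prior_sd = Inf,
                           proposal_scales = NULL) {
  stopifnot(n_chains >= 1, burnin >= 1, iterations >= 1, beta1_prior_sd > 0)
  structure(list(n_chains = as.integer(n_chains), burnin = as.integer(burnin),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 beta1_prior_sd = beta1_prior_sd,
                 proposal_scales = proposal_scales),
            class = "circglm_config")
}

#' von Mises circular regression log-likelihood
#'
#' Log-likelihood of angles `theta` under the model
#' `theta_i ~ VM(mu_i, kappa)` with
#' `mu_i = beta0 + 2 * atan(beta1 * (x_i - x_center))`:
#' `sum_i kappa * cos(theta_i - mu_i) - n * log(2 * pi * I0(kappa))`.
#' The Bessel term is computed on the log scale so the value stays finite
#' for large kappa.
#'
#' @param theta response angles in radians.
#' @param x predictor (collection years).
#' @param beta0 circular intercept (radians).
#' @param beta1 link-scale slope per predictor unit.
#' @param kappa concentration (> 0).
#' @param x_center centering constant subtracted from `x`.
#' @return scalar log-likelihood.
#' @export
vm_loglik <- function(theta, x, beta0, beta1, kappa, x_center = 0) {
  stopifnot(length(theta) == length(x))
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  mu <- beta0 + 2 * atan(beta1 * (x - x_center))
  sum(kappa * cos(theta - mu)) -
    length(theta) * (log(2 * pi) + log_bessel_i0(kappa))
}

# Gelman-Rubin potential scale reduction over an iterations x chains matrix
.gelman_rhat <- function(mat) {
  m <- ncol(mat)
  if (m < 2) return(NA_real_)
  n <- nrow(mat)
  mu_c <- colMeans(mat)
  W <- mean(apply(mat, 2, stats::var))
  B <- n * stats::var(mu_c)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the Bayesian von Mises circular regression
#'
#' Regresses a circular response (flowering angle) on a linear predictor
#' (collection year) with the inverse tan-half link, by MCMC:
#' the circular intercept is Gibbs-sampled from its von Mises full
#' conditional, and the slope and log-concentration move by random-walk
#' Metropolis with scales adapted during burn-in only. Priors are
#' noninformative by default: uniform on the circle for the intercept, flat
#' for the slope (optionally Gaussian), flat on kappa > 0. The predictor is
#' centred at its mean before sampling.
#'
#' @param series data.frame with columns `year` and `theta` (see
#'   [build_series()]).
#' @param config a [circglm_config()].
#' @return object of class `circglm_fit`: posterior draws
#'   (`beta0_samples`, `beta1_samples`, `kappa_samples`, pooled over
#'   chains), posterior summaries, per-parameter Gelman-Rubin `rhat`, a
#'   `converged` flag (all rhat < 1.1), `x_center`, `x_range`, `n_obs`.
#' @export
fit_circular_glm <- function(series, config = circglm_config()) {
  stopifnot(inherits(config, "circglm_config"))
  th <- series$theta
  x <- series$year
  n <- length(th)
  if (n < 3) stop("need at least 3 observations, got ", n)
  if (length(unique(x)) < 2) {
    stop("no temporal contrast: all observations share one year")
  }
  x_center <- mean(x)
  xc <- x - x_center

  # moment-based starting values
  b0_hat <- circ_mean(th)
  kap_hat <- max(kappa_mle(circ_resultant(th)), 0.05)
  r0 <- wrap_angle(th - b0_hat)
  b1_hat <- stats::cov(r0, xc) / stats::var(xc) / 2

  # proposal scales from approximate Fisher information at the start values
  if (is.null(config$proposal_scales)) {
    s_b1 <- 2.4 / sqrt(max(4 * kap_hat * sum(xc^2), 1e-8))
    A <- besselI(kap_hat, 1, TRUE) / besselI(kap_hat, 0, TRUE)
    Ap <- max(1 - A^2 - A / kap_hat, 1e-6)
    s_lk <- min(2, max(0.05, 2.4 / sqrt(n * kap_hat^2 * Ap)))
  } else {
    s_b1 <- config$proposal_scales$beta1
    s_lk <- config$proposal_scales$log_kappa
  }

  lprior_b1 <- if (is.finite(config$beta1_prior_sd)) {
    function(b) -0.5 * (b / config$beta1_prior_sd)^2
  } else {
    function(b) 0
  }
  cos_sum <- function(b0, b1) sum(cos(th - b0 - 2 * atan(b1 * xc)))

  total <- config$burnin + config$iterations
  draws <- lapply(seq_len(config$n_chains), function(chain) {
    set.seed(config$seed + chain)
    # overdispersed chain starts around the moment estimates
    b0 <- wrap_angle(b0_hat + stats::rnorm(1, 0, 0.2))
    b1 <- b1_hat + stats::rnorm(1, 0, 2 * s_b1)
    kap <- kap_hat * exp(stats::rnorm(1, 0, 0.3))
    s1 <- s_b1
    s2 <- s_lk
    acc1 <- acc2 <- 0L
    out <- matrix(NA_real_, config$iterations, 3)
    for (t in seq_len(total)) {
      # Gibbs for beta0: VM full conditional given the link offsets
      rr <- th - 2 * atan(b1 * xc)
      S <- sum(sin(rr)); C <- sum(cos(rr))
      b0 <- rvonmises(1, atan2(S, C), kap * sqrt(S^2 + C^2))
      # random-walk Metropolis for beta1
      cur <- kap * cos_sum(b0, b1) + lprior_b1(b1)
      b1p <- b1 + stats::rnorm(1, 0, s1)
      prop <- kap * cos_sum(b0, b1p) + lprior_b1(b1p)
      if (log(stats::runif(1)) < prop - cur) {
        b1 <- b1p
        acc1 <- acc1 + 1L
      }
      # random-walk Metropolis for log(kappa); flat prior on kappa gives a
      # +log(kappa) Jacobian term
      cs <- cos_sum(b0, b1)
      lkp <- log(kap) + stats::rnorm(1, 0, s2)
      kp <- exp(lkp)
      lr <- (kp - kap) * cs - n * (log_bessel_i0(kp) - log_bessel_i0(kap)) +
        (lkp - log(kap))
      if (log(stats::runif(1)) < lr) {
        kap <- kp
        acc2 <- acc2 + 1L
      }
      if (t <= config$burnin && t %% 25 == 0) {
        s1 <- s1 * exp(acc1 / 25 - 0.44)
        s2 <- s2 * exp(acc2 / 25 - 0.44)
        acc1 <- acc2 <- 0L
      }
      if (t > config$burnin) out[t - config$burnin, ] <- c(b0, b1, kap)
    }
    out
  })

  b0_mat <- sapply(draws, function(d) d[, 1])
  b1_mat <- sapply(draws, function(d) d[, 2])
  k_mat <- sapply(draws, function(d) d[, 3])
  b0_all <- as.vector(b0_mat)
  # unwrap beta0 around its circular mean so linear diagnostics apply
  b0_ctr <- circ_mean(b0_all)
  rhat <- c(beta0 = .gelman_rhat(wrap_angle(b0_mat - b0_ctr)),
            beta1 = .gelman_rhat(b1_mat),
            kappa = .gelman_rhat(k_mat))
  fit <- structure(list(
    beta0_samples = b0_all,
    beta1_samples = as.vector(b1_mat),
    kappa_samples = as.vector(k_mat),
    beta0_mean = b0_ctr,
    beta0_sd = circ_sd(b0_all),
    beta1_mean = mean(b1_mat),
    beta1_sd = stats::sd(as.vector(b1_mat)),
    kappa_mean = mean(k_mat),
    rhat = rhat,
    converged = all(rhat < 1.1, na.rm = TRUE),
    x_center = x_center,
    x_range = range(x),
    n_obs = n
  ), class = "circglm_fit")
  if (!fit$converged) {
    warning("chains may not have converged (max rhat = ",
            round(max(rhat, na.rm = TRUE), 3), ")")
  }
  fit
}

#' @export
print.circglm_fit <- function(x, ...) {
  cat("Bayesian von Mises circular regression\n")
  cat(sprintf("  n = %d, years %d-%d (centred at %.1f)\n", x$n_obs,
              x$x_range[1], x$x_range[2], x$x_center))
  cat(sprintf("  beta0 (circular): %.4f rad (sd %.4f)\n",
              x$beta0_mean, x$beta0_sd))
  cat(sprintf("  beta1 (link/yr):  %.5f (sd %.5f)\n",
              x$beta1_mean, x$beta1_sd))
  cat(sprintf("  kappa:            %.2f\n", x$kappa_mean))
  cat(sprintf("  rhat: beta0 %.3f, beta1 %.3f, kappa %.3f%s\n",
              x$rhat["beta0"], x$rhat["beta1"], x$rhat["kappa"],
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Posterior mean flowering direction at a given year
#'
#' Evaluates `mu(year) = beta0 + 2 * atan(beta1 * (year - x_center))` for
#' every posterior draw and returns the circular mean of those directions.
#'
#' @param fit a `circglm_fit`.
#' @param year predictor value.
#' @return angle in (-pi, pi].
#' @export
predict_mean_direction <- function(fit, year) {
  stopifnot(inherits(fit, "circglm_fit"))
  mu <- fit$beta0_samples +
    2 * atan(fit$beta1_samples * (year - fit$x_center))
  circ_mean(mu)
}
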