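#' Wrap angles to the interval (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped into (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  w <- ((theta + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' Circular mean direction
#'
#' Direction of the resultant vector of a sample of angles.
#'
#' @param theta numeric vector of angles in radians.
#' @return mean direction in (-pi, pi].
#' @export
circ_mean <- function(theta) {
  wrap_angle(atan2(sum(sin(theta)), sum(cos(theta))))
}

#' Mean resultant length
#'
#' @param theta numeric vector of angles in radians.
#' @return Rbar in [0, 1].
#' @export
circ_resultant <- function(theta) {
  sqrt(sum(sin(theta))^2 + sum(cos(theta))^2) / length(theta)
}

#' Circular standard deviation
#'
#' sqrt(-2 log Rbar), the standard circular dispersion measure.
#'
#' @param theta numeric vector of angles in radians.
#' @return circular SD in radians.
#' @export
circ_sd <- function(theta) {
  r <- circ_resultant(theta)
  if (r <= 0) return(Inf)
  sqrt(-2 * log(r))
}

#' Log of the modified Bessel function I0
#'
#' Computed via the exponentially scaled Bessel function so it stays finite
#' for large concentrations (besselI overflows near kappa ~ 700 otherwise).
#'
#' @param kappa non-negative numeric vector.
#' @return log I0(kappa).
#' @keywords internal
log_bessel_i0 <- function(kappa) {
  log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
}

#' Maximum-likelihood estimate of the von Mises concentration
#'
#' Inverts A1(kappa) = I1/I0 using the standard piecewise approximation
#' (Fisher 1993), accurate enough for initial values and moment estimates.
#'
#' @param rbar mean resultant length in [0, 1).
#' @return estimated kappa.
#' @export
kappa_mle <- function(rbar) {
  stopifnot(rbar >= 0, rbar <= 1)
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) wrapped-Cauchy rejection sampler. Falls back to the
#' circular uniform for very small kappa.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration, >= 0.
#' @return n angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f))) + mu
      i <- i + 1L
    }
  }
  wrap_angle(out)
}
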