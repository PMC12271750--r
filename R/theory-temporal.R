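#' Exposure-averaged inter-frame correlation factor 1/nu_psi
#'
#' The temporal correlation factor between two frames separated by `psi`
#' frame intervals, for time-integrated speckle acquired with exposure `T`
#' and dead time `delta` between frames. It is the double average of the
#' squared field correlation `g1^2` over the two exposure windows,
#' parameterized by the dimensionless exposure `x = T/tau_c` and dead-time
#' ratio `delta_ratio = delta/T`. `psi = 0` gives the within-frame
#' (autocorrelation) factor; the factor decays from 1 (fully correlated) to
#' 0 (decorrelated) as `psi` or `x` grows.
#'
#' The Gaussian family corresponds to the field correlation
#' `g1(tau) = exp(-pi tau^2 / (2 tc^2))` and the Lorentzian family to
#' `g1(tau) = exp(-|tau|/tc)`; both are normalized so that
#' `integral |g1|^2 dtau = tc` (Mandel's definition of the correlation
#' time).
#'
#' @param psi Non-negative integer frame separation(s). Vectorized.
#' @param x Positive dimensionless exposure `T/tau_c`. Vectorized.
#' @param delta_ratio Non-negative dead-time ratio `delta/T`.
#' @param family `"gaussian"` or `"lorentzian"` field correlation.
#' @return Numeric vector of correlation factors in `[0, 1]`.
#' @seealso [nu_inv_quadrature()] for the quadrature oracle,
#'   [temporal_contrast_sq()] for the contrast built from these factors.
#' @examples
#' nu_inv(0:3, x = 0.5, family = "lorentzian")
#' @export
nu_inv <- function(psi, x, delta_ratio = 0,
                   family = c("gaussian", "lorentzian")) {
  family <- match.arg(family)
  if (any(!is.finite(psi)) || any(psi < 0) || any(psi != round(psi)))
    stop("`psi` must be non-negative integers", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("`x` must be positive", call. = FALSE)
  check_scalar(delta_ratio, "delta_ratio", lower = 0)
  n <- max(length(psi), length(x))
  psi <- rep_len(psi, n)
  x <- rep_len(x, n)
  if (family == "gaussian") nu_inv_gaussian(psi, x, delta_ratio)
  else nu_inv_lorentzian(psi, x, delta_ratio)
}

# Closed form for the Gaussian family. The three exponentials all tend to 1
# as x -> 0; expm1 keeps the (1 - 2 + 1) cancellation exact.
nu_inv_gaussian <- function(psi, x, D) {
  a0 <- psi - 1 + psi * D
  a1 <- psi + psi * D
  a2 <- psi + 1 + psi * D
  s <- sqrt(pi)
  term_erf <- (erf(s * a1 * x) - erf(s * a0 * x)) * (1 - a1) +
    (erf(s * a2 * x) - erf(s * a1 * x)) * (1 + a1)
  term_exp <- expm1(-pi * a0^2 * x^2) - 2 * expm1(-pi * a1^2 * x^2) +
    expm1(-pi * a2^2 * x^2)
  term_erf / (2 * x) + term_exp / (2 * pi * x^2)
}

# Closed form for the Lorentzian family; separate psi = 0 branch because of
# the |tau| kink inside the exposure window.
nu_inv_lorentzian <- function(psi, x, D) {
  out <- numeric(length(psi))
  z <- psi == 0
  if (any(z)) {
    xz <- x[z]
    out[z] <- (2 * xz + expm1(-2 * xz)) / (2 * xz^2)
  }
  if (any(!z)) {
    p <- psi[!z]
    xp <- x[!z]
    e1 <- expm1(-2 * (p - 1 + p * D) * xp)
    e2 <- expm1(-2 * (p + p * D) * xp)
    e3 <- expm1(-2 * (p + 1 + p * D) * xp)
    out[!z] <- (e1 - 2 * e2 + e3) / (4 * xp^2)
  }
  out
}

#' Temporal speckle contrast squared with inter-frame correlation
#'
#' Expected squared temporal contrast `K_t^2` of a pixel observed over `L`
#' consecutive frames when frames up to `S` intervals apart are treated as
#' correlated:
#' `K_t^2 = 1/nu_0 - (2 / (L (L-1))) * sum_{psi=1}^{S} (L - psi) / nu_psi`.
#' With `S = 0` only the within-frame factor remains and the classic
#' independent-frame result [autocorr_contrast_sq()] is recovered. The
#' variance underlying the contrast uses the unbiased (L - 1) divisor, so
#' `L >= 2` is required.
#'
#' @param x Positive dimensionless exposure `T/tau_c`. Vectorized.
#' @param L Number of frames in the contrast window (integer `>= 2`).
#' @param S Number of frame intervals treated as correlated
#'   (`0 <= S <= L - 1`); `S = L - 1` correlates every pair in the window.
#' @inheritParams nu_inv
#' @return Numeric vector of squared contrasts (non-negative). Tiny negative
#'   round-off (magnitude below 1e-12) is truncated to zero; anything more
#'   negative signals a bug and raises an error.
#' @examples
#' sqrt(temporal_contrast_sq(c(0.01, 0.1, 1), L = 30, family = "lorentzian"))
#' @export
temporal_contrast_sq <- function(x, L, S = L - 1, delta_ratio = 0,
                                 family = c("gaussian", "lorentzian")) {
  family <- match.arg(family)
  check_scalar(L, "L", lower = 2, integer = TRUE)
  check_scalar(S, "S", lower = 0, upper = L - 1, integer = TRUE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("`x` must be positive", call. = FALSE)
  out <- nu_inv(0, x, delta_ratio, family)
  if (S >= 1) {
    psi <- seq_len(S)
    lat <- vapply(x, function(xi)
      sum((L - psi) * nu_inv(psi, xi, delta_ratio, family)), numeric(1))
    out <- out - 2 / (L * (L - 1)) * lat
  }
  if (any(out < -1e-12))
    stop("temporal contrast squared is significantly negative; ",
         "this indicates an implementation error", call. = FALSE)
  pmax(out, 0)
}

#' Independent-frame (autocorrelation-only) temporal contrast squared
#'
#' The `S = 0` limit of [temporal_contrast_sq()]: only the within-frame
#' correlation contributes, so the result depends on `x = T/tau_c` alone.
#' Gaussian: `erf(sqrt(pi) x)/x + (exp(-pi x^2) - 1)/(pi x^2)`.
#' Lorentzian: `(2x + exp(-2x) - 1) / (2 x^2)` (the classic single-exposure
#' result). Tends to 1 as `x -> 0` and to 0 as `x -> Inf`.
#'
#' @inheritParams nu_inv
#' @return Numeric vector of squared contrasts.
#' @export
autocorr_contrast_sq <- function(x, family = c("gaussian", "lorentzian")) {
  family <- match.arg(family)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("`x` must be positive", call. = FALSE)
  nu_inv(0, x, 0, family)
}

#' Pixel-size spatial correction factor beta^(1/2)
#'
#' Contrast reduction from integrating speckle over a finite pixel in the
#' absence of inter-pixel correlation:
#' `beta^(1/2)(M) = erf(sqrt(pi M))/sqrt(M) - (1 - exp(-pi M))/(pi M)`,
#' where `M` is the pixel-to-speckle-grain area ratio. `M = 0` is the point
#' pixel limit, `beta^(1/2) = 1`; a small-`M` series is used below
#' `M = 1e-4` to avoid cancellation.
#'
#' @param M Non-negative pixel-to-speckle area ratio. Vectorized.
#' @return `beta^(1/2)` values in `(0, 1]`.
#' @export
beta_half <- function(M) {
  if (any(!is.finite(M)) || any(M < 0))
    stop("`M` must be non-negative", call. = FALSE)
  out <- numeric(length(M))
  small <- M < 1e-4
  if (any(small)) {
    u <- pi * M[small]
    out[small] <- 1 - u / 6 + u^2 / 30
  }
  if (any(!small)) {
    m <- M[!small]
    out[!small] <- erf(sqrt(pi * m)) / sqrt(m) - (1 - exp(-pi * m)) / (pi * m)
  }
  out
}

#' Classic independent-frame contrast model (Lorentzian dynamics)
#'
#' The widely used extended temporal contrast model without inter-frame
#' correlation:
#' `K = alpha^(1/2) beta^(1/2)(M) [rho^2 (e^(-2x) - 1 + 2x)/(2x^2)
#'   + 4 rho (1 - rho) (e^(-x) - 1 + x)/x^2 + Cn]^(1/2)`,
#' with normalization `alpha`, dynamic-scatterer fraction `rho`, additive
#' noise term `Cn` (inside the bracket, as commonly printed), and the pixel
#' factor [beta_half()]. With `alpha = 1, rho = 1, Cn = 0, M = 0` it reduces
#' to the square root of the Lorentzian [autocorr_contrast_sq()].
#'
#' @param x Positive dimensionless exposure `T/tau_c`. Vectorized.
#' @param alpha Normalization factor in `(0, 1]`.
#' @param rho Fraction of light from dynamic scatterers, in `[0, 1]`.
#' @param Cn Non-negative additive noise term.
#' @param M Non-negative pixel-to-speckle area ratio.
#' @return Numeric vector of contrasts `K` (not squared).
#' @export
classic_contrast <- function(x, alpha = 1, rho = 1, Cn = 0, M = 0) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("`x` must be positive", call. = FALSE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(rho, "rho", lower = 0, upper = 1)
  check_scalar(Cn, "Cn", lower = 0)
  check_scalar(M, "M", lower = 0)
  dyn <- rho^2 * (expm1(-2 * x) + 2 * x) / (2 * x^2)
  het <- 4 * rho * (1 - rho) * (expm1(-x) + x) / x^2
  sqrt(alpha) * beta_half(M) * sqrt(dyn + het + Cn)
}

#' Census of frame-pair correlation types in a window of L frames
#'
#' In a window of `L` frames, each ordered frame pair `(m, n)` is classified
#' by its separation `psi = |m - n|`: `psi = 0` pairs are *central*
#' (autocorrelations, `L` of them), pairs with `1 <= psi <= S` are *lateral*
#' (`2 (L - psi)` of each type), and pairs with `psi > S` are *outsiders*,
#' treated as uncorrelated; there are `(L - S - 1)(L - S)` of those. The
#' counts always sum to `L^2`.
#'
#' @param L Number of frames (integer `>= 2`).
#' @param S Correlation window in frame intervals (`0 <= S <= L - 1`).
#' @return An object of class `"pair_census"`: a list with elements
#'   `central`, `lateral` (integer vector of length `S`, element `psi` being
#'   the count of psi-type pairs), `outsiders`, and `total`.
#' @examples
#' correlation_pair_census(L = 5, S = 2)
#' @export
correlation_pair_census <- function(L, S) {
  check_scalar(L, "L", lower = 2, integer = TRUE)
  check_scalar(S, "S", lower = 0, upper = L - 1, integer = TRUE)
  lateral <- if (S >= 1) 2L * (L - seq_len(S)) else integer(0)
  out <- list(central = as.integer(L),
              lateral = as.integer(lateral),
              outsiders = as.integer((L - S - 1) * (L - S)),
              total = as.integer(L^2))
  class(out) <- "pair_census"
  out
}

#' @export
print.pair_census <- function(x, ...) {
  cat("Frame-pair census: central =", x$central,
      "| lateral =", sum(x$lateral),
      "| outsiders =", x$outsiders,
      "| total =", x$total, "\n")
  invisible(x)
}
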