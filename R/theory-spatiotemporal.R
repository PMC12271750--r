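#' Spatial correlation factor 1/mu_{eta,xi} for pixel offsets
#'
#' Correlation factor between two pixels offset by `(eta, xi)` pixel units
#' within a sliding window, for a speckle field whose spatial correlation is
#' separable per axis. By separability the factor is the product of two 1-D
#' pixel-integral factors, each identical in form to the temporal factor
#' [nu_inv()] evaluated at `x = sqrt(M)` (the linear pixel-to-grain ratio)
#' and zero dead time:
#' `1/mu_{eta,xi} = f_eta(sqrt(M)) * f_xi(sqrt(M))`,
#' `f_psi(y) = nu_inv(psi, y, 0, family)`.
#' Symmetric in `(eta, xi)`.
#'
#' @param eta,xi Non-negative integer pixel offsets along the two axes.
#' @param M Positive pixel-to-speckle-grain area ratio.
#' @inheritParams nu_inv
#' @return The spatial correlation factor in `[0, 1]`.
#' @export
mu_inv <- function(eta, xi, M, family = c("gaussian", "lorentzian")) {
  family <- match.arg(family)
  check_scalar(M, "M", lower = 0, strict_lower = TRUE)
  y <- sqrt(M)
  nu_inv(eta, y, 0, family) * nu_inv(xi, y, 0, family)
}

#' Spatial speckle contrast squared for a correlated sliding window
#'
#' Expected squared spatial contrast `Ks^2` of an `n x n` sliding window of
#' pixels with pixel-to-grain area ratio `M`, when pixels up to `p` offsets
#' apart are treated as correlated:
#' \deqn{Ks^2 = 1/\mu_{0,0} - \frac{1}{n^2 (n^2 - 1)} \Big[
#'   4 \sum_{\eta=1}^{p} (n-\eta) n / \mu_{\eta,0}
#'   + 4 \sum_{\eta=1}^{p} (n-\eta)^2 / \mu_{\eta,\eta}
#'   + 8 \sum_{\xi=1}^{p-1} \sum_{\eta=\xi+1}^{p}
#'       (n-\eta)(n-\xi) / \mu_{\eta,\xi} \Big].}
#' The sums run over pixel offsets within the `n x n` window (hence the
#' `(n - eta)` multiplicities) while the prefactor normalizes over the
#' `n^2` window pixels. With `p = 0` the result is exactly `1/mu_{0,0}`,
#' the squared pixel-size factor [beta_half()]`^2`.
#'
#' @param M Positive pixel-to-speckle-grain area ratio.
#' @param n Odd linear window size (`n x n` pixels, `n >= 3`).
#' @param p Correlation subregion size in pixel offsets
#'   (`0 <= p <= n - 1`).
#' @inheritParams nu_inv
#' @return The squared spatial contrast (non-negative scalar).
#' @export
spatial_contrast_sq <- function(M, n, p, family = c("gaussian", "lorentzian")) {
  family <- match.arg(family)
  check_scalar(M, "M", lower = 0, strict_lower = TRUE)
  check_scalar(n, "n", lower = 3, integer = TRUE)
  if (n %% 2 == 0)
    stop("`n` must be odd (an n x n sliding window)", call. = FALSE)
  check_scalar(p, "p", lower = 0, integer = TRUE)
  if (p >= n)
    stop("`p` must satisfy p <= n - 1", call. = FALSE)
  y <- sqrt(M)
  f <- nu_inv(0:max(p, 0), y, 0, family)  # f[k + 1] = f_k(sqrt(M))
  out <- f[1]^2
  if (p >= 1) {
    eta <- seq_len(p)
    corr <- 4 * sum((n - eta) * n * f[eta + 1] * f[1]) +
      4 * sum((n - eta)^2 * f[eta + 1]^2)
    if (p >= 2) {
      for (xi in seq_len(p - 1)) {
        eta2 <- (xi + 1):p
        corr <- corr + 8 * sum((n - eta2) * (n - xi) * f[eta2 + 1] * f[xi + 1])
      }
    }
    out <- out - corr / (n^2 * (n^2 - 1))
  }
  out
}

#' Combined spatio-temporal speckle contrast squared
#'
#' By the space-time separability of the field correlation, the expected
#' squared contrast of a correlated sliding window tracked over correlated
#' frames factorizes:
#' `K^2 = alpha * Ks^2(M, n, p) * Kt^2(x, L, S) + Cn`.
#'
#' @inheritParams spatial_contrast_sq
#' @inheritParams temporal_contrast_sq
#' @param alpha Normalization factor in `(0, 1]`.
#' @param Cn Non-negative additive noise floor (added to the squared
#'   contrast).
#' @return Numeric vector (over `x`) of squared contrasts.
#' @export
spatiotemporal_contrast_sq <- function(M, n, p, x, L, S = L - 1,
                                       delta_ratio = 0,
                                       family = c("gaussian", "lorentzian"),
                                       alpha = 1, Cn = 0) {
  family <- match.arg(family)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(Cn, "Cn", lower = 0)
  alpha * spatial_contrast_sq(M, n, p, family) *
    temporal_contrast_sq(x, L, S, delta_ratio, family) + Cn
}

#' Table of beta^(1/2) calibration factors for correlated sliding windows
#'
#' The spatial contrast correction `beta^(1/2) = sqrt(Ks^2)` for the
#' standard sliding windows 3x3, 5x5, 7x7 and 9x9 with correlation
#' subregion sizes p = 1, 2, 3, 4, at the Nyquist-Shannon pixel-to-grain
#' ratio `M = 0.5` (speckle grain at least twice the pixel), for both
#' correlation families.
#'
#' @param M Positive pixel-to-speckle-grain area ratio (default 0.5, the
#'   Nyquist-Shannon sampling criterion).
#' @return A data frame with columns `n`, `p`, `family`, `beta_half`
#'   (8 rows).
#' @examples
#' table1()
#' @export
table1 <- function(M = 0.5) {
  grid <- expand.grid(family = c("gaussian", "lorentzian"),
                      i = 1:4, stringsAsFactors = FALSE)
  n <- c(3, 5, 7, 9)[grid$i]
  p <- c(1, 2, 3, 4)[grid$i]
  bh <- mapply(function(ni, pi, fam) sqrt(spatial_contrast_sq(M, ni, pi, fam)),
               n, p, grid$family)
  out <- data.frame(n = n, p = p, family = grid$family, beta_half = bh)
  out[order(out$family, out$n), c("n", "p", "family", "beta_half")]
}
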