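#' Normalized field correlation kernel
#'
#' A first-order (field) correlation function `g1(tau)` with its Mandel
#' correlation time `tc = integral |g1(tau)|^2 dtau`. The built-in families
#' are `gaussian`, `g1(tau) = exp(-pi tau^2 / (2 tc^2))`, and `lorentzian`,
#' `g1(tau) = exp(-|tau| / tc)`; both satisfy the Mandel normalization
#' exactly. A custom even function with `g1(0) = 1` may be supplied via
#' `g1`; its Mandel normalization is then checked numerically.
#'
#' @param family `"gaussian"` or `"lorentzian"`; ignored when `g1` is given.
#' @param tc Positive correlation time (time units).
#' @param g1 Optional custom correlation function of `tau`.
#' @param check Check `g1(0) = 1` and the Mandel normalization of a custom
#'   kernel (default `TRUE`).
#' @return An object of class `"g1_kernel"`: list with elements `g1`
#'   (function) and `tc`.
#' @export
g1_kernel <- function(family = c("gaussian", "lorentzian"), tc = 1,
                      g1 = NULL, check = TRUE) {
  check_scalar(tc, "tc", lower = 0, strict_lower = TRUE)
  if (is.null(g1)) {
    family <- match.arg(family)
    g1 <- if (family == "gaussian") {
      function(tau) exp(-pi * tau^2 / (2 * tc^2))
    } else {
      function(tau) exp(-abs(tau) / tc)
    }
  } else {
    if (!is.function(g1)) stop("`g1` must be a function", call. = FALSE)
    family <- "custom"
    if (check) {
      if (abs(g1(0) - 1) > 1e-12)
        stop("custom kernel must satisfy g1(0) = 1", call. = FALSE)
      mandel <- stats::integrate(function(tau) g1(tau)^2, -Inf, Inf,
                                 rel.tol = 1e-10)$value
      if (abs(mandel - tc) > 1e-6 * tc)
        warning(sprintf(paste0("custom kernel has Mandel correlation time ",
                               "%.6g, not the stated tc = %.6g"), mandel, tc))
    }
  }
  structure(list(g1 = g1, tc = tc, family = family), class = "g1_kernel")
}

#' Quadrature oracle for the inter-frame correlation factor
#'
#' Evaluates `1/nu_psi` for an arbitrary field correlation kernel by
#' adaptive quadrature of the triangular-weight single-integral form:
#' \deqn{1/\nu_\psi = \frac{1}{T^2}\Big[\int_{l_1}^{l_2}
#'   (T - T\psi - \delta\psi + \tau)\, g_1^2(\tau)\, d\tau +
#'   \int_{l_2}^{l_3} (T + T\psi + \delta\psi - \tau)\, g_1^2(\tau)\,
#'   d\tau\Big],}
#' with `l1 = (psi-1) T + psi delta`, `l2 = psi T + psi delta`,
#' `l3 = (psi+1) T + psi delta`. For `psi = 0` the lower limit is negative;
#' the kernels handle this through `|tau|`, no branching required. This is
#' the ground-truth reference against which the closed forms [nu_inv()] are
#' validated.
#'
#' @inheritParams nu_inv
#' @param kernel A [g1_kernel()]; its `tc` together with `x` fixes the
#'   exposure `T = x * tc`.
#' @param abs.tol Absolute quadrature tolerance (default `1e-10`).
#' @return The correlation factor (scalar).
#' @export
nu_inv_quadrature <- function(psi, x, delta_ratio = 0,
                              kernel = g1_kernel("gaussian"),
                              abs.tol = 1e-10) {
  check_scalar(psi, "psi", lower = 0, integer = TRUE)
  check_scalar(x, "x", lower = 0, strict_lower = TRUE)
  check_scalar(delta_ratio, "delta_ratio", lower = 0)
  stopifnot(inherits(kernel, "g1_kernel"))
  Texp <- x * kernel$tc
  delta <- delta_ratio * Texp
  l1 <- (psi - 1) * Texp + psi * delta
  l2 <- psi * Texp + psi * delta
  l3 <- (psi + 1) * Texp + psi * delta
  g1sq <- function(tau) kernel$g1(tau)^2
  q <- function(f, lo, hi) {
    r <- tryCatch(
      stats::integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = abs.tol / 2,
                       subdivisions = 1000L),
      error = function(e)
        stop(sprintf(paste0("quadrature failed on [%g, %g] ",
                            "(psi = %d, x = %g, delta_ratio = %g): %s"),
                     lo, hi, psi, x, delta_ratio, conditionMessage(e)),
             call. = FALSE))
    r$value
  }
  i1 <- q(function(tau) (Texp - Texp * psi - delta * psi + tau) * g1sq(tau),
          l1, l2)
  i2 <- q(function(tau) (Texp + Texp * psi + delta * psi - tau) * g1sq(tau),
          l2, l3)
  (i1 + i2) / Texp^2
}

# Low-accuracy 2-D double-integral form of the same factor, kept as an
# independent cross-check of the change of variables behind the triangular
# weight. Iterated adaptive quadrature; tolerances are deliberately looser.
nu_inv_quadrature_2d <- function(psi, x, delta_ratio = 0,
                                 kernel = g1_kernel("gaussian")) {
  stopifnot(inherits(kernel, "g1_kernel"))
  Texp <- x * kernel$tc
  delta <- delta_ratio * Texp
  a <- psi * (Texp + delta)
  b <- (psi + 1) * Texp + psi * delta
  inner <- function(t) {
    vapply(t, function(ti) {
      # split at tp = ti where g1(ti - tp) may have a |tau| kink (psi = 0)
      cuts <- unique(c(a, if (ti > a && ti < b) ti, b))
      sum(vapply(seq_len(length(cuts) - 1L), function(j)
        stats::integrate(function(tp) kernel$g1(ti - tp)^2,
                         cuts[j], cuts[j + 1L], rel.tol = 1e-9,
                         abs.tol = 1e-12)$value, numeric(1)))
    }, numeric(1))
  }
  stats::integrate(inner, 0, Texp, rel.tol = 1e-7,
                   abs.tol = 1e-10)$value / Texp^2
}
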