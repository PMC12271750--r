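#' Configuration for a synthetic dynamic-speckle stack
#'
#' Full recipe for generating a time-integrated dynamic speckle stack with
#' known ground truth: field decorrelation time `tau_c`, exposure `T`, dead
#' time `delta`, frame count `L`, image size, target pixel-to-speckle-grain
#' area ratio `speckle_M`, correlation family, and the number of
#' within-exposure integration sub-steps.
#'
#' @param tau_c Field correlation time (seconds, `> 0`), Mandel-normalized.
#' @param exposure Exposure time `T` per frame (seconds, `> 0`).
#' @param delta Dead time between frames (seconds, `>= 0`).
#' @param L Number of frames (`>= 2`).
#' @param height,width Image size in pixels.
#' @param speckle_M Target pixel-to-speckle-grain area ratio, in
#'   `(0, pi/4]` (the speckle grain must be resolvable on the grid).
#' @param family `"gaussian"` or `"lorentzian"` temporal field correlation.
#' @param substeps Integration sub-samples per exposure (`>= 1`, default
#'   32). The within-exposure sub-step should not exceed `tau_c / 5`.
#' @param seed Integer RNG seed; identical configs give bit-identical
#'   stacks.
#' @param mean_intensity Target mean intensity (arbitrary units, `> 0`).
#' @param bit_depth Optional integer quantization depth (e.g. 12); `NULL`
#'   (default) keeps floating-point intensities.
#' @param rho Fraction of dynamic light in `(0, 1]`; `rho < 1` adds a
#'   static speckle field component (for exercising the classic
#'   mixed-scatterer model).
#' @param max_timeline Cap on the `L * substeps` timeline length for the
#'   Gaussian-family covariance factorization (default 4096).
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(tau_c, exposure = 1, delta = 0, L = 30,
                              height = 256, width = 256, speckle_M = 0.5,
                              family = c("lorentzian", "gaussian"),
                              substeps = 32, seed = 1, mean_intensity = 1,
                              bit_depth = NULL, rho = 1,
                              max_timeline = 4096) {
  family <- match.arg(family)
  check_scalar(tau_c, "tau_c", lower = 0, strict_lower = TRUE)
  check_scalar(exposure, "exposure", lower = 0, strict_lower = TRUE)
  check_scalar(delta, "delta", lower = 0)
  check_scalar(L, "L", lower = 2, integer = TRUE)
  check_scalar(height, "height", lower = 4, integer = TRUE)
  check_scalar(width, "width", lower = 4, integer = TRUE)
  check_scalar(speckle_M, "speckle_M", lower = 0, upper = pi / 4,
               strict_lower = TRUE)
  check_scalar(substeps, "substeps", lower = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(mean_intensity, "mean_intensity", lower = 0,
               strict_lower = TRUE)
  if (!is.null(bit_depth))
    check_scalar(bit_depth, "bit_depth", lower = 1, upper = 32,
                 integer = TRUE)
  check_scalar(rho, "rho", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(max_timeline, "max_timeline", lower = 2, integer = TRUE)
  structure(list(tau_c = tau_c, exposure = exposure, delta = delta, L = L,
                 height = height, width = width, speckle_M = speckle_M,
                 family = family, substeps = substeps, seed = seed,
                 mean_intensity = mean_intensity, bit_depth = bit_depth,
                 rho = rho, max_timeline = max_timeline),
            class = "simulation_config")
}

# One fully developed speckle field: circular complex Gaussian phasors on
# an elliptical pupil (FFT-frequency layout), Fourier-transformed to the
# image plane and normalized to unit mean intensity. The pupil occupancy
# fraction equals the coherence-area ratio M exactly (Parseval), so the
# rendered pixel-to-grain area ratio is speckle_M by construction.
speckle_pupil_mask <- function(height, width, M) {
  rr <- height * sqrt(M / pi)
  rc <- width * sqrt(M / pi)
  fr <- c(0:(height %/% 2), -rev(seq_len(height - height %/% 2 - 1)))
  fc <- c(0:(width %/% 2), -rev(seq_len(width - width %/% 2 - 1)))
  outer((fr / rr)^2, (fc / rc)^2, "+") <= 1
}

speckle_field <- function(mask, n_pupil) {
  d <- dim(mask)
  z <- matrix(complex(real = rnorm(prod(d), sd = 1 / sqrt(2)),
                      imaginary = rnorm(prod(d), sd = 1 / sqrt(2))),
              d[1], d[2])
  stats::fft(z * mask) / sqrt(n_pupil)
}

# Cholesky factor of the timeline field covariance with an escalating
# diagonal nugget; the Gaussian kernel is near-singular for dense sampling.
chol_with_nugget <- function(C) {
  for (nug in c(1e-12, 1e-10, 1e-8, 1e-6)) {
    U <- tryCatch(chol(C + diag(nug, nrow(C))), error = function(e) NULL)
    if (!is.null(U)) return(U)
  }
  # last resort: eigen factorization with clipped spectrum
  e <- eigen(C, symmetric = TRUE)
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0))))
}

#' Simulate a time-integrated dynamic-speckle stack
#'
#' Generates `L` frames of fully developed dynamic speckle whose complex
#' field has the spatial statistics of an elliptical-pupil speckle pattern
#' with pixel-to-grain area ratio `speckle_M` and whose temporal field
#' correlation equals `g1` of the configured family with the configured
#' `tau_c`. Each frame integrates the instantaneous intensity over the
#' exposure by midpoint averaging of `substeps` sub-samples; the dead time
#' `delta` is skipped between frames.
#'
#' Temporal evolution: the Lorentzian family uses an exact first-order
#' autoregressive (Ornstein-Uhlenbeck) update of the field between
#' sub-steps; the Gaussian family uses a Cholesky factorization of the full
#' sub-step timeline covariance (exact, at the cost of an
#' `L * substeps` square factor, capped by `max_timeline`). Pixels are
#' point samples of the field, so per-pixel temporal statistics follow the
#' temporal model directly with no pixel-area averaging.
#'
#' @param config A [simulation_config()].
#' @return A [speckle_stack()] whose `meta` records the ground truth
#'   (`tau_c`, `family`, `speckle_M`, `seed`, `substeps`, `rho`, `x`,
#'   `delta_ratio`).
#' @examples
#' cfg <- simulation_config(tau_c = 10, L = 4, height = 32, width = 32,
#'                          substeps = 4, seed = 7)
#' st <- simulate_stack(cfg)
#' @export
simulate_stack <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  dt <- cf$exposure / cf$substeps
  if (dt > cf$tau_c / 5)
    warning(sprintf(paste0("within-exposure sub-step (%g s) exceeds tau_c/5 ",
                           "(%g s); the exposure integral is coarsely ",
                           "sampled"), dt, cf$tau_c / 5))
  frames <- with_seed(cf$seed, simulate_frames(cf, dt))
  frames <- frames * cf$mean_intensity
  if (!is.null(cf$bit_depth))
    frames <- pmin(round(frames), 2^cf$bit_depth - 1)
  speckle_stack(frames, exposure = cf$exposure, delta = cf$delta,
                meta = list(tau_c = cf$tau_c, family = cf$family,
                            speckle_M = cf$speckle_M, seed = cf$seed,
                            substeps = cf$substeps, rho = cf$rho,
                            x = cf$exposure / cf$tau_c,
                            delta_ratio = cf$delta / cf$exposure))
}

simulate_frames <- function(cf, dt) {
  H <- cf$height; W <- cf$width; L <- cf$L; s <- cf$substeps
  mask <- speckle_pupil_mask(H, W, cf$speckle_M)
  n_pupil <- sum(mask)
  # midpoint sub-sample times within each exposure window
  times <- as.vector(vapply(0:(L - 1), function(f)
    f * (cf$exposure + cf$delta) + (seq_len(s) - 0.5) * dt, numeric(s)))
  static <- if (cf$rho < 1) speckle_field(mask, n_pupil) else NULL
  frames <- if (cf$family == "lorentzian") {
    frames_ar1(cf, mask, n_pupil, times, static)
  } else {
    frames_chol(cf, mask, n_pupil, times, static)
  }
  array(frames, dim = c(H, W, L))
}

# Lorentzian family: g1(tau) = exp(-|tau|/tc) is the OU correlation, so the
# field update E <- r E + sqrt(1 - r^2) G with a fresh independent speckle
# field G is exact for any (possibly unequal) time step.
frames_ar1 <- function(cf, mask, n_pupil, times, static) {
  H <- cf$height; W <- cf$width; L <- cf$L; s <- cf$substeps
  frames <- array(0, dim = c(H, W, L))
  E <- speckle_field(mask, n_pupil)
  a <- sqrt(cf$rho); b <- sqrt(1 - cf$rho)
  for (i in seq_along(times)) {
    if (i > 1) {
      r <- exp(-(times[i] - times[i - 1]) / cf$tau_c)
      E <- r * E + sqrt(1 - r^2) * speckle_field(mask, n_pupil)
    }
    Et <- if (is.null(static)) E else a * E + b * static
    f <- (i - 1) %/% s + 1
    frames[, , f] <- frames[, , f] + Re(Et * Conj(Et)) / s
  }
  frames
}

# Gaussian family: exact covariance factorization over the sub-step
# timeline. Independent speckle fields F_k are mixed by the Cholesky factor
# of C[i, j] = g1(t_i - t_j), giving a field timeline with the target
# temporal correlation at every pixel; pixels are processed in chunks to
# bound memory.
frames_chol <- function(cf, mask, n_pupil, times, static) {
  n <- length(times)
  if (n > cf$max_timeline)
    stop(sprintf(paste0("Gaussian-family timeline (L * substeps = %d) ",
                        "exceeds max_timeline = %d; reduce substeps or ",
                        "raise the cap"), n, cf$max_timeline), call. = FALSE)
  H <- cf$height; W <- cf$width; L <- cf$L; s <- cf$substeps
  npix <- H * W
  Cm <- exp(-pi * outer(times, times, "-")^2 / (2 * cf$tau_c^2))
  U <- chol_with_nugget(Cm)  # C = t(U) %*% U, so rows of t(U) mix modes
  Fm <- matrix(0i, n, npix)
  for (k in seq_len(n)) Fm[k, ] <- as.vector(speckle_field(mask, n_pupil))
  agg <- matrix(0, L, n)  # frame-averaging operator over sub-steps
  for (f in seq_len(L)) agg[f, ((f - 1) * s + 1):(f * s)] <- 1 / s
  a <- sqrt(cf$rho); b <- sqrt(1 - cf$rho)
  mix <- t(U)
  frames <- matrix(0, L, npix)
  chunk <- 8192L
  for (lo in seq(1L, npix, by = chunk)) {
    idx <- lo:min(lo + chunk - 1L, npix)
    E <- mix %*% Fm[, idx, drop = FALSE]
    if (!is.null(static))
      E <- a * E + b * matrix(as.vector(static)[idx], n, length(idx),
                              byrow = TRUE)
    frames[, idx] <- agg %*% Re(E * Conj(E))
  }
  array(t(frames), dim = c(H, W, L))
}
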