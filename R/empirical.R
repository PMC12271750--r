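#' Per-pixel temporal speckle contrast map
#'
#' For each pixel, the temporal contrast `K = s / m` over a window of
#' `L_window` consecutive frames, where `m` is the temporal mean and `s`
#' the square root of the *unbiased* temporal variance (divisor
#' `L_window - 1`). Pixels with zero temporal mean are flagged `NA`, never
#' infinite.
#'
#' @param stack A [speckle_stack()].
#' @param L_window Number of frames in the window (default: all frames;
#'   must be `>= 2`).
#' @param start Index of the first frame of the window (1-based).
#' @return A `height x width` numeric matrix of contrasts (`NA` where the
#'   temporal mean is zero).
#' @export
temporal_contrast_map <- function(stack, L_window = n_frames(stack),
                                  start = 1) {
  stopifnot(inherits(stack, "speckle_stack"))
  L <- n_frames(stack)
  check_scalar(L_window, "L_window", lower = 2, integer = TRUE)
  check_scalar(start, "start", lower = 1, integer = TRUE)
  if (start + L_window - 1 > L)
    stop("window [start, start + L_window - 1] exceeds the stack length",
         call. = FALSE)
  d <- dim(stack$frames)
  X <- matrix(stack$frames[, , start:(start + L_window - 1)],
              nrow = d[1] * d[2])
  m <- rowMeans(X)
  v <- rowSums((X - m)^2) / (L_window - 1)
  K <- sqrt(v) / m
  K[m <= 0] <- NA_real_
  matrix(K, d[1], d[2])
}

#' Mean and standard deviation of a contrast map over a region of interest
#'
#' @param map A contrast map matrix (as from [temporal_contrast_map()]).
#' @param roi Optional region `c(row_min, row_max, col_min, col_max)`,
#'   1-based inclusive; `NULL` means the full map.
#' @return A list with `mean`, `sd` and `n_valid` (count of non-`NA`
#'   pixels used).
#' @export
roi_contrast_summary <- function(map, roi = NULL) {
  if (!is.matrix(map)) stop("`map` must be a matrix", call. = FALSE)
  roi <- resolve_roi(roi, dim(map))
  vals <- map[roi[1]:roi[2], roi[3]:roi[4]]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L)
    stop("no valid pixels in the region of interest", call. = FALSE)
  list(mean = mean(vals), sd = stats::sd(vals), n_valid = length(vals))
}

#' Ensemble-ratio temporal contrast of a region of interest
#'
#' Estimates the squared temporal contrast as the ratio of ROI-averaged
#' moments, `K^2 = mean(v) / mean(m)^2`, where `v` and `m` are the
#' per-pixel unbiased temporal variance and temporal mean. This estimates
#' the ensemble quantity `E[variance] / E[intensity]^2` that the temporal
#' model predicts, and unlike the mean of per-pixel `s/m` values it is free
#' of the finite-window Jensen bias (see the package vignette).
#'
#' @inheritParams temporal_contrast_map
#' @param roi Optional region `c(row_min, row_max, col_min, col_max)`.
#' @return The ROI contrast `K` (scalar).
#' @export
roi_contrast_ensemble <- function(stack, L_window = n_frames(stack),
                                  start = 1, roi = NULL) {
  stopifnot(inherits(stack, "speckle_stack"))
  L <- n_frames(stack)
  check_scalar(L_window, "L_window", lower = 2, integer = TRUE)
  if (start + L_window - 1 > L)
    stop("window exceeds the stack length", call. = FALSE)
  d <- dim(stack$frames)
  roi <- resolve_roi(roi, d[1:2])
  sub <- stack$frames[roi[1]:roi[2], roi[3]:roi[4],
                      start:(start + L_window - 1), drop = FALSE]
  X <- matrix(sub, nrow = dim(sub)[1] * dim(sub)[2])
  m <- rowMeans(X)
  v <- rowSums((X - m)^2) / (L_window - 1)
  if (mean(m) <= 0) stop("zero mean intensity in ROI", call. = FALSE)
  sqrt(mean(v)) / mean(m)
}

#' Frame-correlation curve of a speckle stack
#'
#' Pearson correlation coefficient between a reference frame and each later
#' frame, over the pixels of a region of interest, as a function of the lag
#' `psi * (T + delta)`. This is the curve from which the decorrelation time
#' is fitted.
#'
#' @param stack A [speckle_stack()] with at least 3 frames.
#' @param ref_index Reference frame (1-based, default the first frame).
#' @param roi Optional region `c(row_min, row_max, col_min, col_max)`.
#' @return A data frame of class `"correlation_curve"` with columns `psi`,
#'   `lag` (seconds) and `coefficient`.
#' @export
frame_correlation_curve <- function(stack, ref_index = 1, roi = NULL) {
  stopifnot(inherits(stack, "speckle_stack"))
  L <- n_frames(stack)
  if (L < 3) stop("need at least 3 frames", call. = FALSE)
  check_scalar(ref_index, "ref_index", lower = 1, upper = L - 1,
               integer = TRUE)
  d <- dim(stack$frames)
  roi <- resolve_roi(roi, d[1:2])
  ref <- as.vector(stack$frames[roi[1]:roi[2], roi[3]:roi[4], ref_index])
  if (stats::sd(ref) == 0)
    stop("reference frame has zero variance over the ROI", call. = FALSE)
  psi <- seq_len(L - ref_index)
  coef <- vapply(psi, function(k) {
    v <- as.vector(stack$frames[roi[1]:roi[2], roi[3]:roi[4], ref_index + k])
    if (stats::sd(v) == 0)
      stop("frame ", ref_index + k, " has zero variance over the ROI",
           call. = FALSE)
    stats::cor(ref, v)
  }, numeric(1))
  out <- data.frame(psi = psi,
                    lag = psi * (stack$exposure + stack$delta),
                    coefficient = coef)
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Fit the decorrelation time to a frame-correlation curve
#'
#' Least-squares fit of the frame-correlation coefficients to the intensity
#' correlation implied by the chosen field correlation family. With
#' `use_siegert = TRUE` (default) the curve is fitted to
#' `|g1|^2` (Siegert relation `g2 - 1 = |g1|^2`): Gaussian
#' `exp(-pi tau^2 / tau_c^2)`, Lorentzian `exp(-2 tau / tau_c)`. With
#' `use_siegert = FALSE` the curve is fitted to `g1` itself. The single
#' parameter `tau_c` is found by golden-section search on `log(tau_c)`.
#'
#' @param curve A [frame_correlation_curve()] result, or any data frame
#'   with columns `lag` and `coefficient` (at least 5 points).
#' @param family `"gaussian"` or `"lorentzian"`.
#' @param use_siegert Fit `|g1|^2` (`TRUE`, default) or `g1` (`FALSE`).
#' @return An object of class `"tau_fit"`: list with `tau_c`, `family`,
#'   `use_siegert`, `rss`, `n_points` and the model function `predict`.
#' @export
fit_correlation_time <- function(curve,
                                 family = c("gaussian", "lorentzian"),
                                 use_siegert = TRUE) {
  family <- match.arg(family)
  if (!all(c("lag", "coefficient") %in% names(curve)))
    stop("`curve` needs columns `lag` and `coefficient`", call. = FALSE)
  lag <- curve$lag
  y <- curve$coefficient
  if (length(lag) < 5) stop("need at least 5 points", call. = FALSE)
  if (any(lag <= 0) || any(diff(lag) <= 0))
    stop("lags must be positive and strictly increasing", call. = FALSE)
  model <- correlation_model(family, use_siegert)
  rss_fun <- function(ltau) sum((y - model(lag, exp(ltau)))^2)
  span <- c(log(min(lag)) - 7, log(max(lag)) + 7)
  opt <- stats::optimize(rss_fun, interval = span, tol = 1e-10)
  if (!is.finite(opt$objective))
    stop("tau_c fit failed to converge; lags in [", min(lag), ", ",
         max(lag), "], initial span exp(", span[1], "..", span[2], ")",
         call. = FALSE)
  tau <- exp(opt$minimum)
  structure(list(tau_c = tau, family = family, use_siegert = use_siegert,
                 rss = opt$objective, n_points = length(lag),
                 predict = function(l) model(l, tau)),
            class = "tau_fit")
}

correlation_model <- function(family, use_siegert) {
  if (family == "gaussian") {
    if (use_siegert) function(l, tau) exp(-pi * l^2 / tau^2)
    else function(l, tau) exp(-pi * l^2 / (2 * tau^2))
  } else {
    if (use_siegert) function(l, tau) exp(-2 * l / tau)
    else function(l, tau) exp(-l / tau)
  }
}

#' @export
print.tau_fit <- function(x, ...) {
  cat(sprintf("tau_c = %g s (%s, %s fit; rss = %.4g over %d points)\n",
              x$tau_c, x$family,
              if (x$use_siegert) "Siegert |g1|^2" else "g1",
              x$rss, x$n_points))
  invisible(x)
}

#' Bin frames to emulate longer exposures
#'
#' Averages non-overlapping groups of `omega` consecutive frames, emulating
#' acquisition with a longer effective exposure. With `gap_policy =
#' "include"` (default) the effective exposure spans the integrated light
#' plus the interior dead times, `T_eff = omega T + (omega - 1) delta`;
#' with `"exclude"` it counts integrated light only, `T_eff = omega T`.
#' The inter-group dead time `delta` is unchanged.
#'
#' @param stack A [speckle_stack()].
#' @param omega Number of frames per bin (`1 <= omega <= L`).
#' @param gap_policy Whether `T_eff` includes interior dead times.
#' @return A [speckle_stack()] with `floor(L / omega)` frames and updated
#'   exposure metadata.
#' @export
bin_frames <- function(stack, omega, gap_policy = c("include", "exclude")) {
  stopifnot(inherits(stack, "speckle_stack"))
  gap_policy <- match.arg(gap_policy)
  L <- n_frames(stack)
  check_scalar(omega, "omega", lower = 1, upper = L, integer = TRUE)
  Lp <- L %/% omega
  d <- dim(stack$frames)
  if (omega == 1L) {
    out <- stack$frames
  } else {
    X <- matrix(stack$frames[, , seq_len(Lp * omega)], nrow = d[1] * d[2])
    out <- array(0, dim = c(d[1], d[2], Lp))
    for (g in seq_len(Lp)) {
      cols <- ((g - 1) * omega + 1):(g * omega)
      out[, , g] <- rowMeans(X[, cols, drop = FALSE])
    }
  }
  T_eff <- if (gap_policy == "include")
    omega * stack$exposure + (omega - 1) * stack$delta
  else omega * stack$exposure
  speckle_stack(out, exposure = T_eff, delta = stack$delta,
                meta = c(stack$meta, list(omega = omega)))
}

#' Time history of the speckle pattern (THSP)
#'
#' Extracts one image column across all frames: the result is a
#' `height x L` matrix whose row `r`, column `t` is frame `t`'s intensity
#' at `(r, column)`. Horizontal stripes correspond to speckle grains that
#' persist over frames; shorter stripes indicate faster dynamics.
#'
#' @param stack A [speckle_stack()].
#' @param column Image column to track (1-based; default the central
#'   column).
#' @return A `height x L` numeric matrix.
#' @export
thsp <- function(stack, column = (dim(stack$frames)[2] + 1) %/% 2) {
  stopifnot(inherits(stack, "speckle_stack"))
  d <- dim(stack$frames)
  check_scalar(column, "column", lower = 1, upper = d[2], integer = TRUE)
  stack$frames[, column, ]
}

#' Mean horizontal run length of a binarized THSP
#'
#' Binarizes a THSP at its global median and returns the mean length of the
#' constant runs along the time axis. Slower dynamics leave speckle grains
#' unchanged over more frames, giving longer runs.
#'
#' @param thsp_matrix A THSP matrix from [thsp()].
#' @return Mean run length (frames).
#' @export
thsp_run_length <- function(thsp_matrix) {
  if (!is.matrix(thsp_matrix)) stop("`thsp_matrix` must be a matrix",
                                    call. = FALSE)
  b <- thsp_matrix > stats::median(thsp_matrix)
  runs <- unlist(lapply(seq_len(nrow(b)), function(r) rle(b[r, ])$lengths))
  mean(runs)
}

#' Temporal contrast versus dimensionless exposure by frame binning
#'
#' Replays the standard slow-dynamics experiment on a stack with known (or
#' fitted) `tau_c`: for each `omega`, frames are binned ([bin_frames()]),
#' the per-pixel temporal contrast map is computed over the first
#' `L_window` binned frames, and summarized over the ROI. The dimensionless
#' exposure is `x = T_eff / tau_c`.
#'
#' @param stack A [speckle_stack()].
#' @param omegas Integer vector of bin sizes.
#' @param L_window Frames per contrast window after binning.
#' @param tau_c Decorrelation time used to form `x` (seconds).
#' @param roi Optional region `c(row_min, row_max, col_min, col_max)`.
#' @param estimator `"per_pixel"` (mean and sd of the per-pixel contrast
#'   map, as conventionally reported) or `"ensemble"`
#'   ([roi_contrast_ensemble()], the bias-free moment-ratio estimator).
#' @return A data frame with columns `omega`, `T_eff`, `x`, `mean_K`,
#'   `sd_K` (`sd_K` is `NA` for the ensemble estimator).
#' @export
contrast_vs_x_experiment <- function(stack, omegas, L_window, tau_c,
                                     roi = NULL,
                                     estimator = c("per_pixel", "ensemble")) {
  stopifnot(inherits(stack, "speckle_stack"))
  estimator <- match.arg(estimator)
  check_scalar(tau_c, "tau_c", lower = 0, strict_lower = TRUE)
  if (any(omegas < 1) || any(omegas != round(omegas)))
    stop("`omegas` must be positive integers", call. = FALSE)
  if (max(omegas) * L_window > n_frames(stack))
    stop("stack too short for max(omegas) * L_window frames", call. = FALSE)
  rows <- lapply(omegas, function(w) {
    binned <- bin_frames(stack, w)
    if (estimator == "per_pixel") {
      map <- temporal_contrast_map(binned, L_window = L_window)
      s <- roi_contrast_summary(map, roi)
      data.frame(omega = w, T_eff = binned$exposure,
                 x = binned$exposure / tau_c,
                 mean_K = s$mean, sd_K = s$sd)
    } else {
      K <- roi_contrast_ensemble(binned, L_window = L_window, roi = roi)
      data.frame(omega = w, T_eff = binned$exposure,
                 x = binned$exposure / tau_c,
                 mean_K = K, sd_K = NA_real_)
    }
  })
  do.call(rbind, rows)
}

#' Fit the correlated temporal contrast model to a contrast-vs-x curve
#'
#' Least-squares fit of
#' `K_model(x) = sqrt(alpha * Kt^2(x * tau_scale, L, S, delta_ratio) + Cn)`
#' to measured `(x, K)` points, freeing any subset of `alpha`
#' (normalization), `Cn` (noise floor) and `tau_scale` (rescaling of the
#' assumed decorrelation time). Parameters not freed are held at
#' `alpha = 1`, `Cn = 0`, `tau_scale = 1`.
#'
#' @param x Dimensionless exposures of the measured points.
#' @param K Measured contrasts.
#' @param family `"gaussian"` or `"lorentzian"`.
#' @param L,S,delta_ratio Temporal model window parameters (see
#'   [temporal_contrast_sq()]).
#' @param free Character subset of `c("alpha", "Cn", "tau_scale")` to
#'   optimize (non-empty).
#' @return An object of class `"contrast_fit"`: list with `alpha`, `Cn`,
#'   `tau_scale`, `free`, `rss`, `n_points` and `predict(x)`.
#' @export
fit_contrast_model <- function(x, K, family = c("gaussian", "lorentzian"),
                               L, S = L - 1, delta_ratio = 0,
                               free = "alpha") {
  family <- match.arg(family)
  if (length(x) != length(K) || length(x) < 3)
    stop("need at least 3 (x, K) points", call. = FALSE)
  free <- match.arg(free, c("alpha", "Cn", "tau_scale"), several.ok = TRUE)
  fixed <- c(alpha = 1, Cn = 0, tau_scale = 1)
  lower <- c(alpha = 1e-8, Cn = 0, tau_scale = 1e-6)
  upper <- c(alpha = 10, Cn = 1, tau_scale = 1e6)
  kfun <- function(x, alpha, Cn, tau_scale)
    sqrt(alpha * temporal_contrast_sq(x * tau_scale, L, S, delta_ratio,
                                      family) + Cn)
  # fixed parameters live in the formula environment; freed ones in start
  env <- list2env(c(list(kfun = kfun),
                    as.list(fixed[setdiff(names(fixed), free)])),
                  parent = environment())
  form <- K ~ kfun(x, alpha, Cn, tau_scale)
  environment(form) <- env
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(x = x, K = K),
                      start = as.list(fixed[free]),
                      lower = lower[free], upper = upper[free],
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
    error = function(e)
      stop("model fit did not converge: ", conditionMessage(e),
           "; starting values were ",
           paste(names(fixed[free]), fixed[free], sep = " = ",
                 collapse = ", "), call. = FALSE))
  pars <- fixed
  pars[free] <- unlist(stats::coef(fit))[free]
  opt <- list(value = sum(stats::residuals(fit)^2))
  structure(list(alpha = unname(pars["alpha"]), Cn = unname(pars["Cn"]),
                 tau_scale = unname(pars["tau_scale"]), free = free,
                 rss = opt$value, n_points = length(x),
                 predict = function(xx)
                   sqrt(pars["alpha"] *
                          temporal_contrast_sq(xx * pars["tau_scale"], L, S,
                                               delta_ratio, family) +
                          pars["Cn"])),
            class = "contrast_fit")
}

#' @export
print.contrast_fit <- function(x, ...) {
  cat(sprintf(paste0("contrast model fit: alpha = %.6g, Cn = %.6g, ",
                     "tau_scale = %.6g (free: %s); rss = %.4g over %d ",
                     "points\n"),
              x$alpha, x$Cn, x$tau_scale, paste(x$free, collapse = ", "),
              x$rss, x$n_points))
  invisible(x)
}
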