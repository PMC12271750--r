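test_that("contrast map implements the unbiased two-frame formula", {
  a <- c(1, 2, 3, 0.5)
  b <- c(4, 2.5, 1, 9)
  st <- speckle_stack(array(c(a, b), dim = c(2, 2, 2)), exposure = 1)
  map <- temporal_contrast_map(st)
  # mean (a+b)/2, unbiased variance (a-b)^2/2 => K = sqrt(2)|a-b|/(a+b)
  expect_equal(as.vector(map), sqrt(2) * abs(a - b) / (a + b))
})

test_that("contrast map handles degenerate pixels and scale", {
  st <- speckle_stack(array(rep(3, 4 * 4 * 5), dim = c(4, 4, 5)),
                      exposure = 1)
  expect_true(all(temporal_contrast_map(st) == 0))
  # zero-mean pixels are NA, never infinite
  fr <- array(rexp(4 * 4 * 5), dim = c(4, 4, 5))
  fr[1, 1, ] <- 0
  map <- temporal_contrast_map(speckle_stack(fr, exposure = 1))
  expect_true(is.na(map[1, 1]))
  expect_true(all(is.finite(map[-1])))
  # scale invariance: K is a ratio
  st2 <- speckle_stack(fr * 37.5, exposure = 1)
  expect_equal(temporal_contrast_map(st2), map)
  # per-pixel K approaches 1 for many i.i.d. exponential frames
  big <- iid_exponential_stack(L = 400, seed = 4)
  expect_equal(roi_contrast_summary(temporal_contrast_map(big))$mean, 1,
               tolerance = 0.02)
  expect_error(temporal_contrast_map(st, L_window = 1), "L_window")
  expect_error(temporal_contrast_map(st, L_window = 5, start = 2), "window")
})

test_that("ROI summaries mask invalid pixels", {
  m <- matrix(0.25, 10, 10)
  s <- roi_contrast_summary(m)
  expect_equal(s$mean, 0.25)
  expect_equal(s$sd, 0)
  m[, 1:5] <- NA
  s2 <- roi_contrast_summary(m)
  expect_equal(s2$n_valid, 50L)
  expect_equal(s2$mean, 0.25)
  expect_error(roi_contrast_summary(matrix(NA_real_, 3, 3)), "valid")
  expect_error(roi_contrast_summary(m, roi = c(0, 5, 1, 5)), "bounds")
  # sub-ROI selection
  m2 <- matrix(seq_len(16) / 16, 4, 4)
  expect_equal(roi_contrast_summary(m2, roi = c(1, 1, 1, 1))$mean, m2[1, 1])
})

test_that("frame-correlation curve behaves on reference stacks", {
  fr <- array(rexp(32 * 32), dim = c(32, 32, 1))[, , rep(1, 6)]
  st <- speckle_stack(array(fr, dim = c(32, 32, 6)), exposure = 1,
                      delta = 0.5)
  curve <- frame_correlation_curve(st)
  expect_equal(curve$coefficient, rep(1, 5))
  expect_equal(curve$lag, (1:5) * 1.5)  # psi (T + delta)
  # independent frames decorrelate to ~0
  st2 <- iid_exponential_stack(h = 64, w = 64, L = 10, seed = 2)
  expect_lt(max(abs(frame_correlation_curve(st2)$coefficient)), 0.06)
  # constant frames carry no correlation information
  st3 <- speckle_stack(array(1, dim = c(8, 8, 4)), exposure = 1)
  expect_error(frame_correlation_curve(st3), "variance")
})

test_that("decorrelation-time fits recover noise-free curves exactly", {
  lag <- (1:60) * 1.347
  lor <- data.frame(lag = lag, coefficient = exp(-2 * lag / 100))
  fit <- fit_correlation_time(lor, "lorentzian")
  expect_equal(fit$tau_c, 100, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  gau <- data.frame(lag = lag, coefficient = exp(-pi * lag^2 / 200^2))
  expect_equal(fit_correlation_time(gau, "gaussian")$tau_c, 200,
               tolerance = 1e-6)
  # direct-g1 fits (no Siegert relation)
  g1l <- data.frame(lag = lag, coefficient = exp(-lag / 80))
  expect_equal(fit_correlation_time(g1l, "lorentzian",
                                    use_siegert = FALSE)$tau_c, 80,
               tolerance = 1e-6)
  # the wrong family fits strictly worse
  expect_gt(fit_correlation_time(lor, "gaussian")$rss, fit$rss)
  expect_error(fit_correlation_time(lor[1:3, ], "lorentzian"), "5 points")
})

test_that("simulated stack recovers its ground-truth decorrelation time", {
  st <- sim_stack_cached()  # tau_c = 60 s, Lorentzian
  curve <- frame_correlation_curve(st)
  fit <- fit_correlation_time(curve, "lorentzian")
  expect_equal(fit$tau_c, 60, tolerance = 0.10)
})

test_that("frame binning averages groups and tracks effective exposure", {
  fr <- array(rexp(8 * 8 * 5), dim = c(8, 8, 5))
  st <- speckle_stack(fr, exposure = 1, delta = 0.347)
  expect_equal(bin_frames(st, 1)$frames, fr)
  b2 <- bin_frames(st, 2)
  expect_equal(n_frames(b2), 2L)
  expect_equal(b2$frames[, , 1], (fr[, , 1] + fr[, , 2]) / 2)
  expect_equal(b2$frames[, , 2], (fr[, , 3] + fr[, , 4]) / 2)
  expect_equal(b2$exposure, 2 * 1 + 1 * 0.347)
  expect_equal(b2$delta, 0.347)
  expect_equal(bin_frames(st, 2, gap_policy = "exclude")$exposure, 2)
  # a constant stack stays constant under any binning
  cst <- speckle_stack(array(2, dim = c(4, 4, 6)), exposure = 1)
  expect_true(all(bin_frames(cst, 3)$frames == 2))
  expect_error(bin_frames(st, 6), "omega")
})

test_that("THSP extracts pixel-time history and tracks dynamics speed", {
  fr <- array(seq_len(4 * 6 * 3), dim = c(4, 6, 3))
  st <- speckle_stack(fr, exposure = 1)
  m <- thsp(st, column = 2)
  expect_equal(dim(m), c(4L, 3L))
  expect_equal(m[3, 2], fr[3, 2, 2])
  # static sample: every row constant
  sst <- speckle_stack(array(rep(rexp(16), 5), dim = c(4, 4, 5)),
                       exposure = 1)
  expect_true(all(apply(thsp(sst, 1), 1, sd) == 0))
  # slower dynamics give longer horizontal stripes
  mk <- function(tau_c, seed) simulate_stack(simulation_config(
    tau_c = tau_c, exposure = 1, delta = 0, L = 60, height = 48, width = 48,
    substeps = 1, seed = seed))
  slow <- thsp_run_length(thsp(mk(1 / 0.003, 31)))
  fast <- thsp_run_length(thsp(mk(1 / 0.09, 32)))
  expect_gt(slow, fast)
  expect_error(thsp(st, column = 7), "column")
})

test_that("binned contrast-vs-x experiment closes against the model", {
  st <- sim_stack_cached()  # tau_c = 60, T = 1, delta = 0, L = 240
  tab <- contrast_vs_x_experiment(st, omegas = c(1, 2, 4, 8),
                                  L_window = 30, tau_c = 60,
                                  estimator = "ensemble")
  expect_equal(tab$x, c(1, 2, 4, 8) / 60)
  pred <- sqrt(temporal_contrast_sq(tab$x, 30, 29, 0, "lorentzian"))
  expect_true(all(abs(tab$mean_K / pred - 1) < 0.05))
  # single-bin experiment equals the plain ROI summary
  one <- contrast_vs_x_experiment(st, omegas = 1, L_window = 30,
                                  tau_c = 60)
  ref <- roi_contrast_summary(temporal_contrast_map(st, L_window = 30))
  expect_equal(one$mean_K, ref$mean)
  expect_equal(one$sd_K, ref$sd)
  # static stack: zero contrast at every omega
  cst <- speckle_stack(array(5, dim = c(8, 8, 12)), exposure = 1)
  flat <- contrast_vs_x_experiment(cst, omegas = c(1, 2), L_window = 3,
                                   tau_c = 10)
  expect_true(all(flat$mean_K == 0))
})

test_that("contrast-model fitting recovers parameters and ranks models", {
  x <- 10^seq(-2.5, 0.3, length.out = 25)
  truth <- sqrt(0.8 * temporal_contrast_sq(x, 30, 29, 0.347,
                                           "lorentzian") + 0.001)
  fit <- fit_contrast_model(x, truth, "lorentzian", L = 30, S = 29,
                            delta_ratio = 0.347, free = c("alpha", "Cn"))
  expect_equal(fit$alpha, 0.8, tolerance = 1e-6)
  expect_equal(fit$Cn, 0.001, tolerance = 1e-6)
  # quadratic alpha scaling: halving K quarters alpha
  base <- sqrt(temporal_contrast_sq(x, 30, 29, 0, "lorentzian"))
  fit2 <- fit_contrast_model(x, 0.5 * base, "lorentzian", L = 30,
                             free = "alpha")
  expect_equal(fit2$alpha, 0.25, tolerance = 1e-6)
  # tau_scale recovery on a horizontally shifted curve
  shifted <- sqrt(temporal_contrast_sq(x * 1.5, 30, 29, 0, "lorentzian"))
  fit3 <- fit_contrast_model(x, shifted, "lorentzian", L = 30,
                             free = "tau_scale")
  expect_equal(fit3$tau_scale, 1.5, tolerance = 1e-4)
  # on correlated simulated data the no-correlation model fits worse
  st <- sim_stack_cached()
  tab <- contrast_vs_x_experiment(st, omegas = c(1, 2, 3, 4, 6, 8),
                                  L_window = 30, tau_c = 60,
                                  estimator = "ensemble")
  f_corr <- fit_contrast_model(tab$x, tab$mean_K, "lorentzian", L = 30,
                               S = 29, free = "alpha")
  f_none <- fit_contrast_model(tab$x, tab$mean_K, "lorentzian", L = 30,
                               S = 0, free = "alpha")
  expect_gt(f_none$rss, f_corr$rss)
  expect_error(fit_contrast_model(x[1:2], truth[1:2], "lorentzian", L = 30),
               "points")
})
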