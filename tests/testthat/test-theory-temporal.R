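test_that("correlation factors match quadrature-frozen values and limits", {
  # frozen against nu_inv_quadrature at abs.tol 1e-10
  expect_equal(nu_inv(0, 0.7071068, 0, "gaussian"), 0.802002313008,
               tolerance = 1e-9)
  expect_equal(nu_inv(1, 0.7071068, 0, "gaussian"), 0.29394033475,
               tolerance = 1e-9)
  expect_equal(nu_inv(0, 0.7071068, 0, "lorentzian"), 0.657330290308,
               tolerance = 1e-9)
  # direct evaluation of the psi = 0 Lorentzian closed form
  expect_equal(nu_inv(0, 0.7071068, 0, "lorentzian"),
               (1 / (2 * 0.5)) * (2 * 0.7071068 + exp(-1.4142136) - 1),
               tolerance = 1e-7)
  # fully correlated and decorrelated limits
  for (fam in c("gaussian", "lorentzian")) {
    expect_equal(nu_inv(0, 1e-6, 0, fam), 1, tolerance = 1e-5)
    expect_lt(nu_inv(40, 5, 0, fam), 1e-10)
    expect_lt(nu_inv(0, 1e4, 0, fam), 1e-3)
  }
})

test_that("correlation factors lie in [0, 1] and decrease with psi", {
  for (fam in c("gaussian", "lorentzian"))
    for (x in c(0.01, 0.1, 0.5, 1, 2, 5))
      for (D in c(0, 0.347, 5)) {
        v <- nu_inv(0:8, x, D, fam)
        expect_true(all(v >= 0 & v <= 1 + 1e-12))
        expect_true(all(diff(v) <= 1e-12))
      }
})

test_that("factor arguments are validated", {
  expect_error(nu_inv(0, -1), "positive")
  expect_error(nu_inv(0, 0), "positive")
  expect_error(nu_inv(-1, 1), "non-negative")
  expect_error(nu_inv(0.5, 1), "integer")
  expect_error(nu_inv(0, 1, delta_ratio = -0.1), "delta_ratio")
})

test_that("temporal contrast combines the pair-weighted factors", {
  # L = 2, S = 1: single lateral pair, K^2 = 1/nu0 - 1/nu1
  expect_equal(temporal_contrast_sq(0.7071068, L = 2, S = 1,
                                    family = "gaussian"),
               0.802002313008 - 0.29394033475, tolerance = 1e-9)
  # S = 0 reduction to the independent-frame model
  for (fam in c("gaussian", "lorentzian"))
    for (x in c(0.01, 0.1, 0.5, 1, 2, 5))
      expect_equal(temporal_contrast_sq(x, L = 30, S = 0, family = fam),
                   autocorr_contrast_sq(x, fam), tolerance = 1e-12)
  # slow dynamics: correlated model far below the independent-frame model
  for (fam in c("gaussian", "lorentzian")) {
    k2 <- temporal_contrast_sq(0.002, L = 30, S = 29, delta_ratio = 0.347,
                               family = fam)
    expect_lt(k2 / autocorr_contrast_sq(0.002, fam), 0.06)
  }
  expect_error(temporal_contrast_sq(1, L = 1), "L")
  expect_error(temporal_contrast_sq(1, L = 10, S = 10), "S")
})

test_that("independent-frame contrast has the documented limits", {
  expect_equal(autocorr_contrast_sq(1e-4, "gaussian"), 1, tolerance = 1e-3)
  expect_equal(autocorr_contrast_sq(1e-4, "lorentzian"), 1, tolerance = 1e-3)
  expect_lt(autocorr_contrast_sq(100, "gaussian"), 0.02)
  expect_lt(autocorr_contrast_sq(100, "lorentzian"), 0.02)
  expect_error(autocorr_contrast_sq(0), "positive")
})

test_that("classic model reduces to the Lorentzian single-exposure form", {
  x <- c(0.01, 0.1, 0.5, 1, 2, 5, 20)
  expect_equal(classic_contrast(x, alpha = 1, rho = 1, Cn = 0, M = 0),
               sqrt(autocorr_contrast_sq(x, "lorentzian")),
               tolerance = 1e-10)
  # K -> 1 as x -> 0 (the failure mode for slow dynamics), K -> 0 as x -> Inf
  expect_equal(classic_contrast(1e-5), 1, tolerance = 1e-4)
  expect_lt(classic_contrast(1e4), 0.02)
  # monotone decreasing without noise
  expect_true(all(diff(classic_contrast(x)) < 0))
  expect_error(classic_contrast(1, rho = 1.2), "rho")
})

test_that("pixel-size factor beta^(1/2) is continuous and bounded", {
  expect_equal(beta_half(0), 1)
  # the small-M series agrees with the exact expression where it takes over
  M0 <- 9.9e-5
  exact <- (2 * pnorm(sqrt(2 * pi * M0)) - 1) / sqrt(M0) -
    (1 - exp(-pi * M0)) / (pi * M0)
  expect_equal(beta_half(M0), exact, tolerance = 1e-9)
  M <- c(0.05, 0.2, 0.5, 1, 2)
  b <- beta_half(M)
  expect_true(all(b > 0 & b < 1))
  expect_true(all(diff(b) < 0))
})

test_that("pair census matches brute-force enumeration", {
  # documented example: L = 5, S = 2
  cen <- correlation_pair_census(5, 2)
  expect_equal(cen$lateral, c(8L, 6L))
  expect_equal(cen$outsiders, 6L)
  expect_equal(cen$central + sum(cen$lateral) + cen$outsiders, 25L)
  # edge cases
  expect_equal(correlation_pair_census(30, 0)$outsiders, 29L * 30L)
  expect_equal(correlation_pair_census(30, 29)$outsiders, 0L)
  # brute-force equality on a sample of window sizes, all S
  for (L in c(2, 3, 7, 20, 50))
    for (S in 0:(L - 1)) {
      cen <- correlation_pair_census(L, S)
      ref <- census_brute(L, S)
      expect_equal(cen$central, ref$central)
      expect_equal(cen$lateral, ref$lateral)
      expect_equal(cen$outsiders, ref$outsiders)
      expect_equal(cen$total, L^2)
    }
  expect_error(correlation_pair_census(5, 5), "S")
})
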