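# Shared oracles and fixtures, built in code at test time.

# Brute-force frame-pair census: classify every ordered pair of frame
# indices by |m - n| and count central / lateral / outsider pairs.
census_brute <- function(L, S) {
  sep <- abs(outer(0:(L - 1), 0:(L - 1), "-"))
  list(central = sum(sep == 0),
       lateral = if (S >= 1) vapply(1:S, function(p) sum(sep == p),
                                    integer(1)) else integer(0),
       outsiders = sum(sep > S))
}

# Small i.i.d.-frame stack (fully developed, uncorrelated in time).
iid_exponential_stack <- function(h = 32, w = 32, L = 50, seed = 1) {
  set.seed(seed)
  speckle_stack(array(rexp(h * w * L), dim = c(h, w, L)), exposure = 1)
}

# Modest simulated Lorentzian stack reused by several empirical tests:
# tau_c = 60 s, T = 1 s, no dead time, 240 frames of 96 x 96 px.
sim_stack_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_stack(simulation_config(
        tau_c = 60, exposure = 1, delta = 0, L = 240, height = 96,
        width = 96, family = "lorentzian", substeps = 4, seed = 20260927))
    cache
  }
})
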