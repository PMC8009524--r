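# Shared, lazily built fixtures.  Heavy objects (SCF ground states, embedded
# ground states) are computed once per test run and memoized here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

water_system <- function() cached("water_system", {
  ks_system(builtin_geometry("h2o"))
})

water_gs <- function() cached("water_gs", {
  scf_ground_state(water_system())
})

water_lr <- function() cached("water_lr", {
  lr_tddft(water_gs(), n_roots = 6)
})

adduct_embedded <- function() cached("adduct_embedded", {
  ad <- builtin_geometry("h2o_nh3_adduct")
  split_scf(ad$active, ad$environment)
})

adduct_isolated_gs <- function() cached("adduct_isolated_gs", {
  ad <- builtin_geometry("h2o_nh3_adduct")
  scf_ground_state(ks_system(ad$active))
})

# embedding response kernel of the converged adduct state
adduct_embedding_kernel <- function() {
  egs <- adduct_embedded()
  sys <- egs$active_gs$system
  rho_I <- density_on_grid(egs$active_gs$D_ao, sys$aovals, egs$grid)
  rtfde:::embedding_kernel(rho_I, egs$env_density)
}

# independent 3D quadrature of a product of two contracted s functions placed
# along z (brute-force box sum; oracle for analytic overlaps)
overlap_quadrature_oracle <- function(exps, coefs, zsep) {
  gl <- rtfde:::gauss_legendre(80)
  L <- 8
  x <- gl$x * L; w <- gl$w * L
  val <- 0
  for (ix in seq_along(x)) for (iy in seq_along(x)) {
    r2a <- x[ix]^2 + x[iy]^2 + (x + zsep / 2)^2
    r2b <- x[ix]^2 + x[iy]^2 + (x - zsep / 2)^2
    chi_a <- colSums(coefs * exp(-outer(exps, r2a)))
    chi_b <- colSums(coefs * exp(-outer(exps, r2b)))
    val <- val + w[ix] * w[iy] * sum(w * chi_a * chi_b)
  }
  val
}

# three delta-kick traces (x, y, z) of the builtin water molecule
water_kick_traces <- function(n_steps = 2000) cached("water_kick_traces", {
  gs <- water_gs()
  lapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), function(d) {
    propagate(gs, field_spec("delta_kick", direction = d, kappa = 1e-5),
              propagation_config(dt = 0.1, n_steps = n_steps))
  })
})

# out-of-plane (y) kick of the adduct's water: embedded and isolated
adduct_y_traces <- function(n_steps = 2000) cached("adduct_y_traces", {
  f <- field_spec("delta_kick", direction = c(0, 1, 0), kappa = 1e-5)
  cfg <- propagation_config(dt = 0.1, n_steps = n_steps, emb_update_stride = 1)
  list(embedded = propagate(adduct_embedded(), f, cfg),
       isolated = propagate(adduct_isolated_gs(), f, cfg))
})

lowest_peak_ev <- function(trace, axis_frac = 1e-4) {
  sp <- strength_function(trace, kappa = 1e-5)
  pk <- find_spectrum_peaks(sp, n_peaks = 3, min_height_frac = axis_frac)
  pk$energy_ev[1]
}
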