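## Polarized ground states for embedded propagation: frozen environment
## density, split-SCF macro-iterations, and the initial MO density matrix.

#' Frozen environment density on a grid
#'
#' Runs an isolated SCF of the environment subsystem and evaluates its
#' converged density at the grid points.
#'
#' @param env environment [subsystem].
#' @param grid target `rt_grid`.
#' @param env_scf optional precomputed `rt_scf` of the environment.
#' @return `rt_grid_density` with the nominal electron count attached; the
#'   converged `rt_scf` and the AO density are attached as attributes
#'   `"scf"` and `"D_ao"`.
#' @export
environment_ground_density <- function(env, grid, env_scf = NULL) {
  if (length(env$atoms) == 0L) stop("environment has no atoms")
  if (is.null(env_scf)) env_scf <- scf_ground_state(env)
  aov <- eval_aos_on_grid(env_scf$system$ints$shells, grid$points)
  rho <- density_on_grid(env_scf$D_ao, aov, grid, n_electrons = env$n_electrons)
  attr(rho, "scf") <- env_scf
  attr(rho, "D_ao") <- env_scf$D_ao
  rho
}

## Build the embedding potential for given active density values on the grid,
## reusing frozen electrostatics.
.build_vemb <- function(rho_I, rho_II, elec, aovals, weights, f, step = 0L) {
  nad <- nonadditive_potential(rho_I, rho_II, f)
  assemble_embedding_potential(elec$v_nuc_env, elec$v_coul_env,
                               nad$v_nad_xc, nad$v_nad_kin,
                               aovals, weights, step = step)
}

#' Split-SCF polarized ground state
#'
#' Produces the initial condition of an embedded propagation by alternating
#' (a) an SCF of the active subsystem in a frozen embedding-potential matrix
#' and (b) a rebuild of the embedding potential from the relaxed active
#' density, until the active SCF energy is stationary. The environment
#' density is computed once and never updated (uncoupled scheme).
#'
#' @param active active [subsystem].
#' @param env environment [subsystem].
#' @param f a [functional_set] for the nonadditive terms.
#' @param grid optional `rt_grid`; defaults to a supramolecular medium grid.
#' @param scope grid scope when `grid` is not supplied.
#' @param conv_macro convergence threshold on successive active SCF energies
#'   (hartree).
#' @param max_macro macro-iteration cap.
#' @param verbose print macro-iteration energies.
#' @return object of class `rt_embedded_scf`: `active_gs` (an `rt_scf`
#'   converged in the final embedding potential), `v_emb0`
#'   (`rt_embedding_potential`), `env_density`, `grid`, `electrostatics`,
#'   `macro_iterations`, `polarization_energy_shift` (hartree, isolated-
#'   functional energy of the polarized minus the isolated density),
#'   `macro_energy_trace`.
#' @export
split_scf <- function(active, env, f = functional_set(), grid = NULL,
                      scope = "supramolecular", conv_macro = 1e-8,
                      max_macro = 50, verbose = FALSE) {
  if (is.null(grid)) grid <- build_grid(active, env, scope = scope)
  sys <- ks_system(active, grid = grid)
  grid <- sys$grid   # ks_system drops points without active basis support

  rho_II <- environment_ground_density(env, grid)
  elec <- environment_electrostatics(env, attr(rho_II, "D_ao"), grid)

  iso <- scf_ground_state(sys)
  e_iso <- iso$scf_energy
  gs <- iso
  e_prev <- Inf
  etrace <- numeric(0)
  vemb <- NULL
  converged <- FALSE
  for (macro in seq_len(max_macro)) {
    rho_I <- density_on_grid(gs$D_ao, sys$aovals, grid,
                             n_electrons = active$n_electrons)
    vemb <- .build_vemb(rho_I, rho_II, elec, sys$aovals, grid$weights, f)
    gs <- scf_ground_state(sys, v_extra = vemb$ao_matrix)
    etrace <- c(etrace, gs$scf_energy)
    if (verbose) {
      message(sprintf("  split-SCF macro %d: E = %.10f", macro, gs$scf_energy))
    }
    if (abs(gs$scf_energy - e_prev) < conv_macro) {
      converged <- TRUE
      break
    }
    e_prev <- gs$scf_energy
  }
  if (!converged) {
    stop("split-SCF did not converge in ", max_macro,
         " macro-iterations; energies: ",
         paste(sprintf("%.8f", utils::tail(etrace, 6)), collapse = " "))
  }

  ## isolated-functional energy of the polarized density minus the isolated
  ## ground-state energy (>= 0 by the variational principle)
  Dp <- gs$D_ao
  J <- coulomb_matrix(sys, Dp)
  xc <- xc_matrix(sys, Dp)
  e_pol <- sum(Dp * sys$ints$core_h) + 0.5 * sum(Dp * J) + xc$E + sys$ints$e_nuc

  structure(list(
    active_gs = gs, v_emb0 = vemb, env_density = rho_II,
    grid = grid, electrostatics = elec, functional_set = f,
    macro_iterations = macro,
    polarization_energy_shift = e_pol - e_iso,
    macro_energy_trace = etrace,
    isolated_gs = iso
  ), class = "rt_embedded_scf")
}

#' @export
print.rt_embedded_scf <- function(x, ...) {
  cat(sprintf(paste0("<embedded ground state: %d macro-iterations, ",
                     "E = %.9f hartree, polarization shift %.3e hartree>\n"),
              x$macro_iterations, x$active_gs$scf_energy,
              x$polarization_energy_shift))
  invisible(x)
}

#' Initial MO-basis density matrix
#'
#' The ground-state projector in the reference MO basis: identity on the
#' occupied block, zero elsewhere, complex-typed for propagation. Its trace
#' equals the number of occupied orbitals and it is exactly idempotent.
#'
#' @param gs an `rt_scf` (or anything with `n_occ` and `mo_coeffs`), or an
#'   integer pair via `n_occ`/`n_basis`.
#' @param n_occ,n_basis explicit dimensions (used when `gs` is missing).
#' @return complex n_basis x n_basis matrix.
#' @export
initial_density <- function(gs = NULL, n_occ = gs$n_occ,
                            n_basis = nrow(gs$mo_coeffs)) {
  if (n_occ > n_basis) stop("n_occ exceeds n_basis")
  D <- matrix(0 + 0i, n_basis, n_basis)
  if (n_occ > 0) diag(D)[seq_len(n_occ)] <- 1 + 0i
  D
}

#' Serialize an embedded ground state to a plain-text file
#'
#' Writes the MO coefficients, orbital energies, grid arrays and embedding
#' potential components in a self-describing text format.
#'
#' @param egs an `rt_embedded_scf`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedded_state <- function(egs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wvec <- function(tag, v) {
    writeLines(sprintf("%s %d", tag, length(v)), con)
    writeLines(paste(format(v, digits = 17), collapse = " "), con)
  }
  gs <- egs$active_gs
  writeLines(sprintf("# rtfde embedded state; n_basis %d n_occ %d macro %d",
                     nrow(gs$mo_coeffs), gs$n_occ, egs$macro_iterations), con)
  wvec("mo_coeffs", as.vector(gs$mo_coeffs))
  wvec("mo_energies", gs$mo_energies)
  wvec("scf_energy", gs$scf_energy)
  wvec("grid_points", as.vector(egs$grid$points))
  wvec("grid_weights", egs$grid$weights)
  wvec("v_emb_total", egs$v_emb0$total)
  invisible(path)
}
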