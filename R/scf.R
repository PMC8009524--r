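## Restricted Kohn-Sham LDA ground states.  A `ks_system` bundles everything
## needed to build Fock matrices repeatedly (integrals, ERI supermatrix, grid,
## AO values on the grid); the SCF accepts an arbitrary extra one-electron
## operator so that embedding potentials and static couplings can be folded
## into the Hamiltonian.

#' Assemble the cached electronic-structure machinery for a subsystem
#'
#' @param spec a [subsystem].
#' @param grid optional `rt_grid`; by default a supramolecular-scope grid over
#'   the subsystem's own atoms at the `medium` preset.
#' @return list of class `rt_ks_system`.
#' @export
ks_system <- function(spec, grid = NULL) {
  ints <- ao_integrals(spec)
  if (is.null(grid)) grid <- build_grid(spec)
  aovals <- eval_aos_on_grid(ints$shells, grid$points)
  ## drop grid points with no basis support: they cannot contribute to any
  ## projected matrix element of this subsystem
  support <- rowSums(aovals^2) * grid$weights
  keep <- support > 1e-16
  if (!all(keep)) {
    grid$points <- grid$points[keep, , drop = FALSE]
    grid$weights <- grid$weights[keep]
    grid$n_points <- sum(keep)
    aovals <- aovals[keep, , drop = FALSE]
  }
  structure(list(
    spec = spec, ints = ints, grid = grid,
    aovals = aovals,
    W = eri_supermatrix(ints$shells),
    n_basis = ints$n_basis, n_occ = ints$n_occ
  ), class = "rt_ks_system")
}

## Coulomb matrix from the (real) AO density
coulomb_matrix <- function(sys, D) {
  n <- sys$n_basis
  matrix(sys$W %*% as.vector(D), n, n)
}

## XC potential matrix (+ energy) by quadrature from the (real) AO density;
## one shared pointwise LDA evaluation serves both
xc_matrix <- function(sys, D, energy = TRUE) {
  rho <- rowSums((sys$aovals %*% D) * sys$aovals)
  rho[rho < 0] <- 0
  lda <- .lda_slater_vwn5(rho, RHO_MIN)
  Vxc <- crossprod(sys$aovals, (sys$grid$weights * lda$v) * sys$aovals)
  Vxc <- (Vxc + t(Vxc)) / 2
  list(V = Vxc, E = if (energy) sum(sys$grid$weights * lda$e) else NA_real_)
}

#' Build the AO Kohn-Sham matrix for a given density
#'
#' F = T + v_nuc + J[rho] + V_xc[rho] (+ v_extra).  For complex densities the
#' Coulomb and XC terms depend on the real part only (the imaginary part of a
#' Hermitian density is antisymmetric and drops out of both), so the returned
#' matrix is real symmetric; it is the Hermitian Fock of the propagation.
#'
#' @param sys an `rt_ks_system` (or a [subsystem], built on the fly).
#' @param D AO density matrix in physical normalization (tr(D S) = n
#'   electrons); may be complex.
#' @param v_extra optional extra one-electron operator (real symmetric).
#' @return real symmetric Fock matrix.
#' @export
build_fock_ao <- function(sys, D, v_extra = NULL) {
  if (inherits(sys, "rt_subsystem")) sys <- ks_system(sys)
  Dr <- Re(D)
  if (!all(dim(Dr) == sys$n_basis)) stop("density dimension mismatch")
  F <- sys$ints$core_h + coulomb_matrix(sys, Dr) + xc_matrix(sys, Dr)$V
  if (!is.null(v_extra)) {
    if (!all(dim(v_extra) == sys$n_basis)) stop("v_extra dimension mismatch")
    F <- F + v_extra
  }
  (F + t(F)) / 2
}

## Generalized symmetric eigensolve F C = S C e via S^(-1/2)
.solve_roothaan <- function(F, Shalf_inv) {
  Ft <- Shalf_inv %*% F %*% Shalf_inv
  e <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  list(energies = e$values[ord], C = Shalf_inv %*% e$vectors[, ord, drop = FALSE])
}

#' Converge the closed-shell ground state (optionally with an extra operator)
#'
#' DIIS-accelerated restricted Kohn-Sham SCF. When `v_extra` is supplied it is
#' added as a one-electron operator; the reported SCF energy includes its full
#' expectation value tr(D v_extra) and carries no double-counting correction
#' (the documented contract - only energy differences are meaningful for
#' embedded runs).
#'
#' @param spec a [subsystem] or prebuilt `rt_ks_system`.
#' @param v_extra optional real symmetric matrix added to the one-electron
#'   Hamiltonian.
#' @param conv_energy,conv_density convergence thresholds (hartree; RMS
#'   density change).
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   energy trace.
#' @return object of class `rt_scf`: `mo_coeffs`, `mo_energies`, `n_occ`,
#'   `scf_energy`, `D_ao` (physical, tr(D S) = n electrons), `system`,
#'   `iterations`, `energy_trace`.
#' @export
scf_ground_state <- function(spec, v_extra = NULL, conv_energy = 1e-9,
                             conv_density = 1e-7, max_iter = 200) {
  sys <- if (inherits(spec, "rt_ks_system")) spec else ks_system(spec)
  n <- sys$n_basis
  nocc <- sys$n_occ
  if (nocc > n) stop("more occupied orbitals than basis functions")
  S <- sys$ints$overlap
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) <= 1e-10) stop("overlap matrix not positive definite")
  Shalf_inv <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  h <- sys$ints$core_h
  if (!is.null(v_extra)) h <- h + (v_extra + t(v_extra)) / 2

  sol <- .solve_roothaan(h, Shalf_inv)
  Cocc <- sol$C[, seq_len(nocc), drop = FALSE]
  D <- 2 * tcrossprod(Cocc)

  e_old <- Inf
  etrace <- numeric(0)
  diis_F <- list(); diis_R <- list()
  for (it in seq_len(max_iter)) {
    J <- coulomb_matrix(sys, D)
    xc <- xc_matrix(sys, D)
    F <- h + J + xc$V
    E <- sum(D * h) + 0.5 * sum(D * J) + xc$E + sys$ints$e_nuc
    etrace <- c(etrace, E)

    ## DIIS on the commutator residual
    R <- F %*% D %*% S - S %*% D %*% F
    diis_F[[length(diis_F) + 1]] <- F
    diis_R[[length(diis_R) + 1]] <- R
    if (length(diis_F) > 8) { diis_F <- diis_F[-1]; diis_R <- diis_R[-1] }
    m <- length(diis_F)
    if (m >= 2) {
      B <- matrix(0, m + 1, m + 1)
      for (i in seq_len(m)) for (j in seq_len(m)) B[i, j] <- sum(diis_R[[i]] * diis_R[[j]])
      B[m + 1, seq_len(m)] <- B[seq_len(m), m + 1] <- -1
      rhs <- c(numeric(m), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf)) F <- Reduce(`+`, Map(`*`, diis_F, cf))
    }

    sol <- .solve_roothaan(F, Shalf_inv)
    Cocc <- sol$C[, seq_len(nocc), drop = FALSE]
    D_new <- 2 * tcrossprod(Cocc)
    drms <- sqrt(mean((D_new - D)^2))
    de <- abs(E - e_old)
    D <- D_new; e_old <- E
    if (de < conv_energy && drms < conv_density && it > 1) {
      return(structure(list(
        mo_coeffs = sol$C, mo_energies = sol$energies, n_occ = nocc,
        scf_energy = E, D_ao = D, system = sys, v_extra = v_extra,
        iterations = it, energy_trace = etrace, converged = TRUE
      ), class = "rt_scf"))
    }
  }
  stop("SCF failed to converge in ", max_iter,
       " iterations; energy trace: ",
       paste(sprintf("%.8f", utils::tail(etrace, 6)), collapse = " "))
}

#' @export
print.rt_scf <- function(x, ...) {
  cat(sprintf("<RKS/LDA ground state: E = %.9f hartree, %d iterations, gap %.4f eV>\n",
              x$scf_energy, x$iterations,
              (x$mo_energies[x$n_occ + 1] - x$mo_energies[x$n_occ]) * HARTREE_EV))
  invisible(x)
}

#' @export
summary.rt_scf <- function(object, ...) {
  cat(sprintf("RKS/LDA SCF on %d basis functions, %d occupied orbitals\n",
              object$system$n_basis, object$n_occ))
  cat(sprintf("  total energy   %.9f hartree\n", object$scf_energy))
  cat(sprintf("  HOMO / LUMO    %.5f / %.5f hartree\n",
              object$mo_energies[object$n_occ],
              object$mo_energies[object$n_occ + 1]))
  cat("  orbital energies (hartree):\n")
  print(round(object$mo_energies, 6))
  invisible(object)
}
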