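## Casida linear-response TDDFT for closed-shell LDA ground states.  Serves
## as the frequency-domain cross-check of the real-time propagation: both
## routes share the integrals but the response algebra here is independent of
## the time-domain machinery.
##
## For a pure density functional (no exact exchange) the closed-shell singlet
## response matrices are
##   A_ia,jb = delta_ij delta_ab (e_a - e_i) + K_ia,jb,   B = K,
##   K_ia,jb = 2 [ (ia|jb) + (ia| f_xc |jb) ],
## with f_xc = d v_xc / d rho at the total ground-state density (the factor 2
## is the spin summation in the density response), so A - B is diagonal and
## the Casida eigenproblem reduces to
##   [ diag(w_ia^2) + 2 sqrt(w_ia) K sqrt(w_jb) ] Z = w^2 Z.

#' Singlet excitation energies from linear response
#'
#' @param gs an `rt_scf` ground state (possibly converged with an embedding
#'   potential as `v_extra`).
#' @param n_roots number of excitations to return.
#' @param kernel_extra optional extra pointwise kernel on the system grid
#'   (numeric vector, hartree bohr^3) added to f_xc; used to fold the
#'   embedding response (nonadditive kinetic + XC kernel at the frozen
#'   environment density) into the reference calculation.
#' @return object of class `rt_casida`: data frame `roots` with
#'   `energy_hartree`, `energy_ev`, `osc_strength`, plus the raw eigenpairs.
#' @export
lr_tddft <- function(gs, n_roots = 5, kernel_extra = NULL) {
  sys <- gs$system
  n <- sys$n_basis
  nocc <- gs$n_occ
  nvir <- n - nocc
  if (nvir < 1) stop("no virtual orbitals; enlarge the basis")
  C <- gs$mo_coeffs
  Cocc <- C[, seq_len(nocc), drop = FALSE]
  Cvir <- C[, nocc + seq_len(nvir), drop = FALSE]

  ## occupied-virtual pair ordering: p = (i-1)*nvir + a (a fastest)
  nov <- nocc * nvir
  ia_i <- rep(seq_len(nocc), each = nvir)
  ia_a <- rep(seq_len(nvir), times = nocc)
  w_ia <- gs$mo_energies[nocc + ia_a] - gs$mo_energies[ia_i]

  ## (ia|jb) via the ERI supermatrix: v_p[mu + n(nu-1)] = Cocc[mu,i] Cvir[nu,a]
  V <- matrix(0, n * n, nov)
  for (p in seq_len(nov)) {
    V[, p] <- as.vector(Cocc[, ia_i[p]] %o% Cvir[, ia_a[p]])
  }
  Kmat <- 2 * crossprod(V, sys$W %*% V)

  ## grid xc (+ embedding) kernel: (ia| f |jb)
  rho <- rowSums((sys$aovals %*% gs$D_ao) * sys$aovals)
  rho[rho < 0] <- 0
  f <- lda_xc_kernel(rho)
  if (!is.null(kernel_extra)) f <- f + kernel_extra
  phi_occ <- sys$aovals %*% Cocc
  phi_vir <- sys$aovals %*% Cvir
  Q <- phi_occ[, ia_i, drop = FALSE] * phi_vir[, ia_a, drop = FALSE]
  Kmat <- Kmat + 2 * crossprod(Q, (sys$grid$weights * f) * Q)
  Kmat <- (Kmat + t(Kmat)) / 2

  sw <- sqrt(w_ia)
  Omega <- diag(w_ia^2, nov) + 2 * (sw %o% sw) * Kmat
  e <- eigen((Omega + t(Omega)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  w2 <- e$values[ord]
  Z <- e$vectors[, ord, drop = FALSE]
  if (any(w2 <= 0)) stop("non-positive excitation eigenvalue; ground state unstable?")
  w <- sqrt(w2)
  nr <- min(n_roots, length(w))

  ## transition dipoles: mu_p = sqrt(2) sum_ia d_ia sqrt(2 w_ia / w_k) Z_ia
  ## (closed-shell spin adaptation); oscillator strength (2/3) w |mu|^2
  dmo <- lapply(sys$ints$dipole, function(P) {
    M <- crossprod(Cocc, P %*% Cvir)
    M[cbind(ia_i, ia_a)]
  })
  osc <- numeric(nr)
  for (k in seq_len(nr)) {
    amp <- sqrt(2) * sqrt(2 * w_ia / w[k]) * Z[, k]
    mu <- vapply(dmo, function(d) sum(d * amp), numeric(1))
    osc[k] <- (2 / 3) * w[k] * sum(mu^2)
  }

  structure(list(
    roots = data.frame(energy_hartree = w[seq_len(nr)],
                       energy_ev = w[seq_len(nr)] * HARTREE_EV,
                       osc_strength = osc),
    omega = w, Z = Z, w_ia = w_ia
  ), class = "rt_casida")
}

#' @export
print.rt_casida <- function(x, ...) {
  cat("<Casida LR-TDDFT singlet roots>\n")
  print(round(x$roots, 5))
  invisible(x)
}
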