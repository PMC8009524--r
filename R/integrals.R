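## R-level interface to the McMurchie-Davidson integral kernels.

#' One-electron AO integrals for a subsystem
#'
#' Computes overlap, core Hamiltonian (kinetic + intrasubsystem nuclear
#' attraction) and the three Cartesian dipole-moment matrices, all in atomic
#' units. Dipole integrals are taken about the subsystem's center of nuclear
#' charge so that absolute dipoles are origin-consistent.
#'
#' @param spec an [subsystem] object.
#' @return a list of class `rt_ao_basis`: `n_basis`, `overlap`, `kinetic`,
#'   `v_nuc`, `core_h`, `dipole` (list of x/y/z matrices), `origin`,
#'   `shells`, `e_nuc` (nuclear repulsion), `n_occ`.
#' @export
ao_integrals <- function(spec) {
  shells <- build_shells(spec)
  one <- .md_one_electron(shells)
  vnuc <- -.md_point_charge(shells, spec$coords, as.numeric(spec$Z))
  origin <- charge_center(spec)
  S <- one$S
  dip <- list(x = one$dx - origin[1] * S,
              y = one$dy - origin[2] * S,
              z = one$dz - origin[3] * S)
  structure(list(
    n_basis = shells$n_basis,
    overlap = S, kinetic = one$T, v_nuc = vnuc,
    core_h = one$T + vnuc,
    dipole = dip, origin = origin,
    shells = shells,
    e_nuc = nuclear_repulsion(spec),
    n_occ = spec$n_electrons %/% 2L
  ), class = "rt_ao_basis")
}

#' Evaluate the AO basis functions at arbitrary points
#'
#' @param spec a [subsystem] object (or a shell structure from
#'   `build_shells`).
#' @param points N x 3 matrix of coordinates in bohr.
#' @return N x n_basis matrix of basis-function values.
#' @export
eval_aos_on_grid <- function(spec, points) {
  shells <- if (inherits(spec, "rt_subsystem")) build_shells(spec) else spec
  points <- matrix(as.numeric(points), ncol = 3)
  if (any(!is.finite(points))) stop("non-finite grid coordinates")
  .md_ao_values(shells, points)
}

#' Electron repulsion integrals as a supermatrix
#'
#' Returns the full tensor of two-electron integrals (mu nu | la si)
#' (chemists' notation) reshaped to an n^2 x n^2 matrix, so that the Coulomb
#' matrix is a single matrix-vector product `J = matrix(W %*% as.vector(D))`.
#'
#' @param spec a [subsystem] object or shell structure.
#' @return n^2 x n^2 numeric matrix.
#' @export
eri_supermatrix <- function(spec) {
  shells <- if (inherits(spec, "rt_subsystem")) build_shells(spec) else spec
  .md_eri(shells)
}

## electrostatic potential of AO density P at points (bohr); P in physical
## normalization (tr(P S) = n_electrons)
esp_of_density <- function(shells, P, points) {
  .md_esp_at_points(shells, P, matrix(as.numeric(points), ncol = 3))
}
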