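## Local density functionals on grids: Thomas-Fermi kinetic energy, Slater
## exchange, VWN5 correlation; potentials (first derivatives), energy
## densities, and kernels (second derivatives, used by the linear-response
## solver).  Densities below `rho_min` are floored to zero so that the
## rho^(-1/3)-type terms cannot amplify grid noise in near-vacuum regions.

RHO_MIN <- 1e-10

#' Choose the nonadditive functional pair
#'
#' @param kinetic kinetic-energy functional for the nonadditive term; only
#'   `"thomas_fermi"` is implemented.
#' @param xc exchange-correlation functional; only `"lda"` (Slater + VWN5).
#' @return a `rt_functional_set`.
#' @export
functional_set <- function(kinetic = "thomas_fermi", xc = "lda") {
  kinetic <- match.arg(kinetic, "thomas_fermi")
  xc <- match.arg(xc, "lda")
  structure(list(kinetic = kinetic, xc = xc), class = "rt_functional_set")
}

.rho_values <- function(rho) {
  if (inherits(rho, "rt_grid_density")) rho$values else as.numeric(rho)
}

#' Thomas-Fermi kinetic potential
#'
#' v_TF(r) = (5/3) C_TF rho^(2/3), with C_TF = (3/10)(3 pi^2)^(2/3).
#'
#' @param rho grid density (`rt_grid_density` or numeric vector, bohr^-3).
#' @return numeric vector (hartree).
#' @export
tf_kinetic_potential <- function(rho) {
  r <- .rho_values(rho)
  v <- numeric(length(r))
  ok <- r > RHO_MIN
  v[ok] <- (5 / 3) * C_TF * r[ok]^(2 / 3)
  v
}

## TF energy density per volume: C_TF rho^(5/3)
tf_energy_density <- function(rho) {
  r <- .rho_values(rho)
  e <- numeric(length(r))
  ok <- r > RHO_MIN
  e[ok] <- C_TF * r[ok]^(5 / 3)
  e
}

## TF kernel d v_TF / d rho = (10/9) C_TF rho^(-1/3)
tf_kernel <- function(rho) {
  r <- .rho_values(rho)
  f <- numeric(length(r))
  ok <- r > RHO_MIN
  f[ok] <- (10 / 9) * C_TF * r[ok]^(-1 / 3)
  f
}

## ---- VWN5 correlation (paramagnetic parametrization) -----------------------
.vwn_A <- 0.0310907
.vwn_b <- 3.72744
.vwn_c <- 12.9352
.vwn_x0 <- -0.10498

## returns list(ec, vc) for the given total density values (> 0)
.vwn5 <- function(r) {
  rs <- (3 / (4 * pi * r))^(1 / 3)
  x <- sqrt(rs)
  b <- .vwn_b; cc <- .vwn_c; x0 <- .vwn_x0; A <- .vwn_A
  X <- x^2 + b * x + cc
  X0 <- x0^2 + b * x0 + cc
  Q <- sqrt(4 * cc - b^2)
  atn <- atan(Q / (2 * x + b))
  ec <- A * (log(x^2 / X) + 2 * b / Q * atn -
             b * x0 / X0 * (log((x - x0)^2 / X) + 2 * (b + 2 * x0) / Q * atn))
  ## d ec / d x
  dX <- 2 * x + b
  datn <- -2 * Q / (Q^2 + (2 * x + b)^2)
  dec <- A * (2 / x - dX / X + 2 * b / Q * datn -
              b * x0 / X0 * (2 / (x - x0) - dX / X + 2 * (b + 2 * x0) / Q * datn))
  ## vc = ec - (rs/3) d ec/d rs = ec - (x/6) d ec/d x
  vc <- ec - (x / 6) * dec
  list(ec = ec, vc = vc)
}

#' LDA exchange-correlation potential
#'
#' Slater exchange v_x = -(3 rho / pi)^(1/3) plus the VWN5 correlation
#' potential, evaluated pointwise on the grid density.
#'
#' @inheritParams tf_kinetic_potential
#' @return numeric vector (hartree).
#' @export
lda_xc_potential <- function(rho) {
  .lda_slater_vwn5(.rho_values(rho), RHO_MIN)$v
}

## LDA xc energy density per volume: rho * (ex + ec)
lda_xc_energy_density <- function(rho) {
  .lda_slater_vwn5(.rho_values(rho), RHO_MIN)$e
}

## LDA kernel f_xc = d v_xc / d rho; exchange part analytic, correlation part
## by central differencing of the analytic vc (relative step), which is ample
## for response work
lda_xc_kernel <- function(rho) {
  r <- .rho_values(rho)
  f <- numeric(length(r))
  ok <- r > RHO_MIN
  if (any(ok)) {
    rr <- r[ok]
    fx <- -(1 / 3) * (3 / pi)^(1 / 3) * rr^(-2 / 3)
    h <- 1e-5 * rr
    fc <- (.vwn5(rr + h)$vc - .vwn5(rr - h)$vc) / (2 * h)
    f[ok] <- fx + fc
  }
  f
}
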