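## Built-in Gaussian basis sets (Pople standard data) and construction of the
## flattened shell representation consumed by the C++ integral kernels.
##
## Each basis entry: list per element of shells, each shell a list with
## l ("s", "p" or "sp"), exps, and contraction coefficient vectors.

.basis_library <- list(
  "sto-3g" = list(
    H = list(list(l = "s", exps = c(3.425250914, 0.6239137298, 0.1688554040),
                  s = c(0.1543289673, 0.5353281423, 0.4446345422))),
    C = list(
      list(l = "s", exps = c(71.61683735, 13.04509632, 3.530512160),
           s = c(0.1543289673, 0.5353281423, 0.4446345422)),
      list(l = "sp", exps = c(2.941249355, 0.6834830964, 0.2222899159),
           s = c(-0.09996722919, 0.3995128261, 0.7001154689),
           p = c(0.1559162750, 0.6076837186, 0.3919573931))),
    N = list(
      list(l = "s", exps = c(99.10616896, 18.05231239, 4.885660238),
           s = c(0.1543289673, 0.5353281423, 0.4446345422)),
      list(l = "sp", exps = c(3.780455879, 0.8784966449, 0.2857143744),
           s = c(-0.09996722919, 0.3995128261, 0.7001154689),
           p = c(0.1559162750, 0.6076837186, 0.3919573931))),
    O = list(
      list(l = "s", exps = c(130.7093200, 23.80886100, 6.443608300),
           s = c(0.1543289673, 0.5353281423, 0.4446345422)),
      list(l = "sp", exps = c(5.033151319, 1.169596125, 0.3803889600),
           s = c(-0.09996722919, 0.3995128261, 0.7001154689),
           p = c(0.1559162750, 0.6076837186, 0.3919573931)))
  ),
  "6-31g" = list(
    H = list(
      list(l = "s", exps = c(18.73113696, 2.825394365, 0.6401216923),
           s = c(0.03349460434, 0.2347269535, 0.8137573261)),
      list(l = "s", exps = 0.1612777588, s = 1.0)),
    N = list(
      list(l = "s",
           exps = c(4173.511460, 627.4579110, 142.9020930, 40.23432930, 13.03269640, 4.603904240),
           s = c(0.001834772160, 0.01399462700, 0.06858655181, 0.2322408730, 0.4690699481, 0.3604551991)),
      list(l = "sp", exps = c(11.62636186, 2.716279807, 0.7722183966),
           s = c(-0.1149611817, -0.1691174786, 1.145851947),
           p = c(0.06757974388, 0.3239072959, 0.7408951398)),
      list(l = "sp", exps = 0.2120314975, s = 1.0, p = 1.0)),
    O = list(
      list(l = "s",
           exps = c(5484.671660, 825.2349460, 188.0469580, 52.96450000, 16.89757040, 5.799635340),
           s = c(0.001831074430, 0.01395017220, 0.06844507810, 0.2327143360, 0.4701928980, 0.3585208530)),
      list(l = "sp", exps = c(15.53961625, 3.599933586, 1.013761750),
           s = c(-0.1107775495, -0.1480262627, 1.130767015),
           p = c(0.07087426823, 0.3397528391, 0.7271585773)),
      list(l = "sp", exps = 0.2700058226, s = 1.0, p = 1.0))
  )
)

## primitive normalization for a Cartesian Gaussian of angular momentum l
.prim_norm <- function(alpha, l) {
  if (l == 0) (2 * alpha / pi)^0.75 else (2 * alpha / pi)^0.75 * 2 * sqrt(alpha)
}

## contracted self-overlap of a single-center shell (closed form)
.contracted_self_overlap <- function(exps, coef, l) {
  s <- 0
  for (a in seq_along(exps)) {
    for (b in seq_along(exps)) {
      p <- exps[a] + exps[b]
      o <- (pi / p)^1.5
      if (l == 1) o <- o / (2 * p)
      s <- s + coef[a] * coef[b] * o
    }
  }
  s
}

#' Build the shell list for a subsystem
#'
#' Expands the named basis set over the atoms of a subsystem into the
#' flattened representation used by the integral kernels. Contraction
#' coefficients are folded with primitive norms and renormalized so that each
#' contracted function has unit self-overlap.
#'
#' @param spec a [subsystem] object.
#' @return internal shell structure (list of `l`, `centers`, `nprim`,
#'   `alpha`, `coef`, plus bookkeeping fields).
#' @keywords internal
build_shells <- function(spec) {
  bname <- tolower(spec$basis)
  bset <- .basis_library[[bname]]
  if (is.null(bset)) {
    stop("unknown basis set '", spec$basis, "'; available: ",
         paste(names(.basis_library), collapse = ", "))
  }
  l <- integer(0); centers <- NULL; nprim <- integer(0)
  alpha <- numeric(0); coef <- numeric(0)
  for (ia in seq_len(nrow(spec$coords))) {
    sym <- spec$atoms[ia]
    shells <- bset[[sym]]
    if (is.null(shells)) {
      stop("basis '", spec$basis, "' has no entry for element ", sym)
    }
    for (sh in shells) {
      comps <- if (sh$l == "sp") c("s", "p") else sh$l
      for (comp in comps) {
        lval <- if (comp == "s") 0L else 1L
        c_raw <- sh[[comp]] * vapply(sh$exps, .prim_norm, numeric(1), l = lval)
        c_raw <- c_raw / sqrt(.contracted_self_overlap(sh$exps, c_raw, lval))
        l <- c(l, lval)
        centers <- rbind(centers, spec$coords[ia, ])
        nprim <- c(nprim, length(sh$exps))
        alpha <- c(alpha, sh$exps)
        coef <- c(coef, c_raw)
      }
    }
  }
  nfun <- ifelse(l == 0L, 1L, 3L)
  list(l = l, centers = centers, nprim = nprim, alpha = alpha, coef = coef,
       n_basis = sum(nfun))
}
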