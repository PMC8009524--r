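## Subsystem definition (geometry + basis + functional + role) and XYZ I/O.

#' Define a molecular subsystem
#'
#' A subsystem is one fragment of the partitioned supersystem: either the
#' `active` molecule, whose density is propagated, or an `environment`
#' fragment, whose ground-state density is frozen and only enters through the
#' embedding potential.
#'
#' @param atoms character vector of element symbols.
#' @param coords numeric matrix (n_atoms x 3) of coordinates in Angstrom.
#' @param basis basis-set name (`"sto-3g"` or `"6-31g"`).
#' @param xc exchange-correlation functional label; only `"lda"`
#'   (Slater exchange + VWN5 correlation) is implemented.
#' @param charge total charge (integer); the electron count must come out even
#'   (closed-shell restriction).
#' @param role `"active"` or `"environment"`.
#' @return an object of class `rt_subsystem` with coordinates stored in bohr
#'   (`$coords`), element symbols (`$atoms`), nuclear charges (`$Z`) and the
#'   electron count (`$n_electrons`).
#' @examples
#' h2o <- builtin_geometry("h2o")
#' h2o$n_electrons  # 10
#' @export
subsystem <- function(atoms, coords, basis = "sto-3g", xc = "lda",
                      charge = 0L, role = c("active", "environment")) {
  role <- match.arg(role)
  if (length(atoms) == 0L) stop("subsystem needs at least one atom")
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) != length(atoms)) stop("atoms/coords length mismatch")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  Z <- element_Z(atoms)
  nel <- sum(Z) - charge
  if (nel %% 2L != 0L) {
    stop("odd electron count (", nel, "); only closed-shell systems supported")
  }
  if (!identical(tolower(xc), "lda")) {
    stop("unknown xc functional '", xc, "'; only 'lda' is implemented")
  }
  structure(list(
    atoms = atoms,
    coords = coords / ANGSTROM_PER_BOHR,  # bohr internally
    basis = basis, xc = tolower(xc),
    charge = as.integer(charge), role = role,
    Z = Z, n_electrons = nel
  ), class = "rt_subsystem")
}

#' @export
print.rt_subsystem <- function(x, ...) {
  cat(sprintf("<%s subsystem: %d atoms (%s), basis %s, xc %s, charge %+d, %d electrons>\n",
              x$role, length(x$atoms), paste(x$atoms, collapse = ""),
              x$basis, x$xc, x$charge, x$n_electrons))
  invisible(x)
}

#' Read an XYZ file into a subsystem
#'
#' Standard XYZ layout: atom count, comment line, then `element x y z` in
#' Angstrom.
#'
#' @inheritParams subsystem
#' @param path path to the XYZ file.
#' @return an `rt_subsystem`.
#' @export
read_xyz <- function(path, basis = "sto-3g", xc = "lda", charge = 0L,
                     role = c("active", "environment")) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  atoms <- vapply(rows, `[[`, character(1), 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  subsystem(atoms, coords, basis = basis, xc = xc, charge = charge, role = role)
}

#' Write a subsystem to an XYZ file
#' @param spec an `rt_subsystem`.
#' @param path output path.
#' @param comment comment line content.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(spec, path, comment = "") {
  ang <- spec$coords * ANGSTROM_PER_BOHR
  lines <- c(as.character(length(spec$atoms)), comment,
             sprintf("%-2s %16.10f %16.10f %16.10f", spec$atoms,
                     ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}

## ---- built-in fixture geometries -------------------------------------------
## Literature-standard monomer geometries plus programmatically generated
## hydrogen-bonded arrangements.  These are synthetic stand-ins: convenient,
## physically sensible fixtures, not coordinates from any specific published
## cluster snapshot.

.geom_h2o <- function(shift = c(0, 0, 0)) {
  xyz <- rbind(c(0.0000000, 0.0000000, 0.1173000),
               c(0.0000000, 0.7572000, -0.4692000),
               c(0.0000000, -0.7572000, -0.4692000))
  list(atoms = c("O", "H", "H"), coords = sweep(xyz, 2, shift, "+"))
}

.geom_nh3 <- function() {
  r <- 1.0124; hnh <- 106.67 * pi / 180
  ct <- sqrt((2 * cos(hnh) + 1) / 3); st <- sqrt(1 - ct^2)
  xyz <- rbind(c(0, 0, 0),
               c(r * st, 0, -r * ct),
               c(-r * st / 2, r * st * sqrt(3) / 2, -r * ct),
               c(-r * st / 2, -r * st * sqrt(3) / 2, -r * ct))
  list(atoms = c("N", "H", "H", "H"), coords = xyz)
}

## active water hydrogen-bonded (donor) to ammonia nitrogen along z
.geom_h2o_nh3 <- function(d_ON = 2.95) {
  nh3 <- .geom_nh3()
  roh <- 0.9572; hoh <- 104.52 * pi / 180
  O <- c(0, 0, d_ON)
  H1 <- c(0, 0, d_ON - roh)                      # donor H toward N
  H2 <- O + roh * c(sin(hoh), 0, -cos(hoh))
  list(active = list(atoms = c("O", "H", "H"), coords = rbind(O, H1, H2)),
       environment = nh3)
}

## ring-shaped hydrogen-bonded water cluster of n molecules; the first water
## is the active one
.geom_h2o_cluster <- function(n) {
  stopifnot(n >= 2, n <= 6)
  roh <- 0.9572; hoh <- 104.52 * pi / 180
  d_OO <- 2.85
  if (n == 2) {
    centers <- rbind(c(0, 0, 0), c(d_OO, 0, 0))
  } else {
    R <- d_OO / (2 * sin(pi / n))
    ang <- 2 * pi * (seq_len(n) - 1) / n
    centers <- cbind(R * cos(ang), R * sin(ang), 0)
  }
  mols <- vector("list", n)
  for (i in seq_len(n)) {
    O <- centers[i, ]
    nxt <- centers[if (i == n) 1 else i + 1, ]
    u <- nxt - O; u <- u / sqrt(sum(u^2))       # donate along the ring
    H1 <- O + roh * u
    # second (free) H out of plane, alternating up/down
    w <- c(0, 0, if (i %% 2 == 0) -1 else 1)
    v <- cos(hoh) * u + sin(hoh) * w
    H2 <- O + roh * v
    mols[[i]] <- list(atoms = c("O", "H", "H"), coords = rbind(O, H1, H2))
  }
  mols
}

#' Built-in fixture geometries
#'
#' Returns standard small-molecule fixtures used throughout the package:
#' `"h2o"`, `"nh3"`, `"h2o_nh3_adduct"` (hydrogen-bonded water-ammonia
#' complex, water active), and `"h2o_cluster_n"` with n = 2..6 (ring-shaped
#' water clusters, first molecule active). These are literature-standard
#' monomer geometries and generated hydrogen-bond arrangements - deliberately
#' documented synthetic stand-ins, not coordinates from any published cluster
#' snapshot.
#'
#' @param name fixture name.
#' @param basis,xc,env_basis basis/functional labels applied to the returned
#'   subsystem objects.
#' @return for monomers, an `rt_subsystem` with role `"active"`; for
#'   complexes, a list with elements `active` and `environment`.
#' @export
builtin_geometry <- function(name, basis = "sto-3g", xc = "lda",
                             env_basis = basis) {
  name <- tolower(name)
  mk <- function(g, role, b) subsystem(g$atoms, g$coords, basis = b, xc = xc, role = role)
  if (name == "h2o") return(mk(.geom_h2o(), "active", basis))
  if (name == "nh3") return(mk(.geom_nh3(), "active", basis))
  if (name == "h2o_nh3_adduct") {
    g <- .geom_h2o_nh3()
    return(list(active = mk(g$active, "active", basis),
                environment = mk(g$environment, "environment", env_basis)))
  }
  m <- regmatches(name, regexec("^h2o_cluster_([2-6])$", name))[[1]]
  if (length(m) == 2) {
    n <- as.integer(m[2])
    mols <- .geom_h2o_cluster(n)
    act <- mk(mols[[1]], "active", basis)
    env_atoms <- do.call(c, lapply(mols[-1], `[[`, "atoms"))
    env_coords <- do.call(rbind, lapply(mols[-1], `[[`, "coords"))
    env <- subsystem(env_atoms, env_coords, basis = env_basis, xc = xc,
                     role = "environment")
    return(list(active = act, environment = env))
  }
  stop("unknown builtin geometry '", name, "'")
}

## nuclear repulsion energy (hartree) of one subsystem
nuclear_repulsion <- function(spec) {
  e <- 0
  n <- length(spec$Z)
  if (n < 2) return(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      e <- e + spec$Z[i] * spec$Z[j] / sqrt(sum((spec$coords[i, ] - spec$coords[j, ])^2))
    }
  }
  e
}

## nuclear dipole (a.u.) about an origin (bohr)
nuclear_dipole <- function(spec, origin = c(0, 0, 0)) {
  colSums(spec$Z * sweep(spec$coords, 2, origin))
}

## center of nuclear charge (bohr)
charge_center <- function(spec) {
  colSums(spec$Z * spec$coords) / sum(spec$Z)
}
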