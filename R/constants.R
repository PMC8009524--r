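## Physical constants and element data (atomic units internally; Angstrom only
## at the XYZ boundary).

#' @keywords internal
ANGSTROM_PER_BOHR <- 0.52917721092

#' @keywords internal
HARTREE_EV <- 27.211386245988

## Thomas-Fermi constant (3/10)(3 pi^2)^(2/3)
C_TF <- 0.3 * (3 * pi^2)^(2 / 3)

.element_table <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne"),
  Z = 1:10,
  # Slater-Bragg radii (Angstrom) used to scale radial grids and fuzzy cells
  radius = c(0.35, 0.31, 1.45, 1.05, 0.85, 0.70, 0.65, 0.60, 0.50, 0.38),
  stringsAsFactors = FALSE
)

element_Z <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ", paste(symbol[is.na(i)], collapse = ", "))
  }
  .element_table$Z[i]
}

element_radius_bohr <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  .element_table$radius[i] / ANGSTROM_PER_BOHR
}
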