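## YAML run configuration: parsing, validation, defaults, serialization.

.config_defaults <- list(
  propagation = list(dt = 0.1, n_steps = 1000, pc_tol = 1e-7, pc_max_iter = 20,
                     emb_update_stride = 1, record_stride = 1),
  grid = list(preset = "medium", scope = "supramolecular"),
  functionals = list(kinetic = "thomas_fermi", xc = "lda"),
  output = list(prefix = "rtfde"),
  seed = 1
)

.known_keys <- list(
  top = c("active", "environment", "functionals", "field", "propagation",
          "grid", "output", "seed"),
  active = c("geometry", "xyz", "basis", "xc", "charge"),
  environment = c("geometry", "xyz", "basis", "xc", "charge"),
  functionals = c("kinetic", "xc"),
  field = c("kick", "pulse"),
  kick = c("kappa", "direction"),
  pulse = c("E0", "omega0", "n_cycles", "tau", "direction"),
  propagation = c("dt", "n_steps", "pc_tol", "pc_max_iter",
                  "emb_update_stride", "record_stride"),
  grid = c("preset", "scope", "nrad", "ntheta", "nphi"),
  output = c("prefix")
)

.check_keys <- function(x, section) {
  unknown <- setdiff(names(x), .known_keys[[section]])
  if (length(unknown)) {
    stop("unknown key(s) in '", section, "': ", paste(unknown, collapse = ", "))
  }
}

.merge_defaults <- function(x, d) {
  for (k in names(d)) if (is.null(x[[k]])) x[[k]] <- d[[k]]
  x
}

.parse_subsystem_block <- function(blk, role, section) {
  .check_keys(blk, section)
  blk <- .merge_defaults(blk, list(basis = "sto-3g", xc = "lda", charge = 0))
  if (!is.null(blk$geometry)) {
    g <- builtin_geometry(blk$geometry, basis = blk$basis, xc = blk$xc)
    if (inherits(g, "rt_subsystem")) {
      if (g$role != role) g$role <- role
      return(g)
    }
    return(g[[role]])
  }
  if (is.null(blk$xyz)) stop("'", section, "' needs a 'geometry' name or an 'xyz' file")
  if (!file.exists(blk$xyz)) stop("XYZ file not found: ", blk$xyz)
  read_xyz(blk$xyz, basis = blk$basis, xc = blk$xc, charge = blk$charge,
           role = role)
}

#' Parse a run configuration file
#'
#' YAML key-value configuration with sections `active`, optional
#' `environment`, `functionals`, `field` (exactly one of a `kick` or `pulse`
#' block), `propagation`, `grid`, `output` and `seed`. Unknown keys are an
#' error (listed by name); omitted optional keys are filled with the
#' documented defaults (dt = 0.1 a.u., pc_tol = 1e-7, emb_update_stride = 1,
#' medium supramolecular grid). Geometry is given in Angstrom (XYZ file) or
#' by a built-in fixture name; field and propagation parameters are atomic
#' units.
#'
#' @param path path to a YAML file.
#' @return list of class `rt_config`: `active`, `environment` (or NULL),
#'   `functional_set`, `field`, `propagation` (`rt_prop_config`), `grid`
#'   options, `output`, `seed`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  .check_keys(raw, "top")
  if (is.null(raw$active)) stop("missing required section 'active'")
  if (is.null(raw$field)) stop("missing required section 'field'")
  .check_keys(raw$field, "field")
  if (!is.null(raw$field$kick) && !is.null(raw$field$pulse)) {
    stop("field: give either a 'kick' or a 'pulse' block, not both")
  }
  if (is.null(raw$field$kick) && is.null(raw$field$pulse)) {
    stop("field: needs a 'kick' or 'pulse' block")
  }

  active <- .parse_subsystem_block(raw$active, "active", "active")
  environment <- if (!is.null(raw$environment)) {
    .parse_subsystem_block(raw$environment, "environment", "environment")
  }

  fun <- .merge_defaults(raw$functionals %||% list(), .config_defaults$functionals)
  .check_keys(fun, "functionals")
  fset <- functional_set(fun$kinetic, fun$xc)

  field <- if (!is.null(raw$field$kick)) {
    blk <- .merge_defaults(raw$field$kick, list(kappa = 1e-5, direction = c(0, 0, 1)))
    .check_keys(blk, "kick")
    field_spec("delta_kick", direction = unlist(blk$direction), kappa = blk$kappa)
  } else {
    blk <- raw$field$pulse
    .check_keys(blk, "pulse")
    if (is.null(blk$E0) || is.null(blk$omega0)) {
      stop("pulse block needs E0 and omega0")
    }
    blk <- .merge_defaults(blk, list(direction = c(0, 0, 1)))
    field_spec("cos2_pulse", direction = unlist(blk$direction), E0 = blk$E0,
               omega0 = blk$omega0, n_cycles = blk$n_cycles, tau = blk$tau)
  }

  prop <- .merge_defaults(raw$propagation %||% list(), .config_defaults$propagation)
  .check_keys(prop, "propagation")
  pcfg <- propagation_config(dt = prop$dt, n_steps = prop$n_steps,
                             pc_tol = prop$pc_tol, pc_max_iter = prop$pc_max_iter,
                             emb_update_stride = prop$emb_update_stride,
                             record_stride = prop$record_stride)

  grid <- .merge_defaults(raw$grid %||% list(), .config_defaults$grid)
  .check_keys(grid, "grid")
  out <- .merge_defaults(raw$output %||% list(), .config_defaults$output)
  .check_keys(out, "output")

  structure(list(active = active, environment = environment,
                 functional_set = fset, field = field, propagation = pcfg,
                 grid = grid, output = out,
                 seed = raw$seed %||% .config_defaults$seed),
            class = "rt_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a parsed configuration back to YAML
#'
#' Round-trips with [parse_config()] (geometries are written as inline XYZ
#' temporary content via builtin names when available, else as coordinates).
#'
#' @param cfg an `rt_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  sub_block <- function(s, xyz_path) {
    write_xyz(s, xyz_path)
    list(xyz = xyz_path, basis = s$basis, xc = s$xc, charge = s$charge)
  }
  base <- sub("\\.ya?ml$", "", path)
  out <- list(
    active = sub_block(cfg$active, paste0(base, "_active.xyz")),
    functionals = list(kinetic = cfg$functional_set$kinetic,
                       xc = cfg$functional_set$xc),
    field = if (cfg$field$kind == "delta_kick") {
      list(kick = list(kappa = cfg$field$kappa,
                       direction = as.numeric(cfg$field$direction)))
    } else {
      list(pulse = list(E0 = cfg$field$E0, omega0 = cfg$field$omega0,
                        tau = cfg$field$tau,
                        direction = as.numeric(cfg$field$direction)))
    },
    propagation = unclass(cfg$propagation),
    grid = cfg$grid,
    output = cfg$output,
    seed = cfg$seed
  )
  if (!is.null(cfg$environment)) {
    out$environment <- sub_block(cfg$environment, paste0(base, "_environment.xyz"))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
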