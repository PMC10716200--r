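#' Default run configuration
#'
#' The full, resolved set of tunable parameters with their defaults
#' (mm / MPa / N units). Of note: the study scaffolds' wall thickness was
#' never reported; `geometry$base_thickness = 0.5` mm is this package's
#' default assumption and is deliberately exposed here.
#'
#' @return Nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    scenario = "control",
    mesh = list(n_axial = 60L, n_circ = 32L),
    geometry = list(inner_diameter = 5, length = 60,
                    base_thickness = 0.5),  # assumed, not measured
    patch = list(enabled = TRUE, axial_center = 19.5, circ_center = pi / 32,
                 axial_halfwidth = 6, circ_halfwidth = 1.0,
                 min_thickness = 0.06, transition = 2),
    helix = list(pitch = NULL, thread_diameter = NULL, n_layers = NULL),
    polymer = list(E = NULL, id = NULL, nu = 0.35),
    bio = list(E0 = 1, eps_y = 0.6, floor = 0.1, PE_ref = 0.0055, nu = 0),
    pressure = list(range = "normo", p_min = NULL, p_max = NULL,
                    n_cycles = 150L, unload = "zero"),
    solver = list(tol = 1e-9, max_iter = 30L, clamped_length = 5),
    noise = list(amplitude = 0, corr_length = 3),
    seed = 1L,
    out_dir = "."
  ), class = "run_config")
}

#' Load and resolve a YAML run configuration
#'
#' Reads a YAML file, validates it against the known configuration keys
#' (unknown keys are rejected, naming the offender -- fail-closed), merges
#' it over [default_config()], and resolves derived entries: a named
#' pressure range fills `p_min`/`p_max`; a scenario name fills helix and
#' polymer parameters not explicitly overridden. An empty file yields all
#' defaults (the control preset).
#'
#' @param file Path to a YAML config (missing/empty file: all defaults).
#' @return Resolved `run_config`.
#' @export
load_config <- function(file = NULL) {
  cfg <- default_config()
  user <- NULL
  if (!is.null(file)) {
    if (!file.exists(file))
      stop("load_config: no such file: ", file, call. = FALSE)
    user <- yaml::read_yaml(file)
  }
  if (!is.null(user)) {
    if (!is.list(user))
      stop("load_config: config must be a YAML mapping", call. = FALSE)
    check_keys(user, cfg, path = "")
    cfg <- merge_config(cfg, user)
  }
  resolve_config(cfg)
}

check_keys <- function(user, ref, path) {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(ref))
      stop("load_config: unknown configuration key '", full, "'",
           call. = FALSE)
    if (is.list(user[[k]]) && is.list(ref[[k]]) && length(names(ref[[k]])))
      check_keys(user[[k]], ref[[k]], full)
  }
}

merge_config <- function(ref, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(ref[[k]])) {
      ref[[k]] <- merge_config(ref[[k]], user[[k]])
    } else {
      ref[[k]] <- user[[k]]
    }
  }
  ref
}

resolve_config <- function(cfg) {
  valid_scen <- c("control", "pvdf", "pcl")
  if (!cfg$scenario %in% valid_scen)
    stop("load_config: scenario must be one of ",
         paste(valid_scen, collapse = ", "), call. = FALSE)
  # pressure range name -> MPa endpoints (explicit p_min/p_max win)
  if (is.null(cfg$pressure$p_min) || is.null(cfg$pressure$p_max)) {
    pr <- pressure_range_mpa(cfg$pressure$range)
    if (is.null(cfg$pressure$p_min)) cfg$pressure$p_min <- pr[1]
    if (is.null(cfg$pressure$p_max)) cfg$pressure$p_max <- pr[2]
  }
  # scenario fills helix/polymer entries not overridden
  preset <- make_preset(cfg$scenario)
  if (!is.null(preset$helix)) {
    if (is.null(cfg$helix$pitch)) cfg$helix$pitch <- preset$helix$pitch
    if (is.null(cfg$helix$thread_diameter))
      cfg$helix$thread_diameter <- preset$helix$thread_diameter
    if (is.null(cfg$helix$n_layers))
      cfg$helix$n_layers <- preset$helix$n_layers
    if (is.null(cfg$polymer$E)) cfg$polymer$E <- preset$polymer$E
    cfg$polymer$id <- preset$polymer$id
  }
  # basic unit sanity (mm / MPa scales)
  if (cfg$geometry$inner_diameter <= 0 || cfg$geometry$inner_diameter > 100)
    stop("load_config: geometry.inner_diameter out of the mm range",
         call. = FALSE)
  if (cfg$pressure$p_max > 1)
    stop("load_config: pressure.p_max looks too large for MPa units",
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Instantiate model and protocol from a resolved configuration
#'
#' @param cfg A `run_config` from [load_config()].
#' @param length Optional specimen-length override, mm.
#' @return List: `model` ([scaffold_model()]), `protocol`
#'   ([pressure_protocol()]), `bc` ([boundary_condition()]).
#' @export
config_build <- function(cfg, length = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  g <- cfg$geometry
  L <- if (is.null(length)) g$length else length
  n_ax <- max(4L, as.integer(round(cfg$mesh$n_axial * L / g$length)))
  tube <- tube_spec(g$inner_diameter, L, g$base_thickness,
                    n_axial = n_ax, n_circ = cfg$mesh$n_circ)
  patches <- list()
  if (isTRUE(cfg$patch$enabled)) {
    p <- cfg$patch
    if (p$axial_center + p$axial_halfwidth <= L) {
      patches <- list(thin_patch_spec(p$axial_center, p$circ_center,
                                      p$axial_halfwidth, p$circ_halfwidth,
                                      p$min_thickness, p$transition))
    }
  }
  th <- build_thickness_field(tube, patches,
                              noise_amplitude = cfg$noise$amplitude,
                              noise_corr_length = cfg$noise$corr_length,
                              seed = cfg$seed)
  bio <- damage_plastic_params(cfg$bio$E0, cfg$bio$eps_y, cfg$bio$floor,
                               cfg$bio$PE_ref, cfg$bio$nu)
  helix <- NULL; polymer <- NULL
  if (!is.null(cfg$helix$pitch) && !is.null(cfg$helix$n_layers) &&
      cfg$helix$n_layers > 0) {
    helix <- helix_spec(cfg$helix$pitch, cfg$helix$thread_diameter,
                        cfg$helix$n_layers, cfg$polymer$id)
    polymer <- polymer_params(cfg$polymer$E, cfg$polymer$id, cfg$polymer$nu)
  }
  mesh <- make_tube_mesh(tube)
  model <- scaffold_model(mesh, th, bio = bio, helix = helix,
                          polymer = polymer)
  protocol <- pressure_protocol(cfg$pressure$p_min, cfg$pressure$p_max,
                                cfg$pressure$n_cycles, cfg$pressure$unload)
  bc <- boundary_condition("encastre", cfg$solver$clamped_length)
  list(model = model, protocol = protocol, bc = bc)
}

#' Write a resolved configuration as YAML
#'
#' Every run writes its resolved configuration (seed included) next to its
#' outputs so the run can be reproduced bit-identically.
#'
#' @param cfg A `run_config`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_config <- function(cfg, file) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), file, precision = 15L)
  invisible(file)
}
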