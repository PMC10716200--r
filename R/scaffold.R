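#' Assemble a scaffold model
#'
#' Bundles the discretized geometry (mesh + per-element thickness), the
#' biological wall material, and the optional helix reinforcement (spec,
#' polymer, per-element coverage) into the object the solvers operate on.
#'
#' @param mesh Native `surface_mesh` from [make_tube_mesh()].
#' @param thickness `thickness_field` on the same element grid (or a single
#'   number for a uniform wall).
#' @param bio [damage_plastic_params()] for the wall, or a `poly_fit`
#'   material law (used below yield, e.g. in compliance studies).
#' @param helix Optional [helix_spec()] (`NULL` for an unreinforced model).
#' @param polymer [polymer_params()]; required when `helix` has layers.
#' @param coverage Optional precomputed [helix_coverage()]; computed from
#'   the helix path when omitted.
#' @return Object of class `scaffold_model`.
#' @export
scaffold_model <- function(mesh, thickness, bio = damage_plastic_params(),
                           helix = NULL, polymer = NULL, coverage = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (isTRUE(mesh$external))
    stop("scaffold_model: requires a native structured mesh", call. = FALSE)
  spec <- mesh$spec
  if (is.numeric(thickness) && length(thickness) == 1L) {
    thickness <- matrix(thickness, spec$n_axial, spec$n_circ)
  }
  thickness <- as.matrix(thickness)
  if (!all(dim(thickness) == c(spec$n_axial, spec$n_circ)))
    stop("scaffold_model: thickness field does not match the element grid",
         call. = FALSE)
  if (any(thickness <= 0))
    stop("scaffold_model: thickness must be positive everywhere", call. = FALSE)
  has_helix <- !is.null(helix) && helix$n_layers > 0L
  if (has_helix && is.null(polymer))
    stop("scaffold_model: a reinforced model needs 'polymer' parameters",
         call. = FALSE)
  if (has_helix && is.null(coverage)) {
    path <- make_helix_path(helix, spec)
    coverage <- helix_coverage(path, mesh)
  }
  if (is.null(coverage)) coverage <- matrix(0, spec$n_axial, spec$n_circ)
  if (any(coverage < 0))
    stop("scaffold_model: coverage must be non-negative", call. = FALSE)
  structure(list(mesh = mesh, spec = spec, thickness = thickness,
                 bio = bio, helix = helix, polymer = polymer,
                 coverage = as.matrix(coverage)),
            class = "scaffold_model")
}

#' @export
print.scaffold_model <- function(x, ...) {
  cat(sprintf("scaffold_model: ID %g mm, L %g mm, wall %.3g-%.3g mm",
              x$spec$inner_diameter, x$spec$length,
              min(x$thickness), max(x$thickness)))
  if (!is.null(x$helix) && x$helix$n_layers > 0L) {
    cat(sprintf(", %s %d-layer helix (pitch %.3g mm, thread %.3g mm, E %g MPa)",
                x$polymer$id, x$helix$n_layers, x$helix$pitch,
                x$helix$thread_diameter, x$polymer$E))
  } else {
    cat(", unreinforced")
  }
  cat("\n")
  invisible(x)
}

# Homogenized helix hoop stiffness per element (N/mm = MPa*mm), i.e. the
# reinforcement's contribution to the hoop membrane stiffness E*t.
# The thread's axial stiffness E_p*A, projected onto the hoop direction
# (cos^2 of the helix angle), is distributed over the wall area it covers;
# because the helix embraces the whole circumference, the coverage of each
# axial row is smeared circumferentially ("tied homogenized coverage"):
# C_row = E_p * A * cos^2(alpha) * (row covered length) / (row wall area).
# For an ideal double helix this equals E_p*A*cos^2(alpha)*n_layers/pitch.
helix_hoop_stiffness <- function(model) {
  spec <- model$spec
  C <- matrix(0, spec$n_axial, spec$n_circ)
  if (is.null(model$helix) || model$helix$n_layers == 0L) return(C)
  h <- model$helix
  A_th <- pi * (h$thread_diameter / 2)^2
  r_w <- tube_radii(spec, h$thread_diameter)$winding
  alpha <- helix_angle(h$pitch, 2 * r_w)
  dz <- spec$length / spec$n_axial
  row_area <- 2 * pi * model$mesh$radius * dz
  row_len <- rowSums(model$coverage)
  C[] <- rep(model$polymer$E * A_th * cos(alpha)^2 * row_len / row_area,
             times = spec$n_circ)
  C
}

# Bio membrane hoop stiffness (tangent, N/mm) and stress (MPa) interface.
# For the damage-plastic law: sigma = f*E0*(eps - PE); for a poly_fit law
# (no damage/plasticity): sigma = f * poly(eps).
bio_stress <- function(model, eps, f, PE) {
  if (inherits(model$bio, "poly_fit")) {
    f * eval_polynomial(model$bio, eps)
  } else {
    f * model$bio$E0 * (eps - PE)
  }
}

bio_tangent <- function(model, eps, f) {
  if (inherits(model$bio, "poly_fit")) {
    f * eval_polynomial(model$bio, eps, deriv = TRUE)
  } else {
    f * model$bio$E0 + 0 * eps
  }
}

bio_nu <- function(model) {
  if (inherits(model$bio, "poly_fit")) 0 else model$bio$nu
}
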