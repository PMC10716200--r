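#' Stress-strain curve container
#'
#' @param strain Strains, mm/mm (strictly increasing).
#' @param stress Stresses, MPa.
#' @param direction `"longitudinal"` or `"transverse"`.
#' @param force Optional force column, N.
#' @return A data frame of class `stress_strain_curve`.
#' @export
stress_strain_curve <- function(strain, stress,
                                direction = c("longitudinal", "transverse"),
                                force = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(strain) == length(stress), all(is.finite(stress)))
  if (length(strain) > 1 && any(diff(strain) <= 0))
    stop("stress_strain_curve: strains must be strictly increasing",
         call. = FALSE)
  out <- data.frame(strain = strain, stress = stress)
  if (!is.null(force)) out$force <- force
  structure(out, class = c("stress_strain_curve", "data.frame"),
            direction = direction, stop_index = NA_integer_)
}

# Annular wall cross-section area of a tube spec, mm^2.
annulus_area <- function(spec) {
  r_in <- spec$inner_diameter / 2
  r_out <- r_in + spec$base_thickness
  pi * (r_out^2 - r_in^2)
}

#' Virtual longitudinal tension test
#'
#' The 60 mm specimen is fixed at the lower end and stretched along the
#' axis. The composite response is a bar of annular cross-section carrying
#' the wall material law (with plasticity/damage accumulating along the
#' ramp for the damage-plastic law) in parallel with the helix acting as a
#' coil spring of axial stiffness `G_p * d^4 / (8 * D_coil^3 * n_turns)`
#' per layer -- orders of magnitude softer than the wall, which is why the
#' helix leaves longitudinal behaviour essentially unchanged.
#'
#' @param model A [scaffold_model()].
#' @param displacement Total applied end displacement, mm
#'   (0 < displacement <= specimen length).
#' @param n_steps Number of ramp steps.
#' @return A [stress_strain_curve()] (`direction = "longitudinal"`) with a
#'   `force` column; stress is force over the annular wall area.
#' @export
solve_longitudinal_tension <- function(model, displacement, n_steps = 100L) {
  stopifnot(inherits(model, "scaffold_model"))
  if (displacement < 0)
    stop("solve_longitudinal_tension: negative displacement", call. = FALSE)
  spec <- model$spec
  if (displacement > spec$length)
    stop("solve_longitudinal_tension: displacement exceeds specimen length",
         call. = FALSE)
  A <- annulus_area(spec)
  u <- seq(0, displacement, length.out = max(2L, n_steps + 1L))
  eps <- u / spec$length

  if (inherits(model$bio, "poly_fit")) {
    sig_wall <- eval_polynomial(model$bio, eps)
  } else {
    st <- material_state(1L)
    sig_wall <- numeric(length(eps))
    for (k in seq_along(eps)) {
      up <- stress_update(eps[k], st, model$bio)
      sig_wall[k] <- up$sigma
      st <- up$state
    }
  }
  F_wall <- A * sig_wall

  F_coil <- 0
  if (!is.null(model$helix) && model$helix$n_layers > 0L) {
    h <- model$helix
    G <- model$polymer$E / (2 * (1 + model$polymer$nu))
    D_coil <- 2 * tube_radii(spec, h$thread_diameter)$winding
    n_turns <- spec$length / h$pitch
    k_coil <- G * h$thread_diameter^4 / (8 * D_coil^3 * n_turns)
    F_coil <- h$n_layers * k_coil * u
  }
  F_tot <- F_wall + F_coil
  stress_strain_curve(eps, F_tot / A, "longitudinal", force = F_tot)
}

#' Classical closed-form deflection of a ring under opposed point loads
#'
#' A slender elastic ring of radius `R` and bending rigidity `EI`, pulled
#' by two opposite radial point loads `F`, changes diameter along the load
#' line by `F * R^3 / (EI) * (pi/4 - 2/pi)`.
#'
#' @param F Load, N.
#' @param R Ring (centreline) radius, mm.
#' @param EI Bending rigidity, N mm^2.
#' @return Diametral deflection, mm.
#' @export
ring_bending_reference <- function(F, R, EI) {
  F * R^3 / EI * (pi / 4 - 2 / pi)
}

# Linear planar frame FE of a closed ring: N straight 2-node beam elements
# (axial + Euler-Bernoulli bending), loaded by opposed point forces along a
# diameter. Returns the diametral stiffness dF/d(delta), N/mm.
ring_fe_stiffness <- function(R, EA, EI, n_elem = 72L) {
  n_elem <- as.integer(n_elem)
  if (n_elem %% 4L != 0L) n_elem <- n_elem + (4L - n_elem %% 4L)
  th <- 2 * pi * (seq_len(n_elem) - 1L) / n_elem
  xy <- cbind(R * cos(th), R * sin(th))
  ndof <- 3L * n_elem
  K <- matrix(0, ndof, ndof)
  for (e in seq_len(n_elem)) {
    a <- e; b <- if (e == n_elem) 1L else e + 1L
    d <- xy[b, ] - xy[a, ]
    L <- sqrt(sum(d^2))
    cth <- d[1] / L; sth <- d[2] / L
    ka <- EA / L
    kb <- EI / L^3
    kl <- matrix(0, 6, 6)
    kl[c(1, 4), c(1, 4)] <- ka * matrix(c(1, -1, -1, 1), 2)
    kl[c(2, 3, 5, 6), c(2, 3, 5, 6)] <- kb * matrix(c(
      12, 6 * L, -12, 6 * L,
      6 * L, 4 * L^2, -6 * L, 2 * L^2,
      -12, -6 * L, 12, -6 * L,
      6 * L, 2 * L^2, -6 * L, 4 * L^2), 4, 4, byrow = TRUE)
    Tm <- diag(6)
    Tm[1:2, 1:2] <- Tm[4:5, 4:5] <- matrix(c(cth, -sth, sth, cth), 2)
    kg <- Tm %*% kl %*% t(Tm)
    dofs <- c(3 * a - 2, 3 * a - 1, 3 * a, 3 * b - 2, 3 * b - 1, 3 * b)
    K[dofs, dofs] <- K[dofs, dofs] + kg
  }
  i_top <- n_elem / 4L + 1L      # node at +y
  i_bot <- 3L * n_elem / 4L + 1L # node at -y
  fix <- c(3 * i_bot - 2, 3 * i_bot - 1,  # bottom pinned
           3 * i_top - 2)                 # symmetry: no lateral motion at top
  free <- setdiff(seq_len(ndof), fix)
  Fv <- numeric(ndof)
  Fv[3 * i_top - 1] <- 1
  u <- numeric(ndof)
  u[free] <- solve(K[free, free], Fv[free])
  1 / u[3 * i_top - 1]
}

#' Virtual transverse (ring) tension test
#'
#' The 15 mm ring specimen is stretched by two rigid pins inside the lumen
#' moving apart. The composite section combines the biological wall
#' (width x thickness at its initial modulus) with the helix threads
#' crossing the section (`n_turns * n_layers` thread areas at the polymer
#' modulus, bending about their own axes -- the helix embraces the wall
#' without fusing to it, so no composite-beam parallel-axis action is
#' assumed). The initial, bending-dominated diametral stiffness comes from
#' a linear planar curved-beam finite-element solve; beyond the
#' inextensional-ovalization limit `(pi - 2) * R` the response transitions
#' smoothly to stretching of the two wall strands (pin wrap frozen, no
#' sliding). Nominal stress is `F / (2 * t * L)` -- force over the two cut
#' wall sections.
#'
#' @param model A [scaffold_model()] with a 15 mm tube spec.
#' @param pin_displacement Total pin-separation increase, mm.
#' @param pin_diameter Pin diameter, mm (must be smaller than the lumen).
#' @param n_steps Number of curve samples.
#' @param n_elem Ring FE discretization.
#' @return A [stress_strain_curve()] (`direction = "transverse"`, strain
#'   `delta / (2R)`, `force` column) with attributes `k_initial` (N/mm)
#'   and `section` (composite EI, EA).
#' @export
solve_transverse_ring <- function(model, pin_displacement, pin_diameter = 2,
                                  n_steps = 60L, n_elem = 72L) {
  stopifnot(inherits(model, "scaffold_model"))
  if (pin_displacement < 0)
    stop("solve_transverse_ring: negative displacement", call. = FALSE)
  spec <- model$spec
  if (pin_diameter >= spec$inner_diameter)
    stop("solve_transverse_ring: pin diameter must be smaller than the lumen",
         call. = FALSE)
  R <- model$mesh$radius
  b <- spec$length
  t_wall <- mean(model$thickness)
  E_bio <- if (inherits(model$bio, "poly_fit")) {
    model$bio$coefficients[["a1"]]
  } else model$bio$E0

  EI <- E_bio * b * t_wall^3 / 12
  EA <- E_bio * b * t_wall
  if (!is.null(model$helix) && model$helix$n_layers > 0L) {
    h <- model$helix
    A_th <- pi * (h$thread_diameter / 2)^2
    I_th <- pi * h$thread_diameter^4 / 64
    n_cross <- (b / h$pitch) * h$n_layers
    EI <- EI + model$polymer$E * n_cross * I_th
    EA <- EA + model$polymer$E * n_cross * A_th
  }

  k_b <- ring_fe_stiffness(R, EA, EI, n_elem)
  delta_max <- (pi - 2) * R              # inextensional ovalization limit
  ell_s <- pi * R - pi * pin_diameter / 2  # free strand length (wrap frozen)

  delta_of_F <- function(F) {
    delta_max * (1 - exp(-F / (k_b * delta_max))) + F * ell_s / (2 * EA)
  }
  deltas <- seq(0, pin_displacement, length.out = max(2L, n_steps + 1L))
  Fv <- numeric(length(deltas))
  for (k in seq_along(deltas)) {
    if (deltas[k] == 0) { Fv[k] <- 0; next }
    hi <- max(1, 4 * k_b * deltas[k])
    while (delta_of_F(hi) < deltas[k]) hi <- hi * 2
    Fv[k] <- stats::uniroot(function(F) delta_of_F(F) - deltas[k],
                            c(0, hi), tol = 1e-10)$root
  }
  curve <- stress_strain_curve(deltas / (2 * R), Fv / (2 * t_wall * b),
                               "transverse", force = Fv)
  attr(curve, "k_initial") <- 1 / (1 / k_b + ell_s / (2 * EA))
  attr(curve, "section") <- c(EI = EI, EA = EA, R = R)
  curve
}
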