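#' Parameters of the damage-coupled elastoplastic wall law
#'
#' The biological wall is linear elastic (initial modulus `E0`) up to a
#' strain-based yield limit `eps_y`. Beyond yield, irreversible (plastic)
#' strain accumulates and the elastic modulus simultaneously degrades:
#' the remaining modulus fraction `f` ramps linearly from 1 down to
#' `floor` as accumulated plastic strain grows from 0 to `PE_ref`, and
#' never falls below the floor. Where yield is not exceeded, deformation
#' stays fully reversible and properties do not degrade.
#'
#' Default calibration: `E0 = 1` MPa and `eps_y = 0.6` mm/mm (bench-derived
#' values for the decellularized wall); `floor = 0.1` (degradation spans
#' 100 down to 10 percent of the initial modulus); `PE_ref = 0.0055` mm/mm,
#' chosen so the modulus floor is reached at the plastic-strain level
#' observed in the most damaged wall regions (0.55 percent).
#'
#' @param E0 Initial elastic modulus, MPa.
#' @param eps_y Yield strain, mm/mm.
#' @param floor Minimal modulus fraction in (0, 1).
#' @param PE_ref Accumulated plastic strain at which the floor is reached,
#'   mm/mm.
#' @param nu Poisson ratio used by the shell membrane/bending stiffness.
#' @return Object of class `damage_plastic_params`.
#' @export
damage_plastic_params <- function(E0 = 1, eps_y = 0.6, floor = 0.1,
                                  PE_ref = 0.0055, nu = 0) {
  stopifnot(E0 > 0, eps_y > 0, PE_ref > 0, nu >= 0, nu < 0.5)
  if (floor <= 0 || floor >= 1)
    stop("damage_plastic_params: 'floor' must be in (0, 1)", call. = FALSE)
  structure(list(E0 = E0, eps_y = eps_y, floor = floor, PE_ref = PE_ref,
                 nu = nu),
            class = "damage_plastic_params")
}

#' Linear-elastic polymer parameters
#'
#' The extruded reinforcement polymers are modelled as linear elastic with
#' no plasticity or property degradation. Measured extruded moduli:
#' PVDF 458 MPa, PCL 321 MPa.
#'
#' @param E Elastic modulus, MPa.
#' @param id `"PVDF"` or `"PCL"`.
#' @param nu Poisson ratio (used for the coil shear modulus).
#' @return Object of class `polymer_params`.
#' @export
polymer_params <- function(E, id = c("PVDF", "PCL"), nu = 0.35) {
  id <- match.arg(id)
  if (!is.numeric(E) || E <= 0)
    stop("polymer_params: 'E' must be > 0", call. = FALSE)
  structure(list(E = E, id = id, nu = nu), class = "polymer_params")
}

#' Per-element material state
#'
#' Tracks, for every wall element, the accumulated plastic strain `PE_acc`
#' (mm/mm, non-decreasing) and the damage factor `f` (remaining modulus
#' fraction, non-increasing, bounded below by the floor).
#'
#' @param n_axial,n_circ Grid dimensions (or pass a single integer
#'   `n_axial` for a flat state vector with `n_circ = 1`).
#' @return Object of class `material_state` with matrices `PE_acc`, `f`.
#' @export
material_state <- function(n_axial, n_circ = 1L) {
  structure(list(PE_acc = matrix(0, n_axial, n_circ),
                 f = matrix(1, n_axial, n_circ)),
            class = "material_state")
}

#' Damage factor from accumulated plastic strain
#'
#' Linear modulus-degradation ramp:
#' `f = max(floor, 1 - (1 - floor) * PE_acc / PE_ref)`.
#' Total and monotone non-increasing in `PE_acc`; `f(0) = 1` and
#' `f(PE_ref) = floor`.
#'
#' @param PE_acc Accumulated plastic strain, mm/mm (vectorized, >= 0).
#' @param params A [damage_plastic_params()].
#' @return Modulus fraction(s) in `[floor, 1]`.
#' @examples
#' damage_factor(0, damage_plastic_params())       # 1
#' damage_factor(0.0055, damage_plastic_params())  # 0.1
#' @export
damage_factor <- function(PE_acc, params = damage_plastic_params()) {
  stopifnot(all(PE_acc >= 0))
  pmax(params$floor, 1 - (1 - params$floor) * PE_acc / params$PE_ref)
}

#' One-shot stress and state update under a total strain
#'
#' Rate-independent, monotonic plasticity with coupled damage. Given the
#' current total (hoop) strain and the element's state:
#' plastic strain updates to `max(PE_old, eps_total - eps_y)` when the
#' yield strain is exceeded (no reverse plasticity; repeated same-sign
#' cycling never unloads plastically); the damage factor follows
#' [damage_factor()] of the updated plastic strain; stress is
#' `f * E0 * (eps_total - PE)`. Below yield the response is exactly linear
#' elastic and the state is unchanged.
#'
#' All arguments vectorize elementwise over strain/state fields.
#'
#' @param eps_total Total strain, mm/mm (>= 0; compression is outside the
#'   model).
#' @param state A [material_state()] (fields recycled to the shape of
#'   `eps_total`).
#' @param params A [damage_plastic_params()].
#' @return List with `sigma` (MPa) and `state` (updated `material_state`).
#' @examples
#' st <- material_state(1)
#' stress_update(0.5, st)$sigma   # 0.5 MPa, still virgin
#' @export
stress_update <- function(eps_total, state, params = damage_plastic_params()) {
  if (any(eps_total < 0))
    stop("stress_update: negative total strain (compression not modelled)",
         call. = FALSE)
  PE_old <- state$PE_acc
  PE_new <- pmax(PE_old, pmax(0, eps_total - params$eps_y))
  f_new <- damage_factor(PE_new, params)
  sigma <- f_new * params$E0 * (eps_total - PE_new)
  dim(sigma) <- dim(eps_total)
  new_state <- state
  dim(PE_new) <- dim(PE_old)
  dim(f_new) <- dim(PE_old)
  new_state$PE_acc <- PE_new
  new_state$f <- f_new
  list(sigma = sigma, state = new_state)
}
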