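#' Compliance from diastolic and systolic diameters
#'
#' `100 * (D_sys - D_dia) / D_dia`: the diameter change expressed as a
#' percentage of the minimum ("diastolic") diameter.
#'
#' @param d_dia Diastolic (lower-pressure) diameter, mm.
#' @param d_sys Systolic (higher-pressure) diameter, mm.
#' @return Compliance, percent.
#' @examples
#' compliance_pct(5.00, 5.10) # 2
#' @export
compliance_pct <- function(d_dia, d_sys) {
  stopifnot(d_dia > 0)
  100 * (d_sys - d_dia) / d_dia
}

#' Virtual compliance test
#'
#' Pressurizes the 60 mm encastre-mounted model statically at the two
#' endpoint pressures of a named physiological range (hypo 0.007--0.012,
#' normo 0.011--0.016, hyper 0.015--0.020 MPa) and reports the outer
#' mid-span diameter change as a percentage of the diastolic diameter.
#'
#' @param model A [scaffold_model()] (60 mm specimen).
#' @param range `"hypo"`, `"normo"` or `"hyper"`.
#' @param bc A [boundary_condition()].
#' @param at Diameter measurement convention, see [outer_diameter()].
#' @param ... Passed to [solve_pressure()].
#' @return Object of class `compliance_result`: `range`, `p_dia`, `p_sys`
#'   (MPa), `d_dia`, `d_sys` (mm), `compliance_pct`, `flagged`.
#' @export
compliance_test <- function(model, range = c("hypo", "normo", "hyper"),
                            bc = boundary_condition(), at = "mid", ...) {
  range <- match.arg(range)
  pr <- pressure_range_mpa(range)
  r1 <- solve_pressure(model, pr[1], bc, ...)
  r2 <- solve_pressure(model, pr[2], bc, ...)
  d1 <- outer_diameter(model, r1, at)
  d2 <- outer_diameter(model, r2, at)
  structure(list(range = range, p_dia = pr[1], p_sys = pr[2],
                 d_dia = d1, d_sys = d2,
                 compliance_pct = compliance_pct(d1, d2),
                 flagged = !(r1$converged && r2$converged) ||
                   r1$validity != "ok" || r2$validity != "ok"),
            class = "compliance_result")
}

#' @export
print.compliance_result <- function(x, ...) {
  cat(sprintf("compliance_result [%s]: %.4f -> %.4f mm, compliance %.3g%%%s\n",
              x$range, x$d_dia, x$d_sys, x$compliance_pct,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Apply the bench stop criterion to a force or stress curve
#'
#' Scans the sampled curve and truncates it at the first sample whose
#' force drops below `(1 - drop_fraction)` of the running maximum -- the
#' bench machines' rupture criterion (30 percent force drop).
#'
#' @param curve A [stress_strain_curve()].
#' @param drop_fraction Relative force drop that triggers the stop.
#' @return The (possibly truncated) curve, with attribute `stop_index`
#'   set to the triggering sample index, or `NA` if never triggered.
#' @export
apply_stop_criterion <- function(curve, drop_fraction = 0.30) {
  stopifnot(inherits(curve, "stress_strain_curve"),
            drop_fraction > 0, drop_fraction < 1)
  y <- if ("force" %in% names(curve)) curve$force else curve$stress
  run_max <- cummax(y)
  hit <- which(y < (1 - drop_fraction) * run_max)
  if (length(hit) == 0L) {
    attr(curve, "stop_index") <- NA_integer_
    return(curve)
  }
  k <- hit[1L]
  out <- curve[seq_len(k), , drop = FALSE]
  attr(out, "direction") <- attr(curve, "direction")
  attr(out, "stop_index") <- k
  class(out) <- class(curve)
  out
}

#' Virtual uniaxial tension test with stop criterion
#'
#' Runs the longitudinal (60 mm bar + coil) or transverse (15 mm ring)
#' virtual test up to `max_strain` and applies the 30-percent force-drop
#' stop criterion to the sampled curve.
#'
#' @param model A [scaffold_model()].
#' @param direction `"longitudinal"` or `"transverse"`.
#' @param max_strain Maximum nominal strain, mm/mm (> 0).
#' @param stop_on_force_drop Force-drop fraction triggering the stop.
#' @param n_steps Curve sampling.
#' @param ... Passed to the underlying solver.
#' @return A [stress_strain_curve()] with `stop_index` attribute.
#' @export
tension_test <- function(model, direction = c("longitudinal", "transverse"),
                         max_strain = 1.0, stop_on_force_drop = 0.30,
                         n_steps = 100L, ...) {
  direction <- match.arg(direction)
  if (max_strain <= 0)
    stop("tension_test: 'max_strain' must be > 0", call. = FALSE)
  curve <- if (direction == "longitudinal") {
    solve_longitudinal_tension(model, max_strain * model$spec$length,
                               n_steps = n_steps, ...)
  } else {
    solve_transverse_ring(model, max_strain * 2 * model$mesh$radius,
                          n_steps = n_steps, ...)
  }
  apply_stop_criterion(curve, stop_on_force_drop)
}

#' Ratio of initial stiffness between two curves
#'
#' Ratio of the initial moduli (slope through the origin over the
#' low-strain window) of a reinforced and a control curve; the radial
#' stiffness-amplification measure.
#'
#' @param curve_reinforced,curve_control Stress-strain curves.
#' @param strain_window Window upper bound, mm/mm.
#' @return The ratio (dimensionless).
#' @export
stiffness_ratio <- function(curve_reinforced, curve_control,
                            strain_window = 0.01) {
  if (strain_window > max(curve_reinforced$strain) ||
      strain_window > max(curve_control$strain))
    stop("stiffness_ratio: window outside one of the curves", call. = FALSE)
  initial_modulus(curve_reinforced, strain_window) /
    initial_modulus(curve_control, strain_window)
}
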