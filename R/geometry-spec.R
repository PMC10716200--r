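#' Specification of an idealized tubular scaffold
#'
#' Defines the cylindrical shell stand-in for a decellularized vascular
#' scaffold segment: a tube of given inner diameter, length and base wall
#' thickness, discretized into a structured grid of `n_axial` x `n_circ`
#' quadrilateral shell elements on the wall mid-surface.
#'
#' @param inner_diameter Inner (lumen) diameter, mm.
#' @param length Axial length of the segment, mm (bench specimens are 15 or
#'   60 mm).
#' @param base_thickness Nominal wall thickness, mm.
#' @param n_axial Number of element rows along the axis (>= 4).
#' @param n_circ Number of elements around the circumference (>= 8, even).
#' @return An object of class `tube_spec`.
#' @examples
#' tube_spec(inner_diameter = 5, length = 60)
#' @export
tube_spec <- function(inner_diameter = 5, length = 60, base_thickness = 0.5,
                      n_axial = 60, n_circ = 32) {
  dims <- c(inner_diameter = inner_diameter, length = length,
            base_thickness = base_thickness)
  for (nm in names(dims)) {
    if (!is.numeric(dims[[nm]]) || length(dims[[nm]]) != 1L ||
        !is.finite(dims[[nm]]) || dims[[nm]] <= 0) {
      stop("tube_spec: '", nm, "' must be a positive finite number", call. = FALSE)
    }
  }
  n_axial <- as.integer(n_axial); n_circ <- as.integer(n_circ)
  if (n_axial < 4L) stop("tube_spec: 'n_axial' must be >= 4", call. = FALSE)
  if (n_circ < 8L) stop("tube_spec: 'n_circ' must be >= 8", call. = FALSE)
  if (n_circ %% 2L != 0L) stop("tube_spec: 'n_circ' must be even", call. = FALSE)
  structure(list(inner_diameter = inner_diameter, length = length,
                 base_thickness = base_thickness,
                 n_axial = n_axial, n_circ = n_circ),
            class = "tube_spec")
}

#' @export
print.tube_spec <- function(x, ...) {
  cat(sprintf("tube_spec: ID %g mm, L %g mm, t %g mm, %d x %d elements\n",
              x$inner_diameter, x$length, x$base_thickness,
              x$n_axial, x$n_circ))
  invisible(x)
}

# Derived radii of a tube_spec. mid = wall mid-surface (the shell reference
# surface), inner = lumen, outer = adventitial surface, winding = centreline
# radius of a helix thread of diameter d lying on the outer surface.
tube_radii <- function(spec, thread_diameter = 0) {
  r_in <- spec$inner_diameter / 2
  list(inner = r_in,
       mid = r_in + spec$base_thickness / 2,
       outer = r_in + spec$base_thickness,
       winding = r_in + spec$base_thickness + thread_diameter / 2)
}

#' Specification of a locally thin wall region
#'
#' Real decellularized scaffolds have uneven walls; the regions of minor
#' thickness are where aneurysmal change concentrates. A thin patch is a
#' smooth (cosine-tapered) local reduction of wall thickness centred at
#' `(axial_center, circ_center)`.
#'
#' @param axial_center Axial position of the patch centre, mm.
#' @param circ_center Circumferential position, radians.
#' @param axial_halfwidth Half-extent along the axis, mm.
#' @param circ_halfwidth Half-extent around the circumference, radians.
#' @param min_thickness Wall thickness at the patch centre, mm.
#' @param transition Smoothness exponent (>= 1) of the cosine taper; larger
#'   values concentrate the thinning near the centre.
#' @return An object of class `thin_patch_spec`.
#' @export
thin_patch_spec <- function(axial_center, circ_center = 0,
                            axial_halfwidth = 6, circ_halfwidth = 1.0,
                            min_thickness = 0.06, transition = 2) {
  stopifnot(is.numeric(axial_center), is.numeric(circ_center),
            axial_halfwidth > 0, circ_halfwidth > 0,
            min_thickness > 0, transition >= 1)
  structure(list(axial_center = axial_center, circ_center = circ_center,
                 axial_halfwidth = axial_halfwidth,
                 circ_halfwidth = circ_halfwidth,
                 min_thickness = min_thickness, transition = transition),
            class = "thin_patch_spec")
}

#' Specification of a polymer reinforcement helix
#'
#' Geometry of the extruded double helix wound onto the scaffold's outer
#' surface. The measured pitches are about 2.25 mm (PVDF) and 2.15 mm (PCL)
#' with thread diameters about 0.33 and 0.30 mm.
#'
#' @param pitch Axial advance per turn, mm (must exceed `thread_diameter`).
#' @param thread_diameter Diameter of the extruded thread, mm.
#' @param n_layers Number of helix layers: 0 (none), 1, or 2 (the double
#'   helix used on the physical scaffolds).
#' @param polymer_id `"PVDF"` or `"PCL"`.
#' @param phase Angular phase of the first layer at z = 0, radians.
#' @param handedness +1 or -1 winding sense.
#' @return An object of class `helix_spec`.
#' @export
helix_spec <- function(pitch = 2.25, thread_diameter = 0.33, n_layers = 2,
                       polymer_id = c("PVDF", "PCL"), phase = 0,
                       handedness = 1) {
  polymer_id <- match.arg(polymer_id)
  if (!is.numeric(pitch) || pitch <= 0)
    stop("helix_spec: 'pitch' must be > 0", call. = FALSE)
  if (pitch <= thread_diameter)
    stop("helix_spec: 'pitch' must exceed 'thread_diameter'", call. = FALSE)
  n_layers <- as.integer(n_layers)
  if (!n_layers %in% 0:2)
    stop("helix_spec: 'n_layers' must be 0, 1 or 2", call. = FALSE)
  if (!handedness %in% c(-1, 1))
    stop("helix_spec: 'handedness' must be +1 or -1", call. = FALSE)
  structure(list(pitch = pitch, thread_diameter = thread_diameter,
                 n_layers = n_layers, polymer_id = polymer_id,
                 phase = phase, handedness = handedness),
            class = "helix_spec")
}

#' Helix angle measured from the hoop direction
#'
#' For a helix of given pitch wound on a cylinder of given diameter the
#' angle between the thread and the circumferential (hoop) direction is
#' `atan(pitch / (pi * diameter))`.
#'
#' @param pitch Helix pitch, mm.
#' @param diameter Winding diameter, mm.
#' @return Angle in radians.
#' @examples
#' helix_angle(2.25, 6) * 180 / pi # about 6.8 degrees
#' @export
helix_angle <- function(pitch, diameter) {
  stopifnot(pitch > 0, diameter > 0)
  atan(pitch / (pi * diameter))
}
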