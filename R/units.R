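# Units used throughout the package: lengths in mm, pressures and moduli in
# MPa, forces in N (1 MPa * 1 mm^2 = 1 N). These are the consistent
# mm-MPa-N unit system common in vascular device FE work.

#' Convert pressure from mmHg to MPa
#'
#' Generic converter using 1 mmHg = 133.322 Pa. The named physiological
#' pressure ranges in [pressure_range_mpa()] use rounded preset values
#' instead of this conversion, matching bench-protocol conventions.
#'
#' @param mmhg Pressure in millimetres of mercury.
#' @return Pressure in MPa.
#' @examples
#' mmhg_to_mpa(120) # ~0.016 MPa
#' @export
mmhg_to_mpa <- function(mmhg) {
  stopifnot(is.numeric(mmhg))
  mmhg * 133.322e-6
}

#' Preset physiological pressure ranges
#'
#' Returns the lower/upper test pressures (MPa) for the three named ranges
#' used in compliance testing: hypotensive 50--90 mmHg (0.007--0.012 MPa),
#' normotensive 80--120 mmHg (0.011--0.016 MPa) and hypertensive
#' 110--150 mmHg (0.015--0.020 MPa). The preset MPa values are the rounded
#' protocol figures, not exact unit conversions.
#'
#' @param range One of `"hypo"`, `"normo"`, `"hyper"`.
#' @return Numeric length-2 vector `c(p_min, p_max)` in MPa.
#' @export
pressure_range_mpa <- function(range = c("hypo", "normo", "hyper")) {
  range <- match.arg(range)
  switch(range,
    hypo  = c(0.007, 0.012),
    normo = c(0.011, 0.016),
    hyper = c(0.015, 0.020)
  )
}
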