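#' Build a per-element wall-thickness field
#'
#' Starts from the tube's base thickness, carves out smooth thin patches
#' (cosine taper to `min_thickness` at each patch centre), and optionally
#' adds seeded correlated random variability emulating the uneven surface
#' of a real decellularized scaffold. The field is deterministic for a
#' fixed seed.
#'
#' @param spec A [tube_spec()].
#' @param patches List of [thin_patch_spec()] objects (possibly empty).
#' @param noise_amplitude Standard deviation of the correlated thickness
#'   noise, mm (0 disables noise).
#' @param noise_corr_length Correlation length of the noise, mm.
#' @param seed Integer seed for the noise; required when
#'   `noise_amplitude > 0`.
#' @return Object of class `thickness_field`: a numeric matrix
#'   `n_axial x n_circ` of per-element thickness (mm) with the generating
#'   parameters attached.
#' @export
build_thickness_field <- function(spec, patches = list(),
                                  noise_amplitude = 0,
                                  noise_corr_length = 3, seed = 1L) {
  stopifnot(inherits(spec, "tube_spec"))
  if (inherits(patches, "thin_patch_spec")) patches <- list(patches)
  if (noise_amplitude < 0)
    stop("build_thickness_field: 'noise_amplitude' must be >= 0", call. = FALSE)
  n_a <- spec$n_axial; n_c <- spec$n_circ
  dz <- spec$length / n_a
  z_e <- (seq_len(n_a) - 0.5) * dz                 # element centres, axial
  phi_e <- 2 * pi * (seq_len(n_c) - 0.5) / n_c     # element centres, circ
  th <- matrix(spec$base_thickness, nrow = n_a, ncol = n_c)

  for (p in patches) {
    stopifnot(inherits(p, "thin_patch_spec"))
    if (p$min_thickness >= spec$base_thickness)
      stop("build_thickness_field: patch min_thickness must be < base_thickness",
           call. = FALSE)
    if (p$axial_center - p$axial_halfwidth < 0 ||
        p$axial_center + p$axial_halfwidth > spec$length)
      stop("build_thickness_field: patch extends outside the mesh span",
           call. = FALSE)
    # smooth bump: 1 at the centre, 0 at the halfwidth edge; the transition
    # exponent (>= 1) flattens the bottom of the thin region, sharpening
    # the taper towards the edge
    bz <- cos(pmin(1, abs(z_e - p$axial_center) /
                     p$axial_halfwidth)^p$transition * pi / 2)
    dphi <- abs(((phi_e - p$circ_center + pi) %% (2 * pi)) - pi)
    bp <- cos(pmin(1, dphi / p$circ_halfwidth)^p$transition * pi / 2)
    bump <- outer(bz, bp)
    th <- th - (spec$base_thickness - p$min_thickness) * bump
  }

  if (noise_amplitude > 0) {
    noise <- correlated_noise(n_a, n_c, dz,
                              circ_step = 2 * pi * tube_radii(spec)$mid / n_c,
                              corr_length = noise_corr_length, seed = seed)
    th <- th + noise_amplitude * noise
  }
  th <- pmax(th, 0.01)  # keep strictly positive even under extreme noise
  structure(th, class = c("thickness_field", "matrix"),
            base_thickness = spec$base_thickness,
            noise_amplitude = noise_amplitude,
            noise_corr_length = noise_corr_length, seed = seed)
}

# Correlated Gaussian field on the element grid: white noise smoothed with
# a separable Gaussian kernel (periodic wrap circumferentially, reflected
# axially), renormalized to unit standard deviation.
correlated_noise <- function(n_a, n_c, dz, circ_step, corr_length, seed) {
  set.seed(as.integer(seed))
  w <- matrix(stats::rnorm(n_a * n_c), n_a, n_c)
  smooth_1d <- function(x, sigma_cells, periodic) {
    if (sigma_cells <= 0.2) return(x)
    half <- max(1L, ceiling(3 * sigma_cells))
    k <- stats::dnorm(seq(-half, half), sd = sigma_cells)
    k <- k / sum(k)
    n <- length(x)
    if (periodic) {
      xx <- c(x[(n - half + 1):n], x, x[1:half])
    } else {
      xx <- c(rev(x[1:half]), x, rev(x[(n - half + 1):n]))
    }
    stats::convolve(xx, rev(k), type = "filter")
  }
  for (j in seq_len(n_c)) w[, j] <- smooth_1d(w[, j], corr_length / dz, FALSE)
  for (i in seq_len(n_a)) w[i, ] <- smooth_1d(w[i, ], corr_length / circ_step, TRUE)
  w / stats::sd(w)
}
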