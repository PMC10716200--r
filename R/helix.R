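#' Generate the 3D polyline of a reinforcement helix
#'
#' The thread centreline lies on the winding radius
#' `inner_diameter/2 + base_thickness + thread_diameter/2`. Layer 1
#' advances +z; for a double helix, layer 2 returns -z with the opposite
#' angular slope and a half-turn phase offset, so the two layers cross in a
#' regular lattice (the crossings fuse on the physical scaffold; fusion is
#' represented purely as shared coverage). Each layer is a continuous
#' polyline; the return stroke starts where the extruder reverses.
#'
#' @param h A [helix_spec()].
#' @param t A [tube_spec()].
#' @param points_per_turn Sampling density of the polyline.
#' @param pitch_jitter_sd Optional seeded jitter (sd, mm) of the axial turn
#'   spacing emulating winding irregularity; 0 (default) disables it.
#' @param seed Seed for the jitter.
#' @return Object of class `helix_path`: a matrix with columns
#'   `x, y, z, layer` (mm; layer index 1 or 2). Zero rows when
#'   `n_layers = 0`.
#' @examples
#' hp <- make_helix_path(helix_spec(), tube_spec(length = 15))
#' @export
make_helix_path <- function(h, t, points_per_turn = 64L,
                            pitch_jitter_sd = 0, seed = 1L) {
  stopifnot(inherits(h, "helix_spec"), inherits(t, "tube_spec"))
  r_w <- tube_radii(t, h$thread_diameter)$winding
  if (h$n_layers == 0L) {
    out <- matrix(numeric(0), ncol = 4L,
                  dimnames = list(NULL, c("x", "y", "z", "layer")))
    return(structure(out, class = c("helix_path", "matrix"),
                     winding_radius = r_w, spec = h))
  }
  n_turns <- t$length / h$pitch
  n_pts <- max(2L, ceiling(n_turns * points_per_turn))
  s <- seq(0, 1, length.out = n_pts)
  z <- s * t$length
  if (pitch_jitter_sd > 0) {
    set.seed(as.integer(seed))
    # jitter turn boundaries, interpolate to the sample points
    n_t <- max(2L, ceiling(n_turns))
    zb <- seq(0, t$length, length.out = n_t + 1L)
    zj <- zb + c(0, stats::rnorm(n_t - 1L, sd = pitch_jitter_sd), 0)
    zj <- sort(zj)
    z <- stats::approx(zb, zj, xout = z)$y
  }
  layer_path <- function(layer) {
    sgn <- if (layer == 1L) h$handedness else -h$handedness
    off <- if (layer == 1L) 0 else pi
    zz <- if (layer == 1L) z else rev(z)
    phi <- h$phase + off + sgn * 2 * pi * zz / h$pitch
    cbind(x = r_w * cos(phi), y = r_w * sin(phi), z = zz,
          layer = rep(layer, length(zz)))
  }
  out <- layer_path(1L)
  if (h$n_layers == 2L) out <- rbind(out, layer_path(2L))
  structure(out, class = c("helix_path", "matrix"),
            winding_radius = r_w, spec = h)
}

#' Total arc length of a helix path
#'
#' @param path A `helix_path`.
#' @return Length in mm (segments are summed within each layer).
#' @export
helix_path_length <- function(path) {
  seg <- helix_segments(path)
  sum(seg$len)
}

# Decompose a helix path into straight segments (within-layer only).
# Returns midpoints, lengths and layer ids.
helix_segments <- function(path) {
  if (nrow(path) < 2L) {
    return(list(mid = matrix(numeric(0), ncol = 3L), len = numeric(0)))
  }
  a <- path[-nrow(path), , drop = FALSE]
  b <- path[-1L, , drop = FALSE]
  same_layer <- a[, "layer"] == b[, "layer"]
  a <- a[same_layer, , drop = FALSE]
  b <- b[same_layer, , drop = FALSE]
  d <- b[, 1:3, drop = FALSE] - a[, 1:3, drop = FALSE]
  list(mid = (a[, 1:3, drop = FALSE] + b[, 1:3, drop = FALSE]) / 2,
       len = sqrt(rowSums(d^2)))
}

#' Assign helix path length to shell elements
#'
#' Each straight segment of the helix polyline is assigned, by its
#' midpoint, to the structured-mesh element whose (z, phi) footprint
#' contains it. The summed coverage equals the total path length (the
#' basis of the homogenized reinforcement stiffness).
#'
#' @param path A `helix_path`.
#' @param mesh A native `surface_mesh` (structured tube).
#' @return Matrix `n_axial x n_circ` of covered path length per element,
#'   mm; class `helix_coverage`.
#' @export
helix_coverage <- function(path, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (isTRUE(mesh$external))
    stop("helix_coverage: requires a native structured mesh", call. = FALSE)
  spec <- mesh$spec
  n_a <- spec$n_axial; n_c <- spec$n_circ
  cov <- matrix(0, n_a, n_c)
  seg <- helix_segments(path)
  if (length(seg$len) == 0L) {
    return(structure(cov, class = c("helix_coverage", "matrix"),
                     total_length = 0))
  }
  mid <- seg$mid
  r_mid <- sqrt(mid[, 1]^2 + mid[, 2]^2)
  d_th <- attr(path, "spec")$thread_diameter
  if (any(abs(r_mid - mesh$radius) > spec$base_thickness / 2 + 2 * d_th)) {
    warning("helix_coverage: path lies radially far from the shell surface; ",
            "geometry mismatch?", call. = FALSE)
  }
  dz <- spec$length / n_a
  i <- pmin(n_a, pmax(1L, 1L + floor(mid[, 3] / dz)))
  phi <- atan2(mid[, 2], mid[, 1]) %% (2 * pi)
  j <- pmin(n_c, pmax(1L, 1L + floor(phi / (2 * pi / n_c))))
  for (k in seq_along(seg$len)) cov[i[k], j[k]] <- cov[i[k], j[k]] + seg$len[k]
  structure(cov, class = c("helix_coverage", "matrix"),
            total_length = sum(seg$len))
}
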