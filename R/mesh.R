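#' Build the structured mid-surface mesh of a tube
#'
#' Nodes lie on the wall mid-surface cylinder of radius
#' `inner_diameter/2 + base_thickness/2`, on a structured grid of
#' `n_axial + 1` axial stations times `n_circ` circumferential positions.
#' The circumferential seam is closed: the node at `phi = 2*pi` is the node
#' at `phi = 0`. Elements are the `n_axial x n_circ` quadrilaterals of the
#' grid, indexed (axial row, circumferential column).
#'
#' @param spec A [tube_spec()].
#' @return An object of class `surface_mesh` with fields `nodes` (N x 3
#'   coordinates, mm), `z`, `phi` (cylindrical parameterization per node),
#'   `quads` (element connectivity, N_e x 4 node indices), `n_z`, `n_c`,
#'   `radius` (mid-surface), `spec`, and `external = FALSE`.
#' @examples
#' m <- make_tube_mesh(tube_spec())
#' nrow(m$quads) # 60 * 32 elements
#' @export
make_tube_mesh <- function(spec) {
  stopifnot(inherits(spec, "tube_spec"))
  r <- tube_radii(spec)$mid
  n_z <- spec$n_axial + 1L
  n_c <- spec$n_circ
  z <- seq(0, spec$length, length.out = n_z)
  phi <- 2 * pi * (seq_len(n_c) - 1L) / n_c
  zz <- rep(z, each = n_c)
  pp <- rep(phi, times = n_z)
  nodes <- cbind(x = r * cos(pp), y = r * sin(pp), z = zz)
  # node index helper: station i (1..n_z), column j (1..n_c)
  idx <- function(i, j) (i - 1L) * n_c + ((j - 1L) %% n_c) + 1L
  quads <- matrix(0L, nrow = spec$n_axial * n_c, ncol = 4L)
  e <- 0L
  for (i in seq_len(spec$n_axial)) {
    for (j in seq_len(n_c)) {
      e <- e + 1L
      quads[e, ] <- c(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j))
    }
  }
  structure(list(nodes = nodes, z = zz, phi = pp, quads = quads,
                 n_z = n_z, n_c = n_c, radius = r, spec = spec,
                 external = FALSE),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  if (isTRUE(x$external)) {
    cat(sprintf("surface_mesh (external): %d nodes, %d triangles\n",
                nrow(x$nodes), nrow(x$tris)))
  } else {
    cat(sprintf("surface_mesh: %d nodes, %d quad elements, mid radius %.3f mm\n",
                nrow(x$nodes), nrow(x$quads), x$radius))
  }
  invisible(x)
}

# Map (row i, col j) element index pairs to linear element id, row-major in
# axial rows: e = (i-1)*n_c + j. Used consistently by thickness fields,
# coverage, and the solver.
element_index <- function(i, j, n_c) (i - 1L) * n_c + j

# Total surface area of a mesh (native quads split into triangles, or
# imported triangles).
mesh_area <- function(mesh) {
  tri_area <- function(a, b, c) {
    v1 <- b - a; v2 <- c - a
    0.5 * sqrt(sum(crossprod3(v1, v2)^2))
  }
  nd <- mesh$nodes
  if (isTRUE(mesh$external)) {
    faces <- mesh$tris
    sum(vapply(seq_len(nrow(faces)), function(k) {
      f <- faces[k, ]
      tri_area(nd[f[1], ], nd[f[2], ], nd[f[3], ])
    }, numeric(1)))
  } else {
    faces <- mesh$quads
    sum(vapply(seq_len(nrow(faces)), function(k) {
      f <- faces[k, ]
      tri_area(nd[f[1], ], nd[f[2], ], nd[f[3], ]) +
        tri_area(nd[f[1], ], nd[f[3], ], nd[f[4], ])
    }, numeric(1)))
  }
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Triangulate a native quad mesh (two triangles per quad), preserving
# outward orientation.
mesh_triangles <- function(mesh) {
  if (isTRUE(mesh$external)) return(mesh$tris)
  q <- mesh$quads
  rbind(q[, c(1, 2, 3)], q[, c(1, 3, 4)])
}
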