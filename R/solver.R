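#' End boundary condition for tube solves
#'
#' Bench specimens are mounted over 5 mm sockets at both ends; the
#' corresponding model constraint fully fixes ("encastre") all nodes within
#' the clamped bands.
#'
#' @param end_constraint `"encastre"` (both end bands fixed) or `"free"`.
#' @param clamped_length Length of each clamped band, mm.
#' @return Object of class `boundary_condition`.
#' @export
boundary_condition <- function(end_constraint = c("encastre", "free"),
                               clamped_length = 5) {
  end_constraint <- match.arg(end_constraint)
  stopifnot(clamped_length > 0)
  structure(list(end_constraint = end_constraint,
                 clamped_length = clamped_length),
            class = "boundary_condition")
}

#' Thin-wall (Laplace) closed-form hoop strain
#'
#' Analytic reference for a long uniform pressurized tube:
#' `eps_hoop = p * r / (t * E)`. Used as the independent oracle for the
#' shell solver.
#'
#' @param p Internal pressure, MPa.
#' @param r Tube radius, mm.
#' @param t Wall thickness, mm.
#' @param E Elastic modulus, MPa.
#' @return Hoop strain, mm/mm. Warns outside the thin-wall regime
#'   (`t > r/5`).
#' @examples
#' laplace_reference(0.016, 2.5, 0.5, 1) # 0.08
#' @export
laplace_reference <- function(p, r, t, E) {
  stopifnot(p >= 0, r > 0, t > 0, E > 0)
  if (t > r / 5)
    warning("laplace_reference: t > r/5, outside the thin-wall regime",
            call. = FALSE)
  p * r / (t * E)
}

#' Solve quasi-static internal-pressure equilibrium on the shell model
#'
#' Reduced kinematics: the wall deforms by a radial displacement field
#' `w(z, phi)` on the structured grid. Per element, the hoop membrane
#' force resultant is `t * sigma_bio(eps; f, PE) / (1 - nu^2)` plus the
#' homogenized helix hoop stiffness times the strain, with
#' `eps = w / r_mid`. Neighbouring wall bridges locally thin regions
#' through axial and circumferential bending (flexural rigidity from the
#' local thickness and damage state), so thin patches are supported rather
#' than free-ballooning. The pressure acts on the lumen
#' (`p * r_in / r_mid` per unit mid-surface area), which makes a uniform
#' unreinforced tube reproduce the Laplace closed form
#' `eps = p * r_in / (t * E)` away from the clamps. Newton iteration on
#' the energy gradient; linear wall laws converge in one step.
#'
#' @param model A [scaffold_model()].
#' @param p Internal pressure, MPa (>= 0).
#' @param bc A [boundary_condition()].
#' @param states Optional [material_state()] on the element grid (damage
#'   factor and accumulated plastic strain); virgin state when omitted.
#' @param tol Relative residual tolerance of the Newton loop.
#' @param max_iter Maximum Newton iterations.
#' @param w_init Optional nodal displacement warm start (as returned in
#'   `U1`, flattened row-major), used by the cyclic driver.
#' @return Object of class `solve_result`: `U1` (radial displacement per
#'   node, `n_z x n_c`, mm), `hoop_strain`, `axial_strain`, `hoop_stress`
#'   (per element, `n_axial x n_circ`), `iterations`, `converged`,
#'   `validity` (`"ok"` or `"model validity exceeded"` when peak strain
#'   exceeds 50 percent), plus grid metadata.
#' @export
solve_pressure <- function(model, p, bc = boundary_condition(),
                           states = NULL, tol = 1e-9, max_iter = 30L,
                           w_init = NULL) {
  stopifnot(inherits(model, "scaffold_model"))
  if (!is.numeric(p) || length(p) != 1L || p < 0)
    stop("solve_pressure: 'p' must be a single pressure >= 0", call. = FALSE)
  spec <- model$spec
  n_a <- spec$n_axial; n_c <- spec$n_circ
  if (is.null(states)) states <- material_state(n_a, n_c)
  stopifnot(all(dim(states$f) == c(n_a, n_c)))
  if (bc$clamped_length >= spec$length / 2)
    stop("solve_pressure: clamped length must be < half the specimen length",
         call. = FALSE)

  asm <- shell_assembly(model, states, bc)
  sol <- shell_newton(asm, F_ext = p * (asm$r_in / asm$r) * asm$A_node,
                      model = model, tol = tol, max_iter = max_iter,
                      w_init = w_init)
  w <- sol$w

  eps_e <- as.numeric(Matrix::crossprod(asm$B, w)) / (4 * asm$r)
  sigma_e <- bio_stress(model, eps_e, asm$f_e, asm$PE_e)
  eps_grid <- matrix(eps_e, n_a, n_c)
  sig_grid <- matrix(sigma_e, n_a, n_c)

  # axial bending surface strain t/2 * curvature, element-averaged
  n_z <- n_a + 1L
  wmat <- matrix(w, nrow = n_c)  # [j, i]
  kz_node <- matrix(0, n_c, n_z)
  dz <- spec$length / n_a
  if (n_z >= 3) {
    kz_node[, 2:(n_z - 1)] <- (wmat[, 1:(n_z - 2)] - 2 * wmat[, 2:(n_z - 1)] +
                                 wmat[, 3:n_z]) / dz^2
  }
  kz_e <- t((kz_node[, 1:n_a, drop = FALSE] +
               kz_node[, 2:n_z, drop = FALSE]) / 2)  # n_a x n_c
  ax_grid <- kz_e * model$thickness / 2

  max_strain <- max(abs(eps_grid))
  validity <- if (max_strain > 0.5) "model validity exceeded" else "ok"
  if (!sol$converged)
    warning("solve_pressure: Newton did not converge in ", max_iter,
            " iterations", call. = FALSE)

  structure(list(U1 = t(wmat),   # n_z x n_c
                 hoop_strain = eps_grid,
                 axial_strain = ax_grid,
                 hoop_stress = sig_grid,
                 iterations = sol$iterations, converged = sol$converged,
                 validity = validity, p = p, bc = bc,
                 z_stations = seq(0, spec$length, length.out = n_z),
                 radius = asm$r),
            class = "solve_result")
}

# Precompute grid operators shared by the Newton loop: node/element
# incidence, bending stiffness (constant within a solve), areas, state
# fields in element-grid order (column-major n_axial x n_circ).
shell_assembly <- function(model, states, bc) {
  spec <- model$spec
  n_a <- spec$n_axial; n_c <- spec$n_circ
  n_z <- n_a + 1L
  N <- n_z * n_c
  r <- model$mesh$radius
  dz <- spec$length / n_a
  dphi <- 2 * pi / n_c
  nid <- function(i, j) (i - 1L) * n_c + ((j - 1L) %% n_c) + 1L

  # element-node incidence, elements in column-major (i fastest) order
  ii <- rep(seq_len(n_a), times = n_c)
  jj <- rep(seq_len(n_c), each = n_a)
  enodes <- cbind(nid(ii, jj), nid(ii, jj + 1L),
                  nid(ii + 1L, jj), nid(ii + 1L, jj + 1L))
  n_e <- n_a * n_c
  B <- Matrix::sparseMatrix(i = as.vector(enodes),
                            j = rep(seq_len(n_e), times = 4L),
                            x = 1, dims = c(N, n_e))

  z_nodes <- rep(seq(0, spec$length, length.out = n_z), each = n_c)
  fixed <- rep(FALSE, N)
  if (bc$end_constraint == "encastre") {
    fixed <- z_nodes <= bc$clamped_length |
      z_nodes >= spec$length - bc$clamped_length
  }

  t_e <- as.vector(model$thickness)
  f_e <- as.vector(states$f)
  PE_e <- as.vector(states$PE_acc)
  C_hx <- as.vector(helix_hoop_stiffness(model))
  nu_b <- bio_nu(model)
  mem_fac <- 1 / (1 - nu_b^2)

  E_lin <- if (inherits(model$bio, "poly_fit")) {
    model$bio$coefficients[["a1"]]
  } else model$bio$E0
  D_e <- f_e * E_lin * t_e^3 / 12 * mem_fac
  D_node <- as.numeric(B %*% D_e) / pmax(as.numeric(B %*% rep(1, n_e)), 1)
  A_node <- r * dphi * ifelse(z_nodes %in% c(0, spec$length), dz / 2, dz)

  # bending stiffness: sum over nodes of A*D*(L w)^2 / 2 for the axial and
  # circumferential second-difference stencils
  trip <- vector("list", 0)
  add_stencil <- function(center, minus, plus, h) {
    cols <- cbind(minus, center, plus)
    coef <- c(1, -2, 1) / h^2
    wf <- A_node[center] * D_node[center]
    out <- vector("list", 9)
    k <- 0
    for (a in 1:3) for (b in 1:3) {
      k <- k + 1
      out[[k]] <- cbind(cols[, a], cols[, b], wf * coef[a] * coef[b])
    }
    do.call(rbind, out)
  }
  st <- list()
  izz <- 2:(n_z - 1L)
  for (j in seq_len(n_c)) {
    st[[length(st) + 1L]] <- add_stencil(nid(izz, j), nid(izz - 1L, j),
                                         nid(izz + 1L, j), dz)
    iz <- seq_len(n_z)
    st[[length(st) + 1L]] <- add_stencil(nid(iz, j), nid(iz, j - 1L),
                                         nid(iz, j + 1L), r * dphi)
  }
  st <- do.call(rbind, st)
  K_bend <- Matrix::sparseMatrix(i = st[, 1], j = st[, 2], x = st[, 3],
                                 dims = c(N, N))

  # axial-slope operator for the von Karman membrane-stretch term:
  # s_e = d w / d z averaged over the element's two node columns
  sgn <- c(-1, -1, 1, 1) / (2 * dz)  # nodes (i,j),(i,j+1),(i+1,j),(i+1,j+1)
  Bz <- Matrix::sparseMatrix(i = as.vector(enodes),
                             j = rep(seq_len(n_e), times = 4L),
                             x = rep(sgn, each = n_e),
                             dims = c(N, n_e))
  Cz_e <- f_e * E_lin * t_e * mem_fac  # axial membrane stiffness, elastic

  list(B = B, Bz = Bz, enodes = enodes, K_bend = K_bend, fixed = fixed,
       free = which(!fixed), A_node = A_node, A_e = r * dphi * dz,
       t_e = t_e, f_e = f_e, PE_e = PE_e, C_hx = C_hx, Cz_e = Cz_e,
       mem_fac = mem_fac,
       r = r, r_in = tube_radii(spec)$inner, N = N, n_e = n_e)
}

# Newton iteration (with backtracking line search on the residual norm)
# for radial equilibrium given an external nodal load. The energy combines
# hoop membrane stress, the von Karman axial membrane-stretch term
# (eps_z = slope^2 / 2, the geometric stiffening that saturates a growing
# bulge), bending, and the pressure work.
shell_newton <- function(asm, F_ext, model, tol, max_iter, w_init = NULL) {
  w <- if (is.null(w_init)) numeric(asm$N) else w_init
  w[asm$fixed] <- 0
  iterations <- 0L
  converged <- TRUE
  f_scale <- max(sqrt(sum(F_ext^2)), 1e-12)
  residual <- function(w) {
    eps_e <- as.numeric(Matrix::crossprod(asm$B, w)) / (4 * asm$r)
    N_theta <- asm$mem_fac * asm$t_e *
      bio_stress(model, eps_e, asm$f_e, asm$PE_e) + asm$C_hx * eps_e
    s_e <- as.numeric(Matrix::crossprod(asm$Bz, w))
    g <- as.numeric(asm$K_bend %*% w) +
      as.numeric(asm$B %*% (asm$A_e * N_theta / (4 * asm$r))) +
      as.numeric(asm$Bz %*% (asm$A_e * asm$Cz_e * s_e^3 / 2))
    res <- g - F_ext
    res[asm$fixed] <- 0
    list(res = res, eps_e = eps_e, s_e = s_e, norm = sqrt(sum(res^2)))
  }
  cur <- residual(w)
  repeat {
    if (cur$norm <= tol * f_scale) break
    if (iterations >= max_iter) { converged <- FALSE; break }
    k_e <- asm$A_e * (asm$mem_fac * asm$t_e *
                        bio_tangent(model, cur$eps_e, asm$f_e) + asm$C_hx) /
      (16 * asm$r^2)
    H <- asm$K_bend +
      asm$B %*% Matrix::Diagonal(x = k_e) %*% Matrix::t(asm$B) +
      asm$Bz %*% Matrix::Diagonal(x = 1.5 * asm$A_e * asm$Cz_e * cur$s_e^2) %*%
        Matrix::t(asm$Bz)
    dw <- numeric(asm$N)
    dw[asm$free] <- as.numeric(
      Matrix::solve(H[asm$free, asm$free, drop = FALSE], -cur$res[asm$free]))
    step <- 1
    repeat {
      nxt <- residual(w + step * dw)
      if (nxt$norm < cur$norm || step < 1 / 64) break
      step <- step / 2
    }
    w <- w + step * dw
    cur <- nxt
    iterations <- iterations + 1L
  }
  list(w = w, iterations = iterations, converged = converged)
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf(paste0("solve_result: p = %g MPa, max U1 = %.4g mm, ",
                     "max hoop strain = %.4g, %d Newton iteration(s), %s%s\n"),
              x$p, max(abs(x$U1)), max(abs(x$hoop_strain)), x$iterations,
              if (x$converged) "converged" else "NOT CONVERGED",
              if (x$validity != "ok") paste0(" [", x$validity, "]") else ""))
  invisible(x)
}

#' Outer diameter of a pressurized model
#'
#' @param model The solved [scaffold_model()].
#' @param result The corresponding `solve_result`.
#' @param at `"mid"` for the circumferential mean diameter at mid-span
#'   (the video-camera bench convention), `"max"` for the widest profile
#'   over the span.
#' @return Outer diameter, mm.
#' @export
outer_diameter <- function(model, result, at = c("mid", "max")) {
  at <- match.arg(at)
  D0 <- model$spec$inner_diameter + 2 * model$spec$base_thickness
  if (at == "mid") {
    i_mid <- ceiling(nrow(result$U1) / 2)
    D0 + 2 * mean(result$U1[i_mid, ])
  } else {
    D0 + 2 * max(rowMeans(result$U1))
  }
}

#' Export per-node and per-element solve results as CSV
#'
#' Writes two files: `<stem>_nodes.csv` (z, phi, U1) and
#' `<stem>_elements.csv` (row, col, thickness, hoop_strain, axial_strain,
#' hoop_stress).
#'
#' @param model The solved model.
#' @param result A `solve_result`.
#' @param stem Output path stem.
#' @return The two file paths, invisibly.
#' @export
export_solve_csv <- function(model, result, stem) {
  n_z <- nrow(result$U1); n_c <- ncol(result$U1)
  nodes <- data.frame(
    z = rep(result$z_stations, each = n_c),
    phi = rep(2 * pi * (seq_len(n_c) - 1) / n_c, times = n_z),
    U1 = as.vector(t(result$U1)))
  f1 <- paste0(stem, "_nodes.csv")
  utils::write.csv(nodes, f1, row.names = FALSE)
  n_a <- model$spec$n_axial
  elems <- data.frame(
    row = rep(seq_len(n_a), times = model$spec$n_circ),
    col = rep(seq_len(model$spec$n_circ), each = n_a),
    thickness = as.vector(model$thickness),
    hoop_strain = as.vector(result$hoop_strain),
    axial_strain = as.vector(result$axial_strain),
    hoop_stress = as.vector(result$hoop_stress))
  f2 <- paste0(stem, "_elements.csv")
  utils::write.csv(elems, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
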