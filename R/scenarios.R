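#' Build one of the three study scenario presets
#'
#' The three comparison arms share the same biological geometry and wall
#' law and differ only in reinforcement:
#' \describe{
#'   \item{control}{5 mm ID, 60 mm long, 0.5 mm base wall with one thin
#'     patch (0.06 mm at its centre), no helix. The patch thickness is the
#'     minimal construction that activates the damage mechanism: at the
#'     120 mmHg systolic peak the patch-centre hoop stress
#'     (p*r/t of order 0.67 MPa) marginally exceeds the yield stress
#'     `E0 * eps_y = 0.6` MPa.}
#'   \item{pvdf}{control geometry + double PVDF helix, pitch 2.25 mm,
#'     thread 0.33 mm, E = 458 MPa.}
#'   \item{pcl}{control geometry + double PCL helix, pitch 2.15 mm,
#'     thread 0.30 mm, E = 321 MPa.}
#' }
#' The protocol is 150 cycles of 80--120 mmHg (0.011--0.016 MPa) with
#' unload to zero.
#'
#' @param name `"control"`, `"pvdf"` or `"pcl"`.
#' @param n_axial,n_circ Mesh resolution of the preset.
#' @return Object of class `scenario_preset`: `name`, `tube`, `patches`,
#'   `helix` (or NULL), `bio`, `polymer` (or NULL), `protocol`.
#' @export
make_preset <- function(name, n_axial = 60L, n_circ = 32L) {
  valid <- c("control", "pvdf", "pcl")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("make_preset: unknown scenario '", name, "'; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  tube <- tube_spec(inner_diameter = 5, length = 60, base_thickness = 0.5,
                    n_axial = n_axial, n_circ = n_circ)
  # patch centre aligned with an element centre so the discretized field
  # attains min_thickness exactly; sized so the first-cycle hoop stress at
  # the centre marginally exceeds the 0.6 MPa yield stress at 120 mmHg
  patches <- list(thin_patch_spec(axial_center = 19.5, circ_center = pi / 32,
                                  axial_halfwidth = 6, circ_halfwidth = 1.0,
                                  min_thickness = 0.06, transition = 2))
  bio <- damage_plastic_params(E0 = 1, eps_y = 0.6, floor = 0.1,
                               PE_ref = 0.0055)
  helix <- switch(name,
    control = NULL,
    pvdf = helix_spec(pitch = 2.25, thread_diameter = 0.33, n_layers = 2,
                      polymer_id = "PVDF"),
    pcl = helix_spec(pitch = 2.15, thread_diameter = 0.30, n_layers = 2,
                     polymer_id = "PCL"))
  polymer <- switch(name,
    control = NULL,
    pvdf = polymer_params(458, "PVDF"),
    pcl = polymer_params(321, "PCL"))
  structure(list(name = name, tube = tube, patches = patches,
                 helix = helix, bio = bio, polymer = polymer,
                 protocol = pressure_protocol(0.011, 0.016, 150L, "zero")),
            class = "scenario_preset")
}

#' Instantiate the scaffold model of a preset
#'
#' Builds the mesh, thickness field (identical across the three arms for
#' equal seeds -- the reinforced scaffolds share the control's biology)
#' and helix coverage.
#'
#' @param preset A `scenario_preset` (or a scenario name).
#' @param length Optional specimen length override, mm (e.g. 15 for
#'   transverse ring specimens; patches are dropped when they do not fit
#'   the shortened span).
#' @param with_patch Keep the thin patch (default TRUE).
#' @param seed Seed for the thickness field noise (the presets use
#'   noise-free walls; the seed matters only if noise is added).
#' @param noise_amplitude Optional thickness-noise amplitude, mm.
#' @return A [scaffold_model()].
#' @export
build_scaffold <- function(preset, length = NULL, with_patch = TRUE,
                           seed = 1L, noise_amplitude = 0) {
  if (is.character(preset)) preset <- make_preset(preset)
  stopifnot(inherits(preset, "scenario_preset"))
  tube <- preset$tube
  if (!is.null(length)) {
    scale <- length / tube$length
    tube <- tube_spec(tube$inner_diameter, length, tube$base_thickness,
                      n_axial = max(4L, as.integer(round(tube$n_axial * scale))),
                      n_circ = tube$n_circ)
  }
  patches <- if (with_patch) preset$patches else list()
  patches <- Filter(function(p) {
    p$axial_center + p$axial_halfwidth <= tube$length &&
      p$axial_center - p$axial_halfwidth >= 0
  }, patches)
  mesh <- make_tube_mesh(tube)
  th <- build_thickness_field(tube, patches, noise_amplitude = noise_amplitude,
                              seed = seed)
  scaffold_model(mesh, th, bio = preset$bio, helix = preset$helix,
                 polymer = preset$polymer)
}

#' Generate a seeded ensemble of pseudo-bench stress-strain curves
#'
#' Emulates the qualitative statistical structure of bench tensile data
#' on biological tissue: each replicate is a J-shaped cubic
#' `sigma_i(eps) = (a1 + delta_i) * eps + (a3 + gamma_i) * eps^3` with
#' replicate-level coefficient perturbations (`delta_i ~ N(0, rep_sd_a1)`,
#' `gamma_i ~ N(0, rep_sd_a3)`) plus pointwise measurement noise
#' `N(0, noise_sd)`. Reproducible per seed.
#'
#' @param a1,a3 Generating coefficients (MPa); `a1 > 0`.
#' @param n Number of replicate curves (>= 1).
#' @param noise_sd Pointwise noise sd, MPa (>= 0).
#' @param rep_sd_a1,rep_sd_a3 Replicate-level coefficient sds.
#' @param strain_max,n_points Strain grid of each curve.
#' @param seed Integer seed.
#' @return Object of class `curve_ensemble`: list of
#'   [stress_strain_curve()]s plus the generator parameters.
#' @export
gen_bench_curves <- function(a1 = 1, a3 = 2.5, n = 5L, noise_sd = 0.02,
                             rep_sd_a1 = 0.15, rep_sd_a3 = 0.4,
                             strain_max = 1.0, n_points = 50L, seed = 1L) {
  if (a1 <= 0) stop("gen_bench_curves: 'a1' must be > 0", call. = FALSE)
  if (n < 1L) stop("gen_bench_curves: 'n' must be >= 1", call. = FALSE)
  if (noise_sd < 0)
    stop("gen_bench_curves: 'noise_sd' must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  eps <- seq(strain_max / n_points, strain_max, length.out = n_points)
  curves <- vector("list", n)
  for (i in seq_len(n)) {
    d <- if (rep_sd_a1 > 0) stats::rnorm(1, 0, rep_sd_a1) else 0
    g <- if (rep_sd_a3 > 0) stats::rnorm(1, 0, rep_sd_a3) else 0
    sig <- (a1 + d) * eps + (a3 + g) * eps^3 +
      if (noise_sd > 0) stats::rnorm(n_points, 0, noise_sd) else 0
    curves[[i]] <- stress_strain_curve(eps, sig, "longitudinal")
  }
  structure(list(curves = curves,
                 params = list(a1 = a1, a3 = a3, n = n, noise_sd = noise_sd,
                               rep_sd_a1 = rep_sd_a1, rep_sd_a3 = rep_sd_a3,
                               seed = seed)),
            class = "curve_ensemble")
}

#' Pool a curve ensemble into one long curve for fitting
#'
#' Concatenates the replicates, averaging stresses at the shared strain
#' grid (replicates share the grid by construction).
#'
#' @param ensemble A `curve_ensemble`.
#' @return A [stress_strain_curve()] of the pooled (mean) response.
#' @export
pool_curves <- function(ensemble) {
  stopifnot(inherits(ensemble, "curve_ensemble"))
  eps <- ensemble$curves[[1]]$strain
  sig <- rowMeans(vapply(ensemble$curves, function(c) c$stress,
                         numeric(length(eps))))
  stress_strain_curve(eps, sig, attr(ensemble$curves[[1]], "direction"))
}

#' Write a curve ensemble as multi-column CSV
#'
#' First column `strain`, then one `stress_i` column per replicate.
#'
#' @param ensemble A `curve_ensemble`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, file) {
  stopifnot(inherits(ensemble, "curve_ensemble"))
  df <- data.frame(strain = ensemble$curves[[1]]$strain)
  for (i in seq_along(ensemble$curves)) {
    df[[paste0("stress_", i)]] <- ensemble$curves[[i]]$stress
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
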