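# Shared fixtures, built in code. Small meshes keep the suite fast; the
# preset-resolution models are built once per test run.

uniform_tube <- function(n_axial = 60L, n_circ = 32L, t = 0.5, L = 60,
                         bio = damage_plastic_params()) {
  ts <- tube_spec(5, L, t, n_axial, n_circ)
  scaffold_model(make_tube_mesh(ts), build_thickness_field(ts), bio = bio)
}

# cached preset models (shared across test files)
.preset_cache <- new.env(parent = emptyenv())
preset_model <- function(name, ...) {
  key <- paste(name, ..., sep = "_")
  if (is.null(.preset_cache[[key]])) {
    .preset_cache[[key]] <- build_scaffold(name, ...)
  }
  .preset_cache[[key]]
}

# least-squares slope through the origin -- the analytic oracle used to
# freeze expected values for initial_modulus
ls_slope_origin <- function(eps, sig) sum(sig * eps) / sum(eps^2)
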