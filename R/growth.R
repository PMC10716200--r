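#' Cyclic pressure protocol
#'
#' Load/unload cycling between `p_min` and `p_max`. The default is the
#' normotensive 80--120 mmHg range (0.011--0.016 MPa presets) for 150
#' cycles, unloading to zero pressure (the relaxed state) after each peak.
#'
#' @param p_min Diastolic pressure, MPa.
#' @param p_max Systolic pressure, MPa (> p_min).
#' @param n_cycles Number of cycles (>= 1).
#' @param unload `"zero"` (relaxed state) or `"p_min"`.
#' @param range Optional named range (`"hypo"`, `"normo"`, `"hyper"`)
#'   overriding `p_min`/`p_max` with the protocol presets.
#' @return Object of class `pressure_protocol`.
#' @export
pressure_protocol <- function(p_min = 0.011, p_max = 0.016, n_cycles = 150L,
                              unload = c("zero", "p_min"), range = NULL) {
  unload <- match.arg(unload)
  if (!is.null(range)) {
    pr <- pressure_range_mpa(range)
    p_min <- pr[1]; p_max <- pr[2]
  }
  if (!(p_min >= 0 && p_min < p_max))
    stop("pressure_protocol: need 0 <= p_min < p_max", call. = FALSE)
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("pressure_protocol: n_cycles must be >= 1",
                          call. = FALSE)
  structure(list(p_min = p_min, p_max = p_max, n_cycles = n_cycles,
                 unload = unload),
            class = "pressure_protocol")
}

#' Run the cyclic-pressure aneurysm-growth simulation
#'
#' Per cycle: (i) solve pressure equilibrium at `p_max` with the current
#' damage/plasticity field; (ii) update each element's plastic strain and
#' damage factor from its peak hoop strain; (iii) unload and record the
#' residual configuration. With the default zero-pressure unload the
#' residual radial displacement is reconstructed as `PE_acc * r_mid` per
#' element (the permanent set of the scalar-hoop plasticity model); with
#' `unload = "p_min"` an additional equilibrium solve at `p_min` supplies
#' the unloaded shape. Elements whose peak strain stays below the yield
#' strain never accumulate damage, so a sound wall cycles fully
#' elastically; at a thin region every cycle deepens the plastic strain
#' and degrades the modulus, growing a localized bulge until the
#' surrounding wall's support saturates the process.
#'
#' @param model A [scaffold_model()] whose `bio` is a
#'   [damage_plastic_params()].
#' @param protocol A [pressure_protocol()].
#' @param bc A [boundary_condition()].
#' @param states Optional starting [material_state()]; virgin by default.
#' @param params Damage-plasticity parameters; defaults to `model$bio`.
#' @param tol,max_iter Passed to [solve_pressure()].
#' @return Object of class `growth_trace`: `per_cycle` data frame (cycle,
#'   max_residual_U1, min_f, max_PE, d_loaded, d_unloaded), `final_state`,
#'   `validity`, `truncated_at` (NA when the run completed), `protocol`.
#' @export
run_cycles <- function(model, protocol = pressure_protocol(),
                       bc = boundary_condition(), states = NULL,
                       params = NULL, tol = 1e-9, max_iter = 30L) {
  stopifnot(inherits(model, "scaffold_model"),
            inherits(protocol, "pressure_protocol"))
  if (is.null(params)) params <- model$bio
  if (!inherits(params, "damage_plastic_params"))
    stop("run_cycles: the growth model needs damage-plastic wall parameters",
         call. = FALSE)
  spec <- model$spec
  if (is.null(states)) states <- material_state(spec$n_axial, spec$n_circ)
  r <- model$mesh$radius
  ID <- spec$inner_diameter

  n <- protocol$n_cycles
  rec <- data.frame(cycle = seq_len(n), max_residual_U1 = NA_real_,
                    min_f = NA_real_, max_PE = NA_real_,
                    d_loaded = NA_real_, d_unloaded = NA_real_)
  validity <- "ok"
  truncated_at <- NA_integer_
  w_prev <- NULL

  for (k in seq_len(n)) {
    res <- withCallingHandlers(
      solve_pressure(model, protocol$p_max, bc, states, tol, max_iter,
                     w_init = w_prev),
      warning = function(w) {
        if (grepl("did not converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (!res$converged) { truncated_at <- k; break }
    if (res$validity != "ok") validity <- res$validity
    w_prev <- as.vector(t(res$U1))

    eps_peak <- pmax(0, res$hoop_strain)
    states <- stress_update(eps_peak, states, params)$state

    if (protocol$unload == "p_min") {
      unl <- solve_pressure(model, protocol$p_min, bc, states, tol, max_iter)
      resid_node <- unl$U1
      resid_max <- max(rowMeans(resid_node))
    } else {
      resid_elem <- states$PE_acc * r
      resid_max <- max(resid_elem)
    }

    rec$max_residual_U1[k] <- resid_max
    rec$min_f[k] <- min(states$f)
    rec$max_PE[k] <- max(states$PE_acc)
    rec$d_loaded[k] <- ID + 2 * max(rowMeans(res$U1))
    rec$d_unloaded[k] <- ID + 2 * resid_max
  }
  if (!is.na(truncated_at)) rec <- rec[seq_len(truncated_at - 1L), , drop = FALSE]

  structure(list(per_cycle = rec, final_state = states,
                 validity = validity, truncated_at = truncated_at,
                 protocol = protocol,
                 thickness = model$thickness, radius = r),
            class = "growth_trace")
}

#' @export
print.growth_trace <- function(x, ...) {
  n <- nrow(x$per_cycle)
  cat(sprintf("growth_trace: %d cycle(s), %g-%g MPa\n",
              n, x$protocol$p_min, x$protocol$p_max))
  if (n > 0) {
    last <- x$per_cycle[n, ]
    cat(sprintf("  final: residual U1 %.4g mm, min f %.3g, max PE %.4g\n",
                last$max_residual_U1, last$min_f, last$max_PE))
  }
  if (!is.na(x$truncated_at))
    cat("  TRUNCATED: solver failed at cycle", x$truncated_at, "\n")
  if (x$validity != "ok") cat("  flag:", x$validity, "\n")
  invisible(x)
}

#' Summary metrics of a growth simulation
#'
#' @param trace A `growth_trace`.
#' @return List: `max_residual_U1_mm`, `min_f` (modulus fraction),
#'   `modulus_decrease_pct` (`100 * (1 - min_f)`), `max_PE_pct`,
#'   `d_loaded_mm`, `d_unloaded_mm`, `flagged` (non-"ok" validity or
#'   truncation), `validity`, `truncated_at`.
#' @export
growth_metrics <- function(trace) {
  stopifnot(inherits(trace, "growth_trace"))
  pc <- trace$per_cycle
  if (nrow(pc) == 0)
    stop("growth_metrics: empty trace (no completed cycles)", call. = FALSE)
  last <- pc[nrow(pc), ]
  list(max_residual_U1_mm = last$max_residual_U1,
       min_f = last$min_f,
       modulus_decrease_pct = 100 * (1 - last$min_f),
       max_PE_pct = 100 * last$max_PE,
       d_loaded_mm = last$d_loaded,
       d_unloaded_mm = last$d_unloaded,
       flagged = trace$validity != "ok" || !is.na(trace$truncated_at),
       validity = trace$validity,
       truncated_at = trace$truncated_at)
}

#' Save / load the per-cycle trace
#'
#' `save_trace` writes the per-cycle metrics as CSV (lossless round-trip;
#' one row per completed cycle, header-only for an empty trace) and,
#' optionally, the final per-element fields (damage factor, plastic
#' strain, thickness) as JSON.
#'
#' @param trace A `growth_trace`.
#' @param file CSV path for the per-cycle metrics.
#' @param fields_file Optional JSON path for the final fields.
#' @return `save_trace`: `file`, invisibly. `load_trace`: a
#'   `growth_trace` (per-cycle metrics only; no final state unless the
#'   JSON is given).
#' @export
save_trace <- function(trace, file, fields_file = NULL) {
  stopifnot(inherits(trace, "growth_trace"))
  utils::write.csv(trace$per_cycle, file, row.names = FALSE)
  if (!is.null(fields_file)) {
    jsonlite::write_json(
      list(f = as.matrix(trace$final_state$f),
           PE_acc = as.matrix(trace$final_state$PE_acc),
           thickness = as.matrix(trace$thickness),
           radius = trace$radius,
           validity = trace$validity,
           p_min = trace$protocol$p_min, p_max = trace$protocol$p_max,
           n_cycles = trace$protocol$n_cycles, unload = trace$protocol$unload),
      fields_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' @rdname save_trace
#' @export
load_trace <- function(file, fields_file = NULL) {
  pc <- utils::read.csv(file)
  want <- c("cycle", "max_residual_U1", "min_f", "max_PE",
            "d_loaded", "d_unloaded")
  if (!identical(names(pc), want))
    stop("load_trace: schema mismatch; expected columns ",
         paste(want, collapse = ", "), call. = FALSE)
  final_state <- NULL; thickness <- NULL; radius <- NA_real_
  protocol <- NULL; validity <- "ok"
  if (!is.null(fields_file)) {
    x <- jsonlite::read_json(fields_file, simplifyVector = TRUE)
    final_state <- structure(list(PE_acc = as.matrix(x$PE_acc),
                                  f = as.matrix(x$f)),
                             class = "material_state")
    thickness <- as.matrix(x$thickness)
    radius <- x$radius
    validity <- x$validity
    protocol <- pressure_protocol(x$p_min, x$p_max, x$n_cycles, x$unload)
  }
  if (is.null(protocol)) {
    protocol <- pressure_protocol(n_cycles = max(1L, nrow(pc)))
  }
  structure(list(per_cycle = pc, final_state = final_state,
                 validity = validity, truncated_at = NA_integer_,
                 protocol = protocol, thickness = thickness, radius = radius),
            class = "growth_trace")
}
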