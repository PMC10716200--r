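#' Fit an odd polynomial stress-strain model through the origin
#'
#' Soft collagenous tissue shows a J-shaped (stiffening) stress-strain
#' response; it is summarized here by an odd polynomial constrained through
#' the origin, `sigma(eps) = a1*eps + a3*eps^3 (+ a5*eps^5 ...)`, fitted by
#' least squares.
#'
#' @param curve A [stress_strain_curve()] or a data frame with numeric
#'   columns `strain` and `stress`.
#' @param degree Highest (odd) power retained; default 3.
#' @return Object of class `poly_fit` with `coefficients` (named
#'   `a1, a3, ...`), `degree`, and `residual` (residual standard error).
#' @examples
#' eps <- seq(0.01, 0.5, length.out = 20)
#' fit_polynomial(data.frame(strain = eps, stress = 0.5 * eps + 8 * eps^3))
#' @export
fit_polynomial <- function(curve, degree = 3) {
  curve <- as.data.frame(curve)
  stopifnot(all(c("strain", "stress") %in% names(curve)))
  eps <- curve$strain; sig <- curve$stress
  if (length(eps) < 5) stop("fit_polynomial: need at least 5 points", call. = FALSE)
  if (any(diff(eps) <= 0))
    stop("fit_polynomial: strains must be strictly increasing", call. = FALSE)
  if (all(sig == 0))
    stop("fit_polynomial: degenerate curve (all-zero stress)", call. = FALSE)
  degree <- as.integer(degree)
  if (degree < 1 || degree %% 2L == 0L)
    stop("fit_polynomial: 'degree' must be a positive odd integer", call. = FALSE)
  powers <- seq(1L, degree, by = 2L)
  X <- vapply(powers, function(p) eps^p, numeric(length(eps)))
  fit <- stats::lm.fit(X, sig)
  coefs <- stats::setNames(fit$coefficients, paste0("a", powers))
  if (coefs[["a1"]] <= 0)
    warning("fit_polynomial: fitted initial slope a1 <= 0; curve is not a ",
            "physical tissue response", call. = FALSE)
  dof <- max(1L, length(eps) - length(powers))
  structure(list(coefficients = coefs, degree = degree,
                 residual = sqrt(sum(fit$residuals^2) / dof)),
            class = "poly_fit")
}

#' Evaluate a fitted polynomial material law
#'
#' @param fit A `poly_fit`.
#' @param eps Strain(s), mm/mm.
#' @param deriv Return the tangent modulus `d sigma / d eps` instead of the
#'   stress.
#' @return Stress (MPa) or tangent modulus (MPa).
#' @export
eval_polynomial <- function(fit, eps, deriv = FALSE) {
  stopifnot(inherits(fit, "poly_fit"))
  powers <- seq(1L, fit$degree, by = 2L)
  out <- 0
  for (k in seq_along(powers)) {
    p <- powers[k]; a <- fit$coefficients[[k]]
    out <- out + if (deriv) a * p * eps^(p - 1) else a * eps^p
  }
  out
}

#' @export
print.poly_fit <- function(x, ...) {
  terms <- paste(sprintf("%.4g*eps^%d", x$coefficients,
                         seq(1L, x$degree, by = 2L)), collapse = " + ")
  cat("poly_fit: sigma(eps) =", terms,
      sprintf(" (residual %.3g MPa)\n", x$residual))
  invisible(x)
}

#' Serialize / restore a polynomial fit as JSON
#'
#' @param fit A `poly_fit`.
#' @param file Path to write to / read from.
#' @return `poly_fit_to_json` returns `file` invisibly;
#'   `poly_fit_from_json` returns the restored `poly_fit`.
#' @export
poly_fit_to_json <- function(fit, file) {
  stopifnot(inherits(fit, "poly_fit"))
  jsonlite::write_json(list(coefficients = as.list(fit$coefficients),
                            degree = fit$degree, residual = fit$residual),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname poly_fit_to_json
#' @export
poly_fit_from_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(coefficients = unlist(x$coefficients),
                 degree = as.integer(x$degree), residual = x$residual),
            class = "poly_fit")
}

#' Initial (small-strain) elastic modulus of a stress-strain curve
#'
#' Slope of the least-squares line through the origin over the low-strain
#' window, emulating the bench practice of isolating the near-physiological
#' initial section of the curve (default: strains up to 1 percent).
#'
#' @param curve A data frame with `strain`, `stress`.
#' @param strain_window Upper strain bound of the window, mm/mm.
#' @return Modulus, MPa.
#' @export
initial_modulus <- function(curve, strain_window = 0.01) {
  curve <- as.data.frame(curve)
  stopifnot(all(c("strain", "stress") %in% names(curve)))
  if (strain_window > max(curve$strain))
    stop("initial_modulus: window exceeds the curve's strain range", call. = FALSE)
  sel <- curve$strain <= strain_window & curve$strain >= 0
  eps <- curve$strain[sel]; sig <- curve$stress[sel]
  if (length(eps) < 2 || sum(eps^2) == 0)
    stop("initial_modulus: fewer than 2 usable points in the strain window",
         call. = FALSE)
  sum(sig * eps) / sum(eps^2)
}
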