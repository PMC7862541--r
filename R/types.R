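## S3 constructors for the pipeline's core containers. Validation lives
## here so every downstream operation can assume its invariants.

#' Bidirectional non-equilibrium work set
#'
#' Container for forward (0 -> 1) and reverse work samples at a temperature.
#' Reverse works are stored as measured along the 1 -> 0 transition; they are
#' not pre-negated. Estimators negate them internally where the forward
#' convention is needed.
#'
#' @param forward_works Numeric vector, kJ/mol.
#' @param reverse_works Numeric vector, kJ/mol, measured along 1 -> 0.
#' @param temperature Temperature in K.
#' @return A `work_set` object.
#' @export
work_set <- function(forward_works, reverse_works, temperature = 300.15) {
  forward_works <- as.numeric(forward_works)
  reverse_works <- as.numeric(reverse_works)
  if (any(!is.finite(forward_works)) || any(!is.finite(reverse_works)))
    stop("work values must be finite (NaN/Inf rejected)")
  stopifnot_scalar(temperature, "temperature", positive = TRUE)
  structure(list(forward_works = forward_works,
                 reverse_works = reverse_works,
                 temperature = temperature),
            class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("work_set: %d forward, %d reverse samples at %.2f K\n",
              length(x$forward_works), length(x$reverse_works),
              x$temperature))
  invisible(x)
}

#' dH/dlambda series along one alchemical transition
#'
#' Lambda values are stored non-decreasing on [0, 1]; a series supplied in
#' descending order is reversed on construction. The `direction` tag records
#' the physical switching direction: forward transitions traverse lambda
#' 0 -> 1, reverse transitions 1 -> 0.
#'
#' @param lambda_values Lambda grid in [0, 1], monotone.
#' @param dhdl_values dH/dlambda in kJ/mol per unit lambda.
#' @param direction "forward" or "reverse".
#' @return A `dhdl_series` object.
#' @export
dhdl_series <- function(lambda_values, dhdl_values,
                        direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  lambda_values <- as.numeric(lambda_values)
  dhdl_values <- as.numeric(dhdl_values)
  n <- length(lambda_values)
  if (n < 2L) stop("need at least 2 lambda points")
  if (length(dhdl_values) != n)
    stop("lambda and dhdl vectors must have equal length")
  if (any(!is.finite(dhdl_values)))
    stop("dH/dlambda values must be finite (NaN/Inf rejected)")
  d <- diff(lambda_values)
  if (all(d <= 0)) {           # supplied descending: normalize storage
    lambda_values <- rev(lambda_values)
    dhdl_values <- rev(dhdl_values)
    d <- -rev(d)
  }
  if (any(d < 0)) stop("lambda values must be monotone")
  if (min(lambda_values) < -1e-9 || max(lambda_values) > 1 + 1e-9)
    stop("lambda values must lie in [0, 1]")
  if (abs(lambda_values[1]) > 1e-6 || abs(lambda_values[n] - 1) > 1e-6)
    stop("lambda grid must span [0, 1] (endpoints ~0 and ~1)")
  structure(list(lambda_values = lambda_values, dhdl_values = dhdl_values,
                 direction = direction),
            class = "dhdl_series")
}

#' Free energy estimate with uncertainty and provenance
#'
#' @param dg Free energy, kJ/mol.
#' @param stderr Standard error, kJ/mol, >= 0 (NA allowed when undefined).
#' @param method Estimator tag: "cft-ml", "jarzynski" or "cgi".
#' @param n_forward,n_reverse Sample counts that produced the estimate.
#' @return An `fe_estimate` object.
#' @export
fe_estimate <- function(dg, stderr, method, n_forward = NA_integer_,
                        n_reverse = NA_integer_) {
  if (!is.na(stderr) && stderr < 0) stop("stderr must be >= 0")
  structure(list(dg = dg, stderr = stderr, method = method,
                 n_forward = n_forward, n_reverse = n_reverse),
            class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat(sprintf("%s: dG = %.4f +- %s kJ/mol (n_f = %s, n_r = %s)\n",
              x$method, x$dg,
              if (is.na(x$stderr)) "NA" else sprintf("%.4f", x$stderr),
              x$n_forward, x$n_reverse))
  invisible(x)
}

#' Trajectory ensemble of superposable coordinate frames
#'
#' @param coordinates frames x atoms x 3 array, nm.
#' @param masses Per-atom masses, amu, > 0.
#' @param selection Atom indices used for analysis (default all).
#' @param label Free-text label, e.g. "apo/gaff1.81".
#' @param superposed Logical flag set by [superpose()].
#' @return A `trajectory_ensemble` object.
#' @export
trajectory_ensemble <- function(coordinates, masses, selection = NULL,
                                label = "", superposed = FALSE) {
  dm <- dim(coordinates)
  if (length(dm) != 3L || dm[3] != 3L)
    stop("coordinates must be a frames x atoms x 3 array")
  n_atoms <- dm[2]
  masses <- as.numeric(masses)
  if (length(masses) != n_atoms) stop("need one mass per atom")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all masses must be finite and > 0")
  selection <- if (is.null(selection)) seq_len(n_atoms) else as.integer(selection)
  if (any(selection < 1L) || any(selection > n_atoms))
    stop("selection indices out of range")
  structure(list(coordinates = coordinates, masses = masses,
                 selection = selection, label = label,
                 superposed = superposed),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  dm <- dim(x$coordinates)
  cat(sprintf("trajectory_ensemble '%s': %d frames, %d atoms (%d selected)%s\n",
              x$label, dm[1], dm[2], length(x$selection),
              if (x$superposed) ", superposed" else ""))
  invisible(x)
}

#' Per-frame geometry observables for pose/unbinding analysis
#'
#' @param frame_index 0-based frame indices.
#' @param orientation_cos Cosine of the guest-axis / host-axis angle.
#' @param com_distance Host-guest centre-of-mass distance, nm, >= 0.
#' @return A `geometry_series` data.frame.
#' @export
geometry_series <- function(frame_index, orientation_cos, com_distance) {
  n <- length(frame_index)
  if (length(orientation_cos) != n || length(com_distance) != n)
    stop("all columns must have equal length")
  if (any(abs(orientation_cos) > 1 + 0.75))  # generous tolerance for noise
    warning("orientation cosines far outside [-1, 1]")
  if (any(com_distance < 0)) stop("com_distance must be >= 0")
  structure(data.frame(frame_index = as.integer(frame_index),
                       orientation_cos = orientation_cos,
                       com_distance = com_distance),
            class = c("geometry_series", "data.frame"))
}
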