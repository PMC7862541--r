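## Conformational analysis: rigid-body superposition, Schlitter
## quasi-harmonic entropy and its contribution to the binding free energy.

## Flatten the selected atoms of an ensemble into a frames x 3n matrix.
.flatten_selection <- function(ens) {
  sel <- ens$selection
  n_frames <- dim(ens$coordinates)[1]
  m <- matrix(0, nrow = n_frames, ncol = 3L * length(sel))
  for (k in seq_along(sel)) {
    m[, (3L * (k - 1L) + 1L):(3L * k)] <- ens$coordinates[, sel[k], ]
  }
  m
}

## Kabsch optimal rotation aligning x (n x 3) onto ref (n x 3), both
## already centred. Returns the 3x3 rotation matrix.
.kabsch <- function(x, ref) {
  h <- crossprod(x, ref)   # 3x3
  s <- svd(h)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Rigid-body least-squares superposition onto a reference
#'
#' Each frame is fitted onto the reference by the optimal translation and
#' rotation (Kabsch algorithm) over the ensemble's selection; the full frame
#' is transformed. Superposition removes the six external degrees of freedom
#' so that the coordinate covariance reflects internal motion only — a
#' prerequisite for the Schlitter entropy and PCA.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param reference Reference coordinates: an atoms x 3 matrix, a 1-based
#'   frame index into the ensemble, or NULL for the iterated mean structure
#'   (mean of frames, fitted, re-meaned; two iterations).
#' @return The superposed `trajectory_ensemble` with an `rmsd` attribute
#'   (per-frame RMSD to the reference over the selection, nm) and
#'   `superposed = TRUE`.
#' @export
superpose <- function(ensemble, reference = NULL) {
  if (!inherits(ensemble, "trajectory_ensemble"))
    stop("ensemble must be a trajectory_ensemble")
  dm <- dim(ensemble$coordinates)
  n_frames <- dm[1]; n_atoms <- dm[2]
  sel <- ensemble$selection
  if (length(sel) < 3L)
    stop("superposition needs a selection of >= 3 atoms")

  fit_to <- function(ens, ref_sel) {
    ## ref_sel: length(sel) x 3 matrix
    ref_c <- ref_sel - matrix(colMeans(ref_sel), nrow(ref_sel), 3,
                              byrow = TRUE)
    if (min(svd(ref_c)$d) < 1e-12 * max(svd(ref_c)$d, 1e-300))
      stop("degenerate (collinear) selection: superposition ill-defined")
    out <- ens$coordinates
    rmsd <- numeric(n_frames)
    for (f in seq_len(n_frames)) {
      xf <- matrix(ens$coordinates[f, , ], n_atoms, 3)
      xs <- xf[sel, , drop = FALSE]
      cs <- colMeans(xs)
      xs_c <- xs - matrix(cs, nrow(xs), 3, byrow = TRUE)
      rot <- .kabsch(xs_c, ref_c)
      xf_new <- (xf - matrix(cs, n_atoms, 3, byrow = TRUE)) %*% rot +
        matrix(colMeans(ref_sel), n_atoms, 3, byrow = TRUE)
      out[f, , ] <- xf_new
      dsel <- xf_new[sel, , drop = FALSE] - ref_sel
      rmsd[f] <- sqrt(mean(rowSums(dsel^2)))
    }
    list(coords = out, rmsd = rmsd)
  }

  ens <- ensemble
  if (is.null(reference)) {
    ## iterated mean reference: fit to frame 1, take mean, refit (x2)
    ref <- matrix(ens$coordinates[1, sel, ], length(sel), 3)
    for (it in 1:2) {
      fitted <- fit_to(ens, ref)
      ens$coordinates <- fitted$coords
      ref <- apply(ens$coordinates[, sel, , drop = FALSE], c(2, 3), mean)
    }
    fitted <- fit_to(ens, ref)
  } else if (is.matrix(reference)) {
    if (nrow(reference) == n_atoms) reference <- reference[sel, , drop = FALSE]
    if (nrow(reference) != length(sel))
      stop("reference atom count matches neither ensemble nor selection")
    fitted <- fit_to(ens, reference)
  } else {
    f <- as.integer(reference)
    if (f < 1L || f > n_frames) stop("reference frame index out of range")
    fitted <- fit_to(ens, matrix(ens$coordinates[f, sel, ], length(sel), 3))
  }
  out <- ensemble
  out$coordinates <- fitted$coords
  out$superposed <- TRUE
  attr(out, "rmsd") <- fitted$rmsd
  out
}

#' Schlitter quasi-harmonic conformational entropy
#'
#' Upper-bound entropy estimate from the mass-weighted covariance of the
#' selected Cartesian coordinates:
#' \deqn{S = \frac{R}{2} \ln\det\left(1 +
#'   \frac{k_B T e^2}{\hbar^2} M^{1/2} C M^{1/2}\right)}
#' with C the coordinate covariance about the ensemble mean, M the diagonal
#' mass matrix and e Euler's number. Evaluated through the eigenvalues of
#' the symmetrized mass-weighted covariance in SI units (amu -> kg,
#' nm^2 -> m^2), so the determinant argument is dimensionless. The +1 inside
#' the determinant makes rank-deficient covariances (fewer frames than
#' coordinates) exact rather than singular.
#'
#' @param ensemble A superposed [trajectory_ensemble()] (set
#'   `require_superposed = FALSE` for ensembles that need no fitting, e.g.
#'   synthetic Gaussian draws).
#' @param temperature Temperature in K.
#' @param require_superposed Refuse non-superposed input (default TRUE).
#' @return Entropy in J/(mol K).
#' @export
schlitter_entropy <- function(ensemble, temperature = 300.15,
                              require_superposed = TRUE) {
  if (!inherits(ensemble, "trajectory_ensemble"))
    stop("ensemble must be a trajectory_ensemble")
  if (require_superposed && !isTRUE(ensemble$superposed))
    stop(paste("ensemble is not superposed; fit it first (or pass",
               "require_superposed = FALSE for pre-aligned data)"))
  n_frames <- dim(ensemble$coordinates)[1]
  if (n_frames < 2L) stop("need >= 2 frames for a covariance")
  x <- .flatten_selection(ensemble)
  cv <- stats::cov(x)                              # nm^2
  m_sel <- rep(ensemble$masses[ensemble$selection], each = 3L)
  schlitter_from_covariance(cv, m_sel, temperature)
}

#' Schlitter entropy from a known coordinate covariance
#'
#' Closed-form evaluation of the Schlitter formula given the covariance
#' directly; used both internally and as the analytic oracle for sampled
#' ensembles whose generating covariance is known.
#'
#' @param covariance 3n x 3n coordinate covariance, nm^2.
#' @param masses_per_coord Mass for each coordinate (atom mass repeated for
#'   x, y, z), amu.
#' @param temperature Temperature in K.
#' @return Entropy in J/(mol K).
#' @export
schlitter_from_covariance <- function(covariance, masses_per_coord,
                                      temperature = 300.15) {
  covariance <- as.matrix(covariance)
  d <- nrow(covariance)
  if (length(masses_per_coord) != d)
    stop("need one mass per coordinate")
  stopifnot_scalar(temperature, "temperature", positive = TRUE)
  sqm <- sqrt(masses_per_coord * .amu_kg)          # kg^(1/2)
  mwc <- covariance * 1e-18 * outer(sqm, sqm)      # kg m^2
  mwc <- (mwc + t(mwc)) / 2
  ev <- eigen(mwc, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  pref <- .kB_SI * temperature * exp(1)^2 / .hbar_SI^2   # 1/(kg m^2)
  r_gas <- .kB_SI * .avogadro
  (r_gas / 2) * sum(log1p(pref * ev))
}

#' Entropy contribution to the binding free energy
#'
#' Converts an apo/holo conformational entropy difference into its
#' contribution to the binding free energy,
#' \eqn{T (S_{holo} - S_{apo})}, reported in kcal/mol with
#' 1 kcal = 4184 J. Negative when the apo (unbound) state has the higher
#' conformational entropy, i.e. when binding costs entropy.
#'
#' @param s_holo,s_apo Entropies of the bound/unbound state, J/(mol K).
#' @param temperature Temperature in K.
#' @return Contribution to dG in kcal/mol.
#' @export
entropy_contribution <- function(s_holo, s_apo, temperature = 300.15) {
  stopifnot_scalar(temperature, "temperature", positive = TRUE)
  temperature * (s_holo - s_apo) / (.kcal_kJ * 1000)
}
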