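## PCA of pooled conformational ensembles and free-energy surfaces over the
## leading principal components.

#' Principal component analysis of pooled trajectory ensembles
#'
#' Eigendecomposition of the pooled (non-mass-weighted) Cartesian covariance
#' over the shared atom selection of one or more superposed ensembles.
#' Pooling apo and holo trajectories into a common model lets their surfaces
#' be drawn in the same collective coordinates. Eigenpairs are sorted by
#' descending eigenvalue; each eigenvector's sign is fixed so its
#' largest-magnitude component is positive.
#'
#' @param ensembles A [trajectory_ensemble()] or list of them, superposed to
#'   a common reference, all with the same selection size.
#' @param mass_weighted Mass-weight the covariance before diagonalizing
#'   (default FALSE: plain Cartesian covariance).
#' @return A `pca_model`: list with `mean` (3n), `eigenvectors` (3n x 3n,
#'   columns), `eigenvalues` (nm^2), `n_frames`.
#' @export
fit_pca <- function(ensembles, mass_weighted = FALSE) {
  if (inherits(ensembles, "trajectory_ensemble")) ensembles <- list(ensembles)
  if (length(ensembles) < 1L) stop("need at least one ensemble")
  mats <- lapply(ensembles, .flatten_selection)
  nc <- unique(vapply(mats, ncol, integer(1)))
  if (length(nc) != 1L) stop("all ensembles must share the selection size")
  x <- do.call(rbind, mats)
  if (nrow(x) < 2L) stop("pooled frame count must be >= 2")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  if (mass_weighted) {
    m <- rep(ensembles[[1]]$masses[ensembles[[1]]$selection], each = 3L)
    xc <- sweep(xc, 2L, sqrt(m), "*")
  }
  cv <- crossprod(xc) / (nrow(x) - 1L)
  eg <- eigen((cv + t(cv)) / 2, symmetric = TRUE)
  vec <- eg$vectors
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  structure(list(mean = mu, eigenvectors = vec,
                 eigenvalues = pmax(eg$values, 0),
                 n_frames = nrow(x), mass_weighted = mass_weighted),
            class = "pca_model")
}

#' Project an ensemble onto principal components
#'
#' @param ensemble A [trajectory_ensemble()] sharing the model's selection
#'   size.
#' @param model A `pca_model` from [fit_pca()].
#' @param components Component indices (default 1:2).
#' @return frames x length(components) matrix of projections (nm).
#' @export
project_pca <- function(ensemble, model, components = 1:2) {
  x <- .flatten_selection(ensemble)
  if (ncol(x) != length(model$mean))
    stop("ensemble selection does not match the PCA model")
  xc <- sweep(x, 2L, model$mean)
  if (isTRUE(model$mass_weighted)) {
    m <- rep(ensemble$masses[ensemble$selection], each = 3L)
    xc <- sweep(xc, 2L, sqrt(m), "*")
  }
  xc %*% model$eigenvectors[, components, drop = FALSE]
}

#' Free-energy surface over the two leading principal components
#'
#' Projects the frames on PC1/PC2, bins them on a 2-D grid and converts the
#' counts to free energies \eqn{\Delta G = -k_B T \ln(c / c_{max})}, so the
#' modal bin is exactly 0 and every occupied bin is >= 0. Empty bins are
#' masked (NA), never reported as zero.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param model A `pca_model` from [fit_pca()].
#' @param temperature Temperature in K.
#' @param bins Number of bins per axis, >= 2.
#' @param keep_frames Optional logical per-frame mask (e.g. the bound frames
#'   from [filter_events()]); surface-bound/unbound states are excluded by
#'   passing only the frames to keep.
#' @param limits Optional list(pc1 = c(lo, hi), pc2 = c(lo, hi)) to fix the
#'   grid (so multiple surfaces share axes).
#' @return A `fes_grid`: list with `pc1_edges`, `pc2_edges`, `free_energy`
#'   (bins x bins matrix, kcal/mol, NA = empty), `counts`, `occupied` mask.
#' @export
project_fes <- function(ensemble, model, temperature = 300.15, bins = 40L,
                        keep_frames = NULL, limits = NULL) {
  if (bins < 2L) stop("bins must be >= 2")
  pr <- project_pca(ensemble, model, 1:2)
  if (!is.null(keep_frames)) pr <- pr[keep_frames, , drop = FALSE]
  if (nrow(pr) < 1L) stop("no frames left to histogram")
  rng <- function(v, lim) {
    if (!is.null(lim)) return(lim)
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5) * max(abs(r[1]), 1e-6)
    r
  }
  r1 <- rng(pr[, 1], limits$pc1); r2 <- rng(pr[, 2], limits$pc2)
  e1 <- seq(r1[1], r1[2], length.out = bins + 1L)
  e2 <- seq(r2[1], r2[2], length.out = bins + 1L)
  i1 <- pmin(pmax(findInterval(pr[, 1], e1, all.inside = TRUE), 1L), bins)
  i2 <- pmin(pmax(findInterval(pr[, 2], e2, all.inside = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (k in seq_len(nrow(pr))) counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1L
  kt_kcal <- kj_to_kcal(1 / beta_kJ(temperature))
  fe <- matrix(NA_real_, bins, bins)
  occ <- counts > 0L
  fe[occ] <- -kt_kcal * log(counts[occ] / max(counts))
  structure(list(pc1_edges = e1, pc2_edges = e2, free_energy = fe,
                 counts = counts, occupied = occ,
                 temperature = temperature),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf("fes_grid: %d x %d bins, %d occupied, max %.2f kcal/mol\n",
              nrow(x$free_energy), ncol(x$free_energy), sum(x$occupied),
              max(x$free_energy, na.rm = TRUE)))
  invisible(x)
}

#' Plot a free-energy surface
#'
#' @param x A `fes_grid`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.fes_grid <- function(x, ...) {
  mid <- function(e) (e[-1] + e[-length(e)]) / 2
  graphics::image(mid(x$pc1_edges), mid(x$pc2_edges), x$free_energy,
                  xlab = "PC1 (nm)", ylab = "PC2 (nm)",
                  col = grDevices::hcl.colors(32, "viridis", rev = TRUE), ...)
  invisible(x)
}
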