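## Synthetic-data generators. Every downstream stage of the pipeline is
## testable against these because the ground truth (free energy, covariance,
## event frames, injected duplicate dihedrals, analytic work integrals) is
## known by construction.

#' Generate a CFT-consistent bidirectional work set
#'
#' Draws Gaussian work samples that satisfy the Crooks fluctuation theorem
#' exactly in distribution: forward (0 -> 1) works from
#' \eqn{N(\Delta G + \beta\sigma^2/2, \sigma^2)} and reverse works, measured
#' along the 1 -> 0 transition, from
#' \eqn{N(-\Delta G + \beta\sigma^2/2, \sigma^2)}. With this pairing the
#' forward-work density and the density of negated reverse works obey
#' \eqn{P_f(W)/P_r(W) = e^{\beta(W - \Delta G)}}.
#'
#' Reverse works are stored as measured along 1 -> 0 (not pre-negated),
#' matching the raw output of an MD engine.
#'
#' @param dg_true True free energy difference of the 0 -> 1 transition,
#'   kJ/mol.
#' @param sigma Work standard deviation (dissipation scale), kJ/mol, >= 0.
#' @param n_forward,n_reverse Sample counts, >= 1.
#' @param temperature Temperature in K.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A `work_set` object: list with `forward_works`, `reverse_works`
#'   (kJ/mol, measured along 1 -> 0) and `temperature`.
#' @export
gen_gaussian_work <- function(dg_true, sigma, n_forward, n_reverse,
                              temperature = 300.15, seed = 1L) {
  stopifnot_scalar(dg_true, "dg_true")
  stopifnot_scalar(sigma, "sigma")
  if (sigma < 0) stop("sigma must be >= 0")
  if (n_forward < 1 || n_reverse < 1)
    stop("n_forward and n_reverse must be >= 1")
  b <- beta_kJ(temperature)
  mu_f <- dg_true + b * sigma^2 / 2
  mu_r <- -dg_true + b * sigma^2 / 2
  with_seed(seed, {
    wf <- stats::rnorm(n_forward, mean = mu_f, sd = sigma)
    wr <- stats::rnorm(n_reverse, mean = mu_r, sd = sigma)
    work_set(wf, wr, temperature)
  })
}

#' Generate a multivariate-Gaussian coordinate ensemble
#'
#' Samples `n_frames` i.i.d. coordinate vectors from a multivariate normal
#' with the requested covariance over the 3N Cartesian coordinates. Used as
#' the ground-truth fixture for the Schlitter entropy and PCA stages: the
#' closed-form entropy of the generating covariance is computable from its
#' eigenvalues.
#'
#' @param covariance Symmetric positive-semidefinite (3N x 3N) matrix, nm^2.
#' @param masses Per-atom masses, amu; length N = nrow(covariance)/3.
#' @param n_frames Number of frames to draw.
#' @param mean Optional mean coordinate vector (default 0).
#' @param seed Integer seed.
#' @return A `trajectory_ensemble` (frames x atoms x 3 array + masses).
#' @export
gen_gaussian_ensemble <- function(covariance, masses, n_frames, mean = NULL,
                                  seed = 1L) {
  covariance <- as.matrix(covariance)
  d <- nrow(covariance)
  if (ncol(covariance) != d) stop("covariance must be square")
  if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, max(abs(covariance))))
    stop("covariance must be symmetric")
  if (d %% 3L != 0L) stop("covariance dimension must be 3 * n_atoms")
  n_atoms <- d %/% 3L
  if (length(masses) != n_atoms) stop("need one mass per atom")
  if (any(masses <= 0)) stop("all masses must be > 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance must be positive semi-definite")
  mu <- if (is.null(mean)) rep(0, d) else as.numeric(mean)
  x <- with_seed(seed, {
    if (all(abs(covariance) == 0)) {
      matrix(rep(mu, each = n_frames), nrow = n_frames)
    } else {
      MASS::mvrnorm(n_frames, mu = mu, Sigma = covariance, tol = 1e-6)
    }
  })
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  coords <- array(0, dim = c(n_frames, n_atoms, 3L))
  for (a in seq_len(n_atoms))
    coords[, a, ] <- x[, (3L * (a - 1L) + 1L):(3L * a), drop = FALSE]
  trajectory_ensemble(coords, masses)
}

#' Generate a pose-orientation / unbinding geometry series
#'
#' Emits the two observables the event filter consumes: the cosine of the
#' guest orientation relative to the host axis (near +1 in the primary pose,
#' switching to near -1 at `flip_frame`) and the host-guest centre-of-mass
#' distance (near `baseline_nm`, jumping above the unbound threshold at
#' `unbind_frame`). Gaussian noise of sd `noise_sd` is added to both
#' (interpreted in cosine units and nm respectively).
#'
#' @param n_frames Number of frames.
#' @param flip_frame 0-based frame of the orientation flip, or NULL.
#' @param unbind_frame 0-based frame of unbinding, or NULL.
#' @param noise_sd Noise standard deviation (cosine units / nm).
#' @param baseline_nm Bound-state COM distance, nm.
#' @param unbound_nm COM distance after unbinding, nm.
#' @param seed Integer seed.
#' @return A `geometry_series` data.frame with columns `frame_index`
#'   (0-based), `orientation_cos`, `com_distance`.
#' @export
gen_pose_series <- function(n_frames, flip_frame = NULL, unbind_frame = NULL,
                            noise_sd = 0, baseline_nm = 0.3, unbound_nm = 2.5,
                            seed = 1L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  for (f in list(flip_frame, unbind_frame)) {
    if (!is.null(f) && (f < 0 || f >= n_frames))
      stop("event frames must satisfy 0 <= frame < n_frames")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  idx <- seq_len(n_frames) - 1L
  cosv <- rep(1, n_frames)
  if (!is.null(flip_frame)) cosv[idx >= flip_frame] <- -1
  dist <- rep(baseline_nm, n_frames)
  if (!is.null(unbind_frame)) dist[idx >= unbind_frame] <- unbound_nm
  with_seed(seed, {
    if (noise_sd > 0) {
      cosv <- cosv + stats::rnorm(n_frames, sd = noise_sd)
      dist <- pmax(0, dist + stats::rnorm(n_frames, sd = noise_sd))
    }
    geometry_series(idx, cosv, dist)
  })
}

## GAFF-like atom-type alphabet used for fixture generation. Wildcard "X"
## is deliberately excluded: injected duplicates must be atom-type specific.
.ff_types <- c("c3", "c2", "c1", "ca", "os", "oh", "o", "n", "n3", "na",
               "hc", "h1", "ho", "hn", "ss", "p5", "f", "cl")

.random_quadruple <- function() {
  q <- sample(.ff_types, 4L, replace = TRUE)
  paste(q, collapse = "-")
}

.canonical_quad_str <- function(q) {
  parts <- strsplit(q, "-", fixed = TRUE)[[1]]
  rev_q <- paste(rev(parts), collapse = "-")
  if (q <= rev_q) q else rev_q
}

.format_dihe_line <- function(quad, idivf, pk_kcal, phase, pn) {
  parts <- strsplit(quad, "-", fixed = TRUE)[[1]]
  sprintf("%-2s-%-2s-%-2s-%-2s %4d %10.5f %10.3f %6.1f",
          parts[1], parts[2], parts[3], parts[4], idivf, pk_kcal, phase, pn)
}

#' Generate an AMBER-style dihedral block with injected over-defined groups
#'
#' Writes a syntactically valid proper-dihedral parameter block containing
#' `n_clean` unique single-term entries plus the requested duplicate groups:
#' each injected group assigns two (or more) different parameter sets, with a
#' shared periodicity but different barriers, to one atom-type-specific
#' quadruple, and the variants are placed non-sequentially (separated by at
#' least one unrelated line). This reproduces the over-definition pathology
#' of the GAFF 2.x parameter files, e.g. the sugar-ring c3-c3-os-c3 dihedral.
#'
#' @param n_clean Number of clean (unique-quadruple) entries, >= 0.
#' @param duplicates List of injected groups. Each element is a list with
#'   `quad` (e.g. "c3-c3-os-c3"; no wildcard "X" types allowed),
#'   `periodicity` (shared integer), and `barriers` (numeric vector, one
#'   barrier in kcal/mol per variant; must have >= 2 distinct values).
#'   Optional `phase` (degrees, default 0).
#' @param seed Integer seed controlling types, values and placement.
#' @return List with `text` (the parameter block, one line per entry),
#'   `truth` (character vector of canonical quadruples injected as
#'   over-defined groups) and `n_lines`.
#' @export
gen_ff_fixture <- function(n_clean, duplicates = list(), seed = 1L) {
  if (n_clean < 0) stop("n_clean must be >= 0")
  for (d in duplicates) {
    parts <- strsplit(d$quad, "-", fixed = TRUE)[[1]]
    if (length(parts) != 4L) stop("duplicate quad must have 4 atom types")
    if (any(parts == "X"))
      stop("injected duplicates must be atom-type specific (no wildcard 'X')")
    if (length(unique(d$barriers)) < 2L)
      stop("each duplicate group needs >= 2 distinct barriers")
  }
  with_seed(seed, {
    dup_canon <- vapply(duplicates, function(d) .canonical_quad_str(d$quad),
                        character(1))
    ## unique clean quadruples, disjoint from the injected ones
    clean <- character(0)
    seen <- dup_canon
    while (length(clean) < n_clean) {
      q <- .random_quadruple()
      cq <- .canonical_quad_str(q)
      if (!(cq %in% seen)) {
        clean <- c(clean, q)
        seen <- c(seen, cq)
      }
    }
    clean_lines <- vapply(clean, function(q)
      .format_dihe_line(q, 1L, round(stats::runif(1, 0.1, 3.0), 5),
                        sample(c(0, 180), 1L), sample(1:4, 1L)),
      character(1))
    dup_lines <- list()
    for (i in seq_along(duplicates)) {
      d <- duplicates[[i]]
      phase <- d$phase %||% 0
      dup_lines[[i]] <- vapply(d$barriers, function(pk)
        .format_dihe_line(d$quad, 1L, pk, phase, d$periodicity), character(1))
    }
    ## Place variants non-sequentially: lay out clean lines, then insert each
    ## group's variants at positions separated by at least one clean line.
    lines <- clean_lines
    for (i in seq_along(dup_lines)) {
      vl <- dup_lines[[i]]
      if (length(lines) < length(vl) - 1L) {
        ## not enough separators available: pad with extra clean lines
        extra_needed <- length(vl) - 1L - length(lines)
        for (k in seq_len(extra_needed)) {
          repeat {
            q <- .random_quadruple()
            cq <- .canonical_quad_str(q)
            if (!(cq %in% seen)) { seen <- c(seen, cq); break }
          }
          lines <- c(lines, .format_dihe_line(q, 1L,
            round(stats::runif(1, 0.1, 3.0), 5), 0, 1L))
        }
      }
      ## choose strictly increasing insertion slots with gaps >= 2 so that
      ## after insertion at least one unrelated line separates the variants
      n_slots <- length(lines) + 1L
      repeat {
        pos <- sort(sample.int(n_slots, length(vl)))
        if (length(pos) < 2L || all(diff(pos) >= 2L)) break
      }
      for (k in rev(seq_along(vl))) {
        lines <- append(lines, vl[k], after = pos[k] - 1L)
      }
    }
    list(text = paste(lines, collapse = "\n"),
         truth = sort(unique(dup_canon)),
         n_lines = length(lines))
  })
}

#' Generate a polynomial dH/dlambda series with its analytic integral
#'
#' Evaluates a polynomial in lambda on an even grid over [0, 1]. The analytic
#' integral over [0, 1] is returned alongside as ground truth for the
#' trapezoidal work integration.
#'
#' @param coefficients Polynomial coefficients, ascending powers:
#'   `c(a0, a1, a2, ...)` means a0 + a1 l + a2 l^2 + ...
#' @param n_points Number of grid points, >= 2.
#' @param direction "forward" (lambda 0 -> 1) or "reverse" (1 -> 0).
#' @return List with `series` (a `dhdl_series`) and `analytic_integral`
#'   (the signed integral along the series' own lambda path).
#' @export
gen_dhdl_series <- function(coefficients, n_points, direction = "forward") {
  if (n_points < 2) stop("n_points must be >= 2")
  direction <- match.arg(direction, c("forward", "reverse"))
  lam <- seq(0, 1, length.out = n_points)
  pw <- seq_along(coefficients) - 1L
  dhdl <- vapply(lam, function(l) sum(coefficients * l^pw), numeric(1))
  integral <- sum(coefficients / (pw + 1))  # over 0 -> 1
  if (direction == "reverse") {
    lam <- rev(lam)
    dhdl <- rev(dhdl)
    integral <- -integral
  }
  list(series = dhdl_series(lam, dhdl, direction),
       analytic_integral = integral)
}
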