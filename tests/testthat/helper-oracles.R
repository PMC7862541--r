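# Independent oracles used to check the package's estimators. These are
# deliberately simple brute-force implementations that share no code with
# the functions they validate.

# Grid + golden-section maximization of the Bennett log-likelihood over dG.
# Independent of the root-bracketing solver in estimate_cft_ml.
grid_bar_oracle <- function(ws, lower, upper) {
  grid <- seq(lower, upper, length.out = 2001L)
  ll <- vapply(grid, function(g) bar_log_likelihood(g, ws), numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 2L)]
  hi <- grid[min(length(grid), i + 2L)]
  stats::optimize(function(g) bar_log_likelihood(g, ws),
                  c(lo, hi), maximum = TRUE, tol = 1e-12)$maximum
}

# Boresch restrained configurational integral by 1-D quadratures (the 6-D
# integral is separable): Z = I_r * I_thetaA * I_thetaB * I_phi^3, and the
# release free energy is -kT ln(8 pi^2 V0 / Z).
#
# jacobian = "full" integrates r^2 sin(thetaA) sin(thetaB) exactly;
# jacobian = "reference" evaluates the Jacobian at the reference geometry
# (the stiff-spring-regime integral the analytical formula corresponds to)
# while still integrating all six Gaussians numerically.
boresch_quadrature_oracle <- function(restr, temperature,
                                      jacobian = c("full", "reference")) {
  jacobian <- match.arg(jacobian)
  kt <- 0.0083144621 * temperature
  b <- 1 / kt
  if (jacobian == "full") {
    i_r <- stats::integrate(function(r)
      r^2 * exp(-b * restr$k_r * (r - restr$r0)^2 / 2),
      lower = 0, upper = Inf, rel.tol = 1e-12)$value
    i_th <- function(k, th0) stats::integrate(function(th)
      sin(th) * exp(-b * k * (th - th0)^2 / 2),
      lower = 0, upper = pi, rel.tol = 1e-12)$value
  } else {
    i_r <- restr$r0^2 * stats::integrate(function(r)
      exp(-b * restr$k_r * (r - restr$r0)^2 / 2),
      lower = -Inf, upper = Inf, rel.tol = 1e-12)$value
    i_th <- function(k, th0) sin(th0) * stats::integrate(function(th)
      exp(-b * k * (th - th0)^2 / 2),
      lower = -Inf, upper = Inf, rel.tol = 1e-12)$value
  }
  i_phi <- function(k) stats::integrate(function(phi)
    exp(-b * k * phi^2 / 2),
    lower = if (jacobian == "full") -pi else -Inf,
    upper = if (jacobian == "full") pi else Inf, rel.tol = 1e-12)$value
  z <- i_r * i_th(restr$k_thetaA, restr$thetaA0) *
    i_th(restr$k_thetaB, restr$thetaB0) *
    i_phi(restr$k_phiA) * i_phi(restr$k_phiB) * i_phi(restr$k_phiC)
  -kt * log(8 * pi^2 * restr$standard_volume / z)
}

# Closed-form Schlitter entropy from a generating covariance (J/(mol K)),
# written out from scratch in SI units.
schlitter_closed_form <- function(covariance, masses_per_coord, temperature) {
  kB <- 1.380649e-23; hbar <- 1.054571817e-34
  amu <- 1.66053906660e-27; nA <- 6.02214076e23
  sqm <- sqrt(masses_per_coord * amu)
  mwc <- as.matrix(covariance) * 1e-18 * outer(sqm, sqm)
  ev <- eigen((mwc + t(mwc)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  (kB * nA / 2) * sum(log1p(kB * temperature * exp(1)^2 / hbar^2 * ev))
}

# Random symmetric PSD covariance over d coordinates with variances of
# order `scale` (nm^2).
random_psd_cov <- function(d, scale = 0.01, seed = 1L) {
  set.seed(seed)
  a <- matrix(rnorm(d * d), d, d)
  cv <- crossprod(a) / d * scale
  (cv + t(cv)) / 2
}

# Rotation matrix about a random axis.
random_rotation <- function(seed = 1L) {
  set.seed(seed)
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- runif(1, 0, 2 * pi)
  k <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
}

# Build a small synthetic work-file tree + manifest for pipeline tests:
# for each pose/repeat/direction writes `n_files` dhdl files whose works
# are exactly the requested values (constant dH/dl = work).
make_work_tree <- function(dir, pose_dgs_kj, n_repeats = 3L, n_files = 5L,
                           sigma = 0.5, temperature = 300.15, seed = 1L,
                           host = "hostA", guest = "g1", ff = "ffA") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- 1 / (0.0083144621 * temperature)
  rows <- list()
  set.seed(seed)
  for (pose in names(pose_dgs_kj)) {
    dg <- pose_dgs_kj[[pose]]
    for (rep in seq_len(n_repeats)) {
      for (dirn in c("forward", "reverse")) {
        mu <- if (dirn == "forward") dg + b * sigma^2 / 2
              else -dg + b * sigma^2 / 2
        for (k in seq_len(n_files)) {
          w <- rnorm(1, mu, sigma)
          fn <- sprintf("%s_%s_r%d_%s_%03d.xvg", pose, dirn, rep, host, k)
          # reverse transitions integrate along 1 -> 0, so a constant
          # dH/dl of -w yields the intended measured work w
          lvl <- if (dirn == "reverse") -w else w
          s <- dhdl_series(c(0, 0.5, 1), rep(lvl, 3), dirn)
          write_dhdl_xvg(s, file.path(dir, fn))
          rows[[length(rows) + 1L]] <- data.frame(
            host = host, guest = guest, forcefield = ff, pose = pose,
            direction = dirn, path = fn, stringsAsFactors = FALSE,
            check.names = FALSE)
          rows[[length(rows)]]$`repeat` <- rep
        }
      }
    }
  }
  m <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(m, mp, row.names = FALSE)
  mp
}
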