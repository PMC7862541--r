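## Assembly of per-pose transition free energies into absolute and relative
## binding free energies: standard-state restraint correction, Boltzmann
## pose combination, repeat and force-field averaging, DDG matrices and
## benchmark metrics.

#' Define a Boresch-style relative restraint
#'
#' One distance, two angles and three dihedrals restraining the guest pose
#' relative to the host, each with a harmonic force constant. The reference
#' geometry and constants determine the analytical standard-state correction.
#'
#' @param r0 Reference host-guest anchor distance, nm, > 0.
#' @param thetaA0,thetaB0 Reference angles, rad, in (0, pi).
#' @param k_r Distance force constant, kJ/(mol nm^2), > 0.
#' @param k_thetaA,k_thetaB Angle force constants, kJ/(mol rad^2), > 0.
#' @param k_phiA,k_phiB,k_phiC Dihedral force constants, kJ/(mol rad^2), > 0.
#' @param standard_volume Standard-state volume per molecule, nm^3
#'   (1.6605 nm^3 corresponds to the 1 M standard state).
#' @return A `restraint_definition` object.
#' @export
restraint_definition <- function(r0, thetaA0, thetaB0, k_r,
                                 k_thetaA, k_thetaB, k_phiA, k_phiB, k_phiC,
                                 standard_volume = 1.6605) {
  ks <- c(k_r = k_r, k_thetaA = k_thetaA, k_thetaB = k_thetaB,
          k_phiA = k_phiA, k_phiB = k_phiB, k_phiC = k_phiC)
  if (any(ks <= 0)) stop("all force constants must be > 0")
  if (r0 <= 0) stop("r0 must be > 0")
  if (thetaA0 <= 0 || thetaA0 >= pi || thetaB0 <= 0 || thetaB0 >= pi)
    stop("reference angles must lie strictly inside (0, pi)")
  if (standard_volume <= 0) stop("standard_volume must be > 0")
  structure(list(r0 = r0, thetaA0 = thetaA0, thetaB0 = thetaB0,
                 k_r = k_r, k_thetaA = k_thetaA, k_thetaB = k_thetaB,
                 k_phiA = k_phiA, k_phiB = k_phiB, k_phiC = k_phiC,
                 standard_volume = standard_volume),
            class = "restraint_definition")
}

#' Boresch analytical standard-state restraint correction
#'
#' Free energy of releasing the restrained, decoupled guest to the
#' standard-state volume:
#' \deqn{\Delta G = -k_B T \ln \frac{8\pi^2 V^0
#'   \sqrt{k_r k_{\theta A} k_{\theta B} k_{\phi A} k_{\phi B} k_{\phi C}}}
#'   {r_0^2 \sin\theta_{A0} \sin\theta_{B0} \, (2\pi k_B T)^3}.}
#' Valid in the stiff-spring regime where the harmonic fluctuations do not
#' reach the Jacobian singularities (theta near 0 or pi, r near 0).
#'
#' @param restr A [restraint_definition()].
#' @param temperature Temperature in K.
#' @return Correction in kJ/mol (negative for typical stiff restraints:
#'   releasing the guest is favourable).
#' @export
restraint_correction <- function(restr, temperature = 300.15) {
  if (!inherits(restr, "restraint_definition"))
    stop("restr must be a restraint_definition")
  kt <- 1 / beta_kJ(temperature)
  sA <- sin(restr$thetaA0); sB <- sin(restr$thetaB0)
  if (abs(sA) < 1e-6 || abs(sB) < 1e-6)
    stop("degenerate collinear reference geometry (sin(theta0) ~ 0)")
  kprod <- restr$k_r * restr$k_thetaA * restr$k_thetaB *
    restr$k_phiA * restr$k_phiB * restr$k_phiC
  arg <- 8 * pi^2 * restr$standard_volume * sqrt(kprod) /
    (restr$r0^2 * sA * sB * (2 * pi * kt)^3)
  -kt * log(arg)
}

#' Per-pose free energy estimate with discard status
#'
#' @param pose "primary" or "secondary".
#' @param dg Binding free energy for the pose, kJ/mol (NA when discarded).
#' @param stderr Standard error, kJ/mol.
#' @param n_repeats Number of independent repeats averaged.
#' @param discarded TRUE when the pose was dropped (flip/unbind).
#' @param reason Discard reason: "", "flip" or "unbind".
#' @return A `pose_estimate` object.
#' @export
pose_estimate <- function(pose, dg = NA_real_, stderr = NA_real_,
                          n_repeats = NA_integer_, discarded = FALSE,
                          reason = "") {
  pose <- match.arg(pose, c("primary", "secondary"))
  if (discarded && is.finite(dg))
    stop("a discarded pose carries no dg")
  if (!discarded && !is.finite(dg))
    stop("a retained pose needs a finite dg")
  if (is.finite(stderr) && stderr < 0) stop("stderr must be >= 0")
  structure(list(pose = pose, dg = dg, stderr = stderr,
                 n_repeats = n_repeats, discarded = discarded,
                 reason = reason),
            class = "pose_estimate")
}

#' Boltzmann combination of binding-pose free energies
#'
#' For mutually exclusive poses the total binding free energy is
#' \deqn{\Delta G = -k_B T \ln \sum_i e^{-\beta \Delta G_i}}
#' over the non-discarded poses (log-sum-exp). The uncertainty is the
#' first-order propagation through the Boltzmann weights:
#' \eqn{\sigma^2 = \sum_i w_i^2 \sigma_i^2} with
#' \eqn{w_i = e^{-\beta\Delta G_i} / \sum_j e^{-\beta\Delta G_j}}.
#'
#' An optional weighted-mean variant (`method = "weighted-mean"`) returns
#' \eqn{\sum_i w_i \Delta G_i} instead of the Boltzmann sum.
#'
#' @param poses List of [pose_estimate()] objects.
#' @param temperature Temperature in K.
#' @param method "boltzmann-sum" (default) or "weighted-mean".
#' @return An [fe_estimate()]; errors if every pose is discarded.
#' @export
combine_poses <- function(poses, temperature = 300.15,
                          method = c("boltzmann-sum", "weighted-mean")) {
  method <- match.arg(method)
  if (inherits(poses, "pose_estimate")) poses <- list(poses)
  keep <- Filter(function(p) !p$discarded, poses)
  if (length(keep) == 0L)
    stop("all poses discarded (too weakly binding): no combined estimate")
  b <- beta_kJ(temperature)
  dgs <- vapply(keep, function(p) p$dg, numeric(1))
  ses <- vapply(keep, function(p) p$stderr, numeric(1))
  lw <- -b * dgs
  w <- exp(lw - logsumexp(lw))
  dg <- if (method == "boltzmann-sum") -logsumexp(lw) / b
        else sum(w * dgs)
  se <- if (all(is.finite(ses))) sqrt(sum((w * ses)^2)) else NA_real_
  fe_estimate(dg, se, paste0("combine-poses/", method))
}

#' Mean and standard error over independent repeats
#'
#' @param values Numeric vector (kJ/mol or any consistent unit), length >= 1.
#' @return List with `mean`, `sem` (sample sd / sqrt(n); NA for n = 1) and
#'   `sem_defined` (FALSE when n = 1).
#' @export
average_repeats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("need at least one value")
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
       sem_defined = n >= 2L,
       n = n)
}

#' One assembled binding free energy record
#'
#' @param host Host label (e.g. "MGLab24").
#' @param guest Guest label ("g1" or "g2").
#' @param forcefield Force-field label.
#' @param dg_kcal Binding free energy, kcal/mol.
#' @param stderr_kcal Standard error, kcal/mol.
#' @return A one-row `binding_record` data.frame.
#' @export
binding_record <- function(host, guest, forcefield, dg_kcal, stderr_kcal) {
  if (is.finite(stderr_kcal) && stderr_kcal < 0) stop("stderr must be >= 0")
  structure(data.frame(host = host, guest = guest, forcefield = forcefield,
                       dg_kcal = dg_kcal, stderr_kcal = stderr_kcal,
                       stringsAsFactors = FALSE),
            class = c("binding_record", "data.frame"))
}

#' Consensus average over force fields
#'
#' Averages the binding free energy of one (host, guest) system over force
#' fields and propagates the per-field standard errors in quadrature:
#' for n fields, stderr = sqrt(sum(se_i^2)) / n (= 1/2 sqrt(se1^2 + se2^2)
#' for the two-field consensus).
#'
#' @param records A data.frame of binding records (columns host, guest,
#'   forcefield, dg_kcal, stderr_kcal) for a single (host, guest).
#' @return A one-row [binding_record()] with forcefield "consensus".
#' @export
consensus <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) < 1L) stop("no records")
  if (length(unique(records$host)) != 1L ||
      length(unique(records$guest)) != 1L)
    stop("consensus requires a single (host, guest) system")
  if (anyDuplicated(records$forcefield))
    stop("duplicate force-field labels")
  n <- nrow(records)
  if (n == 1L)
    warning("consensus over a single force field: returning it unchanged")
  dg <- mean(records$dg_kcal)
  se <- sqrt(sum(records$stderr_kcal^2)) / n
  binding_record(records$host[1], records$guest[1], "consensus", dg, se)
}

#' Assemble a binding free energy from transition and restraint terms
#'
#' \deqn{\Delta G_{bind} = s\,\Delta G_{transition} + \Delta G_{restraint}}
#' where the sign s is fixed by the declared end-state convention of the
#' double-system/single-box (DSSB) setup. Under the default convention
#' ("unbinding", end state A = guest coupled in the host with the second
#' guest decoupled in solvent) the A -> B transition is an unbinding event
#' and s = -1. The opposite convention ("binding") uses s = +1.
#'
#' @param transition_dg Transition free energy, kJ/mol.
#' @param restr_corr Restraint standard-state correction, kJ/mol.
#' @param convention "unbinding" (default, s = -1) or "binding" (s = +1).
#' @return Binding free energy, kJ/mol.
#' @export
assemble_binding <- function(transition_dg, restr_corr,
                             convention = c("unbinding", "binding")) {
  convention <- match.arg(convention)
  if (!is.finite(transition_dg) || !is.finite(restr_corr))
    stop("both inputs must be finite")
  s <- if (convention == "unbinding") -1 else 1
  s * transition_dg + restr_corr
}

#' All non-redundant relative binding free energies for one guest
#'
#' Computes every host pair's DDG = dG_i - dG_j (pairs ordered by host
#' label), n(n-1)/2 rows, with errors in quadrature.
#'
#' @param records Binding records for a single guest, one row per host.
#' @return data.frame with columns host_i, host_j, ddg_kcal, stderr_kcal.
#' @export
ddg_matrix <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) < 2L) stop("need >= 2 hosts")
  if (anyDuplicated(records$host)) stop("duplicate host labels")
  if (length(unique(records$guest)) > 1L)
    stop("ddg_matrix operates on a single guest")
  records <- records[order(records$host), , drop = FALSE]
  n <- nrow(records)
  idx <- utils::combn(n, 2L)
  data.frame(
    host_i = records$host[idx[1, ]],
    host_j = records$host[idx[2, ]],
    ddg_kcal = records$dg_kcal[idx[1, ]] - records$dg_kcal[idx[2, ]],
    stderr_kcal = sqrt(records$stderr_kcal[idx[1, ]]^2 +
                       records$stderr_kcal[idx[2, ]]^2),
    stringsAsFactors = FALSE)
}

#' Benchmark metrics: AUE and Pearson correlation with bootstrap errors
#'
#' Average unsigned error (mean |calc - exp|) and the Pearson product-moment
#' correlation between calculated and experimental values, with
#' uncertainties estimated as the standard deviation of each metric over
#' paired bootstrap resamples of the systems.
#'
#' @param calc,exp Numeric vectors of equal length >= 2 (kcal/mol).
#' @param n_boot Number of paired bootstrap resamples.
#' @param seed Integer seed.
#' @return List with `aue`, `aue_err`, `pearson`, `pearson_err`, `n`;
#'   `pearson` is NA (flagged via `pearson_defined`) when either vector has
#'   zero variance.
#' @export
binding_metrics <- function(calc, exp, n_boot = 1000L, seed = 1L) {
  calc <- as.numeric(calc); exp <- as.numeric(exp)
  n <- length(calc)
  if (length(exp) != n || n < 2L) stop("calc and exp must have equal length >= 2")
  if (any(!is.finite(calc)) || any(!is.finite(exp)))
    stop("inputs must be finite")
  aue <- mean(abs(calc - exp))
  r_defined <- stats::sd(calc) > 0 && stats::sd(exp) > 0
  r <- if (r_defined) stats::cor(calc, exp) else NA_real_
  aue_err <- pearson_err <- NA_real_
  if (n_boot >= 2L) {
    bs <- with_seed(seed, {
      aues <- numeric(n_boot); rs <- numeric(n_boot)
      for (i in seq_len(n_boot)) {
        j <- sample.int(n, replace = TRUE)
        aues[i] <- mean(abs(calc[j] - exp[j]))
        rs[i] <- if (stats::sd(calc[j]) > 0 && stats::sd(exp[j]) > 0)
          stats::cor(calc[j], exp[j]) else NA_real_
      }
      list(aue = stats::sd(aues), r = stats::sd(rs, na.rm = TRUE))
    })
    aue_err <- bs$aue
    pearson_err <- if (r_defined) bs$r else NA_real_
  }
  list(aue = aue, aue_err = aue_err, pearson = r, pearson_err = pearson_err,
       pearson_defined = r_defined, n = n)
}
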