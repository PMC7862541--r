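## Free energy estimators for bidirectional non-equilibrium work sets.
##
## Conventions: reverse works enter as measured along the 1 -> 0 transition;
## internally they are negated into the forward (0 -> 1) convention where a
## common work axis is required. All energies kJ/mol.

#' Integrate a dH/dlambda series into a work value
#'
#' Trapezoidal quadrature of dH/dlambda over the series' own lambda path:
#' forward series give the work of the 0 -> 1 switch, reverse series the work
#' of the 1 -> 0 switch (no sign flip is applied beyond the direction of the
#' path itself).
#'
#' @param series A [dhdl_series()].
#' @return Work in kJ/mol.
#' @export
integrate_work <- function(series) {
  if (!inherits(series, "dhdl_series")) stop("series must be a dhdl_series")
  lam <- series$lambda_values
  y <- series$dhdl_values
  n <- length(lam)
  w <- sum(diff(lam) * (y[-1] + y[-n]) / 2)   # integral over lambda 0 -> 1
  if (series$direction == "reverse") -w else w
}

## Fermi / logistic function, numerically safe for large |x|.
.fermi <- function(x) 1 / (1 + exp(pmin(x, 700)))

## BAR/Crooks-ML implicit function. wf: forward works; wfr: negated reverse
## works (forward convention). Root in dg.
.bar_fn <- function(dg, wf, wfr, b, M) {
  sum(.fermi(b * (M + wf - dg))) - sum(.fermi(-b * (M + wfr - dg)))
}

## Log-likelihood of the direction labels given dg (Shirts et al. logistic
## form); maximized at the BAR root. Used by the grid oracle in tests and by
## diagnostics here.
#' Bennett log-likelihood of a bidirectional work set
#'
#' The logistic-regression log-likelihood whose maximum over dG is the
#' Crooks maximum-likelihood (BAR) estimate. Exposed so independent
#' maximization can cross-check the root-finding estimator.
#'
#' @param dg Candidate free energy, kJ/mol.
#' @param works A [work_set()].
#' @return Log-likelihood value.
#' @export
bar_log_likelihood <- function(dg, works) {
  b <- beta_kJ(works$temperature)
  wf <- works$forward_works
  wfr <- -works$reverse_works
  M <- log(length(wf) / length(wfr)) / b
  plog <- function(x) -log1p(exp(pmin(-x, 700)))  # log sigmoid
  sum(plog(b * (wf - dg) + b * M)) + sum(plog(-b * (wfr - dg) - b * M))
}

#' Crooks maximum-likelihood (BAR) free energy estimate
#'
#' Solves the Bennett acceptance ratio self-consistency equation for
#' bidirectional work samples,
#' \deqn{\sum_i \frac{1}{1 + e^{\beta(M + W_i^f - \Delta G)}} -
#'       \sum_j \frac{1}{1 + e^{-\beta(M + \bar W_j - \Delta G)}} = 0,}
#' with \eqn{\bar W_j = -W_j^{rev}} (reverse works measured along 1 -> 0,
#' negated into the forward convention) and offset
#' \eqn{M = \beta^{-1}\ln(n_f/n_r)}. This is the maximum-likelihood
#' estimator derived from the Crooks fluctuation theorem.
#'
#' The root is bracketed by the range of all forward and negated-reverse
#' works, expanded geometrically up to 10x before failure is declared
#' (non-overlapping work distributions), and solved to |f| < 1e-10.
#'
#' @param works A [work_set()]; both directions non-empty.
#' @param uncertainty "analytic" for the asymptotic ML variance (default),
#'   "bootstrap" for [bootstrap_stderr()].
#' @param n_boot,seed Bootstrap controls when `uncertainty = "bootstrap"`.
#' @return An [fe_estimate()] with method "cft-ml".
#' @export
estimate_cft_ml <- function(works, uncertainty = c("analytic", "bootstrap"),
                            n_boot = 200L, seed = 1L) {
  uncertainty <- match.arg(uncertainty)
  if (!inherits(works, "work_set")) stop("works must be a work_set")
  wf <- works$forward_works
  wfr <- -works$reverse_works
  nf <- length(wf); nr <- length(wfr)
  if (nf < 1L || nr < 1L)
    stop("CFT-ML needs at least one sample in each direction")
  b <- beta_kJ(works$temperature)
  M <- log(nf / nr) / b

  ## the BAR equation always has a formal root, but with disjoint work
  ## supports it is a pure extrapolation; refuse with a diagnostic instead
  if (min(wf) > max(wfr) + 1e-12 || min(wfr) > max(wf) + 1e-12) {
    gap <- max(min(wf) - max(wfr), min(wfr) - max(wf))
    stop(sprintf(paste("non-overlapping work distributions: forward works",
                       "span [%.3f, %.3f] kJ/mol, negated reverse works",
                       "[%.3f, %.3f] (gap %.3f); the CFT-ML estimate would",
                       "be an uncontrolled extrapolation"),
                 min(wf), max(wf), min(wfr), max(wfr), gap))
  }

  ## initial bracket: range of all forward and negated-reverse works,
  ## expanded geometrically up to 10x before declaring failure
  lo0 <- min(wf, wfr); hi0 <- max(wf, wfr)
  width0 <- max(hi0 - lo0, 1e-6)
  lo <- lo0; hi <- hi0
  flo <- .bar_fn(lo, wf, wfr, b, M)
  fhi <- .bar_fn(hi, wf, wfr, b, M)
  while (flo * fhi > 0 && (hi - lo) < 10 * width0) {
    lo <- lo - width0; hi <- hi + width0
    flo <- .bar_fn(lo, wf, wfr, b, M)
    fhi <- .bar_fn(hi, wf, wfr, b, M)
  }
  if (flo * fhi > 0)
    stop(paste("CFT-ML root not bracketed: forward and reverse work",
               "distributions do not overlap; bracket",
               sprintf("[%.3f, %.3f] f=[%.3g, %.3g]", lo, hi, flo, fhi)))
  if (flo == 0) {
    dg <- lo
  } else if (fhi == 0) {
    dg <- hi
  } else {
    dg <- stats::uniroot(.bar_fn, c(lo, hi), wf = wf, wfr = wfr, b = b, M = M,
                         tol = .Machine$double.eps^0.9)$root
    ## polish to |f| < 1e-10 by bisection if needed
    f <- .bar_fn(dg, wf, wfr, b, M)
    iter <- 0L
    dlo <- lo; dhi <- hi
    while (abs(f) > 1e-10 && iter < 200L && (dhi - dlo) > 0) {
      if (f * flo < 0) dhi <- dg else { dlo <- dg; flo <- f }
      dg <- (dlo + dhi) / 2
      f <- .bar_fn(dg, wf, wfr, b, M)
      iter <- iter + 1L
      if (dhi - dlo < .Machine$double.eps * max(1, abs(dg))) break
    }
  }

  if (uncertainty == "analytic") {
    ## Asymptotic ML variance (Shirts et al. form): sum over the pooled
    ## forward-convention works of the Fermi-function product.
    w_all <- c(wf, wfr)
    x <- b * (M + w_all - dg)
    s <- .fermi(x) * .fermi(-x)
    v <- (1 / sum(s) - (nf + nr) / (nf * nr)) / b^2
    se <- if (is.finite(v) && v > 0) sqrt(v) else NA_real_
  } else {
    se <- bootstrap_stderr("cft-ml", works, n_boot = n_boot, seed = seed)
  }
  fe_estimate(dg, se, "cft-ml", nf, nr)
}

#' Jarzynski exponential-average free energy estimate
#'
#' \deqn{\Delta G = -\beta^{-1} \ln \frac{1}{n} \sum_i e^{-\beta W_i}}
#' computed with a log-sum-exp formulation. The works are interpreted along
#' their own switching direction: applied to forward works this yields the
#' 0 -> 1 free energy, applied to measured reverse works the 1 -> 0 free
#' energy (negate for the forward convention).
#'
#' @param works Numeric vector of work values (kJ/mol), or a [work_set()]
#'   together with `direction`.
#' @param temperature Temperature in K (ignored when `works` is a work_set).
#' @param direction Which direction of a work_set to use.
#' @param n_boot,seed Bootstrap stderr controls (set `n_boot = 0` to skip).
#' @return An [fe_estimate()] with method "jarzynski".
#' @export
estimate_jarzynski <- function(works, temperature = 300.15,
                               direction = c("forward", "reverse"),
                               n_boot = 200L, seed = 1L) {
  direction <- match.arg(direction)
  if (inherits(works, "work_set")) {
    temperature <- works$temperature
    w <- if (direction == "forward") works$forward_works else works$reverse_works
  } else {
    w <- as.numeric(works)
  }
  if (length(w) < 1L) stop("need at least one work sample")
  if (any(!is.finite(w))) stop("work values must be finite")
  b <- beta_kJ(temperature)
  jar <- function(w) -(logsumexp(-b * w) - log(length(w))) / b
  dg <- jar(w)
  se <- NA_real_
  if (n_boot >= 2L) {
    se <- with_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(i)
        jar(w[sample.int(length(w), replace = TRUE)]), numeric(1))
      stats::sd(reps)
    })
  }
  nf <- if (direction == "forward") length(w) else 0L
  nr <- if (direction == "reverse") length(w) else 0L
  fe_estimate(dg, se, "jarzynski", nf, nr)
}

#' Crooks Gaussian intersection (CGI) free energy estimate
#'
#' Fits Gaussians to the forward works and to the negated reverse works and
#' returns the intersection point of the two densities. Under the Crooks
#' fluctuation theorem with Gaussian work distributions the densities cross
#' at W = dG. With equal variances the intersection is the midpoint of the
#' means (the degenerate quadratic is solved analytically); otherwise the
#' quadratic root lying between the two means is chosen.
#'
#' @param works A [work_set()] with >= 2 samples per direction.
#' @param n_boot,seed Bootstrap stderr controls (set `n_boot = 0` to skip).
#' @return An [fe_estimate()] with method "cgi".
#' @export
estimate_cgi <- function(works, n_boot = 200L, seed = 1L) {
  if (!inherits(works, "work_set")) stop("works must be a work_set")
  if (length(works$forward_works) < 2L || length(works$reverse_works) < 2L)
    stop("CGI needs >= 2 samples per direction")
  cgi <- function(wf, wfr) {
    m1 <- mean(wf); s1 <- stats::sd(wf)
    m2 <- mean(wfr); s2 <- stats::sd(wfr)
    if (s1 == 0 || s2 == 0) stop("CGI undefined for zero-variance direction")
    if (abs(s1 - s2) < 1e-12 * max(s1, s2)) return((m1 + m2) / 2)
    ## intersection of N(m1,s1^2) and N(m2,s2^2):
    ## (x-m1)^2/s1^2 - (x-m2)^2/s2^2 = 2 ln(s2/s1)
    a <- 1 / s1^2 - 1 / s2^2
    bq <- -2 * (m1 / s1^2 - m2 / s2^2)
    cq <- m1^2 / s1^2 - m2^2 / s2^2 - 2 * log(s2 / s1)
    disc <- bq^2 - 4 * a * cq
    if (disc < 0) stop("CGI: no real intersection")
    roots <- (-bq + c(-1, 1) * sqrt(disc)) / (2 * a)
    lo <- min(m1, m2); hi <- max(m1, m2)
    inside <- roots >= lo - 1e-12 & roots <= hi + 1e-12
    if (any(inside)) roots[inside][1]
    else roots[which.min(pmax(lo - roots, roots - hi))]  # nearest to the gap
  }
  dg <- cgi(works$forward_works, -works$reverse_works)
  se <- if (n_boot >= 2L)
    bootstrap_stderr("cgi", works, n_boot = n_boot, seed = seed)
  else NA_real_
  fe_estimate(dg, se, "cgi",
              length(works$forward_works), length(works$reverse_works))
}

#' Bootstrap standard error of a free energy estimator
#'
#' Resamples with replacement within each direction, re-runs the estimator,
#' and returns the standard deviation of the resampled estimates.
#' Deterministic given the seed.
#'
#' @param estimator "cft-ml", "jarzynski" or "cgi".
#' @param works A [work_set()].
#' @param n_boot Number of resamples, >= 2.
#' @param seed Integer seed.
#' @return Standard error in kJ/mol.
#' @export
bootstrap_stderr <- function(estimator, works, n_boot = 200L, seed = 1L) {
  estimator <- match.arg(estimator, c("cft-ml", "jarzynski", "cgi"))
  if (n_boot < 2L) stop("n_boot must be >= 2")
  wf <- works$forward_works; wr <- works$reverse_works
  point <- function(ws) {
    switch(estimator,
      "cft-ml" = estimate_cft_ml(ws, uncertainty = "analytic")$dg,
      "jarzynski" = estimate_jarzynski(ws, direction = "forward",
                                       n_boot = 0L)$dg,
      "cgi" = estimate_cgi(ws, n_boot = 0L)$dg)
  }
  with_seed(seed, {
    reps <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      ws <- work_set(wf[sample.int(length(wf), replace = TRUE)],
                     wr[sample.int(length(wr), replace = TRUE)],
                     works$temperature)
      reps[i] <- tryCatch(point(ws), error = function(e)
        stop(sprintf("estimator '%s' failed on bootstrap resample %d: %s",
                     estimator, i, conditionMessage(e)), call. = FALSE))
    }
    stats::sd(reps)
  })
}
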