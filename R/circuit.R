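#' Force-displacement law of two Kelvin-Voigt elements in series
#'
#' A trapped probe (trap stiffness `k_ot`, trap centre at `x1 = v t`) couples
#' to a network modelled as a spring `kappa` and dashpot `gamma` in parallel.
#' The probe position `x2` obeys the massless force balance
#' `gamma dx2/dt + (kappa + k_ot) x2 = k_ot v t` with `x2(0) = 0`, and the
#' measured force is `F = k_ot (x1 - x2)`. The closed-form solution is
#'
#' `F(x1) = (k_ot kappa / (k_ot + kappa)) x1 +
#'   (gamma v k_ot^2 / (k_ot + kappa)^2) (1 - exp(-(k_ot + kappa) x1 / (gamma v)))`
#'
#' with initial slope `k_ot` (the probe re-equilibrates in the trap), terminal
#' slope `k_ot kappa / (k_ot + kappa)` (the series-spring value), and, in the
#' fluid limit `kappa -> 0`, a viscous force plateau `gamma v`.
#'
#' @param x1 stage position(s) in um, non-negative
#' @param kappa network spring constant, pN/um
#' @param gamma network drag coefficient, pN s/um
#' @param k_ot trap stiffness, pN/um (default 68)
#' @param v stage speed, um/s
#' @return force in pN, same length as `x1`
#' @export
circuit_force <- function(x1, kappa, gamma, k_ot = 68, v = 24) {
  if (kappa <= 0 || gamma <= 0 || k_ot <= 0 || v <= 0)
    stop("kappa, gamma, k_ot and v must all be positive")
  if (any(x1 < 0)) stop("x1 must be non-negative")
  ks <- k_ot + kappa
  k_ot * kappa / ks * x1 +
    gamma * v * k_ot^2 / ks^2 * (1 - exp(-ks * x1 / (gamma * v)))
}

#' Fit the Kelvin-Voigt circuit model to an averaged force curve
#'
#' Weighted nonlinear least squares over `(kappa, gamma)` with the trap
#' stiffness held fixed at its calibrated value. Initial values come from the
#' terminal slope `m` of the curve (`kappa0 = k_ot m / (k_ot - m)`) and the
#' late-curve intercept; if the terminal slope reaches or exceeds `k_ot` a
#' coarse grid search supplies the start. 95 percent confidence intervals are
#' Wald intervals from the parameter covariance.
#'
#' @param curve an [ensemble_average()] result, or any data frame with
#'   columns `x` (um) and `F` (pN); a `sem` column, when present and
#'   positive, provides inverse-variance weights
#' @param k_ot trap stiffness, pN/um (fixed, not fitted)
#' @param v stage speed, um/s
#' @return object of class `circuit_fit`: list with `kappa`, `gamma`, their
#'   95 percent CIs, the residual norm, and the underlying `nls` object
#' @export
fit_circuit <- function(curve, k_ot = 68, v = 24) {
  x <- curve$x
  f <- curve$F
  keep <- is.finite(x) & is.finite(f)
  x <- x[keep]; f <- f[keep]
  if (length(x) < 5) stop("curve too short to fit")
  w <- rep(1, length(x))
  if (!is.null(curve$sem)) {
    s <- curve$sem[keep]
    if (all(is.finite(s)) && all(s > 0)) w <- 1 / s^2
  }
  # initialisation from the late linear regime
  late <- x >= quantile(x, 0.6)
  lf <- lm(f[late] ~ x[late])
  m <- unname(coef(lf)[2])
  b <- unname(coef(lf)[1])
  if (is.finite(m) && m > 0 && m < k_ot) {
    kappa0 <- k_ot * m / (k_ot - m)
    gamma0 <- max(b, 1e-3) * (k_ot + kappa0)^2 / (v * k_ot^2)
  } else {
    # grid search fallback
    grid <- expand.grid(kappa = 10^seq(-2, 3, length.out = 25),
                        gamma = 10^seq(-3, 2, length.out = 25))
    sse <- vapply(seq_len(nrow(grid)), function(i) {
      sum(w * (f - circuit_force(x, grid$kappa[i], grid$gamma[i], k_ot, v))^2)
    }, numeric(1))
    kappa0 <- grid$kappa[which.min(sse)]
    gamma0 <- grid$gamma[which.min(sse)]
  }
  dat <- data.frame(x = x, f = f)
  fit <- minpack.lm::nlsLM(
    f ~ circuit_force(x, kappa, gamma, k_ot, v),
    data = dat, start = list(kappa = kappa0, gamma = max(gamma0, 1e-3)),
    weights = w, lower = c(1e-6, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  tq <- qt(0.975, df = length(x) - 2)
  ci <- rbind(est - tq * se, est + tq * se)
  dimnames(ci) <- list(c("lower", "upper"), names(est))
  structure(list(kappa = unname(est["kappa"]), gamma = unname(est["gamma"]),
                 kappa_ci = unname(ci[, "kappa"]),
                 gamma_ci = unname(ci[, "gamma"]),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 k_ot = k_ot, v = v, fit = fit),
            class = "circuit_fit")
}

#' @export
print.circuit_fit <- function(x, ...) {
  cat(sprintf(
    "Kelvin-Voigt circuit fit (k_OT = %g pN/um, v = %g um/s)\n", x$k_ot, x$v))
  cat(sprintf("  kappa = %.4g pN/um   [%.4g, %.4g]\n", x$kappa,
              x$kappa_ci[1], x$kappa_ci[2]))
  cat(sprintf("  gamma = %.4g pN s/um [%.4g, %.4g]\n", x$gamma,
              x$gamma_ci[1], x$gamma_ci[2]))
  invisible(x)
}
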