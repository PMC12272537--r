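#' Oscillatory forcing protocol for in-silico microrheology
#'
#' @param F0 force amplitude in pN (default 100)
#' @param freq oscillation frequency in Hz (one of 0.25, 0.5, 1 in the study
#'   conditions, but any positive value is accepted)
#' @param periods number of full periods (default 20)
#' @param r_sph probe radius in um (default 0.625)
#' @param steps_per_period integration/sampling points per period
#'   (default 256, at least 64)
#' @return list of class `oscillation_protocol`
#' @export
oscillation_protocol <- function(F0 = 100, freq = 0.25, periods = 20,
                                 r_sph = 0.625, steps_per_period = 256) {
  if (F0 <= 0 || freq <= 0 || periods <= 0 || r_sph <= 0)
    stop("all protocol parameters must be positive")
  if (steps_per_period < 64) stop("need at least 64 samples per period")
  structure(list(F0 = F0, freq = freq, periods = periods, r_sph = r_sph,
                 steps_per_period = as.integer(steps_per_period)),
            class = "oscillation_protocol")
}

#' Embed a probe bead in a simulated composite
#'
#' Places the bead at a uniformly random empty lattice site (sites within the
#' bead radius are vacated) and couples it mechanically to every filament
#' within the interaction reach: each attachment is a linear spring whose
#' stiffness grows with that filament's engaged crosslink count,
#' `kappa_i = kappa_attach (1 + n_xl_i)`, and attachments dragged beyond
#' `d_yield` slip (detach and re-anchor), providing dissipation. The bead
#' drag is `gamma0 + gamma_attach * n_attachments`.
#'
#' This coupling is the package's mechanical closure for the bead-network
#' interaction; all constants are arguments with defaults documented here
#' and in the methods vignette.
#'
#' @param traj a `composite_trajectory`; the final snapshot defines the
#'   quasi-steady composite the bead probes
#' @param protocol an [oscillation_protocol()]
#' @param kappa_attach spring stiffness per attachment, pN/um (default 1)
#' @param gamma0 background bead drag, pN s/um (default 2)
#' @param gamma_attach added drag per attachment, pN s/um (default 0.05)
#' @param d_yield slip displacement of an attachment, um (default 2)
#' @return object of class `bead_coupling`: spring constants, drag, and bead
#'   site
#' @export
embed_bead <- function(traj, protocol = oscillation_protocol(),
                       kappa_attach = 1, gamma0 = 2, gamma_attach = 0.05,
                       d_yield = 2) {
  snap <- traj$snapshots[[length(traj$snapshots)]]
  geom <- traj$geom
  occ_idx <- as.integer(snap$r) * geom$nq + as.integer(snap$q) + 1L
  empty <- setdiff(seq_len(geom$n_sites), occ_idx)
  if (length(empty) == 0) stop("no vacancy available for the bead")
  site <- empty[sample.int(length(empty), 1L)]
  bx <- geom$x[site]; by <- geom$y[site]
  reach <- traj$params$interaction_range * traj$params$spacing
  # min-image distance of every filament from the bead
  dq <- as.integer(snap$q) - ((site - 1L) %% geom$nq)
  dr <- as.integer(snap$r) - ((site - 1L) %/% geom$nq)
  mi <- hex_min_image(dq, dr, geom)
  near <- which(mi[, "dist"] <= reach + 1e-9 & mi[, "dist"] > 1e-9)
  kappas <- kappa_attach * (1 + snap$n_xl[near])
  # drag from the crosslinked surroundings mirrors the stiffness rule
  structure(list(site = site, x = bx, y = by,
                 attached = near, kappas = kappas,
                 gamma = gamma0 + gamma_attach * sum(1 + snap$n_xl[near]),
                 d_yield = d_yield, protocol = protocol),
            class = "bead_coupling")
}

#' @export
print.bead_coupling <- function(x, ...) {
  cat(sprintf(
    "bead_coupling: %d attachments, total stiffness %.3g pN/um, drag %.3g pN s/um\n",
    length(x$kappas), sum(x$kappas), x$gamma))
  invisible(x)
}

#' Oscillate an embedded bead and record force and displacement
#'
#' Integrates the overdamped 1D dynamics
#' `gamma dx/dt = F0 sin(2 pi f t) - sum_i kappa_i (x - a_i)` with
#' elastoplastic anchors: an anchor stretched beyond `d_yield` slips to the
#' yield surface. The integrator is an exponential step (exact for the linear
#' relaxation with the drive frozen at the substep midpoint), so the error is
#' second order in the step; a stability guard still rejects explicit steps
#' that are too coarse for the total stiffness.
#'
#' @param coupling a [embed_bead()] result, or a bare list with elements
#'   `kappas`, `gamma`, `d_yield` for synthetic couplings
#' @param protocol an [oscillation_protocol()] (default: the one stored in
#'   the coupling)
#' @param substeps integration substeps per recorded sample; `NULL` (default)
#'   chooses the smallest stable value automatically, an explicit value that
#'   is too coarse for the total stiffness raises an error
#' @return data frame of class `rheology_series` with columns `t`, `F`, `x`
#' @export
oscillate_bead <- function(coupling, protocol = coupling$protocol,
                           substeps = NULL) {
  if (is.null(protocol)) stop("no oscillation protocol supplied")
  kap <- coupling$kappas
  gam <- coupling$gamma
  dy <- coupling$d_yield
  if (is.null(dy)) dy <- Inf
  dt <- 1 / (protocol$freq * protocol$steps_per_period)
  if (is.null(substeps))
    substeps <- max(1L, ceiling(sum(kap) * dt / (0.02 * gam)))
  if (sum(kap) * (dt / substeps) / gam > 0.5)
    stop("integration step too large for total stiffness ", sum(kap),
         "; increase steps_per_period or substeps")
  n <- protocol$steps_per_period * protocol$periods
  tt <- (seq_len(n) - 1) * dt
  Fdrive <- protocol$F0 * sin(2 * pi * protocol$freq * tt)
  x <- numeric(n)
  anchors <- rep(0, length(kap))
  h <- dt / substeps
  w <- 2 * pi * protocol$freq
  K <- sum(kap)
  # start on the steady-state orbit of the linearized system so the initial
  # relaxation transient does not contaminate the Fourier extraction
  xi <- if (K > 0) {
    -protocol$F0 / sqrt(K^2 + (w * gam)^2) * sin(atan2(w * gam, K))
  } else {
    -protocol$F0 / (gam * w)
  }
  for (i in seq_len(n)) {
    x[i] <- xi  # position at the sample time, before advancing
    for (s in seq_len(substeps)) {
      ts <- tt[i] + (s - 0.5) * h  # drive frozen at the substep midpoint
      B <- protocol$F0 * sin(w * ts) + sum(kap * anchors)
      if (K > 0) {
        xeq <- B / K
        xi <- xeq + (xi - xeq) * exp(-K * h / gam)
      } else {
        xi <- xi + B * h / gam
      }
      stretch <- xi - anchors
      over <- abs(stretch) > dy
      if (any(over))
        anchors[over] <- xi - sign(stretch[over]) * dy
    }
  }
  out <- data.frame(t = tt, F = Fdrive, x = x)
  attr(out, "protocol") <- protocol
  class(out) <- c("rheology_series", "data.frame")
  out
}

# amplitude and phase of a series at the forcing frequency, by discrete
# Fourier transform (the record length is an integer number of periods, so
# the forcing frequency sits exactly on a DFT bin)
fourier_component <- function(y, dt, freq) {
  n <- length(y)
  k <- round(freq * n * dt)
  if (k < 1 || k >= n / 2)
    stop("forcing frequency not resolvable from the series length")
  Y <- fft(y)[k + 1]
  list(amplitude = 2 * Mod(Y) / n, phase = Arg(Y))
}

#' Extract viscoelastic moduli from an oscillation record
#'
#' The displacement amplitude `x` and the phase lag `phi` between force and
#' displacement are taken from the discrete Fourier component at the forcing
#' frequency (steady-state portion only: the first two periods are discarded
#' as transient). The moduli follow the probe-response convention
#' `G' = (F0 / x) cos(phi) / r_sph` and `G'' = (F0 / x) sin(phi) / r_sph`;
#' the inverse loss tangent is `G'/G''`.
#'
#' @param series a [oscillate_bead()] record (columns `t`, `F`, `x`)
#' @param protocol the [oscillation_protocol()] used (default: stored in the
#'   series)
#' @param discard_periods leading periods dropped as transient (default 2)
#' @return object of class `rheology_result`: amplitude, phase difference,
#'   `G_p` (storage), `G_pp` (loss), `inv_loss_tan`
#' @export
extract_moduli <- function(series, protocol = attr(series, "protocol"),
                           discard_periods = 2) {
  if (is.null(protocol)) stop("no oscillation protocol supplied")
  dt <- series$t[2] - series$t[1]
  spp <- round(1 / (protocol$freq * dt))
  if (nrow(series) - discard_periods * spp < 2 * spp)
    stop("series must cover at least two full periods after the transient")
  keep <- seq.int(discard_periods * spp + 1, nrow(series))
  Fc <- fourier_component(series$F[keep], dt, protocol$freq)
  Xc <- fourier_component(series$x[keep], dt, protocol$freq)
  phi <- Fc$phase - Xc$phase
  phi <- atan2(sin(phi), cos(phi))  # wrap to (-pi, pi]
  phi <- abs(phi)
  amp <- Xc$amplitude
  gp <- protocol$F0 / amp * cos(phi) / protocol$r_sph
  gpp <- protocol$F0 / amp * sin(phi) / protocol$r_sph
  structure(list(amplitude = amp, phi = phi,
                 G_p = gp, G_pp = gpp,
                 inv_loss_tan = gp / gpp,
                 freq = protocol$freq),
            class = "rheology_result")
}

#' @export
print.rheology_result <- function(x, ...) {
  cat(sprintf(
    "rheology at %g Hz: |x| = %.4g um, phi = %.4g rad, G' = %.4g, G'' = %.4g, G'/G'' = %.4g\n",
    x$freq, x$amplitude, x$phi, x$G_p, x$G_pp, x$inv_loss_tan))
  invisible(x)
}

#' Normalized relative elasticity with bootstrap uncertainty
#'
#' Mean inverse loss tangent of a condition divided by the mean for the
#' motor-free reference, with a standard deviation over bootstrap resamples
#' of both ensembles.
#'
#' @param values inverse loss tangents for the condition (over beads and
#'   replicates)
#' @param reference inverse loss tangents for the `c_k = 0` condition
#' @param n_boot number of bootstrap resamples (default 10)
#' @return list with `relative`, `sd`
#' @export
relative_elasticity <- function(values, reference, n_boot = 10) {
  if (length(values) < 2 || length(reference) < 2)
    stop("need at least two results per condition")
  rel <- mean(values) / mean(reference)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(values, replace = TRUE)) /
      mean(sample(reference, replace = TRUE))
  }, numeric(1))
  list(relative = rel, sd = sd(boots))
}
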