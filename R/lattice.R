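#' Parameters of the hexagonal lattice-gas composite model
#'
#' Collects every tunable of the kinetic Monte Carlo simulator in one place.
#' Defaults reproduce the study conditions: a 100 x 100 um box, lattice
#' spacing 1.25 um, 5-um filaments interacting within four grid points, a
#' 45:55 actin:microtubule composite at total occupancy 0.35, and 5 simulated
#' minutes.
#'
#' The motor-activity mapping is: per microtubule pair within reach, a motor
#' cluster engages with probability `min(eng_per_R * R, 1)` where
#' `R = c_k / (4 c_T)` is the experimental motor-to-tubulin ratio; an engaged
#' motor pulls the pair together with probability `pull_prob`, otherwise
#' pushes, with force `motor_force` along the centre-to-centre line, and
#' also acts as a crosslink adding `crosslink_friction` to the filament drag.
#'
#' @param box box dimensions in um, length-2 (default `c(100, 100)`)
#' @param spacing lattice spacing a in um (default 1.25)
#' @param filament_length filament length in um (default 5); bookkeeping only,
#'   used to validate that the interaction reach covers one filament length
#' @param interaction_range interaction reach in grid points (default 4)
#' @param occupancy total site occupancy fraction (default 0.35)
#' @param actin_frac fraction of filaments that are actin (default 0.45,
#'   the 45:55 actin:tubulin molar ratio at equal filament lengths)
#' @param c_k kinesin cluster concentration in nM
#' @param c_tubulin total tubulin molarity in uM for the motor ratio
#' @param motor_force engaged-motor force magnitude in pN (default 5)
#' @param eng_per_R proportionality between motor ratio R and per-pair
#'   engagement probability (default 5)
#' @param pull_prob probability that an engaged motor pulls rather than
#'   pushes (default 0.5)
#' @param crosslink_friction added drag per engaged crosslink, pN s/um
#' @param drag passive filament drag zeta, pN s/um (default 0.1)
#' @param kBT thermal energy, pN um (default 4.11e-3, room temperature)
#' @param duration simulated duration T_S in seconds (default 300)
#' @param snapshot_interval seconds between recorded snapshots (default 30)
#' @param motor_refresh motor engagement turnover interval in seconds
#' @param orient_thresh net-force magnitude above which a filament aligns
#'   with its net force, pN
#' @param orient_jitter rotational diffusion step (radians) applied when the
#'   net force is below `orient_thresh`
#' @param seed optional RNG seed; if set, [run_simulation()] seeds the RNG
#' @return object of class `lattice_params`
#' @export
lattice_params <- function(box = c(100, 100), spacing = 1.25,
                           filament_length = 5, interaction_range = 4,
                           occupancy = 0.35, actin_frac = 0.45,
                           c_k = 0, c_tubulin = 1.65,
                           motor_force = 5, eng_per_R = 5, pull_prob = 0.5,
                           crosslink_friction = 0.5, drag = 0.1,
                           kBT = 4.11e-3, duration = 300,
                           snapshot_interval = 30, motor_refresh = 0.5,
                           orient_thresh = 0.1, orient_jitter = 0.05,
                           seed = NULL) {
  stopifnot(length(box) == 2)
  if (any(box <= 0) || spacing <= 0)
    stop("box dimensions and spacing must be positive")
  if (occupancy < 0 || occupancy > 1 || actin_frac < 0 || actin_frac > 1)
    stop("occupancy and actin_frac must lie in [0, 1]")
  if (duration <= 0) stop("duration must be positive")
  if (c_k < 0) stop("c_k must be non-negative")
  if (interaction_range * spacing < filament_length)
    warning("interaction reach (", interaction_range * spacing,
            " um) does not cover one filament length (", filament_length,
            " um)")
  f_a <- occupancy * actin_frac
  f_m <- occupancy * (1 - actin_frac)
  if (f_a + f_m > 1) stop("f_A + f_M must not exceed 1")
  R <- motor_ratio(c_k, c_tubulin)
  p <- structure(list(
    box = box, spacing = spacing, filament_length = filament_length,
    interaction_range = interaction_range,
    f_A = f_a, f_M = f_m, c_k = c_k, c_tubulin = c_tubulin,
    motor_ratio = R, p_eng = min(eng_per_R * R, 1),
    motor_force = motor_force, pull_prob = pull_prob,
    crosslink_friction = crosslink_friction, drag = drag, kBT = kBT,
    duration = duration, snapshot_interval = snapshot_interval,
    motor_refresh = motor_refresh, orient_thresh = orient_thresh,
    orient_jitter = orient_jitter, seed = seed
  ), class = "lattice_params")
  p
}

#' @export
print.lattice_params <- function(x, ...) {
  cat("Hexagonal lattice-gas parameters\n")
  cat(sprintf("  box %.4g x %.4g um, spacing %.4g um, reach %d grid points\n",
              x$box[1], x$box[2], x$spacing, x$interaction_range))
  cat(sprintf("  f_A = %.4g, f_M = %.4g, c_k = %g nM (R = %.4g, p_eng = %.4g)\n",
              x$f_A, x$f_M, x$c_k, x$motor_ratio, x$p_eng))
  cat(sprintf("  duration %g s, snapshots every %g s\n",
              x$duration, x$snapshot_interval))
  invisible(x)
}

#' Build the periodic hexagonal site graph
#'
#' Constructs a triangular (six-coordinated) lattice on a periodic torus.
#' Axial coordinates `(q, r)` map to positions `x = a (q + r/2)`,
#' `y = a r sqrt(3)/2`; the number of rows is rounded so the realized box is
#' as close as possible to the requested one while tiling exactly.
#'
#' @param params a [lattice_params()] object
#' @return list of class `hex_lattice` with site counts, positions, and the
#'   six nearest-neighbour offsets
#' @export
build_hex_lattice <- function(params) {
  a <- params$spacing
  nq <- max(2L, as.integer(round(params$box[1] / a)))
  nr <- max(2L, as.integer(round(params$box[2] / (a * sqrt(3) / 2))))
  geom <- hex_geometry_cpp(nq, nr, a)
  nn <- geom$nn
  colnames(nn) <- c("dq", "dr", "dist")
  structure(list(
    nq = nq, nr = nr, a = a, n_sites = nq * nr,
    x = geom$x, y = geom$y,
    box_realized = c(nq * a, nr * a * sqrt(3) / 2),
    nn = nn
  ), class = "hex_lattice")
}

#' Minimum-image displacements between lattice sites
#'
#' @param dq,dr integer axial offsets
#' @param geom a `hex_lattice`
#' @return matrix with columns `dx`, `dy`, `dist` (um)
#' @export
hex_min_image <- function(dq, dr, geom) {
  out <- min_image_cpp(as.integer(dq), as.integer(dr), geom$nq, geom$nr,
                       geom$a)
  colnames(out) <- c("dx", "dy", "dist")
  out
}

#' Seed a composite lattice with random filaments
#'
#' Each site is independently a microtubule centre (probability `f_M`), an
#' actin centre (`f_A`), or empty; orientations are uniform on `[0, 2 pi)`.
#'
#' @param params a [lattice_params()] object
#' @param geom optional pre-built [build_hex_lattice()] geometry
#' @return object of class `composite_lattice`
#' @export
seed_composite <- function(params, geom = build_hex_lattice(params)) {
  if (params$f_A + params$f_M > 1) stop("f_A + f_M must not exceed 1")
  n <- geom$n_sites
  kinds <- sample.int(3L, n, replace = TRUE,
                      prob = c(1 - params$f_A - params$f_M,
                               params$f_A, params$f_M)) - 1L
  theta <- runif(n, 0, 2 * pi)
  theta[kinds == 0L] <- 0
  structure(list(params = params, geom = geom, kinds = kinds, theta = theta,
                 time = 0), class = "composite_lattice")
}

#' @export
print.composite_lattice <- function(x, ...) {
  cat(sprintf(
    "composite_lattice: %d x %d sites (a = %g um), %d actin + %d MT, t = %g s\n",
    x$geom$nq, x$geom$nr, x$geom$a, sum(x$kinds == 1L), sum(x$kinds == 2L),
    x$time))
  invisible(x)
}

# interaction-shell offsets (dq, dr, dx, dy, dist) within reach, in um;
# one representative per residue class so small tori are never double-counted
reach_offsets <- function(geom, reach_um) {
  grid <- expand.grid(dq = 0:(geom$nq - 1), dr = 0:(geom$nr - 1))
  grid <- grid[!(grid$dq == 0 & grid$dr == 0), ]
  mi <- hex_min_image(grid$dq, grid$dr, geom)
  keep <- mi[, "dist"] <= reach_um + 1e-9
  cbind(as.matrix(grid[keep, , drop = FALSE]), mi[keep, , drop = FALSE])
}

site_index <- function(q, r, geom) {
  (r %% geom$nr) * geom$nq + (q %% geom$nq) + 1L
}

#' Motor and crosslink interactions of one filament
#'
#' Enumerates all filaments within the interaction reach of filament at site
#' `site` and the pair forces they contribute. Active (motor) forces act only
#' on microtubule-microtubule pairs; actin pairs contribute crosslink-free
#' excluded-volume neighbours with zero force. Forces are antisymmetric: the
#' force this filament receives from a partner is minus the force the partner
#' receives from it.
#'
#' @param lattice a `composite_lattice`
#' @param site 1-based site index of the reference filament
#' @param engagements optional data frame with columns `site_i`, `site_j`,
#'   `sign` (+1 pull, -1 push) fixing which pairs carry an engaged motor; by
#'   default pairs engage independently with probability `p_eng` and pull
#'   with probability `pull_prob`
#' @return data frame with partner site, kind, displacement, and the force
#'   contribution (pN) on the reference filament
#' @export
pairwise_interactions <- function(lattice, site, engagements = NULL) {
  p <- lattice$params
  geom <- lattice$geom
  if (lattice$kinds[site] == 0L) stop("site ", site, " holds no filament")
  offs <- reach_offsets(geom, p$interaction_range * p$spacing)
  q <- (site - 1L) %% geom$nq
  r <- (site - 1L) %/% geom$nq
  targets <- site_index(q + offs[, "dq"], r + offs[, "dr"], geom)
  occ <- lattice$kinds[targets] != 0L
  targets <- targets[occ]
  offs <- offs[occ, , drop = FALSE]
  if (length(targets) == 0L)
    return(data.frame(site = integer(), kind = integer(), dx = numeric(),
                      dy = numeric(), dist = numeric(), fx = numeric(),
                      fy = numeric()))
  fx <- fy <- numeric(length(targets))
  both_mt <- lattice$kinds[site] == 2L & lattice$kinds[targets] == 2L
  for (k in which(both_mt)) {
    sgn <- 0
    if (!is.null(engagements)) {
      hit <- (engagements$site_i == site & engagements$site_j == targets[k]) |
             (engagements$site_j == site & engagements$site_i == targets[k])
      if (any(hit)) sgn <- engagements$sign[which(hit)[1]]
    } else if (runif(1) < p$p_eng) {
      sgn <- if (runif(1) < p$pull_prob) 1 else -1
    }
    if (sgn != 0) {
      u <- offs[k, c("dx", "dy")] / offs[k, "dist"]
      fx[k] <- sgn * p$motor_force * u[1]
      fy[k] <- sgn * p$motor_force * u[2]
    }
  }
  data.frame(site = targets, kind = lattice$kinds[targets],
             dx = offs[, "dx"], dy = offs[, "dy"], dist = offs[, "dist"],
             fx = fx, fy = fy, row.names = NULL)
}

#' Transition rates of every admissible filament hop
#'
#' First-passage drift-diffusion rate for a hop of length `a` toward an empty
#' nearest-neighbour site: `k = D/a^2 + max(F_par, 0) / (zeta a)` with
#' `D = kBT / zeta`, where `F_par` is the component of the filament's net
#' force along the hop and `zeta = drag + crosslink_friction * n_crosslinks`.
#'
#' @param lattice a `composite_lattice`
#' @param forces optional matrix (n_sites x 2) of net forces in pN; zero if
#'   omitted
#' @param crosslinks optional integer vector of engaged crosslink counts per
#'   site; zero if omitted
#' @return data frame of class `move_set` with columns `from`, `to`, `rate`
#' @export
move_probabilities <- function(lattice, forces = NULL, crosslinks = NULL) {
  p <- lattice$params
  geom <- lattice$geom
  occ_sites <- which(lattice$kinds != 0L)
  if (is.null(forces)) forces <- matrix(0, geom$n_sites, 2)
  if (is.null(crosslinks)) crosslinks <- integer(geom$n_sites)
  nn <- geom$nn
  mi <- hex_min_image(nn[, "dq"], nn[, "dr"], geom)
  out <- vector("list", nrow(nn))
  q <- (occ_sites - 1L) %% geom$nq
  r <- (occ_sites - 1L) %/% geom$nq
  for (d in seq_len(nrow(nn))) {
    to <- site_index(q + nn[d, "dq"], r + nn[d, "dr"], geom)
    free <- lattice$kinds[to] == 0L
    zeta <- p$drag + p$crosslink_friction * crosslinks[occ_sites]
    D <- p$kBT / zeta
    u <- mi[d, c("dx", "dy")] / mi[d, "dist"]
    fpar <- forces[occ_sites, 1] * u[1] + forces[occ_sites, 2] * u[2]
    rate <- (D / geom$a^2 + pmax(fpar, 0) / (zeta * geom$a)) * free
    out[[d]] <- data.frame(from = occ_sites, to = to, rate = rate)
  }
  ms <- do.call(rbind, out)
  ms <- ms[ms$rate > 0, ]
  class(ms) <- c("move_set", "data.frame")
  ms
}

#' Execute one Gillespie event
#'
#' Picks a hop with probability proportional to its rate, executes it, and
#' advances the simulated clock by an exponential waiting time with mean
#' `1 / sum(rates)`. If no move is admissible (fully jammed) the clock is
#' advanced by the motor refresh interval with a warning and no move.
#'
#' @param lattice a `composite_lattice`
#' @param moveset optional precomputed [move_probabilities()] result
#' @param forces,crosslinks forwarded to [move_probabilities()]
#' @return updated `composite_lattice`
#' @export
step_lattice <- function(lattice, moveset = NULL, forces = NULL,
                         crosslinks = NULL) {
  if (is.null(moveset))
    moveset <- move_probabilities(lattice, forces, crosslinks)
  tot <- sum(moveset$rate)
  if (nrow(moveset) == 0L || tot <= 0) {
    warning("lattice jammed: no admissible move; clock advanced")
    lattice$time <- lattice$time + lattice$params$motor_refresh
    return(lattice)
  }
  lattice$time <- lattice$time + stats::rexp(1, tot)
  i <- sample.int(nrow(moveset), 1L, prob = moveset$rate)
  from <- moveset$from[i]; to <- moveset$to[i]
  lattice$kinds[to] <- lattice$kinds[from]
  lattice$kinds[from] <- 0L
  lattice$theta[to] <- lattice$theta[from]
  lattice$theta[from] <- 0
  lattice
}

#' Run the kinetic Monte Carlo simulation
#'
#' Seeds a composite, then evolves it with the compiled Gillespie engine:
#' motor engagements are resampled every `motor_refresh` seconds and updated
#' locally after every hop; snapshots (positions, kinds, orientations, net
#' forces, crosslink counts) are recorded every `snapshot_interval` seconds
#' including t = 0 and t = duration.
#'
#' @param params a [lattice_params()] object
#' @param lattice optional pre-seeded `composite_lattice` (otherwise seeded
#'   from `params`)
#' @return object of class `composite_trajectory`: list of snapshot data
#'   frames plus event counters
#' @export
run_simulation <- function(params, lattice = NULL) {
  if (!inherits(params, "lattice_params")) stop("params must be lattice_params")
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(lattice)) lattice <- seed_composite(params)
  geom <- lattice$geom
  snap_times <- unique(c(seq(0, params$duration, by = params$snapshot_interval),
                         params$duration))
  res <- kmc_run_cpp(
    kinds0 = lattice$kinds, theta0 = lattice$theta,
    nq = geom$nq, nr = geom$nr, a = geom$a,
    reach_um = params$interaction_range * params$spacing,
    kBT = params$kBT, zeta0 = params$drag,
    zeta_xl = params$crosslink_friction, F_m = params$motor_force,
    p_eng = params$p_eng, p_pull = params$pull_prob,
    tau_m = params$motor_refresh, snap_times = snap_times,
    T_s = params$duration, orient_thresh = params$orient_thresh,
    orient_jitter = params$orient_jitter)
  if (res$n_jammed > 0)
    warning("simulation encountered ", res$n_jammed, " jammed intervals")
  snaps <- lapply(res$snapshots, function(s) {
    df <- as.data.frame(s$filaments)
    df$time <- rep(s$time, nrow(df))
    df
  })
  structure(list(params = params, geom = geom,
                 times = snap_times, snapshots = snaps,
                 n_events = res$n_events, n_jammed = res$n_jammed,
                 n_filaments = res$n_filaments),
            class = "composite_trajectory")
}

#' @export
print.composite_trajectory <- function(x, ...) {
  cat(sprintf(
    "composite_trajectory: %d filaments, %d snapshots over %g s, %g events (c_k = %g nM)\n",
    x$n_filaments, length(x$snapshots), max(x$times), x$n_events,
    x$params$c_k))
  invisible(x)
}

#' Rebuild a `composite_lattice` from a trajectory snapshot
#'
#' @param traj a `composite_trajectory`
#' @param i snapshot index (default: final snapshot)
#' @return a `composite_lattice` whose kinds/orientations are taken from the
#'   snapshot
#' @export
snapshot_lattice <- function(traj, i = length(traj$snapshots)) {
  snap <- traj$snapshots[[i]]
  geom <- traj$geom
  kinds <- integer(geom$n_sites)
  theta <- numeric(geom$n_sites)
  idx <- as.integer(snap$r) * geom$nq + as.integer(snap$q) + 1L
  kinds[idx] <- as.integer(snap$kind)
  theta[idx] <- snap$theta
  structure(list(params = traj$params, geom = geom, kinds = kinds,
                 theta = theta, time = snap$time[1]),
            class = "composite_lattice")
}

#' Write trajectory snapshots to delimited text
#'
#' One CSV per snapshot, named `snap_t<seconds>.csv`, with columns
#' `site_x_um`, `site_y_um`, `kind`, `theta_rad`, `fx_pN`, `fy_pN`, `n_xl`,
#' plus a JSON metadata file with the run parameters and event counts.
#'
#' @param traj a `composite_trajectory`
#' @param dir output directory (created if needed)
#' @return the directory path, invisibly
#' @export
write_snapshots <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in traj$snapshots) {
    out <- data.frame(site_x_um = s$x, site_y_um = s$y,
                      kind = c("actin", "microtubule")[s$kind],
                      theta_rad = s$theta, fx_pN = s$fx, fy_pN = s$fy,
                      n_xl = s$n_xl)
    write.csv(out, file.path(dir, sprintf("snap_t%g.csv", s$time[1])),
              row.names = FALSE)
  }
  meta <- traj$params
  meta$n_events <- traj$n_events
  meta$n_filaments <- traj$n_filaments
  yaml::write_yaml(meta[!vapply(meta, is.null, logical(1))],
                   file.path(dir, "run.yaml"))
  invisible(dir)
}

#' Read lattice parameters from a YAML config file
#'
#' Every field of [lattice_params()] may appear as a top-level key; unknown
#' keys raise an error naming the key.
#'
#' @param path path to a YAML file
#' @return a `lattice_params` object
#' @export
read_lattice_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(lattice_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(lattice_params, cfg)
}
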