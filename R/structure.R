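#' Pair distribution function on the hexagonal lattice
#'
#' `g_ij(r) = N_i(r) / (f_i N(r))`, averaged over all reference filaments of
#' kind `j`: `N_i(r)` is the number of kind-`i` filaments at lattice distance
#' `r` from a reference filament, `N(r)` the maximum possible number of
#' neighbours at that distance (counted exactly from the lattice geometry),
#' and `f_i` the volume fraction of kind `i` (self-excluded for like pairs so
#' that an ideal random configuration gives `g = 1` exactly in expectation).
#' Distances are binned on a uniform grid of width one lattice spacing
#' centred at multiples of the spacing; the first bin is r0 = 1.25 um at the
#' default spacing.
#'
#' @param lattice a `composite_lattice`
#' @param i_kind counted filament kind, `"A"` or `"M"`
#' @param j_kind reference filament kind, `"A"` or `"M"`
#' @param r_max largest distance analysed, um (default 25)
#' @return object of class `pair_correlation`: data frame with columns `r`
#'   (um) and `g`
#' @export
pair_distribution <- function(lattice, i_kind = "M", j_kind = i_kind,
                              r_max = 25) {
  i_code <- match(match.arg(i_kind, c("A", "M")), c("A", "M"))
  j_code <- match(match.arg(j_kind, c("A", "M")), c("A", "M"))
  geom <- lattice$geom
  pc <- count_pairs_cpp(lattice$kinds, geom$nq, geom$nr, geom$a, r_max,
                        geom$a)
  n_ref <- if (j_code == 1) pc$n_actin else pc$n_mt
  if (n_ref == 0) stop("no filaments of reference kind ", j_kind)
  n_i <- if (i_code == 1) pc$n_actin else pc$n_mt
  f_i <- (n_i - (i_code == j_code)) / (pc$n_sites - 1)
  if (f_i <= 0) stop("no filaments of counted kind ", i_kind)
  nbins <- length(pc$nmax)
  counts <- pc$counts[, j_code, i_code]
  g <- counts / (n_ref * f_i * pc$nmax)
  out <- data.frame(r = seq_len(nbins) * geom$a, g = g)
  out <- out[pc$nmax > 0, ]  # bins with no sites at that distance
  rownames(out) <- NULL
  attr(out, "i_kind") <- i_kind
  attr(out, "j_kind") <- j_kind
  attr(out, "time") <- lattice$time
  class(out) <- c("pair_correlation", "data.frame")
  out
}

#' Difference of two pair correlation curves
#'
#' `Delta g(r) = g_now(r) - g_ref(r)` element-wise; the two curves must share
#' identical r bins.
#'
#' @param g_now,g_ref `pair_correlation` objects (or any data frames with
#'   columns `r` and `g`)
#' @return object of class `delta_g`: data frame with columns `r`, `dg`
#' @export
delta_g <- function(g_now, g_ref) {
  if (nrow(g_now) != nrow(g_ref) ||
      any(abs(g_now$r - g_ref$r) > 1e-9))
    stop("r bins of the two curves do not match")
  out <- data.frame(r = g_now$r, dg = g_now$g - g_ref$g)
  attr(out, "i_kind") <- attr(g_now, "i_kind")
  attr(out, "j_kind") <- attr(g_now, "j_kind")
  class(out) <- c("delta_g", "data.frame")
  out
}

#' Delta g of a simulated trajectory against its initial state
#'
#' Averages `g_ij(r)` over the final 10 percent of recorded snapshots (at
#' least one) and subtracts `g_ij(r)` of the t = 0 snapshot.
#'
#' @param traj a `composite_trajectory`
#' @param i_kind,j_kind filament kinds as in [pair_distribution()]
#' @param r_max largest distance analysed, um
#' @param final_frac fraction of the trajectory tail averaged (default 0.1)
#' @return a `delta_g` object; the averaged final and initial curves are
#'   attached as attributes `g_final` and `g_initial`
#' @export
trajectory_delta_g <- function(traj, i_kind = "M", j_kind = i_kind,
                               r_max = 25, final_frac = 0.1) {
  times <- vapply(traj$snapshots, function(s) s$time[1], numeric(1))
  t_cut <- max(times) - final_frac * (max(times) - min(times))
  idx <- which(times >= t_cut - 1e-9)
  if (length(idx) == 0) idx <- length(traj$snapshots)
  gs <- lapply(idx, function(i)
    pair_distribution(snapshot_lattice(traj, i), i_kind, j_kind, r_max))
  g_fin <- gs[[1]]
  if (length(gs) > 1)
    g_fin$g <- rowMeans(vapply(gs, function(g) g$g, numeric(nrow(g_fin))))
  g0 <- pair_distribution(snapshot_lattice(traj, 1L), i_kind, j_kind, r_max)
  out <- delta_g(g_fin, g0)
  attr(out, "g_final") <- g_fin
  attr(out, "g_initial") <- g0
  out
}

#' Correlation lengths of a Delta g curve
#'
#' `l0` is the first linearly interpolated zero crossing beyond the first
#' bin; the second length is the location of the first local extremum beyond
#' `l0`, detected as the first strict sign change of the discrete derivative
#' (ties broken toward smaller r). For like-filament curves the extremum is a
#' minimum (`lmin`), for unlike-filament curves a maximum (`lmax`).
#'
#' @param dg a `delta_g` object (or data frame with columns `r` and either
#'   `dg` or `g`)
#' @return list with `l0`, `l_ext` (um; `NA` when undefined) and `ext_type`
#' @export
correlation_lengths <- function(dg) {
  r <- dg$r
  v <- if (!is.null(dg$dg)) dg$dg else dg$g
  n <- length(v)
  out <- list(l0 = NA_real_, l_ext = NA_real_, ext_type = NA_character_)
  if (all(abs(v) < 1e-12)) return(out)
  s <- sign(v)
  cross <- which(s[-n] * s[-1] < 0 | (s[-n] != 0 & s[-1] == 0))
  if (length(cross) == 0) return(out)
  k <- cross[1]
  # linear interpolation between bins k and k+1
  out$l0 <- r[k] + (r[k + 1] - r[k]) * v[k] / (v[k] - v[k + 1])
  beyond <- which(r > out$l0)
  if (length(beyond) >= 3) {
    vv <- v[beyond]
    d <- diff(vv)
    turn <- which(d[-length(d)] * d[-1] <= 0 & d[-length(d)] != 0)
    if (length(turn) > 0) {
      idx <- beyond[turn[1] + 1]
      out$l_ext <- r[idx]
      out$ext_type <- if (v[idx] < 0) "min" else "max"
    }
  }
  out
}

# hexagonal tiling of the (rectangularised) periodic box: tile centres on a
# staggered grid with spacing ~ `tile`; returns tile id per point
hex_tile_assign <- function(x, y, box, tile) {
  ncx <- max(1L, round(box[1] / tile))
  ncy <- max(1L, round(box[2] / (tile * sqrt(3) / 2)))
  sx <- box[1] / ncx
  sy <- box[2] / ncy
  centers <- do.call(rbind, lapply(0:(ncy - 1), function(j) {
    cbind(cx = (0:(ncx - 1) + 0.5 + 0.5 * (j %% 2)) * sx, cy = (j + 0.5) * sy)
  }))
  xw <- x %% box[1]
  yw <- y %% box[2]
  id <- integer(length(xw))
  for (i in seq_along(xw)) {
    dx <- abs(xw[i] - centers[, "cx"])
    dx <- pmin(dx, box[1] - dx)
    dy <- abs(yw[i] - centers[, "cy"])
    dy <- pmin(dy, box[2] - dy)
    id[i] <- which.min(dx^2 + dy^2)
  }
  id
}

#' Force heterogeneity of a simulated composite
#'
#' Tiles the box into ~20-um hexagonal tiles and computes, per tile, the
#' coefficient of variation of filament force magnitudes
#' `delta_f = sigma_f / <f>`, then the local heterogeneity `h_f =
#' mean(delta_f)`, global heterogeneity `H_f = sd(delta_f)`, and patchiness
#' `p_f = H_f / h_f`. Tiles holding fewer than two filaments are excluded
#' (the standard deviation is undefined there).
#'
#' @param traj a `composite_trajectory` (final snapshot is analysed) or a
#'   single snapshot data frame with columns `x`, `y`, `fx`, `fy`
#' @param tile tile size in um (default 20)
#' @return object of class `force_heterogeneity`: list with per-tile
#'   `delta_f` and summary `h_f`, `H_f`, `p_f`
#' @export
force_heterogeneity <- function(traj, tile = 20) {
  if (inherits(traj, "composite_trajectory")) {
    snap <- traj$snapshots[[length(traj$snapshots)]]
    box <- traj$geom$box_realized
  } else {
    snap <- traj
    box <- attr(traj, "box")
    if (is.null(box)) box <- c(max(snap$x), max(snap$y))
  }
  f <- sqrt(snap$fx^2 + snap$fy^2)
  if (all(f == 0))
    stop("force heterogeneity undefined: all filament forces are zero ",
         "(no motor activity, c_k = 0)")
  id <- hex_tile_assign(snap$x, snap$y, box, tile)
  delta <- vapply(split(f, id), function(ff) {
    if (length(ff) < 2 || mean(ff) == 0) return(NA_real_)
    sd(ff) / mean(ff)
  }, numeric(1))
  delta <- delta[!is.na(delta)]
  if (length(delta) < 2) stop("fewer than two usable tiles")
  h <- mean(delta)
  H <- sd(delta)
  structure(list(delta_f = delta, h_f = h, H_f = H,
                 p_f = if (h > 0) H / h else NA_real_, tile = tile),
            class = "force_heterogeneity")
}

#' @export
print.force_heterogeneity <- function(x, ...) {
  cat(sprintf(
    "force heterogeneity (%g um tiles, %d tiles): h_f = %.4g, H_f = %.4g, p_f = %.4g\n",
    x$tile, length(x$delta_f), x$h_f, x$H_f, x$p_f))
  invisible(x)
}
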