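# Shared simulation fixtures: full-size runs are expensive, so replicate
# trajectories are computed once per session and reused across test files.
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(ck, rep = 1) {
  key <- sprintf("ck%s_rep%d", ck, rep)
  if (is.null(.sim_cache[[key]])) {
    set.seed(20000L + 97L * rep + as.integer(ck))
    .sim_cache[[key]] <- run_simulation(lattice_params(c_k = ck))
  }
  .sim_cache[[key]]
}

# Small composite lattice with filaments placed by hand at given (q, r)
# axial coordinates; kinds: 1 = actin, 2 = microtubule.
hand_lattice <- function(placements, params = lattice_params(box = c(25, 25))) {
  geom <- build_hex_lattice(params)
  kinds <- integer(geom$n_sites)
  for (i in seq_len(nrow(placements))) {
    s <- (placements$r[i] %% geom$nr) * geom$nq +
      (placements$q[i] %% geom$nq) + 1L
    kinds[s] <- placements$kind[i]
  }
  structure(list(params = params, geom = geom, kinds = kinds,
                 theta = numeric(geom$n_sites), time = 0),
            class = "composite_lattice")
}

# Brute-force periodic spatial autocorrelation (O(n^2) in pixels): direct
# shift-and-multiply sums, no FFT, same normalization and radial binning
# conventions as sia().
sia_direct_oracle <- function(frame, pixel_size, r_max = NULL) {
  d <- frame - mean(frame)
  nx <- nrow(frame); ny <- ncol(frame)
  ac <- matrix(0, nx, ny)
  for (i in 0:(nx - 1)) {
    for (j in 0:(ny - 1)) {
      shifted <- d[((0:(nx - 1) + i) %% nx) + 1, ((0:(ny - 1) + j) %% ny) + 1]
      ac[i + 1, j + 1] <- mean(d * shifted)
    }
  }
  ac <- ac / mean(frame)^2
  if (is.null(r_max)) r_max <- min(nx, ny) / 2 * pixel_size
  sx <- pmin(0:(nx - 1), nx - 0:(nx - 1))
  sy <- pmin(0:(ny - 1), ny - 0:(ny - 1))
  rpx <- sqrt(outer(sx^2, sy^2, `+`))
  bin <- round(rpx)
  keep <- bin >= 1 & bin <= floor(r_max / pixel_size)
  data.frame(r = sort(unique(bin[keep])) * pixel_size,
             g = as.numeric(tapply(ac[keep], bin[keep], mean)))
}

site_of <- function(lattice, q, r) {
  (r %% lattice$geom$nr) * lattice$geom$nq + (q %% lattice$geom$nq) + 1L
}

# Exhaustive O(n^2) pair-count oracle for g_ij(r), independent of the binned
# lattice-shift implementation: enumerates all filament pairs by minimum-image
# distance and normalizes by a brute-force per-bin site count.
brute_pair_g <- function(lattice, i_kind, j_kind, r_max = 25) {
  geom <- lattice$geom
  a <- geom$a
  codes <- c(A = 1L, M = 2L)
  sites <- which(lattice$kinds != 0L)
  kinds <- lattice$kinds[sites]
  q <- (sites - 1L) %% geom$nq
  r <- (sites - 1L) %/% geom$nq
  nbins <- round(r_max / a)
  # per-bin maximum neighbour count from one reference site (lattice is
  # translation invariant)
  dq_all <- ((0:(geom$n_sites - 1)) %% geom$nq)
  dr_all <- ((0:(geom$n_sites - 1)) %/% geom$nq)
  d_all <- hex_min_image(dq_all, dr_all, geom)[, "dist"]
  bins_all <- round(d_all / a)
  nmax <- vapply(1:nbins, function(k) sum(bins_all == k), numeric(1))
  refs <- which(kinds == codes[j_kind])
  counts <- numeric(nbins)
  for (ii in refs) {
    d <- hex_min_image(q - q[ii], r - r[ii], geom)[, "dist"]
    b <- round(d / a)
    sel <- kinds == codes[i_kind] & b >= 1 & b <= nbins
    counts <- counts + vapply(1:nbins, function(k) sum(b[sel] == k),
                              numeric(1))
  }
  n_i <- sum(kinds == codes[i_kind])
  f_i <- (n_i - (i_kind == j_kind)) / (geom$n_sites - 1)
  data.frame(r = (1:nbins) * a,
             g = counts / (length(refs) * f_i * nmax))
}
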