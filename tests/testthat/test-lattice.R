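test_that("hexagonal lattice is six-coordinated with correct site count", {
  p <- lattice_params()
  geom <- build_hex_lattice(p)
  # every site has exactly 6 nearest neighbours at one lattice spacing
  expect_equal(nrow(geom$nn), 6)
  expect_equal(unname(geom$nn[, "dist"]), rep(1.25, 6), tolerance = 1e-12)
  # site count from explicit row/column construction of the layout
  nq_expected <- round(100 / 1.25)
  nr_expected <- round(100 / (1.25 * sqrt(3) / 2))
  expect_equal(geom$n_sites, nq_expected * nr_expected)
  expect_equal(length(geom$x), geom$n_sites)
  # rejected degenerate geometry
  expect_error(lattice_params(spacing = -1), "positive")
  expect_error(lattice_params(box = c(0, 100)), "positive")
})

test_that("minimum-image distances are bounded by the half-diagonal", {
  geom <- build_hex_lattice(lattice_params())
  set.seed(3)
  dq <- sample(0:(geom$nq - 1), 300, replace = TRUE)
  dr <- sample(0:(geom$nr - 1), 300, replace = TRUE)
  d <- hex_min_image(dq, dr, geom)[, "dist"]
  half_diag <- sqrt(sum((geom$box_realized / 2)^2))
  expect_true(all(d <= half_diag + 1e-9))
})

test_that("random seeding respects occupancy fractions and determinism", {
  p <- lattice_params()
  expect_error(lattice_params(occupancy = 1.5), "\\[0, 1\\]")
  # zero occupancy: empty lattice
  set.seed(1)
  empty <- seed_composite(lattice_params(occupancy = 0))
  expect_true(all(empty$kinds == 0L))
  # same seed twice: identical lattice
  set.seed(11); l1 <- seed_composite(p)
  set.seed(11); l2 <- seed_composite(p)
  expect_identical(l1$kinds, l2$kinds)
  expect_identical(l1$theta, l2$theta)
  # realized 45:55 actin:MT split within the binomial 99% interval
  set.seed(5)
  l <- seed_composite(p)
  n_a <- sum(l$kinds == 1L); n_m <- sum(l$kinds == 2L)
  ci <- qbinom(c(0.005, 0.995), n_a + n_m, 0.45)
  expect_gte(n_a, ci[1])
  expect_lte(n_a, ci[2])
  # orientations uniform on [0, 2pi)
  th <- l$theta[l$kinds != 0L]
  expect_true(all(th >= 0 & th < 2 * pi))
})

test_that("pair interactions respect reach, kind rules, and action-reaction", {
  # isolated filament: nothing within four grid points
  lat <- hand_lattice(data.frame(q = 5, r = 5, kind = 2))
  expect_equal(nrow(pairwise_interactions(lat, site_of(lat, 5, 5))), 0)
  # two microtubules 2 sites (2.5 um) apart with a forced pulling motor
  lat2 <- hand_lattice(data.frame(q = c(5, 7), r = c(5, 5), kind = c(2, 2)))
  s1 <- site_of(lat2, 5, 5); s2 <- site_of(lat2, 7, 5)
  engage <- data.frame(site_i = s1, site_j = s2, sign = 1)
  i1 <- pairwise_interactions(lat2, s1, engage)
  i2 <- pairwise_interactions(lat2, s2, engage)
  expect_equal(i1$dist, 2.5)
  # force on each is toward the other, equal and opposite
  expect_equal(i1$fx, -i2$fx)
  expect_equal(i1$fy, -i2$fy)
  expect_gt(i1$fx, 0)  # filament 1 pulled in +x toward filament 2
  expect_equal(i1$fy, 0, tolerance = 1e-12)
  # actin-actin pairs carry no motor force at any engagement state
  lat3 <- hand_lattice(data.frame(q = c(5, 7), r = c(5, 5), kind = c(1, 1)),
                       lattice_params(box = c(25, 25), c_k = 640))
  i3 <- pairwise_interactions(lat3, site_of(lat3, 5, 5), engage)
  expect_equal(nrow(i3), 1)
  expect_equal(i3$fx, 0)
  expect_equal(i3$fy, 0)
})

test_that("hop rates follow the drift-diffusion first-passage form", {
  p <- lattice_params(box = c(25, 25))
  lat <- hand_lattice(data.frame(q = c(4, 6, 5), r = c(4, 4, 7),
                                 kind = c(2, 2, 1)), p)
  # no forces: all hops of every filament share the purely diffusive rate
  ms0 <- move_probabilities(lat)
  expect_equal(nrow(ms0), 18)  # 3 filaments x 6 free neighbours
  expect_equal(unique(signif(ms0$rate, 12)),
               signif(p$kBT / p$drag / p$spacing^2, 12))
  # force exactly along one neighbour direction makes that hop fastest
  forces <- matrix(0, lat$geom$n_sites, 2)
  s <- site_of(lat, 4, 4)
  forces[s, ] <- c(3, 0)  # +x is a lattice direction
  ms <- move_probabilities(lat, forces)
  mine <- ms[ms$from == s, ]
  best <- mine$to[which.max(mine$rate)]
  expect_equal(best, site_of(lat, 5, 4))
  # rates match an independent scalar evaluation of the rate formula
  xl <- integer(lat$geom$n_sites); xl[s] <- 2L
  ms2 <- move_probabilities(lat, forces, xl)
  zeta <- p$drag + p$crosslink_friction * 2
  expected_max <- p$kBT / zeta / p$spacing^2 + 3 / (zeta * p$spacing)
  expect_equal(max(ms2$rate[ms2$from == s]), expected_max, tolerance = 1e-12)
  expect_true(all(ms2$rate >= 0))
})

test_that("single events conserve filaments and respect occupancy", {
  p <- lattice_params(box = c(25, 25))
  set.seed(2)
  lat <- seed_composite(p)
  counts0 <- table(factor(lat$kinds, levels = 0:2))
  set.seed(9); lat1 <- step_lattice(lat)
  set.seed(9); lat2 <- step_lattice(lat)
  expect_identical(lat1$kinds, lat2$kinds)   # reproducible under seed
  expect_gt(lat1$time, 0)
  expect_equal(table(factor(lat1$kinds, levels = 0:2)), counts0)
  # fully occupied lattice is jammed: warning, clock advance, no move
  full <- lat; full$kinds[] <- 1L
  expect_warning(fj <- step_lattice(full), "jammed")
  expect_identical(fj$kinds, full$kinds)
  expect_gt(fj$time, full$time)
})

test_that("trajectories conserve filament counts, occupancy, and reproduce under a seed", {
  p <- lattice_params(box = c(50, 50), duration = 30, snapshot_interval = 10,
                      c_k = 320, seed = 77)
  tr <- run_simulation(p)
  counts <- lapply(tr$snapshots, function(s) table(factor(s$kind, levels = 1:2)))
  expect_true(all(vapply(counts, identical, logical(1), counts[[1]])))
  # single occupancy after every recorded event
  for (s in tr$snapshots)
    expect_equal(anyDuplicated(cbind(s$q, s$r)), 0)
  # action-reaction: pair forces cancel over the whole system
  fin <- tr$snapshots[[length(tr$snapshots)]]
  expect_equal(sum(fin$fx), 0, tolerance = 1e-8)
  expect_equal(sum(fin$fy), 0, tolerance = 1e-8)
  # bitwise reproducibility under the stored seed
  tr2 <- run_simulation(p)
  expect_identical(tr$snapshots, tr2$snapshots)
  expect_identical(tr$n_events, tr2$n_events)
})

test_that("an isolated filament diffuses isotropically", {
  p <- lattice_params(box = c(25, 25), duration = 2000,
                      snapshot_interval = 2000)
  geom <- build_hex_lattice(p)
  kinds <- integer(geom$n_sites)
  start_q <- 10L; start_r <- 10L
  set.seed(101)
  disp <- t(vapply(1:60, function(i) {
    lat <- structure(list(params = p, geom = geom, kinds = kinds,
                          theta = numeric(geom$n_sites), time = 0),
                     class = "composite_lattice")
    lat$kinds[start_r * geom$nq + start_q + 1L] <- 2L
    tr <- run_simulation(p, lattice = lat)
    fin <- tr$snapshots[[length(tr$snapshots)]]
    dqr <- hex_min_image(as.integer(fin$q) - start_q,
                         as.integer(fin$r) - start_r, geom)
    c(dqr[1, "dx"], dqr[1, "dy"])
  }, numeric(2)))
  # zero-mean displacement in both components (3 sigma of the sample mean)
  for (j in 1:2) {
    se <- sd(disp[, j]) / sqrt(nrow(disp))
    expect_lt(abs(mean(disp[, j])), 3 * se + 1e-12)
  }
})

test_that("a persistently pulling microtubule pair approaches on average", {
  # pull_prob = 1 and saturated engagement: every motor event pulls
  p <- lattice_params(box = c(25, 25), duration = 10, snapshot_interval = 10,
                      c_k = 640, eng_per_R = 1e4, pull_prob = 1)
  expect_equal(p$p_eng, 1)
  geom <- build_hex_lattice(p)
  set.seed(303)
  dist_change <- vapply(1:100, function(i) {
    kinds <- integer(geom$n_sites)
    q0 <- c(8L, 11L); r0 <- c(8L, 8L)  # 3 sites = 3.75 um apart
    kinds[r0 * geom$nq + q0 + 1L] <- 2L
    lat <- structure(list(params = p, geom = geom, kinds = kinds,
                          theta = numeric(geom$n_sites), time = 0),
                     class = "composite_lattice")
    tr <- run_simulation(p, lattice = lat)
    fin <- tr$snapshots[[length(tr$snapshots)]]
    d <- hex_min_image(as.integer(fin$q[1]) - as.integer(fin$q[2]),
                       as.integer(fin$r[1]) - as.integer(fin$r[2]),
                       geom)[1, "dist"]
    d - 3.75
  }, numeric(1))
  expect_lt(mean(dist_change), 0)
})

test_that("snapshots export to per-time CSV files with a run manifest", {
  p <- lattice_params(box = c(25, 25), duration = 20, snapshot_interval = 10,
                      seed = 41)
  tr <- run_simulation(p)
  dir <- tempfile("snaps")
  write_snapshots(tr, dir)
  files <- list.files(dir)
  expect_setequal(files, c("snap_t0.csv", "snap_t10.csv", "snap_t20.csv",
                           "run.yaml"))
  back <- read.csv(file.path(dir, "snap_t20.csv"))
  expect_equal(nrow(back), tr$n_filaments)
  expect_true(all(back$kind %in% c("actin", "microtubule")))
  expect_equal(yaml::read_yaml(file.path(dir, "run.yaml"))$seed, 41)
})

test_that("YAML config round-trips lattice parameters and flags unknown keys", {
  cfg <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(c_k = 160, occupancy = 0.2, duration = 60), cfg)
  p <- read_lattice_config(cfg)
  expect_equal(p$c_k, 160)
  expect_equal(p$f_A + p$f_M, 0.2)
  expect_equal(p$duration, 60)
  yaml::write_yaml(list(c_k = 160, bogus_knob = 1), cfg)
  expect_error(read_lattice_config(cfg), "bogus_knob")
})
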