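test_that("SIA matches brute-force autocorrelation to machine precision", {
  set.seed(41)
  for (dims in list(c(32, 32), c(24, 40))) {
    frame <- matrix(rexp(prod(dims), 1 / 50), dims[1], dims[2])
    fftv <- sia(frame, pixel_size = 0.41)
    direct <- sia_direct_oracle(frame, pixel_size = 0.41)
    expect_equal(fftv$r, direct$r)
    expect_equal(fftv$g, direct$g, tolerance = 1e-10)
  }
  # Gaussian-blob frame, as in the generator
  st <- gen_image_stack(frame_px = 64, n_blobs = 6, blob_radius = 5 * 0.41,
                        seed = 52)
  fr <- st$frames[[1]]
  expect_equal(sia(fr, 0.41)$g, sia_direct_oracle(fr, 0.41)$g,
               tolerance = 1e-10)
})

test_that("SIA handles degenerate frames and responds to clustering", {
  expect_warning(g0 <- sia(matrix(7, 32, 32), 0.41), "constant")
  expect_true(all(g0$g == 0))
  # clustered blobs versus well-mixed noise: larger g_I at small r
  clustered <- gen_image_stack(frame_px = 96, n_blobs = 8, blob_radius = 3,
                               blob_intensity = 200, background = 20,
                               seed = 61)
  mixed <- gen_image_stack(frame_px = 96, n_blobs = 0, background = 100,
                           noise = "poisson", seed = 62)
  g_c <- sia(clustered$frames[[1]], 0.41)
  g_m <- sia(mixed$frames[[1]], 0.41)
  expect_gt(g_c$g[2], g_m$g[2])
})

test_that("SIA is gain invariant and offset rescales by the squared mean ratio", {
  set.seed(43)
  frame <- matrix(rpois(48 * 48, 60), 48, 48)
  g <- sia(frame, 0.41)
  g_gain <- sia(3.7 * frame, 0.41)
  expect_equal(g_gain$g, g$g, tolerance = 1e-12)
  offset <- 25
  g_off <- sia(frame + offset, 0.41)
  ratio <- (mean(frame) / (mean(frame) + offset))^2
  expect_equal(g_off$g, g$g * ratio, tolerance = 1e-12)
})

test_that("stack differencing is zero against itself and flags bin mismatch", {
  st <- gen_image_stack(frame_px = 64, n_frames = 3, n_blobs = 5,
                        blob_radius = 2, noise = "gaussian", noise_sd = 2,
                        seed = 44)
  d_self <- delta_g_image(st, st)
  expect_true(all(d_self$dg == 0))
  expect_true(all(d_self$sem >= 0))
  st2 <- gen_image_stack(frame_px = 64, pixel_size = 0.2, seed = 45)
  expect_error(delta_g_image(st, st2), "pixel size")
  # denser (brighter) clusters raise the contact value of Delta g_I
  ref <- gen_image_stack(frame_px = 96, n_frames = 2, n_blobs = 0,
                         background = 60, noise = "poisson", seed = 46)
  lo <- gen_image_stack(frame_px = 96, n_frames = 2, n_blobs = 8,
                        blob_radius = 2.5, blob_intensity = 60,
                        background = 60, noise = "poisson", seed = 47)
  hi <- gen_image_stack(frame_px = 96, n_frames = 2, n_blobs = 8,
                        blob_radius = 2.5, blob_intensity = 240,
                        background = 60, noise = "poisson", seed = 48)
  d_lo <- delta_g_image(lo, ref)
  d_hi <- delta_g_image(hi, ref)
  expect_gt(d_hi$dg[1], d_lo$dg[1])
  expect_gt(d_lo$dg[1], 0)
})

test_that("SIA correlation lengths track the generator ground truth", {
  # damped cosine with zero at 30 um
  r <- seq(0.41, 160, by = 0.41)
  curve <- data.frame(r = r, g = cos(pi * r / 60) * exp(-r / 80))
  expect_equal(sia_lengths(curve)$l0, 30, tolerance = 1e-3)
  # monotone positive curve: l0 undefined
  expect_true(is.na(sia_lengths(data.frame(r = r, g = exp(-r / 40)))$l0))
  # growing blob size increases the measured correlation length
  l0s <- vapply(c(2, 5), function(rad) {
    st <- gen_image_stack(frame_px = 128, pixel_size = 1, n_blobs = 10,
                          blob_radius = rad, seed = 70 + rad)
    g <- sia(st$frames[[1]], 1)
    correlation_lengths(data.frame(r = g$r, dg = g$g))$l0
  }, numeric(1))
  expect_gt(l0s[2], l0s[1])
  # 1/e decay length of the SIA of sigma = 5 px blobs is ~ 2 sigma = 10 px
  st5 <- gen_image_stack(frame_px = 128, pixel_size = 1, n_blobs = 12,
                         blob_radius = 5, seed = 81)
  g5 <- sia(st5$frames[[1]], 1)
  r_e <- approx(g5$g / g5$g[1], g5$r, 1 / exp(1))$y
  expect_equal(r_e, 10, tolerance = 0.2)
})

test_that("intensity distributions expose bimodality and tails", {
  flat <- image_stack(matrix(5, 32, 32), pixel_size = 0.41)
  pd <- intensity_distribution(flat)
  expect_equal(nrow(pd), 1)
  expect_equal(attr(pd, "peaks"), 5)
  # dim background plus bright blobs: bimodal P(I)
  set.seed(55)
  img <- matrix(rnorm(128 * 128, 20, 2), 128, 128)
  img[1:40, 1:128] <- rnorm(40 * 128, 80, 2)
  pd2 <- intensity_distribution(image_stack(img, 0.41), bins = 64)
  peaks <- attr(pd2, "peaks")
  big <- peaks[pd2$p[match(peaks, pd2$I)] > 0.2 * max(pd2$p)]
  expect_gte(length(big), 2)
  expect_gt(max(big) - min(big), 30)
  expect_equal(sum(pd2$p * diff(pd2$I)[1]), 1, tolerance = 1e-6)
})

test_that("tile heterogeneity separates well-mixed from de-mixed fields", {
  # constant image: all metrics collapse, patchiness undefined
  flat <- image_stack(matrix(3, 100, 100), pixel_size = 1)
  th <- tile_heterogeneity(flat, tile = 20)
  expect_equal(th$h_I, 0)
  expect_equal(th$H_I, 0)
  expect_true(is.na(th$p_I))
  # i.i.d. noise: p << 1 (well mixed at the tile scale)
  set.seed(66)
  noisy <- image_stack(matrix(rpois(200 * 200, 50), 200, 200), pixel_size = 1)
  th_n <- tile_heterogeneity(noisy, tile = 20)
  expect_lt(th_n$p_I, 0.3)
  # de-mixed tiling: a minority of tiles hold all the structure -> p > 1
  img <- matrix(10, 200, 200)
  set.seed(67)
  for (k in 1:12) {  # 12 of 100 tiles get a bright blob
    i <- sample(0:9, 1) * 20 + 10
    j <- sample(0:9, 1) * 20 + 10
    img[(i - 5):(i + 5), (j - 5):(j + 5)] <- 300
  }
  th_d <- tile_heterogeneity(image_stack(img, 1), tile = 20)
  expect_gt(th_d$p_I, 1)
  # edge tiles are discarded deterministically
  odd <- image_stack(matrix(rpois(50 * 70, 30), 50, 70), pixel_size = 1)
  th_o <- tile_heterogeneity(odd, tile = 20)
  expect_equal(th_o$tiles_per_frame, 2 * 3)
  expect_error(tile_heterogeneity(image_stack(matrix(1, 10, 10), 1),
                                  tile = 20), "fit within")
})

test_that("image stacks round-trip through TIFF with metadata sidecars", {
  st <- gen_image_stack(frame_px = 32, n_frames = 2, n_blobs = 3,
                        blob_radius = 2, seed = 90)
  st$meta <- list(ck_nM = 160)
  path <- tempfile(fileext = ".tif")
  write_image_stack(st, path)
  back <- read_image_stack(path)
  expect_equal(back$pixel_size, st$pixel_size)
  expect_equal(back$meta$ck_nM, 160)
  expect_equal(length(back$frames), 2)
  # 16-bit quantization: correlation structure is preserved
  g_orig <- sia(st$frames[[1]], st$pixel_size)
  g_back <- sia(back$frames[[1]] * back$meta$intensity_scale, st$pixel_size)
  expect_equal(g_back$g, g_orig$g, tolerance = 1e-3)
})
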