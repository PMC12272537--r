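#' Construct a fluorescence image stack
#'
#' @param frames a list of numeric matrices (all the same dimensions), or a
#'   single matrix
#' @param pixel_size pixel size in um
#' @param frame_interval seconds between frames (optional)
#' @param meta named list of condition metadata (e.g. `ck_nM`)
#' @return object of class `image_stack`
#' @export
image_stack <- function(frames, pixel_size, frame_interval = NA_real_,
                        meta = list()) {
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) == 0) stop("empty stack")
  dims <- lapply(frames, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all frames must share the same dimensions")
  if (pixel_size <= 0) stop("pixel size must be positive")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, meta = meta),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_stack: %d frame(s) of %d x %d px (%g um/px)\n",
              length(x$frames), d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Read / write an image stack as multi-page TIFF with a YAML sidecar
#'
#' The sidecar (same path, `.yaml` extension) carries `pixel_size_um` and any
#' further metadata; pixel size is per-stack metadata, never hard-coded.
#'
#' @param path TIFF path
#' @param pixel_size pixel size in um; overrides the sidecar when given
#' @return an `image_stack`
#' @export
read_image_stack <- function(path, pixel_size = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(frames)) frames <- list(frames)
  side <- sub("\\.[^.]+$", ".yaml", path)
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
  if (is.null(pixel_size))
    stop("pixel size not given and no pixel_size_um in sidecar")
  fi <- if (!is.null(meta$frame_interval_s)) meta$frame_interval_s else NA_real_
  image_stack(frames, pixel_size, fi, meta)
}

#' @rdname read_image_stack
#' @param stack an `image_stack`
#' @export
write_image_stack <- function(stack, path) {
  mx <- max(vapply(stack$frames, max, numeric(1)), 1)
  tiff::writeTIFF(lapply(stack$frames, function(f) f / mx), path,
                  bits.per.sample = 16L)
  meta <- stack$meta
  meta$pixel_size_um <- stack$pixel_size
  meta$intensity_scale <- mx
  if (!is.na(stack$frame_interval)) meta$frame_interval_s <- stack$frame_interval
  yaml::write_yaml(meta, sub("\\.[^.]+$", ".yaml", path))
  invisible(path)
}

# periodic 2D autocovariance of the mean-subtracted field, FFT-based
autocov_fft <- function(frame) {
  d <- frame - mean(frame)
  Re(fft(Mod(fft(d))^2, inverse = TRUE)) / length(d)^2
}

#' Spatial image autocorrelation of a single frame
#'
#' Autocorrelation of the mean-subtracted intensity field computed by FFT
#' (transform, squared modulus, inverse transform), normalized by the squared
#' mean intensity, then radially averaged onto annular bins one pixel wide.
#' The mean subtraction makes `g_I` decay to zero (and admit the negative
#' minima that indicate depletion zones) rather than to one.
#'
#' @param frame numeric matrix of pixel intensities
#' @param pixel_size pixel size in um
#' @param r_max largest separation analysed, um (default: half the smaller
#'   frame dimension)
#' @return object of class `sia_curve`: data frame with columns `r` (um,
#'   bin centres) and `g`
#' @export
sia <- function(frame, pixel_size, r_max = NULL) {
  if (pixel_size <= 0) stop("pixel size must be positive")
  mu <- mean(frame)
  if (sd(frame) == 0) {
    warning("constant frame: g_I is identically zero beyond r = 0")
    ac <- matrix(0, nrow(frame), ncol(frame))
  } else {
    if (mu == 0) stop("zero-mean frame cannot be normalized by its mean")
    ac <- autocov_fft(frame) / mu^2
  }
  nx <- nrow(frame); ny <- ncol(frame)
  if (is.null(r_max)) r_max <- min(nx, ny) / 2 * pixel_size
  # minimum-image radial distance of every shift
  sx <- pmin(0:(nx - 1), nx - 0:(nx - 1))
  sy <- pmin(0:(ny - 1), ny - 0:(ny - 1))
  rpx <- sqrt(outer(sx^2, sy^2, `+`))
  bin <- round(rpx)
  kmax <- floor(r_max / pixel_size)
  keep <- bin >= 1 & bin <= kmax
  g <- as.numeric(tapply(ac[keep], bin[keep], mean))
  kk <- sort(unique(bin[keep]))
  out <- data.frame(r = kk * pixel_size, g = g)
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("sia_curve", "data.frame")
  out
}

#' Average SIA of a stack and difference against a reference condition
#'
#' Computes `g_I(r)` for every frame of both stacks, averages per condition,
#' and returns the difference `Delta g_I(r) = g_I(r) - g_I_ref(r)` with the
#' standard error over the condition frames.
#'
#' @param stack an `image_stack` for the condition of interest
#' @param reference an `image_stack` for the reference (`c_k = 0`) condition
#' @param r_max largest separation analysed, um
#' @return data frame of class `sia_curve` with columns `r`, `g`, `dg`,
#'   `sem`
#' @export
delta_g_image <- function(stack, reference, r_max = NULL) {
  if (abs(stack$pixel_size - reference$pixel_size) > 1e-12)
    stop("stacks have different pixel sizes: r bins do not match")
  gs <- lapply(stack$frames, sia, pixel_size = stack$pixel_size,
               r_max = r_max)
  gr <- lapply(reference$frames, sia, pixel_size = reference$pixel_size,
               r_max = r_max)
  if (nrow(gs[[1]]) != nrow(gr[[1]]))
    stop("r bins of condition and reference do not match")
  m <- vapply(gs, function(g) g$g, numeric(nrow(gs[[1]])))
  m <- matrix(m, nrow = nrow(gs[[1]]))
  mr <- vapply(gr, function(g) g$g, numeric(nrow(gr[[1]])))
  mr <- matrix(mr, nrow = nrow(gr[[1]]))
  out <- data.frame(r = gs[[1]]$r, g = rowMeans(m),
                    dg = rowMeans(m) - rowMeans(mr),
                    sem = if (ncol(m) > 1) apply(m, 1, sd) / sqrt(ncol(m))
                          else 0)
  class(out) <- c("sia_curve", "data.frame")
  out
}

#' Correlation lengths of an SIA curve
#'
#' Shares the detection rules of [correlation_lengths()]: interpolated first
#' zero crossing (`l0`) and first local extremum beyond it.
#'
#' @param curve a `sia_curve`; the `dg` column is used when present,
#'   otherwise `g`
#' @return list with `l0`, `l_ext`, `ext_type`
#' @export
sia_lengths <- function(curve) {
  correlation_lengths(curve)
}

#' Pixel intensity distribution of a stack
#'
#' Normalized histogram over all pixels of all frames, with detected peak
#' locations (local maxima of the binned density).
#'
#' @param stack an `image_stack`
#' @param bins number of histogram bins (default 256)
#' @return data frame of class `intensity_distribution` with columns `I`
#'   (bin centres) and `p` (density); peak locations in attribute `peaks`
#' @export
intensity_distribution <- function(stack, bins = 256) {
  px <- unlist(lapply(stack$frames, as.numeric))
  rng <- range(px)
  if (rng[1] == rng[2]) {
    out <- data.frame(I = rng[1], p = 1)
    attr(out, "peaks") <- rng[1]
    class(out) <- c("intensity_distribution", "data.frame")
    return(out)
  }
  h <- hist(px, breaks = seq(rng[1], rng[2], length.out = bins + 1),
            plot = FALSE)
  p <- h$density
  mid <- h$mids
  ispeak <- which(diff(sign(diff(c(-Inf, p, -Inf)))) == -2)
  out <- data.frame(I = mid, p = p)
  attr(out, "peaks") <- mid[ispeak]
  class(out) <- c("intensity_distribution", "data.frame")
  out
}

#' Tile-based intensity heterogeneity of a stack
#'
#' Divides every frame into square tiles of side `tile` um (edge tiles
#' smaller than the full size are discarded), computes the per-tile
#' heterogeneity factor `delta_I = sigma_I / <I>`, and summarizes across all
#' tiles of all frames: local heterogeneity `h_I = mean(delta_I)`, global
#' heterogeneity `H_I = sd(delta_I)`, patchiness `p_I = H_I / h_I`. A
#' well-mixed field gives `p_I` near zero; a field de-mixed on the tile scale
#' gives `p_I > 1`.
#'
#' @param stack an `image_stack`
#' @param tile tile side in um (default 20)
#' @return object of class `intensity_heterogeneity`: per-tile `delta_I` and
#'   summary `h_I`, `H_I`, `p_I` (`p_I` is `NA` when `h_I = 0`)
#' @export
tile_heterogeneity <- function(stack, tile = 20) {
  npx <- floor(tile / stack$pixel_size)
  d <- dim(stack$frames[[1]])
  if (npx < 2 || npx > min(d))
    stop("tile size must fit within the frame and span at least 2 pixels")
  ntx <- d[1] %/% npx
  nty <- d[2] %/% npx
  deltas <- unlist(lapply(stack$frames, function(fr) {
    vapply(seq_len(ntx * nty), function(k) {
      i <- (k - 1) %% ntx
      j <- (k - 1) %/% ntx
      blk <- fr[(i * npx + 1):((i + 1) * npx),
                (j * npx + 1):((j + 1) * npx)]
      m <- mean(blk)
      if (m == 0) return(NA_real_)
      sd(blk) / m
    }, numeric(1))
  }))
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) < 1) stop("no usable tiles")
  h <- mean(deltas)
  H <- if (length(deltas) > 1) sd(deltas) else 0
  structure(list(delta_I = deltas, h_I = h, H_I = H,
                 p_I = if (h > 0) H / h else NA_real_,
                 tile = tile, tiles_per_frame = ntx * nty),
            class = "intensity_heterogeneity")
}

#' @export
print.intensity_heterogeneity <- function(x, ...) {
  cat(sprintf(
    "intensity heterogeneity (%g um tiles): h_I = %.4g, H_I = %.4g, p_I = %.4g\n",
    x$tile, x$h_I, x$H_I, x$p_I))
  invisible(x)
}
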