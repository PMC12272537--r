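#' Generate a synthetic fluorescence-like image stack
#'
#' Frames contain isotropic Gaussian blobs (intensity `blob_intensity`,
#' s.d. `blob_radius`) at random positions over a uniform background, with
#' optional Poisson shot noise or additive Gaussian noise. Blob centres and
#' radii are returned as ground truth so correlation-length estimators can be
#' validated against the generator.
#'
#' @param frame_px frame side in pixels (square frames)
#' @param pixel_size pixel size in um (default 0.41)
#' @param n_frames number of frames (default 1)
#' @param n_blobs blobs per frame
#' @param blob_radius blob Gaussian s.d. in um
#' @param blob_intensity peak intensity per blob
#' @param background background intensity
#' @param noise `"none"`, `"poisson"` (intensities are Poisson rates), or
#'   `"gaussian"`
#' @param noise_sd s.d. of Gaussian noise (ignored otherwise)
#' @param seed optional RNG seed
#' @return an [image_stack()] with attribute `truth` (list of per-frame blob
#'   centres in um, and the radius)
#' @export
gen_image_stack <- function(frame_px = 128, pixel_size = 0.41, n_frames = 1,
                            n_blobs = 20, blob_radius = 2,
                            blob_intensity = 100, background = 10,
                            noise = c("none", "poisson", "gaussian"),
                            noise_sd = 1, seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  if (blob_radius <= 0 && n_blobs > 0) stop("blob radius must be positive")
  if (blob_intensity < 0 || background < 0) stop("intensities must be >= 0")
  fov <- frame_px * pixel_size
  if (n_blobs > 0 && blob_radius > fov / 2)
    stop("blob larger than the frame")
  ax <- (seq_len(frame_px) - 0.5) * pixel_size
  truth <- vector("list", n_frames)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- matrix(background, frame_px, frame_px)
    centers <- NULL
    if (n_blobs > 0) {
      centers <- cbind(runif(n_blobs, 0, fov), runif(n_blobs, 0, fov))
      for (b in seq_len(n_blobs)) {
        # periodic (wrapped) distances keep the field statistically uniform
        dx <- abs(ax - centers[b, 1]); dx <- pmin(dx, fov - dx)
        dy <- abs(ax - centers[b, 2]); dy <- pmin(dy, fov - dy)
        img <- img + blob_intensity *
          outer(exp(-dx^2 / (2 * blob_radius^2)),
                exp(-dy^2 / (2 * blob_radius^2)))
      }
    }
    if (noise == "poisson") {
      img <- matrix(rpois(length(img), lambda = img), frame_px, frame_px)
    } else if (noise == "gaussian") {
      img <- img + matrix(rnorm(length(img), 0, noise_sd),
                          frame_px, frame_px)
    }
    frames[[f]] <- img
    truth[[f]] <- centers
  }
  st <- image_stack(frames, pixel_size)
  attr(st, "truth") <- list(centers = truth, blob_radius = blob_radius,
                            n_blobs = n_blobs)
  st
}

#' Generate a synthetic first-pull force trace
#'
#' Three response shapes mimic the observed classes: `"circuit"` follows the
#' Kelvin-Voigt circuit closed form [circuit_force()] with the supplied
#' `(kappa, gamma)`; `"plateau"` rises and saturates (yielding);
#' `"superlinear"` grows quadratically (stiffening). Gaussian noise of s.d.
#' `noise_sd` is added and the ground-truth parameters are attached.
#'
#' @param shape `"circuit"`, `"plateau"`, or `"superlinear"`
#' @param kappa,gamma circuit parameters (circuit shape), pN/um and pN s/um
#' @param k_ot trap stiffness, pN/um
#' @param v stage speed, um/s
#' @param stroke stroke length, um (default 20)
#' @param rate sampling rate in Hz (default 2000; at least 2 samples per um)
#' @param noise_sd force noise s.d., pN
#' @param f_plateau plateau force for the yielding shape, pN
#' @param x_c rise distance of the yielding shape, um
#' @param quad_coef quadratic coefficient of the stiffening shape, pN/um^2
#' @param seed optional RNG seed
#' @return a `force_trace` with attribute `truth`
#' @export
gen_force_trace <- function(shape = c("circuit", "plateau", "superlinear"),
                            kappa = 3, gamma = 1.5, k_ot = 68, v = 24,
                            stroke = 20, rate = 2000, noise_sd = 0,
                            f_plateau = 30, x_c = 2, quad_coef = 0.25,
                            seed = NULL) {
  shape <- match.arg(shape)
  if (!is.null(seed)) set.seed(seed)
  if (rate < 2 * v) stop("sampling rate below 2 samples per um of stroke")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  tt <- seq(0, stroke / v, by = 1 / rate)
  x <- v * tt
  f <- switch(shape,
    circuit = circuit_force(x, kappa, gamma, k_ot, v),
    plateau = f_plateau * (1 - exp(-x / x_c)),
    superlinear = quad_coef * x^2)
  if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
  tr <- data.frame(t = tt, x = x, F = f)
  truth <- switch(shape,
    circuit = list(shape = shape, kappa = kappa, gamma = gamma, k_ot = k_ot,
                   v = v),
    plateau = list(shape = shape, f_plateau = f_plateau, x_c = x_c, v = v),
    superlinear = list(shape = shape, quad_coef = quad_coef, v = v))
  attr(tr, "truth") <- truth
  attr(tr, "meta") <- list(v_um_s = v, stroke_um = stroke, k_ot = k_ot)
  class(tr) <- c("force_trace", "data.frame")
  tr
}

#' Analytic Kelvin-Voigt oscillation record
#'
#' Steady-state response of a single overdamped Kelvin-Voigt element
#' (spring `kappa_b`, dashpot `gamma_b`) to sinusoidal forcing: displacement
#' amplitude `F0 / sqrt(kappa_b^2 + (2 pi f gamma_b)^2)` and phase lag
#' `atan(2 pi f gamma_b / kappa_b)`. Serves as the exact oracle for
#' [extract_moduli()].
#'
#' @param kappa_b spring constant, pN/um (>= 0)
#' @param gamma_b drag coefficient, pN s/um (>= 0; not both zero)
#' @param protocol an [oscillation_protocol()]
#' @return a `rheology_series` data frame (`t`, `F`, `x`) with attribute
#'   `truth` holding the analytic amplitude and phase
#' @export
gen_kv_response <- function(kappa_b, gamma_b,
                            protocol = oscillation_protocol()) {
  if (kappa_b < 0 || gamma_b < 0) stop("parameters must be non-negative")
  if (kappa_b == 0 && gamma_b == 0)
    stop("kappa_b and gamma_b must not both be zero")
  w <- 2 * pi * protocol$freq
  amp <- protocol$F0 / sqrt(kappa_b^2 + (w * gamma_b)^2)
  phi <- atan2(w * gamma_b, kappa_b)
  dt <- 1 / (protocol$freq * protocol$steps_per_period)
  tt <- (seq_len(protocol$steps_per_period * protocol$periods) - 1) * dt
  out <- data.frame(t = tt,
                    F = protocol$F0 * sin(w * tt),
                    x = amp * sin(w * tt - phi))
  attr(out, "protocol") <- protocol
  attr(out, "truth") <- list(amplitude = amp, phi = phi)
  class(out) <- c("rheology_series", "data.frame")
  out
}
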