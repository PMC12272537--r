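#' Read an optical-tweezers force trace
#'
#' Traces are delimited text with header columns `t_s`, `x_um`, `F_pN`
#' (time in seconds, stage position in um, force in pN). A YAML metadata
#' sidecar (same path with extension `.yaml`), when present, supplies
#' condition metadata such as `ck_nM`, `v_um_s`, `stroke_um`, `k_ot`.
#' Rows with non-finite force are dropped with a warning; non-monotone time
#' is rejected.
#'
#' @param path path to the CSV file
#' @return object of class `force_trace`: data frame `t`, `x`, `F` with a
#'   `meta` attribute
#' @export
read_trace <- function(path) {
  df <- read.csv(path, comment.char = "#")
  need <- c("t_s", "x_um", "F_pN")
  if (!all(need %in% names(df)))
    stop("trace file must have columns ", paste(need, collapse = ", "))
  tr <- data.frame(t = df$t_s, x = df$x_um, F = df$F_pN)
  bad <- !is.finite(tr$F)
  if (any(bad)) {
    warning("dropped ", sum(bad), " rows with non-finite force")
    tr <- tr[!bad, ]
  }
  if (any(diff(tr$t) <= 0)) stop("time column is not strictly increasing")
  side <- sub("\\.[^.]+$", ".yaml", path)
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  attr(tr, "meta") <- meta
  class(tr) <- c("force_trace", "data.frame")
  tr
}

#' Write a force trace (with optional metadata sidecar)
#'
#' @param trace a `force_trace` or data frame with columns `t`, `x`, `F`
#' @param path output CSV path
#' @param meta optional metadata list written to a `.yaml` sidecar
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path, meta = attr(trace, "meta")) {
  out <- data.frame(t_s = trace$t, x_um = trace$x, F_pN = trace$F)
  write.csv(out, path, row.names = FALSE)
  if (!is.null(meta) && length(meta) > 0)
    yaml::write_yaml(meta, sub("\\.[^.]+$", ".yaml", path))
  invisible(path)
}

#' Restrict a trace to its first forward stroke
#'
#' Locates the first contiguous region of positive stage velocity (the first
#' `+x` half-cycle of the sawtooth), rebases the stage position to start at
#' zero, and trims the final 1 percent of the stroke (0.2 um for the default
#' 20-um stroke) where the stage reverses.
#'
#' @param trace a `force_trace`
#' @param stroke stroke length s in um (default 20, or the `stroke_um`
#'   metadata value if present)
#' @param trim_frac trailing fraction of the stroke removed (default 0.01)
#' @return a `force_trace` covering stage positions `[0, (1 - trim_frac) s]`
#' @export
segment_first_pull <- function(trace, stroke = NULL, trim_frac = 0.01) {
  meta <- attr(trace, "meta")
  if (is.null(stroke))
    stroke <- if (!is.null(meta$stroke_um)) meta$stroke_um else 20
  v <- diff(trace$x) / diff(trace$t)
  fwd <- v > 0
  if (!any(fwd)) stop("no forward stroke found (stage never moves in +x)")
  i0 <- which(fwd)[1]
  i1 <- i0
  while (i1 < length(fwd) && fwd[i1 + 1]) i1 <- i1 + 1
  seg <- trace[i0:(i1 + 1), , drop = FALSE]
  seg$x <- seg$x - seg$x[1]
  keep <- seg$x <= (1 - trim_frac) * stroke + 1e-9
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg) < 3) stop("forward stroke too short after trimming")
  attr(seg, "meta") <- meta
  attr(seg, "stroke") <- stroke
  class(seg) <- c("force_trace", "data.frame")
  seg
}

# secant stiffness of the (smoothed) force curve over a stage-position window
secant_stiffness <- function(x, f, lo, hi) {
  f_lo <- approx(x, f, lo, rule = 2)$y
  f_hi <- approx(x, f, hi, rule = 2)$y
  (f_hi - f_lo) / (hi - lo)
}

#' Classify a first-pull force response
#'
#' Compares secant stiffness over an early window (10-30 percent of the
#' stroke, past the trap re-equilibration transient) against a late window
#' (70-100 percent of the retained stroke). With ratio
#' `rho = k_late / k_early`: `rho > rho_hi` is "stiffening",
#' `rho < rho_lo` is "yielding", otherwise "elastic". The force is smoothed
#' by a moving average spanning 1 percent of samples before the secants are
#' taken, so classification is insensitive to high-frequency noise and to
#' uniform rescaling of the force units.
#'
#' @param trace a trimmed first pull from [segment_first_pull()]
#' @param rho_lo,rho_hi classification thresholds (defaults 0.5 and 1.5)
#' @param stroke nominal stroke in um (default from segmentation, else 20)
#' @return object of class `response_class`: list with `label` in
#'   `c("elastic", "yielding", "stiffening")` and diagnostics
#' @export
classify_response <- function(trace, rho_lo = 0.5, rho_hi = 1.5,
                              stroke = NULL) {
  if (is.null(stroke)) {
    stroke <- attr(trace, "stroke")
    if (is.null(stroke)) stroke <- 20
  }
  x <- trace$x
  f <- trace$F
  wlen <- max(1L, round(0.01 * length(f)))
  if (wlen > 1) {
    kern <- rep(1 / wlen, wlen)
    fs <- as.numeric(stats::filter(f, kern, sides = 2))
    f <- ifelse(is.na(fs), f, fs)
  }
  x_max <- max(x)
  early <- c(0.10, 0.30) * stroke
  late <- c(0.70 * stroke, x_max)
  if (early[2] > x_max || late[1] >= late[2])
    stop("classification windows fall outside the retained stroke")
  k_early <- secant_stiffness(x, f, early[1], early[2])
  k_late <- secant_stiffness(x, f, late[1], late[2])
  if (!is.finite(k_early) || k_early == 0)
    stop("early-window stiffness undefined")
  rho <- k_late / k_early
  label <- if (rho > rho_hi) "stiffening" else if (rho < rho_lo) "yielding"
           else "elastic"
  structure(list(label = label, rho = rho, k_early = k_early,
                 k_late = k_late, windows = list(early = early, late = late)),
            class = "response_class")
}

#' @export
print.response_class <- function(x, ...) {
  cat(sprintf("response: %s (k_early = %.3g, k_late = %.3g, rho = %.3g)\n",
              x$label, x$k_early, x$k_late, x$rho))
  invisible(x)
}

#' Ensemble-average force traces onto a common stage-position grid
#'
#' Each trace is linearly interpolated onto `n_grid` uniform points over
#' `[0, x_max]` and the pointwise mean and standard error are returned.
#'
#' @param traces list of first-pull `force_trace` objects
#' @param n_grid number of grid points (default 200)
#' @param x_max terminal stage position (default: the smallest trace maximum)
#' @return object of class `ensemble_curve`: data frame with columns `x`,
#'   `F`, `sem`, `n`
#' @export
ensemble_average <- function(traces, n_grid = 200, x_max = NULL) {
  if (length(traces) == 0) stop("empty trace group")
  if (is.null(x_max))
    x_max <- min(vapply(traces, function(tr) max(tr$x), numeric(1)))
  grid <- seq(0, x_max, length.out = n_grid)
  mat <- vapply(traces, function(tr) approx(tr$x, tr$F, grid, rule = 2)$y,
                numeric(n_grid))
  mat <- matrix(mat, nrow = n_grid)
  n <- ncol(mat)
  mu <- rowMeans(mat)
  sem <- if (n > 1) apply(mat, 1, sd) / sqrt(n) else rep(0, n_grid)
  out <- data.frame(x = grid, F = mu, sem = sem, n = n)
  class(out) <- c("ensemble_curve", "data.frame")
  out
}

#' Normalized maximum force of an ensemble curve
#'
#' Terminal mean force of the condition curve divided by the terminal mean
#' force of the motor-free (`c_k = 0`) reference curve.
#'
#' @param curve,reference `ensemble_curve` objects sharing the same terminal
#'   stage position
#' @return dimensionless force ratio
#' @export
fmax_ratio <- function(curve, reference) {
  if (abs(max(curve$x) - max(reference$x)) > 1e-6)
    stop("curves do not share the same terminal stage position")
  f_ref <- reference$F[nrow(reference)]
  if (f_ref == 0) stop("reference terminal force is zero")
  curve$F[nrow(curve)] / f_ref
}

#' Response-class fractions per condition
#'
#' @param labels character vector of classification labels for one condition
#' @return named numeric vector of fractions over
#'   `c("elastic", "yielding", "stiffening")`, summing to 1
#' @export
class_fractions <- function(labels) {
  lv <- c("elastic", "yielding", "stiffening")
  if (length(labels) == 0) stop("no classified traces")
  if (!all(labels %in% lv)) stop("unknown label(s)")
  tab <- table(factor(labels, levels = lv))
  setNames(as.numeric(tab) / length(labels), lv)
}
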