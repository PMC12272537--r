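#' Mesh sizes of the actin, microtubule, and composite networks
#'
#' Mesh size of an entangled semiflexible network from its molar
#' concentration: `xi_A = 1.46 c_A^(-1/2)` and `xi_M = 2.68 c_T^(-1/2)`
#' (concentrations in uM, mesh sizes in um). The composite mesh size
#' combines the two single-network values by inverse-cube addition,
#' `xi = (xi_A^-3 + xi_M^-3)^(-1/3)`, so the composite is always finer than
#' either constituent network.
#'
#' @param c_actin actin molarity in uM (default 1.35, the composite recipe)
#' @param c_tubulin tubulin dimer molarity in uM (default 1.55, the
#'   unlabeled tubulin in the recipe; labeled tubulin does not add mesh)
#' @return list with `xi_A`, `xi_M`, `xi` (um)
#' @examples
#' mesh_sizes()          # xi ~ 1.19 um
#' mesh_sizes(1.35, 1.55)$xi_A  # ~ 1.26 um
#' @export
mesh_sizes <- function(c_actin = 1.35, c_tubulin = 1.55) {
  if (c_actin <= 0 || c_tubulin <= 0)
    stop("concentrations must be positive")
  xi_a <- 1.46 / sqrt(c_actin)
  xi_m <- 2.68 / sqrt(c_tubulin)
  xi <- (xi_a^-3 + xi_m^-3)^(-1 / 3)
  list(xi_A = xi_a, xi_M = xi_m, xi = xi)
}

#' Kinesin-cluster-to-tubulin motor ratio
#'
#' `R = c_k / (4 c_T)`: the factor of four accounts for the four kinesin
#' motors (two dimers) per NeutrAvidin-assembled cluster.
#'
#' @param c_k kinesin concentration in nM
#' @param c_tubulin total tubulin dimer molarity in uM (default 1.65,
#'   labeled plus unlabeled)
#' @return dimensionless motor ratio
#' @examples
#' motor_ratio(c(0, 40, 80, 160, 320, 640))
#' @export
motor_ratio <- function(c_k, c_tubulin = 1.65) {
  if (c_tubulin <= 0) stop("c_tubulin must be positive")
  if (any(c_k < 0)) stop("c_k must be non-negative")
  c_k / (4 * c_tubulin * 1000)
}

#' Strain rate of a dragged probe
#'
#' Shear strain rate experienced at the surface of a probe of radius `r_p`
#' dragged at speed `v`: `3 v / (sqrt(2) r_p)`.
#'
#' @param v stage speed in um/s
#' @param r_p probe radius in um (default 2.25)
#' @return strain rate in 1/s
#' @examples
#' strain_rate(c(6, 12, 24))  # ~5.7, ~11, ~23 /s
#' @export
strain_rate <- function(v, r_p = 2.25) {
  if (any(v <= 0) || r_p <= 0) stop("v and r_p must be positive")
  3 * v / (sqrt(2) * r_p)
}

#' Equivalent oscillation frequency of a constant-speed stroke
#'
#' A stroke of length `s` at speed `v` corresponds approximately to forcing
#' at frequency `v / s`.
#'
#' @param v stage speed in um/s
#' @param s stroke length in um (default 20)
#' @return frequency in Hz
#' @export
frequency_estimate <- function(v, s = 20) {
  if (s <= 0) stop("stroke must be positive")
  if (any(v < 0)) stop("v must be non-negative")
  v / s
}
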