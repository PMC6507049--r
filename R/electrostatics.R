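#' Electrostatic model parameters
#'
#' Parameters of the screened-Coulomb (Debye-Hueckel) model: a single
#' relative dielectric for the whole system and an ionic strength that sets
#' the screening length. The inverse Debye length \code{kappa} is derived on
#' construction.
#'
#' @param eps_r relative dielectric constant (default 78.4, water at 25 C).
#' @param ionic_strength ionic strength in mol/L (default 0.15).
#' @param temperature absolute temperature in K (default 298.15).
#' @return an object of class \code{es_params} with fields \code{eps_r},
#'   \code{ionic_strength}, \code{temperature} and \code{kappa} (1/Angstrom).
#' @examples
#' p <- es_params()
#' 1 / p$kappa  # Debye length, ~7.9 Angstrom at 0.15 M
#' @export
es_params <- function(eps_r = 78.4, ionic_strength = 0.15,
                      temperature = 298.15) {
  if (ionic_strength < 0) stop("ionic strength must be >= 0")
  if (eps_r <= 0 || temperature <= 0) stop("eps_r and temperature must be > 0")
  p <- list(eps_r = eps_r, ionic_strength = ionic_strength,
            temperature = temperature)
  p$kappa <- debye_kappa(p)
  class(p) <- "es_params"
  p
}

#' @export
print.es_params <- function(x, ...) {
  cat("Debye-Hueckel parameters\n")
  cat(sprintf("  eps_r: %.2f  I: %.3f M  T: %.2f K\n",
              x$eps_r, x$ionic_strength, x$temperature))
  if (x$kappa > 0) {
    cat(sprintf("  kappa: %.5f 1/A  (Debye length %.2f A)\n",
                x$kappa, 1 / x$kappa))
  } else cat("  kappa: 0 (no screening)\n")
  invisible(x)
}

#' Inverse Debye screening length
#'
#' \eqn{\kappa = \sqrt{2 N_A e^2 I \cdot 1000 / (\epsilon_0 \epsilon_r k_B T)}}
#' converted to 1/Angstrom. At 0.15 M, 298.15 K and eps_r 78.4 the Debye
#' length 1/kappa is about 7.9 Angstrom.
#'
#' @param params an \code{\link{es_params}} object (or bare list with the
#'   same fields).
#' @return kappa in 1/Angstrom; 0 when the ionic strength is 0.
#' @export
debye_kappa <- function(params) {
  I <- params$ionic_strength
  if (I < 0) stop("ionic strength must be >= 0")
  if (I == 0) return(0)
  k2 <- 2 * .NA_CONST * .E_CHARGE^2 * I * 1000 /
    (.EPS0 * params$eps_r * .KB * params$temperature)
  sqrt(k2) * 1e-10
}

#' Screened-Coulomb potential at points
#'
#' Superposition of Debye-Hueckel monopole potentials
#' \eqn{\phi(p) = \sum_i q_i e \exp(-\kappa d_i)/(4\pi\epsilon_0\epsilon_r d_i)}
#' in millivolts.
#'
#' @param charges numeric matrix/data.frame with columns x, y, z, q
#'   (positions in Angstrom, charges in elementary units).
#' @param points numeric matrix with 3 columns (or length-3 vector).
#' @param params \code{\link{es_params}}.
#' @return numeric vector of potentials, mV, one per point.
#' @export
potential_at_points <- function(charges, points, params = es_params()) {
  charges <- as.matrix(as.data.frame(charges)[, c("x", "y", "z", "q")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (nrow(charges) == 0) return(rep(0, nrow(points)))
  phi <- numeric(nrow(points))
  kap <- params$kappa
  for (i in seq_len(nrow(charges))) {
    d <- sqrt((points[, 1] - charges[i, 1])^2 +
              (points[, 2] - charges[i, 2])^2 +
              (points[, 3] - charges[i, 3])^2)
    if (any(d <= 0.1)) {
      stop("evaluation point within 0.1 A of a charge centre")
    }
    phi <- phi + charges[i, 4] * exp(-kap * d) / d
  }
  as.numeric(phi * .K_COUL_MV / params$eps_r)
}

#' Pairwise charge-charge interaction matrix
#'
#' \eqn{W_{ij} = N_A e^2 \exp(-\kappa r_{ij}) / (4\pi\epsilon_0\epsilon_r r_{ij})}
#' in kJ/mol per unit-charge pair; the diagonal is zero.
#'
#' @param sites matrix/data.frame with columns x, y, z (Angstrom).
#' @param params \code{\link{es_params}}.
#' @return symmetric numeric matrix, kJ/mol.
#' @export
interaction_matrix <- function(sites, params = es_params()) {
  sites <- as.matrix(as.data.frame(sites)[, c("x", "y", "z")])
  n <- nrow(sites)
  if (n < 1) stop("need at least one site")
  W <- matrix(0, n, n)
  if (n == 1) return(W)
  d <- as.matrix(stats::dist(sites))
  if (any(d[upper.tri(d)] <= 0.5)) stop("sites closer than 0.5 A (coincident?)")
  off <- upper.tri(d) | lower.tri(d)
  W[off] <- .K_COUL_KJ * exp(-params$kappa * d[off]) / (params$eps_r * d[off])
  W
}

#' Electrostatic potential over a dot surface
#'
#' Evaluates the screened-Coulomb potential of a structure's formal charges
#' at every surface dot.
#'
#' @param surface a \code{\link{build_dot_surface}} result.
#' @param structure a charged \code{protein_structure}
#'   (see \code{\link{assign_charges}}).
#' @param params \code{\link{es_params}}.
#' @return numeric vector of potentials (mV), aligned with
#'   \code{surface$dots}.
#' @export
surface_potential <- function(surface, structure, params = es_params()) {
  at <- structure$atoms
  ch <- at[at$charge != 0, , drop = FALSE]
  if (nrow(ch) == 0) return(rep(0, nrow(surface$dots)))
  potential_at_points(
    data.frame(x = ch$x, y = ch$y, z = ch$z, q = ch$charge),
    as.matrix(surface$dots[, c("x", "y", "z")]), params)
}
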