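#' Onsager spontaneous surface enantiomeric excess
#'
#' Exact zero-field magnetization of the 2D square-lattice Ising model,
#' read as the spontaneous surface enantiomeric excess of a saturated
#' monolayer in equilibrium with a racemic gas on an achiral surface:
#' `ees = [1 - sinh(dE/(R T))^(-4)]^(1/8)` for temperatures below the
#' critical temperature, and 0 at or above it. The argument uses the full
#' exchange energy `dE` (per-pair coupling `dE/2`), matching
#' [critical_temperature()].
#'
#' A heterochiral-favouring system (`exch_energy <= 0`) has no spontaneous
#' symmetry breaking; the monolayer stays racemic and 0 is returned.
#'
#' @param exch_energy Homochiral-heterochiral exchange energy, J/mol.
#' @param temperature Temperature in kelvin (> 0); vectorised.
#' @return Spontaneous |ees| in \[0, 1).
#' @examples
#' onsager_ees(2310, 250)   # deep in the ordered phase
#' onsager_ees(2310, 460)   # above Tc: racemic monolayer
#' @export
onsager_ees <- function(exch_energy, temperature) {
  stopifnot(length(exch_energy) == 1L, is.finite(exch_energy),
            all(temperature > 0))
  if (exch_energy <= 0) return(rep(0, length(temperature)))
  x <- exch_energy / (GAS_CONSTANT * temperature)
  ees <- numeric(length(x))
  ordered <- x > log(1 + sqrt(2))  # T < Tc
  ees[ordered] <- (1 - sinh(x[ordered])^(-4))^(1 / 8)
  ees
}

#' Critical temperature of the order-disorder transition
#'
#' `Tc = exch_energy / (R ln(1 + sqrt(2)))`: below this temperature a
#' racemic gas over an achiral surface spontaneously forms a monolayer
#' with non-zero enantiomeric excess (sign undetermined). About 315 K for
#' an exchange energy of 2.31 kJ/mol.
#'
#' @param exch_energy Exchange energy in J/mol (> 0; non-positive values
#'   have no transition and are rejected).
#' @return Critical temperature in kelvin.
#' @export
critical_temperature <- function(exch_energy) {
  stopifnot(is.numeric(exch_energy))
  if (any(exch_energy <= 0))
    stop("no order-disorder transition for exch_energy <= 0")
  exch_energy / (GAS_CONSTANT * log(1 + sqrt(2)))
}

#' Single-component Langmuir coverage
#'
#' `theta = K P / (1 + K P)`: fractional coverage of non-interacting,
#' non-dissociative adsorbates at equilibrium constant `K` and partial
#' pressure `P`. Saturates to 1 as `K P -> Inf`.
#'
#' @param K Adsorption equilibrium constant (per pressure unit).
#' @param P Partial pressure (same pressure unit); vectorised.
#' @return Coverage in \[0, 1\].
#' @export
langmuir_coverage <- function(K, P) {
  kp <- K * P
  if (any(kp < 0, na.rm = TRUE)) stop("K * P must be non-negative")
  ifelse(is.infinite(kp), 1, kp / (1 + kp))
}

#' Competitive Langmuir coverages of two adsorbates
#'
#' `theta_A = K_A P_A / (1 + K_A P_A + K_B P_B)` and symmetrically for B:
#' the non-interacting baseline for competitive co-adsorption. With equal
#' equilibrium constants, in the saturation limit the surface ee equals
#' the gas-phase ee — the behaviour the interacting Ising model departs
#' from.
#'
#' @param K_A,K_B Adsorption equilibrium constants.
#' @param P_A,P_B Partial pressures (non-negative).
#' @return Named list with elements `theta_A` and `theta_B`.
#' @export
competitive_coverages <- function(K_A, P_A, K_B, P_B) {
  ka <- K_A * P_A; kb <- K_B * P_B
  if (any(c(ka, kb) < 0, na.rm = TRUE)) stop("K * P must be non-negative")
  denom <- 1 + ka + kb
  list(theta_A = ka / denom, theta_B = kb / denom)
}

#' Onsager ees curve over a temperature grid
#'
#' @param exch_energy Exchange energy, J/mol (> 0).
#' @param temperatures Vector of temperatures in kelvin.
#' @return Data frame with columns `temperature` and `ees`.
#' @export
onsager_curve <- function(exch_energy, temperatures) {
  if (length(temperatures) < 1L) stop("empty temperature grid")
  data.frame(temperature = temperatures,
             ees = onsager_ees(exch_energy, temperatures))
}

#' Exact Boltzmann averages on a small lattice
#'
#' Enumerates all `2^(N^2)` configurations of an N x N periodic lattice
#' (N = 3 or 4 only, as a cost guard) and returns exact Boltzmann-weighted
#' expectations of the surface ee, |ee|, energy per site and homochiral
#' pair fraction. This is the ground truth against which the Metropolis
#' sampler is validated.
#'
#' @param params An [ising_params()] object with finite effective field.
#' @param side Lattice side, 3 or 4.
#' @return List with `mean_ees`, `mean_abs_ees`, `mean_energy_per_site`,
#'   `mean_homochiral_fraction`.
#' @export
exact_enumeration <- function(params, side) {
  stopifnot(inherits(params, "ising_params"))
  side <- as.integer(side)
  if (!side %in% c(3L, 4L))
    stop("exact enumeration is restricted to side 3 or 4")
  h <- effective_field(params)
  if (!is.finite(h)) stop("exact enumeration requires |gas_ee| < 1")
  jp <- pair_coupling(params)
  n2 <- side * side

  # All configurations as a 2^(n2) x n2 matrix of +/-1.
  cfg <- as.matrix(expand.grid(rep(list(c(-1, 1)), n2)))
  dimnames(cfg) <- NULL

  # Unordered periodic NN pairs: each site with its down and right
  # neighbour (column-major site indexing).
  m <- matrix(seq_len(n2), side, side)
  down <- m[c(2:side, 1L), , drop = FALSE]
  right <- m[, c(2:side, 1L), drop = FALSE]
  pi_ <- c(m, m); pj_ <- c(down, right)
  pairsum <- rowSums(cfg[, pi_] * cfg[, pj_])

  spinsum <- rowSums(cfg)
  energy <- -h * spinsum - jp * pairsum
  w <- exp(-(energy - min(energy)) / rt_energy(params))
  w <- w / sum(w)

  ees <- spinsum / n2
  list(mean_ees = sum(w * ees),
       mean_abs_ees = sum(w * abs(ees)),
       mean_energy_per_site = sum(w * energy) / n2,
       mean_homochiral_fraction = sum(w * (1 + pairsum / (2 * n2)) / 2))
}
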