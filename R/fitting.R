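#' Construct an ees-versus-eeg experiment dataset
#'
#' Tabular (eeg, ees) observations, measured or synthetic, consumed by the
#' exchange-energy fitting pipeline.
#'
#' @param eeg Gas-phase ee values, unique, in \[-1, 1\].
#' @param ees Observed surface ee values, in \[-1, 1\].
#' @param temperature Measurement temperature, kelvin.
#' @param label Free-text label.
#' @param provenance `"measured"` or `"synthetic"`.
#' @param generator For synthetic data, the generator parameter list.
#' @return An `experiment_dataset` data frame with columns `eeg`, `ees`.
#' @export
experiment_dataset <- function(eeg, ees, temperature, label = "",
                               provenance = c("measured", "synthetic"),
                               generator = NULL) {
  provenance <- match.arg(provenance)
  eeg <- as.numeric(eeg); ees <- as.numeric(ees)
  if (length(eeg) != length(ees)) stop("eeg and ees lengths differ")
  if (any(duplicated(eeg))) stop("eeg values must be unique")
  if (any(eeg < -1 | eeg > 1) || any(ees < -1 | ees > 1))
    stop("eeg and ees must lie in [-1, 1]")
  structure(data.frame(eeg = eeg, ees = ees),
            temperature = as.numeric(temperature), label = label,
            provenance = provenance, generator = generator,
            class = c("experiment_dataset", "data.frame"))
}

#' Residual deviation between observations and a simulated isotherm
#'
#' Unweighted sum of squared residuals
#' `chi^2 = sum_rows (ees_obs - ees_sim)^2`, the objective minimised by
#' the exchange-energy grid scan. The isotherm must have been evaluated
#' at exactly the dataset's eeg values.
#'
#' @param dataset An [experiment_dataset()].
#' @param isotherm An `ising_isotherm` from [isotherm_scan()].
#' @return Non-negative chi-square value.
#' @export
chi_square <- function(dataset, isotherm) {
  stopifnot(inherits(dataset, "experiment_dataset"),
            inherits(isotherm, "ising_isotherm"))
  ord <- order(dataset$eeg)
  obs <- dataset[ord, , drop = FALSE]
  if (nrow(obs) != nrow(isotherm) ||
      any(abs(obs$eeg - isotherm$eeg) > 1e-9))
    stop("isotherm eeg grid does not match the dataset")
  sum((obs$ees - isotherm$ees_mean)^2)
}

#' Chi-square scan over an exchange-energy grid
#'
#' The simulation-based estimation procedure for the
#' homochiral-heterochiral exchange energy: one Monte Carlo isotherm per
#' candidate energy, evaluated at the dataset's eeg values, scored by
#' [chi_square()]. The same base seed is used for every grid energy
#' (common random numbers), so chi^2 varies smoothly along the grid and
#' the subsequent cubic fit is stable.
#'
#' @param dataset An [experiment_dataset()].
#' @param grid Strictly increasing exchange energies, J/mol, length >= 4
#'   (a cubic needs four points). The conventional scan covers 2100 to
#'   2700 J/mol in 100 J/mol steps.
#' @param params_base [ising_params()] carrying temperature and
#'   adsorption-energy difference; its exchange energy and gas ee are
#'   replaced during the scan.
#' @param settings [mc_settings()] for the per-point sampler runs.
#' @param side Lattice side N. Default 100.
#' @return A `fit_result` list: `grid`, `chi_square`, and placeholders for
#'   the cubic stage (complete it with [cubic_fit_minimum()]).
#' @export
exchange_energy_scan <- function(dataset, grid, params_base, settings,
                                 side = 100L) {
  stopifnot(inherits(dataset, "experiment_dataset"),
            inherits(params_base, "ising_params"),
            inherits(settings, "mc_settings"))
  grid <- as.numeric(grid)
  if (length(grid) < 4L)
    stop("grid must have at least 4 energies (cubic fit)")
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  eeg_values <- sort(dataset$eeg)
  chisq <- vapply(grid, function(de) {
    p <- ising_params(params_base$temperature, de,
                      params_base$ads_energy_diff)
    iso <- isotherm_scan(p, eeg_values, settings, side)
    chi_square(dataset, iso)
  }, numeric(1))
  structure(list(grid = grid, chi_square = chisq,
                 cubic_coefficients = NULL,
                 best_exchange_energy = NA_real_, boundary_flag = NA),
            class = "fit_result")
}

#' Cubic-polynomial minimum of a chi-square scan
#'
#' Completes a `fit_result`: ordinary least-squares cubic through the
#' (energy, chi^2) pairs, then the minimising energy as the real root of
#' the derivative inside the grid range with positive second derivative.
#' If the fitted cubic has no interior minimum (e.g. monotone chi^2),
#' `boundary_flag` is set and the grid argmin is reported instead.
#'
#' @param result A `fit_result` from [exchange_energy_scan()], or any list
#'   with numeric `grid` and `chi_square` of equal length >= 4.
#' @return The completed `fit_result` with `cubic_coefficients` (a0..a3),
#'   `best_exchange_energy` (J/mol) and `boundary_flag`.
#' @export
cubic_fit_minimum <- function(result) {
  x <- result$grid; y <- result$chi_square
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (any(duplicated(x))) stop("degenerate design: duplicate grid values")
  # centre/scale for conditioning; coefficients mapped back afterwards
  xm <- mean(x); xs <- stats::sd(x)
  z <- (x - xm) / xs
  fit <- stats::lm(y ~ z + I(z^2) + I(z^3))
  b <- unname(stats::coef(fit))              # y = b0 + b1 z + b2 z^2 + b3 z^3
  # back-transform to a0 + a1 x + a2 x^2 + a3 x^3
  a3 <- b[4] / xs^3
  a2 <- b[3] / xs^2 - 3 * b[4] * xm / xs^3
  a1 <- b[2] / xs - 2 * b[3] * xm / xs^2 + 3 * b[4] * xm^2 / xs^3
  a0 <- b[1] - b[2] * xm / xs + b[3] * xm^2 / xs^2 - b[4] * xm^3 / xs^3
  coefs <- c(a0, a1, a2, a3)

  # critical points of the derivative 3 a3 x^2 + 2 a2 x + a1 (in z-space
  # for stability): 3 b3 z^2 + 2 b2 z + b1 = 0
  crit_z <- if (abs(b[4]) < 1e-12 * max(abs(b), 1)) {
    if (abs(b[3]) > 0) -b[2] / (2 * b[3]) else numeric(0)
  } else {
    disc <- 4 * b[3]^2 - 12 * b[4] * b[2]
    if (disc < 0) numeric(0)
    else (-2 * b[3] + c(-1, 1) * sqrt(disc)) / (6 * b[4])
  }
  # keep interior critical points with positive second derivative
  sec <- 2 * b[3] + 6 * b[4] * crit_z
  zlo <- min(z); zhi <- max(z)
  ok <- crit_z >= zlo & crit_z <= zhi & sec > 0
  if (any(ok)) {
    cand <- crit_z[ok]
    val <- b[1] + b[2] * cand + b[3] * cand^2 + b[4] * cand^3
    best <- cand[which.min(val)] * xs + xm
    flag <- FALSE
  } else {
    best <- x[which.min(y)]
    flag <- TRUE
  }
  result$cubic_coefficients <- coefs
  result$best_exchange_energy <- best
  result$boundary_flag <- flag
  result
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Exchange-energy chi-square scan\n")
  cat(sprintf("  grid  : %s J/mol\n", paste(signif(x$grid, 5),
                                            collapse = ", ")))
  cat(sprintf("  chi^2 : %s\n", paste(signif(x$chi_square, 4),
                                      collapse = ", ")))
  if (!is.na(x$best_exchange_energy)) {
    cat(sprintf("  best exchange energy: %.1f J/mol%s\n",
                x$best_exchange_energy,
                if (isTRUE(x$boundary_flag)) " (grid boundary)" else ""))
  }
  invisible(x)
}

#' Full exchange-energy estimation pipeline
#'
#' [exchange_energy_scan()] followed by [cubic_fit_minimum()].
#'
#' @inheritParams exchange_energy_scan
#' @return A completed `fit_result`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(default_asp_cu111_config())
#' fit <- fit_exchange_energy(ds, seq(2100, 2700, 100),
#'   ising_params(460, 2310), mc_settings(seed = 1,
#'     burn_in_sweeps = 200, measure_sweeps = 400), side = 30)
#' fit$best_exchange_energy
#' }
#' @export
fit_exchange_energy <- function(dataset, grid, params_base, settings,
                                side = 100L) {
  cubic_fit_minimum(
    exchange_energy_scan(dataset, grid, params_base, settings, side))
}
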