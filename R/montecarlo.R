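#' Monte Carlo sampler settings
#'
#' Controls for the Metropolis sampler: seeding, equilibration length,
#' measurement length, sampling stride, initial configuration, and the
#' number of contiguous batches used for batch-mean standard errors.
#'
#' @param seed Integer seed. All randomness flows through R's RNG, so a
#'   fixed seed gives bit-identical trajectories.
#' @param burn_in_sweeps Equilibration sweeps discarded before measuring
#'   (one sweep = N^2 attempted flips). Default 2000.
#' @param measure_sweeps Measurement sweeps. Default 5000.
#' @param sample_interval Sweeps between retained samples. Default 1.
#' @param init_mode Initial lattice: `"random_racemic"`, `"all_D"`,
#'   `"all_L"`, or `"fixed_ee"` (see [new_lattice()]). Below the critical
#'   temperature at zero field, start from `"all_D"`/`"all_L"` to measure
#'   the spontaneous |ees| branch without waiting out domain coarsening.
#' @param init_ee Target ee for `init_mode = "fixed_ee"`.
#' @param batches Number of contiguous batches for standard errors
#'   (>= 10). Default 20.
#' @return An object of class `mc_settings`.
#' @export
mc_settings <- function(seed = 1L, burn_in_sweeps = 2000L,
                        measure_sweeps = 5000L, sample_interval = 1L,
                        init_mode = c("random_racemic", "all_D", "all_L",
                                      "fixed_ee"),
                        init_ee = 0, batches = 20L) {
  init_mode <- match.arg(init_mode)
  seed <- as.integer(seed)
  burn_in_sweeps <- as.integer(burn_in_sweeps)
  measure_sweeps <- as.integer(measure_sweeps)
  sample_interval <- as.integer(sample_interval)
  batches <- as.integer(batches)
  if (is.na(seed)) stop("seed must be an integer")
  if (burn_in_sweeps < 0L) stop("burn_in_sweeps must be >= 0")
  if (measure_sweeps < 1L) stop("measure_sweeps must be >= 1")
  if (sample_interval < 1L) stop("sample_interval must be >= 1")
  if (batches < 10L) stop("batches must be >= 10")
  if (measure_sweeps %/% sample_interval < batches)
    stop("measure_sweeps / sample_interval must be >= batches")
  structure(list(seed = seed, burn_in_sweeps = burn_in_sweeps,
                 measure_sweeps = measure_sweeps,
                 sample_interval = sample_interval, init_mode = init_mode,
                 init_ee = init_ee, batches = batches),
            class = "mc_settings")
}

#' Derive a per-point seed from a base seed and a grid index
#'
#' Fixed mixing rule used by scans so each grid point gets an independent
#' but reproducible stream:
#' `(base * 69069 + 12345 + index * 1000003) mod (2^31 - 1)`, mapped to
#' `1` when the residue is 0. Results always fit a 32-bit signed integer.
#'
#' @param base_seed Integer base seed.
#' @param index Integer grid index (1-based).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, index) {
  m <- 2147483647
  s <- (as.numeric(base_seed) %% m * 69069 + 12345 +
          as.numeric(index) * 1000003) %% m
  s <- as.integer(s)
  if (s <= 0L) s <- s + 1L
  s
}

#' Run Metropolis sweeps on a lattice
#'
#' Performs `sweeps` Metropolis sweeps (N^2 attempted single-site flips
#' per sweep at uniformly random sites) under the current R RNG state;
#' call `set.seed()` beforehand for reproducibility. Flips are accepted
#' with probability `min(1, exp(-dE/(R T)))`, giving detailed balance
#' with respect to `exp(-H/(R T))`.
#'
#' @param lattice A `chirality_lattice`.
#' @param params An [ising_params()] object with finite effective field
#'   (an enantiopure gas freezes the lattice; callers handle that case).
#' @param sweeps Number of sweeps to run.
#' @return The updated `chirality_lattice`.
#' @export
metropolis_sweep <- function(lattice, params, sweeps = 1L) {
  stopifnot(inherits(lattice, "chirality_lattice"),
            inherits(params, "ising_params"))
  h <- effective_field(params)
  if (!is.finite(h))
    stop("metropolis_sweep requires |gas_ee| < 1; an enantiopure gas ",
         "freezes the lattice")
  out <- mc_run_cpp(unclass(lattice), h, pair_coupling(params),
                    rt_energy(params), as.integer(sweeps), 0L, 1L)
  as_lattice(out$lattice)
}

batch_stderr <- function(x, batches) {
  n <- length(x)
  block <- n %/% batches
  idx <- rep(seq_len(batches), each = block)
  means <- tapply(x[seq_len(block * batches)], idx, mean)
  stats::sd(means) / sqrt(batches)
}

new_equilibrium_estimate <- function(mean_ees, mean_abs_ees, std_error_ees,
                                     mean_energy_per_site,
                                     mean_homochiral_fraction, n_samples,
                                     seed, lattice = NULL,
                                     std_error_abs_ees = 0,
                                     std_error_energy = 0,
                                     std_error_homochiral = 0) {
  structure(list(mean_ees = mean_ees, mean_abs_ees = mean_abs_ees,
                 std_error_ees = std_error_ees,
                 std_error_abs_ees = std_error_abs_ees,
                 mean_energy_per_site = mean_energy_per_site,
                 std_error_energy = std_error_energy,
                 mean_homochiral_fraction = mean_homochiral_fraction,
                 std_error_homochiral = std_error_homochiral,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 lattice = lattice),
            class = "equilibrium_estimate")
}

#' @export
print.equilibrium_estimate <- function(x, ...) {
  cat("Equilibrium estimate (Metropolis MC)\n")
  cat(sprintf("  mean ees        : % .5f +/- %.5f (batch-mean SE)\n",
              x$mean_ees, x$std_error_ees))
  cat(sprintf("  mean |ees|      : % .5f\n", x$mean_abs_ees))
  cat(sprintf("  energy per site : % .4f J/mol\n", x$mean_energy_per_site))
  cat(sprintf("  homochiral frac : % .5f\n", x$mean_homochiral_fraction))
  cat(sprintf("  samples, seed   : %d, %d\n", x$n_samples, x$seed))
  invisible(x)
}

#' Equilibrate a lattice and measure equilibrium observables
#'
#' Runs the Metropolis sampler: burn-in, then measurement of the surface
#' enantiomeric excess, energy per site and homochiral pair fraction every
#' `sample_interval` sweeps. The standard error of the mean ees comes from
#' batch means over `batches` contiguous blocks.
#'
#' An enantiopure gas (`gas_ee = +/-1`) short-circuits to the deterministic
#' frozen pure-D or pure-L monolayer without sampling (`ees = +/-1`,
#' homochiral fraction 1, energy reported as `NA` since the field
#' diverges).
#'
#' @param params An [ising_params()] object.
#' @param settings An [mc_settings()] object.
#' @param side Lattice side N. Default 100, the standard simulation size.
#' @param keep_lattice Keep the final configuration in the result (for
#'   snapshot export)? Default `FALSE`.
#' @return An `equilibrium_estimate`: mean ees, mean |ees|, batch-mean
#'   standard error, mean energy per site (J/mol), mean homochiral pair
#'   fraction, sample count and seed.
#' @examples
#' p <- ising_params(460, 2310, gas_ee = 0.05)
#' est <- equilibrate_and_measure(p, mc_settings(seed = 7,
#'   burn_in_sweeps = 50, measure_sweeps = 100), side = 20)
#' est$mean_ees
#' @export
equilibrate_and_measure <- function(params, settings, side = 100L,
                                    keep_lattice = FALSE) {
  stopifnot(inherits(params, "ising_params"),
            inherits(settings, "mc_settings"))
  if (params$gas_ee %in% c(-1, 1)) {
    s <- params$gas_ee
    lat <- if (keep_lattice)
      new_lattice(side, if (s > 0) "all_D" else "all_L") else NULL
    return(new_equilibrium_estimate(s, 1, 0, NA_real_, 1, 0L,
                                    settings$seed, lat))
  }
  set.seed(settings$seed)
  lat <- new_lattice(side, settings$init_mode, settings$init_ee)
  out <- mc_run_cpp(unclass(lat), effective_field(params),
                    pair_coupling(params), rt_energy(params),
                    settings$burn_in_sweeps, settings$measure_sweeps,
                    settings$sample_interval)
  s <- out$samples
  new_equilibrium_estimate(
    mean_ees = mean(s[, 1]),
    mean_abs_ees = mean(abs(s[, 1])),
    std_error_ees = batch_stderr(s[, 1], settings$batches),
    std_error_abs_ees = batch_stderr(abs(s[, 1]), settings$batches),
    mean_energy_per_site = mean(s[, 2]),
    std_error_energy = batch_stderr(s[, 2], settings$batches),
    mean_homochiral_fraction = mean(s[, 3]),
    std_error_homochiral = batch_stderr(s[, 3], settings$batches),
    n_samples = nrow(s), seed = settings$seed,
    lattice = if (keep_lattice) as_lattice(out$lattice) else NULL)
}

#' Scan an adsorption isotherm over gas-phase enantiomeric excess
#'
#' Runs one [equilibrate_and_measure()] per `eeg` value, with independent
#' per-point seeds derived from `settings$seed` and the grid index through
#' [derive_seed()]. This is the simulated ees-versus-eeg isotherm; for a
#' positive exchange energy above the critical temperature it shows
#' auto-amplification, `|ees| >= |eeg|`, with exact equality at
#' `eeg = 0, +/-1`.
#'
#' @param params_base An [ising_params()] object; its `gas_ee` is replaced
#'   by each grid value in turn.
#' @param eeg_values Strictly increasing vector of gas-phase ee values in
#'   \[-1, 1\]; duplicates are rejected.
#' @param settings An [mc_settings()] object.
#' @param side Lattice side N. Default 100.
#' @return An `ising_isotherm` data frame with columns `eeg`, `ees_mean`,
#'   `ees_abs_mean`, `ees_stderr`, `energy_per_site`,
#'   `homochiral_fraction`, `n_samples`, `seed`, plus `params` and
#'   `settings` attributes.
#' @export
isotherm_scan <- function(params_base, eeg_values, settings, side = 100L) {
  stopifnot(inherits(params_base, "ising_params"),
            inherits(settings, "mc_settings"))
  eeg_values <- as.numeric(eeg_values)
  if (length(eeg_values) < 1L) stop("eeg_values must be non-empty")
  if (any(eeg_values < -1 | eeg_values > 1))
    stop("eeg values must lie in [-1, 1]")
  if (any(duplicated(eeg_values))) stop("duplicate eeg values")
  if (is.unsorted(eeg_values, strictly = TRUE))
    stop("eeg values must be strictly increasing")
  rows <- lapply(seq_along(eeg_values), function(k) {
    p <- ising_params(params_base$temperature, params_base$exch_energy,
                      params_base$ads_energy_diff, eeg_values[k])
    st <- settings
    st$seed <- derive_seed(settings$seed, k)
    est <- equilibrate_and_measure(p, st, side)
    data.frame(eeg = eeg_values[k], ees_mean = est$mean_ees,
               ees_abs_mean = est$mean_abs_ees,
               ees_stderr = est$std_error_ees,
               energy_per_site = est$mean_energy_per_site,
               homochiral_fraction = est$mean_homochiral_fraction,
               n_samples = est$n_samples, seed = est$seed)
  })
  res <- do.call(rbind, rows)
  params_noee <- params_base[c("temperature", "exch_energy",
                               "ads_energy_diff", "gas_constant")]
  structure(res, params = params_noee, settings = unclass(settings),
            side = as.integer(side),
            class = c("ising_isotherm", "data.frame"))
}
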