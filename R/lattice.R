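#' Saturated chirality lattice
#'
#' An N x N periodic square grid of chirality labels, +1 for the D
#' enantiomer and -1 for L. The lattice is always saturated: every site
#' holds exactly one adsorbate, so coverage theta_D + theta_L = 1 and the
#' system maps onto a two-state Ising model.
#'
#' @param side Lattice side N (integer, >= 3; 2x2 is rejected because the
#'   periodic left/right and up/down neighbours of a site coincide).
#' @param init One of `"random_racemic"` (each site iid +/-1), `"all_D"`,
#'   `"all_L"`, or `"fixed_ee"` (a random arrangement with the D count
#'   matching `init_ee` as closely as integer counts allow).
#' @param init_ee Target surface ee for `init = "fixed_ee"`.
#' @return Integer matrix of +/-1 with class `chirality_lattice`.
#' @examples
#' set.seed(1)
#' lat <- new_lattice(8)
#' surface_ee(lat)
#' @export
new_lattice <- function(side,
                        init = c("random_racemic", "all_D", "all_L",
                                 "fixed_ee"),
                        init_ee = 0) {
  init <- match.arg(init)
  side <- as.integer(side)
  if (is.na(side) || side < 3L) stop("lattice side must be an integer >= 3")
  n2 <- side * side
  chi <- switch(init,
    random_racemic = sample(c(-1L, 1L), n2, replace = TRUE),
    all_D = rep(1L, n2),
    all_L = rep(-1L, n2),
    fixed_ee = {
      if (init_ee < -1 || init_ee > 1) stop("init_ee must lie in [-1, 1]")
      n_d <- round((1 + init_ee) / 2 * n2)
      sample(c(rep(1L, n_d), rep(-1L, n2 - n_d)))
    })
  as_lattice(matrix(chi, side, side))
}

#' Validate and class a +/-1 matrix as a chirality lattice
#' @param chi Square integer matrix with entries +1 (D) or -1 (L).
#' @return The matrix with class `chirality_lattice`.
#' @export
as_lattice <- function(chi) {
  if (!is.matrix(chi) || nrow(chi) != ncol(chi))
    stop("lattice must be a square matrix")
  if (nrow(chi) < 3L) stop("lattice side must be >= 3")
  if (!all(chi == 1L | chi == -1L))
    stop("lattice entries must all be +1 (D) or -1 (L)")
  storage.mode(chi) <- "integer"
  structure(chi, class = "chirality_lattice")
}

#' @export
print.chirality_lattice <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("chirality_lattice %d x %d (periodic), ees = %.4f\n",
              n, n, surface_ee(x)))
  invisible(x)
}

#' Surface enantiomeric excess of a lattice
#'
#' `ees = (n_D - n_L) / (n_D + n_L)` = mean of the chirality labels.
#' Positive values mean a D excess.
#'
#' @param lattice A `chirality_lattice`.
#' @return Dimensionless value in \[-1, 1\].
#' @export
surface_ee <- function(lattice) {
  stopifnot(inherits(lattice, "chirality_lattice"))
  mean(lattice)
}

# Periodic row/column shifts used by the energy bookkeeping. Each site's
# right and down neighbour generates every unordered NN pair exactly once
# (2 N^2 pairs on the torus).
shift_down <- function(m) m[c(nrow(m), seq_len(nrow(m) - 1L)), , drop = FALSE]
shift_right <- function(m) m[, c(ncol(m), seq_len(ncol(m) - 1L)), drop = FALSE]

#' Sum of chi_i * chi_j over unordered periodic NN pairs
#' @keywords internal
pair_sum <- function(lattice) {
  sum(lattice * shift_down(lattice)) + sum(lattice * shift_right(lattice))
}

#' Fraction of homochiral nearest-neighbour pairs
#'
#' Fraction of the 2 N^2 unordered periodic nearest-neighbour pairs whose
#' two sites hold the same enantiomer. 1 for an enantiopure monolayer,
#' 0 for a perfect checkerboard, about 0.5 for uncorrelated sites. This is
#' the clustering diagnostic: above-critical equilibria with positive
#' exchange energy show homochiral clustering even when ees = 0.
#'
#' @param lattice A `chirality_lattice`.
#' @return Dimensionless value in \[0, 1\].
#' @export
homochiral_pair_fraction <- function(lattice) {
  stopifnot(inherits(lattice, "chirality_lattice"))
  n_pairs <- 2 * length(lattice)
  (1 + pair_sum(lattice) / n_pairs) / 2
}

#' Total configurational energy of a lattice
#'
#' Evaluates the saturated-monolayer Hamiltonian
#' `H = -h * sum_i chi_i - J_pair * sum_{unordered NN pairs} chi_i chi_j`
#' with periodic boundaries, where `h` is [effective_field()] and `J_pair`
#' is [pair_coupling()]. Each unordered pair is counted exactly once.
#'
#' @param lattice A `chirality_lattice`.
#' @param params An [ising_params()] object with `|gas_ee| < 1` (an
#'   enantiopure gas gives a divergent field and is rejected).
#' @return Energy in J/mol.
#' @export
total_energy <- function(lattice, params) {
  stopifnot(inherits(lattice, "chirality_lattice"))
  h <- effective_field(params)
  if (!is.finite(h))
    stop("total_energy is undefined for an enantiopure gas (gas_ee = +/-1)")
  -h * sum(lattice) - pair_coupling(params) * pair_sum(lattice)
}

#' Energy change of a single chirality flip
#'
#' Exact increment `total_energy(after flip) - total_energy(before)` for
#' flipping the enantiomer at one site:
#' `dE = 2 chi_site (h + J_pair * sum of the 4 periodic neighbours)`.
#'
#' @param lattice A `chirality_lattice`.
#' @param params An [ising_params()] object with finite field.
#' @param site Integer vector `c(row, col)`, 1-based.
#' @return Energy difference in J/mol.
#' @export
flip_delta_energy <- function(lattice, params, site) {
  stopifnot(inherits(lattice, "chirality_lattice"))
  h <- effective_field(params)
  if (!is.finite(h))
    stop("flip_delta_energy is undefined for an enantiopure gas")
  n <- nrow(lattice)
  i <- as.integer(site[1L]); j <- as.integer(site[2L])
  if (is.na(i) || is.na(j) || i < 1L || i > n || j < 1L || j > n)
    stop("site out of bounds")
  up <- if (i == 1L) n else i - 1L
  dn <- if (i == n) 1L else i + 1L
  lf <- if (j == 1L) n else j - 1L
  rt <- if (j == n) 1L else j + 1L
  nn <- lattice[up, j] + lattice[dn, j] + lattice[i, lf] + lattice[i, rt]
  2 * lattice[i, j] * (h + pair_coupling(params) * nn)
}

#' Export a lattice as a D/L label grid
#'
#' Row-major character grid of `"D"`/`"L"` labels, suitable for CSV export
#' and plotting; [grid_to_lattice()] is its lossless inverse.
#'
#' @param lattice A `chirality_lattice`.
#' @return Character matrix of `"D"` and `"L"`.
#' @export
snapshot <- function(lattice) {
  stopifnot(inherits(lattice, "chirality_lattice"))
  m <- matrix(ifelse(unclass(lattice) == 1L, "D", "L"),
              nrow(lattice), ncol(lattice))
  m
}

#' Rebuild a lattice from a D/L label grid
#' @param grid Character matrix of `"D"`/`"L"` (as produced by [snapshot()]).
#' @return A `chirality_lattice`.
#' @export
grid_to_lattice <- function(grid) {
  if (!all(grid %in% c("D", "L"))) stop("grid entries must be 'D' or 'L'")
  as_lattice(matrix(ifelse(grid == "D", 1L, -1L), nrow(grid), ncol(grid)))
}
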