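test_that("parameter invariants are enforced", {
  expect_error(ising_params(0, 2310), "temperature")
  expect_error(ising_params(-10, 2310), "temperature")
  expect_error(ising_params(460, 2310, gas_ee = 1.5), "gas_ee")
  p <- ising_params(460, 2310, gas_ee = 0.3)
  expect_identical(p$gas_constant, 8.314)
})

test_that("effective field matches the closed form and its sentinels", {
  # racemic gas on an achiral surface: both field terms vanish
  expect_identical(effective_field(ising_params(460, 2310, 0, 0)), 0)
  # frozen high-precision value at eeg = 0.05 (spin convention: half the
  # D/L per-site energy difference)
  expect_equal(effective_field(ising_params(460, 2310, 0, 0.05)),
               FROZEN$spin_field_460_ee005, tolerance = 1e-12)
  # 2h is the full per-site D/L energy difference
  expect_equal(2 * effective_field(ising_params(460, 0, 0, 0.05)),
               FROZEN$field_coeff_460_ee005, tolerance = 1e-12)
  # enantiopure gas: signed infinite sentinel
  expect_identical(effective_field(ising_params(460, 2310, 0, 1)), Inf)
  expect_identical(effective_field(ising_params(460, 2310, 0, -1)), -Inf)
  # adsorption-energy difference enters with the same spin factor 1/2
  expect_equal(effective_field(ising_params(460, 2310, 500, 0)), 250)
})

test_that("pair coupling is half the exchange energy, sign passed through", {
  expect_equal(pair_coupling(ising_params(460, 2310)), 1155)
  expect_equal(pair_coupling(ising_params(460, 0)), 0)
  expect_equal(pair_coupling(ising_params(460, -2310)), -1155)
})

test_that("total energy matches hand counts and the brute-force oracle", {
  p <- ising_params(300, 2000, gas_ee = 0)  # h = 0, J_pair = 1000
  jp <- pair_coupling(p)
  n <- 4
  allD <- as_lattice(matrix(1L, n, n))
  expect_equal(total_energy(allD, p), -2 * n^2 * jp)
  expect_equal(total_energy(checkerboard(n), p), +2 * n^2 * jp)

  # random lattices, finite field, against the independent enumeration
  p2 <- ising_params(350, 1500, 200, 0.2)
  h2 <- effective_field(p2); jp2 <- pair_coupling(p2)
  set.seed(42)
  for (rep in 1:5) {
    lat <- random_lattice(3)
    expect_equal(total_energy(lat, p2), brute_energy(lat, h2, jp2))
  }
  expect_error(total_energy(allD, ising_params(460, 0, gas_ee = 1)),
               "enantiopure")
})

test_that("total energy is extensive and spin-flip symmetric at h = 0", {
  p <- ising_params(400, 1800, gas_ee = 0)
  set.seed(7)
  lat3 <- random_lattice(3)
  # replicate the 3x3 pattern onto 6x6: energy scales by 4
  lat6 <- as_lattice(rbind(cbind(lat3, lat3), cbind(lat3, lat3)))
  expect_equal(total_energy(lat6, p), 4 * total_energy(lat3, p))
  # global chirality flip leaves the h = 0 energy unchanged, negates ees
  flipped <- as_lattice(-unclass(lat3))
  expect_equal(total_energy(flipped, p), total_energy(lat3, p))
  expect_equal(surface_ee(flipped), -surface_ee(lat3))
})

test_that("flip_delta_energy is an exact increment of total_energy", {
  p <- ising_params(320, 2100, 150, 0.1)
  # hand case: centre of all-D 3x3 at h = 0 breaks 4 aligned bonds
  p0 <- ising_params(320, 2100, 0, 0)
  allD3 <- as_lattice(matrix(1L, 3, 3))
  expect_equal(flip_delta_energy(allD3, p0, c(2, 2)),
               8 * pair_coupling(p0))
  # balanced neighbours at h = 0 cost nothing
  bal <- as_lattice(matrix(c(1L, -1L, 1L,
                             -1L, 1L, 1L,
                             1L, 1L, -1L), 3, 3, byrow = TRUE))
  # site (1,1): neighbours are (3,1)=1,(2,1)=-1,(1,3)=1,(1,2)=-1 -> sum 0
  expect_equal(flip_delta_energy(bal, p0, c(1, 1)), 0)

  set.seed(99)
  for (rep in 1:100) {
    n <- sample(3:6, 1)
    lat <- random_lattice(n)
    site <- sample(n, 2, replace = TRUE)
    after <- unclass(lat)
    after[site[1], site[2]] <- -after[site[1], site[2]]
    expect_equal(flip_delta_energy(lat, p, site),
                 total_energy(as_lattice(after), p) -
                   total_energy(lat, p))
  }
  expect_error(flip_delta_energy(allD3, p, c(4, 1)), "bounds")
})

test_that("surface_ee and homochiral_pair_fraction count correctly", {
  allD <- as_lattice(matrix(1L, 3, 3))
  expect_identical(surface_ee(allD), 1)
  expect_identical(homochiral_pair_fraction(allD), 1)
  cb <- checkerboard(4)
  expect_identical(surface_ee(cb), 0)
  expect_identical(homochiral_pair_fraction(cb), 0)
  # 6 D and 3 L on 3x3
  mix <- as_lattice(matrix(c(rep(1L, 6), rep(-1L, 3)), 3, 3))
  expect_equal(surface_ee(mix), 1 / 3)
  # single L in all-D 3x3 touches 4 of the 18 pairs
  oneL <- as_lattice(matrix(c(rep(1L, 4), -1L, rep(1L, 4)), 3, 3))
  expect_equal(homochiral_pair_fraction(oneL), 7 / 9)
})

test_that("homochiral fraction identity holds on random lattices", {
  p <- ising_params(300, 1000, gas_ee = 0)
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    lat <- random_lattice(n)
    # energy at h=0, J_pair=1 encodes the pair sum
    pairsum <- -total_energy(lat, ising_params(300, 2, gas_ee = 0))
    expect_equal(homochiral_pair_fraction(lat),
                 (1 + pairsum / (2 * n^2)) / 2)
  }
})

test_that("lattice constructors enforce the saturated two-state contract", {
  expect_error(new_lattice(2), ">= 3")
  expect_error(as_lattice(matrix(0L, 3, 3)), "\\+1")
  expect_error(as_lattice(matrix(1L, 3, 4)), "square")
  set.seed(1)
  lat <- new_lattice(10, "fixed_ee", init_ee = 0.5)
  expect_equal(surface_ee(lat), 0.5, tolerance = 0.03)
  expect_identical(surface_ee(new_lattice(5, "all_L")), -1)
})
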