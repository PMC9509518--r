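# CSDA ranges and the condensed-history voxel deposition simulator.

test_that("CSDA ranges are monotone, plausible and match a fine-grid quadrature oracle", {
  e <- c(1, 5, 10, 50, 100, 500, 1000, 5000, 1e4)
  r <- csda_range(e)
  expect_true(all(diff(r) > 0))
  expect_gt(csda_range(100), csda_range(10))
  # electrons at the mean lutetium-177 beta energy travel ~0.23 mm
  expect_gt(csda_range(133), 150)
  expect_lt(csda_range(133), 350)
  expect_error(csda_range(0.5), "\\[1, 1e4\\]")
  expect_error(csda_range(2e4), "\\[1, 1e4\\]")
  # oracle: trapezoid integration of the inverse stopping power on a grid
  # 10x denser than the internal one
  tab <- stopping_power_table()
  fine <- exp(seq(log(0.5), log(1e4), length.out = 4000))
  s <- exp(approx(log(tab$energy_keV), log(tab$collision + tab$radiative),
                  xout = log(pmin(pmax(fine, 1), 1e4)), rule = 2)$y)
  inv <- 1 / (s * 1000)
  r0 <- fine[1] * inv[1] / 1.75
  cum <- r0 + c(0, cumsum((inv[-1] + inv[-length(inv)]) * diff(fine) / 2))
  cum_um <- cum / 1.03 * 1e4
  for (E in c(10, 100, 1000, 9000)) {
    oracle <- exp(approx(log(fine), log(cum_um), xout = log(E))$y)
    expect_equal(csda_range(E), oracle, tolerance = 5e-3)
  }
})

test_that("a 1 keV emitter deposits essentially everything in the central voxel", {
  nuc <- radionuclide("cold", 1, list(),
                      list(discrete_emission(1, 1, "auger")))
  cfg <- transport_config(n_decays = 2000, voxel_side_um = 50,
                          tally_extent_um = 100, seed = 1)
  t <- simulate_point_source(nuc, cfg)
  c_idx <- t$half_n + 1
  expect_gt(t$grid[c_idx, c_idx, c_idx] / t$total_emitted_keV, 0.99)
})

test_that("fixed seeds reproduce tallies exactly", {
  nuc <- bundled_nuclide("lu177")
  cfg <- transport_config(n_decays = 500, voxel_side_um = 50,
                          tally_extent_um = 100, seed = 99)
  t1 <- simulate_point_source(nuc, cfg)
  t2 <- simulate_point_source(nuc, cfg)
  expect_identical(t1$grid, t2$grid)
  expect_identical(t1$total_deposited_keV, t2$total_deposited_keV)
})

test_that("percentile radii are monotone and respect nuclide range ordering", {
  cfg <- transport_config(n_decays = 2000, voxel_side_um = 50,
                          tally_extent_um = 50, seed = 5)
  tb <- simulate_point_source(bundled_nuclide("tb161"), cfg)
  y <- simulate_point_source(bundled_nuclide("y90"), cfg)
  r_tb <- energy_percentile_radii(tb, c(30, 50, 90))
  r_y <- energy_percentile_radii(y, c(30, 50, 90))
  expect_true(all(diff(r_tb) >= 0))
  expect_true(all(diff(r_y) >= 0))
  expect_true(all(r_tb < r_y))
  expect_error(energy_percentile_radii(tb, c(0, 50)), "between 0 and 100")
  # delta-like tally: a 1 keV emitter concentrates everything near origin
  cold <- simulate_point_source(
    radionuclide("cold", 1, list(), list(discrete_emission(1, 1, "auger"))),
    transport_config(n_decays = 500, voxel_side_um = 10,
                     tally_extent_um = 10, seed = 2))
  r_cold <- energy_percentile_radii(cold, c(30, 50, 90))
  expect_true(all(r_cold <= sqrt(3) * 10))
})

test_that("energy is conserved up to the radiative (escaping) share", {
  for (n in c("tb161", "y90")) {
    t <- simulate_point_source(
      bundled_nuclide(n),
      transport_config(n_decays = 1000, voxel_side_um = 50,
                       tally_extent_um = 50, seed = 3))
    expect_lte(t$total_deposited_keV, t$total_emitted_keV * (1 + 1e-12))
    expect_gte(t$total_deposited_keV / t$total_emitted_keV, 0.95)
    expect_true(all(t$grid >= 0))
  }
})

test_that("self-absorbed fraction shrinks with voxel size and its SE scales as 1/sqrt(n)", {
  nuc <- bundled_nuclide("tb161")
  f50 <- central_voxel_fraction(nuc, 50,
                                transport_config(n_decays = 3000, seed = 8,
                                                 tally_extent_um = 50))
  f8 <- central_voxel_fraction(nuc, 8.2,
                               transport_config(n_decays = 3000, seed = 8,
                                                tally_extent_um = 50))
  expect_lt(f8$fraction, f50$fraction)
  expect_gt(f8$fraction, 0)
  se1 <- central_voxel_fraction(nuc, 50,
                                transport_config(n_decays = 1000, seed = 4,
                                                 tally_extent_um = 50))$se
  se9 <- central_voxel_fraction(nuc, 50,
                                transport_config(n_decays = 9000, seed = 4,
                                                 tally_extent_um = 50))$se
  expect_gt(se1 / se9, 2)
  expect_lt(se1 / se9, 4.5)
})

test_that("deposition agrees with a straight-ahead CSDA oracle at the right scale", {
  # straight tracks: energy within radius r equals the energy lost over the
  # first r micrometres of path; scattering can only pull deposition inward
  nuc <- bundled_nuclide("y90")
  cfg <- transport_config(n_decays = 4000, voxel_side_um = 50,
                          tally_extent_um = 50, seed = 13)
  t <- simulate_point_source(nuc, cfg)
  prof <- radial_profile(t)
  sp <- composite_electron_spectrum(nuc)$spectrum
  g <- marrowdose:::transport_grid()
  e_at_range <- function(r) exp(approx(log(g$range_um), log(g$energy_keV),
                                       xout = log(pmax(r, min(g$range_um))),
                                       rule = 2)$y)
  straight_frac <- function(r) {
    rng <- exp(approx(log(g$energy_keV), log(g$range_um),
                      xout = log(pmax(sp$grid, 0.5)), rule = 2)$y)
    lost <- ifelse(rng <= r, sp$grid, sp$grid - e_at_range(rng - r))
    sum(sp$density * lost) / sum(sp$density * sp$grid)
  }
  for (r in c(100, 200, 500)) {
    sim <- prof$cumulative_fraction[which.min(abs(prof$r_um - r))]
    oracle <- straight_frac(r)
    expect_gt(sim, 0.8 * oracle)   # not below the ballistic expectation
    expect_lt(sim, 3.0 * oracle)   # inward-pulled, but same scale
  }
  # cumulative deposition grows with radius and is small at 200 um
  f200 <- prof$cumulative_fraction[which.min(abs(prof$r_um - 200))]
  expect_lt(f200, 0.2)
  expect_true(all(diff(prof$cumulative_fraction) >= 0))
})

test_that("tally export writes flat TSV, radial profile and manifest", {
  nuc <- bundled_nuclide("lu177")
  cfg <- transport_config(n_decays = 200, voxel_side_um = 50,
                          tally_extent_um = 100, seed = 6)
  t <- simulate_point_source(nuc, cfg)
  dir <- tempfile()
  write_tally(t, dir)
  files <- list.files(dir)
  expect_true(any(grepl("_tally\\.tsv$", files)))
  expect_true(any(grepl("_radial\\.tsv$", files)))
  mf <- jsonlite::read_json(list.files(dir, "manifest", full.names = TRUE)[1])
  expect_equal(mf$seed, 6)
  expect_equal(mf$n_decays, 200)
  flat <- read.delim(list.files(dir, "_tally", full.names = TRUE)[1])
  expect_equal(sum(flat$energy_keV <= 0), 0)
  expect_true(all(abs(flat$ix) <= t$half_n))
})
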