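# Continuous beta spectra, discrete lines and per-decay summaries.

test_that("branch spectra integrate to the branching fraction and vanish for zero yield", {
  grid <- default_energy_grid(600)
  for (seed in 1:5) {
    set.seed(seed)
    b <- beta_branch(runif(1, 100, 590), runif(1, 0.05, 1), sample(20:80, 1))
    sp <- build_beta_spectrum(b, grid)
    expect_equal(marrowdose:::trapz(sp$grid, sp$density), b$fraction,
                 tolerance = 1e-12)
    expect_true(all(sp$density >= 0))
  }
  zero <- build_beta_spectrum(beta_branch(300, 0, 50), grid)
  expect_identical(zero$density, rep(0, length(grid)))
})

test_that("allowed spectrum with F = 1 matches a fine-grid quadrature oracle", {
  q <- 100
  b <- beta_branch(q, 1, 0)  # Z = 0 switches off the Coulomb correction
  sp <- build_beta_spectrum(b, seq(0.02, q, by = 0.02))
  mean_pkg <- marrowdose:::trapz(sp$grid, sp$grid * sp$density) /
    marrowdose:::trapz(sp$grid, sp$density)
  # independent oracle: Riemann sum of p * W * (Q - E)^2 on a 1e5-point grid
  e <- seq(q / 2e5, q - q / 2e5, length.out = 1e5)
  w <- 1 + e / 510.998950
  p <- sqrt(w^2 - 1)
  d <- p * w * (q - e)^2
  mean_oracle <- sum(d * e) / sum(d)
  expect_equal(mean_pkg, mean_oracle, tolerance = 1e-3)
  # integral over the package grid equals the branching fraction
  expect_equal(marrowdose:::trapz(sp$grid, sp$density), 1, tolerance = 1e-12)
})

test_that("bundled nuclides reproduce the reference per-decay summaries", {
  means <- c(lu177 = 133, tb161 = 154, y90 = 933)
  totals <- c(lu177 = 148.0, tb161 = 202.5, y90 = 933.1)
  for (n in names(means)) {
    nuc <- bundled_nuclide(n)
    expect_lt(abs(mean_beta_energy(nuc) / means[[n]] - 1), 0.03)
    expect_lt(abs(total_electron_energy(nuc) / totals[[n]] - 1), 0.03)
  }
  expect_equal(count_electrons_below(bundled_nuclide("tb161"), 50), 12.36,
               tolerance = 1e-8)
  expect_equal(bundled_nuclide("lu177")$half_life_days, 6.65)
})

test_that("composite spectrum is linear in branches and passes lines through", {
  grid <- default_energy_grid(500)
  one <- radionuclide("one", 1, list(beta_branch(400, 1, 40)),
                      list(discrete_emission(10, 0.5, "auger")))
  two <- radionuclide("two", 1, list(beta_branch(400, 0.5, 40),
                                     beta_branch(400, 0.5, 40)))
  c1 <- composite_electron_spectrum(one, grid)
  c2 <- composite_electron_spectrum(two, grid)
  expect_equal(c1$spectrum$density, c2$spectrum$density, tolerance = 1e-12)
  expect_equal(c1$discrete$energy_keV, 10)
  expect_equal(c1$discrete$yield, 0.5)
  none <- radionuclide("none", 1, list(),
                       list(discrete_emission(20, 2, "conversion")))
  cn <- composite_electron_spectrum(none, grid)
  expect_true(all(cn$spectrum$density == 0))
  expect_equal(total_electron_energy(none), 40)
})

test_that("summary operations handle counts, thresholds and degenerate input", {
  fix <- radionuclide("fix", 1, list(), list(
    discrete_emission(10, 0.5, "auger"),
    discrete_emission(40, 0.25, "conversion"),
    discrete_emission(60, 1.0, "conversion")))
  expect_equal(count_electrons_below(fix, 50), 0.75)
  expect_equal(count_electrons_below(fix, 5), 0)
  expect_error(count_electrons_below(fix, -1), "threshold")
  expect_error(mean_beta_energy(fix), "no beta branches")
  empty <- radionuclide("empty", 1)
  expect_equal(total_electron_energy(empty), 0)
})

test_that("energy bookkeeping ties the total to spectrum and lines", {
  for (seed in c(3, 11)) {
    nuc <- random_nuclide(seed)
    cs <- composite_electron_spectrum(nuc)
    expected <- marrowdose:::trapz(cs$spectrum$grid,
                                   cs$spectrum$grid * cs$spectrum$density) +
      sum(cs$discrete$yield * cs$discrete$energy_keV)
    expect_equal(total_electron_energy(nuc), expected, tolerance = 1e-10)
  }
})

test_that("decay tables round-trip and malformed input is rejected with line numbers", {
  for (n in c("lu177", "tb161", "y90")) {
    path <- system.file("extdata", "decay", paste0(n, ".tsv"),
                        package = "marrowdose")
    tmp <- tempfile(fileext = ".tsv")
    write_decay_table(read_decay_table(path), tmp)
    expect_identical(readLines(tmp), readLines(path))
    back <- read_decay_table(tmp)
    orig <- read_decay_table(path)
    expect_equal(back, orig)
  }
  empty <- tempfile(); file.create(empty)
  expect_error(read_decay_table(empty), "empty")
  bad <- tempfile()
  writeLines(c("name\tx", "half_life_d\t1", "[beta]",
               "100\t0.5\t40\tnot_a_kind"), bad)
  expect_error(read_decay_table(bad), ":4:.*not_a_kind")
  neg <- tempfile()
  writeLines(c("name\tx", "half_life_d\t1", "[discrete]",
               "50\t-0.2\tauger"), neg)
  expect_error(read_decay_table(neg), ":4:")
})

test_that("build_beta_spectrum validates its inputs", {
  b <- beta_branch(100, 0.5, 40)
  expect_error(build_beta_spectrum(b, numeric(0)), "two finite")
  expect_error(build_beta_spectrum(b, c(1, 50)), "below")
  expect_error(build_beta_spectrum(b, c(50, 10, 110)), "increasing")
  expect_error(beta_branch(-5, 0.5, 40), "endpoint")
})
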