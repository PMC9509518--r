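# S-value convolution, averaging formulas, cellularity and ratios.

KEV_J <- 1.602176634e-16

test_that("constant-SAF S-values reduce to total energy times SAF", {
  nuc <- random_nuclide(21)
  tb <- const_saf(0.37)
  expected <- total_electron_energy(nuc) * KEV_J * 0.37 * 1e9
  expect_equal(site_s_value(nuc, tb), expected, tolerance = 1e-10)
  none <- radionuclide("none", 1)
  expect_equal(site_s_value(none, tb), 0)
})

test_that("a single 100 keV line against SAF 2/kg gives the hand-computed S-value", {
  nuc <- radionuclide("line", 1, list(),
                      list(discrete_emission(100, 1, "conversion")))
  tb <- const_saf(2)
  expect_equal(site_s_value(nuc, tb), 3.204353268e-5, tolerance = 1e-9)
})

test_that("engine matches the brute-force term-sum oracle", {
  for (seed in c(1, 7, 23)) {
    nuc <- random_nuclide(seed)
    tb <- random_saf_table(seed)
    expect_equal(site_s_value(nuc, tb), brute_force_svalue(nuc, tb),
                 tolerance = 1e-3)
  }
})

test_that("S-values are linear in emission yields", {
  nuc <- random_nuclide(5)
  doubled <- radionuclide(
    "x2", 1,
    lapply(nuc$beta_branches, function(b)
      beta_branch(b$endpoint_keV, min(1, 2 * b$fraction) , b$daughter_Z,
                  b$kind)),
    lapply(nuc$discrete, function(d)
      discrete_emission(d$energy_keV, 2 * d$yield, d$kind)))
  # scale check done on the discrete part alone to keep fractions legal
  lines_only <- radionuclide("l", 1, list(), nuc$discrete)
  lines_x2 <- radionuclide("l2", 1, list(),
                           lapply(nuc$discrete, function(d)
                             discrete_emission(d$energy_keV, 2 * d$yield,
                                               d$kind)))
  tb <- random_saf_table(5)
  expect_equal(site_s_value(lines_x2, tb), 2 * site_s_value(lines_only, tb),
               tolerance = 1e-12)
})

test_that("skeletal averaging reproduces hand-evaluated weights", {
  nuc <- radionuclide("line", 1, list(),
                      list(discrete_emission(100, 1, "conversion")))
  # single site: the average is that site's S-value
  one <- toy_skeleton(1, 0.5, 0.8)
  sv1 <- svalue_set(nuc, one)
  expect_equal(skeletal_average(sv1, one, "AM"),
               marrowdose:::lookup_s(sv1, "site_a", "AM"), tolerance = 1e-12)
  # two sites, equal target and source masses: (a + b) / 4
  two <- toy_skeleton(c(1, 1), c(0.5, 0.5), c(1, 1))
  # give the sites different S-values via different SAF magnitudes
  cc <- 1 / 1.5
  tabs <- list(const_saf(0.10, site = "site_a", source = "AM",
                         cellularity = cc),
               const_saf(0.30, site = "site_b", source = "AM",
                         cellularity = cc))
  for (src in c("IM", "TBV", "TBS")) {
    tabs <- c(tabs, list(const_saf(0.05, site = "site_a", source = src,
                                   cellularity = cc),
                         const_saf(0.05, site = "site_b", source = src,
                                   cellularity = cc)))
  }
  sites <- lapply(c("site_a", "site_b"), function(nm)
    skeletal_site(nm, 1, 0.5, 1, 1 / 1.5))
  m2 <- skeleton_model("male", sites, tabs, n_sites = 2)
  sv2 <- svalue_set(nuc, m2)
  a <- marrowdose:::lookup_s(sv2, "site_a", "AM")
  b <- marrowdose:::lookup_s(sv2, "site_b", "AM")
  expect_equal(skeletal_average(sv2, m2, "AM"), (a + b) / 4,
               tolerance = 1e-14)
  expect_error(skeletal_average(sv1, two, "AM"), "site_b")
})

test_that("spongiosa averaging is the mass-weighted source mix", {
  nuc <- radionuclide("line", 1, list(),
                      list(discrete_emission(100, 1, "conversion")))
  # equal AM/IM/TB masses: arithmetic mean of the three source averages
  eq <- toy_skeleton(1, 1, 1, cellularity = 0.5)
  sv <- svalue_set(nuc, eq)
  means <- vapply(c("AM", "IM", "TBS"), function(src)
    skeletal_average(sv, eq, src), numeric(1))
  expect_equal(spongiosa_s_value(sv, eq), mean(means), tolerance = 1e-14)
  # all mass in one compartment: that compartment's S-value
  am_only <- toy_skeleton(1, 0, 1e-12, cellularity = 1)
  sv_am <- svalue_set(nuc, am_only)
  expect_equal(spongiosa_s_value(sv_am, am_only),
               skeletal_average(sv_am, am_only, "AM"), tolerance = 1e-9)
})

test_that("cellularity follows the volume definition", {
  expect_equal(cellularity(7, 3), 0.7)
  expect_equal(cellularity(1, 0), 1)
  expect_equal(cellularity(0, 1), 0)
  expect_error(cellularity(0, 0), "both volumes")
  expect_error(cellularity(-1, 1), ">= 0")
})

test_that("cellularity curves equal the generator's closed form when S scales as 1/c", {
  nuc <- bundled_nuclide("tb161")
  # synthetic tables built with Phi(E; c) = Phi(E) * c_ref / c (w = 0)
  cfg <- synthetic_config(seed = 3, cell_w_max = 0)
  model <- generate_skeleton(cfg)
  site <- "lumbar_vertebrae"
  ref_c <- model$sites[[site]]$cellularity
  cc <- c(0.1, 0.3, 0.7, 1)
  curve <- cellularity_curve(nuc, model, site, cc)
  expect_equal(unname(curve), ref_c / cc, tolerance = 1e-9)
  expect_equal(unname(curve[cc == ref_c]), 1)
  # generic model: S rises monotonically as cellularity drops (cf. observed
  # low-cellularity amplification of self-irradiation)
  model2 <- generate_skeleton(synthetic_config(seed = 3))
  curve2 <- cellularity_curve(nuc, model2, site, seq(0.1, 1, 0.1))
  expect_true(all(diff(unname(curve2)) < 0))
})

test_that("rudimentary ratio recovers closed forms", {
  nuc <- bundled_nuclide("lu177")
  mass <- 1.17
  rud <- total_electron_energy(nuc) * KEV_J / mass * 1e9
  expect_equal(rudimentary_ratio(nuc, mass, rud), 1, tolerance = 1e-10)
  expect_equal(rudimentary_ratio(nuc, mass, rud / 2), 2, tolerance = 1e-10)
  expect_error(rudimentary_ratio(nuc, 0, 1), "mass_AM")
})

test_that("source and nuclide orderings hold on the synthetic skeleton", {
  model <- generate_skeleton(synthetic_config(seed = 1))
  nucs <- lapply(c("lu177", "tb161", "y90"), bundled_nuclide)
  avg <- sapply(nucs, function(nuc) {
    sv <- svalue_set(nuc, model)
    vapply(c("AM", "TBS", "IM", "TBV"), function(src)
      skeletal_average(sv, model, src), numeric(1))
  })
  colnames(avg) <- c("lu177", "tb161", "y90")
  for (n in colnames(avg)) {
    expect_true(avg["AM", n] >= avg["TBS", n])
    expect_true(avg["TBS", n] >= avg["IM", n])
    expect_true(avg["IM", n] >= avg["TBV", n])
  }
  for (src in rownames(avg)) {
    expect_gt(avg[src, "y90"], avg[src, "tb161"])
    expect_gt(avg[src, "tb161"], avg[src, "lu177"])
  }
})
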