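test_that("energy spec and model params validate their domains", {
  expect_error(beam_energy_spec(-70, 4), "energy")
  expect_error(beam_energy_spec(200, 0), "sigma0")
  for (e in c(70, 110, 150, 200, 240))
    for (s in c(2, 4, 11, 21, 42))
      expect_s3_class(beam_energy_spec(e, s), "vhee_energy_spec")
  p <- analytic_model_params()
  expect_equal(p$radiation_length_water, 360.8)
  expect_equal(p$highland_constant, 14.1)
  expect_equal(p$collisional_stopping_power, 0.2)
  ## attenuation strictly decreasing, buildup non-decreasing in energy
  es <- c(70, 110, 150, 200, 240)
  expect_true(all(diff(attenuation_coefficient(p, es)) < 0))
  expect_true(all(diff(buildup_length(p, es)) >= 0))
})

test_that("generated base data satisfies its invariants", {
  for (e in c(70, 110, 150, 200, 240)) {
    bd <- generate_analytic_base_data(beam_energy_spec(e, 4))
    expect_equal(max(bd$depth_dose$idd), 1)
    expect_true(all(bd$depth_dose$idd >= 0))
    expect_identical(bd$lateral_spread$sigma_scatter[1], 0)
    expect_true(all(diff(bd$lateral_spread$sigma_scatter) >= 0))
    expect_identical(bd$depth_dose$depths, bd$lateral_spread$depths)
  }
  expect_error(generate_analytic_base_data(beam_energy_spec(200, 4),
                                           max_depth = 200), "max_depth")
  expect_error(generate_analytic_base_data(beam_energy_spec(200, 4),
                                           step = 2), "step")
})

test_that("scattering sigma decreases with energy; distal IDD increases", {
  es <- c(70, 110, 150, 200, 240)
  bds <- lapply(es, function(e)
    generate_analytic_base_data(beam_energy_spec(e, 4)))
  for (z in c(20, 50, 100, 150, 200, 250)) {
    sig <- vapply(bds, function(b) sigma_total(0, z, b), numeric(1))
    expect_true(all(diff(sig) < 0),
                info = sprintf("sigma ordering at z = %g", z))
  }
  idd250 <- vapply(bds, function(b) idd_at(b, 250), numeric(1))
  expect_gt(idd250[[4]], idd250[[1]])  # 200 vs 70 MeV
})

test_that("Fermi-Eyges moments match independent quadrature within 0.5%", {
  set.seed(42)
  for (e in c(70, 200)) {
    bd <- generate_analytic_base_data(beam_energy_spec(e, 4))
    zq <- sort(sample(seq(10, 340, by = 1), 10))
    got <- vapply(zq, function(z) sigma_total(0, z, bd), numeric(1))
    want <- vapply(zq, function(z) oracle_sigma_scatter(e, z), numeric(1))
    expect_true(all(abs(got / want - 1) < 0.005),
                info = sprintf("%g MeV, max rel err %.2g", e,
                               max(abs(got / want - 1))))
  }
})

test_that("sigma_total combines in quadrature and clamps at the surface", {
  bd <- generate_analytic_base_data(beam_energy_spec(200, 4))
  expect_equal(sigma_total(4, 0, bd), 4)
  ## find a depth where sigma_scatter crosses 4 mm, then 3-4-5 quadrature
  ss <- bd$lateral_spread$sigma_scatter
  if (max(ss) > 4) {
    i <- which(ss >= 4)[1]
    zstar <- bd$lateral_spread$depths[i]
    ## interpolate exactly: use tabulated value directly
    expect_equal(sigma_total(3, zstar, bd), sqrt(9 + ss[i]^2))
  }
  ## normalised sigma at fixed depth decreases as sigma0 grows
  ratios <- vapply(c(2, 4, 11, 21, 42), function(s0)
    sigma_total(s0, 200, bd) / s0, numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_error(sigma_total(-1, 10, bd), "sigma0")
})

test_that("idd_at interpolation rules", {
  bd <- generate_analytic_base_data(beam_energy_spec(150, 4))
  d <- bd$depth_dose
  expect_equal(idd_at(bd, d$depths[51]), d$idd[51])
  mid <- (d$depths[10] + d$depths[11]) / 2
  expect_equal(idd_at(bd, mid), (d$idd[10] + d$idd[11]) / 2)
  expect_identical(idd_at(bd, max(d$depths) + 50), 0)
  expect_error(idd_at(bd, -1), "depth")
})

test_that("fwhm_from_sigma constant ratio and anchor value", {
  expect_equal(fwhm_from_sigma(42), 98.90, tolerance = 1e-4)
  expect_identical(fwhm_from_sigma(0), 0)
  expect_equal(fwhm_from_sigma(4), 2 * sqrt(2 * log(2)) * 4)
  sig <- c(0.5, 2, 4, 11, 21, 42)
  expect_equal(fwhm_from_sigma(sig) / sig,
               rep(2 * sqrt(2 * log(2)), length(sig)))
  expect_error(fwhm_from_sigma(-1), "sigma")
})

test_that("base data round-trips through CSV and rejects bad files", {
  bd <- generate_analytic_base_data(beam_energy_spec(110, 11))
  f <- tempfile(fileext = ".csv")
  save_base_data(bd, f)
  bd2 <- load_base_data(f)
  expect_equal(bd2$depth_dose$idd, bd$depth_dose$idd, tolerance = 1e-9)
  expect_equal(bd2$lateral_spread$sigma_scatter,
               bd$lateral_spread$sigma_scatter, tolerance = 1e-9)
  expect_equal(bd2$spec$energy_mev, 110)
  expect_equal(bd2$provenance$kind, "analytic")

  ## corrupt the depth monotonicity
  df <- utils::read.csv(f)
  df$depth_mm[5] <- df$depth_mm[7]
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  expect_error(load_base_data(f), "strictly increasing")
})

test_that("tabulated data is interchangeable with analytic in the engine", {
  bd <- generate_analytic_base_data(beam_energy_spec(200, 4))
  f <- tempfile(fileext = ".csv")
  save_base_data(bd, f)
  bd2 <- load_base_data(f)

  grid <- tiny_water_grid(12, 4)
  fld <- field_geometry(0, c(24, 24, 24))
  dm <- radiological_depth(grid, fld)
  d1 <- spot_dose(c(0, 0), fld, grid, dm, bd, sigma0 = 4)
  d2 <- spot_dose(c(0, 0), fld, grid, dm, bd2, sigma0 = 4)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-9)
})
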