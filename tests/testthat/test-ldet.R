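test_that("oxygen penetration depth interpolates the detection-limit crossing", {
  p <- depth_profile(c(0, 4, 8, 12), c(280, 140, 0, 0), "O2")
  expect_equal(as.numeric(oxygen_penetration_depth(p)),
               8 * (1 - 0.3 / 280), tolerance = 1e-9)

  zeros <- depth_profile(c(0, 5, 10), c(0, 0, 0), "O2")
  expect_equal(as.numeric(oxygen_penetration_depth(zeros)), 0)

  high <- depth_profile(c(0, 9, 18), c(280, 200, 150), "O2")
  opd <- oxygen_penetration_depth(high)
  expect_equal(as.numeric(opd), 18)
  expect_equal(attr(opd, "qc_flags"), "not_reached")
})

test_that("diffusive oxygen uptake matches the linear-profile arithmetic", {
  core <- simple_core(list(O2 = linear_o2()))
  dou <- diffusive_oxygen_uptake(core$profiles$O2, core)
  expect_equal(dou$flux, 8.64e6 * 0.34 * 2.06e-5 * 35, tolerance = 1e-6)

  flat <- depth_profile(seq(0, 10, 0.5), rep(250, 21), "O2")
  expect_equal(diffusive_oxygen_uptake(flat, simple_core(list(O2 = flat)))$flux,
               0, tolerance = 1e-9)
})

test_that("pH extrema follow the oxic-max / sulfidic-min signature with shallow tie-break", {
  d <- c(0, 2.5, 5, 10, 20, 27.5, 35)
  ph <- depth_profile(d, c(7.4, 7.6, 7.8, 7.6, 7.4, 7.3, 7.35), "pH")
  ext <- detect_ph_extrema(ph, opd = 8, smooth = 1)
  expect_equal(unname(ext$ph_max), c(5, 7.8))
  expect_equal(unname(ext$ph_min), c(27.5, 7.3))
  expect_length(ext$qc_flags, 0)

  dec <- depth_profile(0:10, seq(7.8, 6.8, by = -0.1), "pH")
  ext2 <- detect_ph_extrema(dec, opd = 8, smooth = 1)
  expect_true("no_LDET_signature" %in% ext2$qc_flags)
  expect_equal(ext2$ph_max[["depth"]], 0)

  # two equal maxima at 4 and 6 mm: report the shallower
  tie <- depth_profile(c(0, 4, 6, 10, 20), c(7.4, 7.8, 7.8, 7.5, 7.3), "pH")
  expect_equal(detect_ph_extrema(tie, opd = 8, smooth = 1)$ph_max[["depth"]], 4)
})

test_that("suboxic zone bounds combine OPD and sulfide appearance with slice uncertainty", {
  o2 <- linear_o2()
  # coarse sulfide slices centred 14, 17, 20 mm (3 mm width): 1 uM crossed
  # between 14 and 17
  h2s <- depth_profile(c(14, 17, 20), c(0, 10, 40), "H2S")
  sz <- suboxic_zone_bounds(o2, h2s)
  expect_equal(sz$top, 8 * (1 - 0.3 / 280), tolerance = 1e-9)
  expect_equal(sz$bottom, 14 + 3 * (1 - 0) / 10, tolerance = 1e-9)
  expect_equal(sz$bottom_uncertainty, 1.5)
  expect_gt(sz$width, 6)

  shallow <- depth_profile(c(0, 5, 10), c(30, 50, 80), "H2S")
  sz2 <- suboxic_zone_bounds(o2, shallow)
  expect_true("overlap" %in% sz2$qc_flags)
  expect_equal(sz2$width, 0)

  none <- depth_profile(c(10, 20, 30), c(0, 0.2, 0.5), "H2S")
  sz3 <- suboxic_zone_bounds(o2, none)
  expect_true(is.na(sz3$bottom))
  expect_true("no_sulfide_detected" %in% sz3$qc_flags)
})

test_that("alkalinity profiles are pointwise speciation and preserve pH ordering", {
  core <- simple_core(list(O2 = linear_o2()))
  flat_ph <- depth_profile(0:5, rep(7.0, 6), "pH")
  alk <- alkalinity_profile(flat_ph, core)
  expect_equal(alk$analyte, "alkalinity")
  expect_true(all(abs(alk$values - alk$values[1]) < 1e-9))
  expect_equal(alk$values[1], alkalinity_from_ph(7.0, 5500))

  ph_hi <- depth_profile(0:5, rep(7.5, 6), "pH")
  expect_true(all(alkalinity_profile(ph_hi, core)$values > alk$values))
})

test_that("CPC on a symmetric alkalinity tent equals twice the one-sided flux", {
  core <- simple_core(list(O2 = linear_o2()))
  d <- seq(0, 10, by = 0.5)
  alk0 <- alkalinity_from_ph(7.4, 5500)
  alk <- alk0 + 30 * pmin(d, 10 - d)           # tent, peak at 5 mm
  ph <- depth_profile(d, ph_from_alkalinity(alk, 5500), "pH")

  cpc <- cathodic_proton_consumption(ph, 5, core,
                                     windows = list(above = c(0, 5),
                                                    below = c(5, 10)))
  comp <- attr(cpc, "components")
  # symmetric tent: the two components are (nearly) mirror images
  expect_equal(comp[["above"]], -comp[["below"]],
               tolerance = 1e-3)
  expect_equal(as.numeric(cpc), 2 * comp[["below"]], tolerance = 2e-3)

  # independent species-resolved oracle for the below-side flux
  j_below_oracle <- 0
  weights <- c(hco3 = 1, co3 = 2, oh = 1, h = -1)
  dnames <- c(hco3 = "HCO3", co3 = "CO3", oh = "OH", h = "H")
  sel <- d >= 5
  for (sp in names(weights)) {
    conc <- vapply(ph$values, function(p)
      carbonate_speciation(p, 5500)[[sp]], numeric(1))
    slope <- coef(lm(conc[sel] ~ d[sel]))[[2]]
    D0 <- physical_constants()$diffusivities[[dnames[[sp]]]]
    j_below_oracle <- j_below_oracle - weights[[sp]] * 8.64e6 * 0.34 * D0 * slope
  }
  expect_equal(comp[["below"]], j_below_oracle, tolerance = 1e-9)

  # flat pH: no convergent transport
  flat <- depth_profile(d, rep(7.4, length(d)), "pH")
  expect_equal(as.numeric(
    cathodic_proton_consumption(flat, 5, core,
                                windows = list(above = c(0, 5),
                                               below = c(5, 10)))), 0,
    tolerance = 1e-9)

  expect_error(cathodic_proton_consumption(ph, 0, core), "strictly inside")
})

test_that("the electrochemical conversion chain reproduces the printed numbers", {
  # CPC 1360 umol H+ m^-2 d^-1 -> 1.5 mA m^-2 at two significant figures
  expect_equal(signif(current_density_from_cpc(1360), 2), 1.5)
  expect_equal(current_density_from_cpc(0), 0)
  expect_error(current_density_from_cpc(-1), ">= 0")
  # the conversion factor is 1/F to four significant figures
  expect_equal(signif(1 / 96485, 4), 1.036e-5)
  expect_equal(physical_constants()$faraday_inverse, 1.036e-5)

  expect_equal(cathodic_oxygen_consumption(1360), 340)
  expect_equal(cathodic_oxygen_consumption(0), 0)

  expect_equal(sulfate_recycling_rate(340), 170)
  expect_equal(sulfate_recycling_rate(0), 0)
  # partial oxidation to S0 (2 electrons per sulfur) quadruples the rate
  expect_equal(sulfate_recycling_rate(340, electrons_per_sulfate = 2), 680)

  # algebraic round trip: COC-equivalent back to the generating current
  cpc <- 4 * cathodic_oxygen_consumption(1360)
  expect_equal(current_density_from_cpc(cpc),
               current_density_from_cpc(1360), tolerance = 1e-12)
})

test_that("ATP converts to cell densities with the extracellular correction", {
  expect_equal(cells_from_atp(5.25e-4, 0), 3e6)
  expect_equal(cells_from_atp(1e-3, 1e-3), 0)
  expect_equal(cells_from_atp(5.25e-4), 3e6)   # sediment policy: no correction
  expect_error(cells_from_atp(1e-4, 2e-4), "exceeds")
})
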