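# The simulator runs used here keep the default 0.25 mm grid on a 40 mm
# column (161 nodes); each steady-state solve takes well under a second.

test_that("the abiotic limit gives monotone O2 decay and flat alkalinity", {
  core <- simulate_geobattery(sim_config(imposed_current = 0,
                                         sulfide_source_flux = 0))
  o2 <- core$profiles$O2$values
  expect_true(all(diff(o2) <= 1e-9))
  # no alkalinity source anywhere: pH profile flat, no interior maximum
  ph <- core$profiles$pH$values
  expect_lt(max(ph) - ph[1], 1e-6)
  expect_equal(attr(core, "ground_truth")$cpc, 0)
})

test_that("electron bookkeeping balances cathode, anode and imposed current", {
  for (I in c(0.8, 2.5)) {
    core <- simulate_geobattery(sim_config(imposed_current = I))
    gt <- attr(core, "ground_truth")
    target_e <- I * 1e-3 * 1.036e-5 * 86400 * 1e6   # umol e- m^-2 day^-1
    expect_equal(gt$cathodic_areal_o2 * 4, target_e, tolerance = 1e-9)
    expect_equal(gt$anodic_areal_sulfide * 8, target_e, tolerance = 1e-9)
  }
})

test_that("simulated profiles satisfy the discrete steady-state balance", {
  core <- simulate_geobattery(sim_config(imposed_current = 1.5))
  res <- steady_state_residuals(core)
  # residual scale: source terms are O(100-1000) uM/day
  expect_lt(res[["O2"]], 1e-4)
  expect_lt(res[["H2S"]], 1e-6)
  expect_lt(res[["alkalinity"]], 1e-6)
})

test_that("the default active column shows the geobattery geometry", {
  core <- simulate_geobattery(sim_config())
  rep <- analyze_core(core)
  expect_gt(rep$opd, 6); expect_lt(rep$opd, 11)     # O2 gone below ~8-10 mm
  # interior oxic pH maximum, deeper minimum inside the anode zone
  expect_gt(rep$ph_max[["depth"]], 0)
  expect_lt(rep$ph_max[["depth"]], rep$opd + 2)
  expect_gt(rep$ph_min[["depth"]], 17)
  expect_gt(rep$ph_max[["pH"]], rep$ph_min[["pH"]])
  # sulfide-free gap of at least 9 mm between oxic and sulfidic zones
  width <- rep$suboxic_zone[["bottom"]] - rep$suboxic_zone[["top"]]
  expect_gt(width, 9)
})

test_that("doubling the imposed current doubles the alkalinity anomaly", {
  # exact linearity of the discrete diffusion system in its source field
  s1 <- attr(simulate_geobattery(sim_config(imposed_current = 1)),
             "ground_truth")$solver
  n <- length(s1$x)
  resolve <- function(src) geobattery:::.solve_steady(
    s1$dphi[["alk"]], s1$h, s1$x, rep(0, n), src,
    top = list(type = "dirichlet", value = s1$alk0),
    bottom = list(type = "flux", value = 0))
  a1 <- resolve(s1$alk_s)
  a2 <- resolve(2 * s1$alk_s)
  expect_equal(a2 - s1$alk0, 2 * (a1 - s1$alk0), tolerance = 1e-9)

  # end to end the anomaly is linear up to the slight redistribution of
  # the first-order cathodic sink within its zone as the O2 field changes
  b2 <- attr(simulate_geobattery(sim_config(imposed_current = 2)),
             "ground_truth")$solver$alk
  expect_equal(max(b2) - s1$alk0, 2 * (max(s1$alk) - s1$alk0),
               tolerance = 0.02)
})

test_that("OPD deepens as the background O2 consumption drops, and the abiotic control is deeper still", {
  rates <- c(800, 600, 400, 250, 120)
  opds <- vapply(rates, function(r) {
    core <- simulate_geobattery(sim_config(imposed_current = 0,
                                           sulfide_source_flux = 0,
                                           background_o2_consumption = r))
    as.numeric(oxygen_penetration_depth(core$profiles$O2))
  }, numeric(1))
  expect_true(all(diff(opds) > 0))   # lower consumption -> deeper OPD

  active <- simulate_geobattery(sim_config())
  control <- make_abiotic_control(sim_config())
  expect_gt(as.numeric(oxygen_penetration_depth(control$profiles$O2)),
            as.numeric(oxygen_penetration_depth(active$profiles$O2)))
  # control: surface pH lowered, no interior oxic maximum
  phc <- control$profiles$pH$values
  expect_lt(max(phc) - phc[1], 1e-6)
  expect_lt(phc[1], simulate_geobattery(sim_config())$profiles$pH$values[1])
})

test_that("measurement noise is seed-deterministic and vanishes at sd 0", {
  core <- simulate_geobattery(sim_config(imposed_current = 1.5))
  n1 <- add_measurement_noise(core, seed = 99)
  n2 <- add_measurement_noise(core, seed = 99)
  expect_identical(n1$profiles$O2$values, n2$profiles$O2$values)
  expect_identical(n1$profiles$pH$values, n2$profiles$pH$values)
  expect_false(identical(
    add_measurement_noise(core, seed = 100)$profiles$O2$values,
    n1$profiles$O2$values))

  clean <- add_measurement_noise(core, noise_sd = c(O2 = 0, pH = 0, H2S = 0),
                                 seed = 1)
  expect_identical(clean$profiles$O2$values, core$profiles$O2$values)

  # the caller's RNG stream is not disturbed
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(add_measurement_noise(core, seed = 5))
  expect_identical(rnorm(3), before)
})

test_that("sulfide slicing averages a linear profile to its midpoints", {
  d <- seq(0, 11.75, by = 0.25)
  core <- simple_core(list(H2S = depth_profile(d, 2 * d, "H2S")))
  sliced <- add_measurement_noise(core, noise_sd = c(H2S = 0), seed = 1,
                                  h2s_slice_width = 3)
  p <- sliced$profiles$H2S
  # slice value = mean of members = 2 * mean depth for a linear profile
  expect_equal(p$values, 2 * p$depths, tolerance = 1e-12)
  expect_equal(length(p$depths), 4)
})
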