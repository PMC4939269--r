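# One-dimensional steady-state reaction-diffusion simulator of a sediment
# geobattery: spatially separated, current-coupled redox half reactions.
#
# Governing balance per dissolved species, porewater concentration C (uM),
# depth x (mm, positive downward):
#
#     phi * D * d2C/dx2  - k(x) * C  + s(x)  =  0
#
# with phi*D in mm^2/day (1 cm^2/s = 8.64e6 mm^2/day), first-order sinks
# k (1/day) and zero-order net sources s (uM/day).  In these units an
# areal rate integral (uM/day * mm) is numerically an areal flux in
# umol m^-2 day^-1, identical to the analyzer's flux units.
#
# Electron bookkeeping (per electron of imposed current):
#   cathode:  1/4 O2 + H+ + e- -> ...   O2 sink I/(4F), alkalinity +1
#   anode:    1/8 HS- -> 1/8 SO4^2- ... sulfide sink I/(8F), alkalinity
#             -alk_per_sulfide/8 (net proton release per sulfide oxidized,
#             partially buffered by FeS dissolution; see sim_config()).
# The cathodic O2 sink is first-order within the cathode zone with its
# rate constant tuned so the areal electron sink equals I/F exactly; the
# anodic sulfide sink is first-order within the anode zone and, with a
# zero-flux top boundary, its areal rate equals the bottom sulfide source
# flux exactly at steady state.

.CGS_TO_MM2_DAY <- 8.64e6

#' Configuration of the geobattery profile simulator
#'
#' Defaults reproduce the incubation-column conditions the package is
#' built around: 40 mm column, porosity 0.34, 20 C, DIC 5500 uM,
#' air-saturated top water (280 uM O2), top pH 7.4, imposed current
#' density 1.5 mA m^-2 with the cathode at 6-8 mm and the anode at
#' 17-30 mm (giving a suboxic gap of roughly 9-17 mm), and a zero-order
#' (Monod-limited) background aerobic respiration of 400 uM/day that by
#' itself sets an oxygen penetration depth near 9 mm.
#'
#' @param domain_depth Column depth, mm.
#' @param grid_step Grid spacing, mm (must divide `domain_depth`).
#' @param porosity Sediment porosity (0, 1).
#' @param temperature Temperature, C.
#' @param dic Dissolved inorganic carbon, uM (constant with depth).
#' @param o2_top O2 concentration at the sediment surface, uM.
#' @param ph_top Porewater pH at the sediment surface.
#' @param imposed_current Imposed LDET current density, mA m^-2 (>= 0).
#' @param cathode_zone Depth interval (mm) of cathodic O2 reduction.
#' @param anode_zone Depth interval (mm) of anodic sulfide oxidation;
#'   must lie entirely below the cathode zone.
#' @param background_o2_consumption Zero-order aerobic respiration rate,
#'   uM/day (Monod-limited in O2 with half-saturation `monod_km`).
#' @param monod_km O2 half-saturation of background respiration, uM.
#' @param sulfide_source_flux Upward sulfide flux from depth (FeS
#'   dissolution proxy), umol m^-2 day^-1; `NULL` balances it to the
#'   imposed current (I/(8F) in sulfide equivalents).
#' @param anode_rate_constant First-order sulfide oxidation rate inside
#'   the anode zone, 1/day.
#' @param alk_per_sulfide Net alkalinity consumed per sulfide oxidized at
#'   the anode (charge equivalents).  Full oxidation to sulfate releases
#'   9 protons of which one is balanced against the HS- charge; dissolving
#'   the next FeS consumes further protons, so the effective net release
#'   is smaller.  The default 6 routes a quarter of the cathodic
#'   alkalinity production to the overlying water, producing the oxic pH
#'   maximum; 8 would close the alkalinity loop entirely inside the
#'   column and flatten the oxic maximum away.
#' @param abiotic_background_factor Fraction of
#'   `background_o2_consumption` retained in the abiotic control
#'   (chemical FeS oxidation only).
#' @param abiotic_ph_drop pH lowering of the control's surface boundary
#'   (CO2 ingassing proxy after autoclaving).
#' @param noise_sd Named vector of measurement noise s.d. per analyte
#'   (uM for O2/H2S, pH units for pH) used by [add_measurement_noise()].
#' @param seed Integer seed for the noise generator.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(domain_depth = 40, grid_step = 0.25,
                       porosity = 0.34, temperature = 20, dic = 5500,
                       o2_top = 280, ph_top = 7.4,
                       imposed_current = 1.5,
                       cathode_zone = c(6, 8), anode_zone = c(17, 30),
                       background_o2_consumption = 400, monod_km = 1,
                       sulfide_source_flux = NULL,
                       anode_rate_constant = 8,
                       alk_per_sulfide = 6,
                       abiotic_background_factor = 0.25,
                       abiotic_ph_drop = 0.7,
                       noise_sd = c(O2 = 1, pH = 0.005, H2S = 2),
                       seed = 1L) {
  stopifnot(domain_depth > 0, grid_step > 0,
            porosity > 0, porosity < 1, dic >= 0, o2_top >= 0,
            imposed_current >= 0, background_o2_consumption >= 0,
            anode_rate_constant > 0, monod_km > 0)
  if (abs(domain_depth / grid_step - round(domain_depth / grid_step)) > 1e-9)
    stop("grid_step must divide domain_depth")
  cathode_zone <- sort(cathode_zone); anode_zone <- sort(anode_zone)
  if (cathode_zone[2] > anode_zone[1])
    stop("cathode and anode zones must be disjoint, cathode above anode")
  if (anode_zone[2] > domain_depth)
    stop("anode zone extends below the domain")
  structure(list(domain_depth = domain_depth, grid_step = grid_step,
                 porosity = porosity, temperature = temperature, dic = dic,
                 o2_top = o2_top, ph_top = ph_top,
                 imposed_current = imposed_current,
                 cathode_zone = cathode_zone, anode_zone = anode_zone,
                 background_o2_consumption = background_o2_consumption,
                 monod_km = monod_km,
                 sulfide_source_flux = sulfide_source_flux,
                 anode_rate_constant = anode_rate_constant,
                 alk_per_sulfide = alk_per_sulfide,
                 abiotic_background_factor = abiotic_background_factor,
                 abiotic_ph_drop = abiotic_ph_drop,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# Solve phi*D*C'' - k*C + s = 0 on a uniform grid.
# top/bottom: list(type = "dirichlet", value =) or list(type = "flux",
# value =) with flux positive INTO the domain.  Flux boundaries use
# half-cell control volumes so the discrete balance telescopes exactly.
.solve_steady <- function(dphi, h, x, k, s, top, bottom) {
  n <- length(x)
  A <- matrix(0, n, n); b <- numeric(n)
  a <- dphi / h^2
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- a
    A[i, i]     <- -2 * a - k[i]
    A[i, i + 1] <- a
    b[i] <- -s[i]
  }
  if (top$type == "dirichlet") {
    A[1, 1] <- 1; b[1] <- top$value
  } else {
    A[1, 1] <- -dphi / h - k[1] * h / 2
    A[1, 2] <- dphi / h
    b[1] <- -top$value - s[1] * h / 2
  }
  if (bottom$type == "dirichlet") {
    A[n, n] <- 1; b[n] <- bottom$value
  } else {
    A[n, n]     <- -dphi / h - k[n] * h / 2
    A[n, n - 1] <- dphi / h
    b[n] <- -bottom$value - s[n] * h / 2
  }
  solve(A, b)
}

# trapezoid-consistent cell widths
.cell_widths <- function(n, h) c(h / 2, rep(h, n - 2), h / 2)

# Solve the O2 profile for a given cathodic rate constant kc; Picard
# iteration on the Monod factor of the background consumption.
.solve_o2 <- function(kc, x, dphi, h, cfg, c_start = NULL) {
  in_cathode <- x >= cfg$cathode_zone[1] & x <= cfg$cathode_zone[2]
  C <- if (is.null(c_start)) rep(cfg$o2_top, length(x)) else c_start
  for (iter in 1:500) {
    k_bg <- cfg$background_o2_consumption / (pmax(C, 0) + cfg$monod_km)
    k <- k_bg + kc * in_cathode
    C_new <- .solve_steady(dphi, h, x, k, rep(0, length(x)),
                           top = list(type = "dirichlet", value = cfg$o2_top),
                           bottom = list(type = "flux", value = 0))
    if (max(abs(C_new - C)) < 1e-11 * max(cfg$o2_top, 1)) {
      C <- C_new; break
    }
    C <- C_new
  }
  list(C = C, k_cathode = kc * in_cathode,
       k_background = cfg$background_o2_consumption /
         (pmax(C, 0) + cfg$monod_km))
}

#' Simulate a steady-state geobattery sediment column
#'
#' Solves the coupled steady-state diffusion problem for O2, total
#' sulfide and alkalinity on a uniform grid, then recovers pH pointwise
#' by inverting the alkalinity-pH relation at constant DIC
#' ([ph_from_alkalinity()]).  The cathodic O2 sink is tuned so the areal
#' electron sink equals `imposed_current / F` exactly; the anodic
#' sulfide sink balances the bottom sulfide source flux exactly at
#' steady state, so cathodic and anodic electron rates match whenever
#' `sulfide_source_flux` is left at its automatic (current-balanced)
#' value.
#'
#' @param config A [sim_config()].
#' @param carb,phys Constants objects.
#' @return A `synthetic_core`: a [sediment_core()] carrying O2, pH and
#'   H2S profiles plus attributes `config`, `ground_truth` (imposed and
#'   achieved areal rates, true DOU, solver fields) for parameter
#'   recovery tests.
#' @examples
#' core <- simulate_geobattery(sim_config(imposed_current = 1.5))
#' attr(core, "ground_truth")$cpc  # ~1343 umol H+ m^-2 day^-1
#' @export
simulate_geobattery <- function(config = sim_config(),
                                carb = carbonate_constants(),
                                phys = physical_constants()) {
  cfg <- config
  h <- cfg$grid_step
  x <- seq(0, cfg$domain_depth, by = h)
  n <- length(x)
  w <- .cell_widths(n, h)
  dphi <- function(sp) cfg$porosity *
    diffusivity_at_temperature(sp, cfg$temperature, phys) * .CGS_TO_MM2_DAY

  # areal electron turnover, umol e- m^-2 day^-1
  target_e <- cfg$imposed_current * 1e-3 * phys$faraday_inverse * 86400 * 1e6
  target_o2 <- target_e / 4            # 4 e- per O2

  ## --- O2 ---------------------------------------------------------------
  d_o2 <- dphi("O2")
  if (target_o2 > 0) {
    areal_cathodic <- function(kc, c_start = NULL) {
      sol <- .solve_o2(kc, x, d_o2, h, cfg, c_start)
      sum(sol$k_cathode * pmax(sol$C, 0) * w)
    }
    k_hi <- 1
    while (areal_cathodic(k_hi) < target_o2) {
      k_hi <- k_hi * 10
      if (k_hi > 1e9)
        stop("imposed current ", cfg$imposed_current,
             " mA m^-2 exceeds the O2 supply to the cathode zone")
    }
    root <- stats::uniroot(function(kc) areal_cathodic(kc) - target_o2,
                           c(0, k_hi), tol = 1e-13 * k_hi)
    # polish by bisection until the areal sink matches to 1e-10 relative
    lo <- root$root * 0.999; hi <- root$root * 1.001
    while (areal_cathodic(lo) > target_o2) lo <- lo * 0.999
    while (areal_cathodic(hi) < target_o2) hi <- hi * 1.001
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      f <- areal_cathodic(mid) - target_o2
      if (abs(f) < 1e-11 * target_o2) break
      if (f < 0) lo <- mid else hi <- mid
    }
    kc <- mid
  } else kc <- 0
  o2_sol <- .solve_o2(kc, x, d_o2, h, cfg)
  o2 <- o2_sol$C
  rate_cathodic <- o2_sol$k_cathode * pmax(o2, 0)      # uM/day
  rate_background <- o2_sol$k_background * pmax(o2, 0)
  cathodic_areal <- sum(rate_cathodic * w)
  dou_true <- sum((rate_cathodic + rate_background) * w)

  ## --- sulfide ----------------------------------------------------------
  d_h2s <- dphi("H2S")
  s_b <- if (is.null(cfg$sulfide_source_flux)) target_e / 8
         else cfg$sulfide_source_flux
  in_anode <- x >= cfg$anode_zone[1] & x <= cfg$anode_zone[2]
  if (s_b > 0) {
    k_a <- cfg$anode_rate_constant * in_anode
    h2s <- .solve_steady(d_h2s, h, x, k_a, rep(0, n),
                         top = list(type = "flux", value = 0),
                         bottom = list(type = "flux", value = s_b))
    rate_anodic <- k_a * h2s                           # uM sulfide/day
  } else {
    h2s <- rep(0, n); rate_anodic <- rep(0, n)
  }
  anodic_areal <- sum(rate_anodic * w)

  ## --- alkalinity and pH ------------------------------------------------
  alk0 <- alkalinity_from_ph(cfg$ph_top, cfg$dic, carb)
  d_alk <- cfg$porosity * .effective_alk_diffusivity(cfg$ph_top, cfg$dic,
                                                     carb, phys) *
    .CGS_TO_MM2_DAY
  s_alk <- phys$protons_per_O2 * rate_cathodic -
    cfg$alk_per_sulfide * rate_anodic
  alk <- .solve_steady(d_alk, h, x, rep(0, n), s_alk,
                       top = list(type = "dirichlet", value = alk0),
                       bottom = list(type = "flux", value = 0))
  ph <- ph_from_alkalinity(alk, cfg$dic, carb)

  profiles <- list(
    O2 = depth_profile(x, pmax(o2, 0), "O2",
                       resolution_note = sprintf("simulated, %g mm grid", h)),
    pH = depth_profile(x, ph, "pH",
                       resolution_note = sprintf("simulated, %g mm grid", h)),
    H2S = depth_profile(x, pmax(h2s, 0), "H2S",
                        resolution_note = sprintf("simulated, %g mm grid", h)))
  core <- sediment_core(profiles, porosity = cfg$porosity,
                        temperature = cfg$temperature, dic = cfg$dic,
                        label = sprintf("simulated geobattery (%g mA m^-2)",
                                        cfg$imposed_current))
  attr(core, "config") <- cfg
  attr(core, "ground_truth") <- list(
    imposed_current = cfg$imposed_current,
    electron_areal = target_e,
    cpc = target_e,                         # 1 H+ per e- at the cathode
    coc = target_o2,
    sulfate_recycling = anodic_areal,
    cathodic_areal_o2 = cathodic_areal,
    anodic_areal_sulfide = anodic_areal,
    dou_true = dou_true,
    alk_source_areal = sum(s_alk * w),
    solver = list(x = x, o2 = o2, h2s = h2s, alk = alk,
                  o2_k = o2_sol$k_background + o2_sol$k_cathode,
                  h2s_k = if (s_b > 0) cfg$anode_rate_constant * in_anode
                          else rep(0, n),
                  alk_s = s_alk, s_b = s_b,
                  dphi = c(O2 = d_o2, H2S = d_h2s, alk = d_alk),
                  alk0 = alk0, h = h))
  class(core) <- c("synthetic_core", class(core))
  core
}

# effective diffusivity (cm^2/s) of alkalinity near a reference pH:
# weighted species diffusivities by each species' contribution to a
# change in alkalinity at constant DIC.
.effective_alk_diffusivity <- function(ph, dic, carb, phys) {
  eps <- 1e-5
  sp1 <- carbonate_speciation(ph - eps, dic, carb)
  sp2 <- carbonate_speciation(ph + eps, dic, carb)
  d <- function(comp) sp2[[comp]] - sp1[[comp]]
  num <- phys$diffusivities[["HCO3"]] * d("hco3") +
         2 * phys$diffusivities[["CO3"]] * d("co3") +
         phys$diffusivities[["OH"]] * d("oh") -
         phys$diffusivities[["H"]] * d("h")
  den <- d("hco3") + 2 * d("co3") + d("oh") - d("h")
  num / den
}

#' Discrete steady-state residuals of a simulated core
#'
#' Maximum absolute residual of the discrete balance
#' `phi*D*Laplacian(C) - k*C + s` at interior nodes, per species, in
#' uM/day.  Near machine-zero for a converged simulation.
#'
#' @param core A `synthetic_core` from [simulate_geobattery()].
#' @return Named numeric vector (`O2`, `H2S`, `alkalinity`).
#' @export
steady_state_residuals <- function(core) {
  s <- attr(core, "ground_truth")$solver
  gt <- attr(core, "ground_truth")
  h <- s$h; n <- length(s$x)
  lap <- function(C) (C[1:(n - 2)] - 2 * C[2:(n - 1)] + C[3:n]) / h^2
  i <- 2:(n - 1)
  c(O2 = max(abs(s$dphi[["O2"]] * lap(s$o2) - (s$o2_k * s$o2)[i])),
    H2S = if (gt$solver$s_b > 0)
      max(abs(s$dphi[["H2S"]] * lap(s$h2s) - (s$h2s_k * s$h2s)[i]))
      else 0,
    alkalinity = max(abs(s$dphi[["alk"]] * lap(s$alk) + s$alk_s[i])))
}

#' Abiotic control column
#'
#' Re-runs [simulate_geobattery()] with no imposed current, the
#' background O2 consumption reduced to chemical FeS oxidation only
#' (default 25% of the active rate), no deep sulfide source, and a
#' surface boundary acidified by `abiotic_ph_drop` pH units (CO2
#' ingassing proxy).  The control therefore shows deeper O2 penetration
#' and no interior oxic pH maximum.
#'
#' @param config A [sim_config()] describing the matched active column.
#' @param carb,phys Constants objects.
#' @return A `synthetic_core`.
#' @export
make_abiotic_control <- function(config = sim_config(),
                                 carb = carbonate_constants(),
                                 phys = physical_constants()) {
  cfg <- config
  cfg$imposed_current <- 0
  cfg$background_o2_consumption <-
    cfg$background_o2_consumption * cfg$abiotic_background_factor
  cfg$sulfide_source_flux <- 0
  cfg$ph_top <- cfg$ph_top - cfg$abiotic_ph_drop
  core <- simulate_geobattery(cfg, carb, phys)
  core$label <- "simulated abiotic control"
  core
}

# evaluate code with a local, restored RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Add measurement noise to a simulated core
#'
#' Adds independent Gaussian noise per analyte (concentrations clipped
#' at 0; pH noise on pH units, unclipped) and optionally coarsens the
#' sulfide profile into slices (emulating sliced-core porewater
#' sampling): slice value = mean of member points, slice depth = mean of
#' member depths.  Deterministic under `seed`; the caller's RNG state is
#' untouched.
#'
#' @param core A `synthetic_core` (or any [sediment_core()]).
#' @param noise_sd Named vector of noise s.d. per analyte; defaults to
#'   the simulation config's `noise_sd` when present.
#' @param seed Integer seed.
#' @param h2s_slice_width Optional slice width (mm) for coarsening the
#'   sulfide profile; `NULL` leaves it at grid resolution.
#' @return The core with noisy profiles; `ground_truth` retained.
#' @export
add_measurement_noise <- function(core, noise_sd = NULL, seed = 1L,
                                  h2s_slice_width = NULL) {
  if (is.null(noise_sd)) {
    cfg <- attr(core, "config")
    noise_sd <- if (!is.null(cfg)) cfg$noise_sd else c(O2 = 1, pH = 0.005,
                                                       H2S = 2)
  }
  stopifnot(all(noise_sd >= 0))
  .with_seed(seed, {
    for (nm in names(core$profiles)) {
      sd_nm <- if (nm %in% names(noise_sd)) noise_sd[[nm]] else 0
      p <- core$profiles[[nm]]
      if (sd_nm > 0) {
        v <- p$values + stats::rnorm(length(p$values), 0, sd_nm)
        if (nm != "pH") v <- pmax(v, 0)
        p <- depth_profile(p$depths, v, p$analyte,
                           resolution_note = p$resolution_note)
      }
      if (nm == "H2S" && !is.null(h2s_slice_width)) {
        idx <- floor((p$depths - min(p$depths)) / h2s_slice_width)
        d_sl <- tapply(p$depths, idx, mean)
        v_sl <- tapply(p$values, idx, mean)
        p <- depth_profile(as.numeric(d_sl), pmax(as.numeric(v_sl), 0),
                           "H2S",
                           resolution_note = sprintf("%g mm slices",
                                                     h2s_slice_width))
      }
      core$profiles[[nm]] <- p
    }
  })
  core
}
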