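# Full LDET analysis of a sediment core: the package's central
# model-fitting-style entry point and its S3 report class.

#' Analyze a sediment core for the LDET geochemical signature
#'
#' Runs the complete diagnostic chain on a [sediment_core()]:
#' oxygen penetration depth (OPD), diffusive oxygen uptake (DOU), pH
#' extrema, alkalinity at constant DIC, cathodic proton consumption
#' (CPC), electric current density, cathodic oxygen consumption (COC),
#' theoretical sulfate recycling, and (when a sulfide profile is
#' present) the suboxic zone geometry.  Stage failures are recorded as
#' qc flags and the corresponding fields left `NA`; a report is always
#' returned.
#'
#' @param core A [sediment_core()] with at least O2 and pH profiles (a
#'   core lacking pH yields a degraded report with OPD/DOU only).
#' @param o2_threshold O2 detection threshold, uM (default 0.3).
#' @param h2s_threshold Sulfide detection threshold, uM (default 1).
#' @param dou_window Optional explicit DOU window, mm.
#' @param cpc_windows Optional explicit CPC windows,
#'   `list(above =, below =)`.
#' @param carb,phys Constants objects ([carbonate_constants()],
#'   [physical_constants()]).
#' @return An object of class `ldet_report`; see Details.  Fields: `opd`
#'   (mm), `dou`, `cpc`, `coc`, `sulfate_recycling` (umol m^-2 day^-1),
#'   `current_density` (mA m^-2), `ph_max`/`ph_min` (depth, value),
#'   `suboxic_zone`, `qc_flags`, plus all intermediate fits under
#'   `$fits`.
#' @examples
#' core <- simulate_geobattery(sim_config(imposed_current = 1.5))
#' rep <- analyze_core(core)
#' rep$current_density
#' @export
analyze_core <- function(core, o2_threshold = 0.3, h2s_threshold = 1,
                         dou_window = NULL, cpc_windows = NULL,
                         carb = carbonate_constants(),
                         phys = physical_constants()) {
  qc <- character()
  rep <- list(opd = NA_real_, dou = NA_real_,
              ph_max = c(depth = NA_real_, pH = NA_real_),
              ph_min = c(depth = NA_real_, pH = NA_real_),
              suboxic_zone = c(top = NA_real_, bottom = NA_real_),
              cpc = NA_real_, current_density = NA_real_, coc = NA_real_,
              sulfate_recycling = NA_real_,
              fits = list(), core_label = core$label,
              constants = list(carb = carb, phys = phys))

  o2 <- core$profiles[["O2"]]
  ph <- core$profiles[["pH"]]
  h2s <- core$profiles[["H2S"]]
  if (is.null(o2)) {
    qc <- c(qc, "missing_O2_profile")
  } else {
    opd <- oxygen_penetration_depth(o2, o2_threshold)
    qc <- c(qc, attr(opd, "qc_flags"))
    rep$opd <- as.numeric(opd)
    dou <- tryCatch(
      diffusive_oxygen_uptake(o2, core, window = dou_window,
                              constants = phys),
      error = function(e) { qc <<- c(qc, paste0("dou_failed: ",
                                                conditionMessage(e))); NULL })
    if (!is.null(dou)) { rep$dou <- dou$flux; rep$fits$dou <- dou }
  }

  if (is.null(ph)) {
    qc <- c(qc, "missing_pH_profile")
  } else if (!is.na(rep$opd)) {
    ext <- detect_ph_extrema(ph, rep$opd)
    qc <- c(qc, ext$qc_flags)
    rep$ph_max <- ext$ph_max; rep$ph_min <- ext$ph_min
    if ("no_LDET_signature" %in% ext$qc_flags) {
      # no interior oxic pH maximum: no cathodic alkalinity source
      rep$cpc <- 0
    } else {
      cpc <- tryCatch(
        cathodic_proton_consumption(ph, ext$ph_max[["depth"]], core,
                                    opd = rep$opd, windows = cpc_windows,
                                    carb = carb, phys = phys),
        error = function(e) { qc <<- c(qc, paste0("cpc_failed: ",
                                                  conditionMessage(e))); NULL })
      if (!is.null(cpc)) {
        qc <- c(qc, attr(cpc, "qc_flags"))
        rep$fits$cpc <- list(windows = attr(cpc, "windows"),
                             components = attr(cpc, "components"))
        rep$cpc <- as.numeric(cpc)
      }
    }
    if (!is.na(rep$cpc)) {
      rep$current_density <- current_density_from_cpc(rep$cpc, phys)
      rep$coc <- cathodic_oxygen_consumption(rep$cpc)
      rep$sulfate_recycling <- sulfate_recycling_rate(rep$coc, phys)
    }
  }

  if (!is.null(h2s) && !is.null(o2)) {
    sz <- suboxic_zone_bounds(o2, h2s, o2_threshold, h2s_threshold)
    qc <- c(qc, sz$qc_flags)
    rep$suboxic_zone <- c(top = sz$top, bottom = sz$bottom)
    rep$fits$suboxic <- sz
  }

  rep$qc_flags <- unique(qc)
  class(rep) <- "ldet_report"
  rep
}

#' @export
print.ldet_report <- function(x, ...) {
  cat("LDET analysis of sediment core",
      if (nzchar(x$core_label)) paste0("'", x$core_label, "'") else "", "\n")
  cat(sprintf("  Oxygen penetration depth: %.1f mm\n", x$opd))
  cat(sprintf("  Diffusive oxygen uptake:  %.0f umol O2 m^-2 d^-1\n", x$dou))
  if (!is.na(x$ph_max[["depth"]]))
    cat(sprintf("  pH maximum %.2f at %.1f mm; minimum %.2f at %.1f mm\n",
                x$ph_max[["pH"]], x$ph_max[["depth"]],
                x$ph_min[["pH"]], x$ph_min[["depth"]]))
  if (!is.na(x$suboxic_zone[["bottom"]]))
    cat(sprintf("  Suboxic zone: %.1f to %.1f mm (width %.1f mm)\n",
                x$suboxic_zone[["top"]], x$suboxic_zone[["bottom"]],
                x$suboxic_zone[["bottom"]] - x$suboxic_zone[["top"]]))
  cat(sprintf("  Cathodic proton consumption: %.0f umol H+ m^-2 d^-1\n",
              x$cpc))
  cat(sprintf("  Current density:             %.2f mA m^-2\n",
              x$current_density))
  cat(sprintf("  Cathodic oxygen consumption: %.0f umol O2 m^-2 d^-1\n",
              x$coc))
  cat(sprintf("  Sulfate recycling:           %.0f umol SO4 m^-2 d^-1\n",
              x$sulfate_recycling))
  if (length(x$qc_flags))
    cat("  QC flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @method summary ldet_report
#' @export
summary.ldet_report <- function(object, ...) {
  print(object)
  if (!is.null(object$fits$dou))
    cat(sprintf("\nDOU window: %.2f-%.2f mm (%d points, rmse %.2g uM)\n",
                object$fits$dou$gradient$window[1],
                object$fits$dou$gradient$window[2],
                object$fits$dou$gradient$n_points,
                object$fits$dou$gradient$rmse))
  if (!is.null(object$fits$cpc)) {
    w <- object$fits$cpc$windows
    cat(sprintf("CPC windows: above %.2f-%.2f mm, below %.2f-%.2f mm\n",
                w$above[1], w$above[2], w$below[1], w$below[2]))
    cat(sprintf("CPC components (downward +): above %.0f, below %.0f umol m^-2 d^-1\n",
                object$fits$cpc$components[["above"]],
                object$fits$cpc$components[["below"]]))
  }
  invisible(object)
}

#' Extract the headline LDET diagnostics
#'
#' @param object An `ldet_report`.
#' @param ... Unused.
#' @return Named numeric vector of the main diagnostics.
#' @method coef ldet_report
#' @export
coef.ldet_report <- function(object, ...) {
  c(opd = object$opd, dou = object$dou, cpc = object$cpc,
    current_density = object$current_density, coc = object$coc,
    sulfate_recycling = object$sulfate_recycling)
}

#' Plot the analyzed core's profiles with LDET annotations
#'
#' Base-graphics panel of O2, pH (and sulfide, when present) against
#' depth, with the oxygen penetration depth, pH extrema and suboxic zone
#' marked.
#'
#' @param x An `ldet_report`.
#' @param core The [sediment_core()] the report was computed from.
#' @param ... Passed to [graphics::plot()].
#' @method plot ldet_report
#' @export
plot.ldet_report <- function(x, core, ...) {
  profs <- core$profiles[intersect(c("O2", "pH", "H2S"), names(core$profiles))]
  old <- graphics::par(mfrow = c(1, length(profs)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(profs)) {
    p <- profs[[nm]]
    graphics::plot(p$values, p$depths, type = "l", ylim = rev(range(p$depths)),
                   xlab = if (nm == "pH") "pH" else paste(nm, "(uM)"),
                   ylab = "depth (mm)", main = nm, ...)
    graphics::abline(h = 0, lty = 3)
    if (!is.na(x$opd)) graphics::abline(h = x$opd, col = "blue", lty = 2)
    if (nm == "pH" && !is.na(x$ph_max[["depth"]])) {
      graphics::points(x$ph_max[["pH"]], x$ph_max[["depth"]], pch = 19,
                       col = "darkgreen")
      graphics::points(x$ph_min[["pH"]], x$ph_min[["depth"]], pch = 19,
                       col = "firebrick")
    }
    if (nm == "H2S" && !is.na(x$suboxic_zone[["bottom"]]))
      graphics::abline(h = x$suboxic_zone[["bottom"]], col = "orange",
                       lty = 2)
  }
  invisible(x)
}
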