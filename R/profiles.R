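# Depth-resolved porewater profiles and sediment cores.
#
# Depth convention: millimetres, positive downward, 0 at the
# sediment-water interface; overlying water is negative.

.ANALYTES <- c("O2", "pH", "H2S", "alkalinity", "other")

#' Construct a depth profile
#'
#' A `depth_profile` carries one analyte's depth series: depths in mm
#' (positive downward, 0 = sediment-water interface) and the measured
#' values (uM for concentrations, pH units for pH).
#'
#' @param depths Numeric vector of depths, mm.  Sorted on construction;
#'   must be strictly increasing after sorting (no duplicate depths) and
#'   contain at least 3 points.
#' @param values Numeric vector of measurements, same length as `depths`.
#' @param analyte One of `"O2"`, `"pH"`, `"H2S"`, `"alkalinity"`,
#'   `"other"`.
#' @param sd Optional per-point standard deviations.
#' @param resolution_note Free-text note on measurement resolution.
#' @return An object of class `depth_profile`.
#' @examples
#' depth_profile(c(0, 4, 8), c(280, 140, 0), "O2")
#' @export
depth_profile <- function(depths, values, analyte = "other", sd = NULL,
                          resolution_note = "") {
  analyte <- match.arg(analyte, .ANALYTES)
  depths <- as.numeric(depths); values <- as.numeric(values)
  if (length(depths) != length(values))
    stop("depths and values must have equal length")
  if (length(depths) < 3)
    stop("a depth profile needs at least 3 points, got ", length(depths))
  ord <- order(depths)
  depths <- depths[ord]; values <- values[ord]
  if (!is.null(sd)) sd <- as.numeric(sd)[ord]
  dup <- depths[duplicated(depths)]
  if (length(dup))
    stop("duplicate depths in profile: ", paste(unique(dup), collapse = ", "),
         " mm")
  if (any(!is.finite(depths)) || any(!is.finite(values)))
    stop("depths and values must be finite")
  if (analyte == "pH") {
    if (any(values <= 0 | values >= 14)) stop("pH values must lie in (0, 14)")
  } else if (analyte != "other") {
    if (any(values < 0)) stop("concentration values must be >= 0")
  }
  structure(list(analyte = analyte, depths = depths, values = values,
                 sd = sd, resolution_note = resolution_note),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %s: %d points, %.2f to %.2f mm\n",
              x$analyte, length(x$depths), min(x$depths), max(x$depths)))
  invisible(x)
}

#' @method as.data.frame depth_profile
#' @export
as.data.frame.depth_profile <- function(x, ...) {
  d <- data.frame(depth_mm = x$depths, value = x$values)
  if (!is.null(x$sd)) d$sd <- x$sd
  d
}

#' Read a depth profile from delimited text
#'
#' Reads a comma- or tab-delimited file (auto-detected) with a header row
#' containing `depth_mm` and `value` columns (optional `sd`).  Rows with
#' missing values are dropped with a warning reporting the count; the
#' profile is sorted by depth.  Missing values are never interpolated at
#' load time.
#'
#' @param path File path.
#' @param analyte Analyte name, see [depth_profile()].
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param depth_col,value_col Column names to use.
#' @return A [depth_profile()].
#' @export
read_profile <- function(path, analyte = "other", sep = NULL,
                         depth_col = "depth_mm", value_col = "value") {
  if (!file.exists(path)) stop("cannot read profile file: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE,
                         na.strings = c("NA", "", "NaN"))
  for (col in c(depth_col, value_col))
    if (!col %in% names(d))
      stop("profile file ", path, " lacks required column '", col, "'")
  keep <- is.finite(suppressWarnings(as.numeric(d[[depth_col]]))) &
          is.finite(suppressWarnings(as.numeric(d[[value_col]])))
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning(n_dropped, " row(s) with missing values dropped from ", path)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 3)
    stop("fewer than 3 valid rows in ", path)
  depth_vals <- as.numeric(d[[depth_col]])
  if (anyDuplicated(depth_vals))
    stop("duplicate depth(s) in ", path, ": ",
         paste(unique(depth_vals[duplicated(depth_vals)]), collapse = ", "),
         " mm")
  depth_profile(depth_vals, as.numeric(d[[value_col]]), analyte,
                sd = if ("sd" %in% names(d)) as.numeric(d$sd))
}

#' Write a depth profile to delimited text
#'
#' Counterpart of [read_profile()]; round trips (depths, values) exactly
#' within the printed precision.
#'
#' @param profile A [depth_profile()].
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_profile <- function(profile, path, sep = ",") {
  utils::write.table(as.data.frame(profile), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Re-zero a profile on a stated sediment surface
#'
#' Shifts all depths by `-surface_offset` so the depth given as the true
#' sediment-water interface becomes 0.  Values are unchanged.  Applying
#' an offset and then its negation returns the original profile exactly.
#'
#' @param profile A [depth_profile()].
#' @param surface_offset Depth (mm, in the profile's current coordinates)
#'   of the actual sediment surface.
#' @return A re-zeroed [depth_profile()].
#' @export
align_to_surface <- function(profile, surface_offset) {
  stopifnot(is.finite(surface_offset))
  profile$depths <- profile$depths - surface_offset
  profile
}

#' Bundle profiles and physical metadata into a sediment core
#'
#' @param profiles Named list of [depth_profile()]s; names are analytes
#'   (`O2`, `pH`, `H2S`, ...).  All profiles must share the convention
#'   that 0 is the sediment-water interface.
#' @param porosity Sediment porosity, dimensionless fraction in (0, 1).
#' @param temperature Temperature, degrees C.
#' @param dic Total dissolved inorganic carbon, uM.
#' @param label Free-text label.
#' @return An object of class `sediment_core`.
#' @examples
#' o2 <- depth_profile(c(0, 4, 8), c(280, 140, 0), "O2")
#' ph <- depth_profile(c(0, 5, 27.5), c(7.4, 7.8, 7.3), "pH")
#' core <- sediment_core(list(O2 = o2, pH = ph), porosity = 0.34)
#' @export
sediment_core <- function(profiles, porosity = 0.34, temperature = 20,
                          dic = 5500, label = "") {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be a named list (analyte -> depth_profile)")
  core <- structure(list(profiles = profiles, porosity = porosity,
                         temperature = temperature, dic = dic,
                         label = label),
                    class = "sediment_core")
  findings <- validate_core(core)
  hard <- attr(findings, "errors")
  if (length(hard)) stop("invalid sediment core: ",
                         paste(hard, collapse = "; "))
  core
}

#' @export
print.sediment_core <- function(x, ...) {
  cat(sprintf("<sediment_core> '%s': %s; porosity %.2f, %g C, DIC %g uM\n",
              x$label, paste(names(x$profiles), collapse = ", "),
              x$porosity, x$temperature, x$dic))
  invisible(x)
}

#' Validate a sediment core
#'
#' Checks the core's type invariants and cross-profile consistency.
#' Returns human-readable findings rather than raising errors, so partial
#' or suspect cores can still be inspected.  Invariant violations
#' (porosity, DIC, profile contents) are also attached as attribute
#' `errors`; soft warnings (e.g. disjoint O2/H2S depth ranges) only as
#' findings.
#'
#' @param core A [sediment_core()] (or a bare list with the same fields).
#' @return Character vector of findings; empty when all checks pass.
#' @export
validate_core <- function(core) {
  findings <- character(); errors <- character()
  if (!is.finite(core$porosity) || core$porosity <= 0 || core$porosity >= 1) {
    msg <- sprintf("porosity out of (0,1): %g", core$porosity)
    findings <- c(findings, msg); errors <- c(errors, msg)
  }
  if (!is.finite(core$dic) || core$dic < 0) {
    msg <- sprintf("dic must be >= 0, got %g", core$dic)
    findings <- c(findings, msg); errors <- c(errors, msg)
  }
  for (nm in names(core$profiles)) {
    p <- core$profiles[[nm]]
    if (!inherits(p, "depth_profile")) {
      msg <- sprintf("profile '%s' is not a depth_profile", nm)
      findings <- c(findings, msg); errors <- c(errors, msg)
    }
  }
  o2 <- core$profiles[["O2"]]; h2s <- core$profiles[["H2S"]]
  if (inherits(o2, "depth_profile") && inherits(h2s, "depth_profile")) {
    if (min(h2s$depths) > max(o2$depths) || min(o2$depths) > max(h2s$depths))
      findings <- c(findings, sprintf(
        "O2 (%g-%g mm) and H2S (%g-%g mm) depth ranges do not overlap",
        min(o2$depths), max(o2$depths), min(h2s$depths), max(h2s$depths)))
  }
  attr(findings, "errors") <- errors
  findings
}

#' Read a sediment core from a YAML metadata file
#'
#' The metadata file holds keys `porosity`, `temperature_c`, `dic_uM` and
#' `profiles: {analyte: path}`; profile paths are resolved relative to
#' the metadata file's directory.
#'
#' @param path Path to the YAML core description.
#' @return A [sediment_core()].
#' @export
read_core <- function(path) {
  meta <- yaml::read_yaml(path)
  base <- dirname(path)
  profs <- lapply(names(meta$profiles), function(an) {
    p <- meta$profiles[[an]]
    if (!file.exists(p)) p <- file.path(base, meta$profiles[[an]])
    read_profile(p, analyte = an)
  })
  names(profs) <- names(meta$profiles)
  sediment_core(profs,
                porosity = meta$porosity,
                temperature = if (!is.null(meta$temperature_c))
                  meta$temperature_c else 20,
                dic = if (!is.null(meta$dic_uM)) meta$dic_uM else 5500,
                label = if (!is.null(meta$label)) meta$label else path)
}
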