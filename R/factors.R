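#' Emission and uptake factors
#'
#' Constructs the set of Tier-1 style emission/uptake factors that convert an
#' annual nitrogen input into gas fluxes. All factors are stored as
#' non-negative magnitudes; the flux engine applies the direction (emission
#' versus uptake), which avoids the double-negation traps of mixed sign
#' conventions in published factor tables.
#'
#' Defaults are the values used throughout the package's reference
#' calculations:
#' \describe{
#'   \item{ef_n2o_direct}{0.01 kg N2O-N per kg N applied (direct emission).}
#'   \item{ef_n2o_leach}{0.0075 kg N2O-N per kg NO3-N leached (indirect).}
#'   \item{frac_leach}{0.3 kg NO3-N leached per kg N applied.}
#'   \item{ef_nh3}{0.1 kg NH3-N per kg N applied.}
#'   \item{ef_nox}{0.005 kg NOx-N per kg N applied.}
#'   \item{ef_ch4_lowland}{0.008 kg CH4-C per kg N (emission from flooded
#'     soil).}
#'   \item{ef_ch4_upland}{0.012 kg CH4-C per kg N (magnitude of suppressed
#'     uptake in aerated soil; counted as a warming-direction increase).}
#'   \item{ef_co2_seq}{0.053 kg CO2-C sequestered per kg N.}
#'   \item{f_lowland}{0.15, the fraction of applied N going to flooded
#'     (lowland) soils; the complement weights the upland CH4 term.}
#' }
#'
#' @param ef_n2o_direct,ef_n2o_leach,frac_leach,ef_nh3,ef_nox Numeric scalars,
#'   kg per kg N (see Details).
#' @param ef_ch4_lowland,ef_ch4_upland,ef_co2_seq Numeric scalars, kg C per
#'   kg N, stored as positive magnitudes.
#' @param f_lowland Fraction in \[0, 1\] of N applied to flooded soils.
#' @return An object of class `ngtp_factors`: a named list of validated
#'   factor values.
#' @seealso [ngtp_coefficients()], [annual_fluxes()], [load_factor_config()]
#' @examples
#' f <- ngtp_factors()
#' f$ef_n2o_direct
#' ngtp_factors(frac_leach = 0.2)
#' @export
ngtp_factors <- function(ef_n2o_direct = 0.01,
                         ef_n2o_leach = 0.0075,
                         frac_leach = 0.3,
                         ef_nh3 = 0.1,
                         ef_nox = 0.005,
                         ef_ch4_lowland = 0.008,
                         ef_ch4_upland = 0.012,
                         ef_co2_seq = 0.053,
                         f_lowland = 0.15) {
  x <- list(
    ef_n2o_direct = ef_n2o_direct, ef_n2o_leach = ef_n2o_leach,
    frac_leach = frac_leach, ef_nh3 = ef_nh3, ef_nox = ef_nox,
    ef_ch4_lowland = ef_ch4_lowland, ef_ch4_upland = ef_ch4_upland,
    ef_co2_seq = ef_co2_seq, f_lowland = f_lowland
  )
  validate_factors(x)
  structure(x, class = "ngtp_factors")
}

validate_factors <- function(x) {
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("factor '", nm, "' must be a single finite number", call. = FALSE)
    }
    if (v < 0) {
      stop("factor '", nm, "' must be non-negative (signs are applied by ",
           "the flux engine)", call. = FALSE)
    }
  }
  for (nm in c("frac_leach", "f_lowland")) {
    if (x[[nm]] > 1) {
      stop("factor '", nm, "' is a fraction and must lie in [0, 1], got ",
           x[[nm]], call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.ngtp_factors <- function(x, ...) {
  cat("Emission/uptake factor set (kg per kg N, stored as magnitudes)\n")
  for (nm in names(x)) cat(sprintf("  %-15s %g\n", nm, x[[nm]]))
  invisible(x)
}

## Pathways of the GTP accounting and the mass basis each coefficient
## multiplies. Bases are mixed by construction: N2O/NH3/CH4/CO2 coefficients
## act on molecular mass, NOx coefficients on the nitrogen mass.
gtp_pathways <- c("n2o", "nox_o3_ch4", "nox_aerosol", "nh3_aerosol",
                  "ch4_flux", "co2_flux")

gtp_mass_basis <- c(
  n2o = "kg N2O", nox_o3_ch4 = "kg NOx-N", nox_aerosol = "kg NOx-N",
  nh3_aerosol = "kg NH3", ch4_flux = "kg CH4", co2_flux = "kg CO2"
)

default_gtp_intervals <- function() {
  list(
    n2o         = list(`20` = c(260, 290),  `100` = c(290, 320)),
    nox_o3_ch4  = list(`20` = c(-55, -37),  `100` = c(-2.9, -0.024)),
    nox_aerosol = list(`20` = c(-31, -7),   `100` = c(-0.0024, 0)),
    nh3_aerosol = list(`20` = c(-9.5, -2.2),`100` = c(-0.022, 0)),
    ch4_flux    = list(`20` = c(37, 77),    `100` = c(2.9, 4.9)),
    co2_flux    = list(`20` = c(1, 1),      `100` = c(1, 1))
  )
}

#' GTP coefficient intervals
#'
#' Constructs the set of Global Temperature change Potential (GTP)
#' coefficient intervals, one `(low, high)` interval per pathway and time
#' horizon (20 and 100 years), in kg CO2-equivalent per kg of the pathway's
#' mass basis. Warming pathways (`n2o`, `ch4_flux`, `co2_flux`) carry
#' positive intervals; cooling pathways (`nox_o3_ch4`, `nox_aerosol`,
#' `nh3_aerosol`) carry non-positive ones. Intervals are collapsed to scalars
#' by [resolve_coefficient()] under a range policy (`"low"`, `"mid"`,
#' `"high"`); the package default is the interval midpoint.
#'
#' The mass basis is pathway-specific: N2O, NH3, CH4 and CO2 coefficients
#' multiply molecular mass, NOx coefficients multiply the nitrogen mass of
#' the NOx flux.
#'
#' @param intervals A named list, one entry per pathway, each a list with
#'   elements `"20"` and `"100"` holding numeric `c(low, high)` intervals.
#'   Missing pathways or horizons take the defaults.
#' @return An object of class `ngtp_coefficients` with elements `intervals`
#'   and `mass_basis`.
#' @examples
#' co <- ngtp_coefficients()
#' resolve_coefficient(co, "n2o", 20)                  # 275
#' resolve_coefficient(co, "nh3_aerosol", 100, "mid")  # -0.011
#' @export
ngtp_coefficients <- function(intervals = list()) {
  base <- default_gtp_intervals()
  if (length(intervals)) {
    bad <- setdiff(names(intervals), gtp_pathways)
    if (length(bad)) {
      stop("unknown GTP pathway(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (p in names(intervals)) {
      for (h in names(intervals[[p]])) {
        if (!h %in% c("20", "100")) {
          stop("unknown horizon '", h, "' for pathway '", p,
               "'; horizons are 20 and 100", call. = FALSE)
        }
        base[[p]][[h]] <- intervals[[p]][[h]]
      }
    }
  }
  x <- structure(list(intervals = base, mass_basis = gtp_mass_basis),
                 class = "ngtp_coefficients")
  validate_coefficients(x)
  x
}

validate_coefficients <- function(x) {
  warming <- c("n2o", "ch4_flux", "co2_flux")
  for (p in gtp_pathways) {
    for (h in c("20", "100")) {
      iv <- x$intervals[[p]][[h]]
      if (!is.numeric(iv) || length(iv) != 2L || any(!is.finite(iv))) {
        stop("interval for ", p, " at ", h, " years must be two finite ",
             "numbers", call. = FALSE)
      }
      if (iv[1] > iv[2]) {
        stop("interval for ", p, " at ", h, " years has low > high",
             call. = FALSE)
      }
      if (p %in% warming && iv[1] <= 0) {
        stop("warming pathway ", p, " requires a positive interval",
             call. = FALSE)
      }
      if (!p %in% warming && iv[2] > 0) {
        stop("cooling pathway ", p, " requires a non-positive interval",
             call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' @export
print.ngtp_coefficients <- function(x, ...) {
  cat("GTP coefficient intervals (kg CO2e per kg of mass basis)\n")
  for (p in gtp_pathways) {
    iv20 <- x$intervals[[p]][["20"]]
    iv100 <- x$intervals[[p]][["100"]]
    cat(sprintf("  %-12s [%g, %g] @20y  [%g, %g] @100y  per %s\n",
                p, iv20[1], iv20[2], iv100[1], iv100[2], x$mass_basis[[p]]))
  }
  invisible(x)
}

#' Collapse a GTP coefficient interval to a scalar
#'
#' @param coeffs An [ngtp_coefficients()] object.
#' @param pathway One of `"n2o"`, `"nox_o3_ch4"`, `"nox_aerosol"`,
#'   `"nh3_aerosol"`, `"ch4_flux"`, `"co2_flux"`.
#' @param horizon Time horizon in years, 20 or 100.
#' @param policy `"low"`, `"mid"` or `"high"`: the lower bound, the exact
#'   midpoint `(low + high) / 2`, or the upper bound of the interval. For
#'   cooling pathways (negative intervals) `"low"` is therefore the largest
#'   cooling magnitude.
#' @return A single signed coefficient, kg CO2e per kg of the pathway's mass
#'   basis.
#' @examples
#' resolve_coefficient(ngtp_coefficients(), "co2_flux", 100, "low")  # 1
#' @export
resolve_coefficient <- function(coeffs, pathway, horizon, policy = "mid") {
  stopifnot(inherits(coeffs, "ngtp_coefficients"))
  if (!pathway %in% names(coeffs$intervals)) {
    stop("unknown GTP pathway: ", pathway, call. = FALSE)
  }
  h <- as.character(horizon)
  if (!h %in% names(coeffs$intervals[[pathway]])) {
    stop("unknown horizon: ", horizon, " (available: 20, 100)",
         call. = FALSE)
  }
  policy <- match.arg(policy, c("low", "mid", "high"))
  iv <- coeffs$intervals[[pathway]][[h]]
  switch(policy,
         low = iv[1],
         mid = (iv[1] + iv[2]) / 2,
         high = iv[2])
}

#' Load factors and GTP coefficients from a flat configuration
#'
#' Reads a flat key-value configuration (a YAML file or an already-parsed
#' named list) and returns a validated factor set and coefficient set. Factor
#' keys are the field names of [ngtp_factors()]; GTP intervals are
#' two-element arrays under keys `<pathway>_gtp20` and `<pathway>_gtp100`
#' (e.g. `n2o_gtp20: [260, 290]`). Any key not present keeps its default, so
#' an empty document yields the default model.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A list with elements `factors` ([ngtp_factors()]) and
#'   `coefficients` ([ngtp_coefficients()]).
#' @examples
#' load_factor_config(list(frac_leach = 0.2))$factors$frac_leach
#' @export
load_factor_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("configuration file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) {
    stop("configuration must be a named list or a YAML file path",
         call. = FALSE)
  }
  if (length(config) && (is.null(names(config)) || any(names(config) == ""))) {
    stop("configuration entries must all be named", call. = FALSE)
  }
  factor_keys <- names(formals(ngtp_factors))
  gtp_keys <- c(outer(gtp_pathways, c("_gtp20", "_gtp100"), paste0))
  bad <- setdiff(names(config), c(factor_keys, gtp_keys))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fargs <- config[intersect(names(config), factor_keys)]
  for (nm in names(fargs)) {
    if (!is.numeric(fargs[[nm]])) {
      stop("configuration key '", nm, "' must be numeric", call. = FALSE)
    }
  }
  intervals <- list()
  for (key in intersect(names(config), gtp_keys)) {
    v <- config[[key]]
    if (!is.numeric(v) || length(v) != 2L) {
      stop("configuration key '", key, "' must be a two-element numeric ",
           "array [low, high]", call. = FALSE)
    }
    p <- sub("_gtp(20|100)$", "", key)
    h <- sub("^.*_gtp", "", key)
    intervals[[p]][[h]] <- as.numeric(v)
  }
  list(
    factors = do.call(ngtp_factors, fargs),
    coefficients = ngtp_coefficients(intervals)
  )
}

#' Serialize factors and GTP coefficients to a flat configuration
#'
#' Inverse of [load_factor_config()]: writes every factor and every interval,
#' so that loading the written document reproduces both objects exactly.
#'
#' @param factors An [ngtp_factors()] object.
#' @param coefficients An [ngtp_coefficients()] object.
#' @param path Optional file path; when given, the configuration is written
#'   as YAML.
#' @return The flat named list, invisibly when `path` is given.
#' @export
write_factor_config <- function(factors, coefficients, path = NULL) {
  stopifnot(inherits(factors, "ngtp_factors"),
            inherits(coefficients, "ngtp_coefficients"))
  out <- unclass(factors)
  for (p in gtp_pathways) {
    out[[paste0(p, "_gtp20")]] <- coefficients$intervals[[p]][["20"]]
    out[[paste0(p, "_gtp100")]] <- coefficients$intervals[[p]][["100"]]
  }
  if (is.null(path)) return(out)
  yaml::write_yaml(out, path, precision = 17L)
  invisible(out)
}
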