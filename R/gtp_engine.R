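cooling_cols <- c("cooling_nh3_aerosol", "cooling_nox_o3_ch4",
                  "cooling_nox_aerosol", "cooling_co2_seq")
warming_cols <- c("warming_n2o", "warming_ch4")

#' CO2-equivalent of a single gas flux
#'
#' Multiplies a flux (in the pathway's mass basis) by the magnitude of the
#' resolved GTP coefficient. The result carries a `direction` attribute
#' (`"warming"` or `"cooling"`) taken from the coefficient's sign; note that
#' the CO2 pathway's unit coefficient is positive while the flux it
#' multiplies is an uptake, which the annual decomposition counts as cooling.
#'
#' @param flux Non-negative flux, Tg of the pathway's mass basis
#'   (vectorized).
#' @param pathway,horizon,policy Passed to [resolve_coefficient()].
#' @param coeffs An [ngtp_coefficients()] object.
#' @return Tg CO2e (magnitude), with attribute `direction`.
#' @examples
#' species_gtp(1.4424, "n2o", 20)  # 396.66 Tg CO2e
#' @export
species_gtp <- function(flux, pathway, horizon,
                        coeffs = ngtp_coefficients(), policy = "mid") {
  if (any(flux < 0)) stop("flux must be non-negative", call. = FALSE)
  k <- resolve_coefficient(coeffs, pathway, horizon, policy)
  structure(flux * abs(k),
            direction = if (k >= 0) "warming" else "cooling")
}

#' Annual warming/cooling decomposition at one horizon
#'
#' Maps an annual flux table to its CO2-equivalent decomposition at a single
#' time horizon. Warming components: N2O (direct + indirect) and the net CH4
#' flux increase. Cooling components: NH3 aerosol formation, NOx-induced
#' ozone/CH4 alteration, NOx aerosol formation, and N-induced CO2
#' sequestration. All components are stored as non-negative magnitudes; the
#' sign convention lives entirely in
#' `net = warming_total - cooling_total`.
#'
#' @param fluxes An `ngtp_fluxes` data frame from [annual_fluxes()].
#' @param horizon Time horizon in years, 20 or 100.
#' @param coeffs An [ngtp_coefficients()] object.
#' @param policy Range policy for [resolve_coefficient()] (default `"mid"`).
#' @return A data frame of class `ngtp_gtp`, one row per year, columns
#'   `year`, `horizon`, the six components, `warming_total`, `cooling_total`
#'   and `net`, all in Tg CO2e.
#' @examples
#' fx <- annual_fluxes(anchor_records())
#' annual_gtp(fx, 20)
#' @export
annual_gtp <- function(fluxes, horizon, coeffs = ngtp_coefficients(),
                       policy = "mid") {
  stopifnot(inherits(fluxes, "ngtp_fluxes"))
  out <- data.frame(
    year = fluxes$year,
    horizon = as.integer(horizon),
    warming_n2o = as.numeric(
      species_gtp(fluxes$n2o_total, "n2o", horizon, coeffs, policy)),
    warming_ch4 = as.numeric(
      species_gtp(fluxes$ch4, "ch4_flux", horizon, coeffs, policy)),
    cooling_nh3_aerosol = as.numeric(
      species_gtp(fluxes$nh3, "nh3_aerosol", horizon, coeffs, policy)),
    cooling_nox_o3_ch4 = as.numeric(
      species_gtp(fluxes$nox_n, "nox_o3_ch4", horizon, coeffs, policy)),
    cooling_nox_aerosol = as.numeric(
      species_gtp(fluxes$nox_n, "nox_aerosol", horizon, coeffs, policy)),
    cooling_co2_seq = as.numeric(
      species_gtp(fluxes$co2_uptake, "co2_flux", horizon, coeffs, policy))
  )
  out$warming_total <- out$warming_n2o + out$warming_ch4
  out$cooling_total <- rowSums(as.matrix(out[cooling_cols]))
  out$net <- out$warming_total - out$cooling_total
  class(out) <- c("ngtp_gtp", class(out))
  out
}

#' Shares of the cooling components
#'
#' Fraction of the cooling total contributed by each cooling pathway. With
#' `subset = "nh3_nox"` (the default reported split) the denominator is
#' restricted to the three short-lived pathways (NH3 aerosol, NOx-ozone/CH4,
#' NOx aerosol), excluding CO2 sequestration.
#'
#' @param gtp An `ngtp_gtp` data frame from [annual_gtp()].
#' @param subset `"nh3_nox"` or `"all"`.
#' @return A data frame with `year`, `horizon` and one fractional column per
#'   included pathway; rows sum to 1.
#' @examples
#' g <- annual_gtp(annual_fluxes(anchor_records()), 20)
#' round(100 * cooling_shares(g)[2, "cooling_nh3_aerosol"])  # 69
#' @export
cooling_shares <- function(gtp, subset = c("nh3_nox", "all")) {
  stopifnot(inherits(gtp, "ngtp_gtp"))
  subset <- match.arg(subset)
  cols <- if (subset == "nh3_nox") {
    setdiff(cooling_cols, "cooling_co2_seq")
  } else {
    cooling_cols
  }
  denom <- rowSums(as.matrix(gtp[cols]))
  if (any(denom <= 0)) {
    stop("cooling shares are undefined when the cooling total is zero",
         call. = FALSE)
  }
  cbind(gtp[c("year", "horizon")],
        as.data.frame(as.matrix(gtp[cols]) / denom))
}

#' Aggregate a multi-year GTP decomposition
#'
#' Component-wise sums over a series of annual decompositions at one
#' horizon, with per-pathway shares of the warming and cooling sides.
#' Because every stage of the model is linear in the annual N input, the sum
#' of annual nets equals the net of the summed components exactly.
#'
#' @param gtp An `ngtp_gtp` data frame; all rows must share one horizon and
#'   have distinct years.
#' @return A list of class `ngtp_period`: `horizon`, `years` (range),
#'   `n_years`, `warming_total`, `cooling_total`, `net` (Tg CO2e over the
#'   period), `warming_shares` and `cooling_shares` (fractions summing
#'   to 1).
#' @export
period_summary <- function(gtp) {
  stopifnot(inherits(gtp, "ngtp_gtp"))
  if (nrow(gtp) == 0L) {
    stop("period summary of an empty decomposition", call. = FALSE)
  }
  if (length(unique(gtp$horizon)) != 1L) {
    stop("period summary requires a single horizon; split by horizon first",
         call. = FALSE)
  }
  if (anyDuplicated(gtp$year)) {
    stop("period summary requires distinct years", call. = FALSE)
  }
  w <- colSums(as.matrix(gtp[warming_cols]))
  co <- colSums(as.matrix(gtp[cooling_cols]))
  structure(list(
    horizon = gtp$horizon[1],
    years = range(gtp$year),
    n_years = nrow(gtp),
    warming_total = sum(w),
    cooling_total = sum(co),
    net = sum(w) - sum(co),
    warming_shares = w / sum(w),
    cooling_shares = co / sum(co)
  ), class = "ngtp_period")
}

#' @export
print.ngtp_period <- function(x, ...) {
  cat(sprintf("GTP period summary, %d-year horizon, %d years (%d-%d)\n",
              x$horizon, x$n_years, x$years[1], x$years[2]))
  cat(sprintf("  warming total: %10.2f Tg CO2e\n", x$warming_total))
  cat(sprintf("  cooling total: %10.2f Tg CO2e\n", x$cooling_total))
  cat(sprintf("  net:           %10.2f Tg CO2e\n", x$net))
  cat("  warming shares (%):",
      paste(sprintf("%s %.1f", sub("warming_", "", names(x$warming_shares)),
                    100 * x$warming_shares), collapse = ", "), "\n")
  cat("  cooling shares (%):",
      paste(sprintf("%s %.1f", sub("cooling_", "", names(x$cooling_shares)),
                    100 * x$cooling_shares), collapse = ", "), "\n")
  invisible(x)
}

#' Low/mid/high GTP envelope
#'
#' Recomputes the annual decomposition under the three range policies,
#' exposing the coefficient intervals as an uncertainty envelope. For
#' warming components `low <= mid <= high`; for cooling components the
#' `"low"` policy selects the lower (more negative) interval bound, so
#' cooling magnitudes are ordered `low >= mid >= high`.
#'
#' @inheritParams annual_gtp
#' @return A named list of three `ngtp_gtp` data frames: `low`, `mid`,
#'   `high`.
#' @export
range_envelope <- function(fluxes, horizon, coeffs = ngtp_coefficients()) {
  stats::setNames(
    lapply(c("low", "mid", "high"), function(p) {
      annual_gtp(fluxes, horizon, coeffs, policy = p)
    }),
    c("low", "mid", "high")
  )
}
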