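## Element-to-molecule mass conversions, fixed at integer atomic weights.
## These are deliberate model constants, not configurable: N2O/N2O-N = 44/28,
## NH3/NH3-N = 17/14, CH4/CH4-C = 16/12, CO2/CO2-C = 44/12.
MASS_N2O_PER_N <- 44 / 28
MASS_NH3_PER_N <- 17 / 14
MASS_CH4_PER_C <- 16 / 12
MASS_CO2_PER_C <- 44 / 12

check_n_total <- function(n_total) {
  if (!is.numeric(n_total) || anyNA(n_total)) {
    stop("n_total must be numeric with no missing values", call. = FALSE)
  }
  if (any(n_total < 0)) {
    stop("n_total must be non-negative", call. = FALSE)
  }
  invisible(n_total)
}

#' Nitrous oxide flux from total N input
#'
#' Direct emission is `n_total * ef_n2o_direct`; the leaching-indirect
#' pathway first routes `frac_leach` of the applied N to nitrate leaching and
#' then applies `ef_n2o_leach` to the leached N. Both terms are computed in
#' N2O-N and converted to molecular N2O mass (factor 44/28). Atmospheric
#' deposition contributes implicitly because deposited N is part of
#' `n_total`.
#'
#' @param n_total Total N input, Tg N per year (vectorized).
#' @param factors An [ngtp_factors()] object.
#' @return A data frame with columns `n2o_direct`, `n2o_indirect_leach`,
#'   `n2o_total`, all in Tg N2O per year.
#' @examples
#' n2o_flux(220.70, ngtp_factors())$n2o_total  # 4.248 -> printed as 4.25
#' @export
n2o_flux <- function(n_total, factors = ngtp_factors()) {
  stopifnot(inherits(factors, "ngtp_factors"))
  check_n_total(n_total)
  direct <- n_total * factors$ef_n2o_direct * MASS_N2O_PER_N
  indirect <- n_total * factors$frac_leach * factors$ef_n2o_leach *
    MASS_N2O_PER_N
  data.frame(n2o_direct = direct, n2o_indirect_leach = indirect,
             n2o_total = direct + indirect)
}

#' Nitrate leaching flux
#'
#' `n_total * frac_leach`, reported on the nitrogen-mass basis (Tg NO3-N).
#'
#' @inheritParams n2o_flux
#' @return Tg NO3-N per year.
#' @export
no3_leach_flux <- function(n_total, factors = ngtp_factors()) {
  stopifnot(inherits(factors, "ngtp_factors"))
  check_n_total(n_total)
  n_total * factors$frac_leach
}

#' Ammonia flux
#'
#' `n_total * ef_nh3`, converted to molecular NH3 mass (factor 17/14).
#'
#' @inheritParams n2o_flux
#' @return Tg NH3 per year.
#' @examples
#' nh3_flux(220.70)  # 26.80 Tg NH3
#' @export
nh3_flux <- function(n_total, factors = ngtp_factors()) {
  stopifnot(inherits(factors, "ngtp_factors"))
  check_n_total(n_total)
  n_total * factors$ef_nh3 * MASS_NH3_PER_N
}

#' NOx flux
#'
#' `n_total * ef_nox`, reported on the nitrogen-mass basis (no molecular
#' conversion): the GTP coefficients for both NOx pathways are defined per
#' kg NOx-N.
#'
#' @inheritParams n2o_flux
#' @return Tg NOx-N per year.
#' @export
nox_flux <- function(n_total, factors = ngtp_factors()) {
  stopifnot(inherits(factors, "ngtp_factors"))
  check_n_total(n_total)
  n_total * factors$ef_nox
}

#' Net methane flux increase attributable to N use
#'
#' N addition increases CH4 emission from flooded (lowland) soils and
#' suppresses CH4 uptake in aerated (upland) soils; both move the atmospheric
#' burden upward, so both enter with warming direction:
#' `n_total * (f_lowland * ef_ch4_lowland + (1 - f_lowland) * ef_ch4_upland)`
#' in CH4-C, converted to molecular CH4 (factor 16/12).
#'
#' @inheritParams n2o_flux
#' @return Tg CH4 per year.
#' @examples
#' ch4_flux(220.70)  # 3.35 Tg CH4
#' @export
ch4_flux <- function(n_total, factors = ngtp_factors()) {
  stopifnot(inherits(factors, "ngtp_factors"))
  check_n_total(n_total)
  ef <- factors$f_lowland * factors$ef_ch4_lowland +
    (1 - factors$f_lowland) * factors$ef_ch4_upland
  n_total * ef * MASS_CH4_PER_C
}

#' CO2 uptake (sequestration) attributable to N use
#'
#' `n_total * ef_co2_seq` in CO2-C, converted to molecular CO2 (factor
#' 44/12), returned as a positive sequestration magnitude; the GTP engine
#' counts it on the cooling side.
#'
#' @inheritParams n2o_flux
#' @return Tg CO2 per year (magnitude of uptake).
#' @examples
#' co2_uptake_flux(220.70)  # 42.89 Tg CO2
#' @export
co2_uptake_flux <- function(n_total, factors = ngtp_factors()) {
  stopifnot(inherits(factors, "ngtp_factors"))
  check_n_total(n_total)
  n_total * factors$ef_co2_seq * MASS_CO2_PER_C
}

#' All annual gas fluxes from an N-source table
#'
#' Composes the single-gas flux operations over [total_n_input()]: every flux
#' is linear in the annual total N, so the whole record is proportional to
#' `n_total` under fixed factors.
#'
#' @param records An `ngtp_sources` data frame (see [n_sources()]).
#' @param factors An [ngtp_factors()] object.
#' @return A data frame of class `ngtp_fluxes`, one row per year, with
#'   columns `year`, `n_total` (Tg N), `n2o_direct`, `n2o_indirect_leach`,
#'   `n2o_total` (Tg N2O), `no3_leach_n` (Tg NO3-N), `nh3` (Tg NH3), `nox_n`
#'   (Tg NOx-N), `ch4` (Tg CH4), `co2_uptake` (Tg CO2).
#' @examples
#' annual_fluxes(anchor_records())
#' @export
annual_fluxes <- function(records, factors = ngtp_factors()) {
  records <- validate_n_sources(records)
  n_total <- total_n_input(records)
  n2o <- n2o_flux(n_total, factors)
  out <- data.frame(
    year = records$year,
    n_total = n_total,
    n2o_direct = n2o$n2o_direct,
    n2o_indirect_leach = n2o$n2o_indirect_leach,
    n2o_total = n2o$n2o_total,
    no3_leach_n = no3_leach_flux(n_total, factors),
    nh3 = nh3_flux(n_total, factors),
    nox_n = nox_flux(n_total, factors),
    ch4 = ch4_flux(n_total, factors),
    co2_uptake = co2_uptake_flux(n_total, factors)
  )
  class(out) <- c("ngtp_fluxes", class(out))
  out
}
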