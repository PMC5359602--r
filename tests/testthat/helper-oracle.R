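## Independent single-expression recomputation of the whole chain from a
## total N input, written directly from the model definition (not from the
## package internals). Used to cross-check the engines on random inputs.
oracle_fluxes <- function(n) {
  list(
    n2o = n * (0.01 + 0.3 * 0.0075) * 44 / 28,
    no3 = n * 0.3,
    nh3 = n * 0.1 * 17 / 14,
    nox = n * 0.005,
    ch4 = n * (0.15 * 0.008 + 0.85 * 0.012) * 16 / 12,
    co2 = n * 0.053 * 44 / 12
  )
}

## Midpoint GTP coefficients per pathway, keyed by horizon.
oracle_mid <- list(
  `20` = c(n2o = 275, nox_o3_ch4 = -46, nox_aerosol = -19,
           nh3_aerosol = -5.85, ch4 = 57, co2 = 1),
  `100` = c(n2o = 305, nox_o3_ch4 = -1.462, nox_aerosol = -0.0012,
            nh3_aerosol = -0.011, ch4 = 3.9, co2 = 1)
)

oracle_net <- function(n, horizon) {
  f <- oracle_fluxes(n)
  k <- oracle_mid[[as.character(horizon)]]
  warming <- f$n2o * k[["n2o"]] + f$ch4 * k[["ch4"]]
  cooling <- f$nh3 * abs(k[["nh3_aerosol"]]) +
    f$nox * abs(k[["nox_o3_ch4"]]) + f$nox * abs(k[["nox_aerosol"]]) +
    f$co2 * k[["co2"]]
  list(warming = warming, cooling = cooling, net = warming - cooling)
}

## One-year source record with a given total, split unevenly across sources.
record_with_total <- function(n, year = 2000L) {
  w <- c(0.4, 0.25, 0.15, 0.1, 0.1)
  n_sources(year, n * w[1], n * w[2], n * w[3], n * w[4], n * w[5])
}
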