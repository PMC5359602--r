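anchor_gtp <- function(horizon, policy = "mid") {
  annual_gtp(annual_fluxes(anchor_records()), horizon,
             ngtp_coefficients(), policy)
}

test_that("species GTP scales flux by the resolved coefficient magnitude", {
  co <- ngtp_coefficients()
  g <- species_gtp(1.4424, "n2o", 20, co)
  expect_equal(round(as.numeric(g), 2), 396.66)
  expect_identical(attr(g, "direction"), "warming")

  g2 <- species_gtp(42.89, "co2_flux", 100, co)
  expect_equal(as.numeric(g2), 42.89)

  g3 <- species_gtp(26.7993, "nh3_aerosol", 20, co)
  expect_equal(round(as.numeric(g3), 2), 156.78)
  expect_identical(attr(g3, "direction"), "cooling")

  expect_error(species_gtp(1, "n2", 20, co), "unknown GTP pathway")
  expect_error(species_gtp(-1, "n2o", 20, co), "non-negative")
})

test_that("annual decomposition reproduces the published 1961/2010 results", {
  g20 <- anchor_gtp(20)
  g100 <- anchor_gtp(100)
  tol <- 0.5
  # 1961 row, 20-year horizon
  expect_equal(g20$warming_n2o[1], 396.67, tolerance = tol / 396.67)
  expect_equal(g20$cooling_total[1], 92.14, tolerance = tol / 92.14)
  expect_equal(g20$net[1], 369.44, tolerance = tol / 369.44)
  # 2010 rows
  expect_equal(g20$net[2], 1088.15, tolerance = tol / 1088.15)
  expect_equal(g100$warming_n2o[2], 1295.78, tolerance = tol / 1295.78)
  expect_equal(g100$net[2], 1264.06, tolerance = tol / 1264.06)
  expect_equal(g100$cooling_total[2], 44.80, tolerance = tol / 44.80)

  zero <- annual_gtp(annual_fluxes(n_sources(2000, 0, 0, 0, 0, 0)), 20)
  expect_true(all(as.matrix(zero[, -(1:2)]) == 0))
})

test_that("decomposition identities hold exactly", {
  for (h in c(20, 100)) {
    g <- anchor_gtp(h)
    expect_identical(g$warming_total, g$warming_n2o + g$warming_ch4)
    expect_equal(g$cooling_total,
                 g$cooling_nh3_aerosol + g$cooling_nox_o3_ch4 +
                   g$cooling_nox_aerosol + g$cooling_co2_seq,
                 tolerance = 1e-15)
    expect_identical(g$net, g$warming_total - g$cooling_total)
    comp <- setdiff(names(g), c("year", "horizon", "net"))
    expect_true(all(as.matrix(g[comp]) >= 0))
  }
})

test_that("cooling shares reproduce the published 69/22/9 aerosol split", {
  g20 <- anchor_gtp(20)
  sh <- cooling_shares(g20, subset = "nh3_nox")
  expect_equal(round(100 * sh$cooling_nh3_aerosol[2]), 69)
  expect_equal(round(100 * sh$cooling_nox_o3_ch4[2]), 22)
  expect_equal(round(100 * sh$cooling_nox_aerosol[2]), 9)
  expect_equal(round(100 * unlist(sh[1, -(1:2)], use.names = FALSE), 1),
               c(68.6, 22.2, 9.2))
  expect_equal(rowSums(sh[, -(1:2)]), c(1, 1), tolerance = 1e-12)

  sh_all <- cooling_shares(g20, subset = "all")
  expect_equal(rowSums(sh_all[, -(1:2)]), c(1, 1), tolerance = 1e-12)

  zero <- annual_gtp(annual_fluxes(n_sources(2000, 0, 0, 0, 0, 0)), 20)
  expect_error(cooling_shares(zero), "undefined")
})

test_that("period aggregation is additive with shares summing to one", {
  g <- anchor_gtp(20)
  one <- period_summary(g[1, ])
  two_years <- g[c(1, 1), ]
  two_years$year <- c(1961L, 1962L)
  doubled <- period_summary(two_years)
  expect_equal(doubled$warming_total, 2 * one$warming_total)
  expect_equal(doubled$cooling_total, 2 * one$cooling_total)
  expect_equal(doubled$net, 2 * one$net)
  expect_equal(sum(doubled$warming_shares), 1, tolerance = 1e-12)
  expect_equal(sum(doubled$cooling_shares), 1, tolerance = 1e-12)

  mixed <- rbind(anchor_gtp(20)[1, ], anchor_gtp(100)[2, ])
  expect_error(period_summary(mixed), "single horizon")
  expect_error(period_summary(g[0, ]), "empty")
  expect_error(period_summary(g[c(1, 1), ]), "distinct years")
})

test_that("coefficient envelope brackets the midpoint decomposition", {
  fx <- annual_fluxes(anchor_records())
  for (h in c(20, 100)) {
    env <- range_envelope(fx, h)
    expect_identical(env$mid, annual_gtp(fx, h))
    for (cl in c("warming_n2o", "warming_ch4")) {
      expect_true(all(env$low[[cl]] <= env$mid[[cl]] &
                        env$mid[[cl]] <= env$high[[cl]]))
    }
    # "low" policy = more negative coefficient = larger cooling magnitude
    for (cl in c("cooling_nh3_aerosol", "cooling_nox_o3_ch4",
                 "cooling_nox_aerosol")) {
      expect_true(all(env$low[[cl]] >= env$mid[[cl]] &
                        env$mid[[cl]] >= env$high[[cl]]))
    }
    expect_true(all(env$low$net <= env$mid$net & env$mid$net <= env$high$net))
  }
  # interval arithmetic check on the N2O warming span, 1961 at 20 years
  env20 <- range_envelope(fx, 20)
  expect_equal(env20$low$warming_n2o[1], fx$n2o_total[1] * 260)
  expect_equal(env20$high$warming_n2o[1], fx$n2o_total[1] * 290)
  # degenerate CO2 interval: identical bounds
  expect_equal(env20$low$cooling_co2_seq, env20$high$cooling_co2_seq)
})

test_that("short-lived cooling shrinks from the 20- to the 100-year horizon", {
  g20 <- anchor_gtp(20)
  g100 <- anchor_gtp(100)
  for (cl in c("cooling_nh3_aerosol", "cooling_nox_o3_ch4",
               "cooling_nox_aerosol")) {
    expect_true(all(g100[[cl]] < g20[[cl]]))
  }
})

test_that("net GTP sits 6.9% (20-yr) and 2.4% (100-yr) below N2O-only GTP", {
  g20 <- anchor_gtp(20)
  g100 <- anchor_gtp(100)
  expect_equal(round(100 * (1 - g20$net[2] / g20$warming_n2o[2]), 1), 6.9)
  expect_equal(round(100 * (1 - g100$net[2] / g100$warming_n2o[2]), 1), 2.4)
})

test_that("period shares are trajectory-independent and match the published split", {
  # every pathway is proportional to cumulative N input under fixed factors,
  # so period shares do not depend on the annual trajectory at all
  s <- generate_series(series_spec(noise_cv = 0))
  p20 <- period_summary(annual_gtp(annual_fluxes(s), 20))
  p100 <- period_summary(annual_gtp(annual_fluxes(s), 100))
  p20_anchor <- period_summary(anchor_gtp(20))
  expect_equal(p20$cooling_shares, p20_anchor$cooling_shares)
  expect_equal(round(100 * unname(p20$cooling_shares), 1),
               c(57.8, 18.7, 7.7, 15.8))
  expect_equal(round(100 * unname(p20$warming_shares)), c(86, 14))
  expect_equal(round(100 * unname(p100$warming_shares)), c(99, 1))
  expect_equal(round(100 * p100$cooling_shares[["cooling_co2_seq"]], 1), 95.7)
})

test_that("decomposition matches hand-rolled arithmetic on the 2x2 grid", {
  fx <- annual_fluxes(anchor_records())
  for (h in c(20, 100)) {
    g <- annual_gtp(fx, h)
    for (i in 1:2) {
      o <- oracle_net(fx$n_total[i], h)
      expect_equal(g$warming_total[i], o$warming, tolerance = 1e-12)
      expect_equal(g$cooling_total[i], o$cooling, tolerance = 1e-12)
      expect_equal(g$net[i], o$net, tolerance = 1e-12)
    }
  }
})
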