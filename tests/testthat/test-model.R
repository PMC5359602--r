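test_that("the model object bundles parameters, fluxes and decomposition", {
  m <- ngtp(anchor_records())
  expect_s3_class(m, "ngtp")
  expect_equal(m$policy, "mid")
  expect_equal(nrow(m$gtp), 4)  # 2 years x 2 horizons
  expect_output(print(m), "net GTP20")
  expect_error(ngtp(horizons = 50), "subset")
  expect_error(ngtp(anchor_records(), policy = "median"), "arg")
})

test_that("coef() returns the resolved pathway-by-horizon matrix", {
  k <- coef(ngtp())
  expect_equal(dim(k), c(6, 2))
  expect_equal(k["n2o", "gtp20"], 275)
  expect_equal(k["nh3_aerosol", "gtp100"], -0.011)
  k_low <- coef(ngtp(policy = "low"))
  expect_equal(k_low["ch4_flux", "gtp20"], 37)
})

test_that("predict() agrees with the decomposition stored at construction", {
  m <- ngtp(anchor_records())
  expect_equal(predict(m, anchor_records()), m$gtp, ignore_attr = TRUE)
  expect_equal(predict(m, anchor_records(), type = "flux"), m$fluxes)
  expect_equal(predict(m, anchor_records(), type = "budget"),
               c(74.94, 220.70))
})

test_that("summary() aggregates each horizon over the attached years", {
  m <- ngtp(anchor_records())
  s <- summary(m)
  expect_named(s$periods, c("gtp20", "gtp100"))
  g20 <- m$gtp[m$gtp$horizon == 20, ]
  expect_equal(s$periods$gtp20$net, sum(g20$net))
  expect_output(print(s), "warming total")
  expect_error(summary(ngtp()), "no data")
})

test_that("plot() renders without data-dependent errors", {
  m <- ngtp(anchor_records())
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(m, components = TRUE))
  expect_error(plot(ngtp()), "no data")
})

test_that("simulate() is reproducible and returns valid source series", {
  m <- ngtp()
  s1 <- simulate(m, nsim = 2, seed = 5,
                 spec = series_spec(noise_cv = 0.05))
  s2 <- simulate(m, nsim = 2, seed = 5,
                 spec = series_spec(noise_cv = 0.05))
  expect_identical(s1, s2)
  expect_length(s1, 2)
  expect_false(identical(s1[[1]], s1[[2]]))
  expect_s3_class(s1[[1]], "ngtp_sources")
})

test_that("run_pipeline writes the complete artifact set from a CSV", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "anchors.csv")
  write.csv(anchor_records(), csv, row.names = FALSE)
  cfg <- run_config(input = csv, output_dir = file.path(dir, "out"),
                    verbose = FALSE)
  res <- run_pipeline(cfg)
  expect_setequal(basename(res$files),
                  c("budget.csv", "fluxes.csv", "gtp_20.csv", "gtp_100.csv",
                    "summary.csv", "summary.txt"))
  expect_true(all(file.exists(res$files)))
  g20 <- read.csv(file.path(dir, "out", "gtp_20.csv"), comment.char = "#")
  expect_equal(round(g20$warming_n2o, 2), c(396.71, 1168.33))
  # machine-readable outputs are unrounded library results
  expect_equal(g20$net, res$model$gtp$net[res$model$gtp$horizon == 20])
})

test_that("pipeline validation fails cleanly without partial outputs", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines("year,fertilizer_n", bad)  # schema-incomplete input
  out <- file.path(dir, "out")
  cfg <- run_config(input = bad, output_dir = out, verbose = FALSE)
  expect_error(run_pipeline(cfg))
  expect_false(dir.exists(out))

  expect_error(run_config(), "exactly one input mode")
  expect_error(run_config(input = "a.csv", simulate = series_spec()),
               "exactly one input mode")
})

test_that("simulate-mode pipeline runs are reproducible end to end", {
  dir <- withr::local_tempdir()
  mk <- function(sub) {
    cfg <- run_config(simulate = series_spec(noise_cv = 0.05, seed = 9L),
                      output_dir = file.path(dir, sub), verbose = FALSE)
    run_pipeline(cfg)
    readLines(file.path(dir, sub, "gtp_20.csv"))
  }
  expect_identical(mk("a"), mk("b"))
})

test_that("the reproduction report covers all references within tolerance", {
  rep <- reproduction_report()
  expect_gte(nrow(rep), 20)
  expect_true(all(rep$within))
  expect_equal(rep$tolerance, pmax(0.005 * abs(rep$reference), 0.5))
  # a relaxed tolerance flags nothing either
  expect_true(all(reproduction_report(tolerance_abs = 1e6)$within))
})
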