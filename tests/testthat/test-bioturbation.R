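test_that("excavation flux matches its closed form and linearities", {
  expect_equal(as.numeric(excavation_flux(0, 0.05)), 0)
  # 0.5 * 0.6 * 1825 * 0.1 * 9.81 * 0.05, evaluated by hand
  expect_equal(as.numeric(excavation_flux(0.1, 0.05)), 26.85488,
               tolerance = 1e-6)
  expect_equal(as.numeric(excavation_flux(0.1, 0.10)),
               2 * as.numeric(excavation_flux(0.1, 0.05)))
  expect_equal(as.numeric(excavation_flux(0.2, 0.05)),
               2 * as.numeric(excavation_flux(0.1, 0.05)))
  expect_error(excavation_flux(0.1, 0.05, rho_s = 1000), "non-sinking")
  expect_error(excavation_flux(-0.1, 0.05), ">= 0")
})

test_that("crack flux matches its closed form and linearities", {
  expect_equal(as.numeric(crack_flux(0, 0.005)), 0)
  # 2 * 1 * 0.1 / (pi * 0.005) by hand
  expect_equal(as.numeric(crack_flux(0.1, 0.005)), 12.7324, tolerance = 1e-5)
  expect_equal(as.numeric(crack_flux(0.1, 0.0025)),
               2 * as.numeric(crack_flux(0.1, 0.005)))
  expect_equal(as.numeric(crack_flux(0.2, 0.005)),
               2 * as.numeric(crack_flux(0.1, 0.005)))
  expect_error(crack_flux(0.1, 0), "> 0")
  expect_error(crack_flux(0.1, 0.005, G_c = -1), "G_c")
})

test_that("discrete excavation work converges to the closed form", {
  closed <- excavation_work(b = 0.005, d = 0.1)
  expect_equal(closed,
               0.5 * 0.6 * 1825 * pi * 0.005^2 * 9.81 * 0.01)
  # midpoint rule is exact for the linear integrand, even with one slab
  expect_equal(excavation_work(0.005, 0.1, method = "riemann",
                               n_segments = 1, rule = "midpoint"), closed)
  # left sums converge from below at order 1/n
  for (n in c(10, 100, 1000)) {
    left <- excavation_work(0.005, 0.1, method = "riemann",
                            n_segments = n, rule = "left")
    expect_equal(left, closed * (n - 1) / n, tolerance = 1e-12)
  }
  big <- excavation_work(0.005, 0.1, method = "riemann", n_segments = 1e5)
  expect_lt(abs(big - closed) / closed, 1e-4)  # < 0.01 %
  expect_equal(excavation_work(0.005, 0), 0)
})

test_that("reworking tables round-trip through CSV with validation", {
  path <- system.file("extdata", "example_reworking_table.csv",
                      package = "seafloorenergy")
  tbl <- read_reworking_table(path)
  expect_s3_class(tbl, "reworking_table")
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$reworking_rate, c(120, 0.5, 5e-4))
  expect_equal(tbl$mode, c("both", "crack_propagation", "excavation"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_reworking_table(tbl, tmp)
  expect_equal(read_reworking_table(tmp), tbl)
})

test_that("table reading reports bad rows and missing columns", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,group,reworking_rate,burrow_radius,burrow_depth",
               "a,molluscs,1,0.01,0.1",
               "b,molluscs,-2,0.01,0.1"), tmp)
  expect_error(read_reworking_table(tmp), "row 2")
  expect_warning(ok <- read_reworking_table(tmp, permissive = TRUE), "row 2")
  expect_equal(ok$taxon, "a")

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,group,reworking_rate", "a,molluscs,1"), tmp2)
  expect_error(read_reworking_table(tmp2), "missing required columns")

  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("taxon,group,reworking_rate,burrow_radius,burrow_depth", tmp3)
  expect_warning(empty <- read_reworking_table(tmp3), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("synthetic tables are deterministic and span the configured decades", {
  t1 <- synthesize_reworking_table(seed = 5)
  t2 <- synthesize_reworking_table(seed = 5)
  expect_identical(t1, t2)
  t3 <- synthesize_reworking_table(seed = 6)
  expect_false(identical(t1$reworking_rate, t3$reworking_rate))
  # excavation fluxes alone separate by >= 9 decades under the defaults
  exc <- as.numeric(excavation_flux(t1$reworking_rate, t1$burrow_depth))
  expect_gte(log10(max(exc) / min(exc)), 9)
  expect_equal(nrow(synthesize_reworking_table(seed = 1,
                                               n_taxa_per_group = 0)), 0)
  expect_error(synthesize_reworking_table(seed = 1, group_specs = NULL),
               "at least one group")
})

test_that("flux distributions use linear-interpolation quartiles", {
  tbl <- reworking_table(taxon = letters[1:5], group = "g",
                         reworking_rate = c(1, 2, 3, 4, 5) / 5370.975,
                         burrow_radius = 0.005, burrow_depth = 1)
  dist <- flux_distributions(tbl, "excavation")
  pooled <- dist[dist$group == "all", ]
  # fluxes are exactly 1..5; type-7 quartiles of 1..5 are 2, 3, 4
  expect_equal(pooled$q25, 2, tolerance = 1e-9)
  expect_equal(pooled$median, 3, tolerance = 1e-9)
  expect_equal(pooled$q75, 4, tolerance = 1e-9)
  expect_equal(pooled$min, 1, tolerance = 1e-9)
  expect_equal(pooled$max, 5, tolerance = 1e-9)
  single <- flux_distributions(tbl[1, ], "excavation")
  expect_true(all(abs(as.numeric(single[1, c("min", "q25", "median",
                                             "q75", "max")]) - 1) < 1e-9))
})

test_that("crack-propagation medians exceed excavation medians on shared rates", {
  for (seed in c(2, 17)) {
    tbl <- synthesize_reworking_table(seed = seed)
    exc <- flux_distributions(tbl, "excavation")
    crk <- flux_distributions(tbl, "crack_propagation")
    expect_gt(crk$median[crk$group == "all"],
              exc$median[exc$group == "all"])
  }
})

test_that("bioturbation scenario levels are ordered quartiles", {
  lv <- bioturbation_levels(synthesize_reworking_table(seed = 3))
  expect_equal(lv[["none"]], 0)
  expect_true(all(diff(lv) > 0))
})
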