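# Integral measures, CSA profiles, WSS histograms, cohort summaries.

test_that("weighted quantiles interpolate the weighted ECDF", {
  expect_equal(weighted_quantile(c(1, 2, 3, 4), rep(1, 4), 0.5), 2.5)
  expect_equal(weighted_quantile(c(1, 2, 3, 4), rep(1, 4), 0), 1)
  expect_equal(weighted_quantile(c(1, 2, 3, 4), rep(1, 4), 1), 4)
  # heavy weight drags the quantile: placements 0.45 / 0.95, so p = 0.5
  # interpolates 1 + (0.05/0.5) * 9 = 1.9
  expect_equal(weighted_quantile(c(1, 10), c(9, 1), 0.5), 1.9,
               tolerance = 1e-12)
  # monotone under pointwise increase of the values
  x <- c(0.1, 0.5, 0.2, 0.9)
  w <- c(1, 2, 3, 4)
  expect_gte(weighted_quantile(x + 0.3, w, 0.999),
             weighted_quantile(x, w, 0.999))
})

test_that("integral measures reduce to closed forms on a uniform tube", {
  g <- template_geometry(circular_template(r_mm = 4, length_mm = 80))
  sols <- simulate_phases(g, flow_mls = 200)
  im <- integral_measures(g, sols$inspiration)
  # u = Q/A everywhere: volume average and percentile collapse
  u_ref <- 100e-6 / (pi * 0.004^2)
  expect_equal(im$u_avg, u_ref, tolerance = 1e-12)
  expect_equal(im$u_p999, u_ref, tolerance = 1e-12)
  expect_equal(im$u_max, u_ref, tolerance = 1e-12)
  # constant wall shear: average = percentile = max
  expect_equal(im$wss_avg, im$wss_p999, tolerance = 1e-12)
  expect_equal(im$wss_avg, im$wss_max, tolerance = 1e-12)
  expect_equal(im$AP_pct, 50)
  expect_lte(im$R_total, min(im$R_left, im$R_right))
  sol_nowall <- solve_bilateral_partition(g)
  expect_error(integral_measures(g, sol_nowall), "wall")
})

test_that("integral-measure invariants hold on nasal-like geometry", {
  g <- template_geometry(small_template())
  sols <- simulate_phases(g, flow_mls = 200, losses = TRUE)
  for (sol in sols) {
    im <- integral_measures(g, sol)
    expect_lte(im$R_total, min(im$R_left, im$R_right))
    expect_gt(im$AP_pct, 0)
    expect_lt(im$AP_pct, 100)
    expect_gte(im$u_p999, im$u_avg)
    expect_gte(im$wss_p999, im$wss_avg)
    expect_gte(im$u_max, im$u_p999)
    expect_gte(im$wss_max, im$wss_p999)
  }
})

test_that("CSA profiles sample the 5% grid and locate the isthmus", {
  g <- template_geometry(circular_template(r_mm = 3))
  cp <- csa_profile(g)
  expect_equal(cp$table$s, rep(seq(0, 1, 0.05), 2))
  expect_equal(cp$table$area_mm2, rep(pi * 9, 42), tolerance = 1e-9)
  expect_equal(cp$min_csa$area_mm2, rep(pi * 9, 2), tolerance = 1e-9)

  gn <- template_geometry(duct_template())  # default nasal template
  cpn <- csa_profile(gn)
  expect_true(all(cpn$min_csa$s >= 0.10 & cpn$min_csa$s <= 0.20))
  # the minimum over the station grid is never above any 5% sample
  expect_lte(cpn$min_csa$area_mm2[1],
             min(cpn$table$area_mm2[cpn$table$side == "left"]))
})

test_that("WSS surface histograms do exact area bookkeeping", {
  # constant 0.005 Pa field falls entirely in the first (0, 0.01] bin
  g <- template_geometry(small_template())
  h <- wss_histogram(rep(0.005, nrow(g$vertices)), g)
  expect_equal(h$area_pct[1], 100)
  expect_equal(sum(h$area_pct), 100, tolerance = 1e-9)

  # two equal-area triangles at 0.005 and 0.5 Pa with edges (0, 0.01, 1]
  mesh <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                c(1, 1, 0)),
               triangles = rbind(c(1, 2, 3), c(2, 4, 3)))
  vals <- c(0.005, 0.005, 0.005, 1.49)  # triangle means 0.005 and 0.5
  h2 <- wss_histogram(vals, mesh, bin_edges = c(0, 0.01, 1))
  expect_equal(h2$area_pct, c(50, 50))
  expect_error(wss_histogram(vals, mesh, bin_edges = c(0, 0, 1)),
               "increasing")
})

test_that("cohort summaries compute Tukey statistics and position flags", {
  measures <- data.frame(phase = "inspiration",
                         R_total = c(0.02, 0.03, 0.04))
  avg <- data.frame(phase = "inspiration", R_total = 0.01)
  s <- corpus_summary(measures, avg)
  expect_equal(s$mean, 0.03)
  expect_equal(s$median, 0.03)
  expect_equal(s$sd, 0.01)
  expect_true(s$below_median)
  expect_false(s$within_iqr)
  expect_lte(s$q1, s$median)
  expect_lte(s$median, s$q3)
  expect_error(corpus_summary(measures,
                              data.frame(phase = "expiration",
                                         R_total = 0.01)),
               "phase mismatch")
  expect_error(corpus_summary(measures[1, ], avg), "two")
})

test_that("expiration ratios use unrounded per-subject ratios", {
  expect_equal(expiration_ratio(c(0.03, 0.02), c(0.03, 0.02))$mean_of_ratios_pct,
               0)
  er <- expiration_ratio(0.030, 0.040)
  expect_equal(er$mean_of_ratios_pct, 100 / 3, tolerance = 1e-9)
  # losses-off proxy: exact reversibility means exactly zero for every subject
  tpl <- small_template()
  spec <- shape_variation(n_modes = 2, mode_sd = c(5, 3), noise_sd = 0.02,
                          seed = 23)
  co <- generate_corpus(tpl, spec, 3)
  R <- vapply(co$members, function(g) {
    s <- simulate_phases(g, losses = FALSE)
    c(s$inspiration$R_total, s$expiration$R_total)
  }, numeric(2))
  er0 <- expiration_ratio(R[1, ], R[2, ])
  expect_equal(er0$per_subject_pct, rep(0, 3), tolerance = 1e-10)
  expect_error(expiration_ratio(0, 0.1), "positive")
})

test_that("report rounding follows the table conventions", {
  x <- data.frame(phase = "inspiration", R_total = 0.0205, u_avg = 0.777,
                  AP_pct = 51.13)
  r <- round_for_report(x)
  expect_equal(r$R_total, 0.020)  # half-to-even at 3 decimals
  expect_equal(r$u_avg, 0.78)
  expect_equal(r$AP_pct, 51.1)
})
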