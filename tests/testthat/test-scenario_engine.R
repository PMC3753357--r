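test_that("percent_change reproduces direct arithmetic and rejects zero baselines", {
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(43.1, 38.2), 100 * (38.2 - 43.1) / 43.1)
  expect_error(percent_change(0, 1), "zero baseline")
})

test_that("land-cover rebalancing keeps the LA:LF ratio and sums to 100", {
  expect_equal(rebalance_landcover(20, 60, 20, 1),
               data.frame(li_pct = 20, la_pct = 60, lf_pct = 20))
  expect_equal(rebalance_landcover(20, 60, 20, 2),
               data.frame(li_pct = 40, la_pct = 45, lf_pct = 15))
  expect_equal(rebalance_landcover(20, 60, 20, 0),
               data.frame(li_pct = 0, la_pct = 75, lf_pct = 25))
  expect_equal(rebalance_landcover(76, 18, 6, 2),
               data.frame(li_pct = 100, la_pct = 0, lf_pct = 0))
  expect_error(rebalance_landcover(20, 60, 10, 1), "sum to 100")
  expect_error(rebalance_landcover(20, 60, 20, -1), "non-negative")
  # property: conservation and ratio preservation over random compositions
  set.seed(5)
  for (i in 1:50) {
    w <- runif(3)
    c0 <- 100 * w / sum(w)
    m <- runif(1, 0, 2)
    out <- rebalance_landcover(c0[1], c0[2], c0[3], m)
    expect_lt(abs(out$li_pct + out$la_pct + out$lf_pct - 100), 1e-9)
    if (out$li_pct < 100) {
      expect_equal(out$la_pct / out$lf_pct, c0[2] / c0[3])
    }
  }
  # zero non-urban cover falls back to the configured split
  expect_equal(rebalance_landcover(100, 0, 0, 0.5, fallback_ratio = 0.25),
               data.frame(li_pct = 50, la_pct = 12.5, lf_pct = 37.5))
})

test_that("pressure multipliers scale S, rebalance cover and leave the rest", {
  r <- make_record(s_ratio = 33.8, li = 20, la = 60, lf = 20)
  expect_identical(apply_multipliers(r, 1, 1), r)
  r2 <- apply_multipliers(r, 0.7, 2)
  expect_equal(r2$s_ratio, 23.66)
  expect_equal(r2$li_pct, 40)
  expect_equal(r2$la_pct, 45)
  expect_equal(r2$depth_m, r$depth_m)
  expect_equal(r2$catchment_area_km2, r$catchment_area_km2)
  expect_error(apply_multipliers(r, -0.1, 1), "non-negative")
  expect_equal(range(scenario_axis()), c(0, 2))
  expect_length(scenario_axis(), 101)
})

test_that("the scenario grid has cell (1,1) equal to baseline predictions", {
  d <- tiny_lakes(n = 10, seed = 44)
  m <- fit_chla_models(d$records, d$observations,
                       forest_hyperparams(n_trees = 60, rng_seed = 2))
  axes <- round(seq(0, 2, 0.5), 10)
  g <- evaluate_grid(m, d$records, m_s_axis = axes, m_li_axis = axes)
  expect_equal(nrow(g), length(axes)^2 * 3)
  base <- predict_chla(m, d$records)
  cell <- g[abs(g$m_s - 1) < 1e-9 & abs(g$m_li - 1) < 1e-9, ]
  expect_identical(cell$mean_chla[cell$stratum == "all"],
                   mean(base$chla_pred))
  for (st in c("drainage", "seepage")) {
    expect_identical(cell$mean_chla[cell$stratum == st],
                     mean(base$chla_pred[base$connectivity == st]))
    expect_identical(cell$pct_eutrophic[cell$stratum == st],
                     100 * mean(base$chla_pred[base$connectivity == st] > 25))
  }
  expect_true(all(g$pct_eutrophic >= 0 & g$pct_eutrophic <= 100))
})

test_that("a constant-prediction model yields a flat surface", {
  d <- tiny_lakes(n = 10, seed = 45)
  m <- constant_models(d$records, value = 7)
  g <- evaluate_grid(m, d$records, m_s_axis = c(0, 1, 2), m_li_axis = c(0, 1, 2))
  expect_equal(unique(g$mean_chla), 7)
  expect_equal(unique(g$pct_eutrophic), 0)
})

test_that("grid slices are exact and refuse off-grid values", {
  d <- tiny_lakes(n = 8, seed = 46)
  m <- fit_chla_models(d$records, d$observations,
                       forest_hyperparams(n_trees = 40, rng_seed = 2))
  g <- evaluate_grid(m, d$records, m_s_axis = scenario_axis(),
                     m_li_axis = c(0, 1, 2))
  cv <- mean_response_curve(g, "m_s", 1, "drainage")
  expect_equal(nrow(cv), 101)
  ref <- g[g$stratum == "drainage" & abs(g$m_li - 1) < 1e-9, ]
  ref <- ref[order(ref$m_s), ]
  expect_identical(cv$mean_chla, ref$mean_chla)
  expect_error(mean_response_curve(g, "m_s", 1.01), "not on the grid")
})

test_that("curve shapes generated from each family are recognised", {
  m <- scenario_axis()
  sat <- data.frame(multiplier = m, mean_chla = m / (0.1 + m))
  expect_equal(characterize_curve_shape(sat)$shape, "saturating")
  lin <- data.frame(multiplier = m, mean_chla = 0.2 + 0.5 * m)
  expect_equal(characterize_curve_shape(lin)$shape, "linear")
  flat <- data.frame(multiplier = m, mean_chla = rep(3, length(m)))
  expect_equal(characterize_curve_shape(flat)$shape, "linear")
  expect_error(characterize_curve_shape(sat[1:4, ]), "at least 5")
  bad <- sat
  bad$mean_chla[3] <- NaN
  expect_error(characterize_curve_shape(bad), "finite")
})

test_that("the contrasting-scenario delta and pressure index are as defined", {
  d <- tiny_lakes(n = 12, seed = 47)
  # constant response: no LI/LA splits possible, so the contrast must vanish
  m <- constant_models(d$records, value = 7)
  dc <- delta_chla_contrast(m, d$records)
  expect_equal(dc$delta_chla, rep(0, nrow(d$records)))
  r <- make_record(lake_id = "T001", li = 10, la = 40, lf = 50)
  r$catchment_area_km2 <- 2
  r2 <- make_record(lake_id = "T002", li = 0, la = 40, lf = 60)
  r2$catchment_area_km2 <- 2
  m2 <- fit_chla_models(d$records, d$observations,
                        forest_hyperparams(n_trees = 20, rng_seed = 1))
  idx <- delta_chla_contrast(m2, rbind(r, r2))
  expect_equal(idx$pressure_index, c(10 / 40 * 2, 0))
})

test_that("threshold finders match closed-form surfaces and brute-force scans", {
  # frequency falling linearly to zero at m_s = 0.5
  g1 <- fake_grid(function(m_s, m_li) max(0, 100 * (m_s - 0.5)))
  r1 <- find_recovery_threshold(g1, "all", "all_recovered")
  expect_true(r1$reached)
  expect_equal(r1$reduction, 0.5)
  # already recovered at baseline
  g0 <- fake_grid(function(m_s, m_li) 0)
  expect_equal(find_recovery_threshold(g0, "all", "all_recovered")$reduction, 0)
  # constant positive frequency: never reached
  gc <- fake_grid(function(m_s, m_li) 40)
  rc <- find_recovery_threshold(gc, "all", "all_recovered")
  expect_false(rc$reached)
  expect_true(is.na(rc$reduction))
  expect_equal(find_recovery_threshold(gc, "all", "frequency_halved")$reached,
               FALSE)

  # compensation on the documented monotone surface
  g2 <- fake_grid(function(m_s, m_li) 100 * max(0, m_s + 0.3 * (m_li - 1) - 0.5))
  expect_equal(find_compensation(g2, "all", 0.52, 2)$m_li, 1.0)
  cmp <- find_compensation(g2, "all", 0.52, 50)
  expect_false(cmp$reached)   # needs m_li = 2.6, off the 0-2 axis
  expect_equal(find_compensation(g2, "all", 0.52, 0)$m_li, 1.0)

  # oracle equivalence on random monotone surfaces
  set.seed(31)
  for (i in 1:10) {
    a <- runif(1, 0, 150); b <- runif(1, 0, 60); c0 <- runif(1, -80, 40)
    f <- function(m_s, m_li) min(100, max(0, a * m_s + b * (m_li - 1) + c0))
    g <- fake_grid(f)
    for (tg in c("all_recovered", "frequency_halved")) {
      expect_equal(find_recovery_threshold(g, "all", tg)$reduction,
                   oracle_recovery(g, "all", tg))
    }
    ref <- runif(1, 0, 100)
    ms <- sample(attr(g, "m_s_axis"), 1)
    expect_equal(find_compensation(g, "all", ms, ref)$m_li,
                 oracle_compensation(g, "all", ms, ref))
  }
})

test_that("the policy report separates observed, baseline and scenario rows", {
  d <- tiny_lakes(n = 16, seed = 48)
  m <- fit_chla_models(d$records, d$observations,
                       forest_hyperparams(n_trees = 80, rng_seed = 2))
  ident <- policy_scenario_2030(m, d$records, d$observations, m = c(1, 1))
  expect_equal(ident$change_mean_pct, rep(0, nrow(ident)))
  expect_equal(ident$scenario_mean, ident$baseline_mean)
  pol <- policy_scenario_2030(m, d$records, d$observations)
  expect_identical(attr(pol, "m"), c(0.70, 1.20))
  expect_setequal(pol$stratum, c("all", "drainage", "seepage"))
  expect_equal(pol$change_mean_pct,
               percent_change(pol$baseline_mean, pol$scenario_mean))
  for (st in pol$stratum) {
    o <- d$observations[
      st == "all" |
        d$observations$lake_id %in% d$records$lake_id[d$records$connectivity == st], ]
    expect_equal(pol$observed_mean[pol$stratum == st], mean(o$chla))
  }
  expect_output(print(pol), "m_S = 0.70")
})
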