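test_that("generation is deterministic and structurally complete", {
  a <- generate_lakes(synthetic_config(n_lakes = 48, rng_seed = 11))
  b <- generate_lakes(synthetic_config(n_lakes = 48, rng_seed = 11))
  expect_identical(a, b)
  expect_equal(nrow(a$records), 48)
  expect_equal(nrow(a$observations), 48 * 4)
  expect_true(all(table(a$observations$lake_id) == 4))
  expect_setequal(unique(a$records$connectivity), c("drainage", "seepage"))
  expect_equal(nrow(validate_records(a$records, a$observations)), 0)
  c2 <- generate_lakes(synthetic_config(n_lakes = 48, rng_seed = 12))
  expect_false(identical(a$observations$chla, c2$observations$chla))
})

test_that("lognormal targets are moment-matched from median and mean", {
  # sdlog from the mean:median ratio; the published drainage catchment pair
  # (29.5, 398.7) gives sqrt(2 log(398.7/29.5)) ~ 2.28
  expect_equal(lakescen:::.lognormal_sdlog(29.5, 398.7), 2.2821, tolerance = 1e-4)
  d <- generate_lakes(synthetic_config(n_lakes = 5000, rng_seed = 4))
  se <- d$records[d$records$connectivity == "seepage", ]
  dr <- d$records[d$records$connectivity == "drainage", ]
  expect_lt(abs(median(se$s_ratio) / 1.2 - 1), 0.3)
  expect_lt(abs(median(dr$s_ratio) / 33.8 - 1), 0.3)
  expect_lt(abs(median(se$lake_area_ha) / 12.3 - 1), 0.3)
  expect_lt(abs(median(dr$lake_area_ha) / 8.8 - 1), 0.3)
  # stored ratio exactly consistent with the derived catchment area
  expect_equal(d$records$s_ratio,
               d$records$catchment_area_km2 * 100 / d$records$lake_area_ha)
  expect_gte(min(d$records$depth_m), 0.5)
  # class balance: Bernoulli(25/48)
  expect_lt(abs(nrow(dr) / 5000 - 25 / 48), 0.03)
})

test_that("infeasible lognormal targets are rejected", {
  expect_error(
    synthetic_config(drainage = list(lake_area = c(median = 10, mean = 5),
                                     s_ratio = c(median = 33.8, mean = 1341.8),
                                     depth = c(mean = 2, sd = 0.9))),
    "infeasible")
})

test_that("the ground-truth response has the stated saturating form", {
  cfg <- plain_response_config(A = 1, K = 10, gamma_li = 0, gamma_la = 0)
  r0 <- make_record(s_ratio = 1, li = 0, la = 0, lf = 100)
  r0$catchment_area_km2 <- r0$s_ratio * r0$lake_area_ha / 100
  sat <- function(S) {
    r <- r0
    r$s_ratio <- S
    true_response(r, "spring", cfg)
  }
  expect_equal(sat(1e-12), 0, tolerance = 1e-10)      # sat(0) = 0, no baseline
  expect_equal(sat(1) / (1 / 10), 10 / 11, tolerance = 1e-9)  # within 10% of linear
  expect_lt(sat(1000) / sat(100), 1.1)                # <10% gain for 10x load
  # monotone: increasing S never decreases the expected response
  S <- sort(10^runif(40, -2, 4))
  expect_true(all(diff(vapply(S, sat, numeric(1))) >= 0))
})

test_that("season multipliers and baseline enter the response as configured", {
  cfg <- synthetic_config()
  r <- make_record(connectivity = "drainage", s_ratio = 100, li = 20, la = 40,
                   lf = 40)
  winter <- true_response(r, "winter", cfg)
  summer <- true_response(r, "summer", cfg)
  b <- cfg$response$baseline
  expect_equal((summer - b) / (winter - b),
               cfg$response$season_mult[["summer"]] /
                 cfg$response$season_mult[["winter"]])
  expect_error(true_response(r, "dry", cfg), "unknown season")
})

test_that("converting urban to agricultural cover raises the response in small
           agricultural catchments and lowers it in large urbanised ones", {
  cfg <- synthetic_config()
  shift_li_away <- function(r) {
    cov <- rebalance_landcover(r$li_pct, r$la_pct, r$lf_pct, 0)
    r$li_pct <- cov$li_pct; r$la_pct <- cov$la_pct; r$lf_pct <- cov$lf_pct
    r
  }
  small_agri <- make_record(s_ratio = 3, lake_area = 10, li = 10, la = 80, lf = 10)
  small_agri$catchment_area_km2 <- 0.3
  expect_gt(true_response(shift_li_away(small_agri), "summer", cfg),
            true_response(small_agri, "summer", cfg))
  big_urban <- make_record(s_ratio = 50, lake_area = 40, li = 50, la = 10, lf = 40)
  big_urban$catchment_area_km2 <- 20
  expect_lt(true_response(shift_li_away(big_urban), "summer", cfg),
            true_response(big_urban, "summer", cfg))
})

test_that("the stratum-mean ground truth is monotone in the load multiplier", {
  cfg <- synthetic_config(n_lakes = 60, rng_seed = 21)
  d <- generate_lakes(cfg)
  for (m_li in c(0, 1, 2)) {
    rec <- apply_multipliers(d$records, 1, m_li)
    for (st in c("drainage", "seepage")) {
      r <- rec[rec$connectivity == st, ]
      curve <- vapply(seq(0, 2, 0.1), function(m) {
        rr <- r
        rr$s_ratio <- r$s_ratio * m
        mean(vapply(lake_seasons, function(s) mean(true_response(rr, s, cfg)),
                    numeric(1)))
      }, numeric(1))
      expect_true(all(diff(curve) >= -1e-12))
    }
  }
})

test_that("calibration report tracks the study's per-class anchors", {
  d <- generate_lakes(synthetic_config(n_lakes = 2000, rng_seed = 1))
  rep <- calibration_report(d$records, d$observations)
  dr <- rep[rep$connectivity == "drainage", ]
  se <- rep[rep$connectivity == "seepage", ]
  expect_gt(dr$mean_chla, 51.5 / 2)
  expect_lt(dr$mean_chla, 51.5 * 2)
  expect_gt(se$mean_chla, 9.6 / 2)
  expect_lt(se$mean_chla, 9.6 * 2)
  expect_gt(dr$frac_over_threshold, 0.5)
  expect_lt(dr$frac_over_threshold, 0.95)
  expect_lt(se$frac_over_threshold, dr$frac_over_threshold)
  empty <- tiny_lakes(0)
  expect_equal(nrow(calibration_report(empty$records, empty$observations)), 0)
})
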