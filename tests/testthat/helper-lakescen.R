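# Shared fixtures, built in code.

# A small deterministic synthetic lake table.
tiny_lakes <- function(n = 10, seed = 123) {
  generate_lakes(synthetic_config(n_lakes = n, rng_seed = seed))
}

# A hand-built record row with controllable covers and sizes.
make_record <- function(lake_id = "T001", connectivity = "seepage",
                        lake_area = 10, depth = 2, s_ratio = 5,
                        li = 10, la = 60, lf = 30,
                        drainage_density = 1, altitude = 100) {
  data.frame(lake_id = lake_id, connectivity = connectivity,
             lake_area_ha = lake_area, depth_m = depth,
             catchment_area_km2 = s_ratio * lake_area / 100,
             s_ratio = s_ratio, li_pct = li, la_pct = la, lf_pct = lf,
             drainage_density = drainage_density, altitude_m = altitude,
             stringsAsFactors = FALSE)
}

# A response configuration with no noise and unit season multipliers,
# convenient for closed-form checks of the ground-truth law.
plain_response_config <- function(A = 1, K = 10, baseline = 0,
                                  gamma_li = 0.8, gamma_la = 0.6) {
  synthetic_config(response = list(
    A = A, K = K, baseline = baseline,
    gamma_li = gamma_li, gamma_la = gamma_la,
    sigma_lake = 0, sigma_obs = 0,
    season_mult = c(winter = 1, spring = 1, summer = 1, autumn = 1)))
}

# Build a scenario_grid object from a frequency function freq(m_s, m_li)
# (and optionally a mean function), bypassing any model fit, so the
# threshold finders can be tested against closed-form surfaces.
fake_grid <- function(freq_fun, mean_fun = function(m_s, m_li) 10,
                      m_s_axis = scenario_axis(),
                      m_li_axis = scenario_axis(),
                      strata = c("all", "drainage", "seepage")) {
  cells <- expand.grid(m_s = m_s_axis, m_li = m_li_axis,
                       stratum = strata, stringsAsFactors = FALSE)
  cells$mean_chla <- mapply(mean_fun, cells$m_s, cells$m_li)
  cells$pct_eutrophic <- mapply(freq_fun, cells$m_s, cells$m_li)
  structure(cells, class = c("scenario_grid", "data.frame"),
            m_s_axis = m_s_axis, m_li_axis = m_li_axis,
            threshold = 25, freq_mode = "regression", n_lakes = NA_integer_)
}

# Regression-only model pair whose forest was trained on a constant response
# (so every prediction equals `value` and no predictor is ever split on).
constant_models <- function(records, value = 7, n_trees = 20) {
  obs <- data.frame(lake_id = rep(records$lake_id, each = 4),
                    season = rep(lake_seasons, nrow(records)),
                    chla = value, stringsAsFactors = FALSE)
  norm <- compute_norm_stats(records)
  enc <- lakescen:::.encode_dataset(records, obs, norm)
  reg <- suppressWarnings(   # constant response is intentional here
    fit_forest(enc$x, enc$y, "regression",
               forest_hyperparams(n_trees = n_trees, rng_seed = 1)))
  structure(list(regression = reg, classification = NULL, norm = norm,
                 threshold = 25),
            class = "chla_models")
}

# Brute-force oracles for the threshold finders: exhaustive scans over all
# grid cells, written directly from the definitions.
oracle_recovery <- function(grid, stratum, target) {
  g <- grid[grid$stratum == stratum & abs(grid$m_li - 1) < 1e-9, ]
  base <- g$pct_eutrophic[abs(g$m_s - 1) < 1e-9]
  goal <- if (target == "all_recovered") 0 else base / 2
  ok <- g$m_s[g$m_s <= 1 + 1e-9 & g$pct_eutrophic <= goal + 1e-9]
  if (length(ok) == 0) return(NA_real_)
  1 - max(ok)
}

oracle_compensation <- function(grid, stratum, m_s_fixed, reference) {
  g <- grid[grid$stratum == stratum & abs(grid$m_s - m_s_fixed) < 1e-9, ]
  ok <- g$m_li[g$m_li >= 1 - 1e-9 & g$pct_eutrophic >= reference - 1e-9]
  if (length(ok) == 0) return(NA_real_)
  min(ok)
}

# Independent Cohen's kappa from a 2x2 confusion table by explicit counting.
oracle_kappa <- function(tt, tf, ft, ff) {
  n <- tt + tf + ft + ff
  po <- (tt + ff) / n
  pe <- ((tt + tf) / n) * ((tt + ft) / n) + ((ft + ff) / n) * ((tf + ff) / n)
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

labels_from_table <- function(tt, tf, ft, ff) {
  list(truth = rep(c(TRUE, TRUE, FALSE, FALSE), c(tt, tf, ft, ff)),
       pred = rep(c(TRUE, FALSE, TRUE, FALSE), c(tt, tf, ft, ff)))
}
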