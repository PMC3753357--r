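# Synthetic lake-catchment generator.
#
# Emulates the statistical structure of the 48-lake Ile-de-France survey:
# two connectivity classes (drainage lakes on the stream network with large
# effective catchments, seepage lakes fed by runoff/groundwater with small
# ones), lognormal lake areas and catchment:lake ratios matched to the
# published per-class medians and means, and a known ground-truth chlorophyll
# response so that model recovery is testable.

#' Configuration for the synthetic lake generator
#'
#' Class-specific marginals are moment-matched lognormals: for a target
#' (median m, mean M), meanlog = log(m) and sdlog = sqrt(2 log(M/m)).
#' The ground-truth chlorophyll response is
#' `E[Chla] = baseline + A * S'/(S' + K) * s_T * exp(lake_effect)` with the
#' effective load `S' = S * (1 + gamma_li * (LI/100) * log10(1 + catchment) +
#' gamma_la * LA/100)`: a single half-saturation constant K makes the curve
#' saturating at drainage-typical S and near-linear at seepage-typical S, and
#' the catchment-size weighting of the urban term makes converting impervious
#' to agricultural cover raise the expected response in small agricultural
#' catchments while lowering it in large urbanised ones.
#'
#' @param n_lakes Number of lakes to generate.
#' @param p_drainage Probability a lake is drainage class (default 25/48).
#' @param rng_seed Integer seed; identical configs generate identical data.
#' @param drainage,seepage Per-class distribution targets: lists with
#'   `lake_area = c(median, mean)` (ha), `s_ratio = c(median, mean)`
#'   (dimensionless), `depth = c(mean, sd)` (m).
#' @param li_mean Named per-class mean impervious cover, percent.
#' @param li_zero_prob Zero-inflation mass of impervious cover.
#' @param li_shape1 First shape of the Beta used for nonzero impervious cover
#'   (the second shape is solved from the class mean).
#' @param la_share_shape Beta shapes for the agricultural share of non-urban
#'   cover.
#' @param depth_floor Truncation floor for lake mean depth, m.
#' @param id_meanlog,id_sdlog Lognormal parameters of drainage-network
#'   density, km/km2 (median 1).
#' @param altitude_range Uniform range of altitude, m.
#' @param response Ground-truth response parameters: `A` (scale, ug/L), `K`
#'   (half-saturation of the S response), `baseline` (ug/L offset),
#'   `gamma_li`, `gamma_la` (load coefficients of urban and agricultural
#'   cover), `sigma_lake` (lognormal sd of the per-lake random effect),
#'   `sigma_obs` (lognormal sd of observation noise), `season_mult` (named
#'   multipliers for winter, spring, summer, autumn).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_lakes = 48,
    p_drainage = 25 / 48,
    rng_seed = 1L,
    drainage = list(lake_area = c(median = 8.8, mean = 18.2),
                    s_ratio = c(median = 33.8, mean = 1341.8),
                    depth = c(mean = 2.0, sd = 0.9)),
    seepage = list(lake_area = c(median = 12.3, mean = 26.5),
                   s_ratio = c(median = 1.2, mean = 5.6),
                   depth = c(mean = 3.3, sd = 1.4)),
    li_mean = c(drainage = 19.5, seepage = 11.8),
    li_zero_prob = 0.15,
    li_shape1 = 1.2,
    la_share_shape = c(1.8, 1.2),
    depth_floor = 0.5,
    id_meanlog = 0,
    id_sdlog = 0.5,
    altitude_range = c(30, 180),
    response = list(A = 95, K = 60, baseline = 1,
                    gamma_li = 0.8, gamma_la = 0.6,
                    sigma_lake = 0.3, sigma_obs = 0.4,
                    season_mult = c(winter = 0.5, spring = 1.0,
                                    summer = 1.7, autumn = 1.2))) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  .check_config(cfg)
  cfg
}

.check_config <- function(cfg) {
  stopifnot(cfg$n_lakes >= 0,
            cfg$p_drainage >= 0, cfg$p_drainage <= 1,
            cfg$li_zero_prob >= 0, cfg$li_zero_prob <= 1,
            cfg$response$K > 0, cfg$response$A >= 0,
            cfg$response$sigma_lake >= 0, cfg$response$sigma_obs >= 0,
            all(cfg$response$season_mult > 0),
            identical(sort(names(cfg$response$season_mult)),
                      sort(lake_seasons)))
  for (cls in c("drainage", "seepage")) {
    for (f in c("lake_area", "s_ratio")) {
      tgt <- cfg[[cls]][[f]]
      if (tgt[["mean"]] < tgt[["median"]]) {
        stop(sprintf("infeasible config: %s %s mean (%g) < median (%g) for a lognormal target",
                     cls, f, tgt[["mean"]], tgt[["median"]]), call. = FALSE)
      }
    }
    if (cfg$li_mean[[cls]] >= 100 * (1 - cfg$li_zero_prob)) {
      stop("infeasible config: impervious-cover mean incompatible with zero inflation",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

# sdlog that matches a lognormal's mean/median ratio: mean/median = exp(s^2/2).
.lognormal_sdlog <- function(median, mean) sqrt(2 * log(mean / median))

.rlnorm_target <- function(n, target) {
  rlnorm(n, log(target[["median"]]),
         .lognormal_sdlog(target[["median"]], target[["mean"]]))
}

# Truncated normal above `floor` by inverse-CDF sampling.
.rtnorm <- function(n, mean, sd, floor) {
  p0 <- pnorm((floor - mean) / sd)
  mean + sd * qnorm(p0 + runif(n) * (1 - p0))
}

#' Ground-truth expected chlorophyll a for lake records
#'
#' Evaluates the generator's deterministic response law (see
#' [synthetic_config()]) for each record row at one season. With
#' `lake_effect = 0` this is the population-level expectation used by the
#' monotonicity and v-shape properties of the generator.
#'
#' @param records Record data frame rows.
#' @param season One of `lake_seasons`.
#' @param config A `synthetic_config`.
#' @param lake_effect Per-row Gaussian log-scale random effect (default 0).
#' @return Numeric vector of expected chlorophyll a, ug/L.
#' @export
true_response <- function(records, season, config, lake_effect = 0) {
  if (!season %in% lake_seasons) stop("unknown season: ", season, call. = FALSE)
  rp <- config$response
  sat <- .saturation(.effective_load(records, config), rp$K)
  rp$baseline + rp$A * sat * rp$season_mult[[season]] * exp(lake_effect)
}

.effective_load <- function(records, config) {
  rp <- config$response
  records$s_ratio * (1 +
    rp$gamma_li * (records$li_pct / 100) * log10(1 + records$catchment_area_km2) +
    rp$gamma_la * records$la_pct / 100)
}

.saturation <- function(load, K) load / (load + K)

#' Generate a synthetic lake-catchment dataset
#'
#' Draws connectivity Bernoulli(p_drainage); per-class lognormal lake areas
#' and S ratios (catchment area derived as S x lake_area / 100, so the stored
#' ratio is exactly consistent with the areas); truncated-normal depths;
#' zero-inflated Beta impervious cover; a Beta split of the remaining cover
#' between agricultural and forest; lognormal drainage density; uniform
#' altitude. Each lake receives four seasonal observations equal to the
#' ground-truth response times multiplicative lognormal noise (both the
#' per-lake effect and the observation noise are mean-one lognormals).
#'
#' @param config A [synthetic_config()].
#' @return List with `records`, `observations` (4 rows per lake, lake-major,
#'   seasons in canonical order), and `truth` (per lake x season expected
#'   chlorophyll a, plus the latent effective load and lake effect).
#' @export
generate_lakes <- function(config = synthetic_config()) {
  .check_config(config)
  n <- config$n_lakes
  set.seed(config$rng_seed)
  if (n == 0) {
    rec <- as.data.frame(setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 9)),
      .record_cols))
    obs <- data.frame(lake_id = character(0), season = character(0),
                      chla = numeric(0), stringsAsFactors = FALSE)
    return(list(records = rec, observations = obs, truth = obs[0, ]))
  }
  cls <- ifelse(rbinom(n, 1, config$p_drainage) == 1, "drainage", "seepage")
  lake_area <- s_ratio <- depth <- li <- numeric(n)
  for (cl in c("drainage", "seepage")) {
    i <- which(cls == cl)
    if (length(i) == 0) next
    lake_area[i] <- .rlnorm_target(length(i), config[[cl]]$lake_area)
    s_ratio[i] <- .rlnorm_target(length(i), config[[cl]]$s_ratio)
    depth[i] <- .rtnorm(length(i), config[[cl]]$depth[["mean"]],
                        config[[cl]]$depth[["sd"]], config$depth_floor)
    cond_mean <- config$li_mean[[cl]] / (100 * (1 - config$li_zero_prob))
    a <- config$li_shape1
    nonzero <- runif(length(i)) >= config$li_zero_prob
    draw <- 100 * rbeta(length(i), a, a * (1 - cond_mean) / cond_mean)
    li[i] <- ifelse(nonzero, draw, 0)
  }
  la_share <- rbeta(n, config$la_share_shape[1], config$la_share_shape[2])
  la <- (100 - li) * la_share
  lf <- 100 - li - la
  records <- data.frame(
    lake_id = sprintf("L%03d", seq_len(n)),
    connectivity = cls,
    lake_area_ha = lake_area,
    depth_m = depth,
    catchment_area_km2 = s_ratio * lake_area / 100,
    s_ratio = s_ratio,
    li_pct = li, la_pct = la, lf_pct = lf,
    drainage_density = rlnorm(n, config$id_meanlog, config$id_sdlog),
    altitude_m = runif(n, config$altitude_range[1], config$altitude_range[2]),
    stringsAsFactors = FALSE
  )
  rp <- config$response
  lake_effect <- rnorm(n, -rp$sigma_lake^2 / 2, rp$sigma_lake)
  mu <- sapply(lake_seasons, function(s)
    true_response(records, s, config, lake_effect))
  noise <- matrix(rlnorm(n * length(lake_seasons), -rp$sigma_obs^2 / 2,
                         rp$sigma_obs), nrow = n)
  # lake-major ordering: all four seasons of lake 1, then lake 2, ...
  ord <- rep(seq_len(n), each = length(lake_seasons))
  seas <- rep(lake_seasons, times = n)
  flat <- cbind(mu = as.vector(t(mu)), noise = as.vector(t(noise)))
  observations <- data.frame(lake_id = records$lake_id[ord], season = seas,
                             chla = flat[, "mu"] * flat[, "noise"],
                             stringsAsFactors = FALSE)
  truth <- data.frame(lake_id = records$lake_id[ord], season = seas,
                      expected_chla = flat[, "mu"],
                      load_index = .effective_load(records, config)[ord],
                      lake_effect = lake_effect[ord],
                      stringsAsFactors = FALSE)
  list(records = records, observations = observations, truth = truth)
}

#' Per-class calibration summary of a lake dataset
#'
#' Means and medians of the record fields plus mean chlorophyll a and the
#' fraction of observations above the eutrophication threshold, by
#' connectivity class, for comparison against the study's published
#' per-class summaries.
#'
#' @param records,observations A lake table.
#' @param threshold Eutrophication boundary, ug/L.
#' @return Data frame with one row per connectivity class present (empty
#'   input yields an empty frame).
#' @export
calibration_report <- function(records, observations, threshold = 25) {
  out <- lapply(intersect(lake_classes, unique(records$connectivity)),
                function(cl) {
    r <- records[records$connectivity == cl, ]
    o <- observations[observations$lake_id %in% r$lake_id, ]
    data.frame(
      connectivity = cl, n_lakes = nrow(r),
      lake_area_median = median(r$lake_area_ha),
      lake_area_mean = mean(r$lake_area_ha),
      depth_mean = mean(r$depth_m),
      catchment_median = median(r$catchment_area_km2),
      catchment_mean = mean(r$catchment_area_km2),
      s_ratio_median = median(r$s_ratio),
      s_ratio_mean = mean(r$s_ratio),
      li_mean = mean(r$li_pct),
      mean_chla = if (nrow(o)) mean(o$chla) else NA_real_,
      frac_over_threshold = if (nrow(o))
        mean(classify_eutrophic(o$chla, threshold)) else NA_real_,
      stringsAsFactors = FALSE)
  })
  if (length(out) == 0) {
    return(data.frame(connectivity = character(0), n_lakes = integer(0)))
  }
  do.call(rbind, out)
}
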