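# Scenario projection machinery: pressure-multiplier grids over the nutrient
# load proxy (S) and the impervious cover (LI), compositional land-cover
# rebalancing, response-surface slices and curve-shape classification,
# contrasting-scenario Chla differences, recovery/compensation threshold
# scans, and the combined 2030 policy scenario report.

#' Percent change of a scenario value against a baseline
#'
#' `100 * (scenario - baseline) / baseline`; vectorised.
#'
#' @param baseline,scenario Numeric; `baseline` must be nonzero.
#' @return Percent change.
#' @export
percent_change <- function(baseline, scenario) {
  if (any(baseline == 0)) stop("percent change undefined for zero baseline",
                               call. = FALSE)
  100 * (scenario - baseline) / baseline
}

#' Rebalance land cover after scaling the impervious fraction
#'
#' Impervious cover is scaled by `m_li` (capped at 100%); the remainder is
#' split between agricultural and forest cover keeping their ratio constant.
#' When the initial non-urban cover is zero the remainder is split by
#' `fallback_ratio` (agricultural share).
#'
#' @param li0,la0,lf0 Initial covers, percent, summing to 100 (vectorised).
#' @param m_li Non-negative multiplier on impervious cover.
#' @param fallback_ratio Agricultural share of freed cover when
#'   `la0 + lf0 = 0`.
#' @return Data frame with columns `li_pct`, `la_pct`, `lf_pct` summing to
#'   100 within 1e-9.
#' @export
rebalance_landcover <- function(li0, la0, lf0, m_li, fallback_ratio = 0.5) {
  if (any(m_li < 0)) stop("land-cover multiplier must be non-negative",
                          call. = FALSE)
  if (any(abs(li0 + la0 + lf0 - 100) > 1e-6)) {
    stop("land covers must sum to 100", call. = FALSE)
  }
  if (isTRUE(all(m_li == 1))) {   # identity is exact, untouched by rounding
    return(data.frame(li_pct = li0, la_pct = la0, lf_pct = lf0))
  }
  li <- pmin(m_li * li0, 100)
  rest <- 100 - li
  denom <- la0 + lf0
  la_share <- ifelse(denom > 0, la0 / denom, fallback_ratio)
  la <- rest * la_share
  data.frame(li_pct = li, la_pct = la, lf_pct = rest - la)
}

#' Apply pressure multipliers to lake records
#'
#' Scales the nutrient-load proxy `s_ratio` by `m_s` and rebalances land
#' cover for `m_li` via [rebalance_landcover()]. Depth, drainage density,
#' altitude and the physical areas are unchanged (the S multiplier models a
#' change in load per unit catchment, not a change in geography), so the
#' stored ratio intentionally departs from the area-implied one in a
#' scenario record. The input is not modified.
#'
#' @param records Lake records.
#' @param m_s,m_li Non-negative multipliers; `(1, 1)` is the identity.
#' @return A transformed copy of `records`.
#' @export
apply_multipliers <- function(records, m_s = 1, m_li = 1) {
  if (m_s < 0 || m_li < 0) stop("pressure multipliers must be non-negative",
                                call. = FALSE)
  out <- records
  out$s_ratio <- records$s_ratio * m_s
  cov <- rebalance_landcover(records$li_pct, records$la_pct, records$lf_pct,
                             m_li)
  out$li_pct <- cov$li_pct
  out$la_pct <- cov$la_pct
  out$lf_pct <- cov$lf_pct
  out
}

#' Default scenario axis: 0 to 2 in 2% steps
#' @return Numeric vector of 101 multiplier values.
#' @export
scenario_axis <- function() round(seq(0, 2, by = 0.02), 10)

.match_axis <- function(value, axis, what) {
  i <- which(abs(axis - value) < 1e-9)
  if (length(i) != 1) {
    stop(what, " = ", value, " is not on the grid axis (no interpolation)",
         call. = FALSE)
  }
  i
}

.strata <- c("all", "drainage", "seepage")

#' Evaluate the scenario response surface
#'
#' For every `(m_s, m_li)` grid cell: transform each lake with
#' [apply_multipliers()], predict all lake x season combinations with the
#' regression model, and aggregate the mean chlorophyll a and the eutrophic
#' frequency (% of predictions strictly above `threshold`) for the whole set
#' and per connectivity stratum. With `freq_mode = "classification"` the
#' frequency is taken from the binomial model's majority vote instead.
#'
#' @param models A [fit_chla_models()] result.
#' @param records Lake records defining the baseline state.
#' @param m_s_axis,m_li_axis Multiplier axes (default [scenario_axis()]).
#' @param seasons Seasons each lake is predicted for.
#' @param threshold Eutrophication boundary, ug/L.
#' @param freq_mode "regression" (default) or "classification".
#' @return An object of class `scenario_grid`: long data frame with columns
#'   `m_s`, `m_li`, `stratum`, `mean_chla`, `pct_eutrophic`, with the axes
#'   and settings as attributes. Strata absent from `records` are omitted
#'   with a warning.
#' @export
evaluate_grid <- function(models, records,
                          m_s_axis = scenario_axis(),
                          m_li_axis = scenario_axis(),
                          seasons = lake_seasons, threshold = 25,
                          freq_mode = c("regression", "classification")) {
  stopifnot(inherits(models, "chla_models"))
  freq_mode <- match.arg(freq_mode)
  if (freq_mode == "classification" && is.null(models$classification)) {
    stop("no classification model available for freq_mode = 'classification'",
         call. = FALSE)
  }
  if (any(m_s_axis < 0) || any(m_li_axis < 0)) {
    stop("multiplier axes must be non-negative", call. = FALSE)
  }
  strata <- list(all = rep(TRUE, nrow(records) * length(seasons)))
  ord <- rep(seq_len(nrow(records)), each = length(seasons))
  for (cl in lake_classes) {
    sel <- records$connectivity[ord] == cl
    if (any(sel)) strata[[cl]] <- sel
    else warning("stratum '", cl, "' absent from records; omitted",
                 call. = FALSE)
  }
  rows <- vector("list", length(m_li_axis))
  for (j in seq_along(m_li_axis)) {
    rec_li <- apply_multipliers(records, 1, m_li_axis[j])
    # batch all m_s cells of this m_li column into one prediction call
    big <- rec_li[rep(ord, times = length(m_s_axis)), , drop = FALSE]
    big$s_ratio <- big$s_ratio * rep(m_s_axis, each = length(ord))
    seas <- rep(rep(seasons, times = nrow(records)), times = length(m_s_axis))
    x <- .design_matrix(big, seas, models$norm)
    pred <- predict_forest(models$regression, x)
    over <- if (freq_mode == "regression") pred > threshold
            else predict_forest(models$classification, x)$label
    cell <- rep(seq_along(m_s_axis), each = length(ord))
    out <- vector("list", length(strata))
    for (k in seq_along(strata)) {
      sel <- rep(strata[[k]], times = length(m_s_axis))
      out[[k]] <- data.frame(
        m_s = m_s_axis,
        m_li = m_li_axis[j],
        stratum = names(strata)[k],
        mean_chla = as.numeric(tapply(pred[sel], cell[sel], mean)),
        pct_eutrophic = 100 * as.numeric(tapply(over[sel], cell[sel], mean)),
        stringsAsFactors = FALSE)
    }
    rows[[j]] <- do.call(rbind, out)
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  structure(grid, class = c("scenario_grid", "data.frame"),
            m_s_axis = m_s_axis, m_li_axis = m_li_axis,
            threshold = threshold, freq_mode = freq_mode,
            n_lakes = nrow(records))
}

#' Slice a scenario grid along one multiplier axis
#'
#' @param grid A `scenario_grid`.
#' @param varying "m_s" or "m_li": the axis the curve runs along.
#' @param fixed_value Value of the other axis; must lie on the grid (no
#'   interpolation).
#' @param stratum "all", "drainage" or "seepage".
#' @return Data frame with `multiplier`, `mean_chla`, `pct_eutrophic`,
#'   ordered along the varying axis.
#' @export
mean_response_curve <- function(grid, varying = c("m_s", "m_li"),
                                fixed_value = 1, stratum = "all") {
  varying <- match.arg(varying)
  stopifnot(inherits(grid, "scenario_grid"), stratum %in% .strata)
  fixed <- setdiff(c("m_s", "m_li"), varying)
  axis <- attr(grid, paste0(fixed, "_axis"))
  .match_axis(fixed_value, axis, fixed)
  sel <- abs(grid[[fixed]] - fixed_value) < 1e-9 & grid$stratum == stratum
  if (!any(sel)) stop("stratum '", stratum, "' not present in grid",
                      call. = FALSE)
  out <- grid[sel, c(varying, "mean_chla", "pct_eutrophic")]
  names(out)[1] <- "multiplier"
  out <- out[order(out$multiplier), ]
  rownames(out) <- NULL
  out
}

# Small-sample-corrected AIC of an lm/nls fit.
.aicc <- function(fit, n) {
  k <- length(coef(fit)) + 1
  AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Classify a response curve as linear or saturating
#'
#' Least-squares fits of a straight line `y = a + b m` and a saturating
#' (Michaelis-Menten-type) curve `y = y0 + c m / (k + m)` are compared by
#' small-sample-corrected AIC; the lower wins. Ties, constant curves and
#' failed saturating fits fall back to "linear" (the simpler model).
#'
#' @param curve Data frame from [mean_response_curve()] (columns `multiplier`
#'   and `mean_chla`), at least 5 points, finite values.
#' @return List with `shape` ("linear" or "saturating"), `aicc_linear`,
#'   `aicc_saturating`, and the fitted objects.
#' @export
characterize_curve_shape <- function(curve) {
  m <- curve$multiplier
  y <- curve$mean_chla
  if (length(m) < 5) stop("need at least 5 curve points", call. = FALSE)
  if (any(!is.finite(m)) || any(!is.finite(y))) {
    stop("curve values must be finite", call. = FALSE)
  }
  lin <- lm(y ~ m)
  aicc_lin <- .aicc(lin, length(m))
  if (sd(y) < 1e-12) {
    return(list(shape = "linear", aicc_linear = aicc_lin,
                aicc_saturating = NA_real_, linear_fit = lin,
                saturating_fit = NULL))
  }
  sat <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + cc * m / (k + m),
                      start = list(y0 = min(y), cc = diff(range(y)), k = 0.25),
                      lower = c(y0 = -Inf, cc = -Inf, k = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  aicc_sat <- if (is.null(sat)) NA_real_ else .aicc(sat, length(m))
  shape <- if (!is.na(aicc_sat) && aicc_sat < aicc_lin - 1e-9) "saturating"
           else "linear"
  list(shape = shape, aicc_linear = aicc_lin, aicc_saturating = aicc_sat,
       linear_fit = lin, saturating_fit = sat)
}

#' Chlorophyll contrast between the reduced-LI and increased-LI scenarios
#'
#' For each lake: the season-averaged regression prediction under complete
#' removal of impervious cover (`m_li = 0`) minus under a doubling
#' (`m_li = 2`), both at unchanged loads (`m_s = 1`). Positive values mean
#' the lake is predicted greener with urban cover removed (cover converted
#' to agriculture). The accompanying pressure index is
#' `(LI / LA) * catchment_area` with LA floored at `la_floor` percent.
#'
#' @param models A [fit_chla_models()] result.
#' @param records Lake records.
#' @param seasons Seasons averaged over.
#' @param la_floor Floor for agricultural cover in the index denominator, %.
#' @return Data frame with `lake_id`, `connectivity`, `delta_chla`,
#'   `pressure_index`.
#' @export
delta_chla_contrast <- function(models, records, seasons = lake_seasons,
                                la_floor = 1) {
  pred_mean <- function(m_li) {
    p <- predict_chla(models, apply_multipliers(records, 1, m_li), seasons)
    as.numeric(tapply(p$chla_pred, match(p$lake_id, records$lake_id), mean))
  }
  reduced <- pred_mean(0)
  increased <- pred_mean(2)
  data.frame(lake_id = records$lake_id,
             connectivity = records$connectivity,
             delta_chla = reduced - increased,
             pressure_index = (records$li_pct / pmax(records$la_pct, la_floor)) *
               records$catchment_area_km2,
             stringsAsFactors = FALSE)
}

#' Load reduction needed to reach a recovery target
#'
#' Scans the `m_li = 1` slice of the grid downward from `m_s = 1`.
#' `"all_recovered"`: the largest `m_s` at which the stratum's eutrophic
#' frequency is zero. `"frequency_halved"`: the largest `m_s` at which it is
#' at most half its baseline (1, 1) value. Grid points only; reported
#' reductions are therefore multiples of the axis step.
#'
#' @param grid A `scenario_grid`.
#' @param stratum "all", "drainage" or "seepage".
#' @param target "all_recovered" or "frequency_halved".
#' @return List with `reached` (logical), `m_s`, `reduction` (`1 - m_s`),
#'   and `baseline_frequency`; `reduction` is `NA` when no grid point
#'   qualifies.
#' @export
find_recovery_threshold <- function(grid, stratum = "all",
                                    target = c("all_recovered",
                                               "frequency_halved")) {
  target <- match.arg(target)
  slice <- mean_response_curve(grid, "m_s", fixed_value = 1, stratum = stratum)
  i1 <- .match_axis(1, slice$multiplier, "m_s")
  baseline <- slice$pct_eutrophic[i1]
  goal <- if (target == "all_recovered") 0 else baseline / 2
  down <- slice[slice$multiplier <= 1 + 1e-9, ]
  down <- down[order(down$multiplier, decreasing = TRUE), ]
  hit <- which(down$pct_eutrophic <= goal + 1e-9)
  if (length(hit) == 0) {
    return(list(reached = FALSE, m_s = NA_real_, reduction = NA_real_,
                baseline_frequency = baseline))
  }
  m_s <- down$multiplier[hit[1]]
  list(reached = TRUE, m_s = m_s, reduction = 1 - m_s,
       baseline_frequency = baseline)
}

#' Impervious-cover increase compensating a load reduction
#'
#' At a fixed `m_s` column of the grid, the smallest `m_li >= 1` at which
#' the stratum's eutrophic frequency climbs back to at least
#' `reference_frequency`.
#'
#' @param grid A `scenario_grid`.
#' @param stratum Stratum name.
#' @param m_s_fixed Fixed load multiplier (must be on the grid).
#' @param reference_frequency Frequency (percent) to reach.
#' @return List with `reached` (logical) and `m_li` (`NA` if never reached).
#' @export
find_compensation <- function(grid, stratum, m_s_fixed, reference_frequency) {
  slice <- mean_response_curve(grid, "m_li", fixed_value = m_s_fixed,
                               stratum = stratum)
  up <- slice[slice$multiplier >= 1 - 1e-9, ]
  up <- up[order(up$multiplier), ]
  hit <- which(up$pct_eutrophic >= reference_frequency - 1e-9)
  if (length(hit) == 0) return(list(reached = FALSE, m_li = NA_real_))
  list(reached = TRUE, m_li = up$multiplier[hit[1]])
}

#' The 2030 policy scenario report
#'
#' Projects the combined policy scenario (default: nutrient loads reduced by
#' 30%, impervious cover up 20%, i.e. multipliers (0.70, 1.20)) and emits,
#' per stratum: the observed current mean chlorophyll a and eutrophic
#' frequency, the model baseline at multipliers (1, 1), the scenario
#' prediction, and percent changes of the scenario against the model
#' baseline (observed and model-baseline rows are kept distinct).
#'
#' @param models A [fit_chla_models()] result.
#' @param records,observations The current-state lake table.
#' @param m Length-2 multipliers `c(m_s, m_li)`.
#' @param threshold Eutrophication boundary, ug/L.
#' @param freq_mode "regression" or "classification" frequency definition.
#' @return An object of class `policy_report`: data frame with one row per
#'   stratum and columns `observed_mean`, `observed_freq`, `baseline_mean`,
#'   `baseline_freq`, `scenario_mean`, `scenario_freq`, `change_mean_pct`,
#'   `change_freq_pct`.
#' @export
policy_scenario_2030 <- function(models, records, observations,
                                 m = c(0.70, 1.20), threshold = 25,
                                 freq_mode = c("regression", "classification")) {
  freq_mode <- match.arg(freq_mode)
  stopifnot(length(m) == 2, all(m >= 0))
  pred_state <- function(rec) {
    p <- predict_chla(models, rec)
    over <- if (freq_mode == "regression") p$chla_pred > threshold else p$label
    list(p = p, over = over)
  }
  base <- pred_state(apply_multipliers(records, 1, 1))
  scen <- pred_state(apply_multipliers(records, m[1], m[2]))
  obs_class <- records$connectivity[match(observations$lake_id, records$lake_id)]
  rows <- lapply(.strata, function(st) {
    in_st <- function(cl) st == "all" | cl == st
    ob <- observations[in_st(obs_class), ]
    bsel <- in_st(base$p$connectivity)
    if (nrow(ob) == 0 || !any(bsel)) return(NULL)
    baseline_mean <- mean(base$p$chla_pred[bsel])
    baseline_freq <- 100 * mean(base$over[bsel])
    scenario_mean <- mean(scen$p$chla_pred[bsel])
    scenario_freq <- 100 * mean(scen$over[bsel])
    data.frame(
      stratum = st,
      observed_mean = mean(ob$chla),
      observed_freq = 100 * mean(classify_eutrophic(ob$chla, threshold)),
      baseline_mean = baseline_mean, baseline_freq = baseline_freq,
      scenario_mean = scenario_mean, scenario_freq = scenario_freq,
      change_mean_pct = percent_change(baseline_mean, scenario_mean),
      change_freq_pct = if (baseline_freq == 0) NA_real_
                        else percent_change(baseline_freq, scenario_freq),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("policy_report", "data.frame"),
            m = m, threshold = threshold, freq_mode = freq_mode)
}

#' @export
print.policy_report <- function(x, ...) {
  m <- attr(x, "m")
  cat(sprintf("Policy scenario at multipliers (m_S = %.2f, m_LI = %.2f)\n",
              m[1], m[2]))
  cat(sprintf("%-9s %12s %12s %12s %12s\n", "stratum",
              "mean Chla", "(change)", "% >25 ug/L", "(change)"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-9s %7.1f->%4.1f %11s %7.1f->%4.1f %11s\n",
                x$stratum[i], x$baseline_mean[i], x$scenario_mean[i],
                sprintf("(%+.1f%%)", x$change_mean_pct[i]),
                x$baseline_freq[i], x$scenario_freq[i],
                if (is.na(x$change_freq_pct[i])) "(-)"
                else sprintf("(%+.1f%%)", x$change_freq_pct[i])))
  }
  invisible(x)
}
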