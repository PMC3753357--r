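# Domain types, tabular I/O, validation, feature encoding, trophic classification.
#
# A lake table is a pair of plain data frames:
#   records:      one row per lake (catchment descriptors + connectivity class)
#   observations: one row per lake x season (chlorophyll a, ug/L)

#' Season levels, in encoding order
#' @export
lake_seasons <- c("winter", "spring", "summer", "autumn")

#' Connectivity classes
#' @export
lake_classes <- c("drainage", "seepage")

# Numeric predictors in the fixed model order (S, LF, LA, LI, Id, D, altitude),
# named by their column in the records table.
.predictor_cols <- c(
  s_ratio = "s_ratio", lf_pct = "lf_pct", la_pct = "la_pct", li_pct = "li_pct",
  drainage_density = "drainage_density", depth_m = "depth_m",
  altitude_m = "altitude_m"
)

.record_cols <- c(
  "lake_id", "connectivity", "lake_area_ha", "depth_m", "catchment_area_km2",
  "s_ratio", "li_pct", "la_pct", "lf_pct", "drainage_density", "altitude_m"
)

.csv_header <- c(.record_cols, "season", "chla_ugL")

.feature_names <- c(names(.predictor_cols), paste0("season_", lake_seasons))

#' Read a lake-catchment table from CSV
#'
#' Reads the long-format CSV schema (one row per lake x season, lake-level
#' fields repeated) and splits it into a per-lake record table and an
#' observation table. The header must match the documented schema exactly:
#' `lake_id,connectivity,lake_area_ha,depth_m,catchment_area_km2,s_ratio,`
#' `li_pct,la_pct,lf_pct,drainage_density,altitude_m,season,chla_ugL`.
#'
#' @param path Path to a CSV file (comma separated, dot decimal, UTF-8).
#' @return A list with elements `records` (one row per lake, first-occurrence
#'   order) and `observations` (columns `lake_id`, `season`, `chla`, in file
#'   order).
#' @export
read_lake_table <- function(path) {
  if (!file.exists(path)) {
    stop("lake table file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  missing <- setdiff(.csv_header, names(raw))
  if (length(missing) > 0) {
    stop("lake table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), .csv_header)
  if (length(extra) > 0) {
    stop("lake table schema error: unknown column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(.csv_header, c("lake_id", "connectivity", "season"))
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("parse error in column '%s', data row %d: '%s' is not numeric",
                   col, bad[1], raw[[col]][bad[1]]), call. = FALSE)
    }
    raw[[col]] <- vals
  }
  bad_class <- setdiff(unique(raw$connectivity), lake_classes)
  if (nrow(raw) > 0 && length(bad_class) > 0) {
    stop("unknown connectivity value(s): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  bad_season <- setdiff(unique(raw$season), lake_seasons)
  if (nrow(raw) > 0 && length(bad_season) > 0) {
    stop("unknown season value(s): ", paste(bad_season, collapse = ", "),
         call. = FALSE)
  }
  records <- raw[!duplicated(raw$lake_id), .record_cols, drop = FALSE]
  rownames(records) <- NULL
  observations <- data.frame(lake_id = raw$lake_id, season = raw$season,
                             chla = raw$chla_ugL, stringsAsFactors = FALSE)
  list(records = records, observations = observations)
}

#' Write a lake-catchment table to CSV
#'
#' Inverse of [read_lake_table()]: joins observations to their lake records
#' and writes the long-format schema. An empty dataset yields a header-only
#' file. Numeric round-trip error through write/read is below 1e-9 relative.
#'
#' @param records Per-lake record data frame.
#' @param observations Observation data frame (`lake_id`, `season`, `chla`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lake_table <- function(records, observations, path) {
  if (nrow(observations) > 0) {
    idx <- match(observations$lake_id, records$lake_id)
    if (anyNA(idx)) {
      stop("observation refers to unknown lake_id: ",
           observations$lake_id[which(is.na(idx))[1]], call. = FALSE)
    }
    out <- records[idx, .record_cols, drop = FALSE]
    out$season <- observations$season
    out$chla_ugL <- observations$chla
  } else {
    out <- as.data.frame(setNames(rep(list(character(0)), length(.csv_header)),
                                  .csv_header))
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("failed to write lake table to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Validate lake records and observations against the domain invariants
#'
#' Checks positivity of areas, depth, S ratio and drainage density; land-cover
#' percentages in \[0, 100\] summing to 100 (tolerance 1e-6); consistency of the
#' stored S ratio with catchment_area_km2 x 100 / lake_area_ha (5% band,
#' reported at severity "warning"); known connectivity and season labels;
#' non-negative chlorophyll a; and at most one observation per lake x season.
#'
#' Violations are returned as data, not raised as errors.
#'
#' @param records,observations Lake table components as from
#'   [read_lake_table()].
#' @return A data frame with columns `lake_id`, `field`, `rule`, `severity`
#'   (zero rows when every invariant holds).
#' @export
validate_records <- function(records, observations) {
  v <- list()
  add <- function(lake_id, field, rule, severity = "error") {
    v[[length(v) + 1]] <<- data.frame(lake_id = lake_id, field = field,
                                      rule = rule, severity = severity,
                                      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    for (f in c("lake_area_ha", "depth_m", "catchment_area_km2", "s_ratio",
                "drainage_density")) {
      if (!is.finite(r[[f]]) || r[[f]] <= 0) add(r$lake_id, f, "positive")
    }
    if (!r$connectivity %in% lake_classes) {
      add(r$lake_id, "connectivity", "known_class")
    }
    for (f in c("li_pct", "la_pct", "lf_pct")) {
      if (!is.finite(r[[f]]) || r[[f]] < 0 || r[[f]] > 100) {
        add(r$lake_id, f, "percent_range")
      }
    }
    comp <- r$li_pct + r$la_pct + r$lf_pct
    if (is.finite(comp) && abs(comp - 100) > 1e-6) {
      add(r$lake_id, "li_pct+la_pct+lf_pct", "composition_sums_to_100")
    }
    if (is.finite(r$s_ratio) && r$s_ratio > 0 &&
        is.finite(r$catchment_area_km2) && r$catchment_area_km2 > 0 &&
        is.finite(r$lake_area_ha) && r$lake_area_ha > 0) {
      implied <- r$catchment_area_km2 * 100 / r$lake_area_ha
      if (abs(implied / r$s_ratio - 1) > 0.05) {
        add(r$lake_id, "s_ratio", "consistent_with_areas", "warning")
      }
    }
  }
  if (nrow(observations) > 0) {
    unknown <- !observations$lake_id %in% records$lake_id
    for (id in unique(observations$lake_id[unknown])) {
      add(id, "lake_id", "known_lake")
    }
    bad_season <- !observations$season %in% lake_seasons
    for (id in unique(observations$lake_id[bad_season])) {
      add(id, "season", "known_season")
    }
    bad_chla <- !is.finite(observations$chla) | observations$chla < 0
    for (id in unique(observations$lake_id[bad_chla])) {
      add(id, "chla", "non_negative")
    }
    key <- paste(observations$lake_id, observations$season)
    for (k in unique(key[duplicated(key)])) {
      add(strsplit(k, " ")[[1]][1], "season", "one_observation_per_lake_season")
    }
  }
  if (length(v) == 0) {
    return(data.frame(lake_id = character(0), field = character(0),
                      rule = character(0), severity = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Normalisation statistics for the numeric predictors
#'
#' Per-predictor mean and sample standard deviation (denominator n - 1),
#' computed on training rows only, used to z-score features at encoding time.
#'
#' @param records A data frame holding the predictor columns; pass the
#'   training rows (for lake-level splits, the training lakes; for
#'   observation-level splits, records repeated per training observation).
#' @return An object of class `norm_stats` with named `mean` and `sd` vectors
#'   in the fixed predictor order (S, LF, LA, LI, Id, D, altitude).
#' @export
compute_norm_stats <- function(records) {
  if (nrow(records) < 2) {
    stop("need at least 2 training rows to compute normalisation statistics",
         call. = FALSE)
  }
  mu <- vapply(.predictor_cols, function(col) mean(records[[col]]), numeric(1))
  sdev <- vapply(.predictor_cols, function(col) sd(records[[col]]), numeric(1))
  const <- names(.predictor_cols)[!is.finite(sdev) | sdev <= 0]
  if (length(const) > 0) {
    stop("constant predictor(s) cannot be normalised: ",
         paste(const, collapse = ", "), call. = FALSE)
  }
  structure(list(mean = mu, sd = sdev), class = "norm_stats")
}

#' Encode one lake record and season as a model feature vector
#'
#' Numeric predictors are z-scored with the training-set statistics in the
#' fixed order (S, LF, LA, LI, Id, D, altitude); the season is appended as a
#' one-hot block over (winter, spring, summer, autumn).
#'
#' @param record A single-row record data frame (or list with the record
#'   fields).
#' @param season One of `lake_seasons`.
#' @param norm A `norm_stats` object from [compute_norm_stats()].
#' @return Named numeric vector of length 11.
#' @export
encode_features <- function(record, season, norm) {
  if (!season %in% lake_seasons) {
    stop("unknown season: ", season, call. = FALSE)
  }
  z <- vapply(seq_along(.predictor_cols), function(i) {
    (record[[.predictor_cols[i]]] - norm$mean[i]) / norm$sd[i]
  }, numeric(1))
  onehot <- as.numeric(lake_seasons == season)
  setNames(c(z, onehot), .feature_names)
}

# Vectorised design matrix for lake x season rows. `records` rows are aligned
# 1:1 with `seasons`.
.design_matrix <- function(records, seasons, norm) {
  stopifnot(nrow(records) == length(seasons))
  bad <- setdiff(unique(seasons), lake_seasons)
  if (length(bad) > 0) stop("unknown season: ", bad[1], call. = FALSE)
  z <- vapply(seq_along(.predictor_cols), function(i) {
    (records[[.predictor_cols[i]]] - norm$mean[i]) / norm$sd[i]
  }, numeric(nrow(records)))
  onehot <- vapply(lake_seasons, function(s) as.numeric(seasons == s),
                   numeric(nrow(records)))
  x <- cbind(z, onehot)
  colnames(x) <- .feature_names
  x
}

# Expand observations into an aligned (x, y) training design.
.encode_dataset <- function(records, observations, norm) {
  idx <- match(observations$lake_id, records$lake_id)
  if (anyNA(idx)) {
    stop("observation refers to unknown lake_id: ",
         observations$lake_id[which(is.na(idx))[1]], call. = FALSE)
  }
  x <- .design_matrix(records[idx, , drop = FALSE], observations$season, norm)
  list(x = x, y = observations$chla, lake_id = observations$lake_id,
       season = observations$season,
       connectivity = records$connectivity[idx])
}

#' Binary eutrophication state at a chlorophyll-a threshold
#'
#' A measurement counts as eutrophic when chlorophyll a strictly exceeds the
#' threshold (default 25 ug/L, the OECD significant-eutrophication boundary);
#' a value exactly at the threshold is not eutrophic.
#'
#' @param chla Chlorophyll a, ug/L (non-negative; vectorised).
#' @param threshold Boundary in ug/L.
#' @return Logical vector.
#' @export
classify_eutrophic <- function(chla, threshold = 25) {
  if (any(!is.finite(chla)) || any(chla < 0)) {
    stop("chlorophyll a must be finite and non-negative", call. = FALSE)
  }
  chla > threshold
}

#' OECD fixed-boundary trophic class from annual-mean chlorophyll a
#'
#' Default annual-mean boundaries: below 2.5 ug/L oligotrophic, 2.5-8
#' mesotrophic, 8-25 eutrophic, above 25 hypertrophic. A value exactly at a
#' boundary falls in the class whose range it opens (2.5 is mesotrophic, 8 is
#' eutrophic), except 25, which stays eutrophic so that "hypertrophic" agrees
#' with the strict > 25 rule of [classify_eutrophic()].
#'
#' @param annual_mean_chla Annual mean chlorophyll a, ug/L (vectorised).
#' @param boundaries Ascending numeric vector of the three class boundaries.
#' @return Character vector over \{oligotrophic, mesotrophic, eutrophic,
#'   hypertrophic\}.
#' @export
oecd_trophic_class <- function(annual_mean_chla,
                               boundaries = c(2.5, 8, 25)) {
  stopifnot(length(boundaries) == 3, !is.unsorted(boundaries))
  if (any(!is.finite(annual_mean_chla)) || any(annual_mean_chla < 0)) {
    stop("annual mean chlorophyll a must be finite and non-negative",
         call. = FALSE)
  }
  out <- rep("oligotrophic", length(annual_mean_chla))
  out[annual_mean_chla >= boundaries[1]] <- "mesotrophic"
  out[annual_mean_chla >= boundaries[2]] <- "eutrophic"
  out[annual_mean_chla > boundaries[3]] <- "hypertrophic"
  out
}
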