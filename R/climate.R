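# Climate module: temperature-humidity index, daily/weekly aggregation,
# herd-to-station assignment and in-utero heat-stress exposure coding.

#' Hourly temperature-humidity index
#'
#' Computes the classic THI from dry-bulb temperature and relative humidity:
#' `THI = (1.8 T + 32) - (0.55 - 0.0055 RH) (1.8 T - 26)`.
#' THI is a unitless heat-load indicator; 60 is the in-utero heat-stress
#' threshold used throughout this package.
#'
#' @param temp_c Air temperature in degrees Celsius (vectorised).
#' @param rh_pct Relative humidity in percent, within \[0, 100\].
#' @return Numeric vector of THI values.
#' @examples
#' thi_hourly(20, 100) # 68: the humidity bracket cancels at RH = 100
#' thi_hourly(26 / 1.8, 10) # 58 regardless of RH: the temperature bracket vanishes
#' @export
thi_hourly <- function(temp_c, rh_pct) {
  if (any(!is.finite(temp_c))) stop("temp_c must be finite")
  if (any(!is.finite(rh_pct)) || any(rh_pct < 0 | rh_pct > 100)) {
    stop("rh_pct must lie in [0, 100]")
  }
  (1.8 * temp_c + 32) - (0.55 - 0.0055 * rh_pct) * (1.8 * temp_c - 26)
}

#' Binary heat-stress indicator
#'
#' @param weekly_thi Numeric vector of weekly mean THI values.
#' @param threshold Heat-stress threshold (default 60).
#' @return Integer vector: 1 where `weekly_thi >= threshold`, else 0.
#' @export
hs_indicator <- function(weekly_thi, threshold = 60) {
  if (any(!is.finite(weekly_thi))) stop("weekly_thi must be finite")
  as.integer(weekly_thi >= threshold)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean radius).
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  ok <- function(lat, lon) all(is.finite(lat)) && all(is.finite(lon)) &&
    all(abs(lat) <= 90) && all(abs(lon) <= 180)
  if (!ok(lat1, lon1) || !ok(lat2, lon2)) {
    stop("coordinates must satisfy |lat| <= 90, |lon| <= 180")
  }
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Assign each herd to its nearest weather station
#'
#' Ties on distance are broken deterministically by the lexicographically
#' smallest `station_id`. The assignment is static: one station per herd.
#'
#' @param herds Data frame with columns `herd_id`, `lat`, `lon`.
#' @param stations Data frame with columns `station_id`, `lat`, `lon`.
#' @return Data frame `herd_id`, `station_id`, `distance_km`.
#' @export
assign_stations <- function(herds, stations) {
  stopifnot(is.data.frame(herds), is.data.frame(stations))
  if (nrow(stations) == 0L) stop("station table is empty")
  if (nrow(herds) == 0L) stop("herd table is empty")
  ord <- order(as.character(stations$station_id))
  stations <- stations[ord, , drop = FALSE]
  res <- lapply(seq_len(nrow(herds)), function(i) {
    d <- haversine_km(herds$lat[i], herds$lon[i], stations$lat, stations$lon)
    j <- which.min(d) # first minimum = smallest station_id after sorting
    data.frame(herd_id = herds$herd_id[i],
               station_id = stations$station_id[j],
               distance_km = d[j], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Daily mean THI per station
#'
#' Averages hourly THI within each calendar day. Days with fewer than
#' `min_hours` hourly records are treated as missing (dropped from the
#' output); days with `min_hours` to 23 records use the mean of the
#' available hours and are flagged `partial`.
#'
#' @param weather Data frame with columns `station_id`, `timestamp`
#'   (POSIXct or ISO-8601 string), `temp_c`, `rh_pct`.
#' @param min_hours Minimum hourly records for a day to be usable (default 18).
#' @return Data frame `station_id`, `date` (Date), `thi`, `n_hours`, `partial`.
#' @export
daily_thi <- function(weather, min_hours = 18) {
  stopifnot(is.data.frame(weather),
            all(c("station_id", "timestamp", "temp_c", "rh_pct") %in%
                  names(weather)))
  if (nrow(weather) == 0L) stop("no hourly records supplied")
  ts <- weather$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  thi <- thi_hourly(weather$temp_c, weather$rh_pct)
  day <- as.Date(ts, tz = "UTC")
  key <- interaction(weather$station_id, day, drop = TRUE)
  agg <- data.frame(
    station_id = tapply(as.character(weather$station_id), key, `[`, 1L),
    date = as.Date(as.vector(tapply(as.numeric(day), key, `[`, 1L)),
                   origin = "1970-01-01"),
    thi = as.vector(tapply(thi, key, mean)),
    n_hours = as.vector(tapply(thi, key, length)),
    stringsAsFactors = FALSE)
  agg$partial <- agg$n_hours < 24L
  agg <- agg[agg$n_hours >= min_hours, , drop = FALSE]
  agg <- agg[order(agg$station_id, agg$date), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Dates covered by a gestation week counted back from birth
#'
#' Week 1 spans days 0-7 before birth (eight calendar days, including the
#' birth day, as conventionally printed); week k >= 2 spans days
#' 7(k-1)+1 .. 7k. With `week1 = "strict7"` week 1 is trimmed to days 1-7
#' so all weeks have seven days.
#'
#' @param birth_date A `Date`.
#' @param week Integer in 1..8.
#' @param week1 Either "printed" (default, 8-day week 1) or "strict7".
#' @return Vector of `Date`s, ascending.
#' @export
gestation_week_days <- function(birth_date, week, week1 = c("printed", "strict7")) {
  week1 <- match.arg(week1)
  stopifnot(length(week) == 1L, week >= 1, week <= 8)
  birth_date <- as.Date(birth_date)
  if (week == 1) {
    offs <- if (week1 == "printed") 0:7 else 1:7
  } else {
    offs <- (7 * (week - 1) + 1):(7 * week)
  }
  sort(birth_date - offs)
}

#' Weekly mean THI for one animal and gestation week
#'
#' @param daily Data frame from [daily_thi()] restricted to one station.
#' @param birth_date Birth date of the animal (`Date`).
#' @param week Gestation week 1..8 (counted backwards from birth).
#' @param week1 Week-1 convention, see [gestation_week_days()].
#' @return Scalar weekly mean THI.
#' @export
weekly_thi <- function(daily, birth_date, week, week1 = "printed") {
  days <- gestation_week_days(birth_date, week, week1)
  idx <- match(days, daily$date)
  if (anyNA(idx)) {
    stop(sprintf("missing daily THI for %d of %d required days (week %d)",
                 sum(is.na(idx)), length(days), week))
  }
  mean(daily$thi[idx])
}

#' Build the in-utero exposure table
#'
#' Joins animals to their herd's assigned weather station, averages daily THI
#' over each requested gestation week before the animal's birth date, and
#' codes the binary heat-stress flag (`weekly_thi >= threshold`).
#'
#' @param animals Data frame with `animal_id`, `herd_id`, `birth_date`.
#' @param daily Data frame from [daily_thi()] (all stations).
#' @param assignment Data frame from [assign_stations()].
#' @param weeks Integer vector of gestation weeks (default 1:8).
#' @param threshold Heat-stress THI threshold (default 60).
#' @param week1 Week-1 convention, see [gestation_week_days()].
#' @return Data frame `animal_id`, `week`, `weekly_thi`, `hs_flag` with one
#'   row per animal x week.
#' @export
build_exposure <- function(animals, daily, assignment, weeks = 1:8,
                           threshold = 60, week1 = "printed") {
  stopifnot(all(c("animal_id", "herd_id", "birth_date") %in% names(animals)))
  station_of <- assignment$station_id[match(animals$herd_id, assignment$herd_id)]
  if (anyNA(station_of)) stop("some herds lack a station assignment")
  by_station <- split(daily, daily$station_id)
  out <- vector("list", length(weeks) * nrow(animals))
  k <- 0L
  for (i in seq_len(nrow(animals))) {
    d <- by_station[[as.character(station_of[i])]]
    if (is.null(d)) stop("no daily THI for station ", station_of[i])
    for (w in weeks) {
      k <- k + 1L
      thi <- weekly_thi(d, animals$birth_date[i], w, week1)
      out[[k]] <- data.frame(animal_id = animals$animal_id[i], week = w,
                             weekly_thi = thi, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$hs_flag <- hs_indicator(res$weekly_thi, threshold)
  res[order(res$animal_id, res$week), ]
}
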