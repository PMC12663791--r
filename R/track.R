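# Cruise-track geometry: great-circle distances, SST-based region
# classification (10/20 degC isotherms), and 1-D along-track linear
# interpolation of station nutrient fields to arbitrary observation points.

.check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(abs(lat) > 90))
    stop("latitude must be finite and within [-90, 90]", call. = FALSE)
  if (any(!is.finite(lon)) || any(abs(lon) > 180))
    stop("longitude must be finite and within [-180, 180]", call. = FALSE)
}

#' Great-circle distance
#'
#' Haversine distance between two points (or two equal-length vectors of
#' points) on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees.
#' @return Distance in km.
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1); .check_coords(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Cumulative along-track distance
#'
#' Distance (km) of each point from the first, accumulated along the point
#' order; non-decreasing by construction.
#'
#' @param lat,lon decimal degrees, in track order.
#' @return Numeric vector of km, first element 0.
#' @export
along_track_distance <- function(lat, lon) {
  .check_coords(lat, lon)
  n <- length(lat)
  if (n == 1) return(0)
  seg <- great_circle_distance(lat[-n], lon[-n], lat[-1], lon[-1])
  c(0, cumsum(seg))
}

#' Classify a sea surface temperature into a region
#'
#' The 20 and 10 degC isotherms split the transect into subtropical
#' (> 20 degC), front (10--20 degC, boundaries inclusive) and subantarctic
#' (< 10 degC) regions.
#'
#' @param sst degC (vectorized, finite).
#' @return Factor with levels `subtropical`, `front`, `subantarctic`.
#' @export
classify_region <- function(sst) {
  if (any(!is.finite(sst))) stop("sst must be finite", call. = FALSE)
  out <- ifelse(sst > 20, "subtropical",
                ifelse(sst < 10, "subantarctic", "front"))
  factor(out, levels = c("subtropical", "front", "subantarctic"))
}

# Along-track coordinate of an observation: project onto the better of the
# two segments adjacent to the nearest station (planar projection along the
# chord), clamped to the track extent.
.track_position <- function(lat, lon, st) {
  x <- st$along_track_km
  d <- great_circle_distance(lat, lon, st$lat, st$lon)
  i <- which.min(d)
  pos <- NA_real_
  for (seg in list(c(i - 1L, i), c(i, i + 1L))) {
    if (seg[1] < 1 || seg[2] > nrow(st)) next
    a <- seg[1]; b <- seg[2]
    Dab <- x[b] - x[a]
    if (Dab <= 0) next
    t <- (d[a]^2 - d[b]^2 + Dab^2) / (2 * Dab^2)
    if (t >= 0 && t <= 1) { pos <- x[a] + t * Dab; break }
  }
  if (is.na(pos)) pos <- x[i]          # off either end, or degenerate: clamp
  min(max(pos, x[1]), x[length(x)])
}

#' Interpolate station nutrients to observation points
#'
#' Linear interpolation of each dissolved solute between the two bracketing
#' stations, in 1-D along cumulative great-circle track distance (the
#' transect analogue of geographical linear interpolation between nearest
#' stations). Observations beyond the track extent are clamped to the
#' terminal station; interpolated values never leave the envelope of the
#' bracketing values.
#'
#' @param lat,lon observation coordinates, decimal degrees (vectorized).
#' @param stations a station table as returned by [read_station_table()] or
#'   [simulate_cruise()]: ordered along track with columns `lat`, `lon` and
#'   solute concentrations in nmol/L.
#' @param fill policy for stations with a missing solute: `"error"`
#'   (default) or `"drop"` (that station is skipped for that solute).
#' @return A [nutrient_field()] with one row per observation.
#' @export
interpolate_nutrients <- function(lat, lon, stations, fill = c("error", "drop")) {
  fill <- match.arg(fill)
  if (is.null(stations) || nrow(stations) == 0)
    stop("empty station list", call. = FALSE)
  if (nrow(stations) < 2)
    stop("need at least 2 stations to interpolate", call. = FALSE)
  st <- stations
  if (is.null(st$along_track_km))
    st$along_track_km <- along_track_distance(st$lat, st$lon)
  .check_coords(lat, lon)
  pos <- vapply(seq_along(lat),
                function(k) .track_position(lat[k], lon[k], st), numeric(1))
  solutes <- c("ammonium", "nitrite", "nitrate", "phosphate", "urea")
  vals <- lapply(solutes, function(s) {
    v <- st[[s]]
    if (is.null(v)) v <- rep(NA_real_, nrow(st))
    if (s != "urea" && any(is.na(v))) {
      if (fill == "error")
        stop("station ", st$station_id[which(is.na(v))[1]],
             " is missing ", s, " (set fill = 'drop' to skip it)",
             call. = FALSE)
      keep <- !is.na(v)
      if (sum(keep) < 2) stop("too few stations carry ", s, call. = FALSE)
      return(stats::approx(st$along_track_km[keep], v[keep], xout = pos,
                           rule = 2)$y)
    }
    if (all(is.na(v))) return(rep(NA_real_, length(pos)))
    stats::approx(st$along_track_km, v, xout = pos, rule = 2)$y
  })
  names(vals) <- solutes
  nutrient_field(vals$ammonium, vals$nitrite, vals$nitrate,
                 vals$phosphate, vals$urea)
}

#' Nearest-in-time underway record
#'
#' Index of the underway observation closest in time to each query time;
#' supplies the per-cell seawater state.
#'
#' @param time POSIXct query times.
#' @param underway an underway table with a POSIXct `time` column.
#' @return Integer indices into `underway`.
#' @export
nearest_in_time <- function(time, underway) {
  if (is.null(underway) || nrow(underway) == 0)
    stop("empty underway table", call. = FALSE)
  ut <- as.numeric(underway$time)
  vapply(as.numeric(time),
         function(t) which.min(abs(ut - t)), integer(1))
}
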