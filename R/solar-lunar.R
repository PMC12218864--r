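## Solar position and lunar illumination.
##
## Dawn/dusk use the NOAA solar-position equations (equation of time +
## declination from the truncated series, hour angle at a configurable solar
## altitude). "Dawn"/"dusk" default to civil twilight (sun altitude -6 deg),
## the convention camera-trap studies inherit from the suncalc ecosystem;
## sunrise/sunset (-0.833 deg, refraction included) is available via
## `twilight_deg`. Lunar illuminated fraction uses the standard low-precision
## ecliptic-longitude series; accuracy is a few thousandths, ample for a
## [0, 1] moonlight covariate.

DEG <- pi / 180

# Julian day number from POSIXct (UTC)
.julian_day <- function(time) as.numeric(time) / 86400 + 2440587.5

# NOAA solar coefficients at Julian centuries T; angles in radians where used
.solar_terms <- function(jd) {
  tc <- (jd - 2451545) / 36525
  L0 <- (280.46646 + 36000.76983 * tc + 0.0003032 * tc^2) %% 360
  M <- 357.52911 + 35999.05029 * tc - 0.0001537 * tc^2
  e <- 0.016708634 - 0.000042037 * tc - 0.0000001267 * tc^2
  C <- sin(M * DEG) * (1.914602 - 0.004817 * tc - 0.000014 * tc^2) +
    sin(2 * M * DEG) * (0.019993 - 0.000101 * tc) +
    sin(3 * M * DEG) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * tc
  lambda <- true_long - 0.00569 - 0.00478 * sin(omega * DEG)
  eps0 <- 23 + (26 + (21.448 - tc * (46.815 + tc * (0.00059 - tc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * DEG)
  decl <- asin(sin(eps * DEG) * sin(lambda * DEG)) / DEG
  y <- tan(eps * DEG / 2)^2
  eot <- 4 / DEG * (
    y * sin(2 * L0 * DEG) - 2 * e * sin(M * DEG) +
      4 * e * y * sin(M * DEG) * cos(2 * L0 * DEG) -
      0.5 * y^2 * sin(4 * L0 * DEG) - 1.25 * e^2 * sin(2 * M * DEG)
  )
  list(declination = decl, eot_min = eot)
}

# hour angle (degrees) at which the sun centre sits at altitude `alt_deg`
.hour_angle <- function(lat, decl, alt_deg) {
  cosH <- (sin(alt_deg * DEG) - sin(lat * DEG) * sin(decl * DEG)) /
    (cos(lat * DEG) * cos(decl * DEG))
  if (any(abs(cosH) > 1)) {
    stopf("sun never crosses altitude %g degrees at latitude %g on this date", alt_deg, lat)
  }
  acos(cosH) / DEG
}

.check_latlon <- function(lat, lon) {
  if (any(abs(lat) >= 66)) {
    stopf("latitudes poleward of 66 degrees are not supported (polar day/night handling not implemented)")
  }
  check_number(lon, "lon", -180, 360)
}

#' Dawn and dusk times for a date and location
#'
#' Computes the instants at which the sun crosses `twilight_deg` degrees of
#' altitude (civil twilight by default), using the NOAA solar-position
#' equations with one refinement iteration, accurate to about a minute at
#' tropical latitudes.
#'
#' @param date a `Date` vector (interpreted as the local civil date).
#' @param lat,lon latitude/longitude in decimal degrees; `abs(lat)` must be
#'   below 66 (no polar handling).
#' @param twilight_deg solar altitude defining dawn/dusk, in degrees.
#'   Default `-6` (civil twilight); use `-0.833` for sunrise/sunset.
#' @param tz_offset_hours offset of the local civil day from UTC, in hours
#'   (default 3, East Africa Time). Only used to anchor which UTC solar noon
#'   belongs to `date`.
#' @return A tibble with columns `date`, `dawn`, `dusk` (POSIXct, UTC),
#'   `lat`, `lon`.
#' @export
#' @examples
#' sun_times(as.Date("2021-02-01"), lat = 0.3, lon = 36.9)
sun_times <- function(date, lat, lon, twilight_deg = -6, tz_offset_hours = 3) {
  .check_latlon(lat, lon)
  date <- as.Date(date)
  # UTC instant of local civil noon for this date
  noon_guess <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC") - tz_offset_hours * 3600
  one_pass <- function(t_ref, side) {
    st <- .solar_terms(.julian_day(t_ref))
    noon_min <- 720 - 4 * lon - st$eot_min
    H <- .hour_angle(lat, st$declination, twilight_deg)
    as.POSIXct(as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC")) +
      60 * (noon_min + side * 4 * H), tz = "UTC", origin = "1970-01-01")
  }
  dawn <- one_pass(noon_guess, -1)
  dawn <- one_pass(dawn, -1) # refine terms at the event time
  dusk <- one_pass(noon_guess, +1)
  dusk <- one_pass(dusk, +1)
  tibble::tibble(date = date, dawn = dawn, dusk = dusk, lat = lat, lon = lon)
}

#' Is a timestamp at night?
#'
#' Night is strictly after that local day's dusk or strictly before its dawn;
#' the boundary instants themselves count as day, as do all instants between.
#'
#' @param time POSIXct vector (UTC).
#' @inheritParams sun_times
#' @return Logical vector.
#' @export
#' @examples
#' is_night(as.POSIXct("2021-02-01 21:00:00", tz = "UTC"), lat = 0.3, lon = 36.9)
is_night <- function(time, lat, lon, twilight_deg = -6, tz_offset_hours = 3) {
  .check_latlon(lat, lon)
  time <- as.POSIXct(time, tz = "UTC")
  local_date <- as.Date(time + tz_offset_hours * 3600)
  st <- sun_times(local_date, lat, lon, twilight_deg, tz_offset_hours)
  time < st$dawn | time > st$dusk
}

#' Illuminated fraction of the lunar disc
#'
#' Low-precision lunar phase: the fraction is `(1 + cos(i)) / 2` where the
#' phase angle `i` comes from the mean elongation of the moon corrected by
#' the leading periodic terms of the lunar and solar ecliptic longitudes.
#' Accuracy is about 0.005 against almanac values.
#'
#' @param time POSIXct vector (UTC), within 1900--2100.
#' @return Numeric vector of fractions in `[0, 1]` (0 = new, 1 = full).
#' @export
#' @examples
#' lunar_fraction(as.POSIXct("2021-01-28 19:16:00", tz = "UTC")) # full moon
lunar_fraction <- function(time) {
  time <- as.POSIXct(time, tz = "UTC")
  yr <- as.integer(format(time, "%Y"))
  if (any(yr < 1900 | yr > 2100)) {
    stopf("timestamps must lie in 1900-2100 for the low-precision lunar series")
  }
  tc <- (.julian_day(time) - 2451545) / 36525
  D <- 297.8501921 + 445267.1114034 * tc - 0.0018819 * tc^2 # mean elongation
  M <- 357.5291092 + 35999.0502909 * tc # solar mean anomaly
  Mp <- 134.9633964 + 477198.8675055 * tc # lunar mean anomaly
  i <- 180 - D -
    6.289 * sin(Mp * DEG) +
    2.100 * sin(M * DEG) -
    1.274 * sin((2 * D - Mp) * DEG) -
    0.658 * sin(2 * D * DEG) -
    0.214 * sin(2 * Mp * DEG) -
    0.110 * sin(D * DEG)
  (1 + cos(i * DEG)) / 2
}

# Daily lunar covariate: illuminated fraction at local midnight of each date.
# (Day-level models need one value per calendar day; midnight is the centre
# of the night period the covariate is meant to describe.)
lunar_fraction_daily <- function(date, tz_offset_hours = 3) {
  midnight <- as.POSIXct(paste(as.Date(date) + 1, "00:00:00"), tz = "UTC") -
    tz_offset_hours * 3600
  lunar_fraction(midnight)
}
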