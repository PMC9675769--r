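# Solar geometry: sun event times, diel classification, sun-anchored time.
#
# Timestamps throughout the package are POSIXct carrying tz = "UTC" whose
# clock value is interpreted as *site-local standard time*, with the zone
# offset derived from longitude as round(longitude / 15) hours. This keeps
# multi-site tables in one column without per-site tz bookkeeping.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

# zenith angles (degrees) defining the diel boundaries
ZENITH_OFFICIAL <- 90.833  # sunrise/sunset: refraction + solar radius
ZENITH_NAUTICAL <- 102     # nautical dawn/dusk: sun 12 deg below horizon

utc_offset_hours <- function(longitude) round(longitude / 15)

# Julian day number at 00:00 UTC of a Date
.jd0 <- function(date) as.numeric(date) + 2440587.5

# NOAA spreadsheet solar position: equation of time (minutes) and
# declination (radians) at a Julian date.
.noaa_sun <- function(jd) {
  jc <- (jd - 2451545) / 36525
  l0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  m  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e  <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  mr <- m * DEG2RAD
  eqctr <- sin(mr) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * mr) * (0.019993 - 0.000101 * jc) +
    sin(3 * mr) * 0.000289
  true_long <- l0 + eqctr
  omega <- (125.04 - 1934.136 * jc) * DEG2RAD
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega)
  obl0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obl <- (obl0 + 0.00256 * cos(omega)) * DEG2RAD
  decl <- asin(sin(obl) * sin(app_long * DEG2RAD))
  y <- tan(obl / 2)^2
  l0r <- l0 * DEG2RAD
  eqtime <- 4 * RAD2DEG *
    (y * sin(2 * l0r) - 2 * e * sin(mr) + 4 * e * y * sin(mr) * cos(2 * l0r) -
       0.5 * y^2 * sin(4 * l0r) - 1.25 * e^2 * sin(2 * mr))
  list(eqtime = eqtime, decl = decl)
}

# hour angle (degrees) at which the sun reaches the given zenith; NA when
# there is no crossing (polar day/night for that threshold)
.hour_angle <- function(lat, decl, zenith) {
  latr <- lat * DEG2RAD
  x <- cos(zenith * DEG2RAD) / (cos(latr) * cos(decl)) - tan(latr) * tan(decl)
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x) & abs(x) <= 1
  out[ok] <- acos(x[ok]) * RAD2DEG
  out
}

# UTC minutes-past-midnight of the morning/evening crossings of `zenith`,
# refined with a second pass at the first-guess time. Vectorised over date.
.sun_utc_minutes <- function(date, lat, lon, zenith) {
  jd <- .jd0(date)
  jd_noon <- jd + 0.5 - lon / 360
  pos <- .noaa_sun(jd_noon)
  ha <- .hour_angle(lat, pos$decl, zenith)
  morning <- 720 - 4 * (lon + ha) - pos$eqtime
  evening <- 720 - 4 * (lon - ha) - pos$eqtime
  refine <- function(minutes) {
    pos2 <- .noaa_sun(jd + minutes / 1440)
    ha2 <- .hour_angle(lat, pos2$decl, zenith)
    list(m = 720 - 4 * (lon + ha2) - pos2$eqtime,
         e = 720 - 4 * (lon - ha2) - pos2$eqtime)
  }
  rm_ <- refine(morning)$m
  re_ <- refine(evening)$e
  list(morning = rm_, evening = re_)
}

#' Sun event times for a site and date
#'
#' Computes nautical dawn, sunrise, sunset and nautical dusk from standard
#' solar-position geometry (NOAA almanac formulas). Sunrise and sunset are
#' defined at solar altitude -0.833 degrees (atmospheric refraction plus the
#' solar radius); nautical dawn and dusk at -12 degrees.
#'
#' @param date `Date` vector.
#' @param latitude,longitude site coordinates in decimal degrees (scalars).
#' @return A data.frame with columns `date`, `nautical_dawn`, `sunrise`,
#'   `sunset`, `nautical_dusk` (POSIXct, site-local clock, see package
#'   conventions) and the same four instants as decimal hours in
#'   `*_hour` columns. Events that do not occur (polar day or night at high
#'   latitude) are `NA` — never a silent default.
#' @export
sun_times <- function(date, latitude, longitude) {
  stopifnot(inherits(date, "Date"), length(latitude) == 1, length(longitude) == 1)
  if (abs(latitude) > 89.9) stop("latitude out of range")
  off <- utc_offset_hours(longitude)
  rs <- .sun_utc_minutes(date, latitude, longitude, ZENITH_OFFICIAL)
  tw <- .sun_utc_minutes(date, latitude, longitude, ZENITH_NAUTICAL)
  to_local <- function(min_utc) min_utc / 60 + off
  hrs <- data.frame(
    nautical_dawn_hour = to_local(tw$morning),
    sunrise_hour       = to_local(rs$morning),
    sunset_hour        = to_local(rs$evening),
    nautical_dusk_hour = to_local(tw$evening)
  )
  base <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  out <- data.frame(date = date)
  for (nm in c("nautical_dawn", "sunrise", "sunset", "nautical_dusk")) {
    h <- hrs[[paste0(nm, "_hour")]]
    out[[nm]] <- base + h * 3600
    out[[nm]][is.na(h)] <- NA
  }
  cbind(out, hrs)
}

# decimal local-clock hour and local Date of a package-convention timestamp
.local_hour <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}
.local_date <- function(timestamp) as.Date(format(timestamp, tz = "UTC"))

.require_sun <- function(st, cols, what) {
  bad <- vapply(cols, function(cn) anyNA(st[[cn]]), logical(1))
  if (any(bad)) {
    stop("no ", paste(cols[bad], collapse = "/"), " on ",
         paste(format(st$date[rowSums(is.na(st[cols])) > 0]), collapse = ", "),
         ": polar day/night — cannot ", what)
  }
}

#' Classify timestamps into day, twilight or night
#'
#' Day is the interval `[sunrise, sunset)`; twilight is
#' `[nautical_dawn, sunrise)` together with `[sunset, nautical_dusk)`;
#' night is everything else. Intervals are half-open (left-closed) so the
#' three categories tile the civil day exactly.
#'
#' @param timestamp POSIXct vector (site-local clock, tz = "UTC" convention).
#' @param latitude,longitude site coordinates in decimal degrees.
#' @return factor with levels `day`, `twilight`, `night`.
#' @export
classify_diel <- function(timestamp, latitude, longitude) {
  d <- .local_date(timestamp)
  h <- .local_hour(timestamp)
  ud <- sort(unique(d))
  st <- sun_times(ud, latitude, longitude)
  .require_sun(st, c("nautical_dawn_hour", "sunrise_hour", "sunset_hour",
                     "nautical_dusk_hour"), "classify diel category")
  i <- match(d, ud)
  dawn <- st$nautical_dawn_hour[i]; sr <- st$sunrise_hour[i]
  ss <- st$sunset_hour[i]; dusk <- st$nautical_dusk_hour[i]
  cat <- rep("night", length(h))
  cat[h >= sr & h < ss] <- "day"
  cat[(h >= dawn & h < sr) | (h >= ss & h < dusk)] <- "twilight"
  factor(cat, levels = c("day", "twilight", "night"))
}

# sunrise/sunset hours for date vector, recycled over three consecutive days
.sr_ss <- function(dates, latitude, longitude) {
  ud <- sort(unique(dates))
  st <- sun_times(ud, latitude, longitude)
  .require_sun(st, c("sunrise_hour", "sunset_hour"), "anchor to sun")
  i <- match(dates, ud)
  list(sr = st$sunrise_hour[i], ss = st$sunset_hour[i])
}

#' Transform clock time to sun-anchored circular time
#'
#' Double anchoring: sunrise maps to pi/2 and sunset to 3*pi/2 for every site
#' and date; daytime instants are interpolated linearly onto `[pi/2, 3*pi/2]`
#' and night instants onto the complementary arc through 0 (solar midnight),
#' so pi is solar noon regardless of photoperiod. The transform is continuous
#' and invertible for a fixed site and date (see [sun_anchor_invert()]).
#'
#' @inheritParams classify_diel
#' @return numeric vector of radians in `[0, 2*pi)`.
#' @export
anchor_to_sun <- function(timestamp, latitude, longitude) {
  d <- .local_date(timestamp)
  h <- .local_hour(timestamp)
  today <- .sr_ss(d, latitude, longitude)
  prev  <- .sr_ss(d - 1, latitude, longitude)
  nxt   <- .sr_ss(d + 1, latitude, longitude)
  theta <- numeric(length(h))
  day_ix <- h >= today$sr & h < today$ss
  theta[day_ix] <- pi / 2 +
    pi * (h[day_ix] - today$sr[day_ix]) / (today$ss[day_ix] - today$sr[day_ix])
  eve <- h >= today$ss
  Ln <- (24 - today$ss) + nxt$sr           # night length starting tonight
  theta[eve] <- 3 * pi / 2 + pi * (h[eve] - today$ss[eve]) / Ln[eve]
  mor <- h < today$sr
  Lp <- (24 - prev$ss) + today$sr          # night length ending this morning
  theta[mor] <- 3 * pi / 2 + pi * (h[mor] + 24 - prev$ss[mor]) / Lp[mor]
  theta %% (2 * pi)
}

#' Invert the sun anchoring for a given site and date
#'
#' Maps an anchored angle back to a clock timestamp: angles in
#' `[pi/2, 3*pi/2)` land in the daytime of `date`; `[3*pi/2, 2*pi)` in the
#' night following sunset of `date`; `[0, pi/2)` in the night ending at
#' sunrise of `date`. Composition with [anchor_to_sun()] is the identity.
#'
#' @param theta radians in `[0, 2*pi)`.
#' @param date `Date` (scalar or same length as `theta`).
#' @param latitude,longitude site coordinates in decimal degrees.
#' @return POSIXct timestamps (site-local clock convention).
#' @export
sun_anchor_invert <- function(theta, date, latitude, longitude) {
  theta <- theta %% (2 * pi)
  n <- length(theta)
  date <- rep(as.Date(date), length.out = n)
  today <- .sr_ss(date, latitude, longitude)
  prev  <- .sr_ss(date - 1, latitude, longitude)
  nxt   <- .sr_ss(date + 1, latitude, longitude)
  h <- numeric(n)
  day_ix <- theta >= pi / 2 & theta < 3 * pi / 2
  h[day_ix] <- today$sr[day_ix] +
    (theta[day_ix] - pi / 2) / pi * (today$ss[day_ix] - today$sr[day_ix])
  eve <- theta >= 3 * pi / 2
  Ln <- (24 - today$ss) + nxt$sr
  h[eve] <- today$ss[eve] + (theta[eve] - 3 * pi / 2) / pi * Ln[eve]
  mor <- theta < pi / 2
  Lp <- (24 - prev$ss) + today$sr
  h[mor] <- today$sr[mor] - (pi / 2 - theta[mor]) / pi * Lp[mor]
  as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC") + h * 3600
}
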