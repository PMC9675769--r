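# Independent oracles used by the tests. These deliberately use different
# algorithms from the package: solar positions follow Michalsky's (1988)
# Astronomical Almanac algorithm with a brute-force 1-minute altitude scan
# (the package uses NOAA hour-angle formulas), and the overlap truth uses
# adaptive quadrature on the exact densities (the package uses KDE +
# trapezoid sums).

# solar elevation (degrees) at UT decimal hour on `date` — Michalsky 1988
.oracle_elevation <- function(date, ut_hour, lat, lon) {
  jd <- as.numeric(date) + 2440587.5 + ut_hour / 24
  n <- jd - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * pi / 180
  lambda <- ((L + 1.915 * sin(g) + 0.020 * sin(2 * g)) %% 360) * pi / 180
  eps <- (23.439 - 4e-7 * n) * pi / 180
  dec <- asin(sin(eps) * sin(lambda))
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda)) * 180 / pi
  gmst <- (6.697375 + 0.0657098242 * n + ut_hour) %% 24
  lmst <- (gmst + lon / 15) %% 24
  ha <- ((lmst * 15 - ra + 180) %% 360 - 180) * pi / 180
  latr <- lat * pi / 180
  asin(sin(latr) * sin(dec) + cos(latr) * cos(dec) * cos(ha)) * 180 / pi
}

# sun event times (local decimal hours, longitude-derived zone) by scanning
# solar elevation on a 1-minute UT grid and interpolating the crossings
oracle_sun_times <- function(date, lat, lon) {
  off <- round(lon / 15)
  ut <- seq(-off, -off + 24, by = 1 / 60)   # covers the local civil day
  el <- .oracle_elevation(date, ut, lat, lon)
  crossing <- function(threshold, rising) {
    d <- el - threshold
    i <- which(d[-length(d)] * d[-1] <= 0 & d[-length(d)] != d[-1])
    if (rising) i <- i[d[i] < 0] else i <- i[d[i] > 0]
    if (!length(i)) return(NA_real_)
    i <- i[1]
    frac <- d[i] / (d[i] - d[i + 1])
    (ut[i] + frac / 60 + off) %% 24
  }
  list(nautical_dawn = crossing(-12, TRUE),
       sunrise = crossing(-0.833, TRUE),
       sunset = crossing(-0.833, FALSE),
       nautical_dusk = crossing(-12, FALSE))
}

# true overlap of two von Mises densities by adaptive quadrature
oracle_vm_overlap <- function(mu1, k1, mu2, k2) {
  stats::integrate(function(t) {
    pmin(dvonmises(t, mu1, k1), dvonmises(t, mu2, k2))
  }, 0, 2 * pi, rel.tol = 1e-10, subdivisions = 400L)$value
}

# minimal trait-table constructor for event-module tests
make_traits <- function(species, mass_g, stratum = "ground",
                        vert = 0, plant = 0.5, invert = 0.2) {
  data.frame(species = species, body_mass_g = mass_g,
             diet_vertebrate = vert, diet_plant = plant,
             diet_invertebrate = invert,
             diet_other = pmax(0, 1 - vert - plant - invert),
             stratum = stratum)
}

# detection table at one equatorial camera with given timestamps
make_detections <- function(timestamps, species = "spA", camera = "C1",
                            area = "PA1", lat = 0, lon = 0) {
  data.frame(protected_area = area, camera = camera, latitude = lat,
             longitude = lon, species = species,
             timestamp = as.POSIXct(timestamps, tz = "UTC"))
}
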