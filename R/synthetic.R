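# Synthetic camera-trap detection streams with known ground truth.
#
# The ground truth is a 3-category multinomial logit on the diel category
# with day as the reference: eta_night = intercept_guild +
# slope_guild * log10(mass_g), eta_twilight = constant. Given its category,
# an event's sun-anchored time is drawn from the matching von Mises
# component truncated to that category's band for the site and date
# (diurnal centred pi, nocturnal centred 0; twilight uniform on its narrow
# arcs), so the realised diel category always agrees with the draw and the
# empirical nocturnal fraction converges to the ground-truth weight.

#' Configuration for the synthetic generator
#'
#' Defaults emulate a standardised multi-area tropical survey: several protected areas
#' between 30S and 30N, 60 cameras per area active ~30 consecutive days, a
#' community of species above 75 g with guild-dependent mass-nocturnality
#' slopes (herbivores and insectivores more nocturnal when larger,
#' carnivores and omnivores the opposite).
#'
#' @param n_sites number of protected areas.
#' @param site_latitudes,site_longitudes site coordinates (length `n_sites`).
#' @param n_cameras_per_site cameras per area.
#' @param deployment_days consecutive active days per camera.
#' @param start_date first deployment date.
#' @param n_species community size.
#' @param mass_range_g body-mass interval in grams (lower bound >= 75).
#' @param guild_proportions named simplex over the four guilds.
#' @param nocturnality_slope_per_guild named vector: logit change of the
#'   night/day odds per unit log10(mass in g).
#' @param nocturnality_intercept_per_guild named vector; defaults centre the
#'   night/day odds at 10 kg.
#' @param twilight_eta constant twilight/day log-odds.
#' @param kappa_activity von Mises concentration of the day/night components.
#' @param coupling_beta predator-prey hourly coupling (log-rate per event).
#' @param photos_per_visit mean photos per visit (shifted Poisson), or the
#'   exact count when `photos_fixed = TRUE`.
#' @param photos_fixed emit exactly `photos_per_visit` photos per visit.
#' @param burst_gap_mean_s mean exponential gap between photos of one visit.
#' @param base_visit_rate expected visits per camera-day summed over species.
#' @param sigma_area named sd of the Gaussian protected-area intercepts for
#'   the `night` and `twilight` logits (used by [simulate_diel_counts()]).
#' @param seed integer root seed.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_sites = 4,
                         site_latitudes = NULL,
                         site_longitudes = NULL,
                         n_cameras_per_site = 60,
                         deployment_days = 30,
                         start_date = as.Date("2015-03-01"),
                         n_species = 20,
                         mass_range_g = c(100, 200000),
                         guild_proportions = c(carnivore = 0.2, herbivore = 0.4,
                                               insectivore = 0.2, omnivore = 0.2),
                         nocturnality_slope_per_guild = c(carnivore = -0.8,
                                                          herbivore = 0.8,
                                                          insectivore = 0.6,
                                                          omnivore = -0.5),
                         nocturnality_intercept_per_guild = NULL,
                         twilight_eta = -2.5,
                         kappa_activity = 1.5,
                         coupling_beta = 0.2,
                         photos_per_visit = 2,
                         photos_fixed = FALSE,
                         burst_gap_mean_s = 120,
                         base_visit_rate = 0.3,
                         sigma_area = c(night = 0.3, twilight = 0.2),
                         seed = 1) {
  guilds <- c("carnivore", "herbivore", "insectivore", "omnivore")
  if (is.null(site_latitudes)) {
    site_latitudes <- seq(-20, 20, length.out = n_sites)
  }
  if (is.null(site_longitudes)) {
    site_longitudes <- seq(-70, -50, length.out = n_sites)
  }
  if (is.null(nocturnality_intercept_per_guild)) {
    nocturnality_intercept_per_guild <- -4 * nocturnality_slope_per_guild
  }
  cfg <- list(n_sites = n_sites, site_latitudes = site_latitudes,
              site_longitudes = site_longitudes,
              n_cameras_per_site = n_cameras_per_site,
              deployment_days = deployment_days, start_date = start_date,
              n_species = n_species, mass_range_g = mass_range_g,
              guild_proportions = guild_proportions[guilds],
              nocturnality_slope_per_guild = nocturnality_slope_per_guild[guilds],
              nocturnality_intercept_per_guild =
                nocturnality_intercept_per_guild[guilds],
              twilight_eta = twilight_eta, kappa_activity = kappa_activity,
              coupling_beta = coupling_beta,
              photos_per_visit = photos_per_visit, photos_fixed = photos_fixed,
              burst_gap_mean_s = burst_gap_mean_s,
              base_visit_rate = base_visit_rate, sigma_area = sigma_area,
              seed = as.integer(seed))
  gp <- cfg$guild_proportions
  if (anyNA(gp)) gp[is.na(gp)] <- 0
  names(gp) <- guilds
  cfg$guild_proportions <- gp
  if (any(gp < 0) || abs(sum(gp) - 1) > 1e-8) {
    stop("guild_proportions must be a simplex over the four guilds")
  }
  if (cfg$mass_range_g[1] < 75) stop("mass_range_g lower bound must be >= 75 g")
  if (cfg$deployment_days < 1) stop("deployment_days must be >= 1")
  if (any(abs(cfg$site_latitudes) > 30)) {
    stop("site latitudes must lie in [-30, 30]")
  }
  if (length(cfg$site_latitudes) != n_sites ||
      length(cfg$site_longitudes) != n_sites) {
    stop("site coordinate vectors must have length n_sites")
  }
  class(cfg) <- "synth_config"
  cfg
}

# deterministic largest-remainder apportionment of n species to guilds
.apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1
  }
  base
}

# diet fractions consistent with a guild under the >= 80% thresholds
.diet_for_guild <- function(guild) {
  main <- stats::runif(1, 0.82, 0.97)
  rest <- 1 - main
  spl <- stats::runif(1)
  v <- p <- iv <- 0
  if (guild == "carnivore") { v <- main; p <- rest * spl; iv <- rest * (1 - spl) }
  if (guild == "herbivore") { p <- main; v <- rest * spl; iv <- rest * (1 - spl) }
  if (guild == "insectivore") { iv <- main; v <- rest * spl; p <- rest * (1 - spl) }
  if (guild == "omnivore") {
    g <- stats::rgamma(3, 1.5)
    f <- 0.75 * g / sum(g)   # each fraction < 0.75 < 0.80 by construction
    v <- f[1]; p <- f[2]; iv <- f[3]
  }
  c(diet_vertebrate = v, diet_plant = p, diet_invertebrate = iv,
    diet_other = max(0, 1 - v - p - iv))
}

#' Generate a synthetic mammal community with known diel ground truth
#'
#' @param config a [synth_config()].
#' @return list of class `synth_community` with elements `traits` (the trait
#'   table consumed by [filter_species()] / [join_traits()]), `truth` (the
#'   per-species category probabilities and the generating coefficients) and
#'   `config`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_species
  counts <- .apportion(n, config$guild_proportions)
  guild <- rep(names(counts), counts)
  mass <- 10^stats::runif(n, log10(config$mass_range_g[1]),
                          log10(config$mass_range_g[2]))
  diets <- t(vapply(guild, .diet_for_guild, numeric(4)))
  species <- sprintf("sp%02d", seq_len(n))
  traits <- data.frame(species = species, body_mass_g = mass, diets,
                       stratum = sample(c("ground", "scansorial"), n,
                                        replace = TRUE, prob = c(0.7, 0.3)),
                       row.names = NULL)
  eta_n <- config$nocturnality_intercept_per_guild[guild] +
    config$nocturnality_slope_per_guild[guild] * log10(mass)
  eta_t <- rep(config$twilight_eta, n)
  den <- 1 + exp(eta_n) + exp(eta_t)
  truth_sp <- data.frame(
    species = species, guild = guild, body_mass_g = mass,
    p_day = 1 / den, p_night = exp(eta_n) / den, p_twilight = exp(eta_t) / den,
    eta_night = eta_n, eta_twilight = eta_t,
    kappa = config$kappa_activity,
    weight = as.numeric(stats::rgamma(n, 2)), row.names = NULL
  )
  truth_sp$weight <- truth_sp$weight / sum(truth_sp$weight)
  truth <- list(
    species = truth_sp,
    intercept_per_guild = config$nocturnality_intercept_per_guild,
    slope_per_guild_log10 = config$nocturnality_slope_per_guild,
    slope_per_guild_ln = config$nocturnality_slope_per_guild / log(10),
    twilight_eta = config$twilight_eta,
    coupling_beta = config$coupling_beta
  )
  structure(list(traits = traits, truth = truth, config = config),
            class = "synth_community")
}

# anchored-band boundaries (dawn angle in [0, pi/2), dusk angle in
# (3pi/2, 2pi)) per unique site/date
.band_angles <- function(date, lat, lon) {
  st <- sun_times(date, lat, lon)
  if (anyNA(st$nautical_dawn_hour) || anyNA(st$sunset_hour)) {
    stop("site latitude/date outside polar feasibility for sun anchoring")
  }
  list(dawn = anchor_to_sun(st$nautical_dawn, lat, lon),
       dusk = anchor_to_sun(st$nautical_dusk, lat, lon))
}

# draw sun-anchored angles conditional on the diel category
.draw_theta <- function(category, dawn, dusk, kappa) {
  n <- length(category)
  theta <- numeric(n)
  for (cat_ in c("day", "night")) {
    ix <- which(category == cat_)
    if (!length(ix)) next
    mu <- if (cat_ == "day") pi else 0
    need <- ix
    while (length(need)) {
      cand <- rvonmises(length(need), mu, kappa)
      ok <- if (cat_ == "day") {
        cand >= pi / 2 & cand < 3 * pi / 2
      } else {
        cand >= dusk[need] | cand < dawn[need]
      }
      theta[need[ok]] <- cand[ok]
      need <- need[!ok]
    }
  }
  ix <- which(category == "twilight")
  if (length(ix)) {
    # uniform over the two narrow twilight arcs, weighted by arc length
    a1 <- pi / 2 - dawn[ix]          # morning arc [dawn, pi/2)
    a2 <- dusk[ix] - 3 * pi / 2      # evening arc [3pi/2, dusk)
    morning <- stats::runif(length(ix)) < a1 / (a1 + a2)
    u <- stats::runif(length(ix))
    theta[ix] <- ifelse(morning, dawn[ix] + u * a1, 3 * pi / 2 + u * a2)
  }
  theta
}

#' Simulate a camera-trap detection stream from a synthetic community
#'
#' Per camera-day and species, visit counts are Poisson with rate
#' `base_visit_rate * species weight`; each visit draws a diel category from
#' the species' ground-truth probabilities and a sun-anchored time from the
#' matching activity component, converted to clock time by inverting the
#' solar anchoring for the site and date. Visits emit one or more photos in
#' a short exponential burst so the downstream independence filter has work
#' to do.
#'
#' @param community a [generate_community()] result.
#' @param config defaults to `community$config`.
#' @param seed defaults to `config$seed + 1`.
#' @return list with `detections` (protected_area, camera, latitude,
#'   longitude, species, timestamp), `deployments` (camera, start_date,
#'   end_date) and `visits` (one row per visit before burst expansion).
#' @export
simulate_detections <- function(community, config = community$config,
                                seed = config$seed + 1) {
  stopifnot(inherits(community, "synth_community"))
  set.seed(seed)
  sp <- community$truth$species
  out <- list(); dep <- list(); vis <- list()
  for (s in seq_len(config$n_sites)) {
    pa <- sprintf("PA%02d", s)
    lat <- config$site_latitudes[s]; lon <- config$site_longitudes[s]
    cams <- sprintf("%s_C%03d", pa, seq_len(config$n_cameras_per_site))
    dates <- config$start_date + 0:(config$deployment_days - 1)
    bands <- .band_angles(dates, lat, lon)
    dep[[s]] <- data.frame(camera = cams, start_date = config$start_date,
                           end_date = config$start_date + config$deployment_days)
    # visits per camera x species over the whole deployment
    lam <- config$deployment_days * config$base_visit_rate * sp$weight
    nv <- stats::rpois(length(cams) * nrow(sp),
                       rep(lam, times = length(cams)))
    if (sum(nv) == 0) next
    v <- data.frame(
      camera = rep(rep(cams, each = nrow(sp)), nv),
      species = rep(rep(sp$species, times = length(cams)), nv)
    )
    si <- match(v$species, sp$species)
    di <- sample.int(length(dates), nrow(v), replace = TRUE)
    pmat <- as.matrix(sp[si, c("p_day", "p_night", "p_twilight")])
    u <- stats::runif(nrow(v))
    category <- ifelse(u < pmat[, 1], "day",
                       ifelse(u < pmat[, 1] + pmat[, 2], "night", "twilight"))
    theta <- .draw_theta(category, bands$dawn[di], bands$dusk[di],
                         config$kappa_activity)
    ts <- sun_anchor_invert(theta, dates[di], lat, lon)
    n_photos <- if (config$photos_fixed) {
      rep(as.integer(config$photos_per_visit), nrow(v))
    } else {
      1L + stats::rpois(nrow(v), max(config$photos_per_visit - 1, 0))
    }
    gaps <- lapply(n_photos, function(k) {
      if (k == 1) 0 else cumsum(c(0, stats::rexp(k - 1, 1 / config$burst_gap_mean_s)))
    })
    det <- data.frame(
      protected_area = pa,
      camera = rep(v$camera, n_photos),
      latitude = lat, longitude = lon,
      species = rep(v$species, n_photos),
      timestamp = rep(ts, n_photos) + unlist(gaps)
    )
    vis[[s]] <- data.frame(protected_area = pa, camera = v$camera,
                           species = v$species, category = category,
                           sun_time_rad = theta, timestamp = ts)
    out[[s]] <- det
  }
  detections <- if (length(out)) do.call(rbind, out) else
    data.frame(protected_area = character(), camera = character(),
               latitude = numeric(), longitude = numeric(),
               species = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"))
  detections <- detections[order(detections$protected_area, detections$camera,
                                 detections$species, detections$timestamp), ,
                           drop = FALSE]
  rownames(detections) <- NULL
  list(detections = detections,
       deployments = if (length(dep)) do.call(rbind, dep) else NULL,
       visits = if (length(vis)) do.call(rbind, vis) else NULL)
}

#' Simulate paired predator/prey hourly counts per site
#'
#' Predator counts per anchored-hour bin follow a smooth night-peaked
#' baseline; prey counts are Poisson with
#' `log E[response] = alpha_site + coupling_beta * predator_count`, with
#' Gaussian site intercepts (random-intercept structure). The sign of
#' `config$coupling_beta` must match the scenario: positive for `bottom_up`,
#' negative for `top_down`, zero for `independent`.
#'
#' @param config a [synth_config()].
#' @param scenario one of `"bottom_up"`, `"top_down"`, `"independent"`.
#' @param n_sites number of protected areas, default 11.
#' @param seed integer seed, defaults to `config$seed`.
#' @return data.frame with `protected_area`, `anchored_hour`,
#'   `predictor_count`, `response_count`.
#' @export
simulate_interaction <- function(config,
                                 scenario = c("bottom_up", "top_down",
                                              "independent"),
                                 n_sites = 11, seed = config$seed) {
  scenario <- match.arg(scenario)
  beta <- config$coupling_beta
  ok <- switch(scenario, bottom_up = beta > 0, top_down = beta < 0,
               independent = beta == 0)
  if (!ok) {
    stop("coupling_beta (", beta, ") does not match scenario '", scenario, "'")
  }
  set.seed(seed)
  th <- 2 * pi * (0:23 + 0.5) / 24
  lam_pred <- exp(0.7 + 0.8 * cos(th))   # night-peaked baseline (0 = midnight)
  alpha <- stats::rnorm(n_sites, 0.3, 0.4)
  res <- lapply(seq_len(n_sites), function(s) {
    pred <- stats::rpois(24, lam_pred)
    resp <- stats::rpois(24, exp(alpha[s] + beta * pred))
    data.frame(protected_area = sprintf("PA%02d", s), anchored_hour = 0:23,
               predictor_count = pred, response_count = resp)
  })
  do.call(rbind, res)
}

#' Simulate event-level diel categories from the community ground truth
#'
#' Draws `n_events` events: species sampled by detection weight, protected
#' area uniformly, and the diel category from the ground-truth multinomial
#' logit with Gaussian area intercepts added to the night and twilight
#' linear predictors. This is the generator behind the model-recovery
#' studies; the full detection-stream simulator additionally exercises the
#' solar and event-filtering stages.
#'
#' @param community a [generate_community()] result.
#' @param n_events number of events.
#' @param n_sites number of protected areas.
#' @param sigma_area named sd for the `night` and `twilight` area intercepts
#'   (defaults from the community's config).
#' @param seed integer seed.
#' @return event-level data.frame with `protected_area`, `species`, `guild`,
#'   `body_mass_g`, `log_mass`, `diel_category`.
#' @export
simulate_diel_counts <- function(community, n_events = 10000, n_sites = 8,
                                 sigma_area = community$config$sigma_area,
                                 seed = community$config$seed) {
  sp <- community$truth$species
  set.seed(seed)
  b_n <- stats::rnorm(n_sites, 0, sigma_area[["night"]])
  b_t <- stats::rnorm(n_sites, 0, sigma_area[["twilight"]])
  si <- sample.int(nrow(sp), n_events, replace = TRUE, prob = sp$weight)
  ai <- sample.int(n_sites, n_events, replace = TRUE)
  en <- sp$eta_night[si] + b_n[ai]
  et <- sp$eta_twilight[si] + b_t[ai]
  den <- 1 + exp(en) + exp(et)
  u <- stats::runif(n_events)
  cat_ <- ifelse(u < 1 / den, "day",
                 ifelse(u < (1 + exp(en)) / den, "night", "twilight"))
  data.frame(protected_area = sprintf("PA%02d", ai),
             species = sp$species[si], guild = sp$guild[si],
             body_mass_g = sp$body_mass_g[si],
             log_mass = log(sp$body_mass_g[si]),
             diel_category = factor(cat_, levels = c("day", "twilight", "night")))
}
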