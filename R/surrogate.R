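#' Default cultivar, ecotype and soil coefficients for the surrogate
#'
#' Mid-range values for all 35 parameters, overridden by the packaged
#' pre-calibration cultivar reference coefficients where those exist (EM-FL, OPTBI,
#' SLOBI, SLAVR, TRIFL).
#'
#' @return Named numeric vector of length 35.
#' @export
canola_defaults <- function() {
  pars <- canola_parameters()
  v <- (pars$lower + pars$upper) / 2
  names(v) <- pars$name
  cc <- canola_cultivar_coefficients()
  v[cc$parameter] <- cc$default
  v
}

# Collapse the layered profile to a few hydrological layers (thickness-
# weighted root growth factor); water contents come from the sampled soil
# parameters, the profile contributes geometry and root access.
aggregate_soil_layers <- function(profile, breaks = c(30, 60, 200)) {
  depth <- profile$depth_cm
  lower <- c(0, depth[-length(depth)])
  dz <- depth - lower
  grp <- findInterval(depth - 1e-9, c(0, breaks), left.open = FALSE)
  out <- data.frame(
    thickness_mm = tapply(dz, grp, sum) * 10,
    srgf = tapply(profile$srgf * dz, grp, sum) / tapply(dz, grp, sum))
  rownames(out) <- NULL
  out
}

#' Simulate one rapeseed season with the surrogate crop model
#'
#' A deterministic, self-contained daily rapeseed growth model exposing the
#' full 35-coefficient interface (12 ecotype, 11 genotype, 12 soil) of the
#' CROPGRO-Canola parameter set, with a designed causal structure:
#' phenology by photothermal-day accumulation (daylength modifier below the
#' critical daylength CSDL, cold penalty of slope SLOBI below OPTBI), leaf
#' area from main-stem leaf appearance (TRIFL) with specific leaf area
#' SLAVR and leaf size SIZLF, biomass from intercepted radiation scaled by
#' a water-stress factor out of a layered tipping-bucket water balance
#' (SLLL/SDUL/SSAT capacities, SLDR/SSKS drainage, SLRO curve-number
#' runoff, SLU1 two-stage evaporation, SRGF root access), and yield from
#' post-flowering harvest-index build-up shaped by PODUR, SFDUR and SDPDV.
#' It is explicitly not CROPGRO: it is the minimal live model the
#' sensitivity/concordance pipeline needs.
#'
#' @param params Named numeric vector; missing entries take
#'   [canola_defaults()].
#' @param weather Daily weather data frame covering the sowing-to-harvest
#'   window, with columns date, tmax, tmin, rain, srad (as produced by
#'   [synth_weather()]).
#' @param soil Layered soil profile data frame (default
#'   [canola_soil_profile()]).
#' @param management List: \code{sowing_date} (default first weather day),
#'   \code{population} plants m-2 (default 45), \code{latitude} (default
#'   the weather series attribute).
#' @return Named numeric vector with elements \code{ADAP}, \code{MDAP}
#'   (days after planting), \code{HWAM}, \code{CWAM} (kg/ha) and
#'   \code{LAIX}; attribute \code{censored} is \code{TRUE} when maturity
#'   was not reached inside the weather window and stage dates were closed
#'   at its end.
#' @export
simulate_season <- function(params = canola_defaults(), weather,
                            soil = canola_soil_profile(),
                            management = list()) {
  p <- canola_defaults()
  if (!is.null(names(params))) p[names(params)] <- params
  sowing <- as.Date(management$sowing_date %||% weather$date[1])
  population <- management$population %||% 45
  latitude <- management$latitude %||% attr(weather, "latitude") %||% 30.47
  if (!(soil$slll[1] < soil$sdul[1] && soil$sdul[1] < soil$ssat[1]) ||
      is.unsorted(soil$depth_cm, strictly = TRUE))
    stop_cropsens("invalid soil profile", class = "cropsens_soil_error")

  w <- weather[as.Date(weather$date) >= sowing, , drop = FALSE]
  nw <- nrow(w)
  if (nw < 90)
    stop_cropsens("weather window too short: ", nw,
                  " days after sowing (need >= 90)",
                  class = "cropsens_weather_error")
  doy <- as.integer(format(as.Date(w$date), "%j"))
  N <- extraterrestrial_radiation(latitude, doy)$N
  tmean <- (w$tmax + w$tmin) / 2

  # development rate: thermal day (1 at >= 17 C above base 5), daylength
  # factor below CSDL, cold penalty below OPTBI
  td <- clamp((tmean - 5) / 12, 0, 1)
  ppf_pre <- clamp(1 - 0.02 * pmax(0, p[["CSDL"]] - N), 0.6, 1)
  ppf_post <- clamp(1 - 0.02 * (1 + p[["R1PPO"]]) * pmax(0, p[["CSDL"]] - N),
                    0.6, 1)
  ct <- clamp(1 - p[["SLOBI"]] * pmax(0, p[["OPTBI"]] - w$tmin), 0.5, 1)
  ptd_fl <- td * ppf_pre * ct
  ptd_mat <- td * ppf_post * clamp(1 - 0.5 * p[["SLOBI"]] *
                                     pmax(0, p[["OPTBI"]] - w$tmin), 0.6, 1)

  censored <- FALSE
  first_at <- function(x, target, fallback) {
    i <- which(x >= target)
    if (length(i)) i[1] else { censored <<- TRUE; fallback }
  }
  cum_td <- cumsum(td)
  day_em <- first_at(cum_td, p[["PL-EM"]], 10L)
  day_juv <- first_at(cum_td, p[["PL-EM"]] + p[["EM-V1"]] + p[["JU-R0"]],
                      day_em + 5L)
  cum_fl <- cumsum(c(rep(0, day_juv), ptd_fl[-seq_len(day_juv)]))
  adap <- first_at(cum_fl, p[["EM-FL"]], nw - 20L)
  adap <- min(max(adap, day_juv + 1L), nw - 15L)
  mat_req <- 0.5 * p[["FL-SD"]] + 0.5 * p[["SD-PM"]] + 0.2 * p[["LNGSH"]] +
    0.2 * p[["R7-R8"]] + 4 * p[["PM09"]]
  cum_mat <- cumsum(c(rep(0, adap), ptd_mat[-seq_len(adap)]))
  mdap <- first_at(cum_mat, mat_req, nw)
  mdap <- min(max(mdap, adap + 1L), nw)
  leaf_end <- first_at(cum_mat, 0.4 * p[["FL-LF"]], adap + 10L)
  leaf_end <- min(max(leaf_end, adap + 1L), mdap)
  pod_start <- first_at(cum_mat, 0.6 * p[["FL-SH"]], adap + 10L)
  pod_start <- min(max(pod_start, adap + 1L), mdap)

  # layered tipping-bucket water balance
  layers <- aggregate_soil_layers(soil)
  dz <- layers$thickness_mm
  srgf <- layers$srgf * p[["SRGF"]]
  ll <- p[["SLLL"]] * dz
  dul <- p[["SDUL"]] * dz
  sat <- p[["SSAT"]] * dz
  W <- ll + 0.8 * (dul - ll)
  S_cn <- 254 * (100 / p[["SLRO"]] - 1)      # SCS retention, mm
  ks_cap <- p[["SSKS"]] * 240                # cm/h -> mm/day
  alb_f <- 1 - (p[["SALB"]] - 0.13)
  fert <- (0.92 + 0.08 * p[["SLNF"]]) *
    (1 + 0.02 * (p[["SLOC"]] - 2.674)) *
    (1 - 0.06 * (p[["SBDM"]] - 1.2))
  # faster leaf turnover keeps the canopy young and efficient
  rue <- 1.9 * (p[["TRIFL"]] / 0.32)^0.7
  pet <- pmax(0, 0.0135 * (tmean + 17.8) * w$srad / 2.45) * alb_f
  ft <- clamp(tmean / 12, 0, 1) * clamp((34 - tmean) / 6, 0, 1)
  kext <- 0.24 * (0.8 + 0.2 * p[["RWDTH"]])
  # canopy grows logistically toward a leaf-rate-driven potential LAI
  canopy_mod <- (p[["SIZLF"]] / 100) * (p[["SLAVR"]] / 237.5) *
    sqrt(p[["RWDTH"]] * p[["RHGHT"]]) * (population / 45)^0.7
  lai_pot <- 6.5 * (p[["TRIFL"]] / 0.32) * canopy_mod
  lai_gain <- 0.26 * (p[["TRIFL"]] / 0.32) * canopy_mod
  hi_max <- 0.34 * (p[["SDPDV"]] / 20)^0.15
  hi_rate <- hi_max / (p[["PODUR"]] + p[["SFDUR"]])

  lai <- 0; laix <- 0; bio <- 0; hi <- 0; cum_ev <- 0
  nlay <- length(dz)
  for (day in seq_len(mdap)) {
    rain <- w$rain[day]
    runoff <- if (rain > 0.2 * S_cn)
      (rain - 0.2 * S_cn)^2 / (rain + 0.8 * S_cn) else 0
    inflow <- rain - runoff
    for (li in seq_len(nlay)) {
      W[li] <- W[li] + inflow
      over <- max(0, W[li] - sat[li])     # saturation overflow passes down
      W[li] <- W[li] - over
      drain <- min(p[["SLDR"]] * max(0, W[li] - dul[li]), ks_cap)
      W[li] <- W[li] - drain
      inflow <- over + drain
    }
    # two-stage soil evaporation from the top layer
    ep <- pet[day] * exp(-0.5 * lai)
    if (rain > 2) cum_ev <- 0
    ev <- if (cum_ev < p[["SLU1"]]) ep else 0.4 * ep
    ev <- min(ev, max(0, W[1] - ll[1]))
    W[1] <- W[1] - ev
    cum_ev <- cum_ev + ev
    if (day >= day_em) {
      avail <- pmax(0, W - ll) * srgf
      tpot <- pet[day] * (1 - exp(-0.5 * lai))
      supply <- 0.12 * sum(avail)
      ws <- if (tpot > 1e-9) min(1, supply / tpot) else 1
      transp <- min(ws * tpot, sum(avail))
      if (transp > 0 && sum(avail) > 0)
        W <- W - transp * avail / sum(avail)
      if (day <= leaf_end) {
        lai <- lai + lai_gain * td[day] * (0.5 + 0.5 * ws) *
          max(0, 1 - lai / lai_pot)
      } else {
        lai <- lai * (1 - 0.03 - 0.03 * (1 - ws))
      }
      laix <- max(laix, lai)
      fpar <- 1 - exp(-kext * lai)
      # radiation-use efficiency declines through the reproductive phase
      rue_stage <- if (day <= adap) 1
        else 1 - 0.75 * (day - adap) / max(1, mdap - adap)
      bio <- bio + rue * 0.48 * w$srad[day] * fpar * ft[day] * ws * fert *
        rue_stage
      if (day >= pod_start)
        hi <- min(hi_max, hi + hi_rate * ptd_mat[day] * (0.6 + 0.4 * ws))
    }
  }
  cwam <- bio * 10                 # g/m2 -> kg/ha
  hwam <- hi * cwam
  out <- c(ADAP = as.numeric(adap), MDAP = as.numeric(mdap),
           HWAM = hwam, CWAM = cwam, LAIX = laix)
  attr(out, "censored") <- censored
  out
}

#' Model adapters over the surrogate
#'
#' \code{canola_model()} binds weather, soil and management into the
#' model-adapter contract used by [efast()]: a function from one named
#' parameter vector to the five season outputs.  \code{make_season_model()}
#' binds a list of seasons (weather + management) into the calibration
#' adapter used by [calibration_objective()]: a function from a parameter
#' vector to a per-season data frame of adap/mdap/hwam/cwam.
#'
#' @param weather Daily weather data frame.
#' @param soil Soil profile.
#' @param management Management list (see [simulate_season()]).
#' @return A function of the parameter vector.
#' @export
canola_model <- function(weather, soil = canola_soil_profile(),
                         management = list()) {
  force(weather); force(soil); force(management)
  function(params) simulate_season(params, weather, soil, management)
}

#' @rdname canola_model
#' @param weathers List of daily weather data frames, one per season.
#' @param managements List of management lists, one per season (recycled
#'   if length one).
#' @export
make_season_model <- function(weathers, soil = canola_soil_profile(),
                              managements = list(list())) {
  force(weathers); force(soil); force(managements)
  if (length(managements) == 1)
    managements <- rep(managements, length(weathers))
  function(params) {
    rows <- lapply(seq_along(weathers), function(i) {
      o <- simulate_season(params, weathers[[i]], soil, managements[[i]])
      data.frame(adap = o[["ADAP"]], mdap = o[["MDAP"]],
                 hwam = o[["HWAM"]], cwam = o[["CWAM"]])
    })
    do.call(rbind, rows)
  }
}

#' Generate noisy synthetic season observations from the surrogate
#'
#' Runs the surrogate under known "true" parameters for each season and
#' adds seeded Gaussian observation noise: an absolute standard deviation
#' in days for phenology, a relative (coefficient-of-variation) one for
#' yield and biomass.  With zero noise the records equal the surrogate
#' outputs exactly.  Used for parameter-recovery experiments.
#'
#' @param true_params Named parameter vector.
#' @param weathers List of weather data frames (one season each).
#' @param soil,managements As in [make_season_model()].
#' @param phen_sd Phenology noise sd, days.
#' @param rel_sd Relative noise sd for yield/biomass.
#' @param seed Integer seed.
#' @return Data frame with columns adap, mdap, yield, biomass (observed,
#'   noisy) and adap_true, mdap_true, yield_true, biomass_true.
#' @export
generate_observations <- function(true_params, weathers,
                                  soil = canola_soil_profile(),
                                  managements = list(list()),
                                  phen_sd = 0, rel_sd = 0, seed = 1) {
  if (phen_sd < 0 || rel_sd < 0)
    stop_cropsens("noise must be nonnegative", class = "cropsens_obs_error")
  truth <- make_season_model(weathers, soil, managements)(true_params)
  ns <- nrow(truth)
  with_seed(seed, data.frame(
    adap = truth$adap + stats::rnorm(ns, 0, phen_sd),
    mdap = truth$mdap + stats::rnorm(ns, 0, phen_sd),
    yield = truth$hwam * (1 + stats::rnorm(ns, 0, rel_sd)),
    biomass = truth$cwam * (1 + stats::rnorm(ns, 0, rel_sd)),
    adap_true = truth$adap, mdap_true = truth$mdap,
    yield_true = truth$hwam, biomass_true = truth$cwam))
}
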