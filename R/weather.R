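#' Extraterrestrial radiation and theoretical daylength
#'
#' Standard FAO-56 solar geometry: inverse relative Earth-Sun distance,
#' solar declination and sunset hour angle give daily extraterrestrial
#' radiation Ra (MJ m-2 d-1) and theoretical sunshine duration N (h).
#'
#' @param latitude Degrees, positive north; |latitude| < 66.5 (no polar
#'   day/night handling).
#' @param doy Day of year (1..366), vectorized.
#' @return List with numeric vectors \code{Ra} (MJ m-2 d-1) and \code{N}
#'   (h).
#' @references Allen, R.G. et al. (1998) Crop evapotranspiration, FAO
#'   Irrigation and Drainage Paper 56, chapter 3.
#' @export
#' @examples
#' extraterrestrial_radiation(30.47, 355)$N   # short winter day at Wuhan
extraterrestrial_radiation <- function(latitude, doy) {
  if (abs(latitude) >= 66.5)
    stop_cropsens("latitude must satisfy |latitude| < 66.5 degrees",
                  class = "cropsens_weather_error")
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(clamp(-tan(phi) * tan(delta), -1, 1))
  Gsc <- 0.0820  # MJ m-2 min-1
  Ra <- 24 * 60 / pi * Gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  list(Ra = pmax(0, Ra), N = 24 / pi * ws)
}

#' Angstrom-Prescott solar radiation from sunshine hours
#'
#' Estimates daily total solar radiation from relative sunshine duration:
#' \eqn{R_s = (a + b\,n/N)\,R_a} with default coefficients a = 0.2,
#' b = 0.5, so an overcast day receives \eqn{0.2 R_a} and a fully sunny day
#' \eqn{0.7 R_a}.
#'
#' @param n Measured sunshine hours (0 <= n <= N).
#' @param N Theoretical sunshine hours.
#' @param Ra Extraterrestrial radiation, MJ m-2 d-1.
#' @param a,b Angstrom coefficients; must satisfy a >= 0, b >= 0,
#'   a + b <= 1.
#' @return Rs, MJ m-2 d-1.
#' @export
#' @examples
#' angstrom_srad(6, 12, 30)  # half sunshine: (0.2 + 0.25) * 30 = 13.5
angstrom_srad <- function(n, N, Ra, a = 0.2, b = 0.5) {
  if (a < 0 || b < 0 || a + b > 1)
    stop_cropsens("Angstrom coefficients need a >= 0, b >= 0, a + b <= 1",
                  class = "cropsens_weather_error")
  if (any(n < -1e-9) || any(n > N + 1e-9))
    stop_cropsens("sunshine hours outside [0, N]: impossible observation",
                  class = "cropsens_weather_error")
  if (any(Ra < 0))
    stop_cropsens("Ra must be nonnegative", class = "cropsens_weather_error")
  (a + b * clamp(n, 0, N) / N) * Ra
}

#' Synthesize a daily weather season from summary targets
#'
#' Generates a daily weather series whose seasonal summaries match supplied
#' targets: season mean temperature (exactly), season rainfall total
#' (exactly, by scaling seeded stochastic rain events) and season total
#' solar radiation (within a fraction of a percent, by solving for the mean
#' relative sunshine fraction under the Angstrom equation and rescaling
#' after daily jitter).  Temperature follows a sinusoidal seasonal cycle
#' (coldest in mid-January, northern hemisphere) plus Gaussian noise.
#'
#' @param latitude Site latitude in degrees.
#' @param start First day of the series (Date or string).
#' @param days Number of days.
#' @param tmean_c Target season mean of daily mean temperature, degC.
#' @param rain_mm Target season rainfall total, mm (0 gives an all-dry
#'   series).
#' @param srad_mj Target season total solar radiation, MJ m-2.
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @param amplitude Seasonal temperature half-amplitude, degC.
#' @param diurnal_range Mean tmax - tmin, degC.
#' @param wet_prob Probability a day is wet before scaling.
#' @return Data frame with columns date, doy, tmax, tmin, rain, sun_hours,
#'   srad; attributes \code{latitude} and \code{targets}.
#' @export
synth_weather <- function(latitude, start, days, tmean_c, rain_mm, srad_mj,
                          seed = 1, amplitude = 10, diurnal_range = 8,
                          wet_prob = 0.25) {
  if (days < 2) stop_cropsens("need at least 2 days",
                              class = "cropsens_weather_error")
  if (rain_mm < 0 || srad_mj <= 0)
    stop_cropsens("totals must be nonnegative (radiation positive)",
                  class = "cropsens_weather_error")
  start <- as.Date(start)
  dates <- start + seq_len(days) - 1
  doy <- as.integer(format(dates, "%j"))
  sol <- extraterrestrial_radiation(latitude, doy)
  with_seed(seed, {
    seasonal <- -amplitude * cos(2 * pi * (doy - 15) / 365)
    tmean_d <- seasonal + stats::rnorm(days, 0, 1.5)
    tmean_d <- tmean_d + (tmean_c - mean(tmean_d))  # hit the mean exactly
    half <- pmax(0.5, diurnal_range / 2 + stats::rnorm(days, 0, 0.8))
    tmax <- tmean_d + half
    tmin <- tmean_d - half
    wet <- stats::runif(days) < wet_prob
    rain <- numeric(days)
    if (rain_mm > 0 && any(wet)) {
      rain[wet] <- stats::rgamma(sum(wet), shape = 0.7, scale = 8)
      rain <- rain * rain_mm / sum(rain)
    }
    # mean sunshine fraction solving the Angstrom totals, then daily jitter
    # (less sun on wet days) rescaled back onto the target
    f0 <- (srad_mj / sum(sol$Ra) - 0.2) / 0.5
    f <- clamp(f0 + stats::rnorm(days, 0, 0.12) - 0.15 * wet, 0, 1)
    for (it in 1:3) {
      scl <- (srad_mj - 0.2 * sum(sol$Ra)) / (0.5 * sum(f * sol$Ra))
      f <- clamp(f * scl, 0, 1)
    }
    out <- data.frame(date = dates, doy = doy,
                      tmax = round(tmax, 2), tmin = round(tmin, 2),
                      rain = round(rain, 2),
                      sun_hours = pmin(round(f * sol$N, 2), sol$N))
    out$srad <- round(angstrom_srad(out$sun_hours, sol$N, sol$Ra), 2)
    # rounding nudges the summaries; restore the exact temperature mean
    shift <- tmean_c - mean((out$tmax + out$tmin) / 2)
    out$tmax <- out$tmax + shift
    out$tmin <- out$tmin + shift
    attr(out, "latitude") <- latitude
    attr(out, "targets") <- c(tmean_c = tmean_c, rain_mm = rain_mm,
                              srad_mj = srad_mj)
    out
  })
}

#' Validate a daily weather series
#'
#' Checks structural validity of a weather data frame and reports every
#' offending row by line number: tmax < tmin, negative rain, sunshine hours
#' exceeding the theoretical daylength (when latitude is known).
#'
#' @param weather Data frame with columns date, tmax, tmin, rain and
#'   optionally sun_hours and/or srad.
#' @param latitude Optional; enables the daylength check.
#' @return The validated data frame, invisibly.
#' @export
validate_weather <- function(weather, latitude = NULL) {
  need <- c("date", "tmax", "tmin", "rain")
  miss <- setdiff(need, names(weather))
  if (length(miss))
    stop_cropsens("weather lacks columns: ", paste(miss, collapse = ", "),
                  class = "cropsens_weather_error")
  probs <- character(0)
  bad <- which(weather$tmax < weather$tmin)
  if (length(bad))
    probs <- c(probs, paste0("tmax < tmin at rows: ",
                             paste(bad, collapse = ", ")))
  bad <- which(weather$rain < 0)
  if (length(bad))
    probs <- c(probs, paste0("negative rain at rows: ",
                             paste(bad, collapse = ", ")))
  latitude <- latitude %||% attr(weather, "latitude")
  if (!is.null(latitude) && "sun_hours" %in% names(weather)) {
    doy <- as.integer(format(as.Date(weather$date), "%j"))
    N <- extraterrestrial_radiation(latitude, doy)$N
    bad <- which(weather$sun_hours > N + 1e-6)
    if (length(bad))
      probs <- c(probs, paste0("sunshine exceeds daylength at rows: ",
                               paste(bad, collapse = ", ")))
  }
  if (length(probs))
    stop_cropsens("invalid weather series:\n  ",
                  paste(probs, collapse = "\n  "),
                  class = "cropsens_weather_error")
  invisible(weather)
}

#' Read and write daily weather files
#'
#' CSV is the primary, lossless interchange format (columns date, tmax,
#' tmin, rain, optional sun_hours and srad).  A DSSAT-style weather writer
#' and reader are provided for interoperability with the crop-model family
#' these analyses target: a station header (site code, latitude, longitude,
#' elevation) followed by fixed-width daily records DATE (YYDDD), SRAD,
#' TMAX, TMIN, RAIN.  When \code{srad} is absent but sunshine hours are
#' present, the writer fills it with [angstrom_srad()].
#'
#' @param path File path.
#' @param weather Daily weather data frame (see [validate_weather()]).
#' @param latitude,longitude,elevation Station metadata for the DSSAT
#'   header; latitude defaults to the series attribute.
#' @param insi Four-character station code.
#' @return Readers return the weather data frame (with \code{latitude}
#'   attribute for the DSSAT dialect); writers return \code{path}
#'   invisibly.
#' @name weather_io
NULL

#' @rdname weather_io
#' @export
read_weather_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  bad <- which(is.na(x$date) | !is.finite(x$tmax) | !is.finite(x$tmin) |
                 !is.finite(x$rain))
  if (length(bad))
    stop_cropsens("malformed weather rows (file line numbers): ",
                  paste(bad + 1L, collapse = ", "),
                  class = "cropsens_weather_error")
  validate_weather(x)
  x
}

#' @rdname weather_io
#' @export
write_weather_csv <- function(weather, path) {
  validate_weather(weather)
  utils::write.csv(weather, path, row.names = FALSE)
  invisible(path)
}

#' @rdname weather_io
#' @export
write_dssat_weather <- function(weather, path, latitude = NULL,
                                longitude = 0, elevation = 0,
                                insi = "CSNS") {
  latitude <- latitude %||% attr(weather, "latitude")
  if (is.null(latitude))
    stop_cropsens("latitude required for the DSSAT dialect",
                  class = "cropsens_weather_error")
  validate_weather(weather, latitude)
  w <- weather
  doy <- as.integer(format(as.Date(w$date), "%j"))
  if (!"srad" %in% names(w) || all(is.na(w$srad))) {
    if (!"sun_hours" %in% names(w))
      stop_cropsens("need srad or sun_hours to write DSSAT weather",
                    class = "cropsens_weather_error")
    sol <- extraterrestrial_radiation(latitude, doy)
    w$srad <- angstrom_srad(w$sun_hours, sol$N, sol$Ra)
  }
  yyddd <- paste0(format(as.Date(w$date), "%y"), sprintf("%03d", doy))
  lines <- c(
    sprintf("*WEATHER DATA : %s", insi),
    "",
    "@ INSI      LAT     LONG  ELEV   TAV   AMP REFHT WNDHT",
    sprintf("  %-4s %8.3f %8.3f %5.0f %5.1f %5.1f  2.00  2.00",
            insi, latitude, longitude, elevation,
            mean((w$tmax + w$tmin) / 2), (max(w$tmax) - min(w$tmin)) / 2),
    "@DATE  SRAD  TMAX  TMIN  RAIN",
    sprintf("%s %5.1f %5.1f %5.1f %5.1f",
            yyddd, w$srad, w$tmax, w$tmin, w$rain))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname weather_io
#' @export
read_dssat_weather <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^@ INSI", lines)
  if (length(hdr) != 1)
    stop_cropsens("no station header (@ INSI) in ", path,
                  class = "cropsens_weather_error")
  st <- strsplit(trimws(lines[hdr + 1]), "\\s+")[[1]]
  latitude <- as.numeric(st[2])
  datahdr <- grep("^@DATE", lines)
  rows <- lines[(datahdr + 1):length(lines)]
  rows <- rows[nzchar(trimws(rows))]
  parts <- strsplit(trimws(rows), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 5)
  if (length(bad))
    stop_cropsens("malformed DSSAT weather rows (file line numbers): ",
                  paste(datahdr + bad, collapse = ", "),
                  class = "cropsens_weather_error")
  m <- do.call(rbind, parts)
  yy <- as.integer(substr(m[, 1], 1, 2))
  ddd <- as.integer(substr(m[, 1], 3, 5))
  year <- ifelse(yy >= 50, 1900 + yy, 2000 + yy)
  out <- data.frame(
    date = as.Date(ddd - 1, origin = paste0(year, "-01-01")),
    srad = as.numeric(m[, 2]), tmax = as.numeric(m[, 3]),
    tmin = as.numeric(m[, 4]), rain = as.numeric(m[, 5]))
  attr(out, "latitude") <- latitude
  validate_weather(out)
  out
}
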