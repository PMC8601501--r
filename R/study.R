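#' Configure a multi-site, multi-year sensitivity study
#'
#' Assembles the study design: one EFAST sensitivity analysis per site-year
#' replicate (weather synthesized from each site's seasonal summaries),
#' followed by factor ranking and top-down concordance across the temporal
#' axis (one site, several years), the spatial axis (one year, several
#' sites) and the pooled set of all replicates.
#'
#' @param replicates Data frame with one row per site-year: columns
#'   \code{site}, \code{year}, \code{latitude}, \code{tmean_c},
#'   \code{rain_mm}, \code{srad_mj}, \code{sowing_date}.  Defaults to the
#'   packaged study fixture via [default_replicates()].
#' @param parameters A [param_table()]; default all 35 crop-model factors.
#' @param M,Ns,Nr EFAST settings (see [efast_design()]).
#' @param index Ranking index, \code{"total"} or \code{"first"}.
#' @param season_days Length of each synthesized season.
#' @param seed Master seed; per-replicate weather seeds are derived from it.
#' @param interannual Jitter the seasonal weather targets across replicates
#'   of a site (interannual variability).  With \code{FALSE} and
#'   \code{identical_weather = TRUE} every replicate sees the same series.
#' @param identical_weather Use one weather realization for all replicates
#'   (diagnostic mode; makes all replicate rankings identical).
#' @return Object of class \code{study_config}.
#' @export
study_config <- function(replicates = default_replicates(),
                         parameters = canola_parameters(),
                         M = 4, Ns = 129, Nr = 1, index = "total",
                         season_days = 240, seed = 1,
                         interannual = TRUE, identical_weather = FALSE) {
  need <- c("site", "year", "latitude", "tmean_c", "rain_mm", "srad_mj",
            "sowing_date")
  miss <- setdiff(need, names(replicates))
  if (length(miss))
    stop_cropsens("replicates lacks columns: ", paste(miss, collapse = ", "),
                  class = "cropsens_config_error")
  if (nrow(replicates) < 1)
    stop_cropsens("need at least one site-year replicate",
                  class = "cropsens_config_error")
  structure(list(replicates = replicates,
                 parameters = as_param_table(parameters),
                 M = M, Ns = Ns, Nr = Nr, index = match.arg(index, c("total", "first")),
                 season_days = season_days, seed = as.integer(seed),
                 interannual = interannual,
                 identical_weather = identical_weather),
            class = "study_config")
}

#' @rdname study_config
#' @details \code{default_replicates()} expands the packaged site table
#'   into the study's replicate set: every single-year site contributes its
#'   study year, and the long-term site contributes one replicate per
#'   season of its experimental period (sowing each year on its recorded
#'   planting day-of-year), its final season coinciding with the spatial
#'   study year.  The default set is 7 temporal + 8 spatial replicates
#'   sharing one season, 14 in all.
#' @export
default_replicates <- function() {
  sites <- canola_sites()
  mgmt <- canola_management()
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    per <- as.character(sites$period[i])
    years <- if (grepl("-", per)) {
      rng <- as.integer(strsplit(per, "-")[[1]])
      seq(rng[1] + 1, rng[2])       # one replicate per consecutive season
    } else as.integer(per)
    pd <- mgmt$planting_date[match(sites$site[i], mgmt$site)]
    for (y in years) {
      rows[[length(rows) + 1L]] <- data.frame(
        site = sites$site[i], year = y, latitude = sites$latitude[i],
        tmean_c = sites$tmean_c[i], rain_mm = sites$rain_mm[i],
        srad_mj = sites$radiation_mj_m2[i],
        sowing_date = as.Date(format(pd, paste0(y, "-%m-%d"))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full sensitivity study
#'
#' Executes, per site-year replicate: weather synthesis, EFAST sampling,
#' surrogate model evaluation and index estimation; then ranks factors per
#' output and computes temporal, spatial and pooled top-down concordance.
#' The whole run is deterministic given the config seed.
#'
#' @param config A [study_config()].
#' @param model_factory Function(weather, management) returning a model
#'   adapter for [efast()]; default binds the packaged surrogate and soil.
#' @param out_dir Optional directory; when given, all tables are persisted
#'   as delimited text via [write_study()].
#' @return Object of class \code{study_report}: list with \code{fits} (one
#'   \code{efast} per replicate), \code{rankings} (one [ranking_set()] per
#'   output), \code{tdcc} (data frame output x axis with TDCC and
#'   p-value), \code{replicates} and \code{config}.
#' @export
run_study <- function(config, model_factory = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  reps <- config$replicates
  model_factory <- model_factory %||% function(weather, management)
    canola_model(weather, management = management)
  fits <- vector("list", nrow(reps))
  labels <- paste0(reps$site, ":", reps$year)
  for (i in seq_len(nrow(reps))) {
    # identical-weather diagnostic mode: every replicate sees replicate 1's
    # site, season and realization, so rankings must agree perfectly
    src <- if (config$identical_weather) 1L else i
    wseed <- child_seed(config$seed, src)
    jit <- if (config$interannual && !config$identical_weather)
      with_seed(child_seed(wseed, 7), c(stats::runif(1, -1, 1),
                                        stats::runif(1, 0.8, 1.2),
                                        stats::runif(1, 0.95, 1.05)))
    else c(0, 1, 1)
    weather <- tryCatch(synth_weather(
      latitude = reps$latitude[src],
      start = reps$sowing_date[src],
      days = config$season_days,
      tmean_c = reps$tmean_c[src] + jit[1],
      rain_mm = reps$rain_mm[src] * jit[2],
      srad_mj = reps$srad_mj[src] * jit[3],
      seed = wseed), error = function(e)
        stop_cropsens("[weather] replicate ", labels[i], ": ",
                      conditionMessage(e), class = "cropsens_stage_error"))
    model <- model_factory(weather,
                           list(sowing_date = reps$sowing_date[src]))
    fits[[i]] <- tryCatch(
      efast(model, config$parameters, M = config$M, Ns = config$Ns,
            Nr = config$Nr, seed = config$seed),
      error = function(e)
        stop_cropsens("[efast] replicate ", labels[i], ": ",
                      conditionMessage(e), class = "cropsens_stage_error"))
  }
  names(fits) <- labels
  outputs <- unique(fits[[1]]$indices$output)
  rankings <- lapply(outputs, function(o)
    rank_sensitivity(fits, o, index = config$index, replicates = labels))
  names(rankings) <- outputs

  site_counts <- table(reps$site)
  temporal_site <- names(site_counts)[which.max(site_counts)]
  year_counts <- table(reps$year[!duplicated(paste(reps$site, reps$year))])
  spatial_year <- as.integer(names(year_counts)[which.max(year_counts)])
  axes <- list(
    temporal = which(reps$site == temporal_site),
    spatial = which(reps$year == spatial_year &
                      !duplicated(reps$site)),
    total = seq_len(nrow(reps)))
  tdcc_rows <- list()
  concordance <- list()
  for (o in outputs) {
    for (ax in names(axes)) {
      sel <- axes[[ax]]
      if (length(sel) < 2) next
      rs <- ranking_set(rankings[[o]]$ranks[, sel, drop = FALSE],
                        ties = "mean")
      cc <- tdcc(rs)
      concordance[[paste(o, ax, sep = ".")]] <- cc
      tdcc_rows[[length(tdcc_rows) + 1L]] <- data.frame(
        output = o, axis = ax, m = cc$m, tdcc = cc$tdcc,
        p_value = cc$p_value, stringsAsFactors = FALSE)
    }
  }
  report <- structure(list(fits = fits, rankings = rankings,
                           tdcc = do.call(rbind, tdcc_rows),
                           concordance = concordance,
                           replicates = reps, config = config),
                      class = "study_report")
  if (!is.null(out_dir)) write_study(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Sensitivity study:", nrow(x$replicates), "site-year replicates,",
      nrow(x$config$parameters), "factors, index =", x$config$index, "\n")
  cat("Top-down concordance (TDCC) by output and axis:\n")
  wide <- stats::reshape(x$tdcc[, c("output", "axis", "tdcc")],
                         idvar = "output", timevar = "axis",
                         direction = "wide")
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Persist study tables as delimited text
#'
#' Writes, under \code{dir}: the replicate table, per-replicate sensitivity
#' indices, per-output rank tables, and the TDCC summary (output x axis
#' with p-values), plus the seed and settings for audit.
#'
#' @param report A \code{study_report}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$replicates, file.path(dir, "replicates.csv"),
                   row.names = FALSE)
  idx <- do.call(rbind, lapply(names(report$fits), function(lb) {
    cbind(replicate = lb, report$fits[[lb]]$indices)
  }))
  utils::write.csv(idx, file.path(dir, "sensitivity_indices.csv"),
                   row.names = FALSE)
  for (o in names(report$rankings))
    utils::write.csv(as.data.frame(report$rankings[[o]]$ranks),
                     file.path(dir, paste0("ranks_", o, ".csv")))
  utils::write.csv(report$tdcc, file.path(dir, "tdcc.csv"), row.names = FALSE)
  cfg <- report$config
  writeLines(c(paste("seed:", cfg$seed), paste("M:", cfg$M),
               paste("Ns:", cfg$Ns), paste("Nr:", cfg$Nr),
               paste("index:", cfg$index),
               paste("season_days:", cfg$season_days)),
             file.path(dir, "settings.txt"))
  invisible(dir)
}
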