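#' Days after planting
#'
#' Exact calendar-day count from sowing to a phenological event, honoring
#' leap years.  Phenology statistics are computed on this scale rather than
#' on calendar ordinals.
#'
#' @param sowing,event Dates (or strings coercible to \code{Date});
#'   \code{event} must not precede \code{sowing}.
#' @return Integer days (0 when the event falls on the sowing date).
#' @export
#' @examples
#' days_after_planting("2014-09-25", "2015-02-22")  # 150
days_after_planting <- function(sowing, event) {
  sowing <- as.Date(sowing); event <- as.Date(event)
  d <- as.integer(event - sowing)
  if (any(d < 0))
    stop_cropsens("event precedes sowing", class = "cropsens_date_error")
  d
}

#' Model evaluation statistics for paired observed/simulated series
#'
#' Computes the goodness-of-fit statistics used to judge crop-model
#' calibration and evaluation: root mean square error, its percentage of
#' the observed mean (nRMSE), mean error with sign convention
#' simulated - observed, relative mean error, and Willmott's index of
#' agreement
#' \deqn{d = 1 - \frac{\sum (P_i - O_i)^2}
#'   {\sum (|P_i - \bar O| + |O_i - \bar O|)^2}.}
#'
#' @param observed,simulated Equal-length numeric vectors (N >= 1).
#' @return Object of class \code{fit_stats}: list with \code{N},
#'   \code{RMSE}, \code{nRMSE} (percent), \code{ME}, \code{rME} (percent)
#'   and \code{d}.  \code{nRMSE} and \code{rME} are \code{NA} with a
#'   warning when the observed mean is zero.  When both series are constant
#'   and identical, \code{d} is defined as 1.
#' @export
#' @examples
#' obs <- c(150, 149); sim <- obs + c(3, 2)
#' fit_statistics(obs, sim)
fit_statistics <- function(observed, simulated) {
  if (length(observed) != length(simulated))
    stop_cropsens("observed and simulated lengths differ",
                  class = "cropsens_stats_error")
  if (length(observed) < 1)
    stop_cropsens("need at least one pair", class = "cropsens_stats_error")
  O <- as.numeric(observed); P <- as.numeric(simulated)
  N <- length(O)
  e <- P - O
  rmse <- sqrt(mean(e^2))
  me <- mean(e)
  obar <- mean(O)
  if (abs(obar) < .Machine$double.eps^0.5) {
    warning("observed mean is zero; nRMSE and rME undefined")
    nrmse <- rme <- NA_real_
  } else {
    nrmse <- 100 * rmse / obar
    rme <- 100 * me / obar
  }
  dden <- sum((abs(P - obar) + abs(O - obar))^2)
  dnum <- sum(e^2)
  d <- if (dden == 0) {
    if (dnum == 0) 1 else NA_real_
  } else 1 - dnum / dden
  structure(list(N = N, RMSE = rmse, nRMSE = nrmse, ME = me, rME = rme, d = d),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("N = %d | RMSE = %.2f | nRMSE = %.2f%% | ME = %.2f | rME = %.2f%% | d = %.2f\n",
              x$N, x$RMSE, x$nRMSE, x$ME, x$rME, x$d))
  invisible(x)
}

#' Normalize printed error statistics by an observed series
#'
#' Converts absolute RMSE and mean error into their percent-of-observed-mean
#' forms.  Useful for checking reported statistics tables when only the
#' absolute errors and the observed values are available.
#'
#' @param rmse,me Absolute root mean square error and mean error.
#' @param observed Observed values whose mean is the normalizer.
#' @return List with \code{nRMSE} and \code{rME}, in percent.
#' @export
normalize_fit_stats <- function(rmse, me, observed) {
  obar <- mean(as.numeric(observed))
  if (abs(obar) < .Machine$double.eps^0.5)
    stop_cropsens("observed mean is zero", class = "cropsens_stats_error")
  list(nRMSE = 100 * rmse / obar, rME = 100 * me / obar)
}

#' Reconstruct an error vector from printed RMSE and mean error
#'
#' Brute-force search for the integer error vector (one entry per season)
#' matching a printed RMSE/ME pair to 2 decimals, preferring same-signed
#' solutions.  Reported evaluation tables often print only RMSE and ME;
#' for small N the generating integer phenology errors are recoverable.
#'
#' @param rmse,me Printed values.
#' @param n Number of seasons.
#' @param max_abs Search window for each integer error.
#' @return Integer vector of length \code{n} (sorted), or \code{NULL} when
#'   no integer solution reproduces both statistics to 2 decimals.
#' @export
reconstruct_errors <- function(rmse, me, n, max_abs = 10) {
  grid <- as.matrix(expand.grid(rep(list(seq(-max_abs, max_abs)), n)))
  keep <- abs(rowMeans(grid) - me) < 0.005 &
    abs(sqrt(rowMeans(grid^2)) - rmse) < 0.005
  if (!any(keep)) return(NULL)
  sols <- unique(t(apply(grid[keep, , drop = FALSE], 1, sort)))
  same_sign <- apply(sols, 1, function(v) all(v >= 0) || all(v <= 0))
  if (any(same_sign)) sols <- sols[same_sign, , drop = FALSE]
  as.integer(sols[1, ])
}

#' Calibration loss over season records
#'
#' Scalar objective for trial-and-error or grid calibration of cultivar
#' coefficients: the weighted sum of nRMSE over anthesis day, maturity day,
#' yield and above-ground biomass between observed season records and the
#' model's simulations under candidate parameters.
#'
#' @param params Named numeric vector of candidate parameter values (merged
#'   over the model adapter's defaults).
#' @param seasons Data frame with observed columns \code{adap}, \code{mdap},
#'   \code{yield}, \code{biomass} (one row per season).
#' @param model A season-model adapter as built by [make_season_model()]:
#'   function from a named parameter vector to a data frame with columns
#'   \code{adap}, \code{mdap}, \code{hwam}, \code{cwam}, one row per season.
#' @param weights Weights on the four nRMSE components.
#' @return Non-negative scalar loss; \code{Inf} (with a warning) when the
#'   model fails under \code{params}.
#' @export
calibration_objective <- function(params, seasons, model,
                                  weights = c(adap = 1, mdap = 1,
                                              yield = 1, biomass = 1)) {
  sim <- tryCatch(model(params), error = function(e) e)
  if (inherits(sim, "error")) {
    warning("model failure during calibration: ", conditionMessage(sim))
    return(Inf)
  }
  comp <- rbind(
    c(w = weights[["adap"]],
      v = fit_statistics(seasons$adap, sim$adap)$nRMSE),
    c(weights[["mdap"]], fit_statistics(seasons$mdap, sim$mdap)$nRMSE),
    c(weights[["yield"]], fit_statistics(seasons$yield, sim$hwam)$nRMSE),
    c(weights[["biomass"]], fit_statistics(seasons$biomass, sim$cwam)$nRMSE))
  sum(comp[, 1] * abs(comp[, 2]))
}

#' Grid-search calibration of one parameter
#'
#' Evaluates [calibration_objective()] over a grid of candidate values of
#' one parameter (all others fixed at \code{base}) and returns the
#' minimizer — the grid analogue of the trial-and-error calibration used
#' with crop models.
#'
#' @param seasons Observed season records (see [calibration_objective()]).
#' @param model Season-model adapter.
#' @param param Name of the parameter searched.
#' @param grid Numeric vector of candidate values.
#' @param base Named vector of fixed values for the remaining parameters.
#' @param weights Passed to [calibration_objective()].
#' @return List with \code{best} (value at the loss minimum), \code{losses}
#'   (data frame value/loss over the grid) and \code{param}.
#' @export
calibrate_grid <- function(seasons, model, param, grid, base,
                           weights = c(adap = 1, mdap = 1,
                                       yield = 1, biomass = 1)) {
  losses <- vapply(grid, function(v) {
    p <- base
    p[param] <- v
    calibration_objective(p, seasons, model, weights)
  }, numeric(1))
  list(best = grid[which.min(losses)],
       losses = data.frame(value = grid, loss = losses),
       param = param)
}

#' Evaluation statistics table for calibration and evaluation seasons
#'
#' Builds the statistics report (one row per attribute and period) from
#' season records and paired simulated values, mirroring the usual
#' crop-model calibration/evaluation summary layout.
#'
#' @param seasons Data frame like [canola_seasons()], with columns
#'   \code{role} (\code{"calibration"}/\code{"evaluation"}),
#'   \code{sowing_date}, \code{anthesis_date}, \code{maturity_date},
#'   \code{yield_kg_ha}, \code{biomass_kg_ha}.
#' @param simulated Data frame with columns \code{adap}, \code{mdap},
#'   \code{hwam}, \code{cwam} aligned with the rows of \code{seasons}.
#' @return Data frame with columns period, attribute, N, RMSE, nRMSE, ME,
#'   rME, d.
#' @export
evaluation_table <- function(seasons, simulated) {
  obs <- data.frame(
    adap = days_after_planting(seasons$sowing_date, seasons$anthesis_date),
    mdap = days_after_planting(seasons$sowing_date, seasons$maturity_date),
    yield = seasons$yield_kg_ha,
    biomass = seasons$biomass_kg_ha)
  simmap <- c(adap = "adap", mdap = "mdap", yield = "hwam", biomass = "cwam")
  rows <- list()
  for (role in unique(seasons$role)) {
    sel <- seasons$role == role
    for (attr in names(simmap)) {
      st <- fit_statistics(obs[[attr]][sel], simulated[[simmap[[attr]]]][sel])
      rows[[length(rows) + 1L]] <- data.frame(
        period = role, attribute = attr, N = st$N, RMSE = st$RMSE,
        nRMSE = st$nRMSE, ME = st$ME, rME = st$rME, d = st$d,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
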