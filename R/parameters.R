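#' Define a model input parameter with sampling bounds
#'
#' A parameter specification names one model input, its sampling range in
#' native units and the group it belongs to (ecotype, genotype or soil
#' coefficients of the crop model).  Sampling is uniform on
#' \code{[lower, upper]}.
#'
#' @param name Parameter identifier, unique within a study.
#' @param lower,upper Numeric bounds in native units, \code{lower < upper}.
#' @param group One of \code{"ecotype"}, \code{"genotype"}, \code{"soil"} or
#'   \code{"other"}.
#' @param definition Optional free-text definition.
#' @return A one-row \code{param_table}.
#' @seealso [param_table()], [canola_parameters()]
#' @export
param_spec <- function(name, lower, upper, group = "other", definition = "") {
  param_table(data.frame(name = name, definition = definition,
                         lower = lower, upper = upper, group = group,
                         stringsAsFactors = FALSE))
}

#' Validate a table of parameter specifications
#'
#' @param x A data frame with columns \code{name}, \code{lower}, \code{upper}
#'   and optionally \code{group} and \code{definition}.
#' @return The validated table with class \code{param_table}.
#' @export
param_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("name", "lower", "upper")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_cropsens("parameter table lacks columns: ", paste(miss, collapse = ", "),
                  class = "cropsens_param_error")
  if (!"group" %in% names(x)) x$group <- "other"
  if (!"definition" %in% names(x)) x$definition <- ""
  x$name <- as.character(x$name)
  x$lower <- as.numeric(x$lower)
  x$upper <- as.numeric(x$upper)
  if (anyDuplicated(x$name))
    stop_cropsens("duplicated parameter names: ",
                  paste(unique(x$name[duplicated(x$name)]), collapse = ", "),
                  class = "cropsens_param_error")
  bad <- which(!(x$lower < x$upper))
  if (length(bad))
    stop_cropsens("lower must be < upper for: ", paste(x$name[bad], collapse = ", "),
                  class = "cropsens_param_error")
  class(x) <- c("param_table", "data.frame")
  x
}

as_param_table <- function(x) {
  if (inherits(x, "param_table")) x else param_table(x)
}

#' Rapeseed crop-model parameter ranges
#'
#' The 35 ecotype, genotype and soil parameters of the rapeseed crop model
#' with their sensitivity-analysis sampling ranges (12 ecotype, 11 genotype
#' and 12 soil coefficients), shipped as a plain-text fixture.
#'
#' @param group Optional subset: any of \code{"ecotype"}, \code{"genotype"},
#'   \code{"soil"}.
#' @return A \code{param_table} with 35 rows (fewer if subset).
#' @export
#' @examples
#' pars <- canola_parameters()
#' nrow(pars)
canola_parameters <- function(group = NULL) {
  path <- system.file("extdata", "parameter_ranges.csv", package = "cropsens",
                      mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(group)) x <- x[x$group %in% group, , drop = FALSE]
  param_table(x)
}

#' Packaged study fixtures
#'
#' Accessors for the plain-text fixtures shipped with the package: study
#' sites with seasonal weather summaries, management practices, the
#' calibration/evaluation season records, the layered soil profile, the
#' cultivar coefficients before and after calibration, and the printed
#' evaluation-statistics reference.
#'
#' @return A data frame; dates are parsed to \code{Date}.
#' @name fixtures
NULL

read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "cropsens", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname fixtures
#' @export
canola_sites <- function() read_fixture("sites.csv")

#' @rdname fixtures
#' @export
canola_management <- function() {
  x <- read_fixture("management.csv")
  x$planting_date <- as.Date(x$planting_date)
  x
}

#' @rdname fixtures
#' @export
canola_seasons <- function() {
  x <- read_fixture("seasons.csv")
  for (col in c("sowing_date", "anthesis_date", "maturity_date"))
    x[[col]] <- as.Date(x[[col]])
  x
}

#' @rdname fixtures
#' @export
canola_soil_profile <- function() read_fixture("soil_profile.csv")

#' @rdname fixtures
#' @export
canola_cultivar_coefficients <- function() read_fixture("cultivar_coefficients.csv")

#' @rdname fixtures
#' @export
evaluation_reference <- function() read_fixture("evaluation_reference.csv")
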