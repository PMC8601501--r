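#' Build an EFAST sampling design
#'
#' Constructs the search-curve design of the extended Fourier Amplitude
#' Sensitivity Test.  Each of the \code{k} factors takes one turn as the
#' driving factor of a block of \code{Ns} model runs, oscillating at the
#' driving frequency \eqn{\omega_{max} = \lfloor (Ns-1)/(2M) \rfloor} while
#' the complementary factors oscillate at low frequencies cycled over
#' \eqn{1..\max(1, \lfloor \omega_{max}/(2M) \rfloor)}.  The whole design is
#' optionally replicated over \code{Nr} resampling curves with fresh random
#' phase offsets.
#'
#' @param parameters A [param_table()] (or coercible data frame) of k >= 2
#'   factors.
#' @param M Interference factor: number of harmonics of the driving frequency
#'   attributed to the driving factor.  Default 4.
#' @param Ns Odd number of model runs per search curve.  Must satisfy
#'   \code{Ns >= 2*M + 1} so the driving frequency is at least 1.
#' @param Nr Number of resampling curves (independent random phases).
#' @param seed Integer seed from which phase offsets are drawn.
#' @return An object of class \code{efast_design}: list with the parameter
#'   table, \code{M}, \code{Ns}, \code{Nr}, \code{omega_max}, the k x k
#'   frequency matrix \code{freq} (row = driving block, column = factor) and
#'   the \code{Nr} x k phase matrix in \eqn{[0, 2\pi)}.
#' @references Saltelli, A., Tarantola, S. and Chan, K. (1999) A quantitative
#'   model-independent method for global sensitivity analysis of model
#'   output. Technometrics 41, 39-56.
#' @export
#' @examples
#' d <- efast_design(canola_parameters(), Ns = 129, seed = 1)
#' d$omega_max        # 16
#' d$total_runs       # 35 * 129 = 4515
efast_design <- function(parameters, M = 4, Ns = 129, Nr = 1, seed = 1) {
  parameters <- as_param_table(parameters)
  k <- nrow(parameters)
  if (k < 2)
    stop_cropsens("EFAST requires at least 2 factors (a complementary set ",
                  "is needed to estimate total-order indices)",
                  class = "cropsens_design_error")
  if (Ns %% 2 == 0)
    stop_cropsens("Ns must be odd, got ", Ns, class = "cropsens_design_error")
  if (Nr < 1) stop_cropsens("Nr must be >= 1", class = "cropsens_design_error")
  omega_max <- (Ns - 1) %/% (2 * M)
  if (omega_max < 1)
    stop_cropsens("Ns = ", Ns, " is too small for interference factor M = ", M,
                  " (driving harmonics would alias); need Ns >= ", 2 * M + 1,
                  class = "cropsens_design_error")
  comp_max <- max(1L, omega_max %/% (2 * M))
  # complementary frequencies spread over 1..comp_max when there is room,
  # cycled when there are more factors than admissible frequencies
  comp <- if (k - 1 <= comp_max)
    as.integer(floor(seq(1, comp_max, length.out = k - 1)))
  else rep_len(seq_len(comp_max), k - 1)
  freq <- matrix(0L, k, k, dimnames = list(NULL, parameters$name))
  for (i in seq_len(k)) {
    freq[i, i] <- as.integer(omega_max)
    freq[i, -i] <- comp
  }
  phases <- with_seed(seed, matrix(stats::runif(Nr * k, 0, 2 * pi), Nr, k,
                                   dimnames = list(NULL, parameters$name)))
  structure(list(parameters = parameters, k = k, M = M, Ns = Ns, Nr = Nr,
                 seed = as.integer(seed), omega_max = omega_max,
                 comp_max = comp_max, freq = freq, phases = phases,
                 total_runs = k * Ns * Nr),
            class = "efast_design")
}

#' @export
print.efast_design <- function(x, ...) {
  cat("EFAST design:", x$k, "factors, M =", x$M, ", Ns =", x$Ns,
      ", Nr =", x$Nr, "\n")
  cat("  driving frequency", x$omega_max,
      "| complementary frequencies 1..", x$comp_max, "\n")
  cat("  total model runs:", x$total_runs, "\n")
  invisible(x)
}

#' Realize the EFAST sample matrix
#'
#' Evaluates the search curves of an EFAST design.  Within the block driven
#' by factor i, factor j at curve position s takes
#' \deqn{x_j = lower_j + (upper_j - lower_j)\,(1/2 + \arcsin(\sin(\omega_j s
#'   + \phi_j))/\pi)}
#' with s evenly spaced over \eqn{(-\pi, \pi]}.  The arcsine transform gives
#' each factor a uniform marginal distribution over its range.
#'
#' @param design An [efast_design()].
#' @return Object of class \code{efast_sample}: list with \code{X}
#'   (total_runs x k numeric matrix in native units) and \code{block}
#'   (data frame: \code{driver} factor name, \code{curve}, \code{s} position
#'   index 1..Ns for every row of X).
#' @export
efast_sample <- function(design) {
  stopifnot(inherits(design, "efast_design"))
  k <- design$k; Ns <- design$Ns; Nr <- design$Nr
  pars <- design$parameters
  s <- -pi + 2 * pi * seq_len(Ns) / Ns
  X <- matrix(NA_real_, k * Ns * Nr, k, dimnames = list(NULL, pars$name))
  driver <- character(k * Ns * Nr); curve <- integer(k * Ns * Nr)
  row0 <- 0L
  for (r in seq_len(Nr)) {
    for (i in seq_len(k)) {
      idx <- row0 + seq_len(Ns)
      for (j in seq_len(k)) {
        g <- 0.5 + asin(sin(design$freq[i, j] * s + design$phases[r, j])) / pi
        X[idx, j] <- pars$lower[j] + (pars$upper[j] - pars$lower[j]) * g
      }
      driver[idx] <- pars$name[i]
      curve[idx] <- r
      row0 <- row0 + Ns
    }
  }
  structure(list(X = X,
                 block = data.frame(driver = driver, curve = curve,
                                    s = rep_len(seq_len(Ns), k * Ns * Nr),
                                    stringsAsFactors = FALSE),
                 design = design),
            class = "efast_sample")
}

# Spectral power at integer frequencies 1..(Ns-1)/2 of one curve of outputs.
curve_spectrum <- function(y) {
  Ns <- length(y)
  lam <- Mod(stats::fft(y))^2 / Ns^2
  lam[1 + seq_len((Ns - 1) %/% 2)]
}

#' Estimate first-order and total-order sensitivity indices from EFAST runs
#'
#' Decomposes the output variance of each search-curve block by its Fourier
#' spectrum.  For the block driven by factor i, the variance attributed to i
#' is read off the driving frequency and its first \code{M} harmonics,
#' \eqn{V_i = 2\sum_{p=1}^{M} \Lambda_{p\,\omega_{max}}}, the total variance
#' is \eqn{V(Y) = 2\sum_{p\ge 1} \Lambda_p}, and the complementary variance
#' (everything not involving i) from the low-frequency band,
#' \eqn{V_{-i} = 2\sum_{p \le \lfloor\omega_{max}/2\rfloor} \Lambda_p}.
#' Then \eqn{S_i = V_i/V(Y)} and \eqn{S_{Ti} = 1 - V_{-i}/V(Y)}, averaged
#' over the \code{Nr} resampling curves.
#'
#' Small negative spectral estimates are clamped into \eqn{[0, 1]}; every
#' clamp is counted in the result.  A block whose output variance is (near)
#' zero is flagged degenerate and its indices are \code{NA}: sensitivity of
#' a constant output is undefined, not zero.
#'
#' @param design An [efast_design()].
#' @param outputs Numeric matrix (total_runs x n_outputs, column names are
#'   output names) or vector of model outputs aligned row-for-row with
#'   [efast_sample()].  Rows from failed model runs may be \code{NA}: any
#'   block containing an \code{NA} is reported incomplete (its indices are
#'   \code{NA}) because the spectrum needs complete, evenly spaced curves.
#' @return Object of class \code{efast}: list with \code{indices} (long data
#'   frame: factor, output, Si, STi), \code{variance} (mean total variance
#'   per output), \code{clamped} (count of clamped index estimates),
#'   \code{degenerate} (outputs with no variance), \code{incomplete}
#'   (blocks dropped for missing runs) and the design.
#' @export
efast_indices <- function(design, outputs) {
  stopifnot(inherits(design, "efast_design"))
  if (is.null(dim(outputs))) outputs <- matrix(outputs, ncol = 1,
                                               dimnames = list(NULL, "Y"))
  outputs <- as.matrix(outputs)
  if (is.null(colnames(outputs)))
    colnames(outputs) <- paste0("Y", seq_len(ncol(outputs)))
  k <- design$k; Ns <- design$Ns; Nr <- design$Nr
  if (nrow(outputs) != k * Ns * Nr)
    stop_cropsens("outputs has ", nrow(outputs), " rows; design expects ",
                  k * Ns * Nr, class = "cropsens_align_error")
  pars <- design$parameters$name
  outs <- colnames(outputs)
  M <- design$M; wmax <- design$omega_max
  p_drive <- seq_len(M) * wmax
  p_comp <- seq_len(max(1L, wmax %/% 2))
  Si <- STi <- array(NA_real_, c(k, length(outs), Nr))
  Vtot <- array(NA_real_, c(k, length(outs), Nr))
  clamped <- 0L
  incomplete <- character(0)
  degenerate <- character(0)
  row0 <- 0L
  for (r in seq_len(Nr)) {
    for (i in seq_len(k)) {
      idx <- row0 + seq_len(Ns)
      for (o in seq_along(outs)) {
        y <- outputs[idx, o]
        if (anyNA(y)) {
          incomplete <- c(incomplete,
                          sprintf("driver=%s curve=%d output=%s (%d missing)",
                                  pars[i], r, outs[o], sum(is.na(y))))
          next
        }
        lam <- curve_spectrum(y)
        V <- 2 * sum(lam)
        Vtot[i, o, r] <- V
        if (V <= 1e-12 * max(1, mean(y)^2)) {
          degenerate <- c(degenerate, sprintf("%s (driver=%s curve=%d)",
                                              outs[o], pars[i], r))
          next
        }
        Vi <- 2 * sum(lam[p_drive])
        Vmi <- 2 * sum(lam[p_comp])
        si <- Vi / V
        sti <- 1 - Vmi / V
        nclamp <- sum(si < 0 | si > 1) + sum(sti < 0 | sti > 1)
        clamped <- clamped + nclamp
        Si[i, o, r] <- clamp(si, 0, 1)
        STi[i, o, r] <- clamp(sti, 0, 1)
      }
      row0 <- row0 + Ns
    }
  }
  mean_keep_na <- function(a) apply(a, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  Sim <- mean_keep_na(Si); STim <- mean_keep_na(STi)
  indices <- data.frame(
    factor = rep(pars, times = length(outs)),
    output = rep(outs, each = k),
    Si = as.vector(Sim), STi = as.vector(STim),
    stringsAsFactors = FALSE)
  variance <- apply(Vtot, 2, mean, na.rm = TRUE)
  names(variance) <- outs
  structure(list(indices = indices, variance = variance,
                 clamped = clamped, degenerate = unique(degenerate),
                 incomplete = incomplete, design = design),
            class = "efast")
}

#' Run a full EFAST sensitivity analysis of a model
#'
#' The one-call interface: builds the design, realizes the sample matrix,
#' evaluates the model on every row, and estimates first-order and
#' total-order sensitivity indices for every model output.
#'
#' @param model A function mapping one named parameter vector to a (named)
#'   numeric vector of outputs; or, with \code{vectorized = TRUE}, mapping
#'   the whole sample matrix to a matrix of outputs.
#' @param parameters A [param_table()].
#' @param M,Ns,Nr,seed Passed to [efast_design()].
#' @param vectorized Does \code{model} accept the full sample matrix?
#' @param on_failure \code{"flag"} (default): a model run that errors or
#'   returns non-finite values makes its whole block incomplete, reported in
#'   the result; \code{"error"}: abort instead.
#' @param artifact_dir Optional directory; when given, the realized sample
#'   and output matrices are persisted as CSV for audit
#'   (see [write_efast_artifacts()]).
#' @return An object of class \code{efast}; see [efast_indices()].  The
#'   realized \code{sample} and \code{outputs} matrices are attached.
#' @export
#' @examples
#' pars <- param_table(data.frame(name = c("x1", "x2"), lower = 0, upper = 1))
#' fit <- efast(function(x) c(y = x[["x1"]] + 2 * x[["x2"]]), pars,
#'              Ns = 257, seed = 1)
#' summary(fit)
efast <- function(model, parameters, M = 4, Ns = 129, Nr = 1, seed = 1,
                  vectorized = FALSE, on_failure = c("flag", "error"),
                  artifact_dir = NULL) {
  on_failure <- match.arg(on_failure)
  design <- efast_design(parameters, M = M, Ns = Ns, Nr = Nr, seed = seed)
  smp <- efast_sample(design)
  Y <- evaluate_model(model, smp$X, vectorized = vectorized,
                      on_failure = on_failure)
  res <- efast_indices(design, Y)
  res$sample <- smp
  res$outputs <- Y
  if (!is.null(artifact_dir)) write_efast_artifacts(res, artifact_dir)
  res
}

evaluate_model <- function(model, X, vectorized = FALSE,
                           on_failure = "flag") {
  if (vectorized) {
    Y <- model(X)
    if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1, dimnames = list(NULL, "Y"))
    return(as.matrix(Y))
  }
  first <- NULL
  rows <- vector("list", nrow(X))
  for (ri in seq_len(nrow(X))) {
    v <- tryCatch(model(X[ri, ]), error = function(e) e)
    if (inherits(v, "error") || !all(is.finite(as.numeric(v)))) {
      if (on_failure == "error")
        stop_cropsens("model failed on run ", ri, ": ",
                      if (inherits(v, "error")) conditionMessage(v)
                      else "non-finite output",
                      class = "cropsens_model_error")
      rows[[ri]] <- NA
    } else {
      v <- as.numeric_named(v)
      if (is.null(first)) first <- v
      rows[[ri]] <- v
    }
  }
  if (is.null(first))
    stop_cropsens("model failed on every run", class = "cropsens_model_error")
  Y <- matrix(NA_real_, nrow(X), length(first),
              dimnames = list(NULL, names(first)))
  for (ri in seq_len(nrow(X)))
    if (!identical(rows[[ri]], NA)) Y[ri, ] <- rows[[ri]]
  Y
}

as.numeric_named <- function(v) {
  nm <- names(v)
  v <- as.numeric(v)
  names(v) <- nm %||% paste0("Y", seq_along(v))
  v
}

#' Persist or reload EFAST run artifacts
#'
#' Writes the realized sample matrix (with its block bookkeeping), the
#' output matrix and the estimated indices as delimited text so a run can be
#' audited or the index estimation repeated without re-running the model.
#'
#' @param fit An \code{efast} object from [efast()] that carries its sample
#'   and outputs.
#' @param dir Directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_efast_artifacts <- function(fit, dir) {
  stopifnot(inherits(fit, "efast"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(fit$sample))
    utils::write.csv(cbind(fit$sample$block, fit$sample$X),
                     file.path(dir, "sample_matrix.csv"), row.names = FALSE)
  if (!is.null(fit$outputs))
    utils::write.csv(as.data.frame(fit$outputs),
                     file.path(dir, "output_matrix.csv"), row.names = FALSE)
  utils::write.csv(fit$indices, file.path(dir, "sensitivity_indices.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @export
print.efast <- function(x, ...) {
  k <- x$design$k
  cat("EFAST sensitivity analysis:", k, "factors,",
      length(unique(x$indices$output)), "output(s),",
      x$design$total_runs, "model runs\n")
  for (o in unique(x$indices$output)) {
    sub <- x$indices[x$indices$output == o, ]
    sub <- sub[order(-sub$STi), ]
    top <- utils::head(sub, 3)
    cat(sprintf("  %s: top factors %s\n", o,
                paste(sprintf("%s (STi=%.3f)", top$factor, top$STi),
                      collapse = ", ")))
  }
  if (x$clamped > 0) cat("  ", x$clamped, "index estimate(s) clamped to [0,1]\n")
  if (length(x$degenerate)) cat("  degenerate (zero-variance) blocks:",
                                length(x$degenerate), "\n")
  if (length(x$incomplete)) cat("  incomplete blocks:", length(x$incomplete), "\n")
  invisible(x)
}

#' @export
summary.efast <- function(object, ...) {
  out <- object$indices
  out <- out[order(out$output, -out$STi), ]
  rownames(out) <- NULL
  structure(list(indices = out, variance = object$variance,
                 clamped = object$clamped,
                 degenerate = object$degenerate,
                 incomplete = object$incomplete),
            class = "summary.efast")
}

#' @export
print.summary.efast <- function(x, ...) {
  cat("Sensitivity indices (sorted by STi within output):\n")
  print(x$indices, digits = 3)
  cat("Mean total variance per output:\n")
  print(x$variance)
  invisible(x)
}

#' Plot EFAST sensitivity profiles
#'
#' Draws, per output, the per-factor first-order (filled) and total-order
#' (open) sensitivity indices in factor order — the sensitivity-profile
#' layout commonly used to compare parameter importance across outputs.
#'
#' @param x An \code{efast} object.
#' @param outputs Which outputs to draw (default all).
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, \code{x}.
#' @export
plot.efast <- function(x, outputs = NULL, ...) {
  outs <- outputs %||% unique(x$indices$output)
  old <- graphics::par(mfrow = c(length(outs), 1),
                       mar = c(6, 4, 2, 1))
  on.exit(graphics::par(old))
  for (o in outs) {
    sub <- x$indices[x$indices$output == o, ]
    h <- rbind(Si = sub$Si, STi = pmax(0, sub$STi - sub$Si))
    graphics::barplot(h, names.arg = sub$factor, las = 2, main = o,
                      ylab = "sensitivity index",
                      legend.text = c("Si", "STi - Si"), ...)
  }
  invisible(x)
}
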