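#' Monte-Carlo Sobol index estimator (pick-freeze)
#'
#' Brute-force Saltelli/Jansen pick-freeze estimator of first-order and
#' total-order Sobol indices, intended as an independent cross-check of the
#' spectral EFAST estimator on cheap test functions.  Two independent
#' uniform sample matrices A and B of size \code{n} are drawn inside the
#' parameter bounds; for each factor i the hybrid matrix AB_i replaces
#' column i of A by that of B.  Then
#' \deqn{S_i = \mathrm{mean}(y_B (y_{AB_i} - y_A)) / V,\qquad
#'       S_{Ti} = \mathrm{mean}((y_A - y_{AB_i})^2) / (2V).}
#'
#' @param model Function from named parameter vector to a single numeric
#'   output (or anything coercible; the first element is used).
#' @param parameters A [param_table()].
#' @param n Base sample size; total model evaluations are \code{n * (k + 2)}.
#' @param seed Integer seed.
#' @return A data frame (factor, Si, STi) with attribute \code{"warning"}
#'   set when \code{n} is small enough that Monte-Carlo error is large.
#' @export
sobol_mc <- function(model, parameters, n = 10000, seed = 1) {
  parameters <- as_param_table(parameters)
  k <- nrow(parameters)
  draw <- function(m) {
    U <- matrix(stats::runif(m * k), m, k)
    X <- sweep(sweep(U, 2, parameters$upper - parameters$lower, "*"),
               2, parameters$lower, "+")
    colnames(X) <- parameters$name
    X
  }
  ev <- function(X) apply(X, 1, function(row) as.numeric(model(row))[1])
  res <- with_seed(seed, {
    A <- draw(n); B <- draw(n)
    yA <- ev(A); yB <- ev(B)
    V <- stats::var(c(yA, yB))
    Si <- STi <- numeric(k)
    for (i in seq_len(k)) {
      ABi <- A; ABi[, i] <- B[, i]
      yABi <- ev(ABi)
      Si[i] <- mean(yB * (yABi - yA)) / V
      STi[i] <- mean((yA - yABi)^2) / (2 * V)
    }
    data.frame(factor = parameters$name, Si = Si, STi = STi,
               stringsAsFactors = FALSE)
  })
  if (n < 1000)
    attr(res, "warning") <- sprintf(
      "n = %d is small; Monte-Carlo error on the indices may exceed 0.05", n)
  res
}
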