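# Shared analytic test functions and fixtures built in code.

ishigami_pars <- param_table(data.frame(
  name = c("x1", "x2", "x3"), lower = -pi, upper = pi))

ishigami_fn <- function(a = 7, b = 0.1) {
  function(x) c(y = sin(x[["x1"]]) + a * sin(x[["x2"]])^2 +
                  b * x[["x3"]]^4 * sin(x[["x1"]]))
}

# closed-form variance decomposition of the Ishigami function on U(-pi,pi)^3
ishigami_true <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  list(S1 = V1 / V, S2 = V2 / V, S3 = 0, ST3 = V13 / V, V = V)
}

unit_pars <- function(k) {
  param_table(data.frame(name = paste0("x", seq_len(k)), lower = 0, upper = 1))
}

linear_fn <- function(coefs) {
  function(x) c(y = sum(coefs * as.numeric(x[paste0("x", seq_along(coefs))])))
}

# site-like season; sub-season windows scale the rain/radiation totals down
wuhan_weather <- function(seed = 3, days = 240, rain = 530.6 * days / 240) {
  synth_weather(30.47, "2018-09-28", days, tmean_c = 17.4, rain_mm = rain,
                srad_mj = 2162.4 * days / 240, seed = seed)
}

# uniform parameter draws inside the sampling bounds
draw_params <- function(pars, n, seed) {
  with_seed <- get("with_seed", asNamespace("cropsens"))
  with_seed(seed, {
    U <- matrix(runif(n * nrow(pars)), n, nrow(pars))
    X <- sweep(sweep(U, 2, pars$upper - pars$lower, "*"), 2, pars$lower, "+")
    colnames(X) <- pars$name
    X
  })
}
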