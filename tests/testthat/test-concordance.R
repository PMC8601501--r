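test_that("savage scores follow the harmonic tail sums", {
  expect_equal(savage_scores(c(1, 2, 3)), c(11 / 6, 5 / 6, 1 / 3))
  expect_equal(savage_scores(1), 1)
  # scores of any full ranking sum to n (telescoping identity)
  set.seed(1)
  for (n in c(2, 4, 9, 40)) {
    r <- sample(n)
    expect_equal(sum(savage_scores(r)), n, tolerance = 1e-12)
  }
  # midrank ties get the mean of the tied positions' scores
  s <- savage_scores(c(1.5, 1.5, 3), ties = "mean")
  expect_equal(s, c((11 / 6 + 5 / 6) / 2, (11 / 6 + 5 / 6) / 2, 1 / 3))
  expect_equal(sum(s), 3, tolerance = 1e-12)
  expect_error(savage_scores(c(1, 1, 3)), "permutation")
  expect_error(savage_scores(c(0, 1, 2)), "1..n")
})

test_that("identical rankings give TDCC = 1 exactly", {
  for (n in 2:6) for (m in 2:8) {
    r <- matrix(rep(sample(n), m), n, m)
    expect_equal(tdcc(r)$tdcc, 1, tolerance = 1e-12)
  }
})

test_that("opposite two-factor rankings give TDCC = 0", {
  r <- cbind(c(1, 2), c(2, 1))
  res <- tdcc(r)
  expect_equal(res$tdcc, 0, tolerance = 1e-12)
  expect_equal(res$df, 1L)
})

test_that("identical rankings at n = 5, m = 8 are significant at <0.001", {
  res <- tdcc(matrix(rep(1:5, 8), 5, 8))
  expect_equal(res$T, 32)
  expect_equal(res$p_value, pchisq(32, 4, lower.tail = FALSE))
  expect_lt(res$p_value, 0.001)
})

test_that("TDCC is invariant to replicate relabeling and factor order", {
  set.seed(7)
  r <- sapply(1:4, function(j) sample(6))
  base <- tdcc(r)$tdcc
  expect_equal(tdcc(r[, c(3, 1, 4, 2)])$tdcc, base, tolerance = 1e-12)
  perm <- sample(6)
  expect_equal(tdcc(r[perm, ])$tdcc, base, tolerance = 1e-12)
})

test_that("TDCC = 1 only for identical rankings (exhaustive, small n)", {
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    p <- perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(i) cbind(i, p + (p >= i))))
  }
  for (n in 2:4) {
    P <- perms(n)
    for (a in seq_len(nrow(P))) for (b in seq_len(nrow(P))) {
      cc <- tdcc(cbind(P[a, ], P[b, ]))$tdcc
      if (a == b) expect_equal(cc, 1, tolerance = 1e-12)
      else expect_lt(cc, 1 - 1e-9)
    }
  }
})

test_that("p-value decreases monotonically in TDCC at fixed n, m", {
  set.seed(11)
  res <- replicate(30, tdcc(sapply(1:5, function(j) sample(8)))[c("tdcc", "p_value")])
  cc <- unlist(res["tdcc", ]); p <- unlist(res["p_value", ])
  o <- order(cc)
  expect_true(all(diff(p[o]) <= 1e-12))
})

test_that("null mean of TDCC matches its concordance expectation 1/m", {
  set.seed(42)
  n <- 10; m <- 7
  v <- replicate(200, tdcc(sapply(seq_len(m), function(j) sample(n)))$tdcc)
  expect_lt(abs(mean(v) - 1 / m), 0.05)
})

test_that("rankings are built from sensitivity results deterministically", {
  mk <- function(sti) {
    structure(list(indices = data.frame(
      factor = paste0("X", seq_along(sti)), output = "Y",
      Si = sti / 2, STi = sti)), class = "efast")
  }
  r1 <- rank_sensitivity(mk(c(0.9, 0.5, 0.2, 0.1)), "Y")
  expect_equal(unname(r1$ranks[, 1]), 1:4)
  rs <- rank_sensitivity(list(mk(c(0.9, 0.5, 0.2, 0.1)),
                              mk(c(0.9, 0.5, 0.2, 0.1))), "Y")
  expect_equal(tdcc(rs)$tdcc, 1, tolerance = 1e-12)
  # ties resolved to midranks and recorded
  rt <- rank_sensitivity(list(mk(c(0.5, 0.5, 0.2, 0.1)),
                              mk(c(0.9, 0.5, 0.2, 0.1))), "Y")
  expect_length(attr(rt, "tie_events"), 1)
  bad <- structure(list(indices = data.frame(
    factor = c("A", "B"), output = "Y", Si = 1:2 / 4, STi = 1:2 / 2)),
    class = "efast")
  expect_error(rank_sensitivity(list(mk(c(0.9, 0.5)), bad), "Y"),
               "factor set")
  expect_error(tdcc(matrix(1, 1, 2)), "n >= 2")
})
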