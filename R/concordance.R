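#' Savage scores of a ranking
#'
#' The savage score of an item ranked \eqn{r} among \eqn{n} is
#' \eqn{S = \sum_{k=r}^{n} 1/k}; it weights agreement at the top of the
#' ranking much more heavily than at the bottom.  Scores of a full ranking
#' always sum to \eqn{n}.
#'
#' @param ranks Integer ranks, 1 = most important.  With
#'   \code{ties = "mean"}, midranks (as produced by
#'   \code{rank(..., ties.method = "average")}) are accepted and tied items
#'   receive the mean of the savage scores of the positions they occupy.
#' @param ties \code{"error"} (default): ranks must be a permutation of
#'   \code{1..n}; \code{"mean"}: Iman-Conover treatment of ties.
#' @return Numeric vector of savage scores, same length and names as
#'   \code{ranks}.
#' @references Iman, R.L. and Conover, W.J. (1987) A measure of top-down
#'   correlation. Technometrics 29, 351-357.
#' @export
#' @examples
#' savage_scores(c(1, 2, 3))  # 11/6, 5/6, 1/3
savage_scores <- function(ranks, ties = c("error", "mean")) {
  ties <- match.arg(ties)
  n <- length(ranks)
  if (n == 0) return(numeric(0))
  if (any(!is.finite(ranks)) || any(ranks < 1 - 1e-9) || any(ranks > n + 1e-9))
    stop_cropsens("ranks must lie in 1..n", class = "cropsens_rank_error")
  # position scores: cum[p] = sum_{k=p}^{n} 1/k
  cum <- rev(cumsum(1 / rev(seq_len(n))))
  if (all(ranks == round(ranks)) && !anyDuplicated(ranks)) {
    out <- cum[as.integer(round(ranks))]
  } else if (ties == "error") {
    stop_cropsens("ranks are not a permutation of 1..n; pass ties = \"mean\" ",
                  "for midrank ties", class = "cropsens_rank_error")
  } else {
    # midranks: a group of t items sharing midrank v occupies positions
    # v-(t-1)/2 .. v+(t-1)/2 and gets the mean position score
    out <- numeric(n)
    for (v in unique(ranks)) {
      sel <- which(abs(ranks - v) < 1e-9)
      t <- length(sel)
      pos <- round(v - (t - 1) / 2) + seq_len(t) - 1
      if (any(pos < 1 | pos > n))
        stop_cropsens("inconsistent midranks", class = "cropsens_rank_error")
      out[sel] <- mean(cum[pos])
    }
  }
  names(out) <- names(ranks)
  out
}

#' Assemble a set of replicate rankings
#'
#' @param ranks An n x m matrix or data frame of ranks: one column per
#'   replicate analysis (site or year), one row per factor, rank 1 = most
#'   sensitive.  Columns must be permutations of 1..n, or midranks when a
#'   tie policy is recorded.
#' @param factors,replicates Optional dimnames.
#' @param ties Tie policy the columns were produced under; stored and used
#'   by [tdcc()].
#' @return Object of class \code{ranking_set}.
#' @export
ranking_set <- function(ranks, factors = NULL, replicates = NULL,
                        ties = c("error", "mean")) {
  ties <- match.arg(ties)
  ranks <- as.matrix(ranks)
  n <- nrow(ranks); m <- ncol(ranks)
  for (j in seq_len(m)) {
    sorted_ok <- isTRUE(all.equal(sort(unname(ranks[, j])),
                                  as.numeric(seq_len(n)), tolerance = 1e-9))
    perm <- !anyDuplicated(ranks[, j]) &&
      all(ranks[, j] == round(ranks[, j])) && sorted_ok
    if (!perm && ties == "error")
      stop_cropsens("replicate ", j, " is not a permutation of 1..", n,
                    class = "cropsens_rank_error")
    if (!perm && !isTRUE(all.equal(sum(ranks[, j]), n * (n + 1) / 2)))
      stop_cropsens("replicate ", j, " has inconsistent midranks",
                    class = "cropsens_rank_error")
  }
  rownames(ranks) <- factors %||% rownames(ranks) %||% paste0("X", seq_len(n))
  colnames(ranks) <- replicates %||% colnames(ranks) %||% paste0("R", seq_len(m))
  structure(list(ranks = ranks, n = n, m = m, ties = ties),
            class = "ranking_set")
}

#' Top-down concordance coefficient across replicate rankings
#'
#' Measures agreement among m replicate rankings of n factors on the savage
#' score scale, emphasizing the top-ranked factors:
#' \deqn{TDCC = \frac{\sum_{i=1}^{n}(\sum_{j=1}^{m} S_{ij})^2 - m^2 n}
#'   {m^2 (n - \sum_{i=1}^{n} 1/i)}}
#' TDCC equals 1 exactly when all replicates rank identically.  Significance
#' is assessed with \eqn{T = m (n-1)\,TDCC}, approximately chi-squared with
#' n-1 degrees of freedom under the null of independent rankings; the
#' approximation is rough for very small n and m.
#'
#' @param rankings A [ranking_set()], or a matrix acceptable to it.
#' @param ties Tie policy when \code{rankings} is a bare matrix.
#' @return Object of class \code{tdcc}: list with \code{tdcc}, \code{T},
#'   \code{df} (= n-1), \code{p_value}, the n x m \code{savage_scores}
#'   table, \code{n} and \code{m}.
#' @export
#' @examples
#' r <- cbind(a = 1:4, b = 1:4, c = c(2, 1, 3, 4))
#' tdcc(r)
tdcc <- function(rankings, ties = c("error", "mean")) {
  if (!inherits(rankings, "ranking_set"))
    rankings <- ranking_set(rankings, ties = match.arg(ties))
  n <- rankings$n; m <- rankings$m
  if (n < 2)
    stop_cropsens("TDCC needs n >= 2 factors (denominator vanishes at n = 1)",
                  class = "cropsens_rank_error")
  if (m < 2)
    stop_cropsens("TDCC needs m >= 2 replicates", class = "cropsens_rank_error")
  S <- apply(rankings$ranks, 2, savage_scores, ties = rankings$ties)
  num <- sum(rowSums(S)^2) - m^2 * n
  den <- m^2 * (n - sum(1 / seq_len(n)))
  cc <- num / den
  Tstat <- m * (n - 1) * cc
  p <- stats::pchisq(Tstat, df = n - 1, lower.tail = FALSE)
  structure(list(tdcc = cc, T = Tstat, df = n - 1L, p_value = p,
                 savage_scores = S, n = n, m = m),
            class = "tdcc")
}

#' @export
print.tdcc <- function(x, ...) {
  cat(sprintf("Top-down concordance: TDCC = %.3f over %d replicates of %d factors\n",
              x$tdcc, x$m, x$n))
  cat(sprintf("  T = %.2f ~ chi-squared(%d), p = %.3g\n", x$T, x$df, x$p_value))
  invisible(x)
}

#' Rank factors from replicate sensitivity analyses
#'
#' Builds a [ranking_set()] from a list of \code{efast} results (one per
#' replicate site or year), ranking factors by descending sensitivity index
#' for a chosen output.  Total-order indices are ranked by default.  Tied
#' indices are resolved deterministically in factor order (so every column
#' is a true permutation and identical replicates always rank identically);
#' \code{ties = "mean"} keeps Iman-Conover midranks instead.  Every tie
#' event is recorded in the result.
#'
#' @param results List of \code{efast} objects sharing one factor set.
#' @param output Output name to rank on.
#' @param index \code{"total"} (STi, default) or \code{"first"} (Si).
#' @param replicates Optional replicate labels.
#' @param ties \code{"first"} (deterministic resolution, default) or
#'   \code{"mean"} (midranks).
#' @return A \code{ranking_set}; attribute \code{"tie_events"} lists any
#'   replicates where ties were resolved.
#' @export
rank_sensitivity <- function(results, output, index = c("total", "first"),
                             replicates = NULL, ties = c("first", "mean")) {
  index <- match.arg(index)
  ties <- match.arg(ties)
  if (inherits(results, "efast")) results <- list(results)
  col <- if (index == "total") "STi" else "Si"
  base <- NULL
  ties_seen <- character(0)
  ranks <- NULL
  for (j in seq_along(results)) {
    idx <- results[[j]]$indices
    sub <- idx[idx$output == output, ]
    if (nrow(sub) == 0)
      stop_cropsens("output '", output, "' absent from replicate ", j,
                    class = "cropsens_rank_error")
    if (is.null(base)) {
      base <- sub$factor
      ranks <- matrix(NA_real_, length(base), length(results),
                      dimnames = list(base, NULL))
    } else if (!setequal(base, sub$factor)) {
      stop_cropsens("replicate ", j, " has a different factor set",
                    class = "cropsens_rank_error")
    }
    v <- sub[[col]][match(base, sub$factor)]
    r <- rank(-v, ties.method = if (ties == "mean") "average" else "first")
    if (anyDuplicated(v))
      ties_seen <- c(ties_seen, paste0("replicate ", j))
    ranks[, j] <- r
  }
  rs <- ranking_set(ranks, factors = base, replicates = replicates,
                    ties = if (ties == "mean") "mean" else "error")
  attr(rs, "tie_events") <- ties_seen
  rs
}
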