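#' Paired sign-flip permutation test
#'
#' Tests whether two aligned samples differ in mean, using the sign-flip null
#' appropriate to a paired design: under the null hypothesis the two
#' treatment labels within each pair are exchangeable, so each paired
#' difference keeps its magnitude and flips its sign independently. The
#' statistic is `mean(values_a) - mean(values_b)`.
#'
#' When `2^n_pairs` is at most `2^20` (and `n_perm` is `NULL` or
#' `"exhaustive"`), all sign assignments are enumerated and the p-value is
#' exact — the observed assignment is part of the enumeration, so `p >=
#' 2^-n_pairs` and identical samples give `p = 1`. Otherwise `n_perm` random
#' sign assignments are drawn and the add-one estimate
#' `p = (1 + #extreme) / (1 + n_perm)` reported.
#'
#' @param values_a,values_b Numeric vectors aligned pair by pair (e.g. the
#'   same colony and release order under two treatments).
#' @param n_perm `NULL`/"exhaustive" for full enumeration when feasible, or a
#'   Monte Carlo draw count.
#' @param seed Integer seed for the Monte Carlo path.
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`,
#'   referring to `mean(values_a) - mean(values_b)`.
#' @return An object of class `htest`.
#' @export
permutation_test <- function(values_a, values_b, n_perm = NULL, seed = NULL,
                             alternative = c("two.sided", "less",
                                             "greater")) {
  alternative <- match.arg(alternative)
  if (length(values_a) != length(values_b)) {
    stop("`values_a` and `values_b` must have equal length", call. = FALSE)
  }
  n <- length(values_a)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- values_a - values_b
  obs <- mean(d)
  exhaustive <- (is.null(n_perm) || identical(n_perm, "exhaustive")) &&
    n <= 20
  if (is.null(n_perm) && n > 20) n_perm <- 10000L
  if (exhaustive) {
    t_null <- as.numeric(sign_flip_matrix(n) %*% d) / n
    p <- mean(perm_extreme(t_null, obs, alternative))
    method <- sprintf("Exact paired sign-flip permutation test (2^%d flips)",
                      n)
  } else {
    n_perm <- as.integer(n_perm)
    t_null <- with_local_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                      n_perm, n)
      as.numeric(signs %*% d) / n
    })
    p <- (1 + sum(perm_extreme(t_null, obs, alternative))) / (1 + n_perm)
    method <- sprintf(
      "Monte Carlo paired sign-flip permutation test (%d draws)", n_perm)
  }
  structure(list(
    statistic = c("mean difference" = obs), p.value = p,
    alternative = alternative, method = method,
    parameter = c(n_pairs = n),
    data.name = "values_a - values_b"), class = "htest")
}

perm_extreme <- function(t_null, obs, alternative) {
  eps <- 1e-12 * max(1, abs(obs))
  switch(alternative,
         two.sided = abs(t_null) >= abs(obs) - eps,
         less = t_null <= obs + eps,
         greater = t_null >= obs - eps)
}

# All 2^n sign assignments as a (2^n) x n matrix of +-1; cached, since the
# same shape recurs across many tests.
sign_flip_matrix <- function(n) {
  key <- as.character(n)
  cached <- .trailmc_cache[[key]]
  if (!is.null(cached)) return(cached)
  m <- 2L^n
  idx <- 0:(m - 1L)
  s <- vapply(seq_len(n), function(j) 1 - 2 * (idx %/% 2L^(j - 1L) %% 2L),
              numeric(m))
  .trailmc_cache[[key]] <- s
  s
}

.trailmc_cache <- new.env(parent = emptyenv())

#' Chi-square goodness-of-fit test for categorical counts
#'
#' Pearson's statistic `sum((O - E)^2 / E)` with `E = N * expected_props`,
#' `k - 1` degrees of freedom, upper-tail p-value.
#'
#' @param counts Nonnegative integer counts.
#' @param expected_props Cell probabilities under the null; defaults to
#'   uniform. Must be strictly positive and sum to one.
#' @return An object of class `htest` with `statistic`, `parameter` (df),
#'   `p.value`, and `expected`.
#' @examples
#' chi_square_gof(c(20, 10, 5, 5))  # X-squared = 15, df = 3
#' @export
chi_square_gof <- function(counts,
                           expected_props = rep(1 / length(counts),
                                                length(counts))) {
  n_total <- sum(counts)
  if (n_total <= 0) stop("total count must be positive", call. = FALSE)
  if (any(expected_props <= 0)) {
    stop("expected proportions must be strictly positive", call. = FALSE)
  }
  if (abs(sum(expected_props) - 1) > 1e-9) {
    stop("expected proportions must sum to 1", call. = FALSE)
  }
  expected <- n_total * expected_props
  stat <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  structure(list(
    statistic = c("X-squared" = stat), parameter = c(df = df),
    p.value = stats::pchisq(stat, df, lower.tail = FALSE),
    expected = expected, method = "Chi-square goodness-of-fit test",
    data.name = deparse(substitute(counts))), class = "htest")
}

#' Exact multinomial goodness-of-fit test
#'
#' Computes the exact point-probability p-value: the total multinomial
#' probability of every outcome vector (composition of `N = sum(counts)` into
#' `length(counts)` cells) whose probability under the null is at most that
#' of the observed vector. Suited to the small samples where the chi-square
#' approximation is unreliable; the enumeration cost is
#' `choose(N + k - 1, k - 1)` outcomes, guarded by `budget`.
#'
#' @param counts Nonnegative integer counts.
#' @param probs Null cell probabilities (strictly positive, summing to one);
#'   defaults to uniform.
#' @param budget Maximum number of outcomes to enumerate before refusing
#'   (with a suggestion to use [chi_square_gof()] instead).
#' @return An object of class `htest`.
#' @examples
#' exact_multinomial_test(c(2, 0))  # p = 0.5
#' @export
exact_multinomial_test <- function(counts,
                                   probs = rep(1 / length(counts),
                                               length(counts)),
                                   budget = 1e6) {
  k <- length(counts)
  n_total <- sum(counts)
  if (n_total < 1) stop("need at least one observation", call. = FALSE)
  if (any(probs <= 0) || abs(sum(probs) - 1) > 1e-9) {
    stop("`probs` must be strictly positive and sum to 1", call. = FALSE)
  }
  if (k != length(probs)) stop("`counts`/`probs` length mismatch",
                               call. = FALSE)
  n_outcomes <- choose(n_total + k - 1, k - 1)
  if (n_outcomes > budget) {
    stop(sprintf(paste0(
      "enumeration of %.0f outcomes exceeds the budget of %.0f; ",
      "consider chi_square_gof() for samples this large"),
      n_outcomes, budget), call. = FALSE)
  }
  p <- if (k == 1) 1 else emt_pvalue(counts, probs)
  structure(list(
    statistic = c(outcomes = n_outcomes), p.value = p,
    method = "Exact multinomial test (point-probability ordering)",
    data.name = deparse(substitute(counts))), class = "htest")
}

# Sum multinomial probabilities over all compositions with probability at
# most that of the observed vector. The first k-2 cells are enumerated
# recursively; the last two are vectorized.
emt_pvalue <- function(counts, probs, tol = 1e-9) {
  k <- length(counts)
  n_total <- sum(counts)
  lp <- log(probs)
  lg_n <- lgamma(n_total + 1)
  logp_obs <- lg_n - sum(lgamma(counts + 1)) + sum(counts * lp)
  total <- 0
  rec <- function(prefix_lg, prefix_lp, m, j) {
    if (j == k - 1L) {
      a <- 0:m
      b <- m - a
      lq <- lg_n + prefix_lg - lgamma(a + 1) - lgamma(b + 1) + prefix_lp +
        a * lp[k - 1L] + b * lp[k]
      q <- exp(lq)
      total <<- total + sum(q[lq <= logp_obs + tol])
    } else {
      for (v in 0:m) {
        rec(prefix_lg - lgamma(v + 1), prefix_lp + v * lp[j], m - v, j + 1L)
      }
    }
  }
  rec(0, 0, n_total, 1L)
  min(1, total)
}
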