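## Monte-Carlo (approximative) permutation tests with resample-based
## standardisation: Z = (T - mean(T*)) / sd(T*), two-sided p via the
## add-one estimator (b + 1) / (B + 1). With `exact = TRUE` the admissible
## permutation group is enumerated and p is the exact tail proportion.

mc_result <- function(method, data.name, Z, p, B, seed, extra = NULL) {
  out <- c(list(statistic = c(Z = Z), p.value = p,
                parameter = c(resamples = B),
                method = method, data.name = data.name, seed = seed),
           extra)
  class(out) <- c("mc_permutation_test", "htest")
  out
}

#' Monte-Carlo Wilcoxon-Pratt signed-rank test
#'
#' Paired two-sided test. Differences are ranked by absolute value with
#' zeros included (Pratt), zero-difference ranks are then discarded from
#' the statistic `T = sum(sign(d) * rank|d|)`; the null is generated by
#' random sign flips of the non-zero ranks.
#'
#' @param x,y paired numeric vectors (or `y = NULL` and `x` already the
#'   differences).
#' @param B number of Monte-Carlo resamples (default 19999).
#' @param seed RNG seed for reproducibility.
#' @param exact if `TRUE`, enumerate all `2^m` sign patterns (m = number of
#'   non-zero differences, capped at 20) and report the exact permutation
#'   p-value.
#' @return an object of classes `mc_permutation_test` and `htest`.
#' @export
signed_rank_pratt_mc <- function(x, y = NULL, B = 19999, seed = 1L,
                                 exact = FALSE) {
  d <- if (is.null(y)) x else x - y
  stopifnot(length(d) >= 1, all(is.finite(d)))
  r <- rank(abs(d))              # Pratt: zeros participate in ranking
  nz <- d != 0
  if (!any(nz))
    return(mc_result("Monte-Carlo Wilcoxon-Pratt signed-rank test",
                     deparse(substitute(x)), 0, 1, B, seed))
  rr <- r[nz]; Tobs <- sum(sign(d[nz]) * rr)
  m <- length(rr)
  if (exact) {
    if (m > 20) stop_input("exact enumeration limited to 20 non-zero pairs")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
    Tstar <- as.vector(signs %*% rr)
    p <- mean(abs(Tstar) >= abs(Tobs) - 1e-12)
    Z <- (Tobs - mean(Tstar)) / stats::sd(Tstar)
    return(mc_result("Exact Wilcoxon-Pratt signed-rank test",
                     deparse(substitute(x)), Z, p, length(Tstar), seed))
  }
  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), m * B, replace = TRUE), m, B)
    Tstar <- as.vector(rr %*% signs)
    mu <- mean(Tstar); sdv <- stats::sd(Tstar)
    Z <- if (sdv > 0) (Tobs - mu) / sdv else 0
    p <- (sum(abs(Tstar - mu) >= abs(Tobs - mu) - 1e-12) + 1) / (B + 1)
    mc_result("Monte-Carlo Wilcoxon-Pratt signed-rank test",
              deparse(substitute(x)), Z, min(p, 1), B, seed)
  })
}

## within-stratum mid-ranks
strat_ranks <- function(v, strata) {
  r <- numeric(length(v))
  for (s in unique(strata)) { i <- strata == s; r[i] <- rank(v[i]) }
  r
}

#' Monte-Carlo stratified Wilcoxon-Mann-Whitney test
#'
#' Two-sample rank-sum test with ranks computed within strata (mid-ranks
#' for ties); the null shuffles group labels independently within each
#' stratum. A stratum containing only one group contributes no permutation
#' variance (a message is emitted).
#'
#' @param values numeric outcomes.
#' @param groups two-level factor/vector of group labels.
#' @param strata stratum labels (e.g. flock).
#' @param B,seed,exact as in [signed_rank_pratt_mc()]; `exact` enumerates
#'   all within-stratum label assignments (product of binomial
#'   coefficients, capped at 1e5).
#' @return `mc_permutation_test` / `htest` object.
#' @export
mwu_stratified_mc <- function(values, groups, strata, B = 19999, seed = 1L,
                              exact = FALSE) {
  stopifnot(length(values) == length(groups), length(values) == length(strata))
  g <- factor(groups)
  if (nlevels(g) != 2) stop_input("groups must have exactly 2 levels")
  mixed <- vapply(split(g, strata), function(x) length(unique(x)) > 1, TRUE)
  if (!any(mixed)) stop_input("no stratum contains both groups")
  if (any(!mixed))
    message(sum(!mixed), " stratum/strata contain a single group; they add no permutation variance")
  r <- strat_ranks(values, strata)
  ind <- as.numeric(g == levels(g)[1])
  Tobs <- sum(ind * r)
  strat_list <- split(seq_along(r), strata)
  if (exact) {
    assigns <- lapply(strat_list, function(idx) {
      n1 <- sum(ind[idx])
      utils::combn(length(idx), n1, simplify = FALSE)
    })
    n_tot <- prod(vapply(assigns, length, 1L))
    if (n_tot > 1e5) stop_input("exact enumeration too large (%d assignments)", n_tot)
    gridix <- expand.grid(lapply(assigns, seq_along))
    Tstar <- apply(gridix, 1, function(row) {
      tot <- 0
      for (k in seq_along(strat_list)) {
        idx <- strat_list[[k]]
        tot <- tot + sum(r[idx][assigns[[k]][[row[k]]]])
      }
      tot
    })
    mu <- mean(Tstar); sdv <- stats::sd(Tstar)
    Z <- if (sdv > 0) (Tobs - mu) / sdv else 0
    p <- mean(abs(Tstar - mu) >= abs(Tobs - mu) - 1e-12)
    return(mc_result("Exact stratified Wilcoxon-Mann-Whitney test",
                     deparse(substitute(values)), Z, p, length(Tstar), seed))
  }
  with_seed(seed, {
    Tstar <- numeric(B)
    for (b in seq_len(B)) {
      tot <- 0
      for (idx in strat_list) {
        ii <- ind[idx][sample.int(length(idx))]
        tot <- tot + sum(ii * r[idx])
      }
      Tstar[b] <- tot
    }
    mu <- mean(Tstar); sdv <- stats::sd(Tstar)
    Z <- if (sdv > 0) (Tobs - mu) / sdv else 0
    p <- (sum(abs(Tstar - mu) >= abs(Tobs - mu) - 1e-12) + 1) / (B + 1)
    mc_result("Monte-Carlo stratified Wilcoxon-Mann-Whitney test",
              deparse(substitute(values)), Z, min(p, 1), B, seed)
  })
}

#' Monte-Carlo stratified Spearman correlation test
#'
#' Spearman correlation computed on within-stratum ranks of x and y; the
#' null permutes y within strata.
#'
#' @param x,y numeric vectors.
#' @param strata stratum labels.
#' @param B,seed,exact as in [mwu_stratified_mc()]; `exact` enumerates the
#'   within-stratum permutations of y (capped at 1e5).
#' @return list with `r_S` (the stratified Spearman coefficient) and
#'   `test` (an `mc_permutation_test`).
#' @export
spearman_stratified_mc <- function(x, y, strata, B = 19999, seed = 1L,
                                   exact = FALSE) {
  stopifnot(length(x) == length(y), length(x) == length(strata), length(x) >= 3)
  rx <- strat_ranks(x, strata); ry <- strat_ranks(y, strata)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop_input("x or y constant within all strata; Spearman undefined")
  r_S <- stats::cor(rx, ry)
  Tobs <- sum(rx * ry)
  strat_list <- split(seq_along(rx), strata)
  if (exact) {
    perms_of <- function(n) {
      if (n == 1) return(list(1L))
      out <- list()
      for (p in perms_of(n - 1)) for (k in seq_len(n))
        out[[length(out) + 1L]] <- append(p, n, after = k - 1)
      out
    }
    per_str <- lapply(strat_list, function(idx) perms_of(length(idx)))
    n_tot <- prod(vapply(per_str, length, 1L))
    if (n_tot > 1e5) stop_input("exact enumeration too large (%d permutations)", n_tot)
    gridix <- expand.grid(lapply(per_str, seq_along))
    Tstar <- apply(gridix, 1, function(row) {
      tot <- 0
      for (k in seq_along(strat_list)) {
        idx <- strat_list[[k]]
        tot <- tot + sum(rx[idx] * ry[idx][per_str[[k]][[row[k]]]])
      }
      tot
    })
    mu <- mean(Tstar); sdv <- stats::sd(Tstar)
    Z <- if (sdv > 0) (Tobs - mu) / sdv else 0
    p <- mean(abs(Tstar - mu) >= abs(Tobs - mu) - 1e-12)
    return(list(r_S = r_S,
                test = mc_result("Exact stratified Spearman correlation test",
                                 "x vs y", Z, p, length(Tstar), seed)))
  }
  with_seed(seed, {
    Tstar <- numeric(B)
    for (b in seq_len(B)) {
      tot <- 0
      for (idx in strat_list)
        tot <- tot + sum(rx[idx] * ry[idx][sample.int(length(idx))])
      Tstar[b] <- tot
    }
    mu <- mean(Tstar); sdv <- stats::sd(Tstar)
    Z <- if (sdv > 0) (Tobs - mu) / sdv else 0
    p <- (sum(abs(Tstar - mu) >= abs(Tobs - mu) - 1e-12) + 1) / (B + 1)
    list(r_S = r_S,
         test = mc_result("Monte-Carlo stratified Spearman correlation test",
                          "x vs y", Z, min(p, 1), B, seed))
  })
}

#' Exact two-sided binomial test (minimum-likelihood method)
#'
#' Two-sided p-value equal to the total Binomial(n, p0) mass of all
#' outcomes whose point probability does not exceed that of the observed
#' count (within 1e-7 relative tolerance).
#'
#' @param x observed successes.
#' @param n trials.
#' @param p0 null success probability.
#' @return scalar p-value.
#' @examples
#' exact_binomial_two_sided(6, 19, 0.2)  # 0.246
#' @export
exact_binomial_two_sided <- function(x, n, p0) {
  if (!(is.numeric(x) && is.numeric(n) && x >= 0 && x <= n && n >= 1))
    stop_input("need 0 <= x <= n")
  if (!(p0 > 0 && p0 < 1)) stop_input("p0 must be in (0, 1)")
  d <- stats::dbinom(0:n, n, p0)
  min(1, sum(d[d <= stats::dbinom(x, n, p0) * (1 + 1e-7)]))
}

#' Per-patch descriptive summaries
#'
#' Mean and sample SD (n - 1), across flocks, of: first-feeder discovery
#' time, average-bird discovery time, and the number of birds that
#' discovered the patch; optional extras (first-approach time, seed mass
#' taken, aggression counts) are summarised the same way per patch rank.
#'
#' @param diffusions a `diffusion_set`.
#' @param extras optional data.frame with `flock_id`, `patch_rank` and
#'   additional numeric columns.
#' @return data.frame, one row per patch rank.
#' @export
patch_descriptives <- function(diffusions, extras = NULL) {
  out <- lapply(sort(unique(diffusions$patch_rank)), function(p) {
    dp <- diffusions[diffusions$patch_rank == p, ]
    per_flock <- lapply(split(dp, dp$flock_id), function(d) {
      fed <- d[!d$censored, ]
      c(first_feeder_s = if (nrow(fed)) min(fed$latency_s) else NA_real_,
        average_bird_s = if (nrow(fed)) mean(fed$latency_s) else NA_real_,
        n_discovered = nrow(fed))
    })
    m <- do.call(rbind, per_flock)
    row <- data.frame(patch_rank = p)
    for (cn in colnames(m)) {
      row[[paste0(cn, "_mean")]] <- mean(m[, cn], na.rm = TRUE)
      row[[paste0(cn, "_sd")]] <- stats::sd(m[, cn], na.rm = TRUE)
    }
    if (!is.null(extras)) {
      ex <- extras[extras$patch_rank == p, , drop = FALSE]
      for (cn in setdiff(names(ex), c("flock_id", "patch_rank"))) {
        row[[paste0(cn, "_mean")]] <- mean(ex[[cn]], na.rm = TRUE)
        row[[paste0(cn, "_sd")]] <- stats::sd(ex[[cn]], na.rm = TRUE)
      }
    }
    row
  })
  do.call(rbind, out)
}
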