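#' Assign first-/second-discovered patch strata
#'
#' Within each flock the physical patch with the earlier first (uncensored)
#' feeding latency becomes patch rank 1, the other rank 2. A patch never
#' fed from is rank 2 by convention (its diffusion has zero acquisitions
#' and all-naive censoring). A tie in first latencies is an error unless a
#' tie-break is configured.
#'
#' @param raw data.frame with columns `flock_id`, `patch` (physical patch
#'   label), `bird_id`, `latency_s`, `censored` (logical).
#' @param censor_time_s the censoring horizon carried by censored records.
#' @param tie_break `"error"` (default) or `"patch_label"` (earlier label
#'   wins).
#' @return a `diffusion_set` data.frame (`flock_id`, `patch_rank`,
#'   `bird_id`, `latency_s`, `censored`) ordered by stratum and latency.
#' @export
assign_patch_strata <- function(raw, censor_time_s = max(raw$latency_s),
                                tie_break = c("error", "patch_label")) {
  tie_break <- match.arg(tie_break)
  need <- c("flock_id", "patch", "bird_id", "latency_s", "censored")
  if (!all(need %in% names(raw)))
    stop_input("latency table needs columns %s", paste(need, collapse = ", "))
  out <- vector("list", 0L)
  for (f in unique(raw$flock_id)) {
    d <- raw[raw$flock_id == f, ]
    patches <- sort(unique(d$patch))
    if (length(patches) > 2) stop_input("flock %s has more than 2 patches", f)
    first <- vapply(patches, function(p) {
      lat <- d$latency_s[d$patch == p & !d$censored]
      if (length(lat)) min(lat) else Inf
    }, 0)
    if (length(patches) == 2 && first[1] == first[2] && is.finite(first[1])) {
      if (tie_break == "error")
        stop_input("flock %s: tied first-feeding latencies; set tie_break", f)
    }
    rank_of <- rank(first, ties.method = "first")
    for (k in seq_along(patches)) {
      dp <- d[d$patch == patches[k], ]
      dp <- dp[order(dp$latency_s, dp$bird_id), ]
      out[[length(out) + 1L]] <- data.frame(
        flock_id = f, patch_rank = as.integer(rank_of[k]),
        bird_id = dp$bird_id, latency_s = dp$latency_s,
        censored = dp$censored, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$patch_rank, res$flock_id, res$latency_s, res$bird_id), ]
  rownames(res) <- NULL
  attr(res, "censor_time_s") <- censor_time_s
  class(res) <- c("diffusion_set", "data.frame")
  res
}

#' Social exposure of a naive bird
#'
#' \eqn{T_i = \sum_{j \ne i} a_{ij} w_j z_j}: the bird's connection to each
#' informed flock-mate, weighted by that demonstrator's transmission
#' weight. `a` follows the stored orientation (row i = rate at which i
#' follows j); pass `orientation = "transpose"` to use the rate at which j
#' follows i instead.
#'
#' @param A flock weight matrix (rows = follower).
#' @param status named 0/1 vector of informed status over the flock.
#' @param weights named transmission weights over the flock.
#' @param bird focal naive bird id.
#' @param orientation `"following"` (default) or `"transpose"`.
#' @return scalar exposure.
#' @export
social_exposure <- function(A, status, weights, bird,
                            orientation = c("following", "transpose")) {
  orientation <- match.arg(orientation)
  if (orientation == "transpose") A <- t(A)
  j <- setdiff(colnames(A), bird)
  sum(A[bird, j] * weights[j] * status[j])
}

#' Next-acquirer probabilities in a risk set
#'
#' Under the multiplicative model the probability that bird i is the next
#' acquirer among the risk set is \eqn{p_i = \lambda_i / \sum_r \lambda_r}
#' with \eqn{\lambda_i = e^{\eta_i} (1 + s T_i)}; the stratum baseline
#' cancels.
#'
#' @param eta linear predictor (covariates plus any frailty) per risk-set
#'   member.
#' @param exposure social exposure T per member.
#' @param s nonnegative social-transmission parameter of the stratum.
#' @return probability vector summing to 1.
#' @export
next_acquirer_probabilities <- function(eta, exposure, s) {
  stopifnot(length(eta) == length(exposure), s >= 0)
  lam <- exp(eta) * (1 + s * exposure)
  if (!any(lam > 0) || any(!is.finite(lam)))
    stop_input("degenerate hazards in risk set")
  lam / sum(lam)
}

## --- internal: model preparation -----------------------------------------

## Precomputes, per stratum, everything the partial likelihood needs:
## member table, full covariate matrix, event order, risk masks and the
## exposure matrix (data-determined once the acquisition order is fixed).
prepare_oada <- function(diffusions, networks, roster,
                         pooling = c("patch", "flock_by_patch"),
                         orientation = c("following", "transpose")) {
  pooling <- match.arg(pooling)
  orientation <- match.arg(orientation)
  stopifnot(inherits(networks, "follow_nets"))
  need <- c("flock_id", "patch_rank", "bird_id", "latency_s", "censored")
  if (!all(need %in% names(diffusions)))
    stop_input("diffusion set needs columns %s", paste(need, collapse = ", "))
  if (!all(diffusions$bird_id %in% roster$bird_id))
    stop_input("diffusion set references birds absent from roster")
  if (any(roster$informed[match(diffusions$bird_id[!diffusions$censored],
                                roster$bird_id)]))
    stop_input("informed demonstrators cannot appear as acquirers")

  Xall <- cbind(age = roster$age, sexM = as.numeric(roster$sex == "M"),
                feeding_activity = roster$feeding_activity)
  rownames(Xall) <- roster$bird_id
  w <- stats::setNames(roster$transmission_weight, roster$bird_id)
  informed <- stats::setNames(roster$informed, roster$bird_id)

  key <- if (pooling == "patch") diffusions$patch_rank
         else paste(diffusions$flock_id, diffusions$patch_rank, sep = ":")
  strata <- lapply(split(seq_len(nrow(diffusions)), key), function(idx) {
    d <- diffusions[idx, ]
    patch <- unique(d$patch_rank); stopifnot(length(patch) == 1L)
    members <- unique(d$bird_id)      # naive birds of the stratum
    fl <- roster$flock_id[match(members, roster$bird_id)]
    ev <- d[!d$censored, ]
    ev <- ev[order(ev$latency_s, ev$flock_id, ev$bird_id), ]
    ties <- anyDuplicated(ev$latency_s) > 0
    E <- nrow(ev); n <- length(members)
    risk <- matrix(TRUE, E, n, dimnames = list(NULL, members))
    Texp <- matrix(0, E, n, dimnames = list(NULL, members))
    acq_idx <- match(ev$bird_id, members)
    ## per-flock informed status evolves as the stratum's events unfold
    z <- lapply(unique(fl), function(f) {
      birds <- roster$bird_id[roster$flock_id == f]
      stats::setNames(as.numeric(informed[birds]), birds)
    })
    names(z) <- unique(fl)
    Amat <- lapply(unique(fl), function(f) {
      A <- networks$adj[[f]]
      if (is.null(A)) stop_input("no network for flock %s", f)
      if (orientation == "transpose") t(A) else A
    })
    names(Amat) <- unique(fl)
    if (E > 0) {
      for (f in unique(fl)) {
        m <- members[fl == f]; cn <- colnames(Amat[[f]])
        Texp[1, m] <- drop(Amat[[f]][m, , drop = FALSE] %*% (w[cn] * z[[f]][cn]))
      }
      if (E > 1) for (e in seq_len(E - 1L)) {
        a_bird <- ev$bird_id[e]; a_fl <- ev$flock_id[e]
        z[[a_fl]][a_bird] <- 1
        Texp[e + 1L, ] <- Texp[e, ]
        m <- members[fl == a_fl]; cn <- colnames(Amat[[a_fl]])
        Texp[e + 1L, m] <- drop(Amat[[a_fl]][m, , drop = FALSE] %*%
                                  (w[cn] * z[[a_fl]][cn]))
      }
      for (e in seq_len(E)) if (e > 1L)
        risk[e, acq_idx[seq_len(e - 1L)]] <- FALSE
    }
    list(patch_rank = patch, members = members, flock = fl,
         X = Xall[members, , drop = FALSE], events = ev, acq_idx = acq_idx,
         risk = risk, Texp = Texp, ties = ties)
  })
  n_events <- sum(vapply(strata, function(s) nrow(s$events), 0L))
  if (any(vapply(strata, function(s) s$ties, TRUE)))
    message("latency ties present; broken by (flock, bird) lexicographic order")
  structure(list(strata = strata, n_events = n_events,
                 covnames = colnames(Xall), pooling = pooling,
                 orientation = orientation,
                 roster = roster), class = "oada_prep")
}

## s value applying to a given patch rank under a scenario.
## s_par is the vector of free s parameters (length 0, 1 or 2).
s_for_patch <- function(scenario, patch_rank, s_par) {
  switch(scenario,
    asocial       = 0,
    shared_s      = s_par[1],
    separate_s    = s_par[patch_rank],
    s_patch1_only = if (patch_rank == 1) s_par[1] else 0,
    s_patch2_only = if (patch_rank == 2) s_par[1] else 0,
    stop_input("unknown scenario '%s'", scenario))
}

n_s_params <- function(scenario)
  switch(scenario, asocial = 0L, shared_s = 1L, separate_s = 2L,
         s_patch1_only = 1L, s_patch2_only = 1L,
         stop_input("unknown scenario '%s'", scenario))
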