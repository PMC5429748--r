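#' Define a synthetic flock scenario
#'
#' Bundles every parameter of the synthetic study system: flock composition,
#' true social-transmission parameters per patch, covariate effects, random
#' effect variances, patch baseline discovery rates, the censoring horizon
#' and the pre-training observation window. Defaults emulate ten captive
#' flocks of ten birds (5 males, 5 females) with two informed demonstrators
#' per flock, two hidden food patches, and a trial horizon of 30420 s.
#'
#' @param n_flocks number of flocks.
#' @param flock_size birds per flock.
#' @param n_informed_per_flock informed demonstrators per flock (one of each
#'   sex while both remain).
#' @param s_true length-2 nonnegative vector: social-transmission parameter
#'   at the first- and second-discovered patch (units: inverse of network
#'   edge rate, i.e. hours per following).
#' @param beta_true named numeric vector of covariate effects on the log
#'   acquisition rate; names among `age`, `sexM`, `feeding_activity`.
#' @param sigma_flock2,sigma_ind2 variances of the flock and
#'   individual-within-flock log-normal frailties.
#' @param baseline_rates length-2 positive vector, asocial acquisition rate
#'   per bird per second at the two patches.
#' @param censor_time_s trial horizon in seconds.
#' @param pretrain_duration_h observation hours of the pre-training feeder
#'   recordings.
#' @param init_rate_per_h mean arrival-initiation rate per bird (events/h);
#'   per-bird rates are this value times a Gamma(shape, scale) draw
#'   normalised to mean 1.
#' @param sociability_shape,sociability_scale Gamma parameters of the
#'   per-bird sociability multipliers (initiation rate and following
#'   propensity).
#' @param follow_prob probability that a given flock-mate follows an
#'   initiator within the 5-s window (scaled per bird by sociability).
#' @param nonfollow_prob probability of a trailing arrival in the (5, 30] s
#'   band that does not constitute a following.
#' @param group_arrival_prob probability that an initiation event is instead
#'   a group arrival (>= 2 birds at the identical timestamp, no initiator).
#' @param seed integer seed; all generator functions derive their streams
#'   from it via [derive_seed()].
#' @return an object of class `flock_scenario`.
#' @examples
#' sc <- flock_scenario(n_flocks = 2, seed = 42)
#' sc
#' @export
flock_scenario <- function(n_flocks = 10L,
                           flock_size = 10L,
                           n_informed_per_flock = 2L,
                           s_true = c(1.5, 0),
                           beta_true = c(sexM = 0.4),
                           sigma_flock2 = 0,
                           sigma_ind2 = 0,
                           baseline_rates = c(2e-5, 8e-6),
                           censor_time_s = 30420,
                           pretrain_duration_h = 20,
                           init_rate_per_h = 3,
                           sociability_shape = 2,
                           sociability_scale = 1,
                           follow_prob = 0.25,
                           nonfollow_prob = 0.10,
                           group_arrival_prob = 0.05,
                           seed = 1L) {
  if (n_flocks < 1 || flock_size < 2)
    stop_input("need at least 1 flock of >= 2 birds")
  if (n_informed_per_flock < 1 || n_informed_per_flock >= flock_size)
    stop_input("n_informed_per_flock must be in [1, flock_size - 1]")
  if (length(s_true) != 2 || any(!is.finite(s_true)) || any(s_true < 0))
    stop_input("s_true must be two finite nonnegative values")
  if (length(baseline_rates) != 2 || any(baseline_rates <= 0) ||
      any(!is.finite(baseline_rates)))
    stop_input("baseline_rates must be two finite positive rates")
  if (censor_time_s <= 0) stop_input("censor_time_s must be positive")
  if (pretrain_duration_h <= 0) stop_input("pretrain_duration_h must be positive")
  if (sigma_flock2 < 0 || sigma_ind2 < 0)
    stop_input("random-effect variances must be nonnegative")
  if (!is.null(names(beta_true)) &&
      !all(names(beta_true) %in% c("age", "sexM", "feeding_activity")))
    stop_input("beta_true names must be among age, sexM, feeding_activity")
  structure(list(
    n_flocks = as.integer(n_flocks), flock_size = as.integer(flock_size),
    n_informed_per_flock = as.integer(n_informed_per_flock),
    s_true = as.numeric(s_true), beta_true = beta_true,
    sigma_flock2 = sigma_flock2, sigma_ind2 = sigma_ind2,
    baseline_rates = as.numeric(baseline_rates),
    censor_time_s = censor_time_s,
    pretrain_duration_h = pretrain_duration_h,
    init_rate_per_h = init_rate_per_h,
    sociability_shape = sociability_shape,
    sociability_scale = sociability_scale,
    follow_prob = follow_prob, nonfollow_prob = nonfollow_prob,
    group_arrival_prob = group_arrival_prob,
    seed = as.integer(seed)), class = "flock_scenario")
}

#' @export
print.flock_scenario <- function(x, ...) {
  cat("Synthetic flock scenario\n")
  cat(sprintf("  %d flocks x %d birds (%d informed/flock), seed %d\n",
              x$n_flocks, x$flock_size, x$n_informed_per_flock, x$seed))
  cat(sprintf("  s = (%.3g, %.3g); beta: %s; sigma2 = (%.3g, %.3g)\n",
              x$s_true[1], x$s_true[2],
              if (length(x$beta_true)) paste(names(x$beta_true), "=",
                                             signif(x$beta_true, 3),
                                             collapse = ", ") else "none",
              x$sigma_flock2, x$sigma_ind2))
  cat(sprintf("  baseline rates %.3g, %.3g /s; censored at %g s\n",
              x$baseline_rates[1], x$baseline_rates[2], x$censor_time_s))
  invisible(x)
}

#' Generate a bird roster for a scenario
#'
#' Creates the per-bird table: flock, sex (balanced as evenly as the flock
#' size allows), age in years, informed flag (informed birds alternate sex),
#' and per-bird latent sociability multipliers used by the arrival-log
#' generator. Feeding activity and transmission weights are filled in later
#' from the pre-training log (see [count_total_visits()] and
#' [transmission_weights()]).
#'
#' @param scenario a [flock_scenario()].
#' @return a `data.frame` of class `bird_roster` with columns `bird_id`,
#'   `flock_id`, `sex`, `age`, `informed`, `sociability_init`,
#'   `sociability_follow`, `feeding_activity`, `transmission_weight`.
#' @export
generate_roster <- function(scenario) {
  stopifnot(inherits(scenario, "flock_scenario"))
  with_seed(derive_seed(scenario$seed, 1L), {
    nF <- scenario$n_flocks; nB <- scenario$flock_size
    flock_id <- rep(sprintf("f%02d", seq_len(nF)), each = nB)
    bird_id <- sprintf("%s_b%02d", flock_id, rep(seq_len(nB), nF))
    nM <- ceiling(nB / 2)
    sex <- rep(c(rep("M", nM), rep("F", nB - nM)), nF)
    age <- round(stats::runif(nF * nB, 1, 6), 1)
    informed <- logical(nF * nB)
    for (f in seq_len(nF)) {
      idx <- which(flock_id == sprintf("f%02d", f))
      males <- idx[sex[idx] == "M"]; females <- idx[sex[idx] == "F"]
      ## informed birds alternate sex: one male, one female, then cycle
      pick <- integer(0); m <- 1L; fe <- 1L
      for (k in seq_len(scenario$n_informed_per_flock)) {
        if (k %% 2 == 1 && m <= length(males)) { pick <- c(pick, males[m]); m <- m + 1L }
        else if (fe <= length(females)) { pick <- c(pick, females[fe]); fe <- fe + 1L }
        else { pick <- c(pick, males[m]); m <- m + 1L }
      }
      informed[pick] <- TRUE
    }
    g <- function(n) {
      x <- stats::rgamma(n, shape = scenario$sociability_shape,
                         scale = scenario$sociability_scale)
      x / (scenario$sociability_shape * scenario$sociability_scale)
    }
    out <- data.frame(
      bird_id = bird_id, flock_id = flock_id, sex = sex, age = age,
      informed = informed,
      sociability_init = g(nF * nB), sociability_follow = g(nF * nB),
      feeding_activity = NA_real_, transmission_weight = NA_real_,
      stringsAsFactors = FALSE)
    class(out) <- c("bird_roster", "data.frame")
    out
  })
}

#' Generate a pre-training arrival log with planted following events
#'
#' Simulates feeder arrivals per flock over the pre-training observation
#' window. Each bird initiates visits as a Poisson process (rate
#' `init_rate_per_h` times its sociability multiplier); at each initiation,
#' every flock-mate independently follows within (0, 5) s with its
#' following probability, and trails in the (5, 30) s band (a non-following
#' visit) with probability `nonfollow_prob`. A fraction of initiations are
#' group arrivals: two or more birds at the identical timestamp with no
#' initiator. Event blocks are spaced so that the 5-s windowing rule
#' recovers the planted follower pairs exactly; the planted events are
#' attached as attribute `"truth"` (a data.frame `flock_id`, `initiator`,
#' `follower`, `time_s`) and planted per-bird arrival counts as attribute
#' `"visits"`.
#'
#' @param roster a `bird_roster`.
#' @param scenario the [flock_scenario()] that produced it.
#' @return a `data.frame` (class `arrival_log`) with columns `flock_id`,
#'   `bird_id`, `timestamp_s`, `location`, sorted by flock and time.
#' @export
generate_pretraining_log <- function(roster, scenario) {
  stopifnot(inherits(roster, "bird_roster"), inherits(scenario, "flock_scenario"))
  with_seed(derive_seed(scenario$seed, 2L), {
    dur_s <- scenario$pretrain_duration_h * 3600
    rows <- vector("list", 0L); truth <- vector("list", 0L)
    for (f in unique(roster$flock_id)) {
      rb <- roster[roster$flock_id == f, ]
      n <- nrow(rb)
      rate_s <- scenario$init_rate_per_h * rb$sociability_init / 3600
      ## merged initiation process over birds
      n_init <- stats::rpois(n, rate_s * dur_s)
      if (sum(n_init) == 0) next
      init_bird <- rep(rb$bird_id, n_init)
      init_time <- stats::runif(sum(n_init), 0, dur_s)
      o <- order(init_time)
      init_bird <- init_bird[o]; init_time <- sort(init_time)
      ## push blocks apart so windows never overlap (keeps planted events
      ## exactly recoverable); spacing preserves the number of arrivals
      min_gap <- 42 + 9.5 * n  # upper bound on a block's span plus 6 s clearance
      for (k in seq_along(init_time)[-1])
        if (init_time[k] - init_time[k - 1] < min_gap)
          init_time[k] <- init_time[k - 1] + min_gap + stats::runif(1, 0, 2)
      nb <- length(init_time)
      a_bird <- vector("list", nb); a_time <- vector("list", nb)
      t_init <- vector("list", nb); t_fol <- vector("list", nb)
      t_time <- vector("list", nb)
      is_group <- stats::runif(nb) < scenario$group_arrival_prob
      for (k in seq_len(nb)) {
        t0 <- init_time[k]; b0 <- init_bird[k]
        oth <- rb$bird_id != b0
        ob <- rb$bird_id[oth]
        if (is_group[k] && length(ob) >= 1) {
          ## group arrival: no initiator, no events
          k_extra <- sample(length(ob), size = min(length(ob),
                                                   1 + stats::rpois(1, 0.5)))
          a_bird[[k]] <- c(b0, ob[k_extra])
          a_time[[k]] <- rep(t0, 1 + length(k_extra))
          next
        }
        p_fol <- pmin(1, scenario$follow_prob * rb$sociability_follow[oth])
        take <- stats::runif(length(ob)) < p_fol
        fol <- ob[take]
        fol_off <- sort(stats::runif(length(fol), 0.5, 4.5))
        rest <- ob[!take]
        nf <- rest[stats::runif(length(rest)) < scenario$nonfollow_prob]
        nf_off <- numeric(length(nf))
        if (length(nf)) {
          if (length(fol)) {
            ## chain trailing arrivals off the last follower: each within
            ## 5 s of the previous arrival (so none opens a window) but
            ## > 5 s after the initiator (so none is a follower)
            cur <- max(5.05, max(fol_off) + 1.0)
            steps <- stats::runif(length(nf), 1, 4.4)
          } else {
            ## no followers: space trailing arrivals >= 6 s apart (each a
            ## solo arrival; opens a window but has no followers)
            cur <- stats::runif(1, 6, 8)
            steps <- stats::runif(length(nf), 6, 9)
          }
          nf_off <- cur + c(0, cumsum(steps))[seq_along(nf)]
        }
        a_bird[[k]] <- c(b0, fol, nf)
        a_time[[k]] <- t0 + c(0, fol_off, nf_off)
        if (length(fol)) {
          t_init[[k]] <- rep(b0, length(fol)); t_fol[[k]] <- fol
          t_time[[k]] <- t0 + fol_off
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        flock_id = f, bird_id = unlist(a_bird),
        timestamp_s = unlist(a_time), stringsAsFactors = FALSE)
      if (length(unlist(t_fol)))
        truth[[length(truth) + 1L]] <- data.frame(
          flock_id = f, initiator = unlist(t_init), follower = unlist(t_fol),
          time_s = unlist(t_time), stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, TRUE)]
    log <- if (length(rows)) do.call(rbind, rows) else
      data.frame(flock_id = character(), bird_id = character(),
                 timestamp_s = numeric(), stringsAsFactors = FALSE)
    log$location <- rep("central_feeder", nrow(log))
    log <- log[order(log$flock_id, log$timestamp_s, log$bird_id), ]
    rownames(log) <- NULL
    tr <- truth[!vapply(truth, is.null, TRUE)]
    tr <- if (length(tr)) do.call(rbind, tr) else
      data.frame(flock_id = character(), initiator = character(),
                 follower = character(), time_s = numeric(),
                 stringsAsFactors = FALSE)
    tr <- tr[order(tr$flock_id, tr$time_s), ]; rownames(tr) <- NULL
    visits <- table(factor(log$bird_id, levels = roster$bird_id))
    attr(log, "truth") <- tr
    attr(log, "visits") <- stats::setNames(as.integer(visits), roster$bird_id)
    class(log) <- c("arrival_log", "data.frame")
    log
  })
}

#' Simulate two-patch trait diffusions on following networks
#'
#' Sequential (Gillespie) simulation of the multiplicative
#' social-transmission model. Within each flock and patch stratum, every
#' naive bird i carries hazard
#' \deqn{\lambda_i = \lambda_{0,patch} \exp(\beta' x_i + u_{flock} + v_i)
#'   (1 + s_{patch} T_i), \quad T_i = \sum_j a_{ij} w_j z_j,}
#' where \eqn{a_{ij}} is i's following rate toward j, \eqn{w_j} the
#' transmission weight and \eqn{z_j} the informed status. Informed
#' demonstrators have \eqn{z = 1} from t = 0 at both patches and never
#' acquire. Waiting times are exponential in the total hazard; the acquirer
#' is categorical with probabilities \eqn{\lambda_i / \sum \lambda}.
#' Simulation stops at the censoring horizon; birds that never acquire are
#' recorded censored with latency equal to the horizon.
#'
#' @param roster a `bird_roster` with `feeding_activity` and
#'   `transmission_weight` filled in (see [transmission_weights()]).
#' @param networks a `follow_nets` object covering all birds.
#' @param scenario the [flock_scenario()].
#' @return a `data.frame` of class `diffusion_set` with columns `flock_id`,
#'   `patch_rank`, `bird_id`, `latency_s`, `censored`, ordered by stratum
#'   and latency; attribute `censor_time_s`.
#' @export
simulate_diffusions <- function(roster, networks, scenario) {
  stopifnot(inherits(roster, "bird_roster"), inherits(networks, "follow_nets"),
            inherits(scenario, "flock_scenario"))
  if (any(is.na(roster$transmission_weight)))
    stop_input("roster transmission weights missing; compute them from the pre-training log first")
  if (!all(unique(roster$flock_id) %in% names(networks$adj)))
    stop_input("networks do not cover all flocks in the roster")
  with_seed(derive_seed(scenario$seed, 3L), {
    bt <- scenario$beta_true
    x <- cbind(age = roster$age, sexM = as.numeric(roster$sex == "M"),
               feeding_activity = roster$feeding_activity)
    eta_fix <- if (length(bt)) drop(x[, names(bt), drop = FALSE] %*% bt) else
      numeric(nrow(roster))
    flocks <- unique(roster$flock_id)
    u <- stats::setNames(stats::rnorm(length(flocks), 0,
                                      sqrt(scenario$sigma_flock2)), flocks)
    v <- stats::setNames(stats::rnorm(nrow(roster), 0, sqrt(scenario$sigma_ind2)),
                         roster$bird_id)
    eta <- eta_fix + u[roster$flock_id] + v
    names(eta) <- roster$bird_id
    out <- vector("list", 0L)
    for (f in flocks) {
      rb <- roster[roster$flock_id == f, ]
      A <- networks$adj[[f]][rb$bird_id, rb$bird_id, drop = FALSE]
      w <- stats::setNames(rb$transmission_weight, rb$bird_id)
      for (patch in 1:2) {
        lam0 <- scenario$baseline_rates[patch]
        s <- scenario$s_true[patch]
        z <- stats::setNames(as.numeric(rb$informed), rb$bird_id)
        naive <- rb$bird_id[!rb$informed]
        t_now <- 0; acq <- character(0); lat <- numeric(0)
        while (length(naive) > 0) {
          Texp <- drop(A[naive, , drop = FALSE] %*% (w * z))
          lam <- lam0 * exp(eta[naive]) * (1 + s * Texp)
          if (any(!is.finite(lam)))
            stop_input("nonfinite hazard in flock %s patch %d", f, patch)
          tot <- sum(lam)
          t_now <- t_now + stats::rexp(1, tot)
          if (t_now > scenario$censor_time_s) break
          who <- naive[sample.int(length(naive), 1L, prob = lam / tot)]
          acq <- c(acq, who); lat <- c(lat, t_now)
          z[who] <- 1; naive <- setdiff(naive, who)
        }
        out[[length(out) + 1L]] <- data.frame(
          flock_id = f, patch_rank = patch,
          bird_id = c(acq, naive),
          latency_s = c(lat, rep(scenario$censor_time_s, length(naive))),
          censored = c(rep(FALSE, length(acq)), rep(TRUE, length(naive))),
          stringsAsFactors = FALSE)
      }
    }
    d <- do.call(rbind, out); rownames(d) <- NULL
    attr(d, "censor_time_s") <- scenario$censor_time_s
    class(d) <- c("diffusion_set", "data.frame")
    d
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running roster -> pre-training log -> following
#' events -> networks -> feeding activity and transmission weights ->
#' diffusions, returning all pieces plus the generating truth.
#'
#' @param scenario a [flock_scenario()].
#' @return a list with elements `scenario`, `roster`, `log`, `events`,
#'   `networks`, `diffusions`.
#' @examples
#' dat <- simulate_flock_study(flock_scenario(n_flocks = 2, seed = 7))
#' head(dat$diffusions)
#' @export
simulate_flock_study <- function(scenario) {
  roster <- generate_roster(scenario)
  log <- generate_pretraining_log(roster, scenario)
  events <- detect_following_events(log)
  nets <- build_following_network(events, roster,
                                  observation_hours = scenario$pretrain_duration_h)
  visits <- count_total_visits(log, roster)
  roster$feeding_activity <- as.numeric(visits[roster$bird_id])
  roster$transmission_weight <-
    transmission_weights(visits, roster$flock_id[match(names(visits), roster$bird_id)])[roster$bird_id]
  diff <- simulate_diffusions(roster, nets, scenario)
  list(scenario = scenario, roster = roster, log = log, events = events,
       networks = nets, diffusions = diff)
}

#' Plot diffusion curves
#'
#' Step curves of the cumulative number of birds having fed from each patch
#' against time, one line per flock, panelled by patch rank.
#'
#' @param x a `diffusion_set`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.diffusion_set <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  censor <- attr(x, "censor_time_s") %||% max(x$latency_s)
  flocks <- unique(x$flock_id)
  cols <- grDevices::hcl.colors(max(3L, length(flocks)), "Dark 3")
  for (p in sort(unique(x$patch_rank))) {
    graphics::plot(NA, xlim = c(0, censor),
                   ylim = c(0, max(table(x$flock_id[x$patch_rank == p & !x$censored])) + 1),
                   xlab = "time (s)", ylab = "birds fed",
                   main = sprintf("patch rank %d", p), ...)
    for (i in seq_along(flocks)) {
      d <- x[x$flock_id == flocks[i] & x$patch_rank == p & !x$censored, ]
      if (!nrow(d)) next
      graphics::lines(stats::stepfun(sort(d$latency_s), 0:nrow(d)),
                      col = cols[i], do.points = FALSE)
    }
  }
  invisible(x)
}
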