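#' Detect following events in an arrival log
#'
#' An arrival opens a window (its bird is the *initiator*) iff no arrival in
#' the same flock precedes it by `window_s` seconds or less. Every arrival
#' within `(0, window_s]` of an initiator's arrival is a following of that
#' initiator. Arrivals sharing the identical timestamp with the window's
#' first arrival form a group arrival with no initiator and yield no
#' events. Arrivals that neither open a window nor fall inside an
#' initiator's window (chained trailing arrivals) yield no events.
#'
#' @param log an arrival log: data.frame with `flock_id`, `bird_id`,
#'   `timestamp_s` (a `location` column is allowed and ignored).
#' @param window_s following window in seconds (default 5, inclusive).
#' @return a data.frame `flock_id`, `initiator`, `follower`, `time_s`
#'   (the follower's arrival time), ordered by flock and time.
#' @examples
#' log <- data.frame(flock_id = "f1", bird_id = c("B", "A", "C"),
#'                   timestamp_s = c(0, 3, 4))
#' detect_following_events(log)  # A and C follow B
#' @export
detect_following_events <- function(log, window_s = 5) {
  validate_arrival_log(log)
  out <- vector("list", 0L)
  for (f in unique(log$flock_id)) {
    d <- log[log$flock_id == f, ]
    d <- d[order(d$timestamp_s, d$bird_id), ]
    t <- d$timestamp_s; b <- d$bird_id; n <- nrow(d)
    new_win <- c(TRUE, diff(t) > window_s)
    wid <- cumsum(new_win)
    start_ix <- which(new_win)
    t_start <- t[start_ix][wid]
    init_bird <- b[start_ix][wid]
    ## group arrival: >1 bird at the identical window-start timestamp
    n_at_start <- tabulate(wid[t == t_start], nbins = max(wid))
    del <- t - t_start
    keep <- del > 0 & del <= window_s & n_at_start[wid] == 1L &
      b != init_bird
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        flock_id = f, initiator = init_bird[keep], follower = b[keep],
        time_s = t[keep], stringsAsFactors = FALSE)
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(flock_id = character(), initiator = character(),
               follower = character(), time_s = numeric(),
               stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  ev
}

validate_arrival_log <- function(log) {
  need <- c("flock_id", "bird_id", "timestamp_s")
  if (!all(need %in% names(log)))
    stop_input("arrival log needs columns %s", paste(need, collapse = ", "))
  if (any(!is.finite(log$timestamp_s)))
    stop_input("arrival timestamps must be finite")
  key <- paste(log$flock_id, log$bird_id, log$timestamp_s)
  if (anyDuplicated(key))
    stop_input("arrival log contains duplicated records (same flock, bird and timestamp)")
  invisible(log)
}

#' Count total feeder visits per bird
#'
#' Every arrival counts once, whether the bird arrived alone, as a
#' follower, or in a group. Used as the feeding-activity proxy.
#'
#' @param log an arrival log.
#' @param roster optional `bird_roster`; if supplied, birds with no
#'   arrivals are included with count 0 and the result is ordered as the
#'   roster.
#' @return named integer vector bird -> visit count.
#' @export
count_total_visits <- function(log, roster = NULL) {
  if (nrow(log)) validate_arrival_log(log)
  birds <- if (!is.null(roster)) roster$bird_id else sort(unique(log$bird_id))
  cnt <- table(factor(log$bird_id, levels = birds))
  stats::setNames(as.integer(cnt), birds)
}

#' Build directed weighted following networks
#'
#' Edge weight a(i, j) is the number of events in which i followed j,
#' divided by the observation time in hours (followings per hour). Edge
#' direction is follower -> followed; a(i, j) and a(j, i) are independent.
#'
#' @param events following events from [detect_following_events()].
#' @param roster a `bird_roster` defining the node set per flock.
#' @param observation_hours positive observation duration in hours.
#' @return an object of class `follow_nets`: list with `adj` (named list of
#'   per-flock weight matrices, rows = follower, cols = followed),
#'   `observation_hours`, and `type = "following"`.
#' @export
build_following_network <- function(events, roster, observation_hours) {
  if (!is.numeric(observation_hours) || observation_hours <= 0)
    stop_input("observation_hours must be positive")
  adj <- list()
  for (f in unique(roster$flock_id)) {
    birds <- roster$bird_id[roster$flock_id == f]
    A <- matrix(0, length(birds), length(birds), dimnames = list(birds, birds))
    ev <- events[events$flock_id == f, , drop = FALSE]
    if (nrow(ev)) {
      bad <- !(ev$follower %in% birds) | !(ev$initiator %in% birds)
      if (any(bad)) stop_input("events reference birds absent from roster flock %s", f)
      tab <- table(factor(ev$follower, levels = birds),
                   factor(ev$initiator, levels = birds))
      A <- A + unclass(tab) / observation_hours
    }
    diag(A) <- 0
    adj[[f]] <- A
  }
  structure(list(adj = adj, observation_hours = observation_hours,
                 type = "following"), class = "follow_nets")
}

#' Homogeneous comparison networks
#'
#' All within-flock connections set to 1 (no edges across flocks, no
#' self-loops): the situation where every bird has equal opportunity to
#' learn from every informed flock-mate, so only the number of informed
#' birds accelerates acquisition.
#'
#' @param roster a `bird_roster`.
#' @return a `follow_nets` object with `type = "homogeneous"`.
#' @export
homogeneous_network <- function(roster) {
  if (!nrow(roster)) stop_input("roster is empty")
  adj <- list()
  for (f in unique(roster$flock_id)) {
    birds <- roster$bird_id[roster$flock_id == f]
    A <- matrix(1, length(birds), length(birds), dimnames = list(birds, birds))
    diag(A) <- 0
    adj[[f]] <- A
  }
  structure(list(adj = adj, observation_hours = NA_real_,
                 type = "homogeneous"), class = "follow_nets")
}

#' @export
print.follow_nets <- function(x, ...) {
  cat(sprintf("%s networks: %d flocks, %s birds/flock, %s\n",
              x$type, length(x$adj),
              paste(unique(vapply(x$adj, nrow, 1L)), collapse = "/"),
              if (is.na(x$observation_hours)) "unit weights"
              else sprintf("%g observation hours", x$observation_hours)))
  invisible(x)
}

#' Node strength metrics
#'
#' Out-strength of bird i is the summed rate at which it follows others
#' (row sum); in-strength is the summed rate at which it is followed, i.e.
#' at which it acted as initiator (column sum).
#'
#' @param networks a `follow_nets` object.
#' @return data.frame with `bird_id`, `flock_id`, `out_strength`,
#'   `in_strength`.
#' @export
node_strengths <- function(networks) {
  stopifnot(inherits(networks, "follow_nets"))
  out <- lapply(names(networks$adj), function(f) {
    A <- networks$adj[[f]]
    data.frame(bird_id = rownames(A), flock_id = f,
               out_strength = rowSums(A), in_strength = colSums(A),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Transmission weights from feeding activity
#'
#' Per-bird visit counts scaled to the maximum value in the bird's flock,
#' so weights lie in (0, 1] and at least one bird per flock has weight 1.
#'
#' @param visits named vector bird -> visit count.
#' @param flock vector of flock ids aligned with `visits`.
#' @return named vector bird -> weight in \[0, 1\].
#' @export
transmission_weights <- function(visits, flock) {
  stopifnot(length(visits) == length(flock))
  w <- numeric(length(visits)); names(w) <- names(visits)
  for (f in unique(flock)) {
    idx <- flock == f
    m <- max(visits[idx])
    if (m <= 0) stop_input("flock %s has no visits; transmission weights undefined", f)
    w[idx] <- visits[idx] / m
  }
  w
}
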