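## Plain-CSV readers/writers for the pipeline's interchange formats.
## All files are UTF-8 with a header row; column names are fixed.

#' @rdname flock_io
#' @param log,roster,networks,diffusions objects to write.
#' @param path file path.
#' @export
write_arrival_log <- function(log, path)
  utils::write.csv(log[, c("flock_id", "bird_id", "timestamp_s", "location")],
                   path, row.names = FALSE)

#' @rdname flock_io
#' @export
read_arrival_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_arrival_log(d)
  class(d) <- c("arrival_log", "data.frame")
  d
}

#' @rdname flock_io
#' @export
write_roster <- function(roster, path)
  utils::write.csv(as.data.frame(roster), path, row.names = FALSE)

#' @rdname flock_io
#' @export
read_roster <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "flock_id", "sex", "age", "informed")
  if (!all(need %in% names(d)))
    stop_input("roster needs columns %s", paste(need, collapse = ", "))
  d$informed <- as.logical(d$informed)
  if (is.null(d$feeding_activity)) d$feeding_activity <- NA_real_
  if (is.null(d$transmission_weight)) d$transmission_weight <- NA_real_
  class(d) <- c("bird_roster", "data.frame")
  d
}

#' Read and write interchange CSVs
#'
#' Edge lists are written one row per nonzero edge
#' (`flock_id,from,to,rate_per_hour`, direction follower -> followed);
#' reading reconstructs the full per-flock weight matrices (birds may be
#' supplied via `roster` to preserve isolated nodes).
#'
#' @name flock_io
#' @param observation_hours carried into the rebuilt `follow_nets`.
#' @export
write_edge_list <- function(networks, path) {
  stopifnot(inherits(networks, "follow_nets"))
  rows <- lapply(names(networks$adj), function(f) {
    A <- networks$adj[[f]]
    idx <- which(A != 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(flock_id = f, from = rownames(A)[idx[, 1]],
               to = colnames(A)[idx[, 2]], rate_per_hour = A[idx],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' @rdname flock_io
#' @export
read_edge_list <- function(path, roster = NULL, observation_hours = NA_real_) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("flock_id", "from", "to", "rate_per_hour")
  if (!all(need %in% names(d)))
    stop_input("edge list needs columns %s", paste(need, collapse = ", "))
  flocks <- if (!is.null(roster)) unique(roster$flock_id) else unique(d$flock_id)
  adj <- list()
  for (f in flocks) {
    birds <- if (!is.null(roster)) roster$bird_id[roster$flock_id == f]
             else sort(unique(c(d$from[d$flock_id == f], d$to[d$flock_id == f])))
    A <- matrix(0, length(birds), length(birds), dimnames = list(birds, birds))
    df <- d[d$flock_id == f, , drop = FALSE]
    if (nrow(df)) A[cbind(df$from, df$to)] <- df$rate_per_hour
    adj[[f]] <- A
  }
  structure(list(adj = adj, observation_hours = observation_hours,
                 type = "following"), class = "follow_nets")
}

#' @rdname flock_io
#' @export
write_diffusions <- function(diffusions, path)
  utils::write.csv(as.data.frame(diffusions)[, c("flock_id", "patch_rank",
                                                 "bird_id", "latency_s",
                                                 "censored")],
                   path, row.names = FALSE)

#' @rdname flock_io
#' @param censor_time_s censoring horizon attribute for the read set.
#' @export
read_diffusions <- function(path, censor_time_s = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("flock_id", "patch_rank", "bird_id", "latency_s", "censored")
  if (!all(need %in% names(d)))
    stop_input("diffusion CSV needs columns %s", paste(need, collapse = ", "))
  d$censored <- as.logical(d$censored)
  attr(d, "censor_time_s") <- censor_time_s %||%
    (if (any(d$censored)) max(d$latency_s[d$censored]) else max(d$latency_s))
  class(d) <- c("diffusion_set", "data.frame")
  d
}

#' Write a fit result as JSON
#'
#' Estimates, boundary flags, log likelihood, AICc bookkeeping and
#' convergence diagnostics, in a stable schema.
#'
#' @param fit an `oada` fit.
#' @param path output path.
#' @param cis optional matrix from [confint.oada()].
#' @export
write_fit_json <- function(fit, path, cis = NULL) {
  stopifnot(inherits(fit, "oada"))
  obj <- list(
    spec = unclass(fit$spec),
    s = fit$s, coefficients = as.list(fit$coefficients),
    sigma2 = as.list(fit$sigma2),
    loglik = fit$logLik, n_events = fit$n_events, k = fit$k,
    aicc = fit$aicc, converged = fit$converged)
  if (!is.null(cis))
    obj$profile_ci <- lapply(seq_len(nrow(cis)), function(i)
      list(parameter = rownames(cis)[i], lower = cis[i, 1], upper = cis[i, 2]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
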