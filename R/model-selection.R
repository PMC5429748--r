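#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik maximised log likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (total acquisition events).
#' @return scalar AICc.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop_input("AICc undefined: n (%d) must exceed k + 1 (%d)", n, k + 1)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_m = exp(-delta_m / 2) / sum exp(-delta / 2)` with
#' `delta_m = AICc_m - min(AICc)`.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(all(is.finite(aicc_values)))
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Enumerate the model grid
#'
#' Full cross product of covariate subsets x scenarios x network types,
#' with asocial specs collapsed across network types (the asocial
#' likelihood is network-free), each spec unique.
#'
#' @param covariates covariate pool; all subsets (including the empty one)
#'   are enumerated.
#' @param scenarios scenario pool.
#' @param network_types network pool.
#' @param random_effects,pooling applied to every spec.
#' @return list of [oada_spec()] objects. With the defaults: 8 covariate
#'   subsets x (4 social x 2 networks + 1 asocial) = 72 specs.
#' @export
enumerate_models <- function(covariates = c("age", "sexM", "feeding_activity"),
                             scenarios = c("asocial", "shared_s", "separate_s",
                                           "s_patch1_only", "s_patch2_only"),
                             network_types = c("following", "homogeneous"),
                             random_effects = "none", pooling = "patch") {
  stopifnot(length(scenarios) >= 1, length(network_types) >= 1)
  covsets <- list(character(0))
  for (cv in covariates)
    covsets <- c(covsets, lapply(covsets, c, cv))
  specs <- list()
  for (cs in covsets) for (sc in scenarios) {
    nets <- if (sc == "asocial") "none" else network_types
    for (nt in nets)
      specs[[length(specs) + 1L]] <-
        oada_spec(if (nt == "none") "following" else nt, sc, cs,
                  random_effects, pooling)
  }
  specs
}

#' Fit every model on the grid and rank by AICc
#'
#' @param diffusions a `diffusion_set`.
#' @param networks named list of `follow_nets` keyed by network type, e.g.
#'   `list(following = ..., homogeneous = ...)`; types not on the grid may
#'   be omitted.
#' @param roster a `bird_roster`.
#' @param specs list of specs from [enumerate_models()] (or a custom list).
#' @param control an [oada_control()].
#' @return object of class `oada_grid`: data.frame `entries` (one row per
#'   converged spec, ranked, with `delta_aicc` and `akaike_weight`),
#'   list `fits`, and `excluded` (non-converged specs, logged out of the
#'   weights).
#' @export
fit_model_grid <- function(diffusions, networks, roster,
                           specs = enumerate_models(),
                           control = oada_control()) {
  if (inherits(networks, "follow_nets"))
    networks <- stats::setNames(list(networks), networks$type)
  preps <- list()
  fits <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    nt <- if (sp$network_type == "none") names(networks)[1] else sp$network_type
    if (!nt %in% names(networks))
      stop_input("no '%s' network supplied", nt)
    key <- paste(nt, sp$pooling)
    if (is.null(preps[[key]]))
      preps[[key]] <- prepare_oada(diffusions, networks[[nt]], roster,
                                   pooling = sp$pooling)
    fits[[i]] <- fit_oada(sp, diffusions, networks[[nt]], roster,
                          control = control, prep = preps[[key]])
  }
  conv <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$aicc), TRUE)
  if (any(!conv))
    message(sum(!conv), " model(s) did not converge; excluded from ranking")
  entries <- do.call(rbind, lapply(which(conv), function(i) {
    f <- fits[[i]]
    data.frame(model = i,
               scenario = f$spec$scenario,
               network_type = f$spec$network_type,
               covariates = paste(f$spec$covariates, collapse = "+"),
               loglik = f$logLik, k = f$k, n = f$n_events, aicc = f$aicc,
               stringsAsFactors = FALSE)
  }))
  entries$delta_aicc <- entries$aicc - min(entries$aicc)
  entries$akaike_weight <- akaike_weights(entries$aicc)
  o <- order(entries$aicc)
  entries <- entries[o, ]; rownames(entries) <- NULL
  structure(list(entries = entries, fits = fits,
                 excluded = which(!conv)), class = "oada_grid")
}

#' @export
print.oada_grid <- function(x, n = 10, ...) {
  cat(sprintf("OADA model grid: %d ranked models (+%d excluded)\n",
              nrow(x$entries), length(x$excluded)))
  print(utils::head(
    x$entries[, c("scenario", "network_type", "covariates", "aicc",
                  "delta_aicc", "akaike_weight")], n),
    digits = 4)
  invisible(x)
}

#' Summed Akaike-weight support by category and network type
#'
#' Sums Akaike weights per social-transmission scenario category and per
#' network type, expressed as percentages (2 d.p.). Asocial support is
#' reported separately and not attributed to any network type; the
#' following/homogeneous support ratio is rounded to 2 d.p.
#'
#' @param grid an `oada_grid`, or a data.frame with columns `scenario`,
#'   `network_type`, `akaike_weight`.
#' @return list with `category_percent` (named), `network_percent`
#'   (named, excluding asocial), `asocial_percent`, and `network_ratio`.
#' @export
category_support <- function(grid) {
  e <- if (inherits(grid, "oada_grid")) grid$entries else as.data.frame(grid)
  stopifnot(all(c("scenario", "network_type", "akaike_weight") %in% names(e)))
  pct <- function(x) round(100 * x, 2)
  cat_sup <- c(tapply(e$akaike_weight, e$scenario, sum))
  soc <- e[e$scenario != "asocial", , drop = FALSE]
  net_sup <- c(tapply(soc$akaike_weight, soc$network_type, sum))
  aso <- sum(e$akaike_weight[e$scenario == "asocial"])
  net_pct <- pct(net_sup)
  ratio <- if (length(net_pct) == 2 && all(net_pct > 0))
    round(max(net_pct) / min(net_pct), 2) else NA_real_
  list(category_percent = pct(cat_sup),
       network_percent = net_pct,
       asocial_percent = pct(aso),
       network_ratio = ratio)
}

#' Best-models set within a delta-AICc window
#'
#' @param grid an `oada_grid`.
#' @param delta AICc window (default 4).
#' @return an `oada_grid` restricted to entries with `delta_aicc <= delta`
#'   (weights kept as computed on the full grid), plus `delta`.
#' @export
best_models_set <- function(grid, delta = 4) {
  stopifnot(inherits(grid, "oada_grid"))
  keep <- grid$entries$delta_aicc <= delta
  structure(list(entries = grid$entries[keep, ],
                 fits = grid$fits, excluded = grid$excluded,
                 delta = delta), class = c("oada_best_set", "oada_grid"))
}
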