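#' Pipeline configuration
#'
#' Validates and normalises the configuration for [run_pipeline()]. Either
#' a synthetic scenario or paths to input CSVs must be given; every
#' stochastic step receives a seed derived from the master seed.
#'
#' @param scenario a [flock_scenario()], or `NULL` when reading inputs
#'   from files.
#' @param paths named list with `arrivals`, `roster` (and optionally
#'   `diffusions`, `edges`) when no scenario is given.
#' @param out_dir output directory (created if missing).
#' @param window_s following-window seconds.
#' @param pooling stratification rule passed to the fits.
#' @param covariates covariate pool for the model grid.
#' @param network_types networks on the grid.
#' @param B permutation resamples for the report statistics.
#' @param delta_aicc best-models window.
#' @param seed master seed.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, paths = NULL, out_dir,
                            window_s = 5, pooling = "patch",
                            covariates = c("age", "sexM", "feeding_activity"),
                            network_types = c("following", "homogeneous"),
                            B = 999, delta_aicc = 4, seed = 1L) {
  if (is.null(scenario) && is.null(paths))
    stop_input("config needs either a scenario or input paths")
  if (is.null(scenario)) {
    for (field in c("arrivals", "roster"))
      if (is.null(paths[[field]]))
        stop_input("config paths missing required field '%s'", field)
  }
  if (missing(out_dir) || !nzchar(out_dir))
    stop_input("config missing required field 'out_dir'")
  stopifnot(window_s > 0, B >= 19, delta_aicc >= 0)
  structure(list(scenario = scenario, paths = paths, out_dir = out_dir,
                 window_s = window_s, pooling = pooling,
                 covariates = covariates, network_types = network_types,
                 B = as.integer(B), delta_aicc = delta_aicc,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' generate/load -> following events and networks -> model grid -> model
#' selection and support -> permutation/binomial statistics -> tables,
#' diffusion-curve figure and run manifest, all written under
#' `config$out_dir`. Any stage failure aborts with a stage-tagged message;
#' outputs written before the failure are preserved.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results (`data`, `grid`,
#'   `best`, `support`, `stats`, `descriptives`, file `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  paths <- list()
  emit <- function(name, writer) {
    p <- file.path(config$out_dir, name)
    writer(p); paths[[name]] <<- p
  }

  dat <- stage("data", {
    if (!is.null(config$scenario)) {
      sc <- config$scenario
      sc$seed <- derive_seed(config$seed, 10L)
      simulate_flock_study(sc)
    } else {
      log <- read_arrival_log(config$paths$arrivals)
      roster <- read_roster(config$paths$roster)
      events <- detect_following_events(log, config$window_s)
      hours <- diff(range(log$timestamp_s)) / 3600
      nets <- build_following_network(events, roster, hours)
      visits <- count_total_visits(log, roster)
      roster$feeding_activity <- as.numeric(visits[roster$bird_id])
      roster$transmission_weight <- transmission_weights(
        visits, roster$flock_id[match(names(visits), roster$bird_id)])[roster$bird_id]
      diff <- if (!is.null(config$paths$diffusions))
        read_diffusions(config$paths$diffusions) else
        stop_input("no diffusion input configured")
      list(roster = roster, log = log, events = events, networks = nets,
           diffusions = diff)
    }
  })

  stage("networks", {
    emit("roster.csv", function(p) write_roster(dat$roster, p))
    emit("arrivals.csv", function(p) write_arrival_log(dat$log, p))
    emit("edges.csv", function(p) write_edge_list(dat$networks, p))
    emit("strengths.csv", function(p)
      utils::write.csv(node_strengths(dat$networks), p, row.names = FALSE))
    emit("diffusions.csv", function(p) write_diffusions(dat$diffusions, p))
  })

  grid <- stage("fit", {
    nets <- list(following = dat$networks)
    if ("homogeneous" %in% config$network_types)
      nets$homogeneous <- homogeneous_network(dat$roster)
    specs <- enumerate_models(covariates = config$covariates,
                              network_types = config$network_types,
                              pooling = config$pooling)
    fit_model_grid(dat$diffusions, nets, dat$roster, specs)
  })

  sel <- stage("select", {
    best <- best_models_set(grid, config$delta_aicc)
    support <- category_support(grid)
    emit("grid.tsv", function(p)
      utils::write.table(grid$entries, p, sep = "\t", row.names = FALSE,
                         quote = FALSE))
    emit("best_models.tsv", function(p)
      writeLines(render_model_table(best), p))
    emit("support.json", function(p)
      jsonlite::write_json(support, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE))
    list(best = best, support = support)
  })

  stats_out <- stage("stats", {
    d <- dat$diffusions; roster <- dat$roster
    seed_s <- derive_seed(config$seed, 4L)
    str <- node_strengths(dat$networks)
    first_feeders <- unlist(lapply(
      split(d[!d$censored, ], list(d$flock_id[!d$censored],
                                   d$patch_rank[!d$censored]), drop = TRUE),
      function(x) x$bird_id[which.min(x$latency_s)]))
    n_events_ff <- length(first_feeders)
    informed_ff <- sum(roster$informed[match(first_feeders, roster$bird_id)])
    p0 <- mean(roster$informed)
    res <- list(
      binomial_informed_first_feeder = list(
        x = informed_ff, n = n_events_ff, p0 = p0,
        p_value = exact_binomial_two_sided(informed_ff, max(n_events_ff, 1), p0)))
    ## out-strength of first feeders vs their flock-mates, flock-stratified
    is_ff <- str$bird_id %in% first_feeders
    naive <- !roster$informed[match(str$bird_id, roster$bird_id)]
    if (length(unique(is_ff[naive])) == 2) {
      mw <- mwu_stratified_mc(str$out_strength[naive],
                              ifelse(is_ff[naive], "first_feeder", "other"),
                              str$flock_id[naive], B = config$B, seed = seed_s)
      res$mwu_out_strength_first_feeders <-
        list(Z = unname(mw$statistic), p_value = mw$p.value, B = config$B)
    }
    ## patch 1 vs patch 2 first-feeding times, paired per flock
    ff_time <- function(p) vapply(split(d, d$flock_id), function(x) {
      xx <- x[x$patch_rank == p & !x$censored, ]
      if (nrow(xx)) min(xx$latency_s) else attr(d, "censor_time_s")
    }, 0)
    sr <- signed_rank_pratt_mc(ff_time(1), ff_time(2), B = config$B,
                               seed = derive_seed(config$seed, 5L))
    res$signed_rank_patch1_vs_patch2 <-
      list(Z = unname(sr$statistic), p_value = sr$p.value, B = config$B)
    emit("stats.json", function(p)
      jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE))
    res
  })

  desc <- stage("report", {
    pd <- patch_descriptives(dat$diffusions)
    emit("descriptives.csv", function(p)
      utils::write.csv(pd, p, row.names = FALSE))
    emit("diffusion_curves.png", function(p) {
      grDevices::png(p, width = 800, height = 700)
      on.exit(grDevices::dev.off())
      plot(dat$diffusions)
    })
    emit("manifest.json", function(p)
      jsonlite::write_json(list(
        package = "flocknbda",
        version = as.character(utils::packageVersion("flocknbda")),
        r_version = R.version.string,
        seed = config$seed,
        config = unclass(config[setdiff(names(config), "scenario")]),
        scenario = if (!is.null(config$scenario)) unclass(config$scenario),
        config_hash = config_hash(unclass(config)),
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
        p, auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA))
    pd
  })

  invisible(list(data = dat, grid = grid, best = sel$best,
                 support = sel$support, stats = stats_out,
                 descriptives = desc, paths = paths))
}

#' Render a ranked-model table with estimates and intervals
#'
#' One row per model: category, network, AICc, delta AICc, Akaike weight,
#' then per-parameter cells formatted `"est [lo-hi]"`. Boundary s
#' estimates render as `"constrained to 0"`; parameters absent from a
#' model render as an em dash. Tab-separated; parses back with
#' [parse_model_table()].
#'
#' @param best an `oada_grid` or `oada_best_set`.
#' @param ci compute profile intervals for each rendered model (slower).
#' @param level CI level.
#' @return character vector of TSV lines.
#' @export
render_model_table <- function(best, ci = FALSE, level = 0.95) {
  stopifnot(inherits(best, "oada_grid"))
  e <- best$entries
  pars <- c("s1", "s2", "s", "age", "sexM", "feeding_activity")
  header <- c("scenario", "network", "AICc", "dAICc", "weight", pars)
  lines <- paste(header, collapse = "\t")
  fmt <- function(est, lo, hi)
    if (is.null(lo)) sprintf("%.3f", est)
    else sprintf("%.3f [%.3f-%.3f]", est, lo, hi)
  for (i in seq_len(nrow(e))) {
    f <- best$fits[[e$model[i]]]
    cis <- if (ci) tryCatch(confint(f, level = level), error = function(e) NULL)
    cells <- vapply(pars, function(p) {
      if (p %in% f$s$parameter) {
        j <- match(p, f$s$parameter)
        if (f$s$constrained_to_0[j]) return("constrained to 0")
        est <- f$s$estimate[j]
      } else if (p %in% names(f$coefficients)) {
        est <- f$coefficients[[p]]
      } else return("—")
      if (!is.null(cis) && p %in% rownames(cis))
        fmt(est, cis[p, 1], cis[p, 2]) else fmt(est, NULL, NULL)
    }, "")
    lines <- c(lines, paste(c(
      e$scenario[i], e$network_type[i],
      sprintf("%.2f", e$aicc[i]), sprintf("%.2f", e$delta_aicc[i]),
      sprintf("%.4f", e$akaike_weight[i]), cells), collapse = "\t"))
  }
  lines
}

#' Parse a rendered model table back to numbers
#'
#' @param lines character vector from [render_model_table()] (or a file
#'   read with `readLines`).
#' @return data.frame with numeric `AICc`, `dAICc`, `weight` and, per
#'   parameter, `<name>_est`, `<name>_lo`, `<name>_hi` (NA where absent;
#'   0 with `constrained = TRUE` at the boundary).
#' @export
parse_model_table <- function(lines) {
  header <- strsplit(lines[1], "\t")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(l, "\t")[[1]])
  out <- data.frame(scenario = vapply(rows, `[`, "", 1),
                    network = vapply(rows, `[`, "", 2),
                    AICc = as.numeric(vapply(rows, `[`, "", 3)),
                    dAICc = as.numeric(vapply(rows, `[`, "", 4)),
                    weight = as.numeric(vapply(rows, `[`, "", 5)),
                    stringsAsFactors = FALSE)
  pars <- header[-(1:5)]
  for (j in seq_along(pars)) {
    cell <- vapply(rows, `[`, "", 5 + j)
    est <- lo <- hi <- rep(NA_real_, length(cell))
    con <- cell == "constrained to 0"
    est[con] <- 0
    m <- regmatches(cell, regexec(
      "^(-?[0-9.]+)(?: \\[(-?[0-9.]+)-(-?[0-9.]+)\\])?$", cell))
    for (i in seq_along(m)) if (length(m[[i]]) >= 2) {
      est[i] <- as.numeric(m[[i]][2])
      if (nzchar(m[[i]][3])) { lo[i] <- as.numeric(m[[i]][3]); hi[i] <- as.numeric(m[[i]][4]) }
    }
    out[[paste0(pars[j], "_est")]] <- est
    out[[paste0(pars[j], "_lo")]] <- lo
    out[[paste0(pars[j], "_hi")]] <- hi
    out[[paste0(pars[j], "_constrained")]] <- con
  }
  out
}
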