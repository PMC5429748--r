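## Hand-built fixtures (independent of the package's generator) and
## brute-force oracles used across the test files.

make_roster <- function(n_flocks = 1, flock_size = 4, n_informed = 1,
                        ages = NULL, weights = 1) {
  flock_id <- rep(sprintf("f%02d", seq_len(n_flocks)), each = flock_size)
  bird_id <- sprintf("%s_b%02d", flock_id, rep(seq_len(flock_size), n_flocks))
  nM <- ceiling(flock_size / 2)
  out <- data.frame(
    bird_id = bird_id, flock_id = flock_id,
    sex = rep(c(rep("M", nM), rep("F", flock_size - nM)), n_flocks),
    age = if (is.null(ages)) rep(2, n_flocks * flock_size) else ages,
    informed = rep(c(rep(TRUE, n_informed),
                     rep(FALSE, flock_size - n_informed)), n_flocks),
    sociability_init = 1, sociability_follow = 1,
    feeding_activity = rep(seq_len(flock_size) * 5, n_flocks),
    transmission_weight = weights,
    stringsAsFactors = FALSE)
  class(out) <- c("bird_roster", "data.frame")
  out
}

make_nets <- function(roster, fill = 1, hours = 10, type = "following") {
  adj <- lapply(split(roster$bird_id, roster$flock_id), function(b) {
    A <- matrix(fill, length(b), length(b), dimnames = list(b, b))
    diag(A) <- 0
    A
  })
  structure(list(adj = adj[unique(roster$flock_id)],
                 observation_hours = hours, type = type),
            class = "follow_nets")
}

random_nets <- function(roster, hours = 10, seed = 1) {
  set.seed(seed)
  adj <- lapply(split(roster$bird_id, roster$flock_id), function(b) {
    A <- matrix(round(runif(length(b)^2, 0, 5), 2), length(b),
                dimnames = list(b, b))
    diag(A) <- 0
    A
  })
  structure(list(adj = adj[unique(roster$flock_id)],
                 observation_hours = hours, type = "following"),
            class = "follow_nets")
}

make_diffusions <- function(df, censor = 30420) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$censored)) df$censored <- FALSE
  attr(df, "censor_time_s") <- censor
  class(df) <- c("diffusion_set", "data.frame")
  df
}

## Brute-force OADA negative log likelihood: explicit nested loops over
## strata and events, recomputing exposures from scratch at every event.
## Independent of the package's prepared-matrix code path.
brute_nll <- function(diffusions, networks, roster, scenario, s_par, beta,
                      covariates, pooling = "patch") {
  X <- cbind(age = roster$age, sexM = as.numeric(roster$sex == "M"),
             feeding_activity = roster$feeding_activity)
  rownames(X) <- roster$bird_id
  w <- setNames(roster$transmission_weight, roster$bird_id)
  s_of <- function(patch)
    switch(scenario, asocial = 0, shared_s = s_par[1],
           separate_s = s_par[patch],
           s_patch1_only = if (patch == 1) s_par[1] else 0,
           s_patch2_only = if (patch == 2) s_par[1] else 0)
  key <- if (pooling == "patch") diffusions$patch_rank
         else paste(diffusions$flock_id, diffusions$patch_rank)
  total2 <- 0
  for (kk in unique(key)) {
    d <- diffusions[key == kk, ]
    patch <- d$patch_rank[1]
    ev <- d[!d$censored, ]
    ev <- ev[order(ev$latency_s, ev$flock_id, ev$bird_id), ]
    acquired <- character(0)
    for (e in seq_len(nrow(ev))) {
      risk <- setdiff(d$bird_id, acquired)
      lam <- sapply(risk, function(i) {
        fl <- roster$flock_id[roster$bird_id == i]
        A <- networks$adj[[fl]]
        flock_birds <- roster$bird_id[roster$flock_id == fl]
        Ti <- 0
        for (j in setdiff(flock_birds, i)) {
          zj <- roster$informed[roster$bird_id == j] || (j %in% acquired)
          Ti <- Ti + A[i, j] * w[j] * as.numeric(zj)
        }
        eta <- if (length(covariates)) sum(X[i, covariates] * beta) else 0
        unname(exp(eta) * (1 + s_of(patch) * Ti))
      })
      total2 <- total2 - log(lam[[ev$bird_id[e]]] / sum(lam))
      acquired <- c(acquired, ev$bird_id[e])
    }
  }
  total2
}
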