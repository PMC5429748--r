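test_that("social exposure and next-acquirer probabilities are exact", {
  roster <- make_roster(flock_size = 3, n_informed = 1, weights = 1)
  b <- roster$bird_id
  A <- matrix(0, 3, 3, dimnames = list(b, b))
  A[b[2], b[1]] <- 2
  z <- setNames(c(1, 0, 0), b); w <- setNames(rep(1, 3), b)
  expect_equal(social_exposure(A, z, w, b[2]), 2)
  expect_equal(social_exposure(A, setNames(rep(0, 3), b), w, b[2]), 0)
  ## transpose orientation reads the other direction
  expect_equal(social_exposure(A, z, w, b[1], orientation = "transpose"), 0)
  expect_equal(social_exposure(t(A), z, w, b[2], orientation = "transpose"), 2)

  expect_equal(next_acquirer_probabilities(rep(0, 3), rep(0, 3), 0),
               rep(1 / 3, 3))
  expect_equal(next_acquirer_probabilities(c(0, 0), c(1, 0), 1),
               c(2 / 3, 1 / 3))
  ## random configurations against the hand-computed ratio
  set.seed(42)
  for (k in 1:20) {
    eta <- rnorm(4); Texp <- runif(4, 0, 3); s <- runif(1, 0, 2)
    lam <- exp(eta) * (1 + s * Texp)
    expect_equal(next_acquirer_probabilities(eta, Texp, s), lam / sum(lam),
                 tolerance = 1e-12)
  }
})

test_that("asocial likelihood equals the closed form and is order-only", {
  roster <- make_roster(flock_size = 4, n_informed = 1)
  nets <- make_nets(roster)
  b <- roster$bird_id[!roster$informed]
  d <- make_diffusions(data.frame(
    flock_id = "f01", patch_rank = 1, bird_id = b,
    latency_s = c(100, 250, 900), censored = FALSE))
  spec <- oada_spec(scenario = "asocial")
  nll <- oada_negloglik(list(s = numeric(0), beta = numeric(0)),
                        spec, d, nets, roster)
  expect_equal(nll, log(6), tolerance = 1e-12)

  ## any strictly monotone latency transform leaves the value unchanged
  d2 <- d; d2$latency_s <- sqrt(d2$latency_s) + 7
  expect_equal(oada_negloglik(list(s = numeric(0), beta = numeric(0)),
                              spec, d2, nets, roster), nll, tolerance = 1e-12)
})

test_that("likelihood matches the brute-force enumeration oracle", {
  set.seed(7)
  for (k in 1:10) {
    roster <- make_roster(flock_size = 4, n_informed = 1,
                          weights = round(runif(4, 0.3, 1), 2))
    roster$age <- round(runif(4, 1, 6), 1)
    nets <- random_nets(roster, seed = k)
    naive <- roster$bird_id[!roster$informed]
    acq <- sample(naive, 2)
    d <- make_diffusions(data.frame(
      flock_id = "f01", patch_rank = rep(1:2, c(2, 1)),
      bird_id = c(acq, setdiff(naive, acq)[1]),
      latency_s = c(100, 300, 200), censored = FALSE))
    ## remaining birds censored in both strata
    cens <- rbind(
      data.frame(flock_id = "f01", patch_rank = 1,
                 bird_id = setdiff(naive, acq), latency_s = 30420,
                 censored = TRUE),
      data.frame(flock_id = "f01", patch_rank = 2,
                 bird_id = setdiff(naive, setdiff(naive, acq)[1]),
                 latency_s = 30420, censored = TRUE))
    d <- make_diffusions(rbind(as.data.frame(d), cens))
    s_par <- round(runif(2, 0, 2), 2); beta <- round(rnorm(1, 0, 0.5), 2)
    spec <- oada_spec("following", "separate_s", "age")
    got <- oada_negloglik(list(s = s_par, beta = beta), spec, d, nets, roster)
    want <- brute_nll(d, nets, roster, "separate_s", s_par, beta, "age")
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("zero networks reduce every scenario to the asocial likelihood", {
  roster <- make_roster(flock_size = 5, n_informed = 1)
  nets0 <- make_nets(roster, fill = 0)
  naive <- roster$bird_id[!roster$informed]
  d <- make_diffusions(data.frame(
    flock_id = "f01", patch_rank = rep(1:2, each = 2),
    bird_id = naive[c(1, 2, 3, 4)], latency_s = c(10, 20, 15, 30),
    censored = FALSE))
  asoc <- oada_negloglik(list(s = numeric(0), beta = numeric(0)),
                         oada_spec(scenario = "asocial"), d, nets0, roster)
  for (sc in c("shared_s", "s_patch1_only", "s_patch2_only")) {
    v <- oada_negloglik(list(s = 1.7, beta = numeric(0)),
                        oada_spec("following", sc), d, nets0, roster)
    expect_equal(v, asoc, tolerance = 1e-12)
  }
  v2 <- oada_negloglik(list(s = c(1.7, 0.4), beta = numeric(0)),
                       oada_spec("following", "separate_s"), d, nets0, roster)
  expect_equal(v2, asoc, tolerance = 1e-12)
})

test_that("edge scaling rescales s and preserves the maximised likelihood", {
  sc <- flock_scenario(n_flocks = 4, flock_size = 6, seed = 15)
  dat <- simulate_flock_study(sc)
  spec <- oada_spec("following", "s_patch1_only")
  f1 <- fit_oada(spec, dat$diffusions, dat$networks, dat$roster)
  nets_c <- dat$networks
  nets_c$adj <- lapply(nets_c$adj, function(A) A * 4)
  f2 <- fit_oada(spec, dat$diffusions, nets_c, dat$roster)
  expect_equal(f2$logLik, f1$logLik, tolerance = 1e-6)
  expect_equal(f2$s$estimate[1], f1$s$estimate[1] / 4, tolerance = 1e-3)
})

test_that("asocial stratified OADA agrees with coxph partial likelihood", {
  skip_if_not_installed("survival")
  sc <- flock_scenario(n_flocks = 5, flock_size = 8, seed = 23,
                       s_true = c(0, 0), beta_true = c(sexM = 0.5, age = -0.2),
                       sigma_flock2 = 0)
  dat <- simulate_flock_study(sc)
  spec <- oada_spec(scenario = "asocial", covariates = c("age", "sexM"))
  fit <- fit_oada(spec, dat$diffusions, dat$networks, dat$roster)
  d <- dat$diffusions
  d$age <- dat$roster$age[match(d$bird_id, dat$roster$bird_id)]
  d$sexM <- as.numeric(dat$roster$sex == "M")[match(d$bird_id,
                                                    dat$roster$bird_id)]
  cph <- survival::coxph(
    survival::Surv(latency_s, !censored) ~ age + sexM +
      survival::strata(patch_rank),
    data = d, ties = "breslow")
  expect_equal(fit$logLik, as.numeric(logLik(cph)), tolerance = 1e-5)
  expect_equal(unname(fit$coefficients[c("age", "sexM")]),
               unname(coef(cph)[c("age", "sexM")]), tolerance = 1e-4)
})

test_that("random effects with zero variance reduce to the fixed fit", {
  sc <- flock_scenario(n_flocks = 3, flock_size = 6, seed = 31)
  dat <- simulate_flock_study(sc)
  spec_f <- oada_spec("following", "s_patch1_only", "sexM")
  fit_f <- fit_oada(spec_f, dat$diffusions, dat$networks, dat$roster)
  spec_r <- oada_spec("following", "s_patch1_only", "sexM",
                      random_effects = "flock_plus_individual")
  fit_r0 <- fit_oada(spec_r, dat$diffusions, dat$networks, dat$roster,
                     control = oada_control(fix_sigma2 = c(0, 0)))
  expect_equal(fit_r0$logLik, fit_f$logLik, tolerance = 1e-6)
  expect_equal(fit_r0$s$estimate, fit_f$s$estimate, tolerance = 1e-4)
  expect_equal(fit_r0$coefficients, fit_f$coefficients, tolerance = 1e-5)

  ## the Laplace marginal likelihood is continuous at sigma2 -> 0
  prep <- flocknbda:::prepare_oada(dat$diffusions, dat$networks, dat$roster)
  v0 <- flocknbda:::nll_prep(prep, "s_patch1_only", 1, 0.3, "sexM")
  vl <- flocknbda:::laplace_nll(prep, "s_patch1_only", 1, 0.3, "sexM",
                                1e-10, 1e-10, "flock_plus_individual")
  expect_equal(vl, v0, tolerance = 1e-4)

  ## positive variances penalise the likelihood (finite, larger nll at the
  ## same fixed effects than the profile mode would give with sigma2 = 0)
  v1 <- flocknbda:::laplace_nll(prep, "s_patch1_only", 1, 0.3, "sexM",
                                0.5, 0.2, "flock_plus_individual")
  expect_true(is.finite(v1))
})

test_that("profile CIs match a dense-grid oracle and respect the boundary", {
  sc <- flock_scenario(n_flocks = 6, flock_size = 6, seed = 19)
  dat <- simulate_flock_study(sc)
  spec <- oada_spec("following", "s_patch1_only", "sexM")
  fit <- fit_oada(spec, dat$diffusions, dat$networks, dat$roster)
  ci <- suppressWarnings(profile_ci(fit, "s1"))
  expect_true(ci[1] <= fit$s$estimate[1] && fit$s$estimate[1] <= ci[2])

  ## dense-grid oracle: profile the likelihood over s on a fine grid,
  ## optimising beta by one-dimensional search, and locate the chi-square
  ## crossings by interpolation
  prep <- flocknbda:::prepare_oada(dat$diffusions, dat$networks, dat$roster)
  prof <- function(s) -optimize(function(b)
    flocknbda:::nll_prep(prep, "s_patch1_only", s, b, "sexM"),
    c(-4, 4), tol = 1e-10)$objective
  cut <- fit$logLik - qchisq(0.95, 1) / 2
  for (side in c("lower", "upper")) {
    bound <- ci[[side]]
    if (!is.finite(bound) || bound <= 0) next
    ## at the reported bound the profile loglik equals the cutoff
    expect_equal(prof(bound), cut, tolerance = 1e-4)
  }

  ## boundary estimate: lower bound exactly 0
  sc0 <- flock_scenario(n_flocks = 5, flock_size = 6, s_true = c(0, 0),
                        beta_true = numeric(0), seed = 91)
  dat0 <- simulate_flock_study(sc0)
  fit0 <- fit_oada(oada_spec("following", "s_patch2_only"),
                   dat0$diffusions, dat0$networks, dat0$roster)
  ci0 <- suppressWarnings(profile_ci(fit0, "s2"))
  expect_identical(ci0[["lower"]], 0)
})

test_that("likelihood-ratio test arithmetic and guards", {
  fake <- function(ll, scen, cov = "sexM") {
    structure(list(logLik = ll,
                   spec = oada_spec("following", scen, cov),
                   s = data.frame(), coefficients = numeric(0)),
              class = "oada")
  }
  eq <- lrt_vs_asocial(fake(-500, "s_patch1_only"), fake(-500, "asocial"))
  expect_equal(unname(eq$statistic), 0)
  expect_equal(eq$p.value, 1)
  lr <- lrt_vs_asocial(fake(-500, "s_patch1_only"), fake(-503, "asocial"))
  expect_equal(unname(lr$statistic), 6)
  expect_equal(lr$p.value, pchisq(6, 1, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(round(lr$p.value, 4), 0.0143)
  lr2 <- lrt_vs_asocial(fake(-500, "separate_s"), fake(-503, "asocial"))
  expect_equal(unname(lr2$parameter), 2)
  expect_error(lrt_vs_asocial(fake(-500, "s_patch1_only", "age"),
                              fake(-503, "asocial", "sexM")), "covariate")
  expect_error(lrt_vs_asocial(fake(-500, "asocial"), fake(-503, "asocial")),
               "free s")
})

test_that("patch strata assignment ranks by first feeding latency", {
  raw <- data.frame(
    flock_id = "f1", patch = rep(c("B", "A"), each = 3),
    bird_id = c("x", "y", "z", "u", "v", "w"),
    latency_s = c(6807.1, 8000, 30420, 13490, 14000, 30420),
    censored = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  d <- assign_patch_strata(raw, censor_time_s = 30420)
  expect_equal(unique(d$patch_rank[d$bird_id %in% c("x", "y", "z")]), 1L)
  expect_equal(unique(d$patch_rank[d$bird_id %in% c("u", "v", "w")]), 2L)
  ## relabeling physical patches leaves ranks unchanged
  raw2 <- raw; raw2$patch <- ifelse(raw$patch == "A", "Q", "P")
  d2 <- assign_patch_strata(raw2, censor_time_s = 30420)
  expect_equal(d2$patch_rank, d$patch_rank)
  ## unexploited patch is rank 2
  raw3 <- raw; raw3$censored[raw3$patch == "A"] <- TRUE
  raw3$latency_s[raw3$patch == "A"] <- 30420
  d3 <- assign_patch_strata(raw3, censor_time_s = 30420)
  expect_equal(unique(d3$patch_rank[d3$bird_id == "u"]), 2L)
  expect_true(all(d3$censored[d3$patch_rank == 2]))
  ## ties error
  raw4 <- raw; raw4$latency_s[4] <- 6807.1
  expect_error(assign_patch_strata(raw4, 30420), "tie")
})
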