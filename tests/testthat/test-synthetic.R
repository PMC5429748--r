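test_that("roster generation respects composition and determinism", {
  sc <- flock_scenario(seed = 4)
  r <- generate_roster(sc)
  expect_equal(nrow(r), 100)
  expect_equal(sum(r$informed), 20)
  comp <- table(r$flock_id, r$sex)
  expect_true(all(comp == 5))
  ## informed birds are one male and one female per flock
  inf_sex <- table(r$flock_id[r$informed], r$sex[r$informed])
  expect_true(all(inf_sex == 1))

  r_min <- generate_roster(flock_scenario(n_flocks = 1, flock_size = 2,
                                          n_informed_per_flock = 1, seed = 1))
  expect_equal(nrow(r_min), 2)
  expect_equal(sum(r_min$informed), 1)

  expect_identical(generate_roster(sc), generate_roster(sc))
  expect_error(flock_scenario(flock_size = 2, n_informed_per_flock = 2),
               "n_informed")
})

test_that("pretraining log: spacing, Poisson counts and planted truth", {
  ## follow_prob = 0: no two arrivals within 5 s of each other
  sc0 <- flock_scenario(n_flocks = 2, flock_size = 5, follow_prob = 0,
                        group_arrival_prob = 0, pretrain_duration_h = 5,
                        seed = 21)
  log0 <- generate_pretraining_log(generate_roster(sc0), sc0)
  gaps <- unlist(lapply(split(log0$timestamp_s, log0$flock_id),
                        function(t) diff(sort(t))))
  expect_true(all(gaps > 5))
  expect_equal(nrow(attr(log0, "truth")), 0)

  ## single bird: arrival count is Poisson(rate * duration)
  counts <- vapply(1:150, function(k) {
    sc1 <- flock_scenario(n_flocks = 1, flock_size = 2,
                          n_informed_per_flock = 1, init_rate_per_h = 2,
                          pretrain_duration_h = 2, follow_prob = 0,
                          nonfollow_prob = 0, group_arrival_prob = 0,
                          sociability_shape = 1e6, seed = 5000 + k)
    r1 <- generate_roster(sc1)
    log1 <- generate_pretraining_log(r1, sc1)
    nrow(log1)
  }, 0L)
  ## two birds at 2/h for 2 h -> mean 8, SE(mean over 150) ~ 0.23
  expect_gt(mean(counts), 8 - 0.8)
  expect_lt(mean(counts), 8 + 0.8)

  ## planted follower pairs are recovered exactly by the detector
  sc <- flock_scenario(n_flocks = 3, flock_size = 8, seed = 77,
                       pretrain_duration_h = 10)
  r <- generate_roster(sc)
  log <- generate_pretraining_log(r, sc)
  ev <- detect_following_events(log)
  tr <- attr(log, "truth")
  expect_setequal(paste(ev$flock_id, ev$initiator, ev$follower,
                        round(ev$time_s, 9)),
                  paste(tr$flock_id, tr$initiator, tr$follower,
                        round(tr$time_s, 9)))
  ## visit counts equal the planted arrival counts
  expect_equal(count_total_visits(log, r), attr(log, "visits"))
  expect_identical(generate_pretraining_log(r, sc),
                   generate_pretraining_log(r, sc))
})

test_that("diffusion simulation: ordering, censoring, and limits", {
  sc <- flock_scenario(n_flocks = 2, flock_size = 6, seed = 8)
  dat <- simulate_flock_study(sc)
  d <- dat$diffusions
  ## latencies nondecreasing within stratum, censored exactly at horizon
  for (g in split(d, list(d$flock_id, d$patch_rank)))
    expect_true(!is.unsorted(g$latency_s))
  expect_true(all(d$latency_s[d$censored] == sc$censor_time_s))
  ## informed birds never acquire
  inf <- dat$roster$bird_id[dat$roster$informed]
  expect_false(any(d$bird_id %in% inf))
  ## determinism
  expect_identical(simulate_diffusions(dat$roster, dat$networks, sc), d)

  ## vanishing baseline: nearly everything censored
  sc_low <- flock_scenario(n_flocks = 2, flock_size = 6,
                           baseline_rates = c(1e-9, 1e-9), seed = 8)
  r <- dat$roster
  d_low <- simulate_diffusions(r, dat$networks, sc_low)
  expect_gt(mean(d_low$censored), 0.95)
})

test_that("null diffusion order is exchangeable (chi-square over permutations)", {
  ## s = 0, beta = 0, sigma2 = 0: acquisition order uniform over the 3! = 6
  ## permutations of the naive birds
  roster <- make_roster(flock_size = 4, n_informed = 1)
  nets <- make_nets(roster)
  base <- flock_scenario(n_flocks = 1, flock_size = 4,
                         n_informed_per_flock = 1,
                         s_true = c(0, 0), beta_true = numeric(0),
                         baseline_rates = c(1e-3, 1e-3), seed = 1)
  n_rep <- 2400
  orders <- character(n_rep)
  for (k in seq_len(n_rep)) {
    sck <- base; sck$seed <- k
    d <- simulate_diffusions(roster, nets, sck)
    d1 <- d[d$patch_rank == 1 & !d$censored, ]
    orders[k] <- paste(d1$bird_id, collapse = ">")
  }
  tab <- table(orders)
  expect_equal(length(tab), 6L)
  chi <- suppressWarnings(chisq.test(tab, p = rep(1 / 6, 6)))
  expect_gt(chi$p.value, 0.01)
})

test_that("first acquirer follows the analytic categorical distribution", {
  ## star-like network: one naive bird strongly connected to the informed
  ## demonstrator; huge s makes it the first acquirer essentially always
  roster <- make_roster(flock_size = 5, n_informed = 1)
  b <- roster$bird_id
  nets <- make_nets(roster, fill = 0)
  nets$adj[["f01"]][b[2], b[1]] <- 10   # naive b2 follows informed b1
  sc_star <- flock_scenario(n_flocks = 1, flock_size = 5,
                            n_informed_per_flock = 1, s_true = c(1e6, 0),
                            beta_true = numeric(0),
                            baseline_rates = c(1e-3, 1e-3), seed = 1)
  first <- vapply(1:300, function(k) {
    sck <- sc_star; sck$seed <- k
    d <- simulate_diffusions(roster, nets, sck)
    d$bird_id[d$patch_rank == 1][1]
  }, "")
  expect_gt(mean(first == b[2]), 0.99)

  ## moderate s: frequencies match lambda / sum(lambda) within 3 MC SE
  sc_mod <- sc_star; sc_mod$s_true <- c(2, 0)
  n_rep <- 4000
  first2 <- vapply(seq_len(n_rep), function(k) {
    sck <- sc_mod; sck$seed <- 10000 + k
    d <- simulate_diffusions(roster, nets, sck)
    d$bird_id[d$patch_rank == 1][1]
  }, "")
  w <- setNames(roster$transmission_weight, b)
  z <- setNames(as.numeric(roster$informed), b)
  naive <- b[!roster$informed]
  lam <- sapply(naive, function(i)
    1 + 2 * social_exposure(nets$adj[["f01"]], z, w, i))
  p_true <- lam / sum(lam)
  for (i in naive) {
    phat <- mean(first2 == i)
    se <- sqrt(p_true[i] * (1 - p_true[i]) / n_rep)
    expect_lt(abs(phat - p_true[i]), 3 * se + 1e-9)
  }
})
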