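test_that("following-event windowing matches the initiator/follower rule", {
  log <- data.frame(flock_id = "f1", bird_id = c("B", "A", "C"),
                    timestamp_s = c(0, 3, 4))
  ev <- detect_following_events(log)
  expect_equal(ev$initiator, c("B", "B"))
  expect_equal(sort(ev$follower), c("A", "C"))

  ## outside the window: no event
  expect_equal(nrow(detect_following_events(
    data.frame(flock_id = "f1", bird_id = c("B", "A"),
               timestamp_s = c(0, 6)))), 0)

  ## exact tie at the window start: group arrival, no initiator
  expect_equal(nrow(detect_following_events(
    data.frame(flock_id = "f1", bird_id = c("B", "A"),
               timestamp_s = c(0, 0)))), 0)

  ## the window is inclusive at exactly 5 s
  ev5 <- detect_following_events(
    data.frame(flock_id = "f1", bird_id = c("B", "A"),
               timestamp_s = c(0, 5)))
  expect_equal(ev5$follower, "A")

  ## chained arrival beyond the initiator's window yields nothing
  ev_ch <- detect_following_events(
    data.frame(flock_id = "f1", bird_id = c("B", "A", "C"),
               timestamp_s = c(0, 4, 7)))
  expect_equal(ev_ch$follower, "A")

  ## duplicated records are rejected
  expect_error(detect_following_events(
    data.frame(flock_id = "f1", bird_id = c("B", "B"),
               timestamp_s = c(0, 0))), "duplicated")
})

test_that("visit counts include every arrival regardless of role", {
  log <- data.frame(flock_id = "f1", bird_id = c("B", "A", "C"),
                    timestamp_s = c(0, 3, 4))
  expect_equal(count_total_visits(log), c(A = 1L, B = 1L, C = 1L))
  roster <- make_roster(flock_size = 4)
  empty <- log[0, ]
  expect_equal(unname(count_total_visits(empty, roster)), rep(0L, 4))
})

test_that("network weights are followings per hour with correct orientation", {
  roster <- make_roster(flock_size = 3)
  b <- roster$bird_id
  ev <- data.frame(flock_id = "f01", initiator = b[2], follower = b[1],
                   time_s = seq_len(10), stringsAsFactors = FALSE)
  net <- build_following_network(ev, roster, observation_hours = 2)
  expect_equal(net$adj[["f01"]][b[1], b[2]], 5.0)
  expect_equal(sum(net$adj[["f01"]]), 5.0)
  expect_error(build_following_network(ev, roster, 0), "positive")
  net0 <- build_following_network(ev[0, ], roster, 2)
  expect_true(all(net0$adj[["f01"]] == 0))
})

test_that("strengths follow the summation definitions and conserve", {
  roster <- make_roster(flock_size = 3)
  b <- roster$bird_id
  nets <- make_nets(roster, fill = 0)
  nets$adj[["f01"]][b[1], b[2]] <- 3
  st <- node_strengths(nets)
  expect_equal(st$out_strength[st$bird_id == b[1]], 3)
  expect_equal(st$in_strength[st$bird_id == b[2]], 3)
  expect_equal(sum(st$out_strength), sum(st$in_strength))

  ## random networks: equality with a per-node brute-force oracle
  roster2 <- make_roster(n_flocks = 2, flock_size = 6)
  for (seed in 1:5) {
    nets2 <- random_nets(roster2, seed = seed)
    st2 <- node_strengths(nets2)
    for (i in sample(nrow(st2), 4)) {
      A <- nets2$adj[[st2$flock_id[i]]]
      bid <- st2$bird_id[i]
      expect_equal(st2$out_strength[i], sum(A[bid, ]), tolerance = 1e-12)
      expect_equal(st2$in_strength[i], sum(A[, bid]), tolerance = 1e-12)
    }
    expect_equal(sum(st2$out_strength), sum(st2$in_strength),
                 tolerance = 1e-12)
  }
})

test_that("transmission weights scale to the flock maximum", {
  w <- transmission_weights(c(A = 20, B = 10, C = 5), rep("f1", 3))
  expect_equal(w, c(A = 1, B = 0.5, C = 0.25))
  expect_equal(unname(transmission_weights(c(A = 7), "f1")), 1)
  w2 <- transmission_weights(c(A = 40, B = 20, C = 10), rep("f1", 3))
  expect_equal(w, w2)
  expect_error(transmission_weights(c(A = 0, B = 0), rep("f1", 2)),
               "undefined")
})

test_that("homogeneous networks give unit edges and uniform exposure", {
  roster <- make_roster(flock_size = 3)
  h <- homogeneous_network(roster)
  A <- h$adj[["f01"]]
  expect_equal(sum(A), 6)
  expect_equal(unname(rowSums(A)), rep(2, 3))
  ## exposure is identical across naive birds: sum over informed weights
  roster4 <- make_roster(flock_size = 4, n_informed = 2,
                         weights = c(0.5, 1, 0.8, 0.3))
  h4 <- homogeneous_network(roster4)
  z <- setNames(as.numeric(roster4$informed), roster4$bird_id)
  w <- setNames(roster4$transmission_weight, roster4$bird_id)
  naive <- roster4$bird_id[!roster4$informed]
  Ts <- sapply(naive, function(b)
    social_exposure(h4$adj[["f01"]], z, w, b))
  expect_equal(unname(Ts), rep(sum(w * z), length(naive)))
})

test_that("event detection is shift-invariant and events map to arrivals", {
  sc <- flock_scenario(n_flocks = 2, flock_size = 6, seed = 33,
                       pretrain_duration_h = 5)
  roster <- generate_roster(sc)
  log <- generate_pretraining_log(roster, sc)
  ev <- detect_following_events(log)
  ## each event's follower arrival exists in the log
  key_log <- paste(log$flock_id, log$bird_id, log$timestamp_s)
  expect_true(all(paste(ev$flock_id, ev$follower, ev$time_s) %in% key_log))
  ## each non-initiator arrival maps to at most one following event
  expect_false(anyDuplicated(paste(ev$flock_id, ev$follower, ev$time_s)) > 0)
  ## shifting all timestamps leaves the network unchanged
  log2 <- log; log2$timestamp_s <- log2$timestamp_s + 1234.5
  ev2 <- detect_following_events(log2)
  n1 <- build_following_network(ev, roster, 5)
  n2 <- build_following_network(ev2, roster, 5)
  expect_equal(n1$adj, n2$adj)
})

test_that("edge lists round-trip through CSV", {
  roster <- make_roster(n_flocks = 2, flock_size = 5)
  nets <- random_nets(roster, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_edge_list(nets, path)
  back <- read_edge_list(path, roster, observation_hours = 10)
  expect_equal(back$adj, nets$adj)
})
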