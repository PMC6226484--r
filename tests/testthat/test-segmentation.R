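test_that("Viterbi equals exhaustive enumeration on tiny trajectories", {
  set.seed(21)
  for (rep in 1:25) {
    m <- rand_model(sample(c("two", "three"), 1))
    N <- sample(4:10, 1)
    tr <- rand_traj(N, mean_gap = 10^runif(1, -4.5, -2.5))
    vp <- viterbi_path(tr, m)
    ref <- enum_viterbi(tr$times, tr$colors, m$K, m$E_diag, m$p_eq)
    expect_identical(vp$states, as.integer(ref))
  }
})

test_that("dominant emission pins the assignment", {
  m <- make_two_state(two_state_params(0.9, 0.1, 2, 2))  # slow exchange
  tr <- photon_trajectory(seq(0, 0.01, length.out = 30), rep(1L, 30))
  vp <- viterbi_path(tr, m)
  expect_true(all(vp$states == 1L))  # all photons bound
})

test_that("assignment accuracy is high at realistic contrast", {
  set.seed(22)
  # alternating dwells of 1 ms at 100 photons/ms -> ~100 photons per dwell
  switches <- seq(1e-3, 29e-3, by = 1e-3)
  states <- rep(c(2L, 1L), length.out = length(switches) + 1)
  sim <- traj_from_path(switches, states, 0.03, 100, c(0.6, 0.25))
  m <- make_two_state(two_state_params(0.6, 0.25, 1000, 1000))
  vp <- viterbi_path(sim$traj, m)
  expect_gt(mean(vp$states == sim$states), 0.95)
})

test_that("residence filtering drops short excursions and keeps real dwells", {
  # helper to fabricate a state_path from dwell lengths
  fab <- function(dwells, states, rate_ms = 200) {
    bounds <- cumsum(c(0, dwells))
    times <- sort(runif(rpois(1, rate_ms * 1000 * sum(dwells)), 0,
                        sum(dwells)))
    s <- states[findInterval(times, bounds[-c(1, length(bounds))]) + 1L]
    structure(list(states = s, times = times,
                   transitions = data.frame(), id = "fab"),
              class = "state_path")
  }
  set.seed(23)
  # B(1 ms) U(50 us) B(1 ms): the excursion is merged away
  p1 <- fab(c(1e-3, 50e-6, 1e-3), c(1L, 2L, 1L))
  expect_equal(nrow(find_transitions(p1, 200e-6)), 0)
  # B(1 ms) U(1 ms): one dissociation
  p2 <- fab(c(1e-3, 1e-3), c(1L, 2L))
  tr2 <- find_transitions(p2, 200e-6)
  expect_equal(nrow(tr2), 1)
  expect_identical(tr2$direction, "dissociation")
  expect_identical(first_event_only(tr2)$direction, character(0))
  # U(1 ms) B(1 ms): one binding; first_event_only keeps it
  p3 <- fab(c(1e-3, 1e-3), c(2L, 1L))
  tr3 <- find_transitions(p3, 200e-6)
  expect_identical(tr3$direction, "binding")
  expect_equal(nrow(first_event_only(tr3)), 1)
})

test_that("raising min_residence never adds transitions", {
  set.seed(24)
  m <- make_two_state(two_state_params(0.6, 0.25, 800, 800))
  cfg <- sim_config(two_state_params(0.6, 0.25, 800, 800), rate_ms = 300,
                    duration = 0.15, n_traj = 4)
  trs <- simulate_ctmc_photons(cfg)
  for (tr in trs) {
    vp <- viterbi_path(tr, m)
    counts <- sapply(c(5e-5, 1e-4, 2e-4, 5e-4, 1e-3),
                     function(r) nrow(find_transitions(vp, r)))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("transition times land within one interphoton interval of truth", {
  # high-contrast regime: single photons discriminate the states, so the
  # flagged interval localizes the switch to ~one interphoton gap
  set.seed(25)
  hits <- 0; total <- 0
  for (rep in 1:6) {
    switches <- cumsum(runif(9, 2e-3, 6e-3))
    states <- rep(c(2L, 1L), 5)
    dur <- max(switches) + 3e-3
    sim <- traj_from_path(switches, states, dur, 100, c(0.85, 0.08))
    m <- make_two_state(two_state_params(0.85, 0.08, 400, 400))
    tt <- find_transitions(viterbi_path(sim$traj, m), 200e-6)
    gaps <- diff(sim$traj$times)
    for (k in seq_len(nrow(tt))) {
      near <- which.min(abs(switches - tt$time[k]))
      total <- total + 1
      tol <- max(gaps) + 1e-4
      if (abs(switches[near] - tt$time[k]) <= tol) hits <- hits + 1
    }
  }
  expect_gt(total, 20)
  expect_gt(hits / total, 0.95)
})

test_that("segment windows obey centring, truncation and bounds", {
  set.seed(26)
  times <- sort(runif(4000, 0, 0.02))
  tr <- photon_trajectory(times, rbinom(4000, 1, 0.4))
  mk_trans <- function(tt, dir = "binding")
    data.frame(time = tt, i_before = NA, i_after = NA, from = 2, to = 1,
               direction = dir, left_dwell_s = 1, right_dwell_s = 1)
  # isolated transition: full 2 ms window, 1 ms per side
  s1 <- extract_segments(tr, mk_trans(0.01))
  expect_length(s1, 1)
  expect_equal(s1[[1]]$window, c(0.009, 0.011))
  # neighbouring transition 300 us away truncates; short remnants are dropped
  tt2 <- rbind(mk_trans(0.0100), mk_trans(0.0103, "dissociation"))
  s2 <- extract_segments(tr, tt2)
  for (s in s2) expect_gte(diff(s$window), 400e-6)
  # a window never contains a second retained transition
  tt3 <- rbind(mk_trans(0.004), mk_trans(0.0058, "dissociation"),
               mk_trans(0.009), mk_trans(0.016, "dissociation"))
  s3 <- extract_segments(tr, tt3)
  for (s in s3) {
    inside <- sum(tt3$time > s$window[1] & tt3$time < s$window[2])
    expect_lte(inside, 1)
  }
  # photon count matches the Poisson expectation for the window
  expect_equal(length(s1[[1]]$times), 2e-3 * 200000,
               tolerance = 3 / sqrt(2e-3 * 200000))
})
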