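test_that("one-state trajectories follow the binomial closed form", {
  m1 <- kinetic_model("S", matrix(0, 1, 1), 0.6, 1)
  # single acceptor photon: ln E
  tr1 <- photon_trajectory(0.001, 1L)
  expect_equal(log_likelihood_eq(tr1, m1), log(0.6))
  # N photons: N_A ln E + N_D ln(1 - E), independent of the arrival times
  set.seed(1)
  for (rep in 1:5) {
    tr <- rand_traj(30, mean_gap = runif(1, 1e-5, 1e-2))
    NA_ <- sum(tr$colors); ND <- 30 - NA_
    expect_equal(log_likelihood_eq(tr, m1), NA_ * log(0.6) + ND * log(0.4))
  }
})

test_that("likelihood matches the brute-force matrix-product oracle", {
  set.seed(2)
  for (kind in c("two", "three", "four", "six")) {
    for (rep in 1:5) {
      m <- rand_model(kind)
      tr <- rand_traj(10, mean_gap = 10^runif(1, -5, -2.5))
      ours <- log_likelihood_eq(tr, m)
      ref <- brute_loglik(tr$times, tr$colors, m$K, m$E_diag, m$p_eq,
                          rep(1, length(m$p_eq)))
      expect_equal(ours, ref, tolerance = 1e-8)
      # endpoint form against the same oracle
      ends <- endpoint_vectors(m, "binding", p_b = 0.8)
      ours2 <- log_likelihood_endpoint(tr, m, ends)
      ref2 <- brute_loglik(tr$times, tr$colors, m$K, m$E_diag,
                           ends$v_ini, ends$v_fin)
      expect_equal(ours2, ref2, tolerance = 1e-8)
    }
  }
})

test_that("endpoint likelihood reduces to the equilibrium likelihood", {
  set.seed(3)
  m <- rand_model("four")
  tr <- rand_traj(40)
  ends <- list(v_ini = m$p_eq, v_fin = rep(1, 4))
  expect_equal(log_likelihood_endpoint(tr, m, ends), log_likelihood_eq(tr, m))
})

test_that("log-likelihood is additive and order-invariant over trajectories", {
  set.seed(4)
  m <- make_two_state(two_state_params(0.6, 0.25, 300, 100))
  trs <- lapply(1:6, function(i) rand_traj(25))
  tot <- total_log_likelihood(trs, m)
  expect_equal(tot, sum(sapply(trs, log_likelihood_eq, model = m)))
  expect_equal(total_log_likelihood(rev(trs), m), tot)
})

test_that("zero-probability photons yield -Inf rather than an error", {
  m0 <- kinetic_model(c("A", "B"), matrix(c(-5, 5, 5, -5), 2, 2), c(0, 0))
  tr <- photon_trajectory(c(0, 1e-3), c(0L, 1L))  # acceptor photon, all E = 0
  expect_identical(log_likelihood_eq(tr, m0), -Inf)
})

test_that("long trajectories stay finite (renormalization contract)", {
  set.seed(5)
  m <- make_two_state(two_state_params(0.6, 0.25, 300, 100))
  tr <- photon_trajectory(cumsum(rexp(2e5, 1e5)), rbinom(2e5, 1, 0.4))
  ll <- log_likelihood_eq(tr, m)
  expect_true(is.finite(ll))
  expect_lt(ll, 0)
})

test_that("transient-complex models nest their instantaneous limits", {
  set.seed(6)
  two <- two_state_params(0.6, 0.25, 300, 100)
  bl <- blink_params(k_b = 3000, k_0 = 500)
  tr <- rand_traj(50, mean_gap = 2e-5)
  # 3-state at t_TC = 1e-9 converges to the halved-rate two-state reference
  tc <- tc_params(t_TC = 1e-9, E_TC = 0.425)
  m3 <- make_three_state_tc(two, tc)
  ref2 <- tcphoton:::reference_model(two, NULL, 500, 1000)
  l3 <- log_likelihood_endpoint(tr, m3, endpoint_vectors(m3, "binding"))
  l2 <- log_likelihood_endpoint(tr, ref2, endpoint_vectors(ref2, "binding"))
  expect_equal(l3, l2, tolerance = 1e-3)
  # 6-state likewise converges to the 4-state reference
  m6 <- make_six_state_tc(two, tc, bl, 500)
  ref4 <- tcphoton:::reference_model(two, bl, 500, 1000)
  pb <- 3000 / (3000 + 500 * 5)
  l6 <- log_likelihood_endpoint(tr, m6, endpoint_vectors(m6, "binding", pb))
  l4 <- log_likelihood_endpoint(tr, ref4, endpoint_vectors(ref4, "binding", pb))
  expect_equal(l6, l4, tolerance = 1e-3)
})

test_that("two-state fits honour constraints and likelihood additivity", {
  set.seed(7)
  cfg <- sim_config(two_state_params(0.6, 0.25, 300, 100), rate_ms = 50,
                    duration = 0.4, n_traj = 6)
  trs <- simulate_ctmc_photons(cfg)
  init <- c(E_B = 0.6, E_U = 0.25, k_A_app = 300, k_D = 100)

  # fixing p_B makes the fitted bound fraction exactly the constraint
  f <- fit_two_state(trs, init = init, fix_pB = 0.75)
  pB_hat <- f$params[["k_A_app"]] / (f$params[["k_A_app"]] + f$params[["k_D"]])
  expect_equal(pB_hat, 0.75)

  # duplicating the data leaves estimates unchanged, shrinks stderr by sqrt(2)
  f1 <- fit_two_state(trs, init = init)
  f2 <- fit_two_state(c(trs, trs), init = init)
  expect_equal(f2$params, f1$params, tolerance = 1e-4)
  expect_equal(f2$stderr / f1$stderr, rep(1 / sqrt(2), 4),
               ignore_attr = TRUE, tolerance = 0.05)
})

test_that("delta lnL is continuous at the instantaneous limit", {
  set.seed(8)
  two <- two_state_params(0.6, 0.25, 300, 100)
  segs <- simulate_transition_segments(10, 2e-4, 0.6, 0.425, 0.25,
                                       rate_ms = 300, window = 1e-3)
  sc <- delta_lnL_scan(segs, two, t_grid = c(1e-8, 1e-7, 1e-4))
  expect_lt(abs(sc$delta_lnL[1]), 0.5)
  expect_lt(abs(sc$delta_fn(1e-9)), 1e-3)
})

test_that("lifetime extraction follows the argmax and interpolation contracts", {
  # peak above +3: refined maximum of the (quadratic) scan closure
  tg <- tcphoton:::default_t_grid(30, 1e-5, 1e-3)
  fn <- function(t) 10 - 5e7 * (t - 183e-6)^2
  sc <- structure(list(t_grid = tg, delta_lnL = vapply(tg, fn, 0),
                       E_TC_mode = "fixed-midpoint", n_segments = 1,
                       n_excluded = 0, delta_fn = fn, E_TC = 0.425),
                  class = "lifetime_scan")
  est <- find_lifetime_or_bound(sc)
  expect_identical(est$type, "lifetime")
  expect_equal(est$t_hat, 183e-6, tolerance = 1e-3)
  expect_true(is.finite(est$stderr) && est$stderr > 0)

  # monotone decreasing curve crossing -3 between 1.8 and 2.2 us:
  # log-linear interpolation puts the upper bound near 2 us
  tg2 <- c(1.0e-6, 1.4e-6, 1.8e-6, 2.2e-6, 3.0e-6)
  d2 <- c(-0.2, -1.0, -2.5, -3.5, -6.0)
  sc2 <- structure(list(t_grid = tg2, delta_lnL = d2,
                        E_TC_mode = "fixed-midpoint", n_segments = 1,
                        n_excluded = 0, delta_fn = function(t) NA_real_,
                        E_TC = 0.425),
                   class = "lifetime_scan")
  est2 <- find_lifetime_or_bound(sc2)
  expect_identical(est2$type, "upper_bound")
  expect_equal(est2$upper_bound, 2e-6, tolerance = 0.05)

  # curve that never reaches -3: explicitly unbounded with advice
  sc3 <- sc2; sc3$delta_lnL <- c(-0.1, -0.3, -0.5, -0.8, -1.0)
  est3 <- find_lifetime_or_bound(sc3)
  expect_identical(est3$type, "unbounded")
  expect_match(est3$note, "widen")
})

test_that("start-state bound fraction is simple counting", {
  mk <- function(E) photon_trajectory(seq(0, 0.1, length.out = 50),
                                      rbinom(50, 1, E))
  set.seed(9)
  trs <- c(lapply(1:6, function(i) mk(0.75)), lapply(1:4, function(i) mk(0.06)))
  expect_equal(estimate_pB_from_start(trs, 0.75, 0.06), 0.6)
  expect_equal(estimate_pB_from_start(trs[1:6], 0.75, 0.06), 1.0)
  expect_error(estimate_pB_from_start(list(), 0.75, 0.06), "no trajectories")
})

test_that("instantaneous-limit blinking fit recovers blink parameters", {
  set.seed(10)
  two <- two_state_params(0.6, 0.25, 300, 100)
  bl <- blink_params(k_b = 3000, k_0 = 600)   # at 500/ms: k_d = 3000, p_b = 0.5
  segs <- simulate_transition_segments(60, 0, 0.6, 0.425, 0.25,
                                       rate_ms = 500, window = 2e-3,
                                       blink = bl)
  f <- fit_blink_at_instantaneous(segs, two,
                                  init = c(E_B = 0.6, E_U = 0.25,
                                           k_b = 2500, p_b = 0.6))
  expect_lt(abs(f$params[["p_b"]] - 0.5) / f$stderr[["p_b"]], 3)
  expect_lt(abs(f$params[["k_b"]] - 3000) / f$stderr[["k_b"]], 3)
  expect_lt(abs(f$params[["E_B"]] - 0.6), 0.03)
  expect_lt(abs(f$params[["E_U"]] - 0.25), 0.03)
})

test_that("joint fit recovers an off-midpoint E_TC that the fixed scan cannot", {
  set.seed(11)
  two <- two_state_params(0.6, 0.25, 300, 100)
  segs <- simulate_transition_segments(60, 4e-4, 0.6, 0.30, 0.25,
                                       rate_ms = 500, window = 2.5e-3)
  f <- fit_joint_six(segs, two, blink = FALSE,
                     init = c(E_B = 0.6, E_U = 0.25, E_TC = 0.4, t_TC = 2e-4))
  expect_lt(abs(f$params[["E_TC"]] - 0.30) / f$stderr[["E_TC"]], 3)
  expect_gt(f$params[["t_TC"]], 4e-4 / 2)
  expect_lt(f$params[["t_TC"]], 4e-4 * 2)
})
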