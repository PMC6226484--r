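test_that("two-state constructor reproduces the textbook layout", {
  m <- make_two_state(two_state_params(0.6, 0.25, 300, 100))
  expect_equal(m$E_diag, c(0.6, 0.25))
  expect_equal(m$p_eq, c(0.75, 0.25))
  expect_equal(m$K, matrix(c(-100, 100, 300, -300), 2, 2))
  expect_equal(m$state_labels, c("B", "U"))
  # symmetric rates give p_B = 1/2
  ms <- make_two_state(two_state_params(0.6, 0.25, 123, 123))
  expect_equal(ms$p_eq, c(0.5, 0.5))
})

test_that("parameter validation rejects bad inputs", {
  expect_error(two_state_params(1.2, 0.25, 300, 100), "E_B")
  expect_error(two_state_params(0.6, 0.25, -3, 100), "k_A_app")
  expect_error(blink_params(k_b = 0, k_0 = 100), "k_b")
  expect_error(tc_params(E_TC = 0.4), "k_TC or t_TC")
  expect_error(tc_params(k_TC = 100, E_TC = 0.4, rate_reduction = 0.5),
               "rate_reduction")
  # efficiency ordering deliberately NOT enforced (donor-only unbound states)
  expect_silent(two_state_params(0.06, 0.75, 10, 10))
})

test_that("four-state blinking model ties k_d to the count rate", {
  two <- two_state_params(0.6, 0.25, 300, 100)
  bl <- blink_params(k_b = 3000, k_0 = 400)
  # at the reference rate, k_d = k_0
  m <- make_four_state(two, bl, n = 100)
  expect_equal(m$K[3, 1], 400)
  # linear scaling: n = 200 ms^-1, k_0 = 400 -> k_d = 800
  m2 <- make_four_state(two, bl, n = 200)
  expect_equal(m2$K[3, 1], 800)
  expect_equal(m2$E_diag, c(0.6, 0.25, 0.06, 0.06))
  # p_eq is the outer product of binding and blinking equilibria
  pb <- 3000 / (3000 + 800)
  expect_equal(m2$p_eq, c(0.75 * pb, 0.25 * pb, 0.75 * (1 - pb),
                          0.25 * (1 - pb)))
  # k_b large: p_b -> 1, bright-state p_eq approaches the two-state one
  m3 <- make_four_state(two, blink_params(k_b = 1e9, k_0 = 400), n = 100)
  expect_equal(m3$p_eq[1:2], c(0.75, 0.25), tolerance = 1e-6)
})

test_that("three-state transient-complex model applies the rate reduction", {
  two <- two_state_params(0.6, 0.25, 300, 100)
  m <- make_three_state_tc(two, tc_params(k_TC = 2500, E_TC = 0.425))
  expect_equal(m$K[2, 1], 0.1)     # k'_D = 100 / 1000
  expect_equal(m$K[2, 3], 0.3)     # k'_A = 300 / 1000
  expect_equal(m$K[1, 2], 2500)
  expect_equal(m$K[3, 2], 2500)
  expect_equal(m$E_diag, c(0.6, 0.425, 0.25))
  expect_equal(tc_lifetime(2500), 200e-6)
  # t_TC * 2 k_TC = 1 exactly
  for (k in c(1, 10, 1234.5)) expect_identical(tc_lifetime(k) * 2 * k, 1)
})

test_that("six-state rate matrix matches a literal hand transcription", {
  set.seed(41)
  for (rep in 1:10) {
    two <- rand_two(); tc <- rand_tc(); bl <- rand_blink()
    n <- runif(1, 50, 600)
    m <- make_six_state_tc(two, tc, bl, n)
    kd <- bl$k_0 * n / 100; kb <- bl$k_b
    kDp <- two$k_D / tc$rate_reduction
    kAp <- two$k_A_app / tc$rate_reduction
    kTC <- tc$k_TC
    K_ref <- rbind(
      c(-kDp - kd, kTC,            0,          kb,        0,              0),
      c(kDp,       -2 * kTC - kd,  kAp,        0,         kb,             0),
      c(0,         kTC,            -kAp - kd,  0,         0,              kb),
      c(kd,        0,              0,          -kDp - kb, kTC,            0),
      c(0,         kd,             0,          kDp,       -2 * kTC - kb,  kAp),
      c(0,         0,              kd,         0,         kTC,            -kAp - kb))
    expect_equal(m$K, K_ref, ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(m$E_diag, c(two$E_B, tc$E_TC, two$E_U, rep(bl$E_d, 3)))
  }
})

test_that("every constructor yields a stationary stochastic generator", {
  set.seed(42)
  for (kind in c("two", "three", "four", "six")) {
    for (rep in 1:10) {
      m <- rand_model(kind)
      scale <- max(abs(m$K))
      expect_lt(max(abs(colSums(m$K))), 1e-12 * scale)
      expect_lt(max(abs(m$K %*% m$p_eq)), 1e-10 * scale)
      expect_true(all(m$p_eq >= 0))
      expect_equal(sum(m$p_eq), 1)
      expect_true(all(m$E_diag >= 0 & m$E_diag <= 1))
      off <- m$K; diag(off) <- 0
      expect_true(all(off >= 0))
    }
  }
})

test_that("six-state model nests the three-state model as blinking vanishes", {
  two <- two_state_params(0.6, 0.25, 300, 100)
  tc <- tc_params(t_TC = 2e-4, E_TC = 0.4)
  m3 <- make_three_state_tc(two, tc)
  m6 <- make_six_state_tc(two, tc, blink_params(k_b = 5000, k_0 = 1e-9), 100)
  expect_equal(m6$K[1:3, 1:3] + diag(1e-9 * 100 / 100, 3), m3$K,
               tolerance = 1e-6)
  expect_equal(m6$p_eq[1:3], m3$p_eq, tolerance = 1e-6)
})

test_that("derived kinetic quantities follow their closed forms", {
  expect_equal(association_rate_coefficient(3.8, 1e-9), 3.8e9)
  expect_equal(association_rate_coefficient(0, 1e-9), 0)
  k1 <- association_rate_coefficient(50, 2e-8)
  expect_equal(association_rate_coefficient(50, 4e-8), k1 / 2)
  expect_error(association_rate_coefficient(50, 0), "positive")

  expect_equal(effective_kA(scheme_params(1e10, 1e5, 1e4)), 9.0909091e8,
               tolerance = 1e-6)
  expect_equal(effective_kA(scheme_params(5e9, 10, 1e6)), 5e9,
               tolerance = 1e-4)  # k_minus << k_f: diffusion limited
  expect_equal(effective_kA(scheme_params(2e9, 500, 500)), 1e9)  # k_f = k_minus
})

test_that("parameter configs round-trip through flat JSON", {
  two <- two_state_params(0.61, 0.27, 312.5, 98)
  bl <- blink_params(k_b = 2750, k_0 = 430, E_d = 0.05)
  tc <- tc_params(k_TC = 2730, E_TC = 0.44, rate_reduction = 1000)
  path <- tempfile(fileext = ".json")
  params_to_config(path, two = two, blink = bl, tc = tc)
  back <- params_from_config(path)
  expect_equal(back$two, two)
  expect_equal(back$blink, bl)
  expect_equal(back$tc, tc)
  keys <- names(jsonlite::fromJSON(path))
  expect_true(all(c("E_B", "E_U", "k_A_app", "k_D", "E_d", "k_b", "k_0",
                    "E_TC", "k_TC", "rate_reduction") %in% keys))
})
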