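test_that("rate matrix has the generator structure inside and outside the window", {
  mod <- demo_model()
  # outside the window only silencing is active
  Qo <- rate_matrix(mod, 1)
  expect_equal(Qo[1, ], c(-mod$silencing_rate, mod$silencing_rate, 0, 0))
  expect_true(all(Qo[2, ] == 0))              # silenced row absorbing
  # inside the window scarring flows 0 -> scar_i at r * s_i
  Qi <- rate_matrix(mod, 5)
  expect_equal(Qi[1, 3:4], mod$edit_rate * mod$scarring_multipliers)
  expect_equal(Qi[3, ], c(0, mod$silencing_rate, -mod$silencing_rate, 0))
  for (tt in c(0, 2.9, 3, 6, 9, 9.1, 20))
    expect_equal(rowSums(rate_matrix(mod, tt)), rep(0, 4), tolerance = 1e-12)
  # no silencing, outside window: nothing happens
  mod0 <- editing_model(0.3, c(1, 1), silencing_rate = 0,
                        window_start = 2, window_end = 4)
  expect_true(all(rate_matrix(mod0, 1) == 0))
  expect_error(rate_matrix(mod, -1), "non-negative")
})

test_that("closed-form transition probabilities match direct expectations", {
  # S = 1 direct read: row 0 of the in-window generator is (-2, 0, 2)
  m1 <- editing_model(2, 1, silencing_rate = 0, window_start = 0, window_end = 10)
  expect_equal(rate_matrix(m1, 5)[1, ], c(-2, 0, 2))
  # zero elapsed time: identity
  mod <- demo_model()
  expect_equal(transition_probabilities(mod, 4, 4), diag(4))
  # saturated editing, no silencing: scar odds proportional to multipliers
  msat <- editing_model(50, c(3, 1), silencing_rate = 0,
                        window_start = 0, window_end = 10)
  P <- transition_probabilities(msat, 0, 10)
  expect_equal(P[1, 3], 0.75, tolerance = 1e-9)
  expect_equal(P[1, 4], 0.25, tolerance = 1e-9)
  # interval straddling the window boundary is a contract violation
  expect_error(transition_probabilities(mod, 1, 5), "straddles")
  expect_error(transition_probabilities(mod, 5, 4))
})

test_that("analytic transition matrices agree with the matrix exponential", {
  skip_if_not_installed("Matrix")
  set.seed(42)
  worst <- 0
  for (i in 1:60) {
    mod <- random_model()
    # window-homogeneous intervals (inside and outside)
    for (iv in list(c(mod$window_start, mod$window_end),
                    sort(runif(2, mod$window_start, mod$window_end)),
                    c(0, mod$window_start),
                    mod$window_end + sort(runif(2, 0, 6)))) {
      if (iv[2] <= iv[1]) next
      P <- transition_probabilities(mod, iv[1], iv[2])
      Q <- rate_matrix(mod, mean(iv))
      Pe <- as.matrix(Matrix::expm(Q * (iv[2] - iv[1])))
      worst <- max(worst, max(abs(P - Pe)))
      expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-12)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("propagation across the window equals the piecewise expm oracle", {
  skip_if_not_installed("Matrix")
  set.seed(7)
  for (i in 1:25) {
    mod <- random_model()
    a <- runif(1, 0, mod$window_start)
    b <- mod$window_end + runif(1, 0, 5)
    P <- propagate_across_window(mod, a, b)
    oracle <- diag(mod$scar_count + 2L)
    cuts <- c(a, mod$window_start, mod$window_end, b)
    for (s in 1:3) {
      Q <- rate_matrix(mod, mean(cuts[s:(s + 1)]))
      oracle <- oracle %*% as.matrix(Matrix::expm(Q * diff(cuts[s:(s + 1)])))
    }
    expect_lt(max(abs(P - oracle)), 1e-9)
    expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-12)
  }
  # with no silencing, nothing outside the window matters
  m0 <- editing_model(0.2, c(1.5, 1), silencing_rate = 0,
                      window_start = 2, window_end = 6)
  P1 <- propagate_across_window(m0, 0, 12)
  expect_equal(P1[1, 1], exp(-0.2 * 2.5 * 4), tolerance = 1e-12)
  expect_equal(propagate_across_window(m0, 2, 6),
               transition_probabilities(m0, 2, 6))
})

test_that("Chapman-Kolmogorov, absorbing silencing and irreversibility hold", {
  set.seed(13)
  for (i in 1:20) {
    mod <- random_model()
    abc <- sort(runif(3, 0, 14))
    P_ac <- propagate_across_window(mod, abc[1], abc[3])
    P_2 <- propagate_across_window(mod, abc[1], abc[2]) %*%
      propagate_across_window(mod, abc[2], abc[3])
    expect_lt(max(abs(P_ac - P_2)), 1e-10)
    # silenced row is the unit vector forever; no transitions out of scars
    expect_equal(P_ac[2, ], c(0, 1, rep(0, mod$scar_count)))
    expect_true(all(P_ac[-(1:2), 1] == 0))
    if (mod$scar_count > 1) {
      offdiag <- P_ac[-(1:2), -(1:2)]; diag(offdiag) <- 0
      expect_true(all(offdiag == 0))
    }
    # silenced mass is non-decreasing in elapsed time
    P_short <- propagate_across_window(mod, abc[1], abc[2])
    expect_true(all(P_ac[, 2] >= P_short[, 2] - 1e-12))
  }
})

test_that("multiplier and clock parameterizations give identical matrices", {
  mod <- demo_model(r = 0.1, s = c(3, 1))
  clk <- as_clock_model(mod)
  expect_equal(clk$edit_rate, 0.4)
  expect_equal(sum(clk$scarring_multipliers), 1)
  for (iv in list(c(3, 9), c(0, 3), c(9, 12)))
    expect_equal(transition_probabilities(mod, iv[1], iv[2]),
                 transition_probabilities(clk, iv[1], iv[2]),
                 tolerance = 1e-12)
  expect_equal(as_multiplier_model(clk)$edit_rate, mod$edit_rate)
})

test_that("degenerate multipliers and JSON round-trip behave", {
  # sigma = 0 via edit_rate = 0: no scarring mass, no 0/0
  m0 <- editing_model(0, c(2, 1), silencing_rate = 0.05,
                      window_start = 0, window_end = 5)
  P <- transition_probabilities(m0, 0, 5)
  expect_equal(P[1, 3:4], c(0, 0))
  expect_equal(P[1, 1], exp(-0.25))
  lst <- editing_model_to_list(demo_model())
  rt <- editing_model_from_list(lst)
  expect_equal(rt, demo_model())
  expect_error(editing_model(0.1, c(2, 2), window_end = 5),
               "last scarring multiplier")
  expect_error(editing_model(0.1, c(0.4, 0.4), window_end = 5,
                             parameterization = "clock"), "summing to 1")
})
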