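test_that("Monod fraction has its defining values and rejects bad k", {
  expect_equal(monod(0, 200), 0)
  expect_equal(monod(200, 200), 0.5)
  expect_equal(monod(50, 200), 0.2)
  expect_error(monod(1, 0), "half-saturation")
  expect_error(monod(-1, 1), ">= 0")
  # monotone, bounded in [0, 1)
  s <- seq(0, 1e4, length.out = 100)
  v <- monod(s, 200)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v >= 0 & v < 1))
})

test_that("double-Monod growth needs both nutrients and saturates at mu", {
  expect_equal(growth_rate(1, 0, 123, eq3), 0)
  expect_equal(growth_rate(2, 123, 0, eq3), 0)
  expect_equal(growth_rate(1, 200, 200, eq3), eq3$mu1 / 4)
  expect_equal(growth_rate(1, 50, 1, eq3), 1600 * (50 / 250) * (1 / 201))
  expect_lt(growth_rate(1, 1e9, 1e9, eq3), eq3$mu1)
  expect_error(growth_rate(3, 1, 1, eq3))
})

test_that("chemostat RHS matches the balance structure", {
  s_in <- c(eq3$s0_in, eq3$s1_in, eq3$s2_in)
  # washout equilibrium: exactly zero derivatives
  expect_equal(unname(chemostat_rhs(c(0, 0, s_in), eq3)), rep(0, 5))
  # empty vessel, no carbon: pure inflow phi * s0_in
  d <- chemostat_rhs(c(0, 0, 0, 1, 1), eq3)
  expect_equal(unname(d["s0"]), 2 * 50)
  # growth balancing outflow freezes the species density
  # (find s0 with f1 = phi at s2 = s2_in via the Monod inverse)
  target <- eq3$phi / (eq3$mu1 * monod(eq3$s2_in, eq3$k12))
  s0_bal <- target * eq3$k10 / (1 - target)
  d2 <- chemostat_rhs(c(5, 0, s0_bal, 1, eq3$s2_in), eq3)
  expect_equal(unname(d2["x1"]), 0, tolerance = 1e-12)
  expect_error(chemostat_rhs(c(-1, 0, 50, 1, 1), eq3), "negative")
})

test_that("eLV RHS matches hand arithmetic and fixes the origin", {
  expect_equal(unname(elv_rhs(0, 0, eq6)), c(0, 0))
  expect_equal(unname(elv_rhs(1, 0, eq6))[1], (0.027 * (50 - 5) - 2) * 1)
  # symmetric coexistence root of 0.2 X^2 - 5 X + (2/0.027 - 50) = 0
  x <- eq6_sym_roots[2]
  expect_equal(unname(elv_rhs(x, x, eq6)), c(0, 0), tolerance = 1e-9)
})

test_that("eLV cross-effect switches from mutualism to competition at b12/(2c1)", {
  x1 <- 0.5
  flip <- eq6$b12 / (2 * eq6$c1)
  dfdx2 <- function(x2) elv_jacobian(eq6, x1, x2)[1, 2]
  expect_gt(dfdx2(flip - 5), 0)
  expect_lt(dfdx2(flip + 5), 0)
})

test_that("simulation reproduces the reference attractors", {
  # low growth rates: extinction for generous initial densities
  tr <- simulate_model("chemostat", fixture("fig2a"),
                       c(10, 10, 50, 1, 1), t_end = 100)
  oc <- classify_outcome(tr)
  expect_false(oc$survives1)
  expect_false(oc$survives2)
  # eLV: origin attracts low densities (r a - d = -0.65 < 0)
  tr2 <- simulate_model("elv", eq6, c(0.01, 0.01), t_end = 400)
  expect_equal(unname(tr2$states[nrow(tr2$states), ]), c(0, 0),
               tolerance = 1e-8)
  # eLV: high densities reach the symmetric coexistence state
  tr3 <- simulate_model("elv", eq6, c(15, 15), t_end = 400)
  expect_equal(unname(tr3$states[nrow(tr3$states), ]),
               rep(eq6_sym_roots[2], 2), tolerance = 1e-5)
})

test_that("outcome classification applies the extinction threshold", {
  tr <- simulate_model("elv", eq6, c(15, 15), t_end = 400)
  oc <- classify_outcome(tr, eps = 1e-6)
  expect_true(oc$survives1 && oc$survives2)
  expect_true(oc$converged)
  # threshold logic on a synthetic near-extinct endpoint
  fake <- tr
  fake$states[nrow(fake$states), ] <- c(2, 1e-9)
  oc2 <- suppressWarnings(classify_outcome(fake, eps = 1e-6))
  expect_true(oc2$survives1)
  expect_false(oc2$survives2)
  # non-converged trajectories warn but still classify
  short <- simulate_model("elv", eq6, c(15, 15), t_end = 0.01)
  expect_warning(classify_outcome(short), "not converged")
})

test_that("states stay nonnegative and washout empties the vessel", {
  set.seed(42)
  for (k in 1:5) {
    p <- random_chemostat_params()
    x0 <- runif(2, 0, 20)
    tr <- simulate_model("chemostat", p,
                         c(x0, p$s0_in, p$s1_in, p$s2_in),
                         t_end = 60 / p$phi, n_out = 101)
    expect_true(all(tr$states >= 0))   # clipped at reporting
  }
  p <- random_chemostat_params()
  tr <- simulate_model("chemostat", p, c(0, 0, 2 * p$s0_in, 0, 5),
                       t_end = 60 / p$phi)
  expect_equal(unname(tr$states[nrow(tr$states), 3:5]),
               c(p$s0_in, p$s1_in, p$s2_in), tolerance = 1e-6)
})

test_that("dilution combinations relax exponentially at rate phi", {
  # Q_j = S_j - sum_i nu_ji X_i obeys dQ/dt = phi (S~_j - Q_j) exactly,
  # so Q_j(t) - S~_j = (Q_j(0) - S~_j) exp(-phi t) along any trajectory.
  set.seed(7)
  for (k in 1:4) {
    p <- if (k == 1) eq3 else random_chemostat_params()
    init <- c(runif(2, 0, 20), p$s0_in * runif(1, 0.5, 2),
              runif(2, 0, 5))
    tr <- simulate_model("chemostat", p, init, t_end = 8 / p$phi,
                         n_out = 81, rtol = 1e-10, atol = 1e-12)
    nus <- rbind(c(p$nu01, p$nu02), c(p$nu11, p$nu12), c(p$nu21, p$nu22))
    s_in <- c(p$s0_in, p$s1_in, p$s2_in)
    X <- tr$states[, 1:2]; S <- tr$states[, 3:5]
    Q <- S - X %*% t(nus)
    Q0 <- init[3:5] - nus %*% init[1:2]
    pred <- outer(exp(-p$phi * tr$times), as.numeric(Q0 - s_in)) +
      rep(s_in, each = nrow(Q))
    expect_equal(unname(Q), unname(pred), tolerance = 1e-5)
  }
})

test_that("trajectory CSV round-trips with the contracted header", {
  tr <- simulate_model("elv", eq6, c(15, 15), t_end = 10, n_out = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  expect_identical(readLines(f, n = 1), "t,X1,X2")
  back <- read.csv(f)
  expect_equal(back$X1, unname(tr$states[, 1]))
  trc <- simulate_model("chemostat", eq3, c(10, 10, 50, 1, 1),
                        t_end = 10, n_out = 11)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(trc, f2)
  expect_identical(readLines(f2, n = 1), "t,X1,X2,S0,S1,S2")
})
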