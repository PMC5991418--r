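test_that("spectrum classification separates stable, saddle, unstable, marginal", {
  expect_identical(stability_of(c(-0.65, -0.65))$verdict, "stable")
  expect_identical(stability_of(c(0.42, -2.18))$verdict, "saddle")
  expect_identical(stability_of(c(0.3, 0.1))$verdict, "unstable")
  m <- stability_of(c(0, -1), tol = 1e-9)
  expect_true(m$marginal)
  expect_identical(stability_of(complex(real = c(-1, -1),
                                        imaginary = c(2, -2)))$verdict,
                   "stable")
})

test_that("eLV Jacobian matches closed forms and finite differences", {
  J0 <- elv_jacobian(eq6, 0, 0)
  expect_equal(J0, diag(c(0.027 * 50 - 2, 0.027 * 50 - 2)))
  x <- eq6_sym_roots[2]
  J <- elv_jacobian(eq6, x, x)
  expect_equal(J[1, 1], -eq6$r1 * eq6$b11 * x, tolerance = 1e-9)
  expect_equal(J[1, 2], J[2, 1], tolerance = 1e-12)
  # central finite differences at a generic point
  h <- 1e-6; pt <- c(3.7, 12.1)
  num <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    num[, j] <- (elv_rhs(pt[1] + e[1], pt[2] + e[2], eq6) -
                 elv_rhs(pt[1] - e[1], pt[2] - e[2], eq6)) / (2 * h)
  }
  expect_equal(elv_jacobian(eq6, pt[1], pt[2]), num, tolerance = 1e-6)
})

test_that("Newton solver lands on the closed-form roots and flags failures", {
  rhs <- function(x) unname(elv_rhs(x[1], x[2], eq6))
  jac <- function(x) elv_jacobian(eq6, x[1], x[2])
  exact <- rep(eq6_sym_roots[2], 2)
  at_root <- newton_solve(rhs, jac, exact)
  expect_true(at_root$converged)
  expect_lte(at_root$iterations, 1L)
  ns <- newton_solve(rhs, jac, c(15, 15), tol = 1e-10)
  expect_true(ns$converged)
  expect_equal(ns$root, exact, tolerance = 1e-8)
  ns2 <- newton_solve(rhs, jac, c(7, 6), tol = 1e-10)
  expect_equal(ns2$root, rep(eq6_sym_roots[1], 2), tolerance = 1e-8)
  # singular Jacobian reported, not silently returned
  bad <- newton_solve(function(x) c(x[1]^2, 1), function(x) matrix(0, 2, 2),
                      c(1, 1))
  expect_false(bad$converged)
})

test_that("reference eLV set has E stable plus a stable/saddle coexistence pair", {
  fps <- elv_fixed_points(eq6)
  labs <- vapply(fps, function(f) f$label, character(1))
  expect_setequal(unique(labs), c("E", "L12"))
  expect_identical(sum(labs == "L12"), 2L)
  E <- fps[[which(labs == "E")]]
  expect_true(E$stable)
  expect_equal(sort(Re(E$eigenvalues)), c(-0.65, -0.65))
  l12 <- fps[labs == "L12"]
  coords <- t(vapply(l12, function(f) f$coords, numeric(2)))
  o <- order(coords[, 1])
  expect_equal(coords[o[1], ], rep(eq6_sym_roots[1], 2), tolerance = 1e-4)
  expect_equal(coords[o[2], ], rep(eq6_sym_roots[2], 2), tolerance = 1e-4)
  expect_identical(l12[[o[1]]]$stability, "saddle")
  expect_true(l12[[o[2]]]$stable)
  expect_equal(sort(Re(l12[[o[2]]]$eigenvalues)), c(-3.796, -1.196),
               tolerance = 1e-3)
})

test_that("low growth removes coexistence; asymmetric growth creates a stable boundary state", {
  p_lo <- eq6; p_lo$r1 <- 0.02; p_lo$r2 <- 0.02
  labs <- vapply(elv_fixed_points(p_lo), function(f) f$label, character(1))
  expect_false("L12" %in% labs)
  p_as <- eq6; p_as$r1 <- 0.05; p_as$r2 <- 0.02
  fps <- elv_fixed_points(p_as)
  l1 <- Filter(function(f) f$label == "L1", fps)
  expect_length(l1, 1)
  expect_equal(l1[[1]]$coords, c((50 - 2 / 0.05) / 5, 0), tolerance = 1e-9)
  expect_true(l1[[1]]$stable)
  # eigenvalues: longitudinal -r1 b11 X1 = -0.5 and transverse
  # r2 (a2 + b21 X1 - c2 X1^2) - d = -0.616
  expect_equal(sort(Re(l1[[1]]$eigenvalues)), c(-0.616, -0.5),
               tolerance = 1e-9)
})

test_that("every returned fixed point is a tight root and matches the scan oracle", {
  set.seed(23)
  for (k in 1:200) {
    p <- random_elv_params()
    fps <- elv_fixed_points(p)
    for (f in fps)
      expect_lt(f$residual, 1e-9)
    got <- t(vapply(Filter(function(f) f$label == "L12", fps),
                    function(f) f$coords, numeric(2)))
    want <- oracle_coexistence_states(p)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      got <- got[order(got[, 2]), , drop = FALSE]
      want <- want[order(want[, 2]), , drop = FALSE]
      expect_equal(unname(got), unname(want), tolerance = 1e-6)
    }
  }
})

test_that("fixed-point sets respect the species-swap symmetry", {
  set.seed(29)
  for (k in 1:30) {
    p <- random_elv_params()
    a <- elv_fixed_points(p)
    b <- elv_fixed_points(swap_species_elv(p))
    sig <- function(fps) {
      m <- t(vapply(fps, function(f) c(f$coords, as.numeric(f$stable)),
                    numeric(3)))
      m[order(m[, 1], m[, 2]), , drop = FALSE]
    }
    swapped <- sig(lapply(b, function(f) {
      f$coords <- rev(f$coords); f
    }))
    expect_equal(sig(a), swapped, tolerance = 1e-6)
  }
})

test_that("chemostat enumeration always returns the exact washout state", {
  set.seed(31)
  for (k in 1:5) {
    p <- if (k == 1) eq3 else random_chemostat_params()
    fps <- chemostat_fixed_points(p, n_starts = 5, sim_starts = FALSE)
    w <- Filter(function(f) f$label == "washout", fps)
    expect_length(w, 1)
    expect_identical(w[[1]]$coords,
                     c(0, 0, p$s0_in, p$s1_in, p$s2_in))
    expect_identical(w[[1]]$residual, 0)
  }
})

test_that("reference chemostat set is bistable; halved growth washes out", {
  fps <- chemostat_fixed_points(eq3, n_starts = 20, seed = 0)
  stable <- Filter(function(f) f$stable, fps)
  labs <- sort(vapply(stable, function(f) f$label, character(1)))
  expect_identical(labs, c("coexistence", "washout"))
  fps2 <- chemostat_fixed_points(fixture("fig2a"), n_starts = 20, seed = 0)
  stable2 <- Filter(function(f) f$stable, fps2)
  expect_identical(vapply(stable2, function(f) f$label, character(1)),
                   "washout")
})

test_that("chemostat stable-state survival pattern matches the reduced model's", {
  chem <- chemostat_fixed_points(eq3, seed = 0)
  chem_pattern <- sort(unique(vapply(Filter(function(f) f$stable, chem),
                                     function(f) f$label, character(1))))
  lv <- elv_fixed_points(reduce_to_lv(eq3, "leading_order",
                                      r_override = c(0.027, 0.027)))
  lv_pattern <- sort(unique(vapply(Filter(function(f) f$stable, lv),
                                   function(f) f$label, character(1))))
  expect_identical(chem_pattern, c("coexistence", "washout"))
  expect_identical(lv_pattern, c("E", "L12"))
})
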