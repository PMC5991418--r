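# Shared helpers: reference parameter sets and random-parameter generators.

eq3 <- fixture("eq3")
eq6 <- fixture("eq6")

# Closed-form symmetric coexistence roots of the eq6 set:
# 0.2 X^2 - 5 X + (2/0.027 - 50) = 0
eq6_sym_roots <- local({
  cc <- 0.2; b <- 5; q <- 2 / 0.027 - 50
  disc <- sqrt(b^2 - 4 * cc * q)
  sort((b + c(-1, 1) * disc) / (2 * cc))   # 6.510, 18.490
})

# Random valid eLV parameter sets spanning mono- and bistable regimes.
random_elv_params <- function() {
  elv_params(d = runif(1, 0.5, 3),
             r1 = exp(runif(1, log(0.01), log(0.1))),
             r2 = exp(runif(1, log(0.01), log(0.1))),
             a1 = runif(1, 20, 100), a2 = runif(1, 20, 100),
             b11 = runif(1, 2, 10), b22 = runif(1, 2, 10),
             b12 = runif(1, 2, 20), b21 = runif(1, 2, 20),
             c1 = runif(1, 0.05, 0.5), c2 = runif(1, 0.05, 0.5))
}

# Random valid chemostat parameter sets (magnitudes around the reference
# set, reference sign pattern).
random_chemostat_params <- function() {
  lu <- function(v) exp(runif(1, log(v / 5), log(v * 5)))
  chemostat_params(phi = lu(2), mu1 = lu(1600), mu2 = lu(1600),
                   s0_in = lu(50), s1_in = lu(1), s2_in = lu(1),
                   k10 = lu(200), k12 = lu(200), k20 = lu(200), k21 = lu(200),
                   nu01 = -lu(1), nu02 = -lu(1),
                   nu11 = lu(0.2), nu12 = -lu(0.1),
                   nu21 = -lu(0.1), nu22 = lu(0.2))
}

# Species-swap maps written out independently of the package internals.
swap_species_elv <- function(p) {
  elv_params(d = p$d, r1 = p$r2, r2 = p$r1, a1 = p$a2, a2 = p$a1,
             b11 = p$b22, b12 = p$b21, b21 = p$b12, b22 = p$b11,
             c1 = p$c2, c2 = p$c1)
}
swap_species_chemostat <- function(p) {
  chemostat_params(phi = p$phi, mu1 = p$mu2, mu2 = p$mu1,
                   s0_in = p$s0_in, s1_in = p$s2_in, s2_in = p$s1_in,
                   k10 = p$k20, k12 = p$k21, k20 = p$k10, k21 = p$k12,
                   nu01 = p$nu02, nu02 = p$nu01,
                   nu11 = p$nu22, nu12 = p$nu21,
                   nu21 = p$nu12, nu22 = p$nu11)
}

# Brute-force coexistence-state oracle: scan the composed nullcline
# residual h(X2) = nullcline-2 evaluated along nullcline-1's explicit
# branch for sign changes, then refine each bracket with uniroot. Fully
# independent of the quartic/companion-matrix route.
oracle_coexistence_states <- function(p, n_grid = 20000L) {
  alpha1 <- p$a1 - p$d / p$r1
  x1_of <- function(x2) (alpha1 + p$b12 * x2 - p$c1 * x2^2) / p$b11
  h <- function(x2) {
    x1 <- x1_of(x2)
    p$a2 - p$d / p$r2 - p$b22 * x2 + p$b21 * x1 - p$c2 * x1^2
  }
  # X2 range where nullcline 1 stays in the positive quadrant
  disc <- p$b12^2 + 4 * p$c1 * alpha1
  hi <- if (p$c1 > 0 && disc >= 0) (p$b12 + sqrt(disc)) / (2 * p$c1)
  else (p$b12 / (2 * p$c1)) + 100
  xs <- seq(1e-9, hi, length.out = n_grid)
  hv <- vapply(xs, h, numeric(1))
  roots <- c()
  for (i in seq_len(length(xs) - 1)) {
    if (is.finite(hv[i]) && is.finite(hv[i + 1]) &&
        sign(hv[i]) * sign(hv[i + 1]) < 0) {
      r <- uniroot(h, c(xs[i], xs[i + 1]), tol = 1e-12)$root
      roots <- c(roots, r)
    }
  }
  keep <- roots[vapply(roots, function(x2) x1_of(x2) > 0, logical(1))]
  cbind(X1 = vapply(keep, x1_of, numeric(1)), X2 = keep)
}
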