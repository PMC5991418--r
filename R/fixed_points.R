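#' Classify a Jacobian spectrum
#'
#' @param eigenvalues Complex or numeric eigenvalues.
#' @param tol Stability tolerance on real parts (default 1e-9).
#' @return List with \code{verdict} (\code{"stable"}, \code{"saddle"} or
#'   \code{"unstable"}) and \code{marginal} (TRUE when any real part lies
#'   within \code{tol} of zero).
#' @export
stability_of <- function(eigenvalues, tol = 1e-9) {
  re <- Re(eigenvalues)
  if (any(!is.finite(re))) stop("stability_of: non-finite eigenvalues")
  marginal <- any(abs(re) <= tol)
  verdict <- if (all(re < -tol)) "stable"
  else if (all(re > tol)) "unstable"
  else "saddle"
  list(verdict = verdict, marginal = marginal)
}

#' Jacobian of the extended Lotka-Volterra model
#'
#' Analytic linearisation at an arbitrary point. At a coexistence fixed
#' point the diagonal entries reduce to \eqn{-r_i b_{ii} X_i}.
#'
#' @param p An [elv_params()] object.
#' @param x1,x2 Densities at which to linearise.
#' @return A 2x2 numeric matrix.
#' @export
elv_jacobian <- function(p, x1, x2) {
  validate_elv_params(p)
  g1 <- p$r1 * (p$a1 - p$b11 * x1 + p$b12 * x2 - p$c1 * x2^2) - p$d
  g2 <- p$r2 * (p$a2 - p$b22 * x2 + p$b21 * x1 - p$c2 * x1^2) - p$d
  matrix(c(g1 - p$r1 * p$b11 * x1,        x1 * p$r1 * (p$b12 - 2 * p$c1 * x2),
           x2 * p$r2 * (p$b21 - 2 * p$c2 * x1), g2 - p$r2 * p$b22 * x2),
         nrow = 2, byrow = TRUE)
}

#' Newton-Raphson root finder
#'
#' Damped Newton iteration for a square system. Never silently returns a
#' non-converged point: the \code{converged} flag must be checked.
#'
#' @param rhs Function: state -> residual vector.
#' @param jac Function: state -> Jacobian matrix.
#' @param start Starting state.
#' @param tol Convergence tolerance on \eqn{\|rhs\|_\infty}.
#' @param max_iter Iteration cap.
#' @return List with \code{root}, \code{converged}, \code{iterations},
#'   \code{residual}, \code{message}.
#' @export
newton_solve <- function(rhs, jac, start, tol = 1e-10, max_iter = 50L) {
  x <- as.numeric(start)
  f <- rhs(x)
  if (any(!is.finite(f)))
    return(list(root = x, converged = FALSE, iterations = 0L,
                residual = Inf, message = "non-finite residual at start"))
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol)
      return(list(root = x, converged = TRUE, iterations = it - 1L,
                  residual = max(abs(f)), message = "converged"))
    J <- jac(x)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(root = x, converged = FALSE, iterations = it - 1L,
                  residual = max(abs(f)),
                  message = "singular or non-finite Jacobian"))
    # damped line search on the residual norm
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- rhs(xn)
      if (all(is.finite(fn)) &&
          (max(abs(fn)) < max(abs(f)) || lambda < 1e-4)) break
      lambda <- lambda / 2
    }
    x <- xn; f <- fn
    if (any(!is.finite(f)))
      return(list(root = x, converged = FALSE, iterations = it,
                  residual = Inf, message = "diverged"))
  }
  conv <- max(abs(f)) < tol
  list(root = x, converged = conv, iterations = max_iter,
       residual = max(abs(f)),
       message = if (conv) "converged" else "max iterations reached")
}

make_fixed_point <- function(coords, label, eigenvalues, residual,
                             stab_tol = 1e-9) {
  st <- stability_of(eigenvalues, stab_tol)
  structure(list(coords = coords, label = label,
                 eigenvalues = eigenvalues,
                 stable = st$verdict == "stable",
                 stability = st$verdict, marginal = st$marginal,
                 residual = residual),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("%s at (%s): %s%s, residual %.2e\n", x$label,
              paste(sprintf("%.6g", x$coords), collapse = ", "),
              x$stability, if (x$marginal) " (marginal)" else "",
              x$residual))
  invisible(x)
}

#' Fixed points of the extended Lotka-Volterra model
#'
#' Enumerates all steady states from the nullcline algebra. The origin E is
#' always a fixed point; the boundary states L1 = ((a1 - d/r1)/b11, 0) and
#' L2 (symmetric) exist when that density is positive. Coexistence states
#' L12 are found globally by substituting the explicit parabola of
#' nullcline 1 into nullcline 2, which yields a quartic in X2 solved via
#' the companion matrix (\code{polyroot}); positive real roots are polished
#' by Newton iteration on the 2-D system and deduplicated. Each state is
#' classified by the eigenvalues of the analytic Jacobian.
#'
#' @param p An [elv_params()] object.
#' @param tol Newton/residual tolerance.
#' @param stab_tol Stability tolerance on eigenvalue real parts.
#' @param dedup_tol Relative merge tolerance for duplicate roots.
#' @return List of \code{fixed_point} objects (E first).
#' @examples
#' fps <- elv_fixed_points(fixture("eq6"))
#' sapply(fps, function(f) f$label)
#' @export
elv_fixed_points <- function(p, tol = 1e-10, stab_tol = 1e-9,
                             dedup_tol = 1e-6) {
  validate_elv_params(p)
  rhs <- function(x) unname(elv_rhs(x[1], x[2], p))
  jac <- function(x) elv_jacobian(p, x[1], x[2])
  fps <- list()

  eig0 <- eigen(jac(c(0, 0)), only.values = TRUE)$values
  fps[[1]] <- make_fixed_point(c(0, 0), "E", eig0, max(abs(rhs(c(0, 0)))),
                               stab_tol)

  l1 <- (p$a1 - p$d / p$r1) / p$b11
  if (is.finite(l1) && l1 > 0) {
    eigs <- eigen(jac(c(l1, 0)), only.values = TRUE)$values
    fps[[length(fps) + 1]] <- make_fixed_point(c(l1, 0), "L1", eigs,
                                               max(abs(rhs(c(l1, 0)))), stab_tol)
  }
  l2 <- (p$a2 - p$d / p$r2) / p$b22
  if (is.finite(l2) && l2 > 0) {
    eigs <- eigen(jac(c(0, l2)), only.values = TRUE)$values
    fps[[length(fps) + 1]] <- make_fixed_point(c(0, l2), "L2", eigs,
                                               max(abs(rhs(c(0, l2)))), stab_tol)
  }

  roots <- elv_coexistence_roots(p)
  kept <- list()
  for (x2 in roots) {
    x1 <- (p$a1 - p$d / p$r1 + p$b12 * x2 - p$c1 * x2^2) / p$b11
    if (!is.finite(x1) || x1 <= 0 || x2 <= 0) next
    ns <- newton_solve(rhs, jac, c(x1, x2), tol = tol)
    if (!ns$converged) next
    if (any(ns$root <= 0)) next
    dup <- any(vapply(kept, function(k)
      max(abs(k - ns$root)) <= dedup_tol * (1 + max(abs(ns$root))), logical(1)))
    if (dup) next
    kept[[length(kept) + 1]] <- ns$root
    eigs <- eigen(jac(ns$root), only.values = TRUE)$values
    fps[[length(fps) + 1]] <- make_fixed_point(ns$root, "L12", eigs,
                                               ns$residual, stab_tol)
  }
  fps
}

# Candidate X2 coordinates of coexistence states: real roots of the quartic
# obtained by substituting nullcline 1's explicit branch into nullcline 2.
elv_coexistence_roots <- function(p) {
  alpha1 <- p$a1 - p$d / p$r1
  alpha2 <- p$a2 - p$d / p$r2
  # X1(X2) = (q0 + q1 X2 + q2 X2^2)/b11
  q <- c(alpha1, p$b12, -p$c1)
  # alpha2 - b22 X2 + (b21/b11)(q0+q1x+q2x^2) - (c2/b11^2)(q0+q1x+q2x^2)^2 = 0
  sq <- c(q[1]^2,
          2 * q[1] * q[2],
          q[2]^2 + 2 * q[1] * q[3],
          2 * q[2] * q[3],
          q[3]^2)
  coef <- c(alpha2, -p$b22, 0, 0, 0) +
    (p$b21 / p$b11) * c(q, 0, 0) -
    (p$c2 / p$b11^2) * sq
  # strip (numerically) vanishing leading coefficients
  scale <- max(abs(coef), 1e-300)
  while (length(coef) > 1 && abs(coef[length(coef)]) < 1e-14 * scale)
    coef <- coef[-length(coef)]
  if (length(coef) <= 1) return(numeric(0))
  z <- polyroot(coef)
  re <- Re(z)[abs(Im(z)) < 1e-7 * (1 + abs(z))]
  sort(unique(re[re > 0]))
}

# Analytic 5x5 Jacobian of the chemostat model.
chemostat_jacobian <- function(state, p) {
  x1 <- state[1]; x2 <- state[2]
  s0 <- state[3]; s1 <- state[4]; s2 <- state[5]
  m10 <- monod(max(s0, 0), p$k10); m12 <- monod(max(s2, 0), p$k12)
  m20 <- monod(max(s0, 0), p$k20); m21 <- monod(max(s1, 0), p$k21)
  f1 <- p$mu1 * m10 * m12
  f2 <- p$mu2 * m20 * m21
  df1_s0 <- p$mu1 * p$k10 / (p$k10 + s0)^2 * m12
  df1_s2 <- p$mu1 * m10 * p$k12 / (p$k12 + s2)^2
  df2_s0 <- p$mu2 * p$k20 / (p$k20 + s0)^2 * m21
  df2_s1 <- p$mu2 * m20 * p$k21 / (p$k21 + s1)^2
  J <- matrix(0, 5, 5)
  J[1, ] <- c(f1 - p$phi, 0, x1 * df1_s0, 0, x1 * df1_s2)
  J[2, ] <- c(0, f2 - p$phi, x2 * df2_s0, x2 * df2_s1, 0)
  nus <- rbind(c(p$nu01, p$nu02), c(p$nu11, p$nu12), c(p$nu21, p$nu22))
  for (j in 1:3) {
    J[2 + j, 1] <- nus[j, 1] * f1
    J[2 + j, 2] <- nus[j, 2] * f2
    J[2 + j, 3] <- nus[j, 1] * x1 * df1_s0 + nus[j, 2] * x2 * df2_s0
    J[2 + j, 4] <- nus[j, 2] * x2 * df2_s1
    J[2 + j, 5] <- nus[j, 1] * x1 * df1_s2
  }
  J[3, 3] <- J[3, 3] - p$phi
  J[4, 4] <- J[4, 4] - p$phi
  J[5, 5] <- J[5, 5] - p$phi
  J
}

#' Fixed points of the chemostat model
#'
#' Multi-start Newton-Raphson enumeration of chemostat steady states. The
#' washout state (X = 0, nutrients at inflow) is an exact equilibrium and is
#' always included. Further deterministic starts are the endpoints of
#' simulations from a fixed ladder of initial densities (the protocol used
#' for outcome classification), augmented by seeded log-uniform random
#' starts. Every converged root is polished, deduplicated, labelled by its
#' survival pattern (washout / single1 / single2 / coexistence) and
#' classified via the analytic 5x5 Jacobian.
#'
#' @param p A [chemostat_params()] object.
#' @param n_starts Number of random starts (default 20).
#' @param seed Seed for the random starts (default 0).
#' @param tol Newton tolerance.
#' @param eps Extinction threshold used for labelling.
#' @param sim_starts If TRUE (default), include simulation endpoints from
#'   the 10-density protocol as Newton starts.
#' @return List of \code{fixed_point} objects, washout first.
#' @export
chemostat_fixed_points <- function(p, n_starts = 20L, seed = 0L,
                                   tol = 1e-9, eps = 1e-6,
                                   sim_starts = TRUE) {
  validate_chemostat_params(p)
  rhs <- function(x) unname(chemostat_rhs(pmax(x, 0), p))
  jac <- function(x) chemostat_jacobian(pmax(x, 0), p)
  s_in <- c(p$s0_in, p$s1_in, p$s2_in)

  washout <- c(0, 0, s_in)
  fps <- list(make_fixed_point(
    washout, "washout",
    eigen(jac(washout), only.values = TRUE)$values,
    max(abs(rhs(washout)))))
  kept <- list(washout)

  starts <- list()
  if (sim_starts) {
    for (x0 in fig2_initial_densities()) {
      tr <- simulate_model("chemostat", p, c(x0, x0, s_in),
                           t_end = 100 / p$phi, n_out = 5L,
                           rtol = 1e-8, atol = 1e-10)
      starts[[length(starts) + 1]] <- tr$states[nrow(tr$states), ]
    }
  }
  xmax <- 10 * max(s_in, 20)
  rs <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    matrix(exp(stats::runif(5L * n_starts, log(1e-3), log(xmax))),
           ncol = 5)
  })
  for (i in seq_len(nrow(rs))) starts[[length(starts) + 1]] <- rs[i, ]

  for (st in starts) {
    ns <- newton_solve(rhs, jac, st, tol = tol)
    if (!ns$converged) next
    root <- ns$root
    root[abs(root) < 1e-8] <- 0   # snap round-off onto the boundary
    if (any(root < 0)) next
    dup <- any(vapply(kept, function(k)
      max(abs(k - root)) <= 1e-6 * (1 + max(abs(root))), logical(1)))
    if (dup) next
    if (max(abs(rhs(root))) > tol * 10) next
    kept[[length(kept) + 1]] <- root
    lab <- survival_label(root[1] > eps, root[2] > eps, chemostat = TRUE)
    fps[[length(fps) + 1]] <- make_fixed_point(
      root, lab, eigen(jac(root), only.values = TRUE)$values,
      max(abs(rhs(root))))
  }
  fps
}

# The outcome-classification protocol: 10 initial densities spanning (0, 20].
fig2_initial_densities <- function() seq(2, 20, by = 2)

survival_label <- function(s1, s2, chemostat = FALSE) {
  if (chemostat) {
    if (s1 && s2) "coexistence" else if (s1) "single1"
    else if (s2) "single2" else "washout"
  } else {
    if (s1 && s2) "L12" else if (s1) "L1" else if (s2) "L2" else "E"
  }
}

#' Fixed points as a data frame
#'
#' @param fps List of \code{fixed_point} objects.
#' @return A data.frame with coordinates, label, stability and the leading
#'   (largest real part) eigenvalue.
#' @export
fixed_points_table <- function(fps) {
  nc <- length(fps[[1]]$coords)
  coord_names <- if (nc == 2) c("X1", "X2") else c("X1", "X2", "S0", "S1", "S2")
  df <- as.data.frame(do.call(rbind, lapply(fps, function(f) f$coords)))
  names(df) <- coord_names
  df$label <- vapply(fps, function(f) f$label, character(1))
  df$stability <- vapply(fps, function(f) f$stability, character(1))
  df$stable <- vapply(fps, function(f) f$stable, logical(1))
  df$leading_eigenvalue <- vapply(fps, function(f)
    max(Re(f$eigenvalues)), numeric(1))
  df$residual <- vapply(fps, function(f) f$residual, numeric(1))
  df
}
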