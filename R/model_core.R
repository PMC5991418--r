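#' Monod saturation function
#'
#' The saturating growth factor \eqn{s/(k+s)}: zero at \eqn{s = 0}, one half
#' at \eqn{s = k}, approaching one as \eqn{s \to \infty}.
#'
#' @param s Nutrient concentration(s), >= 0.
#' @param k Half-saturation constant, > 0.
#' @return Value(s) in \[0, 1).
#' @examples
#' monod(200, 200)  # 0.5
#' @export
monod <- function(s, k) {
  if (!all(is.finite(k)) || any(k <= 0))
    stop("monod: half-saturation constant k must be > 0")
  if (any(s < 0)) stop("monod: concentration s must be >= 0")
  s / (k + s)
}

#' Double-Monod growth rate
#'
#' Per-capita growth rate of a species that strictly requires both the
#' shared carbon source and its cross-fed nutrient:
#' \eqn{f_1(S_0, S_2) = \mu_1 \frac{S_0}{K_{10}+S_0}\frac{S_2}{K_{12}+S_2}}
#' and symmetrically \eqn{f_2(S_0, S_1)}. The product form means growth
#' stops when either nutrient is absent.
#'
#' @param species 1 or 2.
#' @param s0 Shared carbon source concentration.
#' @param scross Cross-fed nutrient concentration (\eqn{S_2} for species 1,
#'   \eqn{S_1} for species 2).
#' @param p A [chemostat_params()] object.
#' @return Growth rate in \[0, mu_i) \[1/time\].
#' @export
growth_rate <- function(species, s0, scross, p) {
  validate_chemostat_params(p)
  if (!species %in% c(1L, 2L)) stop("growth_rate: species must be 1 or 2")
  if (species == 1L) p$mu1 * monod(s0, p$k10) * monod(scross, p$k12)
  else               p$mu2 * monod(s0, p$k20) * monod(scross, p$k21)
}

#' Chemostat model right-hand side
#'
#' Time derivatives of the five-variable chemostat model: species grow at
#' their double-Monod rates and are diluted at the flow rate, nutrients flow
#' in at their inflow concentrations, dilute out, and are produced or
#' consumed in proportion to growth (\eqn{\nu_{ji} f_i X_i}).
#'
#' @param state Numeric vector \code{c(x1, x2, s0, s1, s2)} (names optional),
#'   all components >= 0.
#' @param p A [chemostat_params()] object.
#' @return Named numeric 5-vector of time derivatives.
#' @export
chemostat_rhs <- function(state, p) {
  validate_chemostat_params(p)
  state <- as.numeric(state)
  if (length(state) != 5L) stop("chemostat_rhs: state must have 5 components")
  if (any(state < 0)) stop("chemostat_rhs: negative state components")
  x1 <- state[1]; x2 <- state[2]
  s0 <- state[3]; s1 <- state[4]; s2 <- state[5]
  f1 <- growth_rate(1L, s0, s2, p)
  f2 <- growth_rate(2L, s0, s1, p)
  c(x1 = (f1 - p$phi) * x1,
    x2 = (f2 - p$phi) * x2,
    s0 = p$phi * (p$s0_in - s0) + p$nu01 * f1 * x1 + p$nu02 * f2 * x2,
    s1 = p$phi * (p$s1_in - s1) + p$nu11 * f1 * x1 + p$nu12 * f2 * x2,
    s2 = p$phi * (p$s2_in - s2) + p$nu21 * f1 * x1 + p$nu22 * f2 * x2)
}

#' Extended Lotka-Volterra right-hand side
#'
#' Time derivatives of the reduced two-variable model
#' \eqn{dX_1/dt = (r_1(a_1 - b_{11}X_1 + b_{12}X_2 - c_1X_2^2) - d)X_1}
#' and symmetrically for \eqn{X_2}. The origin is always a fixed point.
#'
#' @param x1,x2 Species densities, >= 0.
#' @param p An [elv_params()] object.
#' @return Named numeric 2-vector \code{c(x1 = ..., x2 = ...)}.
#' @export
elv_rhs <- function(x1, x2, p) {
  validate_elv_params(p)
  c(x1 = (p$r1 * (p$a1 - p$b11 * x1 + p$b12 * x2 - p$c1 * x2^2) - p$d) * x1,
    x2 = (p$r2 * (p$a2 - p$b22 * x2 + p$b21 * x1 - p$c2 * x1^2) - p$d) * x2)
}

# Internal: parameter vectors in the order the C derivative functions expect.
chemostat_parm_vec <- function(p) {
  unlist(p[c("phi", "mu1", "mu2", "s0_in", "s1_in", "s2_in",
             "k10", "k12", "k20", "k21",
             "nu01", "nu02", "nu11", "nu12", "nu21", "nu22")])
}
elv_parm_vec <- function(p) {
  unlist(p[c("d", "r1", "r2", "a1", "a2",
             "b11", "b12", "b21", "b22", "c1", "c2")])
}

#' Simulate either model
#'
#' Integrates the chemostat or the extended Lotka-Volterra model with an
#' adaptive stiff-capable solver (deSolve's \code{lsoda}, compiled
#' right-hand sides) on a uniform output grid. Small negative excursions due
#' to round-off are clipped to zero in the returned states.
#'
#' @param model \code{"chemostat"} or \code{"elv"}.
#' @param params Matching parameter object.
#' @param init Initial state: length 5 \code{(x1, x2, s0, s1, s2)} for the
#'   chemostat, length 2 \code{(x1, x2)} for the eLV; all >= 0.
#' @param t_end End time; default \code{50 / phi} (chemostat) or
#'   \code{50 / d} (eLV), long after the dilution transient.
#' @param n_out Number of output points (uniform grid from 0 to t_end).
#' @param rtol,atol Relative/absolute integrator tolerances.
#' @return A \code{trajectory} object: list with \code{times},
#'   \code{states} (matrix, one row per time), \code{model}, \code{params}.
#' @examples
#' tr <- simulate_model("elv", fixture("eq6"), c(15, 15), t_end = 400)
#' tail(tr$states, 1)  # near the coexistence state (18.49, 18.49)
#' @export
simulate_model <- function(model = c("chemostat", "elv"), params, init,
                           t_end = NULL, n_out = 201L,
                           rtol = 1e-8, atol = 1e-10) {
  model <- match.arg(model)
  init <- as.numeric(init)
  if (any(init < 0)) stop("simulate_model: initial state must be >= 0")
  if (model == "chemostat") {
    validate_chemostat_params(params)
    if (length(init) != 5L) stop("simulate_model: chemostat init needs 5 components")
    if (is.null(t_end)) t_end <- 50 / params$phi
    names(init) <- c("X1", "X2", "S0", "S1", "S2")
    parms <- chemostat_parm_vec(params)
    func <- "mutucomp_chemo_derivs"; initf <- "mutucomp_chemo_init"
  } else {
    validate_elv_params(params)
    if (length(init) != 2L) stop("simulate_model: elv init needs 2 components")
    if (is.null(t_end)) t_end <- if (params$d > 0) 50 / params$d else 50
    names(init) <- c("X1", "X2")
    parms <- elv_parm_vec(params)
    func <- "mutucomp_elv_derivs"; initf <- "mutucomp_elv_init"
  }
  if (!is.finite(t_end) || t_end <= 0) stop("simulate_model: t_end must be > 0")
  times <- seq(0, t_end, length.out = max(2L, as.integer(n_out)))
  sol <- deSolve::ode(y = init, times = times, func = func, parms = parms,
                      dllname = "mutucomp", initfunc = initf,
                      method = "lsoda", rtol = rtol, atol = atol)
  d <- diagnostics_ok(sol, length(times))
  if (!d$ok) stop("simulate_model: integration failed: ", d$msg)
  states <- unname(as.matrix(sol[, -1, drop = FALSE]))
  if (anyNA(states) || any(!is.finite(states)))
    stop("simulate_model: NaN/Inf in integrated states")
  states[states < 0] <- 0   # round-off clipping
  colnames(states) <- names(init)
  structure(list(times = as.numeric(sol[, 1]), states = states,
                 model = model, params = params,
                 rtol = rtol, atol = atol),
            class = "trajectory")
}

diagnostics_ok <- function(sol, n_expected) {
  if (nrow(sol) < n_expected)
    return(list(ok = FALSE, msg = sprintf("solver stopped early (%d/%d steps)",
                                          nrow(sol), n_expected)))
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[1] < 0)
    return(list(ok = FALSE, msg = paste("istate =", istate[1])))
  list(ok = TRUE, msg = "")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %d time points on [0, %g]\n",
              x$model, length(x$times), max(x$times)))
  cat("final state:", paste(sprintf("%s = %.6g", colnames(x$states),
                                    x$states[nrow(x$states), ]),
                            collapse = ", "), "\n")
  invisible(x)
}

# Final-state derivative of a trajectory; used for convergence checks.
trajectory_final_rhs <- function(traj) {
  fin <- traj$states[nrow(traj$states), ]
  if (traj$model == "chemostat") chemostat_rhs(fin, traj$params)
  else elv_rhs(fin[1], fin[2], traj$params)
}

#' Classify the outcome of a simulation
#'
#' Decides for each species whether it survived (final density above the
#' extinction threshold) or went extinct. A trajectory whose final
#' derivative norm exceeds \code{conv_tol} is flagged as non-converged (with
#' a warning), not rejected.
#'
#' @param traj A \code{trajectory} from [simulate_model()].
#' @param eps Extinction threshold in density units (default 1e-6).
#' @param conv_tol Convergence tolerance on the final \eqn{\|RHS\|_\infty}.
#' @return List with \code{survives1}, \code{survives2}, \code{final_state},
#'   \code{converged} (class \code{outcome_pattern}).
#' @export
classify_outcome <- function(traj, eps = 1e-6, conv_tol = 1e-6) {
  stopifnot(inherits(traj, "trajectory"))
  fin <- traj$states[nrow(traj$states), ]
  fin[fin < 0] <- 0
  conv <- max(abs(trajectory_final_rhs(traj))) < conv_tol
  if (!conv)
    warning("classify_outcome: trajectory not converged at t_end; ",
            "outcome flagged", call. = FALSE)
  structure(list(survives1 = unname(fin[1] > eps),
                 survives2 = unname(fin[2] > eps),
                 final_state = fin, converged = conv),
            class = "outcome_pattern")
}

#' Write a trajectory to CSV
#'
#' Header is \code{t,X1,X2} for the reduced model and
#' \code{t,X1,X2,S0,S1,S2} for the chemostat.
#'
#' @param traj A \code{trajectory}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(t = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
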