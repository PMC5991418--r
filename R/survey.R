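#' Sampling specification for the random-parameter survey
#'
#' Describes how random chemostat parameter sets are drawn. Every positive
#' parameter is drawn log-uniformly over two decades centred on the
#' benchmark reference value (bounds value/10 to value*10); the production/
#' consumption constants nu keep their reference signs and have their
#' magnitudes drawn the same way. In \code{constrained} mode the operating
#' regime that favours the cross-feeding feedback loop is enforced: the
#' carbon inflow is pinned high (\code{s0_in = 50}) and the cross-fed
#' nutrient inflows are drawn low, from \[0.1, 2\]. Any per-parameter range
#' can be overridden: a length-2 entry in \code{ranges} is a (lo, hi)
#' log-uniform bound, a length-1 entry pins the value.
#'
#' @param n Number of draws.
#' @param seed Integer seed; draws are fully reproducible from (spec, seed).
#' @param constrained Logical (default FALSE).
#' @param ranges Named list of overrides (see above).
#' @return A \code{sampling_spec} object.
#' @export
sampling_spec <- function(n = 10000L, seed = 0L, constrained = FALSE,
                          ranges = list()) {
  ref <- fixture("eq3")
  fields <- setdiff(names(unclass(ref)), NULL)
  base <- lapply(unclass(ref)[fields], function(v) {
    c(abs(v) / 10, abs(v) * 10)   # two decades, magnitude scale
  })
  # Unconstrained sampling imposes no hierarchy among the inflows: all
  # three are drawn from one common range spanning the kinetic scales
  # involved. The constrained mode is what creates the high-carbon /
  # low-metabolite operating regime.
  base$s0_in <- base$s1_in <- base$s2_in <- c(0.1, 500)
  if (constrained) {
    base$s0_in <- 50            # pinned high carbon inflow
    base$s1_in <- c(0.1, 2)     # low cross-fed nutrient inflow
    base$s2_in <- c(0.1, 2)
  }
  for (nm in names(ranges)) {
    if (!nm %in% fields)
      stop("sampling_spec: unknown parameter '", nm, "' in ranges")
    base[[nm]] <- ranges[[nm]]
  }
  for (nm in fields) {
    b <- base[[nm]]
    if (!length(b) %in% 1:2 || any(!is.finite(b)) || any(b < 0) ||
        (length(b) == 2 && diff(b) < 0))
      stop("sampling_spec: invalid bounds for '", nm, "'")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 constrained = constrained, bounds = base,
                 signs = vapply(unclass(ref)[fields], sign, numeric(1))),
            class = "sampling_spec")
}

#' Draw random chemostat parameter sets
#'
#' @param spec A [sampling_spec()].
#' @return List of [chemostat_params()] objects of length \code{spec$n};
#'   deterministic given \code{spec$seed}.
#' @export
sample_parameters <- function(spec) {
  stopifnot(inherits(spec, "sampling_spec"))
  if (spec$n == 0L) return(list())
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(spec$seed)
  fields <- names(spec$bounds)
  out <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    vals <- vapply(fields, function(nm) {
      b <- spec$bounds[[nm]]
      mag <- if (length(b) == 1L) b
      else if (b[1] == b[2]) b[1]
      else if (b[1] == 0) stats::runif(1, b[1], b[2])
      else exp(stats::runif(1, log(b[1]), log(b[2])))
      mag * if (spec$signs[[nm]] < 0) -1 else 1
    }, numeric(1))
    out[[i]] <- do.call(chemostat_params, as.list(vals))
  }
  out
}

#' Detect bistability of a chemostat parameter set
#'
#' Simulates the chemostat from the 10-density protocol (equal initial
#' densities spanning (0, 20\], nutrients at inflow) and cross-checks every
#' endpoint against the steady-state equations: each endpoint is
#' Newton-polished onto its fixed point, verified to be attracting (no
#' Jacobian eigenvalue with positive real part), and the polished roots are
#' clustered. The draw is bistable when at least two distinct stable
#' attractors are reached. Endpoints whose Newton polish fails are kept
#' only if the trajectory itself has converged tightly; draws where no
#' start yields an attractor are flagged indeterminate, never counted as
#' bistable.
#'
#' @param p A [chemostat_params()] object.
#' @param t_end Integration horizon (default 100 / phi).
#' @param eps Extinction threshold (attractors closer than this in every
#'   species coordinate are the same survival pattern).
#' @param cluster_tol Relative attractor clustering radius (default 1e-3).
#' @param rtol,atol Integrator tolerances (survey default 1e-7 / 1e-9).
#' @return List with \code{bistable}, \code{n_states}, \code{states}
#'   (matrix of distinct attractors), \code{indeterminate}.
#' @export
detect_bistability <- function(p, t_end = NULL, eps = 1e-6,
                               cluster_tol = 1e-3,
                               rtol = 1e-7, atol = 1e-9) {
  validate_chemostat_params(p)
  if (is.null(t_end)) t_end <- 100 / p$phi
  s_in <- c(p$s0_in, p$s1_in, p$s2_in)
  rhs <- function(x) unname(chemostat_rhs(pmax(x, 0), p))
  jac <- function(x) chemostat_jacobian(pmax(x, 0), p)
  attractors <- list()
  n_ok <- 0L
  for (x0 in fig2_initial_densities()) {
    tr <- tryCatch(
      simulate_model("chemostat", p, c(x0, x0, s_in), t_end = t_end,
                     n_out = 3L, rtol = rtol, atol = atol),
      error = function(e) NULL)
    if (is.null(tr)) next
    fin <- tr$states[nrow(tr$states), ]
    ns <- newton_solve(rhs, jac, fin, tol = 1e-9, max_iter = 50L)
    cand <- NULL
    if (ns$converged) {
      root <- ns$root
      root[abs(root) < 1e-8] <- 0
      if (all(root >= 0) &&
          # polish must stay local: reject jumps to a remote root
          sqrt(sum((root - fin)^2)) <= 0.05 * (1 + sqrt(sum(fin^2)))) {
        ev <- eigen(jac(root), only.values = TRUE)$values
        if (max(Re(ev)) < 1e-8) cand <- root   # attracting (or neutral)
      }
    }
    if (is.null(cand) &&
        max(abs(rhs(fin))) < 1e-8 * (1 + max(abs(fin))))
      cand <- fin   # Newton missed but the trajectory itself has settled
    if (is.null(cand)) next
    n_ok <- n_ok + 1L
    dup <- any(vapply(attractors, function(a)
      sqrt(sum((a - cand)^2)) <= cluster_tol * (1 + sqrt(sum(a^2))),
      logical(1)))
    if (!dup) attractors[[length(attractors) + 1]] <- cand
  }
  if (n_ok == 0L)
    return(list(bistable = FALSE, n_states = 0L,
                states = matrix(numeric(0), 0, 5), indeterminate = TRUE))
  states <- do.call(rbind, attractors)
  list(bistable = length(attractors) >= 2L, n_states = length(attractors),
       states = states, indeterminate = FALSE)
}

#' Monte-Carlo survey of bistability frequency
#'
#' Applies [detect_bistability()] to every draw of a [sampling_spec()] and
#' reports the bistable fraction with an exact binomial confidence
#' interval. The headline fraction uses the full denominator (indeterminate
#' draws count as non-bistable); the fraction over determinate draws only
#' is reported separately.
#'
#' @param spec A [sampling_spec()].
#' @param conf_level Confidence level for the binomial CI (default 0.95).
#' @param progress If TRUE, print a dot every 500 draws.
#' @return A \code{survey_result}: \code{n}, \code{n_bistable},
#'   \code{fraction}, \code{ci} (length 2), \code{n_indeterminate},
#'   \code{fraction_determinate}, \code{regimes} (per-draw state counts),
#'   and the spec echo.
#' @export
survey_fraction <- function(spec, conf_level = 0.95, progress = FALSE) {
  stopifnot(inherits(spec, "sampling_spec"))
  if (spec$n < 1L) stop("survey_fraction: spec$n must be >= 1")
  draws <- sample_parameters(spec)
  bist <- logical(spec$n)
  indet <- logical(spec$n)
  nstates <- integer(spec$n)
  for (i in seq_along(draws)) {
    det <- detect_bistability(draws[[i]])
    bist[i] <- det$bistable
    indet[i] <- det$indeterminate
    nstates[i] <- det$n_states
    if (progress && i %% 500L == 0L) cat(".")
  }
  if (progress) cat("\n")
  k <- sum(bist)
  ci <- as.numeric(stats::binom.test(k, spec$n,
                                     conf.level = conf_level)$conf.int)
  nd <- sum(!indet)
  structure(list(n = spec$n, n_bistable = k, fraction = k / spec$n,
                 ci = ci, conf_level = conf_level,
                 n_indeterminate = sum(indet),
                 fraction_determinate = if (nd > 0) sum(bist & !indet) / nd
                 else NA_real_,
                 n_states = nstates, spec = spec),
            class = "survey_result")
}

#' @export
print.survey_result <- function(x, ...) {
  cat(sprintf(
    "bistability survey: %d/%d draws bistable (%.3f%%), %g%% CI [%.3f%%, %.3f%%]\n",
    x$n_bistable, x$n, 100 * x$fraction, 100 * x$conf_level,
    100 * x$ci[1], 100 * x$ci[2]))
  cat(sprintf("  mode: %s; indeterminate draws: %d\n",
              if (x$spec$constrained) "constrained (high S0 inflow, low S1/S2 inflow)"
              else "unconstrained", x$n_indeterminate))
  invisible(x)
}
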