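regime_from_stable_set <- function(labels) {
  # two stable states sharing a survival pattern (e.g. a double
  # coexistence) fall outside the R1-R7 taxonomy
  if (anyDuplicated(labels)) return("other")
  key <- paste(sort(labels), collapse = "+")
  switch(key,
         "E" = "R1", "L1" = "R2", "L2" = "R3",
         "E+L12" = "R4", "L1+L12" = "R5", "L12+L2" = "R6",
         "L12" = "R7",
         "other")
}

chemo_label_to_elv <- function(lab) {
  c(washout = "E", single1 = "L1", single2 = "L2", coexistence = "L12")[lab]
}

#' Classify a parameter set into a dynamical regime
#'
#' Enumerates the stable fixed points and maps the stable set onto the
#' regime taxonomy: R1 extinction only, R2/R3 competitive exclusion (only
#' species 1 / 2 survives), R4 bistability between extinction and
#' coexistence, R5/R6 bistability between single-species survival and
#' coexistence, R7 global coexistence. Any other stable set (e.g. two
#' coexistence states) is labelled \code{"other"}. Chemostat fixed points
#' are mapped to the E/L1/L2/L12 taxonomy by their survival pattern; the
#' enumeration is seeded by simulations from the 10-density protocol, so a
#' Newton miss falls back to the simulated attractor itself.
#'
#' @param model \code{"chemostat"} or \code{"elv"}.
#' @param params Matching parameter object.
#' @param ... Passed to the fixed-point enumerator
#'   ([chemostat_fixed_points()] or [elv_fixed_points()]).
#' @return A \code{regime_label}: list with \code{regime} (\code{"R1"} ...
#'   \code{"R7"} or \code{"other"}) and \code{stable_set}.
#' @examples
#' regime_classify("elv", fixture("eq6"))$regime   # "R4"
#' @export
regime_classify <- function(model = c("chemostat", "elv"), params, ...) {
  model <- match.arg(model)
  res <- tryCatch({
    if (model == "elv") {
      fps <- elv_fixed_points(params, ...)
      stable <- vapply(Filter(function(f) f$stable, fps),
                       function(f) f$label, character(1))
    } else {
      fps <- chemostat_fixed_points(params, ...)
      stable <- chemo_label_to_elv(
        vapply(Filter(function(f) f$stable, fps),
               function(f) f$label, character(1)))
      if (length(stable) == 0) {
        # Newton missed every attractor: classify straight from the
        # simulated endpoints of the 10-density protocol.
        stable <- unique(vapply(fig2_initial_densities(), function(x0) {
          tr <- simulate_model("chemostat", params,
                               c(x0, x0, params$s0_in, params$s1_in,
                                 params$s2_in),
                               t_end = 100 / params$phi, n_out = 3L)
          oc <- suppressWarnings(classify_outcome(tr))
          survival_label(oc$survives1, oc$survives2)
        }, character(1)))
      }
    }
    list(regime = regime_from_stable_set(stable),
         stable_set = sort(stable))
  }, error = function(e) list(regime = "other",
                              stable_set = character(0),
                              error = conditionMessage(e)))
  structure(res, class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("regime %s (stable set: {%s})\n", x$regime,
              paste(x$stable_set, collapse = ", ")))
  invisible(x)
}

set_param_field <- function(params, name, value) {
  if (!name %in% names(params))
    stop("scan_2d: unknown parameter field '", name, "'")
  params[[name]] <- value
  params
}

#' Two-parameter regime scan
#'
#' Classifies every cell of a 2-D parameter grid into a dynamical regime
#' (growth-rate planes mu1 x mu2 or r1 x r2, or operating planes such as
#' phi x s0_in). Per-cell failures are recorded as \code{"other"} and never
#' abort the scan.
#'
#' @param model \code{"chemostat"} or \code{"elv"}.
#' @param axis1,axis2 Axis specs: \code{list(name, from, to, n)} where
#'   \code{name} is a parameter field of the model.
#' @param base Baseline parameter object; the axis fields are overridden
#'   cell by cell.
#' @param ... Passed to [regime_classify()].
#' @return A \code{regime_map}: axis vectors, character label matrix
#'   (rows indexing axis1) and per-regime counts.
#' @export
scan_2d <- function(model = c("chemostat", "elv"), axis1, axis2, base, ...) {
  model <- match.arg(model)
  for (ax in list(axis1, axis2))
    if (!all(c("name", "from", "to", "n") %in% names(ax)))
      stop("scan_2d: axis spec needs fields name, from, to, n")
  v1 <- seq(axis1$from, axis1$to, length.out = as.integer(axis1$n))
  v2 <- seq(axis2$from, axis2$to, length.out = as.integer(axis2$n))
  labels <- matrix(NA_character_, length(v1), length(v2))
  for (i in seq_along(v1)) {
    for (j in seq_along(v2)) {
      p <- set_param_field(base, axis1$name, v1[i])
      p <- set_param_field(p, axis2$name, v2[j])
      labels[i, j] <- regime_classify(model, p, ...)$regime
    }
  }
  structure(list(axis1 = list(name = axis1$name, values = v1),
                 axis2 = list(name = axis2$name, values = v2),
                 labels = labels, model = model,
                 counts = table(labels)),
            class = "regime_map")
}

#' @export
print.regime_map <- function(x, ...) {
  cat(sprintf("regime map (%s): %s x %s, %d x %d cells\n", x$model,
              x$axis1$name, x$axis2$name,
              length(x$axis1$values), length(x$axis2$values)))
  print(x$counts)
  invisible(x)
}

#' Write a regime map as TSV + JSON
#'
#' @param rm A \code{regime_map}.
#' @param stem Output path stem (without extension).
#' @return Character vector of the two paths, invisibly.
#' @export
write_regime_map <- function(rm, stem) {
  stopifnot(inherits(rm, "regime_map"))
  tsv <- paste0(stem, ".tsv"); js <- paste0(stem, ".json")
  utils::write.table(rm$labels, tsv, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(model = rm$model, axis1 = rm$axis1,
                            axis2 = rm$axis2,
                            counts = as.list(rm$counts)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Closed-form bifurcation points of the symmetric reduced model
#'
#' Under the species-exchange symmetry (a1 = a2 = a, b11 = b22, b12 = b21,
#' c1 = c2 = c) and a symmetric sweep r1 = r2 = r, the symmetric coexistence
#' states solve \eqn{cX^2 - (b_{12}-b_{11})X + (d/r - a) = 0}. The
#' saddle-node where the pair is born has zero discriminant,
#' \eqn{(b_{12}-b_{11})^2 = 4c\,(d/r - a)}, giving
#' \deqn{r_{SN} = d / (a + (b_{12}-b_{11})^2/(4c)),}
#' and the extinction state loses stability in a transcritical bifurcation
#' at \eqn{r_T = d/a}.
#'
#' @param p A symmetric [elv_params()] object (r1/r2 are ignored; they are
#'   the sweep variable).
#' @param rel_tol Symmetry check tolerance.
#' @return List with \code{r_SN}, \code{r_T} and an \code{audit} string of
#'   the algebra evaluated.
#' @examples
#' symmetric_closed_forms(fixture("eq6"))   # r_SN = 2/81.25, r_T = 0.04
#' @export
symmetric_closed_forms <- function(p, rel_tol = 1e-9) {
  validate_elv_params(p)
  sym <- function(u, v) abs(u - v) <= rel_tol * max(1, abs(u), abs(v))
  if (!(sym(p$a1, p$a2) && sym(p$b11, p$b22) && sym(p$b12, p$b21) &&
        sym(p$c1, p$c2)))
    stop("symmetric_closed_forms: parameters are not species-symmetric")
  a <- p$a1; b11 <- p$b11; b12 <- p$b12; cc <- p$c1
  r_T <- if (a > 0) p$d / a else NA_real_
  denom <- if (cc > 0) a + (b12 - b11)^2 / (4 * cc) else NA_real_
  r_SN <- if (is.finite(denom) && denom > 0 && b12 > b11) p$d / denom
  else NA_real_
  list(r_SN = r_SN, r_T = r_T,
       audit = sprintf(paste0(
         "r_T = d/a = %.10g; r_SN = d/(a + (b12-b11)^2/(4c)) = ",
         "%.10g/(%.10g + %.10g) = %.10g"),
         r_T, p$d, a, (b12 - b11)^2 / (4 * cc), r_SN))
}

# Number of strictly positive coexistence roots at symmetric growth scale r.
l12_count_at <- function(p, r) {
  q <- p; q$r1 <- r; q$r2 <- r
  sum(vapply(elv_fixed_points(q), function(f) f$label == "L12", logical(1)))
}

leading_eig_of_label <- function(p, r, label) {
  q <- p; q$r1 <- r; q$r2 <- r
  fps <- elv_fixed_points(q)
  hit <- Filter(function(f) f$label == label, fps)
  if (length(hit) == 0) NA_real_ else max(Re(hit[[1]]$eigenvalues))
}

bisect_change <- function(f, lo, hi, flo, n_iter = 60L) {
  for (k in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    if (identical(f(mid), flo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Trace fixed-point branches along a symmetric growth-rate sweep
#'
#' Follows every fixed-point branch of the reduced model as the growth
#' scale r = r1 = r2 increases, by re-enumerating the analytic fixed points
#' on a grid (each point is Newton-polished) and refining detected events
#' by bisection: a saddle-node (SN) where the number of coexistence states
#' changes, and a transcritical (T) where the extinction state E (or a
#' boundary state L1/L2) changes stability.
#'
#' @param p Baseline [elv_params()] (r1/r2 overridden by the sweep).
#' @param r_range Numeric \code{c(lo, hi)} of the sweep.
#' @param n Number of grid points (default 121).
#' @return A \code{branch_diagram}: \code{branches} data.frame (r, X1, X2,
#'   label, stability), \code{bifurcations} data.frame (type, r,
#'   description).
#' @examples
#' bd <- branch_trace_1d(fixture("eq6"), c(0.01, 0.06), n = 51)
#' bd$bifurcations
#' @export
branch_trace_1d <- function(p, r_range, n = 121L) {
  validate_elv_params(p)
  if (length(r_range) != 2L || r_range[1] <= 0 || diff(r_range) <= 0)
    stop("branch_trace_1d: r_range must be increasing and positive")
  rs <- seq(r_range[1], r_range[2], length.out = as.integer(n))
  rows <- list()
  counts <- integer(length(rs))
  e_stab <- logical(length(rs))
  l1_eig <- l2_eig <- rep(NA_real_, length(rs))
  for (k in seq_along(rs)) {
    q <- p; q$r1 <- rs[k]; q$r2 <- rs[k]
    fps <- elv_fixed_points(q)
    counts[k] <- sum(vapply(fps, function(f) f$label == "L12", logical(1)))
    for (f in fps) {
      rows[[length(rows) + 1]] <- data.frame(
        r = rs[k], X1 = f$coords[1], X2 = f$coords[2],
        label = f$label, stability = f$stability)
      if (f$label == "E") e_stab[k] <- f$stable
      if (f$label == "L1") l1_eig[k] <- max(Re(f$eigenvalues))
      if (f$label == "L2") l2_eig[k] <- max(Re(f$eigenvalues))
    }
  }
  bif <- list()
  count_events <- list()
  for (k in seq_len(length(rs) - 1)) {
    if (counts[k] != counts[k + 1]) {
      r_sn <- bisect_change(function(r) l12_count_at(p, r),
                            rs[k], rs[k + 1], counts[k])
      count_events[[length(count_events) + 1]] <- list(
        r = r_sn, from = counts[k], to = counts[k + 1])
    }
    if (e_stab[k] != e_stab[k + 1]) {
      r_t <- bisect_change(function(r) leading_eig_of_label(p, r, "E") < 0,
                           rs[k], rs[k + 1], e_stab[k])
      bif[[length(bif) + 1]] <- data.frame(
        type = "T", r = r_t, description = "extinction state E changes stability")
    }
    for (side in c("L1", "L2")) {
      ev <- if (side == "L1") l1_eig else l2_eig
      if (!is.na(ev[k]) && !is.na(ev[k + 1]) &&
          sign(ev[k]) != sign(ev[k + 1])) {
        r_t <- bisect_change(function(r) {
          e <- leading_eig_of_label(p, r, side); !is.na(e) && e < 0
        }, rs[k], rs[k + 1], ev[k] < 0)
        bif[[length(bif) + 1]] <- data.frame(
          type = "T", r = r_t,
          description = sprintf("boundary state %s changes stability", side))
      }
    }
  }
  # A change in the coexistence count is a saddle-node only when two
  # interior states merge; a count change at the same parameter value as a
  # boundary-state transcritical is that branch crossing the axis, not an SN.
  t_rs <- vapply(bif, function(b) b$r, numeric(1))
  for (ev in count_events) {
    near_t <- length(t_rs) && any(abs(t_rs - ev$r) <= 1e-5 * max(1, ev$r))
    if (near_t) next
    bif[[length(bif) + 1]] <- data.frame(
      type = "SN", r = ev$r,
      description = sprintf("coexistence count %d -> %d", ev$from, ev$to))
  }
  bif <- bif[order(vapply(bif, function(b) b$r, numeric(1)))]
  structure(list(branches = do.call(rbind, rows),
                 bifurcations = if (length(bif)) do.call(rbind, bif)
                 else data.frame(type = character(), r = numeric(),
                                 description = character()),
                 r_range = r_range),
            class = "branch_diagram")
}

#' @export
print.branch_diagram <- function(x, ...) {
  cat(sprintf("branch diagram over r in [%g, %g]: %d branch samples\n",
              x$r_range[1], x$r_range[2], nrow(x$branches)))
  if (nrow(x$bifurcations)) {
    cat("bifurcations:\n")
    for (i in seq_len(nrow(x$bifurcations)))
      cat(sprintf("  %s at r = %.6g (%s)\n", x$bifurcations$type[i],
                  x$bifurcations$r[i], x$bifurcations$description[i]))
  } else cat("no bifurcations detected in range\n")
  invisible(x)
}

#' Cellwise regime agreement between the chemostat and its reduction
#'
#' Scans a mu1 x mu2 grid of the chemostat model and, cell by cell, the
#' reduced model with the growth scales mapped through
#' \eqn{r_i = \rho\,\mu_i/(K_{i0} K_{i,cross})} (all other reduced
#' parameters from [reduce_to_lv()]), then reports the fraction of cells on
#' which the two regime classifications agree.
#'
#' The reduction derivation fixes the growth scales r only up to the base
#' point of its Taylor expansion, so the comparison needs a calibration.
#' The default, \code{r_scale = "washout"}, sets
#' \eqn{r_i = f_i(\tilde S)/a_i} — the choice under which both models have
#' the *same* low-density growth eigenvalues at the washout state, which is
#' the natural base point for a reduction built around low densities; since
#' \eqn{f_i \propto \mu_i} it is a constant factor across the grid
#' (0.796 for the benchmark K = 200, inflow (50, 1, 1) geometry). A numeric
#' \code{r_scale} multiplies the plain product instead (1 = plain mapping;
#' 0.675 reproduces the growth scale of the published reduced counterpart
#' of the benchmark set).
#'
#' @param base A [chemostat_params()] baseline.
#' @param mu1_range,mu2_range Numeric \code{c(lo, hi)} growth-rate ranges.
#' @param n Cells per axis (default 21).
#' @param mode Reduction mode (see [reduce_to_lv()]).
#' @param r_scale \code{"washout"} (default) or a numeric factor \eqn{\rho}
#'   (see above).
#' @param ... Passed to the chemostat [regime_classify()].
#' @return List with \code{agreement} (fraction in \[0, 1\]),
#'   \code{chemostat} and \code{elv} regime maps.
#' @export
regime_agreement <- function(base, mu1_range, mu2_range, n = 21L,
                             mode = "leading_order", r_scale = "washout",
                             ...) {
  validate_chemostat_params(base)
  ax1 <- list(name = "mu1", from = mu1_range[1], to = mu1_range[2], n = n)
  ax2 <- list(name = "mu2", from = mu2_range[1], to = mu2_range[2], n = n)
  chem_map <- scan_2d("chemostat", ax1, ax2, base, ...)
  elv_labels <- matrix(NA_character_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      p <- base
      p$mu1 <- chem_map$axis1$values[i]
      p$mu2 <- chem_map$axis2$values[j]
      lv <- reduce_to_lv(p, mode)
      if (identical(r_scale, "washout")) {
        if (lv$a1 > 0) lv$r1 <- growth_rate(1L, p$s0_in, p$s2_in, p) / lv$a1
        if (lv$a2 > 0) lv$r2 <- growth_rate(2L, p$s0_in, p$s1_in, p) / lv$a2
      } else {
        lv$r1 <- lv$r1 * r_scale
        lv$r2 <- lv$r2 * r_scale
      }
      elv_labels[i, j] <- regime_classify("elv", lv)$regime
    }
  }
  elv_map <- structure(list(
    axis1 = list(name = "r1 (mapped from mu1)", values = chem_map$axis1$values),
    axis2 = list(name = "r2 (mapped from mu2)", values = chem_map$axis2$values),
    labels = elv_labels, model = "elv", counts = table(elv_labels)),
    class = "regime_map")
  list(agreement = mean(chem_map$labels == elv_labels),
       chemostat = chem_map, elv = elv_map)
}
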