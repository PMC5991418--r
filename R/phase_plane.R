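#' Nullcline of one species in the reduced model
#'
#' The dX_i/dt = 0 set consists of the axis branch X_i = 0 (species absent)
#' and, when the species is alive, the parabola
#' \eqn{X_i = (a_i - d/r_i + b_{ij}X_j - c_i X_j^2)/b_{ii}} as an explicit
#' function of the partner density. Points where the explicit branch dips
#' below zero are flagged as outside the biological quadrant.
#'
#' @param p An [elv_params()] object with \code{b_ii > 0}.
#' @param species 1 or 2.
#' @param other_grid Numeric grid of partner densities X_j.
#' @return data.frame with columns \code{other} (X_j), \code{self} (X_i on
#'   the alive branch) and \code{feasible} (\code{self >= 0}).
#' @export
nullcline <- function(p, species, other_grid) {
  validate_elv_params(p)
  if (!species %in% c(1L, 2L)) stop("nullcline: species must be 1 or 2")
  bii <- if (species == 1L) p$b11 else p$b22
  if (bii <= 0) stop("nullcline: self-inhibition b_ii must be > 0")
  xj <- as.numeric(other_grid)
  self <- if (species == 1L)
    (p$a1 - p$d / p$r1 + p$b12 * xj - p$c1 * xj^2) / p$b11
  else
    (p$a2 - p$d / p$r2 + p$b21 * xj - p$c2 * xj^2) / p$b22
  data.frame(other = xj, self = self, feasible = self >= 0)
}

#' Basin-of-attraction map for the reduced model
#'
#' Simulates the extended Lotka-Volterra model from the centre of every
#' cell of a rectangular grid and assigns each cell to the stable fixed
#' point its trajectory converges to. In a bistable regime the map has
#' exactly two attractor labels; the boundary between them traces the
#' stable manifold of the intervening saddle.
#'
#' @param p An [elv_params()] object.
#' @param grid List with \code{x1 = c(lo, hi)}, \code{x2 = c(lo, hi)},
#'   \code{n} (cells per axis). Default: 101 cells over
#'   \[0, 1.5 x max attractor coordinate\].
#' @param t_end Integration horizon per cell (default 400).
#' @param match_tol Relative attractor matching radius (default 1e-3).
#' @return A \code{basin_map}: \code{x1}, \code{x2} (cell-centre
#'   coordinates), \code{labels} (integer matrix, rows indexing x1; 0 =
#'   non-converged sentinel), \code{attractors} (list of stable
#'   \code{fixed_point}s the labels refer to), \code{n_unresolved}.
#' @examples
#' bm <- basin_map(fixture("eq6"), grid = list(x1 = c(0, 30), x2 = c(0, 30), n = 11))
#' table(bm$labels)
#' @export
basin_map <- function(p, grid = NULL, t_end = 400, match_tol = 1e-3) {
  validate_elv_params(p)
  fps <- elv_fixed_points(p)
  att <- Filter(function(f) f$stable, fps)
  if (length(att) == 0)
    stop("basin_map: no stable fixed point exists for these parameters")
  if (is.null(grid)) {
    hi <- 1.5 * max(1, vapply(att, function(f) max(f$coords), numeric(1)))
    grid <- list(x1 = c(0, hi), x2 = c(0, hi), n = 101L)
  }
  n <- as.integer(grid$n)
  # cell centres: never exactly on the axes, where an absent species could
  # never invade and the planar attractors are unreachable
  x1s <- grid$x1[1] + (seq_len(n) - 0.5) * diff(grid$x1) / n
  x2s <- grid$x2[1] + (seq_len(n) - 0.5) * diff(grid$x2) / n
  amat <- do.call(rbind, lapply(att, function(f) f$coords))
  labels <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      tr <- simulate_model("elv", p, c(x1s[i], x2s[j]), t_end = t_end,
                           n_out = 3L, rtol = 1e-8, atol = 1e-10)
      fin <- tr$states[nrow(tr$states), ]
      d2 <- sqrt(rowSums(sweep(amat, 2, fin)^2))
      radius <- match_tol * (1 + sqrt(rowSums(amat^2)))
      hit <- which(d2 <= radius)
      labels[i, j] <- if (length(hit)) hit[1] else 0L
    }
  }
  structure(list(x1 = x1s, x2 = x2s, labels = labels, attractors = att,
                 t_end = t_end, n_unresolved = sum(labels == 0L)),
            class = "basin_map")
}

#' @export
print.basin_map <- function(x, ...) {
  cat(sprintf("basin map: %d x %d cells, %d attractor(s), %d unresolved\n",
              length(x$x1), length(x$x2), length(x$attractors),
              x$n_unresolved))
  for (k in seq_along(x$attractors)) {
    f <- x$attractors[[k]]
    cat(sprintf("  [%d] %s at (%s): %d cells\n", k, f$label,
                paste(sprintf("%.4g", f$coords), collapse = ", "),
                sum(x$labels == k)))
  }
  invisible(x)
}

#' Write a basin map as TSV + JSON
#'
#' The label matrix goes to \code{<stem>.tsv} (rows = X1 cells); the
#' attractor table and grid metadata to \code{<stem>.json}.
#'
#' @param bm A \code{basin_map}.
#' @param stem Output path stem (without extension).
#' @return Character vector of the two paths, invisibly.
#' @export
write_basin_map <- function(bm, stem) {
  stopifnot(inherits(bm, "basin_map"))
  tsv <- paste0(stem, ".tsv"); js <- paste0(stem, ".json")
  utils::write.table(bm$labels, tsv, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  meta <- list(
    x1 = bm$x1, x2 = bm$x2, t_end = bm$t_end,
    n_unresolved = bm$n_unresolved,
    attractors = lapply(seq_along(bm$attractors), function(k) {
      f <- bm$attractors[[k]]
      list(id = k, label = f$label, coords = f$coords)
    }))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
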