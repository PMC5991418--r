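#' Chemostat parameter set
#'
#' Bundles the 14 constants of the five-variable chemostat model: two
#' microbial species growing on a shared carbon source \eqn{S_0} while
#' cross-feeding the metabolites \eqn{S_1} and \eqn{S_2}. Production and
#' consumption constants \eqn{\nu_{ji}} (nutrient j, species i) are positive
#' for production and negative for consumption.
#'
#' @param phi Flow (dilution) rate \eqn{\Phi} [1/time]; must be > 0.
#' @param mu1,mu2 Maximal growth rates [1/time]; must be > 0.
#' @param s0_in,s1_in,s2_in Inflow concentrations \eqn{\tilde S_j}
#'   [mass/volume]; must be >= 0.
#' @param k10,k12,k20,k21 Half-saturation constants [mass/volume]; must be
#'   > 0. \code{k10}/\code{k12} belong to species 1 (carbon / cross-fed
#'   nutrient), \code{k20}/\code{k21} to species 2.
#' @param nu01,nu02,nu11,nu12,nu21,nu22 Production (+) / consumption (-)
#'   constants [mass/number], indexed (nutrient, species).
#' @return An object of class \code{chemostat_params} (named list).
#' @seealso [elv_params()], [fixture()], [reduce_to_lv()]
#' @examples
#' p <- fixture("eq3")
#' p$phi
#' @export
chemostat_params <- function(phi, mu1, mu2, s0_in, s1_in, s2_in,
                             k10, k12, k20, k21,
                             nu01, nu02, nu11, nu12, nu21, nu22) {
  p <- list(phi = phi, mu1 = mu1, mu2 = mu2,
            s0_in = s0_in, s1_in = s1_in, s2_in = s2_in,
            k10 = k10, k12 = k12, k20 = k20, k21 = k21,
            nu01 = nu01, nu02 = nu02, nu11 = nu11, nu12 = nu12,
            nu21 = nu21, nu22 = nu22)
  p <- lapply(p, as.numeric)
  class(p) <- "chemostat_params"
  validate_chemostat_params(p)
  p
}

validate_chemostat_params <- function(p) {
  stopifnot(is.list(p))
  need <- c("phi", "mu1", "mu2", "s0_in", "s1_in", "s2_in",
            "k10", "k12", "k20", "k21",
            "nu01", "nu02", "nu11", "nu12", "nu21", "nu22")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("chemostat_params: missing fields: ", paste(miss, collapse = ", "))
  vals <- unlist(p[need])
  if (any(!is.finite(vals)))
    stop("chemostat_params: all fields must be finite numbers")
  if (p$phi <= 0) stop("chemostat_params: phi must be > 0")
  if (p$mu1 <= 0 || p$mu2 <= 0)
    stop("chemostat_params: maximal growth rates must be > 0")
  if (any(vals[c("k10", "k12", "k20", "k21")] <= 0))
    stop("chemostat_params: half-saturation constants must be > 0")
  if (any(vals[c("s0_in", "s1_in", "s2_in")] < 0))
    stop("chemostat_params: inflow concentrations must be >= 0")
  invisible(p)
}

#' Extended Lotka-Volterra parameter set
#'
#' Bundles the 11 constants of the reduced two-variable model
#' \deqn{dX_i/dt = (r_i(a_i - b_{ii}X_i + b_{ij}X_j - c_i X_j^2) - d)\,X_i,}
#' in which the linear cross term \eqn{b_{ij}X_j} encodes mutualism and the
#' quadratic term \eqn{c_i X_j^2} competition, so that the partner is
#' beneficial at low density and detrimental at high density.
#'
#' @param d Death/outflow rate [1/time]; must be >= 0.
#' @param r1,r2 Growth-rate scales; must be > 0.
#' @param a1,a2 Inflow (basal growth) terms.
#' @param b11,b22 Self-inhibition coefficients.
#' @param b12,b21 Mutualism coefficients.
#' @param c1,c2 Competition coefficients; must be >= 0.
#' @return An object of class \code{elv_params} (named list).
#' @seealso [chemostat_params()], [elv_fixed_points()]
#' @export
elv_params <- function(d, r1, r2, a1, a2, b11, b12, b21, b22, c1, c2) {
  p <- list(d = d, r1 = r1, r2 = r2, a1 = a1, a2 = a2,
            b11 = b11, b12 = b12, b21 = b21, b22 = b22, c1 = c1, c2 = c2)
  p <- lapply(p, as.numeric)
  class(p) <- "elv_params"
  validate_elv_params(p)
  p
}

validate_elv_params <- function(p) {
  stopifnot(is.list(p))
  need <- c("d", "r1", "r2", "a1", "a2",
            "b11", "b12", "b21", "b22", "c1", "c2")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("elv_params: missing fields: ", paste(miss, collapse = ", "))
  vals <- unlist(p[need])
  if (any(!is.finite(vals)))
    stop("elv_params: all fields must be finite numbers")
  if (p$d < 0) stop("elv_params: d must be >= 0")
  if (p$r1 <= 0 || p$r2 <= 0) stop("elv_params: r1, r2 must be > 0")
  if (p$c1 < 0 || p$c2 < 0) stop("elv_params: c1, c2 must be >= 0")
  invisible(p)
}

#' @export
print.chemostat_params <- function(x, ...) {
  cat("Chemostat parameters (5-variable model)\n")
  cat(sprintf("  phi = %g   mu = [%g, %g]\n", x$phi, x$mu1, x$mu2))
  cat(sprintf("  inflow S~ = [%g, %g, %g]\n", x$s0_in, x$s1_in, x$s2_in))
  cat(sprintf("  K = [k10 %g, k12 %g, k20 %g, k21 %g]\n",
              x$k10, x$k12, x$k20, x$k21))
  cat(sprintf("  nu = [%g, %g, %g, %g, %g, %g]  (nu01 nu02 nu11 nu12 nu21 nu22)\n",
              x$nu01, x$nu02, x$nu11, x$nu12, x$nu21, x$nu22))
  invisible(x)
}

#' @export
print.elv_params <- function(x, ...) {
  cat("Extended Lotka-Volterra parameters (2-variable model)\n")
  cat(sprintf("  d = %g   r = [%g, %g]   a = [%g, %g]\n",
              x$d, x$r1, x$r2, x$a1, x$a2))
  cat(sprintf("  b = [b11 %g, b12 %g, b21 %g, b22 %g]   c = [%g, %g]\n",
              x$b11, x$b12, x$b21, x$b22, x$c1, x$c2))
  invisible(x)
}

# Swap the two species' roles; used by the symmetry property checks.
swap_species <- function(p) {
  if (inherits(p, "elv_params")) {
    elv_params(d = p$d, r1 = p$r2, r2 = p$r1, a1 = p$a2, a2 = p$a1,
               b11 = p$b22, b12 = p$b21, b21 = p$b12, b22 = p$b11,
               c1 = p$c2, c2 = p$c1)
  } else if (inherits(p, "chemostat_params")) {
    chemostat_params(phi = p$phi, mu1 = p$mu2, mu2 = p$mu1,
                     s0_in = p$s0_in, s1_in = p$s2_in, s2_in = p$s1_in,
                     k10 = p$k20, k12 = p$k21, k20 = p$k10, k21 = p$k12,
                     nu01 = p$nu02, nu02 = p$nu01,
                     nu11 = p$nu22, nu12 = p$nu21,
                     nu21 = p$nu12, nu22 = p$nu11)
  } else stop("swap_species: unknown parameter class")
}

#' Reference parameter fixtures
#'
#' Returns the printed reference parameter sets: \code{"eq3"} is the
#' chemostat benchmark set (phi = 2, mu = [1600, 1600], inflow [50, 1, 1],
#' all K = 200, nu = [-1, -1, 0.2, -0.1, -0.1, 0.2]); \code{"eq6"} is its
#' published reduced counterpart (d = 2, r = [0.027, 0.027], a = [50, 50],
#' b = [5, 10, 10, 5], c = [0.2, 0.2]). The \code{"fig2a"}-\code{"fig2d"}
#' variants override only the chemostat growth rates mu, the
#' \code{"fig3a"}-\code{"fig3d"} variants only the reduced growth scales r,
#' and \code{"s2fig"} is the reduced set with weakened self-inhibition
#' (b11 = b22 = 2, r = [0.023, 0.023]) for which the parabolic nullclines
#' intersect more than twice.
#'
#' @param name One of \code{"eq3"}, \code{"eq6"}, \code{"fig2a"} ...
#'   \code{"fig2d"}, \code{"fig3a"} ... \code{"fig3d"}, \code{"s2fig"}.
#' @return A \code{chemostat_params} or \code{elv_params} object.
#' @examples
#' fixture("fig2c")$mu1   # 2400
#' fixture("fig3c")$r2    # 0.02
#' @export
fixture <- function(name) {
  known <- c("eq3", "eq6", paste0("fig2", letters[1:4]),
             paste0("fig3", letters[1:4]), "s2fig")
  if (!is.character(name) || length(name) != 1L || !(name %in% known))
    stop("fixture: unknown name; available: ", paste(known, collapse = ", "))
  eq3 <- chemostat_params(phi = 2, mu1 = 1600, mu2 = 1600,
                          s0_in = 50, s1_in = 1, s2_in = 1,
                          k10 = 200, k12 = 200, k20 = 200, k21 = 200,
                          nu01 = -1, nu02 = -1, nu11 = 0.2, nu12 = -0.1,
                          nu21 = -0.1, nu22 = 0.2)
  eq6 <- elv_params(d = 2, r1 = 0.027, r2 = 0.027, a1 = 50, a2 = 50,
                    b11 = 5, b12 = 10, b21 = 10, b22 = 5, c1 = 0.2, c2 = 0.2)
  set_mu <- function(p, mu) { p$mu1 <- mu[1]; p$mu2 <- mu[2]; p }
  set_r <- function(p, r) { p$r1 <- r[1]; p$r2 <- r[2]; p }
  switch(name,
         eq3 = eq3,
         eq6 = eq6,
         fig2a = set_mu(eq3, c(800, 800)),
         fig2b = set_mu(eq3, c(1600, 1600)),
         fig2c = set_mu(eq3, c(2400, 1200)),
         fig2d = set_mu(eq3, c(2400, 2400)),
         fig3a = set_r(eq6, c(0.02, 0.02)),
         fig3b = set_r(eq6, c(0.027, 0.027)),
         fig3c = set_r(eq6, c(0.05, 0.02)),
         fig3d = set_r(eq6, c(0.05, 0.05)),
         s2fig = { p <- set_r(eq6, c(0.023, 0.023)); p$b11 <- 2; p$b22 <- 2; p })
}
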