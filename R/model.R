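# Dimensional and dimensionless forms of the diffusive two-predators/one-prey
# model, its reaction kinetics, and equilibria.
#
# Dimensional system:
#   u_t - D1 Lap(u) = a1 u - a2 u^2 - a3 u v - a4 u v^2
#   v_t - D2 Lap(v) = a3 u v - a5 v - a6 v^2 + a4 u v^2
# with D1 = 0 (prey does not diffuse). After scaling, the dimensionless system
# keeps two parameters:
#   U_t = U - U^2 - U V - U V^2
#   V_t = V_XX - k1 k2 V - k1 V^2 + k1 U V + k1 U V^2
# where k1 = sqrt(a1 a4)/a2 (interaction strength) and k2 = a5/(a1 k1)
# (scaled predator mortality). k1 > 1 corresponds to a4 > a2^2/a1, the
# biologically admitted regime; both exact-solution families degenerate at
# k1 = 1 (they divide by k1 - 1).

#' Dimensional model parameters
#'
#' Container for the positive rate constants of the dimensional
#' predator-prey system and the two diffusion coefficients. `a1` is the prey
#' growth rate, `a2` the intraspecific prey competition rate, `a3` the
#' one-predator/one-prey predation rate, `a4` the two-predators/one-prey
#' interaction rate, `a5` the predator mortality and `a6` the predator
#' competition rate. The model assumes the prey does not diffuse (`D1 = 0`).
#'
#' @param a1,a2,a3,a4,a5,a6 positive rate constants.
#' @param D1 prey diffusion coefficient (nonnegative; 0 in the model).
#' @param D2 positive predator diffusion coefficient.
#' @return An object of class `dimensional_params`.
#' @seealso [nondimensionalize()]
#' @export
dimensional_params <- function(a1, a2, a3, a4, a5, a6, D1 = 0, D2 = 1) {
  a <- c(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6)
  if (any(!is.finite(a)) || any(a <= 0))
    stop("all rate constants a1..a6 must be positive and finite")
  if (!is.finite(D1) || D1 < 0) stop("D1 must be nonnegative")
  if (!is.finite(D2) || D2 <= 0) stop("D2 must be positive")
  structure(list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6,
                 D1 = D1, D2 = D2),
            class = "dimensional_params")
}

#' Dimensionless model parameters
#'
#' @param k1 positive dimensionless interaction strength. `k1 > 1` is the
#'   biologically admitted regime (it encodes `a4 > a2^2/a1`); `k1 = 1` is
#'   accepted here but rejected by every solver (both solution families
#'   divide by `k1 - 1`).
#' @param k2 positive dimensionless predator-mortality ratio.
#' @return An object of class `scaled_params` with logical flags
#'   `admissible` (`k1 > 1`) and `degenerate` (`k1 == 1`).
#' @examples
#' p <- scaled_params(k1 = 3, k2 = 0.5)
#' kinetics(1, 1, p)
#' @export
scaled_params <- function(k1, k2) {
  if (!is.finite(k1) || k1 <= 0) stop("k1 must be positive and finite")
  if (!is.finite(k2) || k2 <= 0) stop("k2 must be positive and finite")
  structure(list(k1 = k1, k2 = k2,
                 admissible = k1 > 1, degenerate = k1 == 1),
            class = "scaled_params")
}

#' @export
print.scaled_params <- function(x, ...) {
  cat(sprintf("scaled_params: k1 = %g, k2 = %g (%s)\n", x$k1, x$k2,
              if (x$degenerate) "degenerate: k1 = 1, solution families undefined"
              else if (x$admissible) "admissible regime k1 > 1"
              else "k1 < 1: regime not biologically admitted"))
  invisible(x)
}

.check_scaled <- function(p) {
  stopifnot(inherits(p, "scaled_params"))
  p
}

# shared guard for the exact-solution machinery
.check_solvable <- function(p) {
  .check_scaled(p)
  if (p$degenerate)
    stop("degenerate: k1 = 1 (both solution families divide by k1 - 1)")
  p
}

#' Reaction kinetics of the dimensionless system
#'
#' Evaluates the reaction terms only (the diffusion term `V_XX` is excluded):
#' `dU = U - U^2 - U*V - U*V^2` and
#' `dV = -k1*k2*V - k1*V^2 + k1*U*V + k1*U*V^2`.
#'
#' @param U,V densities (vectorized).
#' @param p a [scaled_params()] object.
#' @return A list with numeric components `du` and `dv`.
#' @export
kinetics <- function(U, V, p) {
  .check_scaled(p)
  list(du = U - U^2 - U * V - U * V^2,
       dv = -p$k1 * p$k2 * V - p$k1 * V^2 + p$k1 * U * V + p$k1 * U * V^2)
}

#' Spatially homogeneous equilibria of the dimensionless system
#'
#' Returns the extinction state (0, 0), the prey carrying-capacity state
#' (1, 0), and every real coexistence root: eliminating U via
#' `U = 1 - V - V^2` (prey nullcline) from the predator nullcline yields the
#' cubic `V^3 + 2 V^2 + V + (k2 - 1) = 0`; its real roots are polished by
#' Newton iteration so the kinetics vanish below 1e-12. Negative branches are
#' kept but flagged `biological = FALSE` rather than suppressed.
#'
#' @param p a [scaled_params()] object.
#' @param tol residual tolerance for accepting a root.
#' @return A data frame with columns `U_star`, `V_star`, `biological`,
#'   `stability_tag` (descriptive label only), sorted by `V_star`.
#' @export
equilibria <- function(p, tol = 1e-12) {
  .check_scaled(p)
  pts <- data.frame(U_star = c(0, 1), V_star = c(0, 0),
                    stability_tag = c("extinction", "prey-capacity"),
                    stringsAsFactors = FALSE)
  # coexistence candidates: cubic in V
  rt <- polyroot(c(p$k2 - 1, 1, 2, 1))
  re <- Re(rt[abs(Im(rt)) < 1e-8])
  cubic <- function(v) v^3 + 2 * v^2 + v + (p$k2 - 1)
  dcubic <- function(v) 3 * v^2 + 4 * v + 1
  for (v in re) {
    for (it in 1:50) {  # Newton polish; derivative can vanish at double roots
      dv <- dcubic(v)
      if (abs(dv) < 1e-14) break
      step <- cubic(v) / dv
      v <- v - step
      if (abs(step) < 1e-15) break
    }
    u <- 1 - v - v^2
    kin <- kinetics(u, v, p)
    if (max(abs(kin$du), abs(kin$dv)) <= tol)
      pts <- rbind(pts, data.frame(U_star = u, V_star = v,
                                   stability_tag = "coexistence",
                                   stringsAsFactors = FALSE))
  }
  # drop duplicates (e.g. the cubic's V = 0 root at k2 = 1 repeats (1, 0))
  key <- paste(round(pts$U_star, 9), round(pts$V_star, 9))
  pts <- pts[!duplicated(key), , drop = FALSE]
  pts$biological <- pts$U_star >= -tol & pts$V_star >= -tol
  pts <- pts[order(pts$V_star, pts$U_star), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Map dimensional rates to the dimensionless parameters
#'
#' Computes `k1 = sqrt(a1*a4)/a2` and `k2 = a5/(a1*k1)`. The square root in
#' `k1` is the reading under which the admissibility condition
#' `a4 > a2^2/a1` maps exactly onto `k1 > 1` and `0 < k1 < 1` onto
#' `a4 < a2^2/a1`, the regime rejected as biologically unreasonable; the
#' returned object's flags report which regime the rates fall in.
#'
#' @param d a [dimensional_params()] object.
#' @return A [scaled_params()] object.
#' @examples
#' nondimensionalize(dimensional_params(4, 2, 1, 4, 2, 1))  # k1 = 2, k2 = 0.25
#' @export
nondimensionalize <- function(d) {
  stopifnot(inherits(d, "dimensional_params"))
  if (d$a1 <= 0 || d$a2 <= 0) stop("invalid parameters: a1 and a2 must be positive")
  k1 <- sqrt(d$a1 * d$a4) / d$a2
  k2 <- d$a5 / (d$a1 * k1)
  p <- scaled_params(k1, k2)
  if (!p$admissible && !p$degenerate)
    message("a4*a1 < a2^2 regime (k1 < 1): not biologically admitted by the model")
  p
}

#' Read a flat key = value configuration file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments,
#' blank lines ignored. Values that parse as numbers are returned numeric.
#'
#' @param path file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("config line without '=': ", ln)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
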