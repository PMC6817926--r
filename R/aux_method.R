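# Generalized auxiliary-equation backend: the quartic auxiliary ODE
# (F')^2 = h0 + h1 F + h2 F^2 + h3 F^3 + h4 F^4, its closed-form solution
# catalog for h0 = h1 = 0, the exact coefficient derivation from the
# collected algebraic system, and the sech^2-pulse evaluator with V = -U.

#' Quartic auxiliary-equation coefficients
#'
#' @param h0,h1,h2,h3,h4 coefficients of the quartic auxiliary ODE.
#' @return An object of class `aux_coefficients` with the cached
#'   discriminant `delta1 = h3^2 - 4 h2 h4`.
#' @export
aux_coefficients <- function(h0 = 0, h1 = 0, h2, h3 = 0, h4 = 0) {
  if (h2 == 0 && h3 == 0 && h4 == 0)
    stop("at least one of h2, h3, h4 must be nonzero")
  structure(list(h0 = h0, h1 = h1, h2 = h2, h3 = h3, h4 = h4,
                 delta1 = h3^2 - 4 * h2 * h4),
            class = "aux_coefficients")
}

.aux_branches <- c("I.1", "I.2", "I.3", "I.4", "I.5",
                   "II.1", "II.2", "II.3", "III.1", "III.2", "III.3")

.precheck <- function(ok, what) {
  if (!ok) stop("branch precondition violated: requires ", what)
}

#' Closed-form solutions of the quartic auxiliary ODE
#'
#' Catalog of generator functions solving `(F')^2 = h2 F^2 + h3 F^3 + h4 F^4`
#' (family I, `h0 = h1 = 0`), the `h3 = 0` family II, and the `h4 = 0`
#' family III. Each branch's sign preconditions are checked and denominator
#' zeros are masked to `NaN` (counted in the `"poles"` attribute). Writing
#' `d1 = h3^2 - 4 h2 h4` and `s = sqrt(h2)`:
#' \describe{
#'   \item{I.1}{`2 h2 sech(s xi) / (sqrt(d1) - h3 sech(s xi))`, `h2 > 0`,
#'     `d1 > 0`.}
#'   \item{I.2}{`2 h2 csch(s xi) / (sqrt(-d1) - h3 csch(s xi))`, `h2 > 0`,
#'     `d1 < 0`.}
#'   \item{I.3}{`-(h2/h3) (1 + sign * tanh(s xi / 2))`, `h2 > 0`, `d1 = 0`.}
#'   \item{I.4}{`h2 sech^2(s xi / 2) / (2 sqrt(h2 h4) tanh(s xi / 2) - h3)`,
#'     `h2 > 0`, `h4 > 0` — the branch behind the model's sech^2 pulse.}
#'   \item{I.5}{`h2 sec^2(sqrt(-h2) xi / 2) / (2 sqrt(-h2 h4) tan(.) - h3)`,
#'     `h2 < 0`, `h4 > 0`.}
#'   \item{II.1}{`sqrt(-h2/h4) sech(s xi)`, `h2 > 0`, `h4 < 0`.}
#'   \item{II.2}{`sqrt(-h2/h4) sec(sqrt(-h2) xi)`, `h2 < 0`, `h4 > 0`.}
#'   \item{II.3}{`1/(sqrt(h4) xi)`, `h2 = 0`, `h4 > 0`.}
#'   \item{III.1}{`-(h2/h3) sech^2(s xi / 2)`, `h2 > 0`.}
#'   \item{III.2}{`-(h2/h3) sec^2(sqrt(-h2) xi / 2)`, `h2 < 0`.}
#'   \item{III.3}{`4/(h3 xi^2)`, `h2 = 0`.}
#' }
#'
#' @param xi numeric vector.
#' @param h an [aux_coefficients()] object (with `h0 = h1 = 0`; family II
#'   additionally `h3 = 0`, family III `h4 = 0`).
#' @param branch branch identifier: `"I.1"`..`"I.5"`, `"II.1"`..`"II.3"`,
#'   or `"III.1"`..`"III.3"`.
#' @param sign sign choice for branch I.3.
#' @return Numeric vector with attribute `poles`.
#' @export
aux_F <- function(xi, h, branch, sign = 1) {
  stopifnot(inherits(h, "aux_coefficients"))
  branch <- match.arg(branch, .aux_branches)
  if (h$h0 != 0 || h$h1 != 0)
    stop("catalog branches require h0 = h1 = 0")
  if (startsWith(branch, "II.") && h$h3 != 0)
    stop("family II branches require h3 = 0")
  if (startsWith(branch, "III.") && h$h4 != 0)
    stop("family III branches require h4 = 0")
  d1 <- h$delta1
  F <- switch(branch,
    "I.1" = {
      .precheck(h$h2 > 0, "h2 > 0"); .precheck(d1 > 0, "delta1 > 0")
      s <- 1 / cosh(sqrt(h$h2) * xi)
      2 * h$h2 * s / (sqrt(d1) - h$h3 * s)
    },
    "I.2" = {
      .precheck(h$h2 > 0, "h2 > 0"); .precheck(d1 < 0, "delta1 < 0")
      s <- 1 / sinh(sqrt(h$h2) * xi)
      2 * h$h2 * s / (sqrt(-d1) - h$h3 * s)
    },
    "I.3" = {
      .precheck(h$h2 > 0, "h2 > 0")
      .precheck(abs(d1) <= 1e-12 * max(1, h$h3^2), "delta1 = 0")
      .precheck(h$h3 != 0, "h3 != 0")
      -(h$h2 / h$h3) * (1 + sign * tanh(sqrt(h$h2) / 2 * xi))
    },
    "I.4" = {
      .precheck(h$h2 > 0, "h2 > 0"); .precheck(h$h4 > 0, "h4 > 0")
      th <- sqrt(h$h2) / 2 * xi
      h$h2 / cosh(th)^2 / (2 * sqrt(h$h2 * h$h4) * tanh(th) - h$h3)
    },
    "I.5" = {
      .precheck(h$h2 < 0, "h2 < 0"); .precheck(h$h4 > 0, "h4 > 0")
      th <- sqrt(-h$h2) / 2 * xi
      h$h2 / cos(th)^2 / (2 * sqrt(-h$h2 * h$h4) * tan(th) - h$h3)
    },
    "II.1" = {
      .precheck(h$h2 > 0, "h2 > 0"); .precheck(h$h4 < 0, "h4 < 0")
      sqrt(-h$h2 / h$h4) / cosh(sqrt(h$h2) * xi)
    },
    "II.2" = {
      .precheck(h$h2 < 0, "h2 < 0"); .precheck(h$h4 > 0, "h4 > 0")
      sqrt(-h$h2 / h$h4) / cos(sqrt(-h$h2) * xi)
    },
    "II.3" = {
      .precheck(h$h2 == 0, "h2 = 0"); .precheck(h$h4 > 0, "h4 > 0")
      1 / (sqrt(h$h4) * xi)
    },
    "III.1" = {
      .precheck(h$h2 > 0, "h2 > 0"); .precheck(h$h3 != 0, "h3 != 0")
      -(h$h2 / h$h3) / cosh(sqrt(h$h2) / 2 * xi)^2
    },
    "III.2" = {
      .precheck(h$h2 < 0, "h2 < 0"); .precheck(h$h3 != 0, "h3 != 0")
      -(h$h2 / h$h3) / cos(sqrt(-h$h2) / 2 * xi)^2
    },
    "III.3" = {
      .precheck(h$h2 == 0, "h2 = 0"); .precheck(h$h3 != 0, "h3 != 0")
      4 / (h$h3 * xi^2)
    })
  bad <- !is.finite(F) | abs(F) > 1e12
  F[bad] <- NaN
  attr(F, "poles") <- sum(bad)
  F
}

.aux_families <- function() {
  if (is.null(.wavepred_cache$aux)) {
    sys <- substitute_and_collect(polynomial_ansatz(), aux_rule_quartic())
    fams <- solve_system(sys)
    fams <- Filter(Negate(function(f) f$trivial), fams)
    # primary family: c stays free (the F' equation is met by alpha1 = -beta1)
    primary <- Filter(function(f) "c" %in% f$free, fams)
    others <- Filter(function(f) !"c" %in% f$free, fams)
    if (length(primary) != 1L) stop("unexpected auxiliary-method branch structure")
    primary <- primary[[1L]]
    primary$case_label <- "aux (c free)"
    others <- lapply(others, function(f) { f$case_label <- "aux (c = 0, standing)"; f })
    .wavepred_cache$aux <- list(primary = primary, others = others,
                                sys = primary$system)
  }
  .wavepred_cache$aux
}

#' Derive the auxiliary-method coefficient family
#'
#' Solves the quartic-rule coefficient system exactly. The surviving odd-F'
#' coefficient forces `c (alpha1 + beta1) = 0`; on the family with the wave
#' speed free this gives `alpha1 = -beta1`, and the remaining equations yield
#' `h1 = 0`, `h2 = 1 + k1 k2`, `h3 = 4 k1 beta1 / 3`,
#' `h4 = (k1 - 1) beta1^2 / 2`, with `h0` left free (set to 0 when building
#' the pulse solution).
#'
#' @param p a [scaled_params()] object with `k1 != 1`.
#' @param beta1 nonzero predator amplitude. For real coefficients in the
#'   pulse denominator `sqrt(h2 h4)`, `k1 > 1` is required (`h4 > 0`).
#' @return An object of class `aux_solution` with numeric `alpha1`, the
#'   [aux_coefficients()] (at `h0 = 0`), and the exact family.
#' @export
derive_aux_coefficients <- function(p, beta1) {
  .check_solvable(p)
  if (beta1 == 0) stop("beta1 must be nonzero")
  fam <- .aux_families()$primary
  env <- list(beta1 = beta1, k1 = p$k1, k2 = p$k2, h0 = 0)
  vals <- family_eval(fam, env)
  h <- aux_coefficients(h0 = 0, h1 = unname(vals["h1"]),
                        h2 = unname(vals["h2"]), h3 = unname(vals["h3"]),
                        h4 = unname(vals["h4"]))
  if (h$h4 < 0)
    warning("k1 < 1 gives h4 < 0: sqrt(h2 h4) is complex; ",
            "the pulse evaluator will refuse these coefficients")
  structure(list(alpha1 = unname(vals["alpha1"]), beta1 = beta1,
                 k1 = p$k1, k2 = p$k2, h = h,
                 catalog_branch = "I.4", family = fam),
            class = "aux_solution")
}

#' @export
print.aux_solution <- function(x, ...) {
  cat(sprintf("auxiliary-method family at beta1 = %g, k1 = %g, k2 = %g:\n",
              x$beta1, x$k1, x$k2))
  cat(sprintf("  alpha1 = %g (= -beta1); h = (%g, %g, %g, %g, %g); delta1 = %g\n",
              x$alpha1, x$h$h0, x$h$h1, x$h$h2, x$h$h3, x$h$h4, x$h$delta1))
  cat(sprintf("  catalog branch %s; c free\n", x$catalog_branch))
  invisible(x)
}

#' Build the sech^2 pulse solution of the auxiliary method
#'
#' With `h0 = 0` the active catalog branch is I.4, giving
#' `U(x, t) = -beta1 h2 sech^2(theta) / (2 sqrt(h2 h4) tanh(theta) - h3)`
#' with `theta = sqrt(h2)(x - c t)/2`, and `V = -U` identically. The
#' denominator cannot vanish when `|h3| > 2 sqrt(h2 h4)`; metadata records
#' the denominator range and whether a pole can enter the window.
#'
#' @param sol an `aux_solution` from [derive_aux_coefficients()].
#' @param c wave speed (free in this family).
#' @return A `travelling_wave_solution` (same contract as
#'   [build_gg_solution()]).
#' @export
build_aux_solution <- function(sol, c = 1) {
  stopifnot(inherits(sol, "aux_solution"))
  h <- sol$h
  if (h$h2 <= 0) stop("pulse branch requires h2 = 1 + k1 k2 > 0")
  if (h$h4 <= 0)
    stop("complex-coefficient case refused: h4 = (k1 - 1) beta1^2 / 2 <= 0 ",
         "(requires k1 > 1)")
  a1 <- sol$alpha1; b1 <- sol$beta1; cc <- c
  s2 <- sqrt(h$h2)
  shh <- sqrt(h$h2 * h$h4)
  Ffun <- function(xi) aux_F(xi, h, "I.4")
  dF <- function(xi) {
    th <- s2 / 2 * xi
    S <- 1 / cosh(th)^2; Tt <- tanh(th)
    D <- 2 * shh * Tt - h$h3
    -h$h2 * s2 * S * (Tt * D + shh * S) / D^2
  }
  d2F <- function(xi) {
    F <- Ffun(xi)
    h$h2 * F + 1.5 * h$h3 * F^2 + 2 * h$h4 * F^3
  }
  den_range <- sort(c(-2 * shh - h$h3, 2 * shh - h$h3))
  structure(list(
    kind = "aux", case = "aux (c free)", alpha1 = a1, beta1 = b1,
    h = h, c = cc, delta = h$delta1,
    params = scaled_params(sol$k1, sol$k2),
    U = function(x, t = 0) a1 * Ffun(x - cc * t),
    V = function(x, t = 0) b1 * Ffun(x - cc * t),
    profile = Ffun,
    profile_pair = profile_pair(
      u = function(xi) a1 * Ffun(xi), v = function(xi) b1 * Ffun(xi),
      du = function(xi) a1 * dF(xi), dv = function(xi) b1 * dF(xi),
      d2u = function(xi) a1 * d2F(xi), d2v = function(xi) b1 * d2F(xi)),
    metadata = list(
      catalog_branch = "I.4",
      c_note = "free parameter (user-supplied)",
      denominator_range = den_range,
      pole_possible = den_range[1] <= 0 && den_range[2] >= 0,
      decays_to = 0)),
    class = "travelling_wave_solution")
}
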