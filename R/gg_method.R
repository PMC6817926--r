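# (G'/G)-expansion backend: generator-function branches, exact case
# derivation from the collected algebraic system, and evaluators for the
# closed-form traveling-wave solutions U = alpha1 F(x - c t),
# V = beta1 F(x - c t).

#' Generator function of the (G'/G) rule
#'
#' General solution of `F' = -F^2 - lambda*F - mu` (equivalently F = G'/G
#' with `G'' + lambda G' + mu G = 0`), with integration constants A1, A2:
#' hyperbolic branch for discriminant `Delta = lambda^2 - 4 mu > 0`,
#' trigonometric for `Delta < 0`, rational `A2/(A1 + A2 xi) - lambda/2` for
#' `Delta = 0`. Poles return `NaN` and are counted in the `"poles"`
#' attribute. With `A1 = 0, A2 = 1` the hyperbolic branch is the bounded
#' tanh-type kink; `A1 = 1, A2 = 0` gives the coth-type branch with a pole
#' at xi = 0.
#'
#' @param xi numeric vector of wave-coordinate values.
#' @param lambda,mu coefficients of the auxiliary ODE.
#' @param A1,A2 integration constants, not both zero.
#' @return Numeric vector `F(xi)` with attribute `poles` (count of masked
#'   points).
#' @examples
#' gg_F(0.7, lambda = 0, mu = -1, A1 = 0, A2 = 1)  # tanh(0.7)
#' @export
gg_F <- function(xi, lambda, mu, A1 = 0, A2 = 1) {
  if (A1 == 0 && A2 == 0) stop("invalid constants: A1 = A2 = 0")
  delta <- lambda^2 - 4 * mu
  tol <- 1e-12 * max(1, lambda^2, abs(mu))
  if (delta > tol) {
    w <- sqrt(delta) / 2
    th <- tanh(w * xi)
    num <- A1 + A2 * th
    den <- A1 * th + A2
    F <- w * num / den - lambda / 2
  } else if (delta < -tol) {
    w <- sqrt(-delta) / 2
    s <- sin(w * xi); co <- cos(w * xi)
    num <- A1 * co - A2 * s
    den <- A1 * s + A2 * co
    F <- w * num / den - lambda / 2
  } else {
    den <- A1 + A2 * xi
    F <- A2 / den - lambda / 2
  }
  bad <- !is.finite(F)
  F[bad] <- NaN
  attr(F, "poles") <- sum(bad)
  F
}

# symbolic gg families are derived once per session and cached
.wavepred_cache <- new.env(parent = emptyenv())

.gg_families <- function() {
  if (is.null(.wavepred_cache$gg)) {
    sys <- substitute_and_collect(polynomial_ansatz(), aux_rule_gg())
    fams <- solve_system(sys)
    fams <- Filter(Negate(function(f) f$trivial), fams)
    is_caseI <- vapply(fams, function(f) {
      mu <- f$assignments[["mu"]]
      !is.null(mu) && !rf_is_zero(mu)
    }, logical(1))
    is_caseII <- vapply(fams, function(f) {
      mu <- f$assignments[["mu"]]
      !is.null(mu) && rf_is_zero(mu)
    }, logical(1))
    if (sum(is_caseI) != 1L || sum(is_caseII) < 1L)
      stop("unexpected (G'/G) branch structure")
    caseI <- fams[is_caseI][[1L]]
    caseI$case_label <- "Case I"
    caseII <- fams[is_caseII]
    for (i in seq_along(caseII))
      caseII[[i]]$case_label <-
        sprintf("Case II (%s)",
                if (!is.null(caseII[[i]]$minpoly) &&
                    caseII[[i]]$minpoly$sign > 0) "+" else "-")
    .wavepred_cache$gg <- list(caseI = caseI, caseII = caseII,
                               sys = caseI$system)
  }
  .wavepred_cache$gg
}

#' Derive the two (G'/G) solution cases
#'
#' Solves the collected coefficient system exactly and evaluates both cases
#' at the given parameters. Case I determines `mu`, `lambda` and the wave
#' speed `c`; Case II has `mu = 0` and two algebraic sign branches for
#' `lambda` (and hence `c`). Both cases share
#' `alpha1 = -2/(beta1 (k1 - 1))`, so `alpha1 beta1 (k1 - 1) + 2 = 0`
#' identically.
#'
#' @param p a [scaled_params()] object with `k1 != 1`.
#' @param beta1 free predator amplitude (nonzero).
#' @param branch sign branch used for Case II's quadratic, `"+"` or `"-"`.
#' @return A list with elements `caseI` and `caseII`, each of class
#'   `gg_solution` carrying numeric `alpha1`, `lambda`, `mu`, `c`
#'   (`c = NA` when free), the discriminant `delta`, validity flags, and the
#'   underlying exact family.
#' @export
derive_gg_cases <- function(p, beta1, branch = c("+", "-")) {
  .check_solvable(p)
  branch <- match.arg(branch)
  if (beta1 == 0) stop("beta1 must be nonzero")
  fams <- .gg_families()
  env <- list(beta1 = beta1, k1 = p$k1, k2 = p$k2)

  mk <- function(fam) {
    vals <- tryCatch(suppressWarnings(family_eval(fam, env)),
                     error = function(e) NULL)
    getv <- function(nm) {
      if (is.null(vals) || !nm %in% names(vals)) return(NA_real_)
      v <- unname(vals[nm])
      if (is.finite(v)) v else NA_real_
    }
    out <- list(case = fam$case_label, family = fam,
                beta1 = beta1, k1 = p$k1, k2 = p$k2,
                alpha1 = getv("alpha1"), lambda = getv("lambda"),
                mu = getv("mu"), c = getv("c"),
                c_free = !"c" %in% names(fam$assignments),
                validity_ok = !is.null(vals) && all(is.finite(vals)),
                conditions = fam$conditions)
    out$delta <- out$lambda^2 -
      4 * (if (is.na(out$mu)) 0 else out$mu)
    structure(out, class = "gg_solution")
  }

  caseI <- mk(fams$caseI)
  ii <- vapply(fams$caseII, function(f) grepl(branch, f$case_label, fixed = TRUE),
               logical(1))
  caseII <- mk(fams$caseII[ii][[1L]])
  # Case II numeric evaluation can hit 0/0 exactly on the slice
  # alpha1 + beta1 = 0; recompute lambda there from the F^2 equation
  if (!is.finite(caseII$lambda)) {
    a1 <- rf_eval(family_resolve(caseII$family)[["alpha1"]], env)
    if (abs(a1 + beta1) < 1e-10) {
      caseII$alpha1 <- a1
      caseII$lambda <- (a1^2 + p$k1 * beta1^2 + 2) / (3 * beta1)
      caseII$mu <- 0
      caseII$c <- NA_real_
      caseII$c_free <- TRUE
      caseII$delta <- caseII$lambda^2
      # the F^1 equation must still close; on the consistent slice it does
      r1 <- beta1 * caseII$lambda^2 + a1 - p$k1 * p$k2 * beta1
      caseII$validity_ok <- abs(r1) < 1e-9 * max(1, abs(beta1 * caseII$lambda^2))
    }
  }
  list(caseI = caseI, caseII = caseII)
}

#' @export
print.gg_solution <- function(x, ...) {
  cat(sprintf("(G'/G) %s at beta1 = %g, k1 = %g, k2 = %g:\n",
              x$case, x$beta1, x$k1, x$k2))
  cat(sprintf("  alpha1 = %g, lambda = %g, mu = %g, c = %s, Delta = %g\n",
              x$alpha1, x$lambda, x$mu,
              if (x$c_free) "free" else sprintf("%g", x$c), x$delta))
  invisible(x)
}

#' Build the traveling-wave evaluator for a (G'/G) case
#'
#' Constructs `U(x, t) = alpha1 F(x - c t)`, `V(x, t) = beta1 F(x - c t)`
#' with `F` from [gg_F()]. The hyperbolic (`Delta > 0`) branch is the
#' kink-type solution the model discussion centres on; `Delta <= 0` branches
#' are evaluable but flagged as outside that discussion. Metadata records the
#' plateau values `-lambda/2 +- sqrt(Delta)/2` (the fixed points of the
#' generator ODE) and any pole location inside a probe window.
#'
#' @param sol a `gg_solution` from [derive_gg_cases()].
#' @param A1,A2 integration constants (default the bounded tanh-type kink).
#' @param c wave speed; required when the case leaves `c` free.
#' @return An object of class `travelling_wave_solution`: functions
#'   `U(x, t)`, `V(x, t)`, `profile(xi)` (= F), analytic profile-pair access,
#'   and `metadata`.
#' @export
build_gg_solution <- function(sol, A1 = 0, A2 = 1, c = NULL) {
  stopifnot(inherits(sol, "gg_solution"))
  if (sol$c_free) {
    if (is.null(c)) stop("this case leaves the wave speed free: supply c")
    cc <- c
    c_note <- "free parameter (user-supplied)"
  } else {
    if (!is.null(c) && abs(c - sol$c) > 1e-9)
      stop("c is determined by this case; do not override")
    cc <- sol$c
    c_note <- "determined by the case"
  }
  lam <- sol$lambda; mu <- sol$mu
  a1 <- sol$alpha1; b1 <- sol$beta1
  delta <- sol$delta
  Ffun <- function(xi) gg_F(xi, lam, mu, A1, A2)
  dF <- function(xi) { F <- Ffun(xi); -(F^2 + lam * F + mu) }
  d2F <- function(xi) { F <- Ffun(xi); (2 * F + lam) * (F^2 + lam * F + mu) }
  plateaus <- if (delta > 0) (-lam + c(-1, 1) * sqrt(delta)) / 2 else NULL
  # pole of the hyperbolic branch: A1 tanh + A2 = 0 within |tanh| < 1
  pole_xi <- NULL
  if (delta > 0 && A1 != 0 && abs(A2 / A1) < 1) {
    pole_xi <- atanh(-A2 / A1) / (sqrt(delta) / 2)
  }
  structure(list(
    kind = "gg", case = sol$case, alpha1 = a1, beta1 = b1,
    lambda = lam, mu = mu, c = cc, delta = delta,
    params = scaled_params(sol$k1, sol$k2),
    U = function(x, t = 0) a1 * Ffun(x - cc * t),
    V = function(x, t = 0) b1 * Ffun(x - cc * t),
    profile = Ffun,
    profile_pair = profile_pair(
      u = function(xi) a1 * Ffun(xi), v = function(xi) b1 * Ffun(xi),
      du = function(xi) a1 * dF(xi), dv = function(xi) b1 * dF(xi),
      d2u = function(xi) a1 * d2F(xi), d2v = function(xi) b1 * d2F(xi)),
    metadata = list(
      A1 = A1, A2 = A2, c_note = c_note,
      branch = if (delta > 0) "hyperbolic (kink-type)" else
        if (delta < 0) "trigonometric (outside the model discussion)" else
          "rational (outside the model discussion)",
      plateaus_F = plateaus,
      plateaus_U = if (!is.null(plateaus)) a1 * plateaus else NULL,
      plateaus_V = if (!is.null(plateaus)) b1 * plateaus else NULL,
      pole_xi = pole_xi)),
    class = "travelling_wave_solution")
}

#' @export
print.travelling_wave_solution <- function(x, ...) {
  cat(sprintf("travelling-wave solution [%s, %s]: c = %g\n",
              x$kind, x$case %||% "", x$c))
  cat(sprintf("  alpha1 = %g, beta1 = %g\n", x$alpha1, x$beta1))
  if (!is.null(x$metadata$plateaus_F))
    cat(sprintf("  F plateaus: %s\n",
                paste(signif(x$metadata$plateaus_F, 6), collapse = ", ")))
  if (!is.null(x$metadata$pole_xi))
    cat(sprintf("  pole at xi = %g\n", x$metadata$pole_xi))
  invisible(x)
}

#' Fig.-2-type caption slice of Case II
#'
#' Imposing `k1 = 2/beta1^2 + 1` on Case II (with `mu = 0`) collapses
#' `alpha1` to `-beta1`, leaves the wave speed free, and determines
#' `lambda = 2 (beta1^2 + 2)/(3 beta1)` and
#' `k2 = (4 beta1^4 + 7 beta1^2 + 16)/(9 beta1^2 + 18)`. The identities are
#' re-derived exactly by solving the coefficient system with `k2` promoted
#' to an unknown; see [gg_case2_slice_symbolic()].
#'
#' @param beta1 nonzero predator amplitude.
#' @return A `gg_solution` on the slice (`c` free).
#' @export
gg_case2_slice <- function(beta1) {
  if (beta1 == 0) stop("beta1 must be nonzero")
  k1 <- 2 / beta1^2 + 1
  k2 <- (4 * beta1^4 + 7 * beta1^2 + 16) / (9 * beta1^2 + 18)
  derive_gg_cases(scaled_params(k1, k2), beta1)$caseII
}

#' Exact derivation of the Case II caption slice
#'
#' Solves the (G'/G) coefficient system with `mu = 0` and
#' `k1 = (2 + beta1^2)/beta1^2` substituted, treating `k2` as an unknown.
#' Returns the exact assignments together with proven identities for
#' `alpha1 + beta1`, `lambda - 2(beta1^2+2)/(3 beta1)` and
#' `k2 - (4 beta1^4 + 7 beta1^2 + 16)/(9 beta1^2 + 18)` (all zero).
#'
#' @return A list with the `solution_family` and logical identity checks.
#' @export
gg_case2_slice_symbolic <- function() {
  if (!is.null(.wavepred_cache$gg_slice)) return(.wavepred_cache$gg_slice)
  sys <- substitute_and_collect(polynomial_ansatz(), aux_rule_gg())
  b1 <- mp_var("beta1")
  k1_val <- rf_new(mp_const(2) + b1^2, b1^2)
  eqs <- lapply(sys$equations, function(e) {
    e <- .eq_subst_rf(e, "k1", k1_val)
    .eq_subst_rf(e, "mu", .rf0())
  })
  eqs <- Filter(Negate(mp_is_zero), eqs)
  sys2 <- sys
  sys2$equations <- eqs
  sys2$unknowns <- c("alpha1", "lambda", "c", "k2")
  sys2$params <- "beta1"
  fams <- solve_system(sys2)
  fams <- Filter(Negate(function(f) f$trivial), fams)
  # the slice family leaves c free
  slice <- Filter(function(f) "c" %in% f$free, fams)
  if (length(slice) != 1L) stop("unexpected slice branch structure")
  fam <- slice[[1L]]
  res <- family_resolve(fam)
  id_alpha <- rf_is_zero(res[["alpha1"]] + rf_new(b1))
  lam_ref <- rf_new(mp_const(2) * (b1^2 + mp_const(2)), mp_const(3) * b1)
  id_lambda <- rf_is_zero(res[["lambda"]] - lam_ref)
  k2_ref <- rf_new(mp_const(4) * b1^4 + mp_const(7) * b1^2 + mp_const(16),
                   mp_const(9) * b1^2 + mp_const(18))
  id_k2 <- rf_is_zero(res[["k2"]] - k2_ref)
  out <- list(family = fam, id_alpha1 = id_alpha, id_lambda = id_lambda,
              id_k2 = id_k2)
  .wavepred_cache$gg_slice <- out
  out
}
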