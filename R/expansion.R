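# Generic function-expansion engine: polynomial ansatz in a generator
# function F(xi), homogeneous balance, substitution of an auxiliary-equation
# rule for F' and F'', exact coefficient collection, and a branching
# triangular solver for the resulting algebraic systems. Everything here is
# exact (see R/algebra.R); "equals zero" means identically zero.

#' Polynomial ansatz u1 = sum alpha_i F^i, v1 = sum beta_i F^i
#'
#' The constant terms default to zero, matching the model pipeline, but
#' nonzero constants are supported by the engine.
#'
#' @param n,m polynomial degrees of the prey and predator profiles (>= 1).
#' @param zero_const if `TRUE` (default) alpha_0 = beta_0 = 0.
#' @return An object of class `polynomial_ansatz`.
#' @export
polynomial_ansatz <- function(n = 1L, m = 1L, zero_const = TRUE) {
  stopifnot(n >= 1L, m >= 1L)
  structure(list(n = as.integer(n), m = as.integer(m), zero_const = zero_const),
            class = "polynomial_ansatz")
}

#' Auxiliary-equation rules for the generator function
#'
#' `aux_rule_gg()` is the (G'/G) rule `F' = -F^2 - lambda*F - mu` (F = G'/G
#' with G'' + lambda G' + mu G = 0). `aux_rule_quartic()` is the generalized
#' auxiliary rule `(F')^2 = h0 + h1 F + h2 F^2 + h3 F^3 + h4 F^4`; only even
#' powers of F' can be rewritten, so any surviving odd F' coefficient must
#' vanish on its own — that is how the `c (alpha1 + beta1) = 0` equation
#' arises.
#'
#' @return An object of class `auxiliary_rule`.
#' @export
aux_rule_gg <- function() {
  F <- mp_var("F")
  structure(list(kind = "gg",
                 fp = -(F^2) - mp_var("lambda") * F - mp_var("mu"),
                 symbols = c("lambda", "mu")),
            class = "auxiliary_rule")
}

#' @rdname aux_rule_gg
#' @export
aux_rule_quartic <- function() {
  F <- mp_var("F")
  fp2 <- mp_var("h0") + mp_var("h1") * F + mp_var("h2") * F^2 +
    mp_var("h3") * F^3 + mp_var("h4") * F^4
  structure(list(kind = "quartic", fp2 = fp2,
                 symbols = c("h0", "h1", "h2", "h3", "h4")),
            class = "auxiliary_rule")
}

#' Homogeneous balance of the ansatz degrees
#'
#' Balances the highest nonlinearity of the combined traveling-wave ODE,
#' `u1 v1^2` (degree n + 2m in F), against the highest derivative `v1''`
#' (degree m + d2 where d2 is the degree gained by differentiating twice; 2
#' for both implemented rules since F' rewrites to a quadratic and (F')^2 to
#' a quartic), while requiring the prey nonlinearities `u1^2` and `u1 v1` to
#' balance each other, which forces n = m.
#'
#' @param rule an [aux_rule_gg()] or [aux_rule_quartic()] object.
#' @param p a [scaled_params()] object (the balance does not depend on its
#'   values; passed for interface symmetry and validity checking).
#' @param d2 degree gained by two xi-derivatives (override for synthetic
#'   rules; default 2).
#' @return Integer vector `c(n, m)`.
#' @export
homogeneous_balance <- function(rule = aux_rule_gg(), p = NULL, d2 = 2L) {
  if (!is.null(p)) .check_scaled(p)
  # n = m (u1^2 vs u1 v1) and n + 2m = m + d2  =>  m = d2/2
  if (d2 %% 2L != 0L || d2 <= 0L)
    stop("no balance: no positive integer degrees satisfy n + 2m = m + ", d2,
         " with n = m")
  m <- d2 %/% 2L
  c(n = m, m = m)
}

# --- building the combined ODE as an exact polynomial ------------------------

# xi-derivative acting on polynomials in {F, Fp, Fpp}
.dxi <- function(p) {
  mp_deriv(p, "F") * mp_var("Fp") + mp_deriv(p, "Fp") * mp_var("Fpp")
}

# combined traveling-wave ODE residual after inserting the ansatz, as an
# mpoly in F, Fp, Fpp, the ansatz coefficients, c, k1, k2
.combined_ansatz_poly <- function(ansatz) {
  F <- mp_var("F")
  u <- mp_const(0); v <- mp_const(0)
  lo <- if (ansatz$zero_const) 1L else 0L
  for (i in lo:ansatz$n) u <- u + mp_var(paste0("alpha", i)) * F^i
  for (i in lo:ansatz$m) v <- v + mp_var(paste0("beta", i)) * F^i
  du <- .dxi(u); dv <- .dxi(v); d2v <- .dxi(dv)
  k1 <- mp_var("k1"); k2 <- mp_var("k2"); cc <- mp_var("c")
  cc * (du + dv) + d2v - k1 * k2 * v - k1 * v^2 + u - u * u -
    (1 - k1) * u * v - (1 - k1) * u * (v^2)
}

# rewrite Fpp and (for gg) Fp, (for quartic) even powers of Fp
.rewrite_rule <- function(poly, rule) {
  if (rule$kind == "gg") {
    g <- rule$fp
    poly <- mp_subst(poly, "Fpp", mp_deriv(g, "F") * mp_var("Fp"))
    poly <- mp_subst(poly, "Fp", g)
  } else {
    fpp <- mp_frac(1, 2) * mp_deriv(rule$fp2, "F")
    poly <- mp_subst(poly, "Fpp", fpp)
    cl <- mp_coeflist(poly, "Fp")
    out <- mp_const(0)
    for (k in seq_along(cl) - 1L) {
      red <- mp_pow(rule$fp2, k %/% 2L)
      if (k %% 2L == 1L) red <- red * mp_var("Fp")
      out <- out + cl[[k + 1L]] * red
    }
    poly <- out
  }
  poly
}

#' Substitute the ansatz into the combined ODE and collect coefficients
#'
#' Inserts the polynomial ansatz into the combined traveling-wave ODE,
#' rewrites `F''` (and `(F')^2` for the quartic rule) through the auxiliary
#' rule, and collects the coefficient of every power of `F` — and of any
#' surviving odd `F'` term — into one polynomial equation each. The result is
#' the machine form of the method's nonlinear algebraic system.
#'
#' @param ansatz a [polynomial_ansatz()]; degrees normally come from
#'   [homogeneous_balance()].
#' @param rule an auxiliary rule.
#' @return An object of class `algebraic_system`: a list of `mpoly` equations
#'   (named by their origin, Fp-coefficients first then descending powers of
#'   F), the ordered unknown names, and the free parameter names.
#' @export
substitute_and_collect <- function(ansatz = polynomial_ansatz(),
                                   rule = aux_rule_gg()) {
  poly <- .rewrite_rule(.combined_ansatz_poly(ansatz), rule)
  if (mp_degree(poly, "Fpp") > 0L || mp_degree(poly, "Fp") > 1L)
    stop("internal-consistency error: rewriting left irreducible derivative powers")
  eqs <- list()
  cl_fp <- mp_coeflist(poly, "Fp")
  if (length(cl_fp) == 2L) {
    byF <- mp_coeflist(cl_fp[[2L]], "F")
    for (k in rev(seq_along(byF) - 1L)) {
      if (!mp_is_zero(byF[[k + 1L]]))
        eqs[[sprintf("F'*F^%d", k)]] <- byF[[k + 1L]]
    }
  }
  byF <- mp_coeflist(cl_fp[[1L]], "F")
  for (k in rev(seq_along(byF) - 1L)) {
    if (!mp_is_zero(byF[[k + 1L]]))
      eqs[[sprintf("F^%d", k)]] <- byF[[k + 1L]]
  }
  lo <- if (ansatz$zero_const) 1L else 0L
  unknowns <- c(paste0("alpha", lo:ansatz$n),
                if (rule$kind == "gg") c("lambda", "mu") else
                  c("h1", "h2", "h3", "h4"),
                "c")
  params <- c(paste0("beta", lo:ansatz$m), "k1", "k2",
              if (rule$kind == "quartic") "h0")
  structure(list(equations = eqs, unknowns = unknowns, params = params,
                 rule = rule$kind, ansatz = ansatz),
            class = "algebraic_system")
}

#' @export
print.algebraic_system <- function(x, ...) {
  cat(sprintf("algebraic system (%s rule): %d equations in {%s}; free: {%s}\n",
              x$rule, length(x$equations),
              paste(x$unknowns, collapse = ", "),
              paste(x$params, collapse = ", ")))
  for (nm in names(x$equations))
    cat(sprintf("  [%s]  %s = 0\n", nm, format(x$equations[[nm]])))
  invisible(x)
}

# --- solver ------------------------------------------------------------------

.rf0 <- function() rf_new(mp_const(0))

# substitute a pure-ratfun assignment into an mpoly equation, clearing the
# denominator (the pivot condition den != 0 is recorded by the caller)
.eq_subst_rf <- function(eq, var, value) {
  d <- mp_degree(eq, var)
  if (d == 0L) return(eq)
  cl <- mp_coeflist(eq, var)
  out <- mp_const(0)
  for (k in 0:d)
    out <- out + cl[[k + 1L]] * mp_pow(value$num, k) * mp_pow(value$den, d - k)
  out
}

.cond_nonzero <- function(p) sprintf("%s != 0", format(p))

`%||%` <- function(a, b) if (is.null(a)) b else a

# depth-first branching solver. Families are "triangular chains": named
# ratfun assignments (which may reference unknowns defined further down the
# chain) plus at most one quadratic minimal polynomial with a sign choice.
.solve_branch <- function(eqs, unknowns, assigns, conds, path, depth = 0L) {
  if (depth > 24L) stop("unsolved: solver recursion limit; system echoed:\n",
                        paste(vapply(eqs, format, ""), collapse = "\n"))
  eqs <- Filter(Negate(mp_is_zero), eqs)
  if (!length(eqs)) {
    return(list(list(assignments = assigns, conditions = conds, path = path,
                     minpoly = NULL,
                     free = setdiff(unknowns, names(assigns)))))
  }
  # an equation with no unknowns left cannot vanish: dead branch
  for (eq in eqs) {
    if (!length(intersect(mp_vars_in(eq), unknowns))) return(list())
  }
  # rule 1: factor out monomial content in the unknowns -> branch per factor
  for (i in seq_along(eqs)) {
    ct <- mp_monomial_content(eqs[[i]], unknowns)
    if (length(ct)) {
      v <- names(ct)[1L]
      rest <- mp_divide_monomial(eqs[[i]], v, ct[[1L]])
      out <- list()
      e1 <- lapply(eqs[-i], function(e) .eq_subst_rf(e, v, .rf0()))
      a1 <- assigns; a1[[v]] <- .rf0()
      out <- c(out, .solve_branch(e1, unknowns, a1, conds,
                                  c(path, sprintf("factor %s = 0", v)),
                                  depth + 1L))
      e2 <- eqs; e2[[i]] <- rest
      out <- c(out, .solve_branch(e2, unknowns, assigns,
                                  c(conds, sprintf("%s != 0", v)),
                                  c(path, sprintf("factor %s != 0", v)),
                                  depth + 1L))
      return(out)
    }
  }
  # rule 2: linear solve with a pivot coefficient free of unknowns
  for (i in seq_along(eqs)) {
    for (v in unknowns[!(unknowns %in% names(assigns))]) {
      if (mp_degree(eqs[[i]], v) != 1L) next
      cl <- mp_coeflist(eqs[[i]], v)
      piv <- cl[[2L]]
      if (length(intersect(mp_vars_in(piv), unknowns))) next
      value <- rf_new(mp_neg(cl[[1L]]), piv)
      rest <- lapply(eqs[-i], function(e) .eq_subst_rf(e, v, value))
      a <- assigns; a[[v]] <- value
      piv_cond <- if (length(mp_vars_in(piv))) .cond_nonzero(piv) else character()
      return(.solve_branch(rest, unknowns, a,
                           c(conds, piv_cond),
                           c(path, sprintf("solve %s", v)),
                           depth + 1L))
    }
  }
  # rule 3: quadratic in a single remaining unknown -> two sign branches
  # sharing the minimal polynomial A v^2 + B v + C = 0
  for (i in seq_along(eqs)) {
    inv <- intersect(mp_vars_in(eqs[[i]]), unknowns)
    if (length(inv) != 1L) next
    v <- inv
    if (mp_degree(eqs[[i]], v) != 2L) next
    cl <- mp_coeflist(eqs[[i]], v)
    A <- cl[[3L]]; B <- cl[[2L]]; C <- cl[[1L]]
    # remaining equations must vanish at both roots: pseudo-remainder
    ok <- TRUE
    for (e in eqs[-i]) {
      left <- intersect(mp_vars_in(e), unknowns)
      if (length(setdiff(left, v))) { ok <- FALSE; break }
      r <- mp_prem_quadratic(e, v, A, B, C)
      if (!mp_is_zero(r)) { ok <- FALSE; break }
    }
    if (!ok) next
    disc <- B * B - 4 * (A * C)
    out <- list()
    for (sgn in c(1, -1)) {
      out <- c(out, list(list(
        assignments = assigns,
        conditions = c(conds, .cond_nonzero(A),
                       sprintf("discriminant (%s) >= 0 for a real branch",
                               format(disc))),
        path = c(path, sprintf("quadratic %s (%s branch)", v,
                               if (sgn > 0) "+" else "-")),
        minpoly = list(var = v, A = A, B = B, C = C, disc = disc, sign = sgn),
        free = setdiff(unknowns, c(names(assigns), v)))))
    }
    return(out)
  }
  stop("unsolved: no applicable elimination step; system echoed:\n",
       paste(vapply(eqs, format, ""), collapse = "\n"))
}

#' Solve a collected algebraic system symbolically
#'
#' Depth-first exact elimination: monomial factors branch the solution tree,
#' equations linear in one unknown (with a pivot free of the remaining
#' unknowns) are solved as rational functions, and a terminal quadratic in a
#' single unknown is kept as a minimal polynomial with two sign branches.
#' Every returned family annihilates the source system; [back_substitute()]
#' re-proves this from scratch. Branches in which the ansatz collapses
#' (`alpha1 = 0`) are returned but tagged trivial. Ordering is deterministic.
#'
#' @param sys an [substitute_and_collect()] system.
#' @return A list of `solution_family` objects, each carrying exact ratfun
#'   `assignments` (a triangular chain over the free parameters), an optional
#'   quadratic `minpoly`, pivot and branch `conditions`, the `free` unknowns,
#'   and the branch `path`.
#' @export
solve_system <- function(sys) {
  stopifnot(inherits(sys, "algebraic_system"))
  raw <- .solve_branch(sys$equations, sys$unknowns, list(), character(),
                       character())
  if (!length(raw)) stop("unsolved: no solution branch found")
  fams <- lapply(raw, function(br) {
    a1 <- br$assignments[["alpha1"]]
    trivial <- !is.null(a1) && rf_is_zero(a1)
    structure(list(assignments = br$assignments, minpoly = br$minpoly,
                   conditions = unique(br$conditions),
                   free = br$free, path = br$path, trivial = trivial,
                   rule = sys$rule, system = sys,
                   case_label = NA_character_),
              class = "solution_family")
  })
  keys <- vapply(fams, function(f)
    paste0(if (f$trivial) "z" else "a", paste(f$path, collapse = ";")), "")
  fams[order(keys)]
}

#' Resolved assignments of a solution family
#'
#' Substitutes the chain into itself until each assignment is a rational
#' function of the free parameters only (plus, where a quadratic minimal
#' polynomial is present, its variable).
#'
#' @param family a `solution_family`.
#' @return Named list of `ratfun`.
#' @export
family_resolve <- function(family) {
  assigns <- family$assignments
  unknowns <- family$system$unknowns
  keep_var <- if (!is.null(family$minpoly)) family$minpoly$var else character()
  for (pass in 1:12) {
    dirty <- FALSE
    for (v in names(assigns)) {
      val <- assigns[[v]]
      deps <- intersect(union(mp_vars_in(val$num), mp_vars_in(val$den)),
                        setdiff(unknowns, keep_var))
      deps <- intersect(deps, names(assigns))
      for (d in deps) {
        val <- rf_subst(val, d, assigns[[d]])
        dirty <- TRUE
      }
      assigns[[v]] <- val
    }
    if (!dirty) return(assigns)
  }
  stop("unsolved: cyclic assignment dependencies")
}

#' @export
print.solution_family <- function(x, ...) {
  cat(sprintf("solution family [%s rule]%s%s\n", x$rule,
              if (!is.na(x$case_label)) paste0(" ", x$case_label) else "",
              if (x$trivial) " (trivial)" else ""))
  res <- family_resolve(x)
  for (v in names(res))
    cat(sprintf("  %s = %s\n", v, format(res[[v]])))
  if (!is.null(x$minpoly))
    cat(sprintf("  %s: root (%s branch) of (%s)*%s^2 + (%s)*%s + (%s) = 0\n",
                x$minpoly$var, if (x$minpoly$sign > 0) "+" else "-",
                format(x$minpoly$A), x$minpoly$var,
                format(x$minpoly$B), x$minpoly$var, format(x$minpoly$C)))
  if (length(x$free)) cat("  free:", paste(x$free, collapse = ", "), "\n")
  if (length(x$conditions))
    cat("  valid if:", paste(x$conditions, collapse = "; "), "\n")
  invisible(x)
}

#' Back-substitute a family into its source system
#'
#' Substitutes the family's exact assignments into every equation and proves
#' (or refutes) that each reduces to zero identically; equations involving
#' the quadratic minimal-polynomial variable are reduced by pseudo-remainder,
#' which certifies both sign branches at once. This is exact arithmetic, not
#' a numeric check.
#'
#' @param family a `solution_family`.
#' @param sys the source system (defaults to the one stored in the family).
#' @return Named logical vector, one entry per equation.
#' @export
back_substitute <- function(family, sys = family$system) {
  unknowns <- sys$unknowns
  mvar <- if (!is.null(family$minpoly)) family$minpoly$var else character()
  vapply(sys$equations, function(eq) {
    work <- rf_new(eq)
    for (pass in 1:24) {
      deps <- intersect(union(mp_vars_in(work$num), mp_vars_in(work$den)),
                        setdiff(unknowns, mvar))
      deps <- intersect(deps, names(family$assignments))
      if (!length(deps)) break
      work <- rf_subst(work, deps[[1L]], family$assignments[[deps[[1L]]]])
    }
    num <- work$num
    if (length(mvar) && mvar %in% mp_vars_in(num))
      num <- mp_prem_quadratic(num, mvar, family$minpoly$A, family$minpoly$B,
                               family$minpoly$C)
    mp_is_zero(num)
  }, logical(1))
}

#' Evaluate a family's assignments numerically
#'
#' Free parameters come from `env`; a quadratic minimal-polynomial variable
#' is evaluated through the quadratic formula with the family's sign branch,
#' then the remaining chain is resolved iteratively.
#'
#' @param family a `solution_family`.
#' @param env named list of numeric values for the free parameters.
#' @return Named numeric vector over the assigned unknowns.
#' @export
family_eval <- function(family, env) {
  vals <- unlist(env)
  targets <- names(family$assignments)
  if (!is.null(family$minpoly)) {
    mp <- family$minpoly
    A <- mp_eval(mp$A, as.list(vals)); B <- mp_eval(mp$B, as.list(vals))
    C <- mp_eval(mp$C, as.list(vals))
    disc <- B^2 - 4 * A * C
    root <- if (disc < 0) NaN else (-B + mp$sign * sqrt(disc)) / (2 * A)
    vals[mp$var] <- root
    targets <- c(targets, mp$var)
  }
  done <- setdiff(names(vals), names(family$assignments))
  for (pass in seq_len(length(targets) + 2L)) {
    for (v in setdiff(names(family$assignments), done)) {
      val <- family$assignments[[v]]
      deps <- union(mp_vars_in(val$num), mp_vars_in(val$den))
      if (all(deps %in% names(vals))) {
        vals[v] <- rf_eval(val, as.list(vals))
        done <- c(done, v)
      }
    }
    if (all(names(family$assignments) %in% done)) break
  }
  if (!all(names(family$assignments) %in% done))
    stop("family_eval: unresolved assignment chain")
  out <- vals[intersect(c(names(family$assignments),
                          if (!is.null(family$minpoly)) family$minpoly$var),
                        names(vals))]
  out
}
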