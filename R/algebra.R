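# Exact sparse multivariate polynomial algebra over the rationals, with
# rational functions and quadratic-remainder reduction on top. This is the
# symbolic engine behind the expansion machinery: coefficients are kept as
# reduced integer fractions (stored in doubles; exact below 2^52), so
# "simplifies to zero" is a decidable, exact statement rather than a numeric
# tolerance.

if (getRversion() >= "2.15.1")
  utils::globalVariables(c("x", "t", "value", "field"))

.MP_OVERFLOW <- 2^52

.rgcd <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(abs(a), n); b <- rep_len(abs(b), n)
  while (any(active <- b > 0.5)) {
    r <- numeric(n)
    r[active] <- a[active] %% b[active]
    a[active] <- b[active]
    b <- r
    b[b < 0.5] <- 0
  }
  a
}

# reduce num/den fraction vectors; den kept positive
.rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  if (any(abs(num) >= .MP_OVERFLOW) || any(abs(den) >= .MP_OVERFLOW))
    stop("mpoly coefficient overflow: exact rational arithmetic exceeded 2^52")
  s <- sign(den)
  num <- num * s; den <- den * s
  g <- .rgcd(num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

.rat_add <- function(n1, d1, n2, d2) .rat_reduce(n1 * d2 + n2 * d1, d1 * d2)
.rat_mul <- function(n1, d1, n2, d2) .rat_reduce(n1 * n2, d1 * d2)

#' @noRd
new_mpoly <- function(vars, expo, num, den) {
  structure(list(vars = vars, expo = expo, num = num, den = den),
            class = "mpoly")
}

.mp_canon <- function(vars, expo, num, den) {
  keep <- num != 0
  expo <- expo[keep, , drop = FALSE]; num <- num[keep]; den <- den[keep]
  # drop variables with all-zero exponents
  if (ncol(expo) > 0L) {
    used <- colSums(expo != 0L) > 0L
    vars <- vars[used]; expo <- expo[, used, drop = FALSE]
  }
  if (length(num) == 0L)
    return(new_mpoly(character(), matrix(0L, 0, 0), numeric(), numeric()))
  o <- order(vars)
  vars <- vars[o]; expo <- expo[, o, drop = FALSE]
  key <- apply(expo, 1L, paste, collapse = ",")
  if (anyDuplicated(key)) {
    idx <- split(seq_along(key), key)
    num2 <- numeric(length(idx)); den2 <- numeric(length(idx))
    expo2 <- matrix(0L, length(idx), ncol(expo))
    for (j in seq_along(idx)) {
      ii <- idx[[j]]
      n <- num[ii[1L]]; d <- den[ii[1L]]
      for (k in ii[-1L]) {
        r <- .rat_add(n, d, num[k], den[k])
        n <- r$num; d <- r$den
      }
      num2[j] <- n; den2[j] <- d
      expo2[j, ] <- expo[ii[1L], ]
    }
    keep <- num2 != 0
    expo <- expo2[keep, , drop = FALSE]; num <- num2[keep]; den <- den2[keep]
    if (length(num) == 0L)
      return(new_mpoly(character(), matrix(0L, 0, 0), numeric(), numeric()))
    if (ncol(expo) > 0L) {
      used <- colSums(expo != 0L) > 0L
      vars <- vars[used]; expo <- expo[, used, drop = FALSE]
    }
  }
  if (max(abs(num), den, 1) >= .MP_OVERFLOW)
    stop("mpoly coefficient overflow: exact rational arithmetic exceeded 2^52")
  # deterministic term order: lexicographic on exponent rows
  if (nrow(expo) > 1L) {
    o <- do.call(order, c(lapply(seq_len(ncol(expo)), function(j) -expo[, j]),
                          list(method = "radix")))
    expo <- expo[o, , drop = FALSE]; num <- num[o]; den <- den[o]
  }
  new_mpoly(vars, expo, num, den)
}

#' Polynomial constructors
#'
#' `mp_const()` builds a constant (rational) polynomial, `mp_var()` a single
#' variable, and `mp_frac()` an exact fraction. Polynomials combine with the
#' usual arithmetic operators, `^` taking nonnegative integer powers.
#'
#' @param num,den integer numerator and denominator.
#' @param name variable name.
#' @return An object of class `mpoly`.
#' @keywords internal
mp_const <- function(num, den = 1) {
  stopifnot(num == round(num), den == round(den), den != 0)
  r <- .rat_reduce(num, den)
  if (r$num == 0)
    return(new_mpoly(character(), matrix(0L, 0, 0), numeric(), numeric()))
  new_mpoly(character(), matrix(0L, 1, 0), r$num, r$den)
}

#' @rdname mp_const
#' @keywords internal
mp_frac <- function(num, den) mp_const(num, den)

#' @rdname mp_const
#' @keywords internal
mp_var <- function(name) {
  new_mpoly(name, matrix(1L, 1, 1), 1, 1)
}

mp_is_zero <- function(p) length(p$num) == 0L

mp_vars_in <- function(p) p$vars

.as_mpoly <- function(x) {
  if (inherits(x, "mpoly")) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    if (x != round(x)) stop("non-integer numeric in mpoly arithmetic; use mp_frac()")
    return(mp_const(x))
  }
  stop("cannot coerce to mpoly")
}

.mp_align <- function(a, b) {
  vars <- sort(union(a$vars, b$vars))
  ea <- matrix(0L, nrow(a$expo), length(vars), dimnames = NULL)
  eb <- matrix(0L, nrow(b$expo), length(vars))
  if (length(a$vars)) ea[, match(a$vars, vars)] <- a$expo
  if (length(b$vars)) eb[, match(b$vars, vars)] <- b$expo
  list(vars = vars, ea = ea, eb = eb)
}

mp_add <- function(a, b) {
  al <- .mp_align(a, b)
  .mp_canon(al$vars, rbind(al$ea, al$eb), c(a$num, b$num), c(a$den, b$den))
}

mp_neg <- function(a) {
  a$num <- -a$num
  a
}

mp_mul <- function(a, b) {
  if (mp_is_zero(a) || mp_is_zero(b))
    return(mp_const(0))
  al <- .mp_align(a, b)
  na <- nrow(al$ea); nb <- nrow(al$eb)
  ia <- rep(seq_len(na), each = nb); ib <- rep(seq_len(nb), times = na)
  expo <- al$ea[ia, , drop = FALSE] + al$eb[ib, , drop = FALSE]
  r <- .rat_mul(a$num[ia], a$den[ia], b$num[ib], b$den[ib])
  .mp_canon(al$vars, expo, r$num, r$den)
}

mp_pow <- function(a, k) {
  stopifnot(k == round(k), k >= 0)
  out <- mp_const(1)
  base <- a
  while (k > 0) {
    if (k %% 2 == 1) out <- mp_mul(out, base)
    k <- k %/% 2
    if (k > 0) base <- mp_mul(base, base)
  }
  out
}

#' @export
Ops.mpoly <- function(e1, e2) {
  if (.Generic == "^") return(mp_pow(.as_mpoly(e1), e2))
  if (missing(e2)) {
    if (.Generic == "-") return(mp_neg(e1))
    if (.Generic == "+") return(e1)
    stop("unsupported unary op for mpoly: ", .Generic)
  }
  a <- .as_mpoly(e1); b <- .as_mpoly(e2)
  switch(.Generic,
         "+" = mp_add(a, b),
         "-" = mp_add(a, mp_neg(b)),
         "*" = mp_mul(a, b),
         "==" = mp_is_zero(mp_add(a, mp_neg(b))),
         "!=" = !mp_is_zero(mp_add(a, mp_neg(b))),
         stop("unsupported op for mpoly: ", .Generic))
}

mp_identical <- function(a, b) mp_is_zero(mp_add(a, mp_neg(b)))

#' Degree of a polynomial in one variable
#' @keywords internal
mp_degree <- function(p, var) {
  j <- match(var, p$vars)
  if (is.na(j) || mp_is_zero(p)) return(0L)
  max(p$expo[, j])
}

#' Coefficients of p as a polynomial in `var`
#'
#' Returns a list of `mpoly`, element k+1 being the coefficient of var^k.
#' @keywords internal
mp_coeflist <- function(p, var) {
  d <- mp_degree(p, var)
  j <- match(var, p$vars)
  out <- vector("list", d + 1L)
  for (k in 0:d) {
    if (is.na(j)) {
      out[[k + 1L]] <- if (k == 0L) p else mp_const(0)
    } else {
      sel <- p$expo[, j] == k
      e <- p$expo[sel, , drop = FALSE]
      e[, j] <- 0L
      out[[k + 1L]] <- .mp_canon(p$vars, e, p$num[sel], p$den[sel])
    }
  }
  out
}

#' Substitute a polynomial for a variable (Horner scheme)
#' @keywords internal
mp_subst <- function(p, var, value) {
  if (!(var %in% p$vars)) return(p)
  cl <- mp_coeflist(p, var)
  out <- cl[[length(cl)]]
  for (k in rev(seq_len(length(cl) - 1L)))
    out <- mp_add(mp_mul(out, value), cl[[k]])
  out
}

#' Partial derivative
#' @keywords internal
mp_deriv <- function(p, var) {
  j <- match(var, p$vars)
  if (is.na(j) || mp_is_zero(p)) return(mp_const(0))
  sel <- p$expo[, j] > 0L
  e <- p$expo[sel, , drop = FALSE]
  num <- p$num[sel] * e[, j]
  den <- p$den[sel]
  e[, j] <- e[, j] - 1L
  .mp_canon(p$vars, e, num, den)
}

#' Numeric evaluation at a named environment of values
#' @keywords internal
mp_eval <- function(p, env) {
  if (mp_is_zero(p)) return(0)
  env <- unlist(env)
  idx <- match(p$vars, names(env))
  if (anyNA(idx)) stop("mp_eval: missing value for variable(s) ",
                       paste(p$vars[is.na(idx)], collapse = ", "))
  vals <- env[idx]  # NaN values propagate; only absent names are an error
  mono <- if (length(p$vars))
    apply(p$expo, 1L, function(e) prod(vals^e)) else rep(1, length(p$num))
  sum(p$num / p$den * mono)
}

# smallest per-variable exponent over all terms, restricted to `vars`
mp_monomial_content <- function(p, vars) {
  vars <- intersect(vars, p$vars)
  if (!length(vars) || mp_is_zero(p)) return(integer(0))
  out <- vapply(vars, function(v) min(p$expo[, match(v, p$vars)]), integer(1))
  out[out > 0L]
}

mp_divide_monomial <- function(p, var, k) {
  j <- match(var, p$vars)
  stopifnot(!is.na(j), all(p$expo[, j] >= k))
  p$expo[, j] <- p$expo[, j] - as.integer(k)
  .mp_canon(p$vars, p$expo, p$num, p$den)
}

#' @export
format.mpoly <- function(x, ...) {
  if (mp_is_zero(x)) return("0")
  terms <- vapply(seq_along(x$num), function(i) {
    co <- if (x$den[i] == 1) sprintf("%g", x$num[i])
          else sprintf("%g/%g", x$num[i], x$den[i])
    mono <- ""
    if (length(x$vars)) {
      e <- x$expo[i, ]
      parts <- character()
      for (j in seq_along(e)) {
        if (e[j] == 1L) parts <- c(parts, x$vars[j])
        else if (e[j] > 1L) parts <- c(parts, sprintf("%s^%d", x$vars[j], e[j]))
      }
      mono <- paste(parts, collapse = "*")
    }
    if (mono == "") co
    else if (co == "1") mono
    else if (co == "-1") paste0("-", mono)
    else paste0(co, "*", mono)
  }, character(1))
  out <- terms[1]
  for (t in terms[-1])
    out <- if (startsWith(t, "-")) paste0(out, " - ", substring(t, 2))
           else paste0(out, " + ", t)
  out
}

#' @export
print.mpoly <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

## ---------------------------------------------------------------- rational

#' Rational functions (quotients of mpoly)
#'
#' Light normalization only (rational content and common monomial factors are
#' cancelled); exactness, not canonical form, is the contract. Zero testing is
#' exact: a ratfun is zero iff its numerator polynomial is identically zero.
#' @keywords internal
rf_new <- function(num, den = mp_const(1)) {
  num <- .as_mpoly(num); den <- .as_mpoly(den)
  if (mp_is_zero(den)) stop("ratfun with zero denominator")
  if (mp_is_zero(num)) return(structure(list(num = mp_const(0), den = mp_const(1)),
                                        class = "ratfun"))
  # cancel common monomial content
  cn <- mp_monomial_content(num, num$vars)
  cd <- mp_monomial_content(den, den$vars)
  for (v in intersect(names(cn), names(cd))) {
    k <- min(cn[[v]], cd[[v]])
    num <- mp_divide_monomial(num, v, k)
    den <- mp_divide_monomial(den, v, k)
  }
  # scale so den has integer coefficients with content 1, leading coeff > 0
  gd <- Reduce(.rgcd, abs(den$num))
  dd <- Reduce(function(a, b) a * b / .rgcd(a, b), den$den)
  sc_num <- gd; sc_den <- dd
  if (sc_num != 1 || sc_den != 1) {
    num <- mp_mul(num, mp_frac(sc_den, sc_num))
    den <- mp_mul(den, mp_frac(sc_den, sc_num))
  }
  if (den$num[1] < 0) {
    num <- mp_neg(num); den <- mp_neg(den)
  }
  structure(list(num = num, den = den), class = "ratfun")
}

.as_ratfun <- function(x) {
  if (inherits(x, "ratfun")) return(x)
  rf_new(.as_mpoly(x))
}

rf_is_zero <- function(r) mp_is_zero(r$num)

rf_eval <- function(r, env) mp_eval(r$num, env) / mp_eval(r$den, env)

#' @export
Ops.ratfun <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") { e1$num <- mp_neg(e1$num); return(e1) }
    if (.Generic == "+") return(e1)
    stop("unsupported unary op for ratfun: ", .Generic)
  }
  if (.Generic == "^") {
    stopifnot(e2 == round(e2))
    if (e2 >= 0) return(rf_new(mp_pow(e1$num, e2), mp_pow(e1$den, e2)))
    return(rf_new(mp_pow(e1$den, -e2), mp_pow(e1$num, -e2)))
  }
  a <- .as_ratfun(e1); b <- .as_ratfun(e2)
  switch(.Generic,
         "+" = rf_new(mp_add(mp_mul(a$num, b$den), mp_mul(b$num, a$den)),
                      mp_mul(a$den, b$den)),
         "-" = rf_new(mp_add(mp_mul(a$num, b$den), mp_neg(mp_mul(b$num, a$den))),
                      mp_mul(a$den, b$den)),
         "*" = rf_new(mp_mul(a$num, b$num), mp_mul(a$den, b$den)),
         "/" = {
           if (mp_is_zero(b$num)) stop("ratfun division by zero")
           rf_new(mp_mul(a$num, b$den), mp_mul(a$den, b$num))
         },
         "==" = rf_is_zero(a - b),
         "!=" = !rf_is_zero(a - b),
         stop("unsupported op for ratfun: ", .Generic))
}

rf_identical <- function(a, b) rf_is_zero(a - b)

#' @export
format.ratfun <- function(x, ...) {
  if (mp_is_zero(x$den - mp_const(1))) return(format(x$num))
  sprintf("(%s) / (%s)", format(x$num), format(x$den))
}

#' @export
print.ratfun <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

## ---------------------------------------------- substitution & reduction

# substitute a ratfun for a variable inside a polynomial (Horner) -> ratfun
.poly_subst_rf <- function(p, var, val) {
  p <- .as_mpoly(p)
  if (!(var %in% p$vars)) return(rf_new(p))
  cl <- mp_coeflist(p, var)
  out <- rf_new(cl[[length(cl)]])
  for (k in rev(seq_len(length(cl) - 1L)))
    out <- out * val + rf_new(cl[[k]])
  out
}

# substitute a ratfun for a variable inside a ratfun
rf_subst <- function(r, var, val) {
  .poly_subst_rf(r$num, var, val) / .poly_subst_rf(r$den, var, val)
}

# pseudo-remainder of p (a polynomial in `var` with mpoly coefficients) by
# the quadratic A*var^2 + B*var + C; the result (degree <= 1 in var) vanishes
# identically iff p vanishes at both roots of the quadratic (A != 0)
mp_prem_quadratic <- function(p, var, A, B, C) {
  while (mp_degree(p, var) >= 2L) {
    d <- mp_degree(p, var)
    cl <- mp_coeflist(p, var)
    lead <- cl[[d + 1L]]
    v <- mp_var(var)
    p <- mp_add(mp_mul(A, p),
                mp_neg(mp_mul(mp_mul(lead, mp_pow(v, d - 2L)),
                              mp_add(mp_mul(A, v^2), mp_add(mp_mul(B, v), C)))))
  }
  p
}
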