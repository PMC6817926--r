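# Exact polynomial/rational algebra engine: ring axioms cross-checked by
# numeric evaluation, substitution, collection, and quadratic-remainder
# reduction.

mp_const <- wavepred:::mp_const
mp_var <- wavepred:::mp_var
mp_frac <- wavepred:::mp_frac
mp_eval <- wavepred:::mp_eval
mp_is_zero <- wavepred:::mp_is_zero
mp_subst <- wavepred:::mp_subst
mp_deriv <- wavepred:::mp_deriv
mp_coeflist <- wavepred:::mp_coeflist
mp_degree <- wavepred:::mp_degree
mp_prem_quadratic <- wavepred:::mp_prem_quadratic
rf_new <- wavepred:::rf_new
rf_is_zero <- wavepred:::rf_is_zero
rf_eval <- wavepred:::rf_eval
rf_subst <- wavepred:::rf_subst

rand_poly <- function(vars, nterm = 4L, maxdeg = 3L) {
  out <- mp_const(sample(-5:5, 1))
  for (i in seq_len(nterm)) {
    term <- mp_const(sample(-5:5, 1))
    for (v in vars) term <- term * mp_var(v)^sample(0:maxdeg, 1)
    out <- out + term
  }
  out
}

test_that("polynomial arithmetic agrees with numeric evaluation", {
  set.seed(11)
  vars <- c("a", "b", "k")
  for (rep in 1:10) {
    p <- rand_poly(vars); q <- rand_poly(vars)
    env <- as.list(stats::setNames(stats::runif(3, -2, 2), vars))
    expect_equal(mp_eval(p + q, env), mp_eval(p, env) + mp_eval(q, env),
                 tolerance = 1e-10)
    expect_equal(mp_eval(p * q, env), mp_eval(p, env) * mp_eval(q, env),
                 tolerance = 1e-10)
    expect_equal(mp_eval(p^3, env), mp_eval(p, env)^3, tolerance = 1e-8)
    # ring identities hold exactly
    expect_true(mp_is_zero((p + q) * (p - q) - (p * p - q * q)))
  }
})

test_that("rational coefficients stay exact", {
  p <- mp_frac(1, 3) * mp_var("a") + mp_frac(1, 6) * mp_var("a")
  expect_true(mp_is_zero(p - mp_frac(1, 2) * mp_var("a")))
  expect_error(mp_var("a") + 0.3, "non-integer")
})

test_that("substitution, derivative and collection are consistent", {
  a <- mp_var("a"); b <- mp_var("b")
  p <- a^2 * b + 2 * a * b^2 - b + 3
  cl <- mp_coeflist(p, "a")
  expect_length(cl, 3L)
  expect_true(mp_is_zero(cl[[1]] + b - 3))
  expect_true(mp_is_zero(cl[[3]] - b))
  # reassemble from coefficients
  re <- mp_const(0)
  for (k in seq_along(cl)) re <- re + cl[[k]] * a^(k - 1)
  expect_true(mp_is_zero(re - p))
  # d/da then substitute a -> b^2, check numerically
  d <- mp_deriv(p, "a")
  s <- mp_subst(d, "a", b * b)
  bv <- 1.37
  expect_equal(mp_eval(s, list(b = bv)), 2 * bv^2 * bv + 2 * bv^2,
               tolerance = 1e-12)
})

test_that("rational functions cancel and test zero exactly", {
  a <- mp_var("a")
  r <- rf_new(a^2 - 1, a + 1) - rf_new(a - 1)
  expect_true(rf_is_zero(r))
  q <- rf_new(mp_const(1), a) + rf_new(mp_const(1), a + 1)
  expect_equal(rf_eval(q, list(a = 2)), 1 / 2 + 1 / 3, tolerance = 1e-14)
  s <- rf_subst(rf_new(a, a + 1), "a", rf_new(mp_const(1), a))
  expect_equal(rf_eval(s, list(a = 4)), (1 / 4) / (1 / 4 + 1),
               tolerance = 1e-14)
})

test_that("quadratic pseudo-remainder vanishes exactly at both roots", {
  set.seed(7)
  v <- mp_var("v"); k <- mp_var("k")
  A <- k + 1; B <- 2 * k; C <- mp_const(-3)
  quad <- A * v^2 + B * v + C
  # any polynomial multiple of the quadratic reduces to zero
  p <- quad * (v^2 - k * v + 2)
  expect_true(mp_is_zero(mp_prem_quadratic(p, "v", A, B, C)))
  # a non-multiple does not
  expect_false(mp_is_zero(mp_prem_quadratic(p + v, "v", A, B, C)))
  # numeric check: remainder of arbitrary p agrees with evaluation at a root
  p2 <- v^3 + k * v - 1
  r <- mp_prem_quadratic(p2, "v", A, B, C)
  kv <- 1.7
  Av <- kv + 1; Bv <- 2 * kv; Cv <- -3
  root <- (-Bv + sqrt(Bv^2 - 4 * Av * Cv)) / (2 * Av)
  # r = A^s * p2 at the root for some power s; both must vanish together or
  # be proportional - compare after normalizing by A^2 (two reduction steps)
  expect_equal(mp_eval(r, list(v = root, k = kv)),
               Av^2 * (root^3 + kv * root - 1), tolerance = 1e-9)
})

test_that("coefficient overflow is detected, not silently lost", {
  expect_error(mp_const(2)^90, "overflow")
})
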