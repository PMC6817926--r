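# The expansion engine: homogeneous balance, coefficient collection against
# the legible anchors of the two printed systems, the numeric evaluation
# oracle (collected system == direct substitution), and exact solving with
# back-substitution proofs.

mp_var <- wavepred:::mp_var
mp_is_zero <- wavepred:::mp_is_zero
mp_eval <- wavepred:::mp_eval
mp_coeflist <- wavepred:::mp_coeflist
rf_is_zero <- wavepred:::rf_is_zero
rf_new <- wavepred:::rf_new
mp_const <- wavepred:::mp_const

test_that("homogeneous balance gives degrees (1, 1) and fails when impossible", {
  expect_identical(homogeneous_balance(aux_rule_gg()), c(n = 1L, m = 1L))
  expect_identical(homogeneous_balance(aux_rule_quartic()), c(n = 1L, m = 1L))
  # synthetic rule whose second derivative gains only one degree
  expect_error(homogeneous_balance(aux_rule_gg(), d2 = 1L), "no balance")
})

test_that("balance degrees are the ones that make the collected system consistent", {
  # at the balanced degrees every equation involves the unknowns, so the
  # system is solvable; the solver finding nontrivial families is the
  # consistency oracle for the balance
  deg <- homogeneous_balance(aux_rule_gg())
  sys <- substitute_and_collect(polynomial_ansatz(deg["n"], deg["m"]),
                                aux_rule_gg())
  fams <- solve_system(sys)
  expect_gt(length(Filter(Negate(function(f) f$trivial), fams)), 0L)
})

test_that("collected (G'/G) system reproduces the printed anchors", {
  sys <- substitute_and_collect(polynomial_ansatz(), aux_rule_gg())
  expect_length(sys$equations, 4L)
  expect_named(sys$equations, c("F^3", "F^2", "F^1", "F^0"))
  # F^3 coefficient: beta1 (alpha1 beta1 (k1 - 1) + 2)
  a1 <- mp_var("alpha1"); b1 <- mp_var("beta1"); k1 <- mp_var("k1")
  ref <- b1 * (a1 * b1 * (k1 - 1) + 2)
  expect_true(mp_is_zero(sys$equations[["F^3"]] - ref))
  # F^0 coefficient: mu (beta1 lambda - c (alpha1 + beta1))
  lam <- mp_var("lambda"); mu <- mp_var("mu"); cc <- mp_var("c")
  ref0 <- mu * (b1 * lam - cc * (a1 + b1))
  expect_true(mp_is_zero(sys$equations[["F^0"]] - ref0))
})

test_that("collected quartic system reproduces the printed anchors", {
  sys <- substitute_and_collect(polynomial_ansatz(), aux_rule_quartic())
  expect_length(sys$equations, 5L)
  # the unrewritable F' term: c (alpha1 + beta1) = 0
  a1 <- mp_var("alpha1"); b1 <- mp_var("beta1"); cc <- mp_var("c")
  expect_true(mp_is_zero(sys$equations[["F'*F^0"]] - cc * (a1 + b1)))
  # the F^0 equation: beta1 h1 / 2 = 0, forcing h1 = 0 either way
  h1 <- mp_var("h1")
  expect_true(mp_is_zero(sys$equations[["F^0"]] * 2 - b1 * h1))
})

test_that("collected system equals direct substitution numerically (oracle)", {
  set.seed(99)
  for (kind in c("gg", "quartic")) {
    rule <- if (kind == "gg") aux_rule_gg() else aux_rule_quartic()
    sys <- substitute_and_collect(polynomial_ansatz(), rule)
    for (rep in 1:20) {
      env <- list(alpha1 = stats::runif(1, -2, 2), beta1 = stats::runif(1, 0.2, 2),
                  c = stats::runif(1, -2, 2), k1 = stats::runif(1, 1.2, 4),
                  k2 = stats::runif(1, 0.2, 2), F = stats::runif(1, -1.5, 1.5),
                  lambda = stats::runif(1, -2, 2), mu = stats::runif(1, -1, 1),
                  h0 = 0, h1 = stats::runif(1, -1, 1), h2 = stats::runif(1, 0.5, 2),
                  h3 = stats::runif(1, -1, 1), h4 = stats::runif(1, 0.1, 1))
      Fv <- env$F
      if (kind == "gg") {
        Fp <- -Fv^2 - env$lambda * Fv - env$mu
        Fpp <- (2 * Fv + env$lambda) * (Fv^2 + env$lambda * Fv + env$mu)
      } else {
        Q <- env$h0 + env$h1 * Fv + env$h2 * Fv^2 + env$h3 * Fv^3 + env$h4 * Fv^4
        if (Q < 0) next
        Fp <- sqrt(Q)
        Fpp <- (env$h1 + 2 * env$h2 * Fv + 3 * env$h3 * Fv^2 +
                  4 * env$h4 * Fv^3) / 2
      }
      # direct substitution of the ansatz into the combined ODE
      u <- env$alpha1 * Fv; v <- env$beta1 * Fv
      du <- env$alpha1 * Fp; dv <- env$beta1 * Fp; d2v <- env$beta1 * Fpp
      direct <- env$c * (du + dv) + d2v - env$k1 * env$k2 * v - env$k1 * v^2 +
        u - u^2 - (1 - env$k1) * u * v - (1 - env$k1) * u * v^2
      # reassembled from the collected coefficients
      collected <- 0
      for (nm in names(sys$equations)) {
        co <- mp_eval(sys$equations[[nm]], env)
        pw <- as.integer(sub(".*F\\^", "", nm))
        collected <- collected + co * Fv^pw * (if (startsWith(nm, "F'")) Fp else 1)
      }
      expect_equal(collected, direct, tolerance = 1e-9)
    }
  }
})

test_that("non-polynomial leftovers raise an internal-consistency error", {
  # a synthetic rule whose rewrite cannot eliminate F''
  bad <- aux_rule_quartic()
  bad$fp2 <- mp_var("Fpp") * mp_var("F")^2
  expect_error(substitute_and_collect(polynomial_ansatz(), bad),
               "internal-consistency")
})

test_that("(G'/G) solving yields Case I closed forms and exact back-substitution", {
  sys <- substitute_and_collect(polynomial_ansatz(), aux_rule_gg())
  fams <- Filter(Negate(function(f) f$trivial), solve_system(sys))
  expect_length(fams, 3L)  # Case I + two Case II sign branches
  for (f in fams) expect_true(all(back_substitute(f)))
  caseI <- Filter(function(f) is.null(f$minpoly), fams)
  expect_length(caseI, 1L)
  res <- wavepred::family_resolve(caseI[[1]])
  b1 <- mp_var("beta1"); k1 <- mp_var("k1"); k2 <- mp_var("k2")
  # alpha1 = -2/(beta1 (k1-1)), mu = k1 k2/2 + 1/(beta1^2 (k1-1)),
  # lambda = 1/beta1 + k1 beta1/2 + 2/(beta1^3 (k1-1)^2),
  # c = lambda beta1^2 (k1-1) / (beta1^2 (k1-1) - 2)
  expect_true(rf_is_zero(res$alpha1 - rf_new(mp_const(-2), b1 * (k1 - 1))))
  mu_ref <- rf_new(k1 * k2, mp_const(2)) + rf_new(mp_const(1), b1^2 * (k1 - 1))
  expect_true(rf_is_zero(res$mu - mu_ref))
  lam_ref <- rf_new(mp_const(1), b1) + rf_new(k1 * b1, mp_const(2)) +
    rf_new(mp_const(2), b1^3 * (k1 - 1)^2)
  expect_true(rf_is_zero(res$lambda - lam_ref))
  c_ref <- lam_ref * rf_new(b1^2 * (k1 - 1)) /
    rf_new(b1^2 * (k1 - 1) - 2)
  expect_true(rf_is_zero(res$c - c_ref))
  # the F^0 relation c (alpha1 + beta1) = lambda beta1 holds symbolically
  expect_true(rf_is_zero(res$c * (res$alpha1 + rf_new(b1)) -
                           res$lambda * rf_new(b1)))
})

test_that("quartic solving yields the printed coefficient set exactly", {
  sys <- substitute_and_collect(polynomial_ansatz(), aux_rule_quartic())
  fams <- Filter(Negate(function(f) f$trivial), solve_system(sys))
  for (f in fams) expect_true(all(back_substitute(f)))
  primary <- Filter(function(f) "c" %in% f$free, fams)
  expect_length(primary, 1L)
  res <- wavepred::family_resolve(primary[[1]])
  b1 <- mp_var("beta1"); k1 <- mp_var("k1"); k2 <- mp_var("k2")
  expect_true(rf_is_zero(res$alpha1 + rf_new(b1)))
  expect_true(rf_is_zero(res$h1))
  expect_true(rf_is_zero(res$h2 - rf_new(1 + k1 * k2)))
  expect_true(rf_is_zero(res$h3 - rf_new(4 * (k1 * b1), mp_const(3))))
  expect_true(rf_is_zero(res$h4 - rf_new((k1 - 1) * b1^2, mp_const(2))))
})

test_that("branch enumeration is deterministic", {
  sys <- substitute_and_collect(polynomial_ansatz(), aux_rule_gg())
  f1 <- solve_system(sys)
  f2 <- solve_system(sys)
  expect_identical(lapply(f1, function(f) f$path),
                   lapply(f2, function(f) f$path))
})
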