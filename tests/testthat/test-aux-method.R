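# Generalized auxiliary-equation backend: the solution catalog against its
# defining ODE, the exact coefficient derivation, and the sech^2 pulse.

test_that("catalog special cases reduce to sech and 1/xi", {
  xi <- seq(0.4, 3, 0.31)
  h <- aux_coefficients(h2 = 1, h4 = -1)
  expect_equal(as.numeric(aux_F(xi, h, "II.1")), 1 / cosh(xi),
               tolerance = 1e-12)
  h <- aux_coefficients(h2 = 0, h4 = 1)
  expect_equal(as.numeric(aux_F(xi, h, "II.3")), 1 / xi, tolerance = 1e-12)
})

test_that("every catalog branch satisfies its defining quartic ODE", {
  # pole-aware windows per branch; relative residual of
  # (F')^2 - (h2 F^2 + h3 F^3 + h4 F^4)
  cases <- list(
    list(branch = "I.1", h = aux_coefficients(h2 = 1.3, h3 = 2.6, h4 = 0.5),
         xi = seq(0.8, 2.5, 0.13)),
    list(branch = "I.2", h = aux_coefficients(h2 = 1.1, h3 = 0.7, h4 = 1.5),
         xi = seq(0.5, 2, 0.11)),
    list(branch = "I.3", h = aux_coefficients(h2 = 1.7, h3 = 1.1,
                                              h4 = 1.1^2 / (4 * 1.7)),
         xi = seq(-2, 2, 0.21)),
    list(branch = "I.4", h = aux_coefficients(h2 = 2.5, h3 = 4, h4 = 1),
         xi = seq(-3, 3, 0.19)),
    list(branch = "I.5", h = aux_coefficients(h2 = -1.5, h3 = 0.8, h4 = 1.2),
         xi = seq(0.6, 1.8, 0.09)),
    list(branch = "II.1", h = aux_coefficients(h2 = 1.4, h4 = -0.9),
         xi = seq(-2, 2, 0.17)),
    list(branch = "II.2", h = aux_coefficients(h2 = -1.4, h4 = 0.9),
         xi = seq(0.1, 1.1, 0.07)),
    list(branch = "II.3", h = aux_coefficients(h2 = 0, h4 = 1.3),
         xi = seq(0.5, 2.5, 0.13)),
    list(branch = "III.1", h = aux_coefficients(h2 = 1.2, h3 = 0.9),
         xi = seq(-2, 2, 0.17)),
    list(branch = "III.2", h = aux_coefficients(h2 = -1.2, h3 = 0.9),
         xi = seq(0.1, 2.2, 0.13)),
    list(branch = "III.3", h = aux_coefficients(h2 = 0, h3 = 1.7),
         xi = seq(0.6, 2.5, 0.13)))
  for (cs in cases) {
    h <- cs$h
    f <- function(x) as.numeric(aux_F(x, h, cs$branch))
    Fv <- f(cs$xi)
    ok <- is.finite(Fv)
    expect_gt(sum(ok), 5)
    fc <- function(x) aux_F(x, h, cs$branch)
    d <- cs_deriv(fc, cs$xi[ok])
    Q <- h$h2 * Fv[ok]^2 + h$h3 * Fv[ok]^3 + h$h4 * Fv[ok]^4
    rel <- (d^2 - Q) / pmax(1, abs(Fv[ok]))^4
    expect_lt(max(abs(rel)), 1e-9)
  }
})

test_that("branch preconditions are enforced by name", {
  expect_error(aux_F(1, aux_coefficients(h2 = -1, h4 = -1), "I.4"), "h2 > 0")
  expect_error(aux_F(1, aux_coefficients(h2 = 1, h4 = -1), "I.4"), "h4 > 0")
  expect_error(aux_F(1, aux_coefficients(h2 = 1, h3 = 1, h4 = 1), "II.1"),
               "h3 = 0")
  expect_error(aux_F(1, aux_coefficients(h0 = 1, h2 = 1, h4 = -1), "II.1"),
               "h0 = h1 = 0")
})

test_that("coefficient derivation matches the printed closed forms", {
  sol <- derive_aux_coefficients(p_pulse(), beta1 = 1)
  expect_equal(sol$alpha1, -1)
  expect_equal(sol$h$h1, 0)
  expect_equal(sol$h$h2, 2.5)   # 1 + k1 k2 = 1 + 1.5
  expect_equal(sol$h$h3, 4)     # 4 k1 beta1 / 3
  expect_equal(sol$h$h4, 1)     # (k1 - 1) beta1^2 / 2
  # the acceptance identities of the collected system
  expect_equal(sol$h$h2 - sol$k1 * sol$k2, 1)
  expect_equal(3 * sol$h$h3, 4 * sol$k1 * sol$beta1)
  expect_equal(2 * sol$h$h4, (sol$k1 - 1) * sol$beta1^2)
  # alpha1 + beta1 = 0 for any admissible parameters
  set.seed(8)
  for (i in 1:10) {
    p <- scaled_params(stats::runif(1, 1.1, 5), stats::runif(1, 0.2, 2))
    b1 <- stats::runif(1, 0.3, 2)
    s <- derive_aux_coefficients(p, b1)
    expect_equal(s$alpha1 + b1, 0, tolerance = 1e-12)
  }
})

test_that("k1 < 1 coefficients are refused by the pulse evaluator", {
  expect_warning(sol <- derive_aux_coefficients(scaled_params(0.5, 1), 1),
                 "complex")
  expect_error(build_aux_solution(sol), "k1 > 1")
})

test_that("the pulse solution satisfies V = -U, decays, and kills the combined ODE", {
  sol <- derive_aux_coefficients(p_pulse(), beta1 = 1)
  tw <- build_aux_solution(sol, c = 1)
  x <- seq(-4, 4, length.out = 81)
  for (tt in c(-2, 0, 1.3))
    expect_identical(max(abs(tw$U(x, tt) + tw$V(x, tt))), 0)
  # denominator provably bounded away from zero at these parameters
  expect_false(tw$metadata$pole_possible)
  rng <- tw$metadata$denominator_range
  expect_equal(rng, c(-2 * sqrt(2.5) - 4, 2 * sqrt(2.5) - 4))
  # pulse decays to the extinction equilibrium
  expect_lt(max(abs(tw$U(c(-30, 30)))), 1e-10)
  kin <- kinetics(0, 0, tw$params)
  expect_identical(c(kin$du, kin$dv), c(0, 0))
  # combined-ODE residual vanishes by construction
  fr <- wave_frame(c = 1, xmin = -4, xmax = 4, n = 401)
  expect_lt(max(abs(residual_combined(tw$profile_pair, fr, tw$params))), 1e-8)
  # evaluator coincides with alpha1 * F of catalog branch I.4
  xi <- seq(-3, 3, 0.21)
  expect_equal(as.numeric(tw$U(xi)),
               sol$alpha1 * as.numeric(aux_F(xi, sol$h, "I.4")),
               tolerance = 1e-12)
})
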