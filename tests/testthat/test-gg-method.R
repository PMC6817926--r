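# (G'/G) backend: generator-function branches against their defining ODE,
# case derivation, the caption slice, and the built kink solutions.

test_that("gg_F reduces to tanh / constant in the documented special cases", {
  xi <- seq(-3, 3, 0.37)
  expect_equal(as.numeric(gg_F(xi, lambda = 0, mu = -1, A1 = 0, A2 = 1)),
               tanh(xi), tolerance = 1e-12)
  # Delta = 0, A2 = 0: rational branch collapses to -lambda/2
  expect_equal(as.numeric(gg_F(xi, lambda = 2, mu = 1, A1 = 1, A2 = 0)),
               rep(-1, length(xi)), tolerance = 1e-12)
  expect_error(gg_F(1, 0, -1, A1 = 0, A2 = 0), "invalid constants")
})

test_that("every gg_F branch satisfies F' = -F^2 - lambda F - mu", {
  set.seed(31)
  for (rep in 1:12) {
    lam <- stats::runif(1, -2, 2)
    # force each discriminant regime in turn
    mu <- switch(rep %% 3 + 1,
                 lam^2 / 4 - stats::runif(1, 0.5, 2),   # Delta > 0
                 lam^2 / 4 + stats::runif(1, 0.5, 2),   # Delta < 0
                 lam^2 / 4)                             # Delta = 0
    A1 <- stats::runif(1, -1, 1); A2 <- stats::runif(1, 0.5, 1.5)
    f <- function(x) as.numeric(gg_F(x, lam, mu, A1, A2))
    xi <- seq(-1.5, 1.5, 0.23)
    Fv <- f(xi)
    ok <- is.finite(Fv) & abs(Fv) < 20  # keep clear of poles
    # exclude points whose stencil neighbourhood touches a pole
    for (j in which(ok)) {
      if (any(!is.finite(f(xi[j] + c(-2, -1, 1, 2) * 1e-3)))) ok[j] <- FALSE
    }
    expect_gt(sum(ok), 3)
    fc <- function(x) gg_F(x, lam, mu, A1, A2)
    res <- cs_deriv(fc, xi[ok]) + Fv[ok]^2 + lam * Fv[ok] + mu
    expect_lt(max(abs(res)), 1e-9)
  }
})

test_that("case derivation satisfies the printed relations at sample parameters", {
  p <- scaled_params(3, 0.5)
  cs <- derive_gg_cases(p, beta1 = 1.2)
  for (sol in cs) {
    # alpha1 beta1 (k1 - 1) + 2 = 0 in both cases
    expect_equal(sol$alpha1 * sol$beta1 * (p$k1 - 1) + 2, 0, tolerance = 1e-12)
  }
  expect_identical(cs$caseII$mu, 0)
  expect_true(abs(cs$caseI$mu) > 0)
  # Case I wave speed obeys c (alpha1 + beta1) = lambda beta1
  s <- cs$caseI
  expect_equal(s$c * (s$alpha1 + s$beta1), s$lambda * s$beta1,
               tolerance = 1e-10)
})

test_that("the caption slice forces the published parameter relations", {
  # k1 = 2/beta1^2 + 1 collapses Case II to alpha1 = -beta1 with c free
  sol <- gg_case2_slice(0.5)
  expect_equal(sol$k1, 9)
  expect_equal(sol$alpha1, -0.5, tolerance = 1e-12)
  expect_equal(sol$lambda, 3, tolerance = 1e-12)
  expect_equal(sol$k2, 8 / 9, tolerance = 1e-12)
  expect_identical(sol$mu, 0)
  expect_true(sol$c_free)
  # and the same relations are proven symbolically for general beta1
  ss <- gg_case2_slice_symbolic()
  expect_true(ss$id_alpha1)
  expect_true(ss$id_lambda)
  expect_true(ss$id_k2)
})

test_that("Case I flags its pole condition beta1^2 (k1 - 1) = 2", {
  cs <- derive_gg_cases(p_kink(), beta1 = 0.5)  # 0.25 * 8 = 2: on the pole
  expect_false(cs$caseI$validity_ok)
  expect_true(is.na(cs$caseI$c))
})

test_that("built kink solutions share F, sit on plateaus, and kill the combined ODE", {
  sol <- gg_case2_slice(0.5)
  tw <- build_gg_solution(sol, A1 = 0, A2 = 1, c = 1)
  xi <- seq(-4, 4, length.out = 201)
  # V/U is the constant beta1/alpha1 wherever defined
  expect_equal(as.numeric(tw$V(xi)) / as.numeric(tw$U(xi)),
               rep(sol$beta1 / sol$alpha1, length(xi)),
               tolerance = 1e-12)
  # plateau values are the roots of F^2 + lambda F + mu = 0
  pl <- sort(tw$metadata$plateaus_F)
  expect_equal(pl, sort(Re(polyroot(c(sol$mu, sol$lambda, 1)))),
               tolerance = 1e-12)
  expect_equal(as.numeric(tw$profile(c(-50, 50))), pl, tolerance = 1e-10)
  # the kink profile is monotone between its plateaus
  Fv <- as.numeric(tw$profile(xi))
  expect_true(all(diff(Fv) > 0) || all(diff(Fv) < 0))
  # combined-ODE residual vanishes by construction
  fr <- wave_frame(c = 1, xmin = -4, xmax = 4, n = 401)
  r <- residual_combined(tw$profile_pair, fr, tw$params)
  expect_lt(max(abs(r)), 1e-8)
})

test_that("coth-type constants put a pole at the origin and are reported", {
  sol <- gg_case2_slice(0.5)
  tw <- build_gg_solution(sol, A1 = 1, A2 = 0, c = 1)
  expect_equal(tw$metadata$pole_xi, 0)
  expect_true(is.nan(tw$U(0)))
  # the bounded default has no pole
  tw2 <- build_gg_solution(sol, A1 = 0, A2 = 1, c = 1)
  expect_null(tw2$metadata$pole_xi)
})

test_that("a free wave speed must be supplied and a fixed one cannot be overridden", {
  sol <- gg_case2_slice(0.5)
  expect_error(build_gg_solution(sol), "supply c")
  p <- scaled_params(3, 0.5)
  caseI <- derive_gg_cases(p, beta1 = 1.2)$caseI
  expect_error(build_gg_solution(caseI, c = caseI$c + 1), "determined")
  tw <- build_gg_solution(caseI)
  expect_identical(tw$c, caseI$c)
})
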