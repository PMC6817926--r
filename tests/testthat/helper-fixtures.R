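# Shared fixtures: reference parameter sets and generators for random smooth
# profile pairs used by the residual-identity property tests.

# pulse-solution reference parameters (figure-3 study conditions)
p_pulse <- function() wavepred::scaled_params(k1 = 3, k2 = 0.5)

# kink-slice reference parameters (figure-2 study conditions, beta1 = 0.5)
p_kink <- function() wavepred::scaled_params(k1 = 9, k2 = 8 / 9)

# random smooth profile pair with analytic derivatives (sums of sin/cos)
random_profile_pair <- function() {
  a <- stats::runif(3, -1, 1)
  b <- stats::runif(3, -1, 1)
  w <- stats::runif(3, 0.3, 1.5)
  u <- function(xi) a[1] * sin(w[1] * xi) + a[2] * cos(w[2] * xi) + a[3]
  du <- function(xi) a[1] * w[1] * cos(w[1] * xi) - a[2] * w[2] * sin(w[2] * xi)
  d2u <- function(xi) -a[1] * w[1]^2 * sin(w[1] * xi) -
    a[2] * w[2]^2 * cos(w[2] * xi)
  v <- function(xi) b[1] * sin(w[3] * xi) + b[2] * cos(w[1] * xi) + b[3]
  dv <- function(xi) b[1] * w[3] * cos(w[3] * xi) - b[2] * w[1] * sin(w[1] * xi)
  d2v <- function(xi) -b[1] * w[3]^2 * sin(w[3] * xi) -
    b[2] * w[1]^2 * cos(w[1] * xi)
  wavepred::profile_pair(u, v, du = du, dv = dv, d2u = d2u, d2v = d2v)
}

# high-order numeric derivative (Richardson 5-point), for convergence checks
num_deriv <- function(f, x, h = 1e-3) {
  (f(x - 2 * h) - 8 * f(x - h) + 8 * f(x + h) - f(x + 2 * h)) / (12 * h)
}

# complex-step first derivative: machine precision for analytic generators;
# f must propagate complex input (no as.numeric inside)
cs_deriv <- function(f, x, h = 1e-100) {
  as.numeric(Im(f(x + 1i * h))) / h
}
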