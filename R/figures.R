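# Parameter studies behind the three reference figures: the sign of the
# Case-I discriminant across k1 (figure 1), the Case II kink surfaces on the
# caption slice (figure 2), and the auxiliary-method sech^2 pulse (figure 3).
# CSV is the canonical output; plotting is optional and never load-bearing.

#' Case-I discriminant scan across k1
#'
#' Evaluates `lambda^2 - 4 mu` of the (G'/G) Case I family over a k1 range
#' with `beta1` and `k2` fixed, recording the sign. The discriminant
#' diverges like `1/(k1 - 1)^2` approaching the degenerate point `k1 = 1`,
#' and is positive on both sides of it, which is why the solutions stay in
#' the hyperbolic (kink) regime.
#'
#' @param beta1,k2 fixed parameters.
#' @param k1_range range of k1 values to scan (must exclude 1).
#' @param n number of sample points.
#' @return A data frame with columns `k1`, `discriminant`, `sign`, `panel`
#'   (`"0<k1<1"` or `"k1>1"`).
#' @export
fig1_scan <- function(beta1 = 0.5, k2 = 0.5,
                      k1_range = c(0.05, 10), n = 120L) {
  stopifnot(length(k1_range) == 2L, k1_range[1] > 0)
  k1s <- seq(k1_range[1], k1_range[2], length.out = n)
  k1s <- k1s[abs(k1s - 1) > 1e-6]
  fam <- .gg_families()$caseI
  disc <- vapply(k1s, function(k1) {
    v <- family_eval(fam, list(beta1 = beta1, k1 = k1, k2 = k2))
    unname(v["lambda"]^2 - 4 * v["mu"])
  }, numeric(1))
  data.frame(k1 = k1s, discriminant = disc, sign = sign(disc),
             panel = ifelse(k1s < 1, "0<k1<1", "k1>1"))
}

.figure_grid <- function(xmin = -4, xmax = 4, tmin = -4, tmax = 4,
                         nx = 81L, nt = 81L) {
  list(x = seq(xmin, xmax, length.out = nx),
       t = seq(tmin, tmax, length.out = nt))
}

.surface_df <- function(tw, grid) {
  df <- expand.grid(x = grid$x, t = grid$t, KEEP.OUT.ATTRS = FALSE)
  df$U <- as.numeric(tw$U(df$x, df$t))
  df$V <- as.numeric(tw$V(df$x, df$t))
  df
}

#' Case II kink surfaces on the caption slice
#'
#' Builds the (G'/G) Case II solution on the slice `k1 = 2/beta1^2 + 1`
#' (where `mu = 0`, `alpha1 = -beta1`, `lambda = 2(beta1^2 + 2)/(3 beta1)`,
#' `k2 = (4 beta1^4 + 7 beta1^2 + 16)/(9 beta1^2 + 18)`) and samples U and V
#' over a rectangular (x, t) window. The wave speed is free on this slice
#' and defaults to 1.
#'
#' @param beta1 predator amplitude (default 0.5).
#' @param c wave speed (free; default 1).
#' @param A1,A2 generator integration constants (default bounded kink).
#' @param grid a list with `x` and `t` vectors (default x, t in [-4, 4]).
#' @return A data frame `(x, t, U, V)` with the resolved parameter set and
#'   kink plateau values attached as attribute `"metadata"`.
#' @export
fig2_profiles <- function(beta1 = 0.5, c = 1, A1 = 0, A2 = 1,
                          grid = .figure_grid()) {
  sol <- gg_case2_slice(beta1)
  tw <- build_gg_solution(sol, A1 = A1, A2 = A2, c = c)
  df <- .surface_df(tw, grid)
  attr(df, "metadata") <- list(
    beta1 = beta1, k1 = sol$k1, k2 = sol$k2, lambda = sol$lambda,
    mu = sol$mu, alpha1 = sol$alpha1, c = c,
    c_note = "free on this slice; caption leaves it unstated",
    plateaus_U = tw$metadata$plateaus_U,
    plateaus_V = tw$metadata$plateaus_V)
  df
}

#' Auxiliary-method pulse surfaces
#'
#' Evaluates the sech^2 solitary-pulse solution at the reference parameters
#' `k2 = 0.5`, `beta1 = 1`, `c = 1`, `k1 = 3` over x, t in [-4, 4]. At these
#' parameters the denominator `2 sqrt(h2 h4) tanh - h3` is bounded away from
#' zero, the pulse decays to the extinction equilibrium (0, 0), and
#' `V = -U` holds to machine precision (recorded in the metadata).
#'
#' @param k1,k2,beta1,c model parameters (caption defaults).
#' @param grid a list with `x` and `t` vectors.
#' @return A data frame `(x, t, U, V)` with attribute `"metadata"`.
#' @export
fig3_profiles <- function(k1 = 3, k2 = 0.5, beta1 = 1, c = 1,
                          grid = .figure_grid()) {
  sol <- derive_aux_coefficients(scaled_params(k1, k2), beta1)
  tw <- build_aux_solution(sol, c = c)
  df <- .surface_df(tw, grid)
  attr(df, "metadata") <- list(
    k1 = k1, k2 = k2, beta1 = beta1, c = c,
    h = unclass(sol$h)[c("h0", "h1", "h2", "h3", "h4")],
    max_U_plus_V = max(abs(df$U + df$V)),
    denominator_range = tw$metadata$denominator_range)
  df
}

#' Write a figure data frame to CSV
#'
#' Deterministic output: identical inputs produce byte-identical files.
#'
#' @param df data frame from a `fig*_` function.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_figure_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a (x, t, U, V) surface data frame
#'
#' Optional convenience (requires ggplot2): filled-raster panels of U and V.
#'
#' @param df data frame from [fig2_profiles()] or [fig3_profiles()].
#' @return A ggplot object.
#' @export
plot_profile_surface <- function(df) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is not available; use the CSV output instead")
  long <- rbind(
    data.frame(x = df$x, t = df$t, value = df$U, field = "U (prey)"),
    data.frame(x = df$x, t = df$t, value = df$V, field = "V (predator)"))
  ggplot2::ggplot(long, ggplot2::aes(x = x, y = t, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~field) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x", y = "t", fill = "density")
}
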