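# Theoretical scattering from coordinates (exact Debye sum; golden-vector
# quadrature) and the standard one-dimensional analyses: Guinier fit,
# coordinate-space pair-distance distribution, Kratky transform, reduced
# chi-square against an experimental profile. All profiles are in vacuo
# (no excluded-volume or hydration-layer term); this is the main fidelity
# gap versus real solution data and is documented in the methods vignette.

ELECTRON_COUNT <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

#' Form-factor table
#'
#' Two modes. `"point"`: every atom scatters with a constant factor
#' (default 1), appropriate for pseudo-atom toys. `"element"`: f(Q) equals
#' the element electron count, the small-angle limit of the atomic form
#' factor (flat to well under 1% for Q <= 0.3 A^-1, the working range
#' here); f(0) is exactly the electron count.
#'
#' @param mode `"point"` or `"element"`
#' @param value constant factor for point mode
#' @return object of class `form_factor_table`
#' @export
form_factor_table <- function(mode = c("point", "element"), value = 1) {
  mode <- match.arg(mode)
  if (mode == "point" && value <= 0) stopf("point form factor must be > 0")
  structure(list(mode = mode, value = value), class = "form_factor_table")
}

# nq x natom matrix of per-atom factors on the q grid
ff_matrix <- function(s, q, ff) {
  n <- n_atoms(s)
  if (ff$mode == "point") {
    matrix(ff$value, length(q), n)
  } else {
    z <- ELECTRON_COUNT[s$atoms$element]
    if (anyNA(z)) {
      stopf("no electron count for element(s): %s",
            paste(unique(s$atoms$element[is.na(z)]), collapse = ", "))
    }
    matrix(rep(z, each = length(q)), length(q), n)
  }
}

ff_zero <- function(s, ff) ff_matrix(s, 0, ff)[1, ]

#' Exact Debye-sum scattering profile
#'
#' I(Q) = sum_ij f_i(Q) f_j(Q) sin(Q r_ij)/(Q r_ij), with sinc(0) = 1, so
#' I(0) = (sum_i f_i(0))^2. In vacuo; the reference evaluator against which
#' the quadrature method is checked.
#'
#' @param s a `saxs_structure` with >= 1 atom
#' @param qgrid momentum-transfer grid, Angstrom^-1, all >= 0
#' @param ff a `form_factor_table`
#' @return a `saxs_profile` (no sigma)
#' @export
debye_profile <- function(s, qgrid, ff = form_factor_table("point")) {
  qgrid <- as.numeric(qgrid)
  if (!length(qgrid)) stopf("empty q grid")
  if (any(qgrid < 0)) stopf("negative Q is not valid")
  if (n_atoms(s) < 1) stopf("structure has no atoms")
  ord <- order(qgrid)
  I <- .debye_sum(coords(s), ff_matrix(s, qgrid[ord], ff), qgrid[ord])
  saxs_profile(qgrid[ord], I)
}

# Quasi-uniform directions on the sphere: spherical Fibonacci (golden-angle)
# lattice.
golden_directions <- function(m) {
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Golden-vector scattering profile
#'
#' Orientational average by quadrature over M quasi-uniform directions from
#' a spherical Fibonacci lattice:
#' I(Q) = (1/M) sum_m |sum_j f_j(Q) exp(i Q v_m . r_j)|^2.
#' Agrees with the exact Debye sum to within quadrature error that shrinks
#' as M grows (about 1% at M ~ 300 for toy structures over the working
#' Q range).
#'
#' @param s a `saxs_structure`
#' @param qgrid momentum-transfer grid, Angstrom^-1
#' @param ff a `form_factor_table`
#' @param n_vectors number of quadrature directions M (>= 1)
#' @return a `saxs_profile`
#' @export
golden_vector_profile <- function(s, qgrid, ff = form_factor_table("point"),
                                  n_vectors = 299) {
  qgrid <- as.numeric(qgrid)
  if (any(qgrid < 0)) stopf("negative Q is not valid")
  if (n_vectors < 1) stopf("n_vectors must be >= 1")
  dirs <- golden_directions(n_vectors)
  xyz <- coords(s)
  fm <- ff_matrix(s, qgrid, ff)
  proj <- dirs %*% t(xyz)  # M x N direction projections
  I <- numeric(length(qgrid))
  for (k in seq_along(qgrid)) {
    ph <- qgrid[k] * proj
    f <- fm[k, ]
    re <- cos(ph) %*% f
    im <- sin(ph) %*% f
    I[k] <- mean(re^2 + im^2)
  }
  ord <- order(qgrid)
  saxs_profile(qgrid[ord], I[ord])
}

#' Guinier analysis
#'
#' Linear fit of ln I versus Q^2 on the largest low-Q window satisfying
#' Qmax * Rg <= `qmax_rg_limit`, found self-consistently (fit, shrink the
#' window to honour the limit with the fitted Rg, repeat to a fixed point).
#' Sigma-weighted when uncertainties are present, unweighted otherwise.
#' Rg = sqrt(-3 * slope), I0 = exp(intercept).
#'
#' @param p a `saxs_profile`
#' @param qmax_rg_limit dimensionless window bound (default 1.3, the
#'   conventional validity limit of the Guinier regime)
#' @param min_points smallest admissible window (>= 3)
#' @return object of class `guinier_fit`: `rg`, `i0`, `window` (Qmin,
#'   Qmax), `qmin_rg`, `qmax_rg`, `r2`, `n_points`
#' @export
guinier_fit <- function(p, qmax_rg_limit = 1.3, min_points = 3) {
  # contiguous positive-intensity run starting at the lowest positive point
  runs <- rle(p$intensity > 0)
  first_true <- which(runs$values)[1]
  if (is.na(first_true)) stopf("no positive intensities for a Guinier fit")
  run_start <- if (first_true == 1) 1L else sum(runs$lengths[1:(first_true - 1)]) + 1L
  usable <- run_start:(run_start + runs$lengths[first_true] - 1L)
  if (length(usable) < min_points) {
    stopf("fewer than %d usable low-Q points for a Guinier fit", min_points)
  }
  q2 <- p$q[usable]^2
  li <- log(p$intensity[usable])
  w <- if (!is.null(p$sigma)) {
    (p$intensity[usable] / p$sigma[usable])^2  # delta-method ln-space weights
  } else rep(1, length(usable))

  k <- length(usable)
  seen <- integer(0)
  for (iter in 1:100) {
    fit <- lm(li[1:k] ~ q2[1:k], weights = w[1:k])
    slope <- coef(fit)[[2]]
    if (!is.finite(slope) || slope >= 0) {
      stopf("Guinier fit failed: non-negative slope (no Guinier regime)")
    }
    rg <- sqrt(-3 * slope)
    k_new <- max(min_points, sum(p$q[usable] * rg <= qmax_rg_limit))
    if (k_new == k || k_new %in% seen) break
    seen <- c(seen, k)
    k <- k_new
  }
  ss_res <- sum(w[1:k] * (li[1:k] - fitted(fit))^2)
  mu <- sum(w[1:k] * li[1:k]) / sum(w[1:k])
  ss_tot <- sum(w[1:k] * (li[1:k] - mu)^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  structure(list(rg = rg, i0 = exp(coef(fit)[[1]]),
                 window = c(p$q[usable][1], p$q[usable][k]),
                 qmin_rg = p$q[usable][1] * rg,
                 qmax_rg = p$q[usable][k] * rg,
                 r2 = r2, n_points = k),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(paste0("Guinier fit: Rg = %.2f A, I(0) = %.4g\n",
                     "  window Q in [%.4g, %.4g] (QminRg %.2f, QmaxRg %.2f),",
                     " %d points, r^2 = %.3f\n"),
              x$rg, x$i0, x$window[1], x$window[2], x$qmin_rg, x$qmax_rg,
              x$n_points, x$r2))
  invisible(x)
}

#' Coordinate-space pair-distance distribution
#'
#' Weighted histogram of all pairwise atom distances (weights
#' f_i(0) f_j(0)), normalized to unit area. Computed from coordinates, not
#' by indirect Fourier transform of data.
#'
#' @param s a `saxs_structure` with >= 2 atoms
#' @param bin_width histogram bin width, Angstrom
#' @param ff a `form_factor_table` supplying the zero-angle weights
#' @return object of class `pair_distribution`: `r` (bin centres), `p`
#'   (density, unit area), `dmax`
#' @export
pair_distribution <- function(s, bin_width = 1,
                              ff = form_factor_table("point")) {
  if (n_atoms(s) < 2) stopf("pair distribution needs >= 2 atoms")
  if (bin_width <= 0) stopf("bin_width must be > 0")
  h <- .pair_hist(coords(s), ff_zero(s, ff), bin_width)
  counts <- h$counts
  r <- (seq_along(counts) - 0.5) * bin_width
  area <- sum(counts) * bin_width
  structure(list(r = r, p = counts / area, dmax = h$dmax,
                 bin_width = bin_width),
            class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("<pair_distribution> %d bins of %.2f A, Dmax = %.2f A\n",
              length(x$r), x$bin_width, x$dmax))
  invisible(x)
}

#' Rg from the second moment of a pair distribution
#'
#' Rg^2 = integral(r^2 p(r) dr) / 2; agrees with the coordinate-space Rg to
#' within binning error.
#'
#' @param pd a `pair_distribution`
#' @return Rg in Angstrom
#' @export
pr_rg <- function(pd) {
  sqrt(sum(pd$r^2 * pd$p) * pd$bin_width / 2)
}

#' Kratky transform
#'
#' Pointwise Q^2 I(Q) versus Q, no smoothing. A bell shape indicates a
#' globular particle; a rising or asymmetric curve indicates extension or
#' flexibility.
#'
#' @param p a `saxs_profile`
#' @return data.frame with columns `q` and `q2i`
#' @export
kratky_transform <- function(p) {
  data.frame(q = p$q, q2i = p$q^2 * p$intensity)
}

#' Chi-square fit configuration
#'
#' The comparison grid defaults to 19 equally spaced momentum-transfer
#' points on (0, 0.19] A^-1 (i.e. 0.01, 0.02, ..., 0.19); the grid starts
#' one spacing above zero since Q = 0 is unmeasurable.
#'
#' @param n_points grid size (>= 3)
#' @param q_max upper grid end, Angstrom^-1
#' @param scale_mode `"fitted"` (analytic least-squares scale, costs one
#'   degree of freedom) or `"fixed"`
#' @param scale fixed scale value when `scale_mode = "fixed"`
#' @param const_sigma sigma policy when the experimental profile has no
#'   uncertainties: a single constant sigma (required in that case)
#' @return object of class `fit_config`
#' @export
fit_config <- function(n_points = 19, q_max = 0.19,
                       scale_mode = c("fitted", "fixed"), scale = 1,
                       const_sigma = NULL) {
  scale_mode <- match.arg(scale_mode)
  if (n_points < 3) stopf("n_points must be >= 3")
  if (q_max <= 0) stopf("q_max must be > 0")
  structure(list(n_points = as.integer(n_points), q_max = q_max,
                 scale_mode = scale_mode, scale = scale,
                 const_sigma = const_sigma),
            class = "fit_config")
}

fit_grid <- function(cfg) seq_len(cfg$n_points) * (cfg$q_max / cfg$n_points)

#' Reduced chi-square between a model and an experimental profile
#'
#' Both profiles are linearly interpolated onto the fit grid (linear in Q
#' and I, linear in sigma). With `scale_mode = "fitted"` the scale c
#' minimizing sum(((c I_m - I_e)/sigma)^2) is solved analytically and one
#' degree of freedom is charged: chi2_red = chi2 / (N - p), p = 1 if the
#' scale is fitted, else 0. Invariant under joint rescaling of the
#' experiment's (I, sigma).
#'
#' @param model a `saxs_profile` (theoretical; sigma ignored)
#' @param experiment a `saxs_profile` with sigma (or a `const_sigma`
#'   policy in `cfg`)
#' @param cfg a `fit_config`
#' @return list with `chi2_red`, `scale`, `n`, `dof`, `grid`
#' @export
reduced_chi2 <- function(model, experiment, cfg = fit_config()) {
  grid <- fit_grid(cfg)
  for (p in list(model, experiment)) {
    if (min(p$q) > grid[1] + 1e-12 || max(p$q) < grid[length(grid)] - 1e-12) {
      stopf("profile Q range [%.4g, %.4g] does not cover the fit grid",
            min(p$q), max(p$q))
    }
  }
  im <- approx(model$q, model$intensity, grid)$y
  ie <- approx(experiment$q, experiment$intensity, grid)$y
  if (!is.null(experiment$sigma)) {
    sg <- approx(experiment$q, experiment$sigma, grid)$y
  } else if (!is.null(cfg$const_sigma)) {
    sg <- rep(cfg$const_sigma, length(grid))
  } else {
    stopf(paste0("experiment has no sigma; set const_sigma in fit_config ",
                 "to state an explicit sigma policy"))
  }
  if (any(sg <= 0)) stopf("sigma must be positive on the fit grid")
  if (cfg$scale_mode == "fitted") {
    scale <- sum(im * ie / sg^2) / sum(im^2 / sg^2)
    dof <- length(grid) - 1L
  } else {
    scale <- cfg$scale
    dof <- length(grid)
  }
  chi2 <- sum(((scale * im - ie) / sg)^2)
  list(chi2_red = chi2 / dof, scale = scale, n = length(grid), dof = dof,
       grid = grid)
}
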