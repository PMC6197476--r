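# Shared fixtures, built once per test run. Everything is generated in
# code; no data files.

fx <- new.env()

fx_antibody <- function() {
  if (is.null(fx$ab)) fx$ab <- make_toy_antibody()
  fx$ab
}

fx_tetramer <- function() {
  if (is.null(fx$ag)) fx$ag <- make_toy_tetramer()
  fx$ag
}

fx_fab <- function() {
  if (is.null(fx$fab)) fx$fab <- extract_fab(fx_antibody(), 1)
  fx$fab
}

fx_poses <- function(n = 8) {
  if (is.null(fx$poses) || length(fx$poses) < n) {
    fx$poses <- lapply(seq_len(n), function(i) {
      make_docked_pose(fx_fab(), fx_tetramer(), gap = 4, seed = 100 + i)
    })
  }
  fx$poses[seq_len(n)]
}

fx_blocks <- function() {
  if (is.null(fx$blocks)) {
    blocks <- list()
    for (p in fx_poses()) {
      for (ax in 1:2) {
        sb <- symmetrize_pose(p, axis = ax)
        if (sb$accepted) blocks[[length(blocks) + 1L]] <- sb$structure
      }
    }
    fx$blocks <- blocks
  }
  fx$blocks
}

fx_tamc <- function() {
  if (is.null(fx$tamc)) {
    fx$tamc <- tamc_sample(fx_antibody(),
                           tamc_config(n_accept = 40, seed = 5))
  }
  fx$tamc
}

# uniform random points in a ball of radius r (rejection-free, seeded by
# the caller's RNG state)
ball_cloud <- function(n, r) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  u * r * runif(n)^(1 / 3)
}

# stratified (jittered-lattice) uniform ball: same density, far lower
# Monte-Carlo variance than i.i.d. sampling, which matters where the
# sphere form factor is orders of magnitude below its forward value
stratified_ball_cloud <- function(n, r) {
  spacing <- (4 / 3 * pi * r^3 / n)^(1 / 3)
  k <- ceiling(r / spacing) + 1L
  g <- as.matrix(expand.grid(x = (-k:k) * spacing, y = (-k:k) * spacing,
                             z = (-k:k) * spacing))
  g <- g[order(sqrt(rowSums(g^2)))[seq_len(n)], ]
  g + matrix(runif(3 * n, -0.5, 0.5) * spacing, n, 3)
}

structure_from_xyz <- function(xyz) {
  n <- nrow(xyz)
  saxs_structure(data.frame(
    serial = seq_len(n), chain = "A", resno = seq_len(n), resid = "GLY",
    elety = "CA", element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# independent exhaustive minimum inter-set distance (pure R / BLAS,
# all-pairs squared-distance matrix)
brute_dist2_matrix <- function(xa, xb) {
  outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
}

brute_min_dist <- function(a, b) {
  xa <- if (inherits(a, "saxs_structure")) coords(a) else a
  xb <- if (inherits(b, "saxs_structure")) coords(b) else b
  sqrt(max(0, min(brute_dist2_matrix(xa, xb))))
}

# brute-force re-check of the inter-unit overlap criterion used by the
# torsion MC sampler (independent of the compiled kernel)
brute_min_interdomain <- function(s, excl_resno = 2) {
  units <- s$info$units
  xyz <- coords(s)
  resno <- s$atoms$resno
  best <- Inf
  for (i in seq_along(units)) {
    for (j in seq_along(units)) {
      if (j <= i) next
      ia <- label_indices(s, units[i])
      ib <- label_indices(s, units[j])
      d2 <- brute_dist2_matrix(xyz[ia, , drop = FALSE],
                               xyz[ib, , drop = FALSE])
      d2[abs(outer(resno[ia], resno[ib], "-")) <= excl_resno] <- Inf
      best <- min(best, min(d2))
    }
  }
  sqrt(max(0, best))
}

all_bond_vectors <- function(s, label) {
  xyz <- coords(s, label)
  sqrt(rowSums(diff(xyz)^2))
}
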