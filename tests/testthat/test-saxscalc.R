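test_that("Debye sum matches closed forms", {
  one <- structure_from_xyz(matrix(c(1, 2, 3), ncol = 3))
  p <- debye_profile(one, c(0, 0.05, 0.1, 0.3))
  expect_equal(p$intensity, rep(1, 4))

  two <- structure_from_xyz(rbind(c(0, 0, 0), c(10, 0, 0)))
  p2 <- debye_profile(two, 0.1)
  expect_equal(p2$intensity, 2 * (1 + sin(1) / 1), tolerance = 1e-12)

  # I(0) = (sum f(0))^2, element mode uses electron counts
  s <- fx_tetramer()
  p3 <- debye_profile(s, 0, form_factor_table("element"))
  expect_equal(p3$intensity, (6 * n_atoms(s))^2)

  expect_error(debye_profile(two, c(-0.1, 0.1)), "negative")
})

test_that("Debye profile of a uniform ball matches the analytic sphere factor", {
  set.seed(71)
  R <- 30
  ball <- structure_from_xyz(stratified_ball_cloud(5000, R))
  q <- seq(0.01, 4 / R, length.out = 15)
  p <- debye_profile(ball, q)
  analytic <- (3 * (sin(q * R) - q * R * cos(q * R)) / (q * R)^3)^2
  expect_lt(max(abs(p$intensity / nrow(coords(ball))^2 - analytic) /
                analytic), 0.03)
})

test_that("golden-vector quadrature converges to the Debye sum", {
  one <- structure_from_xyz(matrix(c(5, -2, 1), ncol = 3))
  for (m in c(1, 31, 299)) {
    expect_equal(golden_vector_profile(one, c(0.01, 0.1),
                                       n_vectors = m)$intensity,
                 rep(1, 2))
  }
  ab <- fx_antibody()
  q <- seq(0.01, 0.2, by = 0.01)
  ref <- debye_profile(ab, q)
  gv <- golden_vector_profile(ab, q, n_vectors = 299)
  expect_lt(max(abs(gv$intensity - ref$intensity) / ref$intensity), 0.01)

  # mean deviation shrinks (on average) as M doubles
  devs <- vapply(c(35, 70, 140, 280), function(m) {
    g <- golden_vector_profile(ab, q, n_vectors = m)
    mean(abs(g$intensity - ref$intensity) / ref$intensity)
  }, 0)
  expect_lt(devs[4], devs[1])
  expect_true(mean(diff(devs) < 0) >= 2 / 3)
})

test_that("Guinier analysis recovers exact and sphere-cloud parameters", {
  q <- seq(0.002, 0.06, by = 0.002)
  exact <- saxs_profile(q, 100 * exp(-q^2 * 50^2 / 3))
  g <- guinier_fit(exact)
  expect_equal(g$rg, 50, tolerance = 1e-6)
  expect_equal(g$i0, 100, tolerance = 1e-6)
  expect_lte(g$qmax_rg, 1.3 + max(diff(q)) * g$rg)
  expect_equal(g$r2, 1, tolerance = 1e-9)

  set.seed(81)
  ball <- structure_from_xyz(ball_cloud(4000, 30))
  qb <- seq(0.004, 0.12, by = 0.004)
  pb <- debye_profile(ball, qb)
  gb <- guinier_fit(pb)
  expect_equal(gb$rg, sqrt(3 / 5) * 30, tolerance = 0.02)
  expect_lte(gb$qmax_rg, 1.3 + max(diff(qb)) * gb$rg)

  # weighted fit: sigma-weighting changes nothing for an exact curve
  exact_s <- saxs_profile(q, 100 * exp(-q^2 * 50^2 / 3),
                          sigma = 0.01 * 100 * exp(-q^2 * 50^2 / 3))
  expect_equal(guinier_fit(exact_s)$rg, 50, tolerance = 1e-6)

  rising <- saxs_profile(q, exp(q^2 * 100))
  expect_error(guinier_fit(rising), "slope")
})

test_that("pair distribution matches closed forms and the moment identity", {
  two <- structure_from_xyz(rbind(c(0, 0, 0), c(10, 0, 0)))
  pd <- pair_distribution(two, bin_width = 1)
  expect_equal(pd$dmax, 10)
  occupied <- which(pd$p > 0)
  expect_length(occupied, 1)
  expect_true(abs(pd$r[occupied] - 10) <= 0.5)
  expect_equal(sum(pd$p) * pd$bin_width, 1)

  # moment identity on an arbitrary toy
  ab <- fx_antibody()
  pda <- pair_distribution(ab, bin_width = 1)
  expect_equal(pr_rg(pda), radius_of_gyration(ab), tolerance = 0.02)

  # uniform sphere PDDF: p(r) proportional to r^2 (1 - 3x/2 + x^3/2)
  set.seed(91)
  R <- 30
  ball <- structure_from_xyz(ball_cloud(4000, R))
  pdb <- pair_distribution(ball, bin_width = 1.5)
  x <- pdb$r / (2 * R)
  shape <- pdb$r^2 * (1 - 1.5 * x + 0.5 * x^3)
  shape[x > 1] <- 0
  shape <- shape / (sum(shape) * pdb$bin_width)
  keep <- x <= 0.95
  expect_lt(max(abs(pdb$p[keep] - shape[keep])) / max(shape), 0.05)

  expect_error(pair_distribution(structure_from_xyz(matrix(0, 1, 3))),
               ">= 2")
})

test_that("Kratky transform is the pointwise parabola with the calculus peak", {
  q <- seq(0, 0.3, by = 0.001)
  flat <- saxs_profile(q[-1], rep(1, length(q) - 1))
  k <- kratky_transform(flat)
  expect_equal(k$q2i, k$q^2)

  rg <- 20
  gauss <- saxs_profile(q, exp(-q^2 * rg^2 / 3))
  kg <- kratky_transform(gauss)
  expect_equal(kg$q2i[1], 0)
  expect_equal(kg$q[which.max(kg$q2i)], sqrt(3) / rg, tolerance = 0.01)
})

test_that("reduced chi-square has the documented exact values and invariances", {
  q <- seq(0.005, 0.2, by = 0.005)
  i <- 100 * exp(-q * 9)
  sig <- 0.05 * i
  ex <- saxs_profile(q, i, sig)

  same <- reduced_chi2(saxs_profile(q, i), ex,
                       fit_config(scale_mode = "fixed", scale = 1))
  expect_equal(same$chi2_red, 0)

  scaled <- reduced_chi2(saxs_profile(q, 3.7 * i), ex, fit_config())
  expect_lt(scaled$chi2_red, 1e-12)
  expect_equal(scaled$scale, 1 / 3.7, tolerance = 1e-9)
  expect_equal(scaled$dof, 18L)

  # +1 sigma at every grid point, fixed scale: chi2_red = 19/19 = 1 exactly
  off <- reduced_chi2(saxs_profile(q, i + sig), ex,
                      fit_config(scale_mode = "fixed", scale = 1))
  expect_equal(off$chi2_red, 1, tolerance = 1e-12)
  expect_equal(off$n, 19L)

  # invariant under joint rescaling of the experiment's (I, sigma)
  model <- saxs_profile(q, i * (1 + 0.1 * q))
  a <- reduced_chi2(model, ex, fit_config())
  b <- reduced_chi2(model, saxs_profile(q, 7 * i, 7 * sig), fit_config())
  expect_equal(a$chi2_red, b$chi2_red, tolerance = 1e-9)

  # sigma policy must be explicit when the experiment has none
  expect_error(reduced_chi2(model, saxs_profile(q, i), fit_config()),
               "sigma policy")
  cc <- reduced_chi2(model, saxs_profile(q, i),
                     fit_config(const_sigma = 1))
  expect_true(is.finite(cc$chi2_red))

  # grid coverage is enforced
  short <- saxs_profile(q[q < 0.1], i[q < 0.1], sig[q < 0.1])
  expect_error(reduced_chi2(short, ex, fit_config()), "cover")
})

test_that("Guinier Rg of a noiseless Debye profile matches coordinate Rg", {
  ag <- fx_tetramer()
  rg <- radius_of_gyration(ag)
  q <- seq(0.002, 1.0 / rg, length.out = 25)
  g <- guinier_fit(debye_profile(ag, q), qmax_rg_limit = 1.0)
  expect_equal(g$rg, rg, tolerance = 0.01)
})
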