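test_that("sensorgram simulation matches closed forms and an ODE oracle", {
  p <- kinetic_params(ka = 1e5, kd = 4e-3, rmax = 100)
  expect_equal(p$kD, 4e-8, tolerance = 1e-12)

  zero <- simulate_sensorgram(p, conc = 0, t_assoc = 60, t_dissoc = 60)
  expect_true(all(zero$response == 0))

  # plateau: Req = rmax C / (C + kD) at t = 50 / (ka C + kd)
  C <- 1e-7
  kobs <- p$ka * C + p$kd
  sg <- simulate_sensorgram(p, conc = C, t_assoc = 50 / kobs,
                            t_dissoc = 10, dt = 50 / kobs / 100)
  req <- p$rmax * C / (C + p$kD)
  plateau <- max(sg$response[sg$phase == "association"])
  expect_equal(plateau, req, tolerance = 1e-9)

  # independent numerical integration of dR/dt = ka C (rmax - R) - kd R
  skip_if_not_installed("deSolve")
  times <- seq(0, 60, by = 1)
  ode <- deSolve::ode(c(R = 0), times, function(t, y, parms) {
    list(p$ka * C * (p$rmax - y[1]) - p$kd * y[1])
  }, NULL, method = "lsoda", rtol = 1e-12, atol = 1e-12)
  sg2 <- simulate_sensorgram(p, conc = C, t_assoc = 60, t_dissoc = 1)
  assoc <- sg2$response[sg2$phase == "association"]
  expect_lt(max(abs(assoc - ode[, "R"])), 1e-8)
})

test_that("global 1:1 fit recovers noiseless parameters exactly", {
  p <- kinetic_params(ka = 1e5, kd = 4e-3, rmax = 120)
  conc <- c(1, 3, 10, 30, 100, 300, 1000) * 1e-9
  sg <- simulate_sensorgram(p, conc, t_assoc = 60, t_dissoc = 120)
  fit <- fit_one_to_one(sg)
  expect_equal(fit$params$ka, p$ka, tolerance = 1e-6)
  expect_equal(fit$params$kd, p$kd, tolerance = 1e-6)
  expect_equal(fit$params$rmax, p$rmax, tolerance = 1e-6)
  expect_equal(fit$params$kD, p$kD, tolerance = 1e-6)
  expect_equal(coef(fit)[["kD"]], fit$params$kd / fit$params$ka)
})

test_that("kD estimate is robust to noise across seeds", {
  p <- kinetic_params(ka = 1e5, kd = 4e-3, rmax = 100)
  conc <- c(1, 5, 20, 80, 300, 1000) * 1e-9
  errs <- vapply(1:25, function(s) {
    sg <- simulate_sensorgram(p, conc, t_assoc = 60, t_dissoc = 120,
                              noise_sd = 1, seed = s)
    f <- fit_one_to_one(sg)
    abs(f$params$kD - p$kD) / p$kD
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("kD is invariant to joint rescaling of the rates", {
  p1 <- kinetic_params(ka = 1e5, kd = 4e-3, rmax = 100)
  p2 <- kinetic_params(ka = 1e6, kd = 4e-2, rmax = 100)
  conc <- c(3, 30, 300) * 1e-9
  f1 <- fit_one_to_one(simulate_sensorgram(p1, conc))
  f2 <- fit_one_to_one(simulate_sensorgram(p2, conc))
  expect_equal(f1$params$kD, f2$params$kD, tolerance = 1e-5)
})

test_that("degenerate designs warn", {
  p <- kinetic_params(ka = 1e5, kd = 4e-3, rmax = 100)
  sg <- simulate_sensorgram(p, conc = 4e-8)
  expect_warning(fit_one_to_one(sg), "single analyte concentration")
  sg2 <- simulate_sensorgram(p, conc = c(4e-8, 8e-8))
  expect_warning(fit_one_to_one(sg2), "10-fold")
})

test_that("stoichiometry search reproduces the worked SEC-MALS example", {
  res <- stoichiometry_search(component_mass("antigen", 63.3, 0.8),
                              component_mass("antibody", 160, 3),
                              component_mass("complex", 447, 12),
                              n_max = 4, z_limit = 1)
  expect_equal(nrow(res$combos), 1L)
  expect_equal(res$combos$n_antigen, 2)
  expect_equal(res$combos$n_antibody, 2)
  expect_equal(res$combos$predicted_mw, 446.6, tolerance = 1e-12)
  expect_equal(round(res$combos$predicted_mw), 447)
  expect_equal(res$combos$predicted_sigma,
               sqrt(4 * 0.8^2 + 4 * 3^2), tolerance = 1e-12)
})

test_that("stoichiometry search edge cases and brute-force equivalence", {
  ag <- component_mass("antigen", 63.3, 0.8)
  ab <- component_mass("antibody", 160, 3)
  pure <- stoichiometry_search(ag, ab, component_mass("x", 160, 0.01),
                               n_max = 4, z_limit = 1)
  expect_equal(nrow(pure$combos), 1L)
  expect_equal(pure$combos$n_antigen, 0)
  expect_equal(pure$combos$n_antibody, 1)

  # independent exhaustive enumeration oracle on random inputs
  set.seed(101)
  for (rep in 1:10) {
    m1 <- component_mass("a", runif(1, 20, 90), runif(1, 0, 3))
    m2 <- component_mass("b", runif(1, 100, 200), runif(1, 0, 5))
    meas <- component_mass("m", runif(1, 100, 700), runif(1, 1, 15))
    res <- stoichiometry_search(m1, m2, meas, n_max = 3, z_limit = 1.5)
    oracle <- NULL
    for (i in 0:3) for (j in 0:3) {
      if (i + j < 1) next
      pred <- i * m1$mw + j * m2$mw
      ps <- sqrt(i^2 * m1$sigma^2 + j^2 * m2$sigma^2)
      if (abs(pred - meas$mw) <= 1.5 * sqrt(ps^2 + meas$sigma^2)) {
        oracle <- rbind(oracle, c(i, j))
      }
    }
    got <- res$combos[order(res$combos$n_antigen, res$combos$n_antibody),
                      c("n_antigen", "n_antibody")]
    if (is.null(oracle)) {
      expect_equal(nrow(res$combos), 0L)
    } else {
      oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
      expect_equal(unname(as.matrix(got)), unname(oracle))
    }
  }

  # swapping the component roles relabels the indices
  sw <- stoichiometry_search(ab, ag, component_mass("complex", 447, 12),
                             n_max = 4, z_limit = 1)
  expect_equal(sw$combos$n_antigen, 2)
  expect_equal(sw$combos$n_antibody, 2)
})
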