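# Quantitative non-scattering computations: 1:1 Langmuir interaction-model
# kinetics for surface-plasmon-resonance sensorgrams (simulation + global
# fit) and the molar-mass stoichiometry enumeration that identifies the
# composition of a complex from SEC-MALS masses.

#' 1:1 interaction-model kinetic parameters
#'
#' @param ka association rate, 1/(M s)
#' @param kd dissociation rate, 1/s
#' @param rmax surface capacity, response units
#' @return object of class `kinetic_params`; `kD = kd/ka` (M) is derived
#' @export
kinetic_params <- function(ka, kd, rmax) {
  if (ka <= 0 || kd <= 0 || rmax <= 0) stopf("ka, kd, rmax must be > 0")
  structure(list(ka = ka, kd = kd, rmax = rmax, kD = kd / ka),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("1:1 kinetics: ka = %.4g /(M s), kd = %.4g /s, Rmax = %.4g RU, KD = %.4g M\n",
              x$ka, x$kd, x$rmax, x$kD))
  invisible(x)
}

# closed-form 1:1 response
assoc_response <- function(p, conc, t) {
  kobs <- p$ka * conc + p$kd
  req <- p$rmax * p$ka * conc / kobs
  req * (1 - exp(-kobs * t))
}

#' Simulate 1:1 interaction sensorgrams
#'
#' Association R(t) = Req (1 - exp(-(ka C + kd) t)) with
#' Req = Rmax ka C / (ka C + kd); dissociation decays from the end of
#' association with rate kd. Additive Gaussian noise, seeded.
#'
#' @param p a `kinetic_params`
#' @param conc analyte concentrations, M
#' @param t_assoc association time, s
#' @param t_dissoc dissociation time, s
#' @param noise_sd Gaussian noise standard deviation, response units
#' @param seed integer seed
#' @param dt sampling interval, s
#' @return data.frame sensorgram table: `time`, `response`, `conc`, `phase`
#' @export
simulate_sensorgram <- function(p, conc, t_assoc = 60, t_dissoc = 120,
                                noise_sd = 0, seed = 1, dt = 1) {
  if (any(conc < 0)) stopf("concentrations must be >= 0")
  ta <- seq(0, t_assoc, by = dt)
  td <- if (t_dissoc >= dt) seq(dt, t_dissoc, by = dt) else numeric(0)
  out <- do.call(rbind, lapply(conc, function(C) {
    ra <- assoc_response(p, C, ta)
    r0 <- assoc_response(p, C, t_assoc)
    rd <- r0 * exp(-p$kd * td)
    data.frame(
      time = c(ta, t_assoc + td),
      response = c(ra, rd),
      conc = C,
      phase = c(rep("association", length(ta)),
                rep("dissociation", length(td))),
      stringsAsFactors = FALSE)
  }))
  if (noise_sd > 0) {
    out$response <- with_seed(seed,
                              out$response + rnorm(nrow(out), 0, noise_sd))
  }
  out
}

#' Global 1:1 interaction-model fit
#'
#' Nonlinear least squares over all curves simultaneously for (ka, kd,
#' Rmax), sharing Rmax across concentrations (one surface). Parameters are
#' fitted on a log scale; asymptotic standard errors and derived KD are
#' reported. Unweighted residuals.
#'
#' @param data sensorgram table from [simulate_sensorgram()] (columns
#'   `time`, `response`, `conc`, `phase`)
#' @param start optional `kinetic_params` starting guess
#' @return object of class `spr_fit`: `params` (a `kinetic_params`),
#'   `se` (relative standard errors of ka, kd, rmax), `kD_se`,
#'   `rss`, `n`, `converged`
#' @export
fit_one_to_one <- function(data, start = NULL) {
  conc <- sort(unique(data$conc[data$conc > 0]))
  if (length(conc) < 2) {
    warning("single analyte concentration: (ka, kd, Rmax) are weakly ",
            "identified; intervals will be wide")
  } else if (max(conc) / min(conc) < 10) {
    warning("concentration span below 10-fold; fit may be ill-conditioned")
  }
  if (!all(c("association", "dissociation") %in% data$phase)) {
    warning("both association and dissociation phases are expected")
  }
  t_assoc <- max(data$time[data$phase == "association"])
  if (is.null(start)) {
    # crude initialization: kd from late dissociation decay, Req scale
    start <- kinetic_params(ka = 1e5, kd = 1e-2,
                            rmax = max(data$response) * 1.5)
  }
  model_response <- function(p, d) {
    r <- numeric(nrow(d))
    ia <- d$phase == "association"
    r[ia] <- assoc_response(p, d$conc[ia], d$time[ia])
    id <- !ia
    r0 <- assoc_response(p, d$conc[id], t_assoc)
    r[id] <- r0 * exp(-p$kd * (d$time[id] - t_assoc))
    r
  }
  resid_fun <- function(lpar) {
    p <- kinetic_params(exp(lpar[1]), exp(lpar[2]), exp(lpar[3]))
    model_response(p, data) - data$response
  }
  fit <- minpack.lm::nls.lm(
    par = log(c(start$ka, start$kd, start$rmax)), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4) {
    stopf("1:1 global fit did not converge (nls.lm info = %d: %s)",
          fit$info, fit$message)
  }
  lpar <- fit$par
  p <- kinetic_params(exp(lpar[1]), exp(lpar[2]), exp(lpar[3]))
  n <- nrow(data)
  dof <- max(1L, n - 3L)
  s2 <- sum(fit$fvec^2) / dof
  cov_l <- tryCatch(s2 * solve(fit$hessian / 2), error = function(e) NULL)
  # log-scale SEs are relative SEs of the natural parameters
  se <- if (is.null(cov_l)) rep(NA_real_, 3) else sqrt(pmax(0, diag(cov_l)))
  kD_se <- if (is.null(cov_l)) NA_real_ else
    sqrt(max(0, cov_l[1, 1] + cov_l[2, 2] - 2 * cov_l[1, 2]))
  structure(list(params = p, se = setNames(se, c("ka", "kd", "rmax")),
                 kD_se = kD_se, rss = sum(fit$fvec^2), n = n,
                 converged = TRUE),
            class = "spr_fit")
}

#' @export
print.spr_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  relative SEs: ka %.2g, kd %.2g, Rmax %.2g; KD %.2g (n = %d)\n",
              x$se[1], x$se[2], x$se[3], x$kD_se, x$n))
  invisible(x)
}

#' @export
coef.spr_fit <- function(object, ...) {
  with(object$params, c(ka = ka, kd = kd, rmax = rmax, kD = kD))
}

#' Component molar mass with uncertainty
#'
#' @param name component name
#' @param mw molar mass, kDa
#' @param sigma standard uncertainty, kDa
#' @return object of class `component_mass`
#' @export
component_mass <- function(name, mw, sigma = 0) {
  if (mw <= 0) stopf("mw must be > 0")
  if (sigma < 0) stopf("sigma must be >= 0")
  structure(list(name = name, mw = mw, sigma = sigma),
            class = "component_mass")
}

#' Integer-stoichiometry search against a measured molar mass
#'
#' Enumerates combinations of i antigens + j antibodies (0 <= i, j <=
#' n_max, i + j >= 1) with predicted mass i*mw_ag + j*mw_ab and propagated
#' uncertainty sqrt(i^2 s_ag^2 + j^2 s_ab^2); a combination is accepted
#' when |predicted - measured| <= z_limit * sqrt(s_pred^2 + s_meas^2).
#'
#' @param antigen,antibody,measured `component_mass` objects
#' @param n_max largest copy number per component (>= 1)
#' @param z_limit acceptance window in combined standard deviations (> 0)
#' @return object of class `stoichiometry_result`: data.frame `combos`
#'   (accepted, sorted by |z|) and data.frame `all` (every combination)
#' @export
stoichiometry_search <- function(antigen, antibody, measured, n_max = 4,
                                 z_limit = 1) {
  if (n_max < 1) stopf("n_max must be >= 1")
  if (z_limit <= 0) stopf("z_limit must be > 0")
  grid <- expand.grid(n_antigen = 0:n_max, n_antibody = 0:n_max)
  grid <- grid[grid$n_antigen + grid$n_antibody >= 1, ]
  grid$predicted_mw <- grid$n_antigen * antigen$mw +
    grid$n_antibody * antibody$mw
  grid$predicted_sigma <- sqrt(grid$n_antigen^2 * antigen$sigma^2 +
                               grid$n_antibody^2 * antibody$sigma^2)
  comb_sd <- sqrt(grid$predicted_sigma^2 + measured$sigma^2)
  grid$z <- (grid$predicted_mw - measured$mw) / ifelse(comb_sd > 0, comb_sd, 1)
  grid$accepted <- abs(grid$predicted_mw - measured$mw) <= z_limit * comb_sd
  combos <- grid[grid$accepted, ]
  combos <- combos[order(abs(combos$z)), ]
  rownames(combos) <- rownames(grid) <- NULL
  structure(list(combos = combos, all = grid, measured = measured,
                 z_limit = z_limit),
            class = "stoichiometry_result")
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  cat(sprintf("Stoichiometry search vs measured %.4g +/- %.2g kDa (z <= %g):\n",
              x$measured$mw, x$measured$sigma, x$z_limit))
  if (nrow(x$combos)) {
    print(x$combos[, c("n_antigen", "n_antibody", "predicted_mw",
                       "predicted_sigma", "z")], row.names = FALSE)
  } else {
    cat("  no combination within the window\n")
  }
  invisible(x)
}
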