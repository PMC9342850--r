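test_that("chi2 matches a brute-force re-summation oracle", {
  set.seed(21)
  p <- random_linear_problem(N = 8, m = 5, seed = 3)
  w <- runif(8); w <- w / sum(w)
  ## independent summation
  manual <- 0
  for (m in 1:5) {
    avg <- sum(w * p$fm$F[, m])
    manual <- manual + ((avg - p$obs$values[m]) / p$obs$sigmas[m])^2
  }
  expect_equal(chi2(w, p$fm), manual, tolerance = 1e-10)
  ## exact agreement and unit-residual cases
  y <- as.numeric(crossprod(w, p$fm$F))
  exact <- observable_set("CS", y, p$obs$sigmas, p$obs$meta)
  fm2 <- structure(list(kind = "CS", F = p$fm$F, obs = exact, params = list()),
                   class = "forward_matrix")
  expect_equal(chi2(w, fm2), 0, tolerance = 1e-18)
  one <- observable_set("CS", y[1] + p$obs$sigmas[1], p$obs$sigmas[1],
                        p$obs$meta[1, , drop = FALSE])
  fm1 <- structure(list(kind = "CS", F = p$fm$F[, 1, drop = FALSE], obs = one,
                        params = list()), class = "forward_matrix")
  expect_equal(chi2(w, fm1), 1, tolerance = 1e-10)
})

test_that("relative entropy has its closed forms and Gibbs inequality", {
  expect_equal(srel(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(srel(c(1, 0), c(0.5, 0.5)), -log(2))
  expect_equal(exp(srel(c(1, 0), c(0.5, 0.5))), 0.5)
  set.seed(4)
  for (k in 1:20) {
    w0 <- runif(6); w0 <- w0 / sum(w0)
    w <- runif(6); w <- w / sum(w)
    expect_lte(srel(w, w0), 0)
  }
  expect_error(srel(c(0.5, 0.5), c(1, 0)), "support")
})

test_that("solver matches the exhaustive simplex grid oracle on small problems", {
  for (seed in 1:4) {
    N <- if (seed %% 2) 2L else 3L
    p <- random_linear_problem(N, m = 2, seed = seed)
    res <- bme_solve(list(CS = p$fm), p$prior, theta = 1)
    L_solver <- 0.5 * chi2(res$weights, p$fm) - 1 * srel(res$weights, p$prior)
    L_grid <- grid_search_bme(list(p$fm), p$prior, theta = 1,
                              step = if (N == 2) 0.001 else 0.002)
    expect_lt(abs(L_solver - L_grid), 1e-4)
  }
})

test_that("prior-dominated limit returns the prior; self-consistent data stay put", {
  ens <- small_coil()
  obs_q <- seq(0.2, 2, length.out = 10)
  Fs <- build_forward_matrix(
    ens, observable_set("SAXS", rep(1, 10), rep(1, 10), data.frame(q = obs_q)))$F
  y <- as.numeric(crossprod(ens$weights, Fs))
  saxs <- observable_set("SAXS", y, pmax(0.02 * y, 1e-9), data.frame(q = obs_q))
  fm <- build_forward_matrix(ens, saxs)
  ## theta -> infinity
  res <- bme_solve(list(SAXS = fm), ens$weights, theta = 1e6)
  expect_gt(res$diagnostics$neff, 0.999)
  expect_lt(max(abs(res$weights - ens$weights)), 1e-3)
  ## zero-noise self-consistent data at moderate theta
  res2 <- bme_solve(list(SAXS = fm), ens$weights, theta = 10)
  expect_lt(res2$diagnostics$chi2_total_reduced, 1e-4)
  expect_gt(res2$diagnostics$neff, 0.999)
})

test_that("posterior has the exponential-tilt form in the row space of F", {
  p <- random_linear_problem(N = 30, m = 4, seed = 12)
  res <- bme_solve(list(CS = p$fm), p$prior, theta = 2)
  lw <- log(res$weights / p$prior)
  fit <- stats::lm(lw ~ p$fm$F)
  expect_lt(max(abs(stats::residuals(fit))), 1e-6)
  ## N_eff = exp(S_REL) identity in the diagnostics
  expect_equal(res$diagnostics$neff, exp(res$diagnostics$srel), tolerance = 1e-12)
})

test_that("theta scan is monotone with warm starts and ends near the prior", {
  ens <- small_coil()
  truth <- make_ground_truth(ens, "Rg", 1.5)
  data <- synthesize_experiments(ens, truth, seed = 6,
                                 q_grid = seq(0.2, 2, length.out = 12),
                                 fret = list(site_a = 1, site_b = 20, R0 = 3),
                                 pre_sites = c(5, 15))
  fms <- list(SAXS = build_forward_matrix(ens, data$saxs),
              CS = build_forward_matrix(ens, data$cs),
              FRET = build_forward_matrix(ens, data$fret))
  grid <- 10^seq(3, -1, length.out = 8)
  sc <- theta_scan(fms, ens$weights, grid, omega = 5,
                   validation = list(ens = ens, pre = data$pre))
  cv <- sc$curve
  expect_true(all(diff(cv$chi2_total) <= 1e-6 * abs(cv$chi2_total[-nrow(cv)])))
  expect_true(all(diff(cv$neff) <= 1e-9))
  expect_gt(cv$neff[1], 0.99)            # largest theta ~ prior diagnostics
  expect_true(all(is.finite(cv$pre_score)))
  expect_error(theta_scan(fms, ens$weights, rev(grid)), "descending")
})

test_that("elbow selection finds the corner of an L-shaped curve", {
  ## synthetic L: steep drop then flat, corner at the 5th point
  mk_scan <- function(chi2, neff, pre = NA) {
    structure(list(curve = data.frame(theta = 2^(length(chi2):1),
                                      chi2_total = chi2, neff = neff,
                                      pre_score = pre, failed = FALSE)),
              class = "scan_curve")
  }
  chi2 <- c(100, 60, 30, 12, 5, 4.5, 4.2, 4.1)
  neff <- c(0.99, 0.97, 0.95, 0.92, 0.9, 0.6, 0.3, 0.1)
  sc <- mk_scan(chi2, neff)
  th <- select_theta(sc, "elbow")
  expect_equal(attr(th, "index"), 5L)
  ## strictly linear trade-off: weak-elbow warning
  lin <- mk_scan(seq(100, 30, length.out = 8), seq(0.9, 0.2, length.out = 8))
  expect_warning(select_theta(lin, "elbow"), "weak elbow")
  ## validation-minimum mode returns the configured minimum
  val <- mk_scan(chi2, neff, pre = c(0.4, 0.35, 0.3, 0.28, 0.26, 0.3, 0.38, 0.5))
  expect_equal(attr(select_theta(val, "validation-minimum"), "index"), 5L)
  expect_error(select_theta(mk_scan(chi2[1:3], neff[1:3])), ">= 4")
})

test_that("PRE validation score is the RMS of per-site RMSDs", {
  ens <- small_coil()
  pp <- pre_params()
  meta <- rbind(data.frame(label_site = 5, resid = c(1:4, 6:20)),
                data.frame(label_site = 15, resid = c(1:14, 16:20)))
  calc <- unlist(lapply(c(5, 15), function(s)
    pre_intensity_ratio(ens, NULL, s, setdiff(1:20, s), pp)$ratio))
  exact <- observable_set("PRE", calc, rep(0.05, length(calc)), meta)
  expect_equal(as.numeric(pre_validation_score(ens$weights, ens, exact, pp)), 0,
               tolerance = 1e-12)
  ## uniform residual 0.1 at one site -> score 0.1; sites 0.3/0.4 -> 0.354
  one <- observable_set("PRE", calc[meta$label_site == 5] + 0.1,
                        rep(0.05, 19), meta[meta$label_site == 5, ])
  expect_equal(as.numeric(pre_validation_score(ens$weights, ens, one, pp)), 0.1,
               tolerance = 1e-9)
  shifted <- observable_set("PRE", calc + ifelse(meta$label_site == 5, 0.3, 0.4),
                            rep(0.05, length(calc)), meta)
  expect_equal(as.numeric(pre_validation_score(ens$weights, ens, shifted, pp)),
               sqrt((0.09 + 0.16) / 2), tolerance = 1e-9)
})

test_that("omega scan improves the FRET fit and defaults include 75", {
  expect_true(75 %in% eval(formals(omega_scan)$omega_grid))
  ens <- small_coil()
  truth <- make_ground_truth(ens, "end_to_end", 1)
  data <- synthesize_experiments(ens, truth, seed = 16,
                                 q_grid = seq(0.2, 2, length.out = 12),
                                 fret = list(site_a = 1, site_b = 20, R0 = 3),
                                 pre_sites = c(5, 15))
  fms <- list(SAXS = build_forward_matrix(ens, data$saxs),
              CS = build_forward_matrix(ens, data$cs),
              FRET = build_forward_matrix(ens, data$fret))
  sc <- omega_scan(fms, ens$weights, omega_grid = c(1, 5, 25, 75), theta = 50)
  expect_true(all(diff(sc$table$chi2_FRET) <= 1e-8))
  expect_true(sc$omega %in% c(1, 5, 25, 75))
  ## no FRET restraint: scan is vacuous
  expect_equal(omega_scan(fms[1:2], ens$weights, theta = 50)$omega, 1)
})
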