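# Shared small selection problem: pool with a planted subset whose averages
# generated the data exactly.
mc_problem <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pool <- generate_prior("coil", tiny_seq(20), 120, seed = 501)
    set.seed(502)
    planted <- sort(sample.int(120, 25))
    sub <- ensemble(pool$conformers[planted])
    d0 <- synthesize_experiments(
      sub, NULL, noise = list(saxs_rel = 0, cs_sigma = 0, fret_sigma = 0, pre_sigma = 0),
      seed = 1, q_grid = seq(0.2, 2, length.out = 12),
      fret = list(site_a = 1, site_b = 20, R0 = 3), pre_sites = c(5, 15))
    mk <- function(o, s) observable_set(o$kind, o$values, s, o$meta)
    ## tight sigmas so that typical random subsets do NOT fit and the
    ## annealing has to search for the planted signal
    datasets <- list(SAXS = mk(d0$saxs, pmax(0.005 * d0$saxs$values, 1e-6)),
                     CS = mk(d0$cs, rep(0.1, length(d0$cs))),
                     PRE = mk(d0$pre, rep(0.02, length(d0$pre))))
    cache <<- list(pool = pool, planted = planted, datasets = datasets,
                   fret = mk(d0$fret, 0.03))
    cache
  }
})

test_that("pseudo-energies vanish on the planted subset and classify fits", {
  p <- mc_problem()
  pe <- pseudo_energies(p$planted, p$pool, p$datasets)
  expect_equal(pe$raw, rep(0, 3), tolerance = 1e-16)
  expect_true(all(pe$fit))
  ## a random subset misfits at least the SAXS data
  set.seed(9)
  pe_rand <- pseudo_energies(sample.int(120, 25), p$pool, p$datasets)
  expect_true(any(pe_rand$normalized > 1))
  expect_identical(pe_rand$fit, pe_rand$normalized < 1)
})

test_that("PRE distance targets round-trip through the forward model inverse", {
  pp <- pre_params()
  ratio <- c(0.2, 0.5, 0.8)
  d <- pre_ratio_to_dist(ratio, pp)
  back <- idpens:::pre_ratio_from_gamma2(idpens:::pre_gamma2(d^-6, pp), pp)
  expect_equal(back, ratio, tolerance = 1e-8)
})

test_that("annealing converges on the planted fixture and is deterministic", {
  p <- mc_problem()
  r1 <- anneal_select(p$pool, p$datasets, M = 25, seed = 3, budget = 2e4)
  expect_true(r1$converged)
  expect_true(all(r1$energies <= 1))
  r2 <- anneal_select(p$pool, p$datasets, M = 25, seed = 3, budget = 2e4)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$trace, r2$trace)
  ## converged flag is exactly the threshold criterion
  expect_identical(r1$converged, all(r1$energies <= 1))
  ## trace bookkeeping
  expect_equal(nrow(r1$trace), r1$trials)
})

test_that("data equal to full-pool averages converge immediately at M = pool size", {
  p <- mc_problem()
  d0 <- synthesize_experiments(
    p$pool, NULL, noise = list(saxs_rel = 0, cs_sigma = 0, fret_sigma = 0, pre_sigma = 0),
    seed = 1, q_grid = seq(0.2, 2, length.out = 12),
    fret = list(site_a = 1, site_b = 20, R0 = 3), pre_sites = c(5, 15))
  mk <- function(o, s) observable_set(o$kind, o$values, s, o$meta)
  datasets <- list(SAXS = mk(d0$saxs, pmax(0.02 * d0$saxs$values, 1e-6)),
                   CS = mk(d0$cs, rep(0.4, length(d0$cs))))
  r <- anneal_select(p$pool, datasets, M = 120, seed = 1, budget = 100)
  expect_true(r$converged)
  expect_equal(r$trials, 0L)
  ## and a strict subset with data from the full pool is also an immediate
  ## fit when sigmas are loose
  r2 <- anneal_select(p$pool, datasets, M = 119, seed = 1, budget = 5000)
  expect_true(r2$converged)
})

test_that("budget exhaustion flags the run instead of erroring", {
  p <- mc_problem()
  hard <- p$datasets
  hard$SAXS <- observable_set("SAXS", hard$SAXS$values * 3, hard$SAXS$sigmas * 0.01,
                              hard$SAXS$meta)
  r <- anneal_select(p$pool, hard, M = 25, seed = 2, budget = 300, settle = 0)
  expect_false(r$converged)
  expect_equal(r$trials, 300)
})

test_that("replicated runs combine into a uniform-weight ensemble with stats", {
  p <- mc_problem()
  sel <- run_replicates(p$pool, p$datasets, n_runs = 3, M = 25, budget = 2e4,
                        seeds = 11:13, validation = p$fret, trace = FALSE)
  expect_equal(length(sel$combined), 75L)
  expect_equal(sel$combined$weights, rep(1 / 75, 75))
  expect_true(sel$all_converged)
  expect_length(sel$runs, 3L)
  ## combined averages equal the mean of run averages (linearity)
  fm <- build_forward_matrix(sel$combined, p$datasets$CS)
  comb_avg <- colMeans(fm$F)
  run_avg <- sapply(sel$runs, function(r) {
    colMeans(build_forward_matrix(ensemble(p$pool$conformers[r$selected]),
                                  p$datasets$CS)$F)
  })
  expect_equal(comb_avg, rowMeans(run_avg), tolerance = 1e-12)
  ## identical seeds -> zero spread
  same <- run_replicates(p$pool, p$datasets, n_runs = 2, M = 25, budget = 2e4,
                         seeds = c(7, 7), trace = FALSE)
  expect_equal(same$energy_sd, 0)
  expect_equal(same$trials_sd, 0)
})

test_that("FRET z-test has closed-form values", {
  ens <- small_coil()
  fm <- build_forward_matrix(
    ens, observable_set("FRET", 0.5, 0.03, data.frame(site_a = 1, site_b = 20, R0_nm = 3)))
  e_ens <- mean(fm$F[, 1])
  mk <- function(E, s) observable_set("FRET", E, s, data.frame(site_a = 1, site_b = 20, R0_nm = 3))
  expect_equal(z_test_fret(ens, mk(e_ens, 0.03)), 0, tolerance = 1e-12)
  expect_equal(z_test_fret(ens, mk(e_ens - 0.03, 0.03)), 1, tolerance = 1e-9)
  expect_equal(z_test_fret(ens, mk(e_ens + 2.5 * 0.02, 0.02)), 2.5, tolerance = 1e-9)
})

test_that("pool replenishment prefers to drop frequently selected conformers", {
  p <- mc_problem()
  gen <- function(n) replicate(n, build_chain(tiny_seq(20), sampler_basin()),
                               simplify = FALSE)
  counts <- rep(0L, 120); counts[7] <- 50L
  set.seed(88)
  dropped7 <- 0
  for (k in 1:60) {
    out <- replenish_pool(p$pool, gen, counts, n_new = 12)
    expect_equal(length(out$pool), 120L)
    expect_equal(length(out$counts), 120L)
    if (!any(out$counts == 50L)) dropped7 <- dropped7 + 1
  }
  ## conformer 7 (count 50 vs 0) should be replaced far more often than the
  ## uniform rate 12/120 = 0.1
  expect_gt(dropped7 / 60, 0.25)
})

test_that("acceptance rule satisfies detailed balance on an enumerable toy", {
  ## 3 distinct conformers, M = 1, one CS point that no conformer fits:
  ## at fixed temperature and fixed restraint weights (gamma = 1) the chain
  ## should visit states with Boltzmann frequencies over the normalized
  ## energies recorded in the trace.
  pool3 <- ensemble(list(helix_conformer(6), extended_conformer(6),
                         build_chain(tiny_seq(6), sampler_fixed(-80, 60))))
  I <- vapply(pool3$conformers, saxs_debye, numeric(1), q = 1)
  y <- max(I) + 0.5 * stats::sd(I)       # outside the range: no state fits
  sg <- stats::sd(I) / 3
  obs <- observable_set("SAXS", y, sg, data.frame(q = 1))
  spec <- pseudo_energy_spec(list(SAXS = obs), gamma = 1)
  raw <- ((I - y) / sg)^2
  expect_true(all(raw > 1))
  temp <- diff(range(raw)) / 2.5
  r <- anneal_select(pool3, list(SAXS = obs), M = 1, spec = spec,
                     schedule = list(T0 = temp, alpha = 1, trials_per_T = 1e9),
                     budget = 2e4, seed = 99, settle = 0)
  expect_false(r$converged)
  lev <- sort(unique(round(r$trace$norm_SAXS, 9)))
  expect_length(lev, 3L)
  visits <- table(factor(round(r$trace$norm_SAXS, 9), levels = lev))
  pi_hat <- as.numeric(visits) / sum(visits)
  pi_exact <- exp(-lev / temp) / sum(exp(-lev / temp))
  expect_lt(max(abs(pi_hat - pi_exact)), 0.03)
})
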