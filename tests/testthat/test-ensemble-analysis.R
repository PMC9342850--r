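test_that("radius of gyration has closed forms and the pairwise identity", {
  ## two CA atoms at distance d -> rg = d/2
  two <- manual_conformer(data.frame(
    resno = c(1, 1, 1, 1, 2, 2, 2, 2), resid = "GLY",
    elety = rep(c("N", "CA", "C", "O"), 2),
    x = c(0, 0, 0.1, 0.2, 1.8, 1.8, 1.9, 2.0), y = 0, z = 0))
  expect_equal(radius_of_gyration(two), 0.9, tolerance = 1e-12)
  ## the 1/(2 n^2) sum over <r_ij^2> identity on random conformers
  ens <- small_coil()
  n <- 20
  rg2_direct <- vapply(ens$conformers, function(cf) radius_of_gyration(cf)^2, numeric(1))
  rg2_pair <- vapply(ens$conformers, function(cf) {
    ca <- cf$xyz[cf$elety == "CA", ]
    sum(as.matrix(stats::dist(ca))^2) / (2 * n^2)
  }, numeric(1))
  expect_equal(rg2_direct, rg2_pair, tolerance = 1e-10)
  ## ensemble Rg^2 is the weighted mean of squared radii
  w <- check_weights(seq_len(length(ens)) / sum(seq_len(length(ens))))
  expect_equal(radius_of_gyration(ens, w)^2, sum(w * rg2_direct), tolerance = 1e-12)
})

test_that("scaling maps are 1 against self, scale affinely, and detect compaction", {
  ens <- small_coil()
  self <- scaling_map(ens, ref = ens)
  expect_true(all(abs(self[upper.tri(self)] - 1) < 1e-12))
  expect_true(is.na(self[3, 3]))
  ## uniformly scaled copy: D = 1.2 everywhere
  scaled <- ensemble(lapply(ens$conformers, function(cf) {
    conformer(cf$xyz * 1.2, cf$resno, cf$resid, cf$elety, validate = FALSE)
  }))
  D <- scaling_map(scaled, ref = ens)
  expect_true(all(abs(D[upper.tri(D)] - 1.2) < 1e-9))
  ## upweighting a compact subpopulation decreases long-range D
  rg <- vapply(ens$conformers, radius_of_gyration, numeric(1))
  w <- ifelse(rg < stats::median(rg), 2, 1)
  w <- w / sum(w)
  Dw <- scaling_map(ens, weights = w, ref = ens)
  long <- abs(row(Dw) - col(Dw)) > 10
  expect_lt(mean(Dw[long], na.rm = TRUE), 1)
  expect_error(scaling_map(ens, ref = ensemble(list(helix_conformer(5)))), "length")
})

test_that("geometric H-bond criteria classify constructed fixtures", {
  hit <- hbond_assign(mk_hbond_fixture(0.20, 175), min_separation = 10)
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$donor, hit$acceptor), c(1, 15))
  expect_equal(nrow(hbond_assign(mk_hbond_fixture(0.40, 175), min_separation = 10)), 0L)
  expect_equal(nrow(hbond_assign(mk_hbond_fixture(0.20, 90), min_separation = 10)), 0L)
  ## sequence-separation filter
  cp <- mk_hbond_fixture(0.20, 175)
  close_pair <- conformer(cp$xyz, ifelse(cp$resno == 15, 2L, 1L),
                          cp$resid, cp$elety, validate = FALSE)
  expect_equal(nrow(hbond_assign(close_pair, min_separation = 10)), 0L)
  expect_equal(nrow(hbond_assign(close_pair, min_separation = 0)), 1L)
})

test_that("H-bond PMFs normalize and average correctly", {
  ens <- small_coil()
  out <- hbond_pmf(ens)
  expect_equal(sum(out$pmf), 1, tolerance = 1e-12)
  ## hand-set counts: (2, 4) with weights (0.25, 0.75) -> mean 3.5
  two <- ensemble(ens$conformers[1:2], weights = c(0.25, 0.75))
  res <- hbond_pmf(two, counts = c(2L, 4L))
  expect_equal(res$mean, 3.5)
  expect_equal(unname(res$pmf[c("2", "4")]), c(0.25, 0.75))
  ## an all-coil ensemble of short chains has no long-range H-bonds
  short <- ensemble(replicate(5, extended_conformer(8), simplify = FALSE))
  res0 <- hbond_pmf(short)
  expect_equal(unname(res0$pmf["0"]), 1)
  expect_equal(res0$mean, 0)
})

test_that("pi contacts classify constructed planar-group geometries", {
  near <- pi_contacts(mk_pi_fixture(0.40, 0))
  expect_equal(unname(near["bb_bb"]), 1L)
  expect_equal(unname(pi_contacts(mk_pi_fixture(1.0, 0))["bb_bb"]), 0L)   # beyond cutoff
  expect_equal(unname(pi_contacts(mk_pi_fixture(0.40, 90))["bb_bb"]), 0L) # perpendicular
  expect_equal(sum(pi_contacts(mk_pi_fixture(0.40, 0, sep_res = 5L))), 0L) # |i-j| <= 10
})

test_that("side-chain planes participate in sc-sc and sc-bb classes", {
  ## an arginine guanidinium plane over a backbone amide plane and another
  ## guanidinium, all parallel (normals aligned)
  sc <- function(resno, z) data.frame(
    resno = resno, elety = c("N", "CA", "C", "O", "CB", "NE", "CZ", "NH1", "NH2"),
    x = c(5, 5.1, 5.2, 5.3, 5.05, 0, 0.12, 0.24, 0.12),
    y = c(5, 5, 5, 5, 5.1, 0, -0.1, 0, 0.12),
    z = z)
  bb <- function(resno, z) data.frame(
    resno = resno, elety = c("N", "CA", "C", "O"),
    x = c(-0.2, -0.1, 0, 0.06), y = c(0.1, 0.12, 0, -0.1), z = z)
  a <- rbind(sc(1, 0), sc(20, 0.35), bb(40, 0.7),
             data.frame(resno = 41, elety = c("N", "CA", "C", "O"),
                        x = c(0.1, 0.25, 0.3, 0.3), y = c(0.08, 0.1, 0.3, 0.5),
                        z = 0.7))
  a$resid <- ifelse(a$resno %in% c(1, 20), "ARG", "GLY")
  counts <- pi_contacts(manual_conformer(a))
  expect_equal(unname(counts["sc_sc"]), 1L)   # residue 1 - residue 20
  expect_gte(unname(counts["sc_bb"]), 1L)     # residue 20 - backbone 40
})

test_that("reduced DSSP assigns helix interiors and leaves strands coil", {
  hel <- helix_conformer(15)
  cls <- dssp3(hel)
  expect_true(all(cls[4:12] == "helix"))
  ext <- extended_conformer(12)
  expect_true(all(dssp3(ext) == "coil"))   # no bridge partner
  expect_equal(dssp3(build_chain("AA", sampler_fixed(-60, -45))), c("coil", "coil"))
})

test_that("secondary-structure propensities partition to 1 with bootstrap SDs", {
  ens <- small_coil()
  out <- ss_propensity(ens, B = 50, seed = 3)
  expect_equal(unname(rowSums(out$propensity)), rep(1, 20), tolerance = 1e-12)
  expect_equal(dim(out$sd), c(20L, 3L))
  ## all-coil ensemble: coil propensity 1 everywhere
  ext <- ensemble(replicate(4, extended_conformer(10), simplify = FALSE))
  pe <- ss_propensity(ext)
  expect_true(all(pe$propensity[, "coil"] == 1))
})

test_that("weighted bootstrap matches the analytic standard error", {
  ens <- small_coil()
  rg2 <- vapply(ens$conformers, function(cf) radius_of_gyration(cf)^2, numeric(1))
  set.seed(10)
  w <- rexp(length(ens)); w <- w / sum(w)
  n <- length(ens)
  analytic <- sqrt(sum(w * (rg2 - sum(w * rg2))^2) / n)
  boot <- bootstrap_sd_values(matrix(rg2, ncol = 1), w, B = 2000, seed = 5)
  expect_lt(abs(boot - analytic) / analytic, 0.1)
  ## determinism and degenerate cases
  expect_identical(boot, bootstrap_sd_values(matrix(rg2, ncol = 1), w, B = 2000, seed = 5))
  expect_equal(bootstrap_sd_values(matrix(rep(2, n), ncol = 1), w, B = 100, seed = 1), 0)
  expect_error(bootstrap_sd_values(matrix(rg2, ncol = 1), w, B = 1), "B must be")
  ## the ensemble-statistic interface agrees with the fast path
  boot2 <- bootstrap_sd(function(e) radius_of_gyration(e)^2, ens, w, B = 300, seed = 5)
  expect_lt(abs(boot2 - analytic) / analytic, 0.2)
})

test_that("conformer compaction correlates with long-range H-bond counts", {
  ## on a compact-tilted ensemble, small rg tends to come with more H-bonds
  ens <- generate_prior("compact", tiny_seq(30), 120, seed = 404)
  rg <- vapply(ens$conformers, radius_of_gyration, numeric(1))
  hb <- vapply(ens$conformers, function(cf) nrow(hbond_assign(cf, 5)), integer(1))
  expect_lt(stats::cor(rg, hb), 0)
})
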