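# Shared fixtures, all built in code at test time.

## A tiny sequence used for fast chain building.
tiny_seq <- function(n = 12) paste(rep("A", n), collapse = "")

## Ideal alpha-helix / extended-strand conformers.
helix_conformer <- function(n = 12) build_chain(tiny_seq(n), sampler_fixed(-60, -45))
extended_conformer <- function(n = 12) build_chain(tiny_seq(n), sampler_fixed(-120, 120))

## Hand-built conformer from explicit per-residue backbone atom positions.
## `atoms` is a data.frame with resno, resid, elety, x, y, z (nm).
manual_conformer <- function(atoms, validate = FALSE) {
  conformer(as.matrix(atoms[, c("x", "y", "z")]), atoms$resno, atoms$resid,
            atoms$elety, validate = validate)
}

## Small cached coil ensemble shared across tests (deterministic).
small_coil <- local({
  cache <- NULL
  function(n = 40, nres = 20, seed = 301) {
    if (is.null(cache))
      cache <<- generate_prior("coil", tiny_seq(nres), n, seed = seed)
    cache
  }
})

## Hydrogen-bond geometry fixture: donor NH of residue 1, acceptor O of
## residue 15 at H...O distance `dHO` (nm) and N-H...O angle `angle_deg`.
mk_hbond_fixture <- function(dHO, angle_deg) {
  a <- data.frame(resno = rep(c(1L, 15L), each = 4),
                  resid = "GLY", elety = rep(c("N", "H", "CA", "O"), 2),
                  x = 0, y = 0, z = 0)
  a[a$resno == 1 & a$elety == "N", c("x", "y", "z")] <- c(-0.1, 0, 0)
  a[a$resno == 1 & a$elety == "CA", c("x", "y", "z")] <- c(-0.1, 0.15, 0)
  a[a$resno == 1 & a$elety == "O", c("x", "y", "z")] <- c(-0.1, -0.5, 0)
  th <- (180 - angle_deg) * pi / 180
  a[a$resno == 15 & a$elety == "O", c("x", "y", "z")] <-
    c(dHO * cos(th), dHO * sin(th), 0)
  a[a$resno == 15 & a$elety == "N", c("x", "y", "z")] <- c(1.5, 1.5, 0)
  a[a$resno == 15 & a$elety == "H", c("x", "y", "z")] <- c(1.6, 1.5, 0)
  a[a$resno == 15 & a$elety == "CA", c("x", "y", "z")] <- c(1.5, 1.6, 0)
  manual_conformer(a)
}

## Pi-contact fixture: two backbone amide planes (residues 1-2 and
## sep_res..sep_res+1) stacked at vertical offset `dz` with the second
## plane's normal tilted by `tilt_deg`.
mk_pi_fixture <- function(dz, tilt_deg, sep_res = 15L) {
  rot <- tilt_deg * pi / 180
  a <- rbind(
    data.frame(resno = 1, elety = c("N", "CA", "C", "O"),
               x = c(-0.2, -0.1, 0, 0.06), y = c(0.1, 0.12, 0, -0.1), z = 0),
    data.frame(resno = 2, elety = c("N", "CA", "C", "O"),
               x = c(0.1, 0.25, 0.3, 0.3), y = c(0.08, 0.1, 0.3, 0.5), z = 0),
    data.frame(resno = sep_res, elety = c("N", "CA", "C", "O"),
               x = c(-0.2, -0.1, 0, 0.06 * cos(rot)),
               y = c(0.1, 0.12, 0, -0.1 * cos(rot)),
               z = c(dz, dz, dz, dz + 0.115 * sin(rot))),
    data.frame(resno = sep_res + 1L, elety = c("N", "CA", "C", "O"),
               x = c(0.1 * cos(rot), 0.25, 0.3, 0.3),
               y = c(0.08, 0.1, 0.3, 0.5),
               z = c(dz + 0.1 * sin(rot), dz, dz, dz)))
  a$resid <- "GLY"
  manual_conformer(a)
}

## Random small linear-observable problem for solver oracle tests:
## N conformers x m observables with synthetic data and sigmas.
random_linear_problem <- function(N, m, seed) {
  set.seed(seed)
  FF <- matrix(stats::rnorm(N * m, 5, 2), N, m)
  w_true <- stats::runif(N); w_true <- w_true / sum(w_true)
  y <- as.numeric(crossprod(w_true, FF)) + stats::rnorm(m, 0, 0.3)
  sg <- stats::runif(m, 0.2, 0.6)
  obs <- observable_set("CS", y, sg,
                        data.frame(resid = seq_len(m), atom = "CA"))
  fm <- structure(list(kind = "CS", F = FF, obs = obs,
                       params = list()), class = "forward_matrix")
  list(fm = fm, obs = obs, prior = rep(1 / N, N))
}

## Exhaustive simplex grid search of the BME objective for N = 2 or 3
## conformers (the independent oracle for the dual solver).
grid_search_bme <- function(fms, prior, theta, omega = 1, step = 0.001) {
  N <- length(prior)
  stopifnot(N %in% c(2L, 3L))
  Lw <- function(w) {
    ct <- 0
    for (f in fms) {
      wt <- if (f$kind == "FRET") omega else 1
      ct <- ct + wt * chi2(w, f)
    }
    0.5 * ct - theta * srel(w, prior)
  }
  g <- seq(0, 1, by = step)
  best <- Inf
  if (N == 2L) {
    for (a in g) best <- min(best, Lw(c(a, 1 - a)))
  } else {
    ## vectorized evaluation over the 2-simplex grid
    ab <- expand.grid(a = g, b = g)
    ab <- ab[ab$a + ab$b <= 1, ]
    W <- cbind(ab$a, ab$b, pmax(1 - ab$a - ab$b, 0))
    ct <- 0
    for (f in fms) {
      wt <- if (f$kind == "FRET") omega else 1
      avg <- W %*% f$F
      ct <- ct + wt * colSums(((t(avg) - f$obs$values) / f$obs$sigmas)^2)
    }
    lw <- suppressWarnings(log(W)); lw[W <= 0] <- 0
    srl <- -rowSums(W * (lw - matrix(log(prior), nrow(W), 3, byrow = TRUE)) * (W > 0))
    best <- min(0.5 * ct - theta * srl)
  }
  best
}
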