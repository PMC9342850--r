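# Simplified forward models: coarse-grained Debye SAXS on CA beads, a
# secondary-structure chemical-shift surrogate, Forster-equation FRET, and a
# point-dipole PRE intensity-ratio model with r^-6 ensemble averaging.

#' Debye scattering profile of a single conformer
#'
#' One Gaussian bead per residue, centred on CA:
#' `I(q) = f(q)^2 * [n + 2 * sum_pairs sin(q r)/(q r)]` with bead form factor
#' `f(q) = exp(-(q*sigma_bead)^2/2)`. The `q -> 0` and `i = j` limits are the
#' analytic `sinc -> 1`.
#'
#' @param conf a [conformer()].
#' @param q scattering vector grid, 1/nm, all `>= 0`.
#' @param sigma_bead Gaussian bead width, nm.
#' @return Intensity vector, arbitrary units (I(0) = n^2 for f = 1).
#' @export
saxs_debye <- function(conf, q, sigma_bead = 0.31) {
  if (any(q < 0)) stop("q must be >= 0")
  ca <- ca_xyz(conf)
  n <- nrow(ca)
  d <- stats::dist(ca)            # all unique pairs
  qr <- outer(as.numeric(q), as.numeric(d))
  s <- sin(qr) / qr
  s[qr < 1e-12] <- 1              # analytic sinc limit
  f2 <- exp(-(q * sigma_bead)^2)  # f(q)^2
  f2 * (n + 2 * rowSums(s))
}

#' Weighted least-squares scale and offset between calculated and observed SAXS
#'
#' Minimizes `sum(((s*calc + c - obs)/sigma)^2)` in closed form. A constant
#' calculated curve is flagged degenerate and fit offset-only (scale fixed
#' at 1).
#'
#' @param calc calculated intensity vector.
#' @param obs an [observable_set()] of kind `"SAXS"` (or a list with
#'   `values` and `sigmas`).
#' @return list with `scale`, `offset`, `fitted` (scaled vector) and
#'   `degenerate` flag.
#' @export
fit_scale_offset <- function(calc, obs) {
  y <- obs$values; sg <- obs$sigmas
  if (length(calc) < 3L) stop("need >= 3 points to fit scale and offset")
  w <- 1 / sg^2
  sw <- sum(w)
  mx <- sum(w * calc) / sw
  my <- sum(w * y) / sw
  vxx <- sum(w * (calc - mx)^2)
  if (vxx < 1e-12 * max(1, mx^2)) {
    off <- my - mx
    return(list(scale = 1, offset = off, fitted = calc + off, degenerate = TRUE))
  }
  s <- sum(w * (calc - mx) * (y - my)) / vxx
  cc <- my - s * mx
  list(scale = s, offset = cc, fitted = s * calc + cc, degenerate = FALSE)
}

#' FRET efficiency of a single conformer
#'
#' `E = 1 / (1 + (r/R0)^6)` with `r` the CA-CA distance between the two
#' labelled residues. Ensemble FRET is the weight-linear average of
#' per-conformer efficiencies.
#'
#' @param conf a [conformer()].
#' @param site_a,site_b residue numbers (PDB numbering) of the dye sites.
#' @param R0 Forster radius, nm.
#' @return Efficiency in `[0, 1]`.
#' @export
fret_efficiency <- function(conf, site_a, site_b, R0) {
  ca <- ca_xyz(conf)
  ures <- unique(conf$resno)
  ia <- match(site_a, ures); ib <- match(site_b, ures)
  if (is.na(ia) || is.na(ib)) stop("unmapped FRET site: ", site_a, "/", site_b)
  r <- vnorm(ca[ia, ] - ca[ib, ])
  1 / (1 + (r / R0)^6)
}

#' PRE model parameters
#'
#' Point-dipole parameters of the simplified Solomon-Bloembergen intensity
#' ratio model. `tau_t` is stored for completeness but unused by the
#' simplified expression.
#'
#' @param tau_c spin-label effective correlation time, s.
#' @param tau_t total correlation time, s (stored, unused).
#' @param t_d total INEPT time, s.
#' @param R2 reduced transverse relaxation rate, Hz.
#' @param omega_H proton Larmor angular frequency, rad/s.
#' @param K point-dipole constant, cm^6 s^-2.
#' @return Object of class `pre_params`.
#' @export
pre_params <- function(tau_c = 2e-9, tau_t = 0.5e-9, t_d = 10e-3, R2 = 10,
                       omega_H = 2 * pi * 500e6, K = 1.23e-32) {
  p <- list(tau_c = tau_c, tau_t = tau_t, t_d = t_d, R2 = R2,
            omega_H = omega_H, K = K)
  if (any(unlist(p) <= 0)) stop("all PRE parameters must be positive")
  class(p) <- "pre_params"
  p
}

## Gamma_2 (1/s) from <r^-6> in nm^-6. 1 nm^-6 = 1e42 cm^-6.
pre_gamma2 <- function(mean_r6_nm, params) {
  spec <- 4 * params$tau_c +
    3 * params$tau_c / (1 + (params$omega_H * params$tau_c)^2)
  params$K * (mean_r6_nm * 1e42) * spec
}

## Intensity ratio in (0, 1] from Gamma_2.
pre_ratio_from_gamma2 <- function(g2, params) {
  params$R2 * exp(-g2 * params$t_d) / (params$R2 + g2)
}

#' PRE intensity ratios for an ensemble
#'
#' The paramagnetic probe is approximated by the CB atom (CA for glycine) of
#' the labelled residue. Per reporting residue, `<r^-6>` is the
#' weight-linear average over conformers of the CB-CB distance to the label,
#' then `Gamma_2 = K * <r^-6> * (4*tau_c + 3*tau_c/(1 + omega_H^2 tau_c^2))`
#' and `ratio = R2 * exp(-Gamma_2 * t_d) / (R2 + Gamma_2)`.
#'
#' @param ens an [ensemble()].
#' @param weights conformer weights (default the ensemble's own).
#' @param label_site residue number carrying the spin label.
#' @param residues reporting residue numbers; the label site itself is
#'   excluded from the output.
#' @param params a [pre_params()] object.
#' @return data.frame with `resid` and `ratio`.
#' @export
pre_intensity_ratio <- function(ens, weights = NULL, label_site, residues,
                                params = pre_params()) {
  if (is.null(weights)) weights <- ens$weights
  weights <- check_weights(weights, length(ens))
  residues <- residues[residues != label_site]
  r6 <- pre_r6_matrix(ens, label_site, residues, params)
  mean_r6 <- as.numeric(crossprod(weights, r6))
  data.frame(resid = residues,
             ratio = pre_ratio_from_gamma2(pre_gamma2(mean_r6, params), params))
}

## Per-conformer r^-6 features (nm^-6): rows conformers, cols residues.
pre_r6_matrix <- function(ens, label_site, residues, params) {
  ures <- unique(ens$conformers[[1L]]$resno)
  il <- match(label_site, ures)
  ir <- match(residues, ures)
  if (is.na(il) || any(is.na(ir)))
    stop("unmapped PRE site or residue for label ", label_site)
  v <- vapply(ens$conformers, function(cf) {
    cb <- cb_or_ca_xyz(cf)
    d <- sqrt(colSums((t(cb[ir, , drop = FALSE]) - cb[il, ])^2))
    d^-6
  }, numeric(length(ir)))
  if (is.matrix(v)) t(v) else matrix(v, ncol = 1L)
}

#' Invert the PRE forward model: ratio -> effective distance
#'
#' Used when treating PRE data as `<r^-6>^(-1/6)` distance restraints. A
#' ratio of exactly 1 has no finite distance solution and returns `Inf`.
#'
#' @param ratio intensity ratio(s) in (0, 1].
#' @param params a [pre_params()] object.
#' @return Effective distance(s), nm.
#' @export
pre_ratio_to_dist <- function(ratio, params = pre_params()) {
  vapply(ratio, function(rr) {
    if (rr >= 1) return(Inf)
    if (rr <= 0) stop("ratio must be in (0, 1]")
    g2 <- stats::uniroot(function(g) pre_ratio_from_gamma2(g, params) - rr,
                         lower = 1e-12, upper = 1e12, tol = 1e-12)$root
    spec <- 4 * params$tau_c +
      3 * params$tau_c / (1 + (params$omega_H * params$tau_c)^2)
    (g2 / (params$K * 1e42 * spec))^(-1 / 6)
  }, numeric(1L))
}

#' Guinier estimate of the radius of gyration from a SAXS profile
#'
#' Weighted linear fit of `ln I` against `q^2` over the Guinier window
#' `q * rg_guess < 1.3`: `ln I = ln I(0) - q^2 Rg^2 / 3`. The standard
#' error propagated from the intensity uncertainties quantifies how
#' precisely the data pin down the ensemble Rg.
#'
#' @param obs a SAXS [observable_set()].
#' @param rg_guess initial Rg guess defining the Guinier window, nm.
#' @return list with `rg` (nm), `se` (nm) and `n_points`.
#' @export
saxs_guinier_rg <- function(obs, rg_guess = 2.5) {
  sel <- obs$meta$q * rg_guess < 1.3 & obs$values > 0
  if (sum(sel) < 3L) stop("fewer than 3 points in the Guinier window")
  q2 <- obs$meta$q[sel]^2
  y <- log(obs$values[sel])
  w <- (obs$values[sel] / obs$sigmas[sel])^2   # var(ln I) = (sigma/I)^2
  fit <- stats::lm(y ~ q2, weights = w)
  rg2 <- -3 * stats::coef(fit)[[2L]]
  if (rg2 <= 0) stop("non-physical Guinier slope")
  se_rg2 <- 3 * sqrt(stats::vcov(fit)[2L, 2L])
  list(rg = sqrt(rg2), se = se_rg2 / (2 * sqrt(rg2)), n_points = sum(sel))
}

## Random-coil CA/CB reference shifts (ppm) by one-letter residue type.
.rc_shifts <- local({
  m <- rbind(
    A = c(52.5, 19.1), R = c(56.0, 30.9), N = c(52.8, 37.9), D = c(54.2, 41.1),
    C = c(58.2, 28.0), Q = c(56.6, 29.4), E = c(56.6, 29.9), G = c(45.1, NA),
    H = c(55.0, 29.0), I = c(61.1, 38.8), L = c(55.1, 42.4), K = c(56.2, 33.1),
    M = c(55.4, 32.9), F = c(57.7, 39.6), P = c(63.3, 32.1), S = c(58.3, 63.8),
    T = c(61.8, 69.8), W = c(57.5, 29.6), Y = c(57.9, 38.8), V = c(62.2, 32.9))
  colnames(m) <- c("CA", "CB")
  m
})

#' Chemical-shift surrogate for CA and CB
#'
#' Random-coil reference shift per residue type plus a secondary-structure
#' offset determined by the 3-class DSSP assignment: helix adds
#' `+delta_helix` to CA (and `-delta_helix` to CB), extended adds
#' `-delta_ext` to CA (`+delta_ext` to CB), coil adds nothing. Glycine has
#' no CB entry.
#'
#' @param conf a [conformer()].
#' @param ss optional precomputed [dssp3()] class vector.
#' @param delta_helix,delta_ext secondary-shift magnitudes, ppm.
#' @return data.frame with `resid`, `atom`, `shift`.
#' @export
cs_predict <- function(conf, ss = NULL, delta_helix = 0.7, delta_ext = 0.7) {
  aa <- strsplit(conf$sequence, "")[[1L]]
  if (any(!aa %in% rownames(.rc_shifts)))
    stop("unknown residue type: ", paste(setdiff(aa, rownames(.rc_shifts)), collapse = ","))
  if (is.null(ss)) ss <- dssp3(conf)
  ures <- unique(conf$resno)
  dca <- ifelse(ss == "helix", delta_helix, ifelse(ss == "extended", -delta_ext, 0))
  out <- data.frame(resid = ures, atom = "CA",
                    shift = .rc_shifts[aa, "CA"] + dca)
  hascb <- aa != "G"
  if (any(hascb)) {
    out <- rbind(out, data.frame(resid = ures[hascb], atom = "CB",
                                 shift = .rc_shifts[aa[hascb], "CB"] - dca[hascb]))
  }
  rownames(out) <- NULL
  out[order(out$resid, out$atom), ]
}

#' Per-conformer forward matrix aligned to an observable set
#'
#' Row `i` is the forward calculation on conformer `i`; columns align to the
#' observable set's data points. For SAXS the rows are unscaled: the
#' scale/offset fit is applied to the weighted-average curve at evaluation
#' time (see [chi2()]).
#'
#' @param ens an [ensemble()].
#' @param obs an [observable_set()].
#' @param config forward-model parameters: `sigma_bead`, `delta_helix`,
#'   `delta_ext`, `pre` (a [pre_params()]).
#' @return Object of class `forward_matrix` with fields `kind`, `F`, `obs`.
#' @export
build_forward_matrix <- function(ens, obs, config = list()) {
  sigma_bead <- config$sigma_bead %||% 0.31
  dh <- config$delta_helix %||% 0.7
  de <- config$delta_ext %||% 0.7
  pp <- config$pre %||% pre_params()
  n <- length(ens)
  as_rows <- function(v) if (is.matrix(v)) t(v) else matrix(v, ncol = 1L)
  FM <- switch(obs$kind,
    SAXS = as_rows(vapply(ens$conformers, saxs_debye, numeric(length(obs)),
                          q = obs$meta$q, sigma_bead = sigma_bead)),
    FRET = {
      m <- obs$meta
      as_rows(vapply(ens$conformers, function(cf)
        vapply(seq_len(nrow(m)), function(k)
          fret_efficiency(cf, m$site_a[k], m$site_b[k], m$R0_nm[k]),
          numeric(1L)), numeric(nrow(m))))
    },
    CS = {
      ## vectorized equivalent of per-conformer cs_predict(): random-coil
      ## reference + class-dependent secondary offsets from dssp3
      ref <- ens$conformers[[1L]]
      aa <- strsplit(ref$sequence, "")[[1L]]
      ures <- unique(ref$resno)
      ir <- match(obs$meta$resid, ures)
      if (any(is.na(ir))) stop("CS observable refers to absent residue/atom")
      is_ca <- obs$meta$atom == "CA"
      if (any(!is_ca & aa[ir] == "G"))
        stop("CS observable refers to absent residue/atom (glycine CB)")
      base <- ifelse(is_ca, .rc_shifts[aa[ir], "CA"], .rc_shifts[aa[ir], "CB"])
      ss <- t(vapply(ens$conformers, dssp3, character(length(ures))))
      dca <- (ss == "helix") * dh - (ss == "extended") * de
      sgn <- ifelse(is_ca, 1, -1)
      matrix(base, n, length(obs), byrow = TRUE) +
        dca[, ir, drop = FALSE] * matrix(sgn, n, length(obs), byrow = TRUE)
    },
    PRE = {
      ## rows are per-conformer INTENSITY RATIOS computed from the
      ## conformer's own r^-6; ensemble averaging of PRE must go through
      ## r^-6 space, so chi2() special-cases PRE via pre_r6_matrix().
      out <- matrix(NA_real_, n, length(obs))
      for (s in unique(obs$meta$label_site)) {
        sel <- obs$meta$label_site == s
        out[, sel] <- pre_r6_matrix(ens, s, obs$meta$resid[sel], pp)
      }
      out
    })
  structure(list(kind = obs$kind, F = FM, obs = obs,
                 params = list(sigma_bead = sigma_bead, delta_helix = dh,
                               delta_ext = de, pre = pp)),
            class = "forward_matrix")
}

#' @export
print.forward_matrix <- function(x, ...) {
  cat("forward matrix:", x$kind, paste(dim(x$F), collapse = " x "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
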