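# Bayesian Maximum Entropy reweighting.
#
# The posterior weights minimize L(w) = 1/2 * chi2_total(w) - theta * S_rel(w)
# over the probability simplex, where chi2_total = chi2_SAXS + chi2_CS +
# Omega * chi2_FRET (non-reduced sums) and S_rel = -sum w_i log(w_i / w0_i).
# The solution has the maximum-entropy exponential-tilt form
# w_i propto w0_i * exp(-sum_m lambda_m F_im); the multipliers are found by
# minimizing the smooth convex dual
#   G(lambda) = log Z(lambda) + sum_m lambda_m y_m + (theta/2) sum_m lambda_m^2 sigma_m^2,
# with the Omega up-weighting of FRET absorbed as sigma_eff = sigma / sqrt(Omega).
# The SAXS scale/offset is re-fit against the weighted-average curve in an
# outer loop around the dual solve.

#' Chi-squared agreement of a weighted ensemble with one observable set
#'
#' Non-reduced sum `sum_m ((<F>_w,m - y_m)/sigma_m)^2` with
#' `<F>_w = t(w) %*% F`. For SAXS, a scale/offset fit of the weighted-average
#' curve against the data precedes the residuals; for PRE, the weighted
#' average runs over the `r^-6` features and is mapped through the intensity
#' ratio model before comparison.
#'
#' @param weights conformer weights.
#' @param fm a [build_forward_matrix()] object.
#' @param obs the aligned [observable_set()] (default `fm$obs`).
#' @return Non-reduced chi-squared (scalar).
#' @export
chi2 <- function(weights, fm, obs = fm$obs) {
  if (length(obs) != ncol(fm$F)) stop("forward matrix and observables misaligned")
  weights <- check_weights(weights, nrow(fm$F))
  avg <- as.numeric(crossprod(weights, fm$F))
  if (fm$kind == "SAXS") {
    avg <- fit_scale_offset(avg, obs)$fitted
  } else if (fm$kind == "PRE") {
    avg <- pre_ratio_from_gamma2(pre_gamma2(avg, fm$params$pre), fm$params$pre)
  }
  sum(((avg - obs$values) / obs$sigmas)^2)
}

#' Relative Shannon entropy of posterior vs prior weights
#'
#' `S_rel = -sum_i w_i log(w_i / w0_i)`, non-positive, zero iff `w == w0`;
#' `0 * log(0)` is taken as 0. The effective fraction of retained
#' conformers is `N_eff = exp(S_rel)`.
#'
#' @param weights posterior weights.
#' @param prior prior weights.
#' @return `S_rel` (scalar, `<= 0`).
#' @export
srel <- function(weights, prior) {
  weights <- check_weights(weights)
  prior <- check_weights(prior, length(weights))
  if (any(weights > 0 & prior == 0))
    stop("support violation: posterior mass where the prior has none")
  pos <- weights > 0
  -sum(weights[pos] * log(weights[pos] / prior[pos]))
}

## Assemble stacked forward matrix, data and effective sigmas from named
## lists of forward matrices / observables. Omega scales FRET sigmas.
bme_stack <- function(fms, omega) {
  kinds <- vapply(fms, `[[`, character(1L), "kind")
  FF <- do.call(cbind, lapply(fms, `[[`, "F"))
  y <- unlist(lapply(fms, function(f) f$obs$values), use.names = FALSE)
  sg <- unlist(lapply(fms, function(f) f$obs$sigmas), use.names = FALSE)
  block <- rep(kinds, vapply(fms, function(f) length(f$obs), integer(1L)))
  sg_eff <- ifelse(block == "FRET", sg / sqrt(omega), sg)
  list(F = FF, y = y, sigma = sg, sigma_eff = sg_eff, block = block)
}

## Convex dual solve at fixed (theta, SAXS scale/offset transform applied to
## the SAXS block of F). Returns lambda and weights.
## Works in sigma-scaled variables (Ft = F/sigma, yt = y/sigma,
## lt = lambda*sigma), where the dual is
##   G(lt) = log Z(lt) + lt.yt + (theta/2)|lt|^2,  Z = sum_i w0_i exp(-Ft_i.lt)
## with gradient  -<Ft>_w + yt + theta*lt  and Hessian  Cov_w(Ft) + theta*I.
## An L-BFGS pass gets close; damped Newton polishes to high precision so
## that scan monotonicity holds to tight tolerance even at small theta.
bme_dual_solve <- function(FF, y, sigma_eff, w0, theta, lambda0 = NULL,
                           tol = 1e-10, max_iter = 2000L) {
  m <- ncol(FF)
  Ft <- sweep(FF, 2L, sigma_eff, "/")
  yt <- y / sigma_eff
  logw0 <- log(w0)
  wts <- function(lt) {
    e <- logw0 - as.numeric(Ft %*% lt)
    mx <- max(e)
    ww <- exp(e - mx)
    list(w = ww / sum(ww), lz = mx + log(sum(ww)))
  }
  obj <- function(lt) {
    p <- wts(lt)
    p$lz + sum(lt * yt) + 0.5 * theta * sum(lt^2)
  }
  grad_at <- function(w, lt) -as.numeric(crossprod(w, Ft)) + yt + theta * lt
  lt <- if (is.null(lambda0)) rep(0, m) else lambda0 * sigma_eff
  fit <- stats::optim(lt, obj, function(l) grad_at(wts(l)$w, l),
                      method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e7))
  lt <- fit$par
  gtol <- 1e-9
  converged <- FALSE
  for (it in seq_len(100L)) {
    p <- wts(lt)
    g <- grad_at(p$w, lt)
    if (max(abs(g)) < gtol) { converged <- TRUE; break }
    Fw <- sqrt(p$w) * Ft
    mu <- as.numeric(crossprod(p$w, Ft))
    H <- crossprod(Fw) - tcrossprod(mu) + diag(theta, m)
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8 * max(diag(H)), m), g))
    f0 <- p$lz + sum(lt * yt) + 0.5 * theta * sum(lt^2)
    a <- 1
    repeat {
      cand <- lt - a * step
      if (obj(cand) <= f0 - 1e-4 * a * sum(g * step) + 1e-14 * abs(f0)) break
      a <- a / 2
      if (a < 1e-6) break
    }
    lt <- lt - a * step
  }
  p <- wts(lt)
  list(lambda = lt / sigma_eff, w = p$w, converged = converged,
       value = obj(lt))
}

#' Solve the BME reweighting problem
#'
#' Minimizes `1/2 * (chi2_SAXS + chi2_CS + Omega * chi2_FRET) - theta * S_rel`
#' in the dual (Lagrange multiplier) parametrization, which enforces
#' positivity and the exponential-tilt posterior form by construction. The
#' SAXS scale/offset is re-fit against the current weighted-average curve in
#' an outer loop.
#'
#' @param fms named list of [build_forward_matrix()] objects (restraints;
#'   any subset of SAXS/CS/FRET).
#' @param prior prior weight vector.
#' @param theta positive confidence hyperparameter.
#' @param omega positive FRET weighting factor.
#' @param lambda0 optional multiplier warm start.
#' @param tol solver tolerance.
#' @param max_iter maximum optimizer iterations.
#' @return Object of class `reweight_result`: `weights`, `lambda`, `theta`,
#'   `omega`, `diagnostics` (list with per-experiment non-reduced and
#'   reduced chi2, `chi2_total`, `chi2_total_reduced`, `srel`, `neff`),
#'   `saxs_fit` (scale/offset), `converged`.
#' @export
bme_solve <- function(fms, prior, theta, omega = 1, lambda0 = NULL,
                      tol = 1e-10, max_iter = 2000L) {
  if (!length(fms)) stop("need at least one restraint set")
  if (theta <= 0 || omega <= 0) stop("theta and omega must be positive")
  prior <- check_weights(prior, nrow(fms[[1L]]$F))
  st <- bme_stack(fms, omega)
  is_saxs <- st$block == "SAXS"
  sc <- list(scale = 1, offset = 0)
  lambda <- lambda0
  w <- prior
  converged <- FALSE
  for (outer in seq_len(if (any(is_saxs)) 30L else 1L)) {
    FF <- st$F
    if (any(is_saxs))
      FF[, is_saxs] <- sc$scale * FF[, is_saxs] + sc$offset
    sol <- bme_dual_solve(FF, st$y, st$sigma_eff, prior, theta, lambda,
                          tol = tol, max_iter = max_iter)
    lambda <- sol$lambda
    w <- sol$w
    if (!any(is_saxs)) { converged <- sol$converged; break }
    avg <- as.numeric(crossprod(w, st$F[, is_saxs, drop = FALSE]))
    newfit <- fit_scale_offset(avg, list(values = st$y[is_saxs],
                                         sigmas = st$sigma[is_saxs]))
    dsc <- abs(newfit$scale - sc$scale) + abs(newfit$offset - sc$offset)
    rel <- dsc / (abs(sc$scale) + abs(sc$offset) + 1e-12)
    sc <- list(scale = newfit$scale, offset = newfit$offset)
    if (rel < 1e-7) { converged <- sol$converged; break }
  }
  diag <- bme_diagnostics(w, fms, prior, omega)
  structure(list(weights = w, lambda = lambda, theta = theta, omega = omega,
                 diagnostics = diag, saxs_fit = sc, converged = converged),
            class = "reweight_result")
}

## Per-experiment diagnostics at given weights.
bme_diagnostics <- function(w, fms, prior, omega) {
  chis <- vapply(fms, function(f) chi2(w, f), numeric(1L))
  m <- vapply(fms, function(f) length(f$obs), integer(1L))
  kinds <- vapply(fms, `[[`, character(1L), "kind")
  names(chis) <- names(m) <- kinds
  wt <- ifelse(kinds == "FRET", omega, 1)
  total <- sum(wt * chis)
  s <- srel(w, prior)
  list(chi2 = chis, chi2_reduced = chis / m, n_points = m,
       chi2_total = total, chi2_total_reduced = total / sum(m),
       srel = s, neff = exp(s))
}

#' @export
print.reweight_result <- function(x, ...) {
  d <- x$diagnostics
  cat("BME reweighting: theta =", x$theta, "omega =", x$omega, "\n")
  cat("  chi2 (reduced):",
      paste(names(d$chi2_reduced), round(d$chi2_reduced, 3), collapse = ", "),
      "\n  chi2_total =", round(d$chi2_total, 3),
      " S_rel =", round(d$srel, 4), " N_eff =", round(d$neff, 4), "\n")
  invisible(x)
}

#' Held-out PRE validation score
#'
#' Per label site, the RMSD between calculated and measured intensity
#' ratios; the final score is the root-mean-square of the per-site RMSDs.
#'
#' @param weights conformer weights.
#' @param ens the [ensemble()] the weights refer to.
#' @param pre_obs an [observable_set()] of kind `"PRE"` (any number of label
#'   sites in its metadata).
#' @param params a [pre_params()] object.
#' @param fm optional precomputed PRE [build_forward_matrix()] for `ens` and
#'   `pre_obs` (avoids recomputing distances across repeated calls).
#' @return The validation score (scalar); attribute `per_site` carries the
#'   per-site RMSDs.
#' @export
pre_validation_score <- function(weights, ens, pre_obs, params = pre_params(),
                                 fm = NULL) {
  if (pre_obs$kind != "PRE") stop("pre_obs must be a PRE observable set")
  sites <- unique(pre_obs$meta$label_site)
  if (!length(sites)) stop("need at least one label site")
  if (is.null(fm)) fm <- build_forward_matrix(ens, pre_obs, list(pre = params))
  weights <- check_weights(weights, nrow(fm$F))
  mean_r6 <- as.numeric(crossprod(weights, fm$F))
  calc <- pre_ratio_from_gamma2(pre_gamma2(mean_r6, params), params)
  rmsds <- vapply(sites, function(s) {
    sel <- pre_obs$meta$label_site == s
    if (!any(sel)) { warning("empty PRE site ", s, " skipped"); return(NA_real_) }
    sqrt(mean((calc[sel] - pre_obs$values[sel])^2))
  }, numeric(1L))
  rmsds <- rmsds[!is.na(rmsds)]
  structure(sqrt(mean(rmsds^2)), per_site = rmsds)
}

#' Scan the confidence hyperparameter theta
#'
#' Solves the BME problem along a descending theta grid (warm-starting each
#' solve from the previous multipliers) and records fit diagnostics plus the
#' held-out PRE validation score at each point.
#'
#' @param fms named list of restraint [build_forward_matrix()] objects.
#' @param prior prior weights.
#' @param theta_grid positive values, sorted descending.
#' @param omega FRET weighting factor.
#' @param validation optional list with `ens`, `pre` (PRE
#'   [observable_set()]) and `params` for the held-out score.
#' @return Object of class `scan_curve`: data.frame `curve` (theta,
#'   chi2 per experiment, chi2_total, srel, neff, pre_score) plus the list
#'   of per-theta weight vectors.
#' @export
theta_scan <- function(fms, prior, theta_grid, omega = 1, validation = NULL) {
  if (is.unsorted(rev(theta_grid), strictly = TRUE))
    stop("theta_grid must be sorted descending")
  lambda <- NULL
  rows <- list()
  weights <- list()
  val_fm <- NULL
  if (!is.null(validation))
    val_fm <- build_forward_matrix(validation$ens, validation$pre,
                                   list(pre = validation$params %||% pre_params()))
  for (k in seq_along(theta_grid)) {
    th <- theta_grid[k]
    res <- tryCatch(bme_solve(fms, prior, th, omega, lambda0 = lambda),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("theta = ", th, " failed: ", conditionMessage(res))
      rows[[k]] <- data.frame(theta = th, chi2_total = NA, srel = NA,
                              neff = NA, pre_score = NA, failed = TRUE)
      weights[[k]] <- rep(NA_real_, length(prior))
      next
    }
    lambda <- res$lambda
    d <- res$diagnostics
    pre <- NA_real_
    if (!is.null(validation))
      pre <- as.numeric(pre_validation_score(res$weights, validation$ens,
                                             validation$pre,
                                             validation$params %||% pre_params(),
                                             fm = val_fm))
    chs <- as.list(d$chi2); names(chs) <- paste0("chi2_", names(chs))
    chr <- as.list(d$chi2_reduced); names(chr) <- paste0("chi2r_", names(chr))
    rows[[k]] <- cbind(data.frame(theta = th), as.data.frame(chs),
                       as.data.frame(chr),
                       data.frame(chi2_total = d$chi2_total,
                                  chi2_total_reduced = d$chi2_total_reduced,
                                  srel = d$srel, neff = d$neff,
                                  pre_score = pre, failed = FALSE))
    weights[[k]] <- res$weights
  }
  structure(list(curve = do.call(rbind, rows), weights = weights,
                 omega = omega), class = "scan_curve")
}

#' @export
print.scan_curve <- function(x, ...) {
  print(x$curve[, c("theta", "chi2_total", "neff", "pre_score")], ...)
  invisible(x)
}

#' Select theta from a scan curve
#'
#' `"elbow"` locates the corner of the L-curve: on the min-max-normalized
#' `(chi2_total, N_eff)` polyline, the interior point with the largest
#' perpendicular distance below the chord joining the curve endpoints (the
#' standard knee criterion; for an ideal L shape it coincides with the
#' maximum-curvature corner but is insensitive to grid spacing).
#' `"validation-minimum"` picks the theta minimizing the held-out PRE
#' score. Ties break toward larger theta (closer to the prior).
#'
#' @param scan a [theta_scan()] result.
#' @param mode `"elbow"` or `"validation-minimum"`.
#' @return Selected theta; attribute `index` gives its grid position.
#' @export
select_theta <- function(scan, mode = c("elbow", "validation-minimum")) {
  mode <- match.arg(mode)
  cv <- scan$curve[!scan$curve$failed, ]
  if (nrow(cv) < 4L) stop("need >= 4 scan points to select theta")
  if (mode == "validation-minimum") {
    if (all(is.na(cv$pre_score))) stop("no validation scores in scan")
    i <- which(cv$pre_score == min(cv$pre_score, na.rm = TRUE))[1L]
  } else {
    norm01 <- function(v) {
      r <- range(v)
      if (diff(r) < 1e-300) rep(0, length(v)) else (v - r[1L]) / diff(r)
    }
    x <- norm01(cv$chi2_total)
    y <- norm01(cv$neff)
    n <- nrow(cv)
    ## signed distance below the endpoint chord a + t*(b - a)
    a <- c(x[1L], y[1L]); b <- c(x[n], y[n])
    ch <- b - a
    len <- vnorm(ch)
    d <- if (len < 1e-300) rep(0, n) else
      abs(ch[1L] * (y - a[2L]) - ch[2L] * (x - a[1L])) / len
    d[c(1L, n)] <- -Inf
    if (max(d[2L:(n - 1L)]) < 1e-6)
      warning("weak elbow: trade-off curve is nearly linear")
    i <- which(d == max(d))[1L]      # grid descending: first index = larger theta
  }
  structure(cv$theta[i], index = i)
}

#' Scan the FRET weighting factor Omega
#'
#' Solves the BME problem at a fixed theta for each Omega in the grid and
#' reports the FRET and SAXS fits, N_eff and (optionally) the PRE score.
#' The selected Omega is the smallest grid value whose reduced FRET
#' chi-squared falls below `fret_target` while the SAXS chi-squared stays
#' within a factor `1 + saxs_tol` of its Omega = 1 value. Without a FRET
#' restraint the scan is vacuous and returns Omega = 1.
#'
#' @param fms named list of restraint forward matrices.
#' @param prior prior weights.
#' @param omega_grid candidate Omega values (>= 2 values; 1 is added if
#'   absent, as the reference point).
#' @param theta fixed theta used for every solve.
#' @param fret_target reduced FRET chi-squared target.
#' @param saxs_tol allowed relative SAXS chi-squared degradation.
#' @param validation optional PRE validation spec as in [theta_scan()].
#' @return list with `omega` (the selection), `table` (per-Omega
#'   diagnostics) and `satisfied` flag.
#' @export
omega_scan <- function(fms, prior, omega_grid = c(1, 5, 10, 25, 50, 75, 100, 150),
                       theta, fret_target = 1, saxs_tol = 0.1,
                       validation = NULL) {
  kinds <- vapply(fms, `[[`, character(1L), "kind")
  if (!"FRET" %in% kinds)
    return(list(omega = 1, table = NULL, satisfied = TRUE))
  if (length(omega_grid) < 2L) stop("omega_grid needs >= 2 values")
  omega_grid <- sort(unique(c(1, omega_grid)))
  rows <- lapply(omega_grid, function(om) {
    res <- bme_solve(fms, prior, theta, om)
    d <- res$diagnostics
    pre <- if (is.null(validation)) NA_real_ else
      as.numeric(pre_validation_score(res$weights, validation$ens,
                                      validation$pre,
                                      validation$params %||% pre_params()))
    data.frame(omega = om,
               chi2_FRET = d$chi2[["FRET"]],
               chi2r_FRET = d$chi2_reduced[["FRET"]],
               chi2_SAXS = if ("SAXS" %in% kinds) d$chi2[["SAXS"]] else NA,
               neff = d$neff, pre_score = pre)
  })
  tab <- do.call(rbind, rows)
  ref_saxs <- tab$chi2_SAXS[tab$omega == 1]
  ok <- tab$chi2r_FRET <= fret_target &
    (is.na(tab$chi2_SAXS) | tab$chi2_SAXS <= (1 + saxs_tol) * ref_saxs)
  if (any(ok)) {
    list(omega = min(tab$omega[ok]), table = tab, satisfied = TRUE)
  } else {
    warning("no Omega satisfies the criteria; returning largest grid value")
    list(omega = max(tab$omega), table = tab, satisfied = FALSE)
  }
}
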