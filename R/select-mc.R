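# Switching Monte-Carlo subset selection under simulated annealing with
# target-normalized pseudo-energies and adaptive restraint weights.
#
# Each restraint carries a pseudo-energy (non-reduced chi2 of the subset
# average for SAXS/CS; a harmonic on <r^-6>^(-1/6) effective distances for
# PRE) normalized by a target energy so that values below 1 count as "fit".
# Every trial swaps one subset member for an outside pool conformer
# (Metropolis acceptance on the weighted total); restraint weights of unfit
# experiments are multiplied up at fixed intervals; the run terminates when
# all normalized energies are <= 1 or the trial budget is exhausted.

#' Pseudo-energy specification for subset selection
#'
#' Target energies default to the number of data points for every restraint
#' (the reduced chi-squared = 1 convention). SAXS/CS residuals are weighted
#' by the measurement sigmas; PRE distance residuals by the per-point
#' distance uncertainty propagated from the ratio uncertainty through the
#' forward model, floored at `dist_tol` (so nearly-flat regions of the
#' ratio-distance curve carry correspondingly weak restraints).
#'
#' @param datasets named list of [observable_set()] restraints (any of
#'   SAXS/CS/PRE).
#' @param targets optional named numeric overrides of the target energies.
#' @param gamma multiplicative weight increase for unfit restraints.
#' @param K trials between weight adaptations.
#' @param omega_max cap on adaptive restraint weights.
#' @param dist_tol floor on the propagated PRE distance uncertainty, nm.
#' @param ratio_max PRE ratios above this carry no distance restraint.
#' @return Object of class `pseudo_energy_spec`.
#' @export
pseudo_energy_spec <- function(datasets, targets = NULL, gamma = 1.2, K = 100,
                               omega_max = 1e3, dist_tol = 0.1,
                               ratio_max = 0.95) {
  kinds <- vapply(datasets, `[[`, character(1L), "kind")
  def <- vapply(datasets, function(d) length(d), numeric(1L))
  names(def) <- kinds
  if (!is.null(targets)) def[names(targets)] <- unlist(targets)
  if (any(def <= 0)) stop("target energies must be positive")
  structure(list(targets = def, gamma = gamma, K = K, omega_max = omega_max,
                 dist_tol = dist_tol, ratio_max = ratio_max, kinds = kinds),
            class = "pseudo_energy_spec")
}

## |d ratio / d distance| of the PRE forward model at distance d (nm).
pre_dratio_dd <- function(d, params) {
  spec <- 4 * params$tau_c +
    3 * params$tau_c / (1 + (params$omega_H * params$tau_c)^2)
  g2 <- params$K * 1e42 * spec * d^-6
  ratio <- pre_ratio_from_gamma2(g2, params)
  ratio * (params$t_d + 1 / (params$R2 + g2)) * 6 * g2 / d
}

## Precompute per-conformer feature matrices for fast subset updates.
## SAXS/CS: forward rows; PRE: r^-6 features plus back-converted target
## distances (ratio -> <r^-6>^(-1/6)); FRET (validation): per-conformer E.
mc_precompute <- function(pool, datasets, config = list(), dist_tol = 0.1,
                          ratio_max = 0.95, M = NULL, rep_samples = 32L) {
  pp <- config$pre %||% pre_params()
  feats <- lapply(datasets, function(obs) {
    fm <- build_forward_matrix(pool, obs, config)
    if (obs$kind == "PRE") {
      ## effective-distance restraints in three regimes of the ratio:
      ## informative mid-range ratios -> two-sided harmonic at the
      ## back-converted distance; bleached residues (ratio within noise of
      ## 0) -> upper bound only; flat high ratios (> ratio_max, incl. 1
      ## where d -> Inf) -> lower bound at d(ratio_max), the unbleached
      ## long-range information
      d_t <- pre_ratio_to_dist(obs$values, pp)
      sigma_d <- pmax(obs$sigmas / pre_dratio_dd(pmin(d_t, 1e6), pp), dist_tol)
      lower <- !is.finite(d_t) | obs$values > ratio_max
      d_bound <- pre_ratio_to_dist(ratio_max, pp)
      sig_bound <- max(mean(obs$sigmas) / pre_dratio_dd(d_bound, pp), dist_tol)
      d_t[lower] <- d_bound
      sigma_d[lower] <- sig_bound
      upper <- !lower & obs$values <= 3 * obs$sigmas
      ## a size-M subset represents the pool's r^-6 averages only up to a
      ## sampling error that dominates the measurement noise for r^-6
      ## statistics; fold that representation error into the tolerance so
      ## the target energy remains the achievable reduced-chi2 = 1
      if (!is.null(M) && M < length(pool)) {
        seed_state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        set.seed(190354)
        sig_rep <- apply(vapply(seq_len(rep_samples), function(b) {
          idx <- sample.int(length(pool), M)
          colMeans(fm$F[idx, , drop = FALSE])^(-1 / 6)
        }, numeric(ncol(fm$F))), 1L, stats::sd)
        if (!is.null(seed_state)) assign(".Random.seed", seed_state, globalenv())
        sigma_d <- sqrt(sigma_d^2 + sig_rep^2)
      }
      list(kind = "PRE", F = fm$F, d_target = d_t, sigma_d = sigma_d,
           side = ifelse(lower, 1L, ifelse(upper, -1L, 0L)))
    } else {
      list(kind = obs$kind, F = fm$F, values = obs$values, sigmas = obs$sigmas)
    }
  })
  names(feats) <- vapply(datasets, `[[`, character(1L), "kind")
  feats
}

## Raw pseudo-energy of one restraint given the subset column sums and size.
mc_energy_one <- function(ft, colsum, M) {
  avg <- colsum / M
  if (ft$kind == "PRE") {
    r <- (avg^(-1 / 6) - ft$d_target) / ft$sigma_d
    r[(ft$side == -1L & r < 0) | (ft$side == 1L & r > 0)] <- 0
    sum(r^2)
  } else {
    sum(((avg - ft$values) / ft$sigmas)^2)
  }
}

#' Pseudo-energies of a conformer subset
#'
#' Raw and target-normalized pseudo-energies of the uniform-weight subset
#' average against each restraint; a normalized value below 1 marks the
#' restraint as fit.
#'
#' @param subset integer indices into the pool.
#' @param pool the pool [ensemble()].
#' @param datasets named list of restraint [observable_set()]s.
#' @param spec a [pseudo_energy_spec()].
#' @param config forward-model configuration (see [build_forward_matrix()]).
#' @return data.frame with `kind`, `raw`, `normalized`, `fit`.
#' @export
pseudo_energies <- function(subset, pool, datasets, spec = pseudo_energy_spec(datasets),
                            config = list()) {
  if (!length(subset)) stop("subset must be non-empty")
  feats <- mc_precompute(pool, datasets, config, dist_tol = spec$dist_tol %||% 0.1,
                         ratio_max = spec$ratio_max %||% 0.95, M = length(subset))
  raw <- vapply(feats, function(ft)
    mc_energy_one(ft, colSums(ft$F[subset, , drop = FALSE]), length(subset)),
    numeric(1L))
  normalized <- raw / spec$targets[names(feats)]
  data.frame(kind = names(feats), raw = raw, normalized = normalized,
             fit = normalized < 1, row.names = NULL)
}

#' Single-run annealed subset selection
#'
#' @param pool the pool [ensemble()].
#' @param datasets named list of restraint [observable_set()]s (SAXS/CS/PRE).
#' @param M subset size.
#' @param spec a [pseudo_energy_spec()].
#' @param schedule list with `T0` (initial temperature, normalized-energy
#'   units), `alpha` (cooling factor per stage), `trials_per_T`.
#' @param budget maximum number of trials.
#' @param seed RNG seed (the run is deterministic given the seed).
#' @param config forward-model configuration.
#' @param validation optional FRET [observable_set()] scored as `z_E` along
#'   the trace (never part of the energy).
#' @param trace record the per-trial energy table (default TRUE).
#' @param feats precomputed [mc_precompute()] features (internal reuse).
#' @param settle after the fit criterion is met, number of additional
#'   Metropolis trials confined to the fit region (decorrelation from the
#'   first-passage boundary; 0 disables).
#' @return Object of class `selection_run`: `selected` (indices),
#'   `converged`, `trials`, `energies` (final normalized), `trace`
#'   (data.frame per trial), `restraint_weights`.
#' @export
anneal_select <- function(pool, datasets, M,
                          spec = pseudo_energy_spec(datasets),
                          schedule = list(T0 = 1, alpha = 0.95, trials_per_T = 200),
                          budget = 5e4, seed = 1, config = list(),
                          validation = NULL, trace = TRUE, feats = NULL,
                          settle = 2000L) {
  n <- length(pool)
  if (M > n) stop("subset size M exceeds pool size")
  set.seed(seed)
  if (is.null(feats))
    feats <- mc_precompute(pool, datasets, config, dist_tol = spec$dist_tol %||% 0.1,
                           ratio_max = spec$ratio_max %||% 0.95, M = M)
  nk <- length(feats)
  kindv <- names(feats)
  targets <- spec$targets[kindv]
  omega_x <- rep(1, nk); names(omega_x) <- kindv
  fretE <- NULL
  if (!is.null(validation)) {
    fm <- build_forward_matrix(pool, validation, config)
    fretE <- as.numeric(fm$F[, 1L])
  }
  ## flattened, transposed features for cheap per-trial column updates
  tF <- do.call(rbind, lapply(feats, function(ft) t(ft$F)))
  mks <- vapply(feats, function(ft) ncol(ft$F), integer(1L))
  seg_end <- cumsum(mks)
  seg <- lapply(seq_len(nk), function(k)
    (c(0L, seg_end)[k] + 1L):seg_end[k])
  evals <- lapply(seq_len(nk), function(k) {
    ft <- feats[[k]]
    if (ft$kind == "PRE") {
      dt <- ft$d_target; isd <- 1 / ft$sigma_d
      up <- ft$side == -1L; lo <- ft$side == 1L
      function(avg) {
        r <- (avg^(-1 / 6) - dt) * isd
        r[(up & r < 0) | (lo & r > 0)] <- 0
        sum(r^2)
      }
    } else {
      y <- ft$values; iv <- 1 / ft$sigmas^2
      function(avg) sum(iv * (avg - y)^2)
    }
  })
  energies_of <- function(cs) {
    vapply(seq_len(nk), function(k) evals[[k]](cs[seg[[k]]] / M), numeric(1L))
  }
  subset <- sample.int(n, M)
  inset <- logical(n); inset[subset] <- TRUE
  colsums <- rowSums(tF[, subset, drop = FALSE])
  raw <- energies_of(colsums)
  norm_e <- raw / targets
  tr <- if (trace) matrix(NA_real_, as.integer(budget), nk + 2L) else NULL
  trial <- 0L
  converged <- all(norm_e <= 1)
  while (!converged && trial < budget) {
    trial <- trial + 1L
    temp <- schedule$T0 * schedule$alpha^((trial - 1L) %/% schedule$trials_per_T)
    out_i <- subset[sample.int(M, 1L)]
    repeat {
      in_i <- sample.int(n, 1L)
      if (!inset[in_i]) break
    }
    newsums <- colsums + tF[, in_i] - tF[, out_i]
    newraw <- energies_of(newsums)
    newnorm <- newraw / targets
    dE <- sum(omega_x * (newnorm - norm_e))
    if (dE <= 0 || stats::runif(1L) < exp(-dE / temp)) {
      inset[out_i] <- FALSE; inset[in_i] <- TRUE
      subset[subset == out_i] <- in_i
      colsums <- newsums
      raw <- newraw
      norm_e <- newnorm
    }
    if (trace) {
      z <- if (is.null(fretE)) NA_real_ else
        abs(sum(fretE[subset]) / M - validation$values[1L]) / validation$sigmas[1L]
      tr[trial, ] <- c(norm_e, temp, z)
    }
    if (trial %% spec$K == 0L)
      omega_x[norm_e > 1] <- pmin(omega_x[norm_e > 1] * spec$gamma,
                                  spec$omega_max %||% 1e3)
    converged <- all(norm_e <= 1)
  }
  ## Decorrelation within the fit region: the first subset to satisfy all
  ## targets sits on the region boundary reached from the starting side,
  ## which biases combined ensembles toward the prior pool. A constrained
  ## Metropolis walk at the termination temperature (moves leaving the fit
  ## region rejected) returns a more typical member of the acceptable set.
  ## Termination is still governed by the fit criterion.
  if (converged && settle > 0L && M < n) {
    temp <- schedule$T0 * schedule$alpha^(trial %/% schedule$trials_per_T)
    for (k in seq_len(settle)) {
      out_i <- subset[sample.int(M, 1L)]
      repeat {
        in_i <- sample.int(n, 1L)
        if (!inset[in_i]) break
      }
      newsums <- colsums + tF[, in_i] - tF[, out_i]
      newraw <- energies_of(newsums)
      newnorm <- newraw / targets
      if (any(newnorm > 1)) next
      dE <- sum(omega_x * (newnorm - norm_e))
      if (dE <= 0 || stats::runif(1L) < exp(-dE / max(temp, 1e-8))) {
        inset[out_i] <- FALSE; inset[in_i] <- TRUE
        subset[subset == out_i] <- in_i
        colsums <- newsums
        raw <- newraw
        norm_e <- newnorm
      }
    }
  }
  if (trace) {
    tr <- tr[seq_len(trial), , drop = FALSE]
    colnames(tr) <- c(paste0("norm_", kindv), "temperature", "z_E")
    tr <- as.data.frame(tr)
    tr <- cbind(trial = seq_len(trial), tr)
  }
  structure(list(selected = sort(subset), converged = converged,
                 trials = trial, energies = stats::setNames(norm_e, kindv),
                 raw_energies = stats::setNames(raw, kindv),
                 total_energy = sum(omega_x * norm_e),
                 restraint_weights = omega_x, trace = tr, seed = seed),
            class = "selection_run")
}

#' @export
print.selection_run <- function(x, ...) {
  cat("annealed selection:", length(x$selected), "conformers,",
      x$trials, "trials,", if (x$converged) "converged" else "NOT converged", "\n")
  cat("  normalized energies:",
      paste(names(x$energies), round(x$energies, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Replicated subset selection and combination
#'
#' Runs `n_runs` independent annealed selections of `M` conformers and
#' concatenates the selected subsets into one combined ensemble with uniform
#' weights (the 5 x 100 -> 500 protocol). Reports the mean and standard
#' deviation of terminal total energies and trial counts across runs, and
#' the FRET z-score of the combined ensemble when a validation set is given.
#'
#' @inheritParams anneal_select
#' @param n_runs number of independent runs.
#' @param seeds integer seeds, one per run.
#' @return Object of class `selection_result`: `runs` (list of
#'   [anneal_select()] results), `combined` (ensemble), `indices`,
#'   `energy_mean`, `energy_sd`, `trials_mean`, `trials_sd`, `z_E`,
#'   `all_converged`.
#' @export
run_replicates <- function(pool, datasets, n_runs = 5, M = 100,
                           spec = pseudo_energy_spec(datasets),
                           schedule = list(T0 = 1, alpha = 0.95, trials_per_T = 200),
                           budget = 5e4, seeds = seq_len(n_runs),
                           config = list(), validation = NULL, trace = TRUE,
                           settle = 2000L) {
  stopifnot(length(seeds) == n_runs)
  feats <- mc_precompute(pool, datasets, config, dist_tol = spec$dist_tol %||% 0.1,
                         ratio_max = spec$ratio_max %||% 0.95, M = M)
  runs <- lapply(seeds, function(s)
    anneal_select(pool, datasets, M, spec, schedule, budget, seed = s,
                  config = config, validation = validation, trace = trace,
                  feats = feats, settle = settle))
  idx <- unlist(lapply(runs, `[[`, "selected"))
  combined <- ensemble(pool$conformers[idx])
  tot <- vapply(runs, `[[`, numeric(1L), "total_energy")
  trl <- vapply(runs, `[[`, numeric(1L), "trials")
  z <- NA_real_
  if (!is.null(validation)) z <- z_test_fret(combined, validation, config)
  structure(list(runs = runs, combined = combined, indices = idx,
                 energy_mean = mean(tot), energy_sd = stats::sd(tot),
                 trials_mean = mean(trl), trials_sd = stats::sd(trl),
                 z_E = z,
                 all_converged = all(vapply(runs, `[[`, logical(1L), "converged"))),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("combined selection ensemble:", length(x$combined), "conformers from",
      length(x$runs), "runs;",
      "energy", round(x$energy_mean, 1), "+/-", round(x$energy_sd, 1),
      "; trials", round(x$trials_mean), "+/-", round(x$trials_sd),
      "; z_E =", round(x$z_E, 3), "\n")
  invisible(x)
}

#' FRET z-test of an ensemble against a measured efficiency
#'
#' `z_E = |E_ens - E_exp| / sigma` with `E_ens` the uniform-weight ensemble
#' average of per-conformer efficiencies.
#'
#' @param ens an [ensemble()].
#' @param fret_obs a FRET [observable_set()] with one pair.
#' @param config forward-model configuration.
#' @return z-score (scalar).
#' @export
z_test_fret <- function(ens, fret_obs, config = list()) {
  if (fret_obs$sigmas[1L] <= 0) stop("sigma must be positive")
  fm <- build_forward_matrix(ens, fret_obs, config)
  e_ens <- mean(fm$F[, 1L])
  abs(e_ens - fret_obs$values[1L]) / fret_obs$sigmas[1L]
}

#' Replenish a selection pool, favouring rarely selected conformers
#'
#' Removes `n_new` conformers drawn with probability proportional to
#' `counts + 1` (so frequently selected conformers are the most likely to be
#' replaced and ties are uniform) and appends `n_new` freshly generated
#' conformers whose counts start at zero. The pool size is preserved.
#'
#' @param pool the pool [ensemble()].
#' @param generator function of `n` returning a list of `n` new
#'   [conformer()]s.
#' @param counts per-conformer selection counts.
#' @param n_new number of conformers to replace.
#' @return list with `pool` (new ensemble) and `counts`.
#' @export
replenish_pool <- function(pool, generator, counts,
                           n_new = ceiling(0.1 * length(pool))) {
  n <- length(pool)
  stopifnot(length(counts) == n, n_new >= 1L, n_new < n)
  drop <- sample.int(n, n_new, prob = counts + 1)
  keep <- setdiff(seq_len(n), drop)
  fresh <- generator(n_new)
  list(pool = ensemble(c(pool$conformers[keep], fresh)),
       counts = c(counts[keep], rep(0L, n_new)))
}
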