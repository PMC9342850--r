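# End-to-end synthetic study: three contrasting priors, one synthetic
# dataset, two optimization methods, six analysed posteriors.

#' Default study configuration
#'
#' All module parameters of the six-way comparison (3 priors x 2 methods) in
#' one nested list. The restraint/validation split is fixed by construction:
#' BME restrains SAXS + CS + FRET and validates against PRE; subset
#' selection restrains SAXS + CS + PRE and validates against FRET.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n conformers per prior ensemble.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 42, n = 1000) {
  list(
    seed = seed,
    synthetic = list(
      n = n, sequence = default_sequence(), oversample = 2,
      q_grid = seq(0.1, 3.0, length.out = 40),
      fret = list(site_a = 1, site_b = 90, R0 = 6.0),
      pre_sites = c(1, 21, 38, 64, 83, 90),
      noise = list(saxs_rel = 0.02, cs_sigma = 0.4, fret_sigma = 0.03,
                   pre_sigma = 0.05),
      truth = list(feature = "Rg", coefficient = -0.5)),
    forward = list(sigma_bead = 0.31, delta_helix = 0.7, delta_ext = 0.7,
                   pre = pre_params()),
    bme = list(theta_grid = 10^seq(3, -2, length.out = 12), omega = 75,
               omega_grid = c(1, 5, 10, 25, 50, 75, 100, 150),
               theta_mode = "elbow"),
    mc = list(M = 100, n_runs = 5,
              schedule = list(T0 = 1, alpha = 0.95, trials_per_T = 200),
              budget = 5e4, gamma = 1.2, K = 100, dist_tol = 0.1),
    analysis = list(min_separation = 10, B = 1000, d_max = 0.49, a_max = 40)
  )
}

#' Run the full synthetic comparison study
#'
#' Generates the three prior ensembles (coil, matched, compact), synthesizes
#' one shared experimental dataset from a ground-truth reweighting of the
#' matched prior, optimizes each prior with both methods, analyses the six
#' posteriors and writes a deterministic directory tree:
#' `priors/`, `data/`, `bme/`, `mc/`, `analysis/`, `report.tsv`, `log.txt`.
#'
#' @param config a [default_config()]-shaped list.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return The study report data.frame (6 rows: prior x method),
#'   invisibly the same as written to `report.tsv`; attribute `posteriors`
#'   carries the weighted posterior ensembles.
#' @export
run_study <- function(config = default_config(), out_dir = tempfile("study"),
                      quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  for (d in c("", "priors", "data", "bme", "mc", "analysis"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste("seed:", config$seed), paste("n:", config$synthetic$n))
  syn <- config$synthetic
  fwd <- config$forward

  say("generating priors ...")
  priors <- list(
    coil    = generate_prior("coil", syn$sequence, syn$n, seed = config$seed + 1L),
    matched = generate_prior("matched", syn$sequence, syn$n, seed = config$seed + 2L),
    compact = generate_prior("compact", syn$sequence, syn$n, seed = config$seed + 3L,
                             oversample = syn$oversample))
  for (nm in names(priors))
    write_ensemble(priors[[nm]], file.path(out_dir, "priors", paste0(nm, ".pdb")))

  say("synthesizing experiments from the matched-prior ground truth ...")
  truth <- make_ground_truth(priors$matched, syn$truth$feature, syn$truth$coefficient)
  data <- synthesize_experiments(priors$matched, truth, syn$noise,
                                 seed = config$seed + 10L, q_grid = syn$q_grid,
                                 fret = syn$fret, pre_sites = syn$pre_sites,
                                 config = fwd)
  for (nm in names(data))
    write_observables(data[[nm]], file.path(out_dir, "data", paste0(nm, ".tsv")))
  log_lines <- c(log_lines,
                 paste("truth tilt:", syn$truth$feature, syn$truth$coefficient),
                 paste("truth mean Rg:",
                       signif(radius_of_gyration(priors$matched, truth$true_weights), 6)))

  rows <- list()
  posteriors <- list()
  for (nm in names(priors)) {
    pool <- priors[[nm]]

    ## --- BME: restrain SAXS + CS + FRET, validate on PRE -----------------
    say("BME reweighting of the ", nm, " prior ...")
    fms <- list(SAXS = build_forward_matrix(pool, data$saxs, fwd),
                CS = build_forward_matrix(pool, data$cs, fwd),
                FRET = build_forward_matrix(pool, data$fret, fwd))
    scan <- theta_scan(fms, pool$weights, config$bme$theta_grid,
                       omega = config$bme$omega,
                       validation = list(ens = pool, pre = data$pre,
                                         params = fwd$pre))
    theta <- select_theta(scan, config$bme$theta_mode)
    w <- scan$weights[[attr(theta, "index")]]
    res <- bme_solve(fms, pool$weights, as.numeric(theta), config$bme$omega)
    utils::write.table(scan$curve, file.path(out_dir, "bme", paste0(nm, "_scan.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_weights(res$weights, file.path(out_dir, "bme", paste0(nm, "_weights.tsv")))
    d <- res$diagnostics
    pre_score <- as.numeric(pre_validation_score(res$weights, pool, data$pre, fwd$pre))
    log_lines <- c(log_lines, paste0("bme/", nm, ": theta=", signif(theta, 4),
                                     " omega=", config$bme$omega,
                                     " converged=", res$converged))
    an <- analyse_posterior(pool, res$weights, config)
    rows[[length(rows) + 1L]] <- data.frame(
      prior = nm, method = "BME",
      chi2r_SAXS = d$chi2_reduced[["SAXS"]], chi2r_CS = d$chi2_reduced[["CS"]],
      chi2r_FRET = d$chi2_reduced[["FRET"]],
      chi2_total_reduced = d$chi2_total_reduced,
      neff_or_trials = d$neff, validation = pre_score, an)
    posteriors[[paste0(nm, "_BME")]] <- list(ens = pool, weights = res$weights)

    ## --- subset selection: restrain SAXS + CS + PRE, validate on FRET ----
    say("subset selection from the ", nm, " prior ...")
    datasets <- list(SAXS = data$saxs, CS = data$cs, PRE = data$pre)
    spec <- pseudo_energy_spec(datasets, gamma = config$mc$gamma,
                               K = config$mc$K, dist_tol = config$mc$dist_tol)
    sel <- run_replicates(pool, datasets, n_runs = config$mc$n_runs,
                          M = config$mc$M, spec = spec,
                          schedule = config$mc$schedule, budget = config$mc$budget,
                          seeds = config$seed + 100L + seq_len(config$mc$n_runs),
                          config = fwd, validation = data$fret)
    for (k in seq_along(sel$runs)) {
      tr <- sel$runs[[k]]$trace
      if (!is.null(tr))
        utils::write.table(tr[seq(1L, nrow(tr), by = max(1L, nrow(tr) %/% 2000L)), ],
                           file.path(out_dir, "mc", paste0(nm, "_run", k, "_trace.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_weights(sel$combined$weights,
                  file.path(out_dir, "mc", paste0(nm, "_weights.tsv")))
    write_ensemble(sel$combined, file.path(out_dir, "mc", paste0(nm, "_combined.pdb")))
    chi_saxs <- chi2(sel$combined$weights,
                     build_forward_matrix(sel$combined, data$saxs, fwd))
    chi_cs <- chi2(sel$combined$weights,
                   build_forward_matrix(sel$combined, data$cs, fwd))
    log_lines <- c(log_lines, paste0("mc/", nm, ": trials=", sel$trials_mean,
                                     "+/-", signif(sel$trials_sd, 3),
                                     " converged=", sel$all_converged,
                                     " z_E=", signif(sel$z_E, 4)))
    an <- analyse_posterior(sel$combined, sel$combined$weights, config)
    rows[[length(rows) + 1L]] <- data.frame(
      prior = nm, method = "MC",
      chi2r_SAXS = chi_saxs / length(data$saxs), chi2r_CS = chi_cs / length(data$cs),
      chi2r_FRET = NA_real_,
      chi2_total_reduced = NA_real_,
      neff_or_trials = sel$trials_mean, validation = sel$z_E, an)
    posteriors[[paste0(nm, "_MC")]] <- list(ens = sel$combined,
                                            weights = sel$combined$weights)
  }

  report <- do.call(rbind, rows)
  utils::write.table(format(report, digits = 8), file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  say("study written to ", out_dir)
  attr(report, "posteriors") <- posteriors
  attr(report, "out_dir") <- out_dir
  invisible(report)
}

## Weighted structural summary of one posterior: mean Rg, mean helix
## propensity, long-range H-bond and pi-contact means.
analyse_posterior <- function(ens, weights, config) {
  ana <- config$analysis
  ssp <- ss_propensity(ens, weights)
  hb <- vapply(ens$conformers,
               function(cf) nrow(hbond_assign(cf, ana$min_separation)), integer(1L))
  pc <- vapply(ens$conformers, function(cf)
    pi_contacts(cf, ana$d_max, ana$a_max, ana$min_separation)[["bb_bb"]],
    integer(1L))
  data.frame(mean_rg = radius_of_gyration(ens, weights),
             helix_prop = mean(ssp$propensity[, "helix"]),
             n_hbonds = sum(weights * hb),
             n_pipi = sum(weights * pc))
}

#' Prior-versus-method variance decomposition of a study report
#'
#' For each numeric summary statistic in the report: the between-prior
#' spread (range over priors of the per-prior method means) and the
#' between-method spread (range over methods of the per-method prior
#' means), plus a flag for which dominates.
#'
#' @param report data.frame from [run_study()] (needs `prior`, `method`
#'   and at least one numeric column).
#' @return data.frame with `statistic`, `prior_spread`, `method_spread`,
#'   `dominant`.
#' @export
compare_report <- function(report) {
  if (length(unique(report$prior)) < 2L || length(unique(report$method)) < 2L)
    stop("need >= 2 priors and >= 2 methods")
  stats_cols <- names(report)[vapply(report, is.numeric, logical(1L))]
  out <- lapply(stats_cols, function(cl) {
    v <- report[[cl]]
    pm <- tapply(v, report$prior, mean, na.rm = TRUE)
    mm <- tapply(v, report$method, mean, na.rm = TRUE)
    if (any(!is.finite(pm)) || any(!is.finite(mm))) return(NULL)
    ps <- diff(range(pm)); ms <- diff(range(mm))
    data.frame(statistic = cl, prior_spread = ps, method_spread = ms,
               dominant = if (ps > ms) "prior" else "method")
  })
  do.call(rbind, out)
}
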