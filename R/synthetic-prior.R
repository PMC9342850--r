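# Synthetic study system: contrasting prior ensembles for a 90-residue
# disordered chain and "experimental" datasets synthesized from a known
# ground-truth reweighting.

#' Default 90-residue disordered sequence
#'
#' A serine/threonine-rich sequence with no negatively charged residues,
#' several aromatics and dispersed prolines — the compositional profile of
#' an N-terminal CDK-inhibitor degron region.
#'
#' @return One-letter sequence string (90 residues).
#' @export
default_sequence <- function() {
  paste0("MTPSTPPRSR", "GTQAQNKLTS", "AAKQLMGSVN", "STPKSQYRTN", "AAFPTKQSLL",
         "SAQNSPMKAQ", "GTFNHKTPSS", "VKAMLQSNFG", "RPTWTSKSAQ")
}

#' Prior ensemble styles
#'
#' Three contrasting statistical models for prior pools:
#' * `coil`: excluded-volume statistical coil (3-basin torsion library);
#' * `matched`: coil plus transient helical segments;
#' * `compact`: transient helices plus a global compaction bias, applied as
#'   an exponential tilt toward low radius of gyration when resampling from
#'   an oversampled pool (so the compaction strength is exactly
#'   controllable).
#'
#' @param name `"coil"`, `"matched"` or `"compact"`.
#' @param helix_segments data.frame with `start`, `end` (residue numbers)
#'   and `propensity` in `[0, 1]`; defaults depend on `name`.
#' @param compaction_bias exponential tilt strength on Rg, 1/nm, `>= 0`.
#' @param basin_probs coil basin probabilities (see [sampler_basin()]).
#' @param jitter_sd torsion jitter, degrees.
#' @return Object of class `prior_style`.
#' @export
prior_style <- function(name = c("coil", "matched", "compact"),
                        helix_segments = NULL, compaction_bias = NULL,
                        basin_probs = c(helix = 0.30, extended = 0.60, left = 0.10),
                        jitter_sd = 12) {
  name <- match.arg(name)
  if (is.null(helix_segments)) {
    helix_segments <- switch(name,
      coil = data.frame(start = integer(), end = integer(), propensity = numeric()),
      matched = data.frame(start = c(12, 40, 62), end = c(22, 50, 72),
                           propensity = c(0.45, 0.35, 0.45)),
      ## same transient helices as `matched`; the compact style differs only
      ## by the global compaction tilt
      compact = data.frame(start = c(12, 40, 62), end = c(22, 50, 72),
                           propensity = c(0.45, 0.35, 0.45)))
  }
  if (is.null(compaction_bias))
    compaction_bias <- if (name == "compact") 3 else 0
  stopifnot(all(helix_segments$propensity >= 0 & helix_segments$propensity <= 1),
            compaction_bias >= 0)
  structure(list(name = name, helix_segments = helix_segments,
                 compaction_bias = compaction_bias, basin_probs = basin_probs,
                 jitter_sd = jitter_sd), class = "prior_style")
}

#' Generate a prior ensemble of a given style
#'
#' Grows `n` self-avoiding chains ([build_chain()]). Helical segments are
#' switched on per conformer with their propensity probability; active
#' segments sample the helical basin with small jitter. A positive
#' compaction bias generates `oversample * n` chains and resamples `n` of
#' them without replacement with probability proportional to
#' `exp(-bias * Rg)`.
#'
#' @param style a [prior_style()] (or style name).
#' @param sequence one-letter sequence.
#' @param n number of conformers.
#' @param seed RNG seed; the ensemble is deterministic given the seed.
#' @param oversample pool multiplier used when `compaction_bias > 0`.
#' @return An [ensemble()] with uniform prior weights.
#' @export
generate_prior <- function(style = prior_style("coil"),
                           sequence = default_sequence(), n, seed = 1,
                           oversample = 2) {
  if (is.character(style)) style <- prior_style(style)
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  seg <- style$helix_segments
  n_grow <- if (style$compaction_bias > 0) ceiling(oversample * n) else n
  coil_sampler <- sampler_basin(style$basin_probs, style$jitter_sd)
  confs <- vector("list", n_grow)
  for (k in seq_len(n_grow)) {
    active <- if (nrow(seg)) stats::runif(nrow(seg)) < seg$propensity else logical()
    in_helix <- rep(FALSE, nchar(sequence))
    for (s in which(active)) in_helix[seg$start[s]:seg$end[s]] <- TRUE
    sampler <- function(i) {
      if (in_helix[i]) .basins["helix", ] + stats::rnorm(2L, 0, 5) else coil_sampler(i)
    }
    confs[[k]] <- build_chain(sequence, sampler)
  }
  if (style$compaction_bias > 0 && n_grow > n) {
    rg <- vapply(confs, radius_of_gyration, numeric(1L))
    lw <- -style$compaction_bias * rg
    p <- exp(lw - max(lw))
    keep <- sample.int(n_grow, n, prob = p / sum(p))
    confs <- confs[keep]
  }
  ensemble(confs)
}

#' Define a ground-truth reweighting by an exponential tilt
#'
#' True weights `w_i propto w0_i * exp(-coefficient * feature_i)` with the
#' feature either the per-conformer radius of gyration or the end-to-end
#' CA-CA distance (nm). Normalization is overflow-guarded by a max-shift.
#' Negative coefficients tilt toward larger feature values.
#'
#' @param ens an [ensemble()].
#' @param tilt_feature `"Rg"` or `"end_to_end"`.
#' @param coefficient tilt strength, 1/nm.
#' @return Object of class `ground_truth`: `true_weights`, `tilt_spec`,
#'   `features`.
#' @export
make_ground_truth <- function(ens, tilt_feature = c("Rg", "end_to_end"),
                              coefficient) {
  tilt_feature <- match.arg(tilt_feature)
  f <- switch(tilt_feature,
    Rg = vapply(ens$conformers, radius_of_gyration, numeric(1L)),
    end_to_end = vapply(ens$conformers, function(cf) {
      ca <- ca_xyz(cf); vnorm(ca[nrow(ca), ] - ca[1L, ])
    }, numeric(1L)))
  lw <- log(ens$weights) - coefficient * f
  w <- exp(lw - max(lw))
  structure(list(true_weights = check_weights(w / sum(w)),
                 tilt_spec = list(feature = tilt_feature, coefficient = coefficient),
                 features = f), class = "ground_truth")
}

#' Synthesize experimental datasets from a ground truth
#'
#' For each experiment kind the synthetic measurement is the truth-weighted
#' forward average plus Gaussian noise of the stated magnitude; the sigma
#' column records the noise level used (floored at 1e-12 so a zero-noise
#' limit stays a valid observable set).
#'
#' @param ens the [ensemble()] defining the ground-truth conformer space.
#' @param truth a [make_ground_truth()] object (default: the ensemble's own
#'   prior weights, i.e. no tilt).
#' @param noise list with `saxs_rel` (relative SAXS noise), `cs_sigma`
#'   (ppm), `fret_sigma`, `pre_sigma`.
#' @param seed RNG seed; datasets are bitwise-reproducible given the seed.
#' @param q_grid SAXS q grid, 1/nm.
#' @param fret list with `site_a`, `site_b`, `R0` (nm).
#' @param pre_sites spin-label residue numbers.
#' @param config forward-model configuration (see [build_forward_matrix()]).
#' @return Named list of [observable_set()]s: `saxs`, `cs`, `fret`, `pre`.
#' @export
synthesize_experiments <- function(ens, truth = NULL,
                                   noise = list(saxs_rel = 0.02, cs_sigma = 0.4,
                                                fret_sigma = 0.03, pre_sigma = 0.05),
                                   seed = 1,
                                   q_grid = seq(0.1, 3.0, length.out = 40),
                                   fret = list(site_a = 1, site_b = 90, R0 = 6.0),
                                   pre_sites = c(1, 21, 38, 64, 83, 90),
                                   config = list()) {
  w <- if (is.null(truth)) ens$weights else check_weights(truth$true_weights, length(ens))
  set.seed(seed)
  pp <- config$pre %||% pre_params()
  ures <- unique(ens$conformers[[1L]]$resno)
  floor_sigma <- function(s) pmax(s, 1e-12)

  ## SAXS
  Fs <- t(vapply(ens$conformers, saxs_debye, numeric(length(q_grid)),
                 q = q_grid, sigma_bead = config$sigma_bead %||% 0.31))
  avg <- as.numeric(crossprod(w, Fs))
  sg <- noise$saxs_rel * avg
  saxs <- observable_set("SAXS", avg + stats::rnorm(length(avg), 0, sg),
                         floor_sigma(sg), data.frame(q = q_grid))

  ## chemical shifts
  aa <- strsplit(ens$conformers[[1L]]$sequence, "")[[1L]]
  meta_cs <- rbind(data.frame(resid = ures, atom = "CA"),
                   data.frame(resid = ures[aa != "G"], atom = "CB"))
  meta_cs <- meta_cs[order(meta_cs$resid, meta_cs$atom), ]
  cs_obs0 <- observable_set("CS", rep(0, nrow(meta_cs)), rep(1, nrow(meta_cs)),
                            meta_cs)
  Fc <- build_forward_matrix(ens, cs_obs0, config)$F
  avg <- as.numeric(crossprod(w, Fc))
  cs <- observable_set("CS", avg + stats::rnorm(length(avg), 0, noise$cs_sigma),
                       floor_sigma(rep(noise$cs_sigma, length(avg))), meta_cs)

  ## FRET (single pair)
  Ef <- vapply(ens$conformers, fret_efficiency, numeric(1L),
               site_a = fret$site_a, site_b = fret$site_b, R0 = fret$R0)
  fret_obs <- observable_set(
    "FRET", sum(w * Ef) + stats::rnorm(1L, 0, noise$fret_sigma),
    floor_sigma(noise$fret_sigma),
    data.frame(site_a = fret$site_a, site_b = fret$site_b, R0_nm = fret$R0))

  ## PRE at the configured label sites, all other residues reporting
  pre_meta <- do.call(rbind, lapply(pre_sites, function(s)
    data.frame(label_site = s, resid = ures[ures != s])))
  ratios <- unlist(lapply(pre_sites, function(s)
    pre_intensity_ratio(ens, w, s, ures[ures != s], pp)$ratio),
    use.names = FALSE)
  noisy <- pmin(pmax(ratios + stats::rnorm(length(ratios), 0, noise$pre_sigma),
                     1e-6), 1)
  pre <- observable_set("PRE", noisy,
                        floor_sigma(rep(noise$pre_sigma, length(ratios))),
                        pre_meta)

  list(saxs = saxs, cs = cs, fret = fret_obs, pre = pre)
}
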