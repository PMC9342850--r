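# Global dimensions, inter-residue scaling maps, secondary-structure
# propensities and weighted-bootstrap uncertainties.

#' Radius of gyration
#'
#' Per-conformer radius of gyration from CA coordinates with equal point
#' masses. For an ensemble the squared radii are averaged with the weights:
#' `Rg^2 = sum_i w_i rg_i^2`, which satisfies the pairwise-distance identity
#' `Rg^2 = (1/(2 n^2)) * sum_ij <r_ij^2>`.
#'
#' @param x a [conformer()] or [ensemble()].
#' @param weights conformer weights (ensembles only; default the ensemble's own).
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(x, weights = NULL) UseMethod("radius_of_gyration")

#' @export
radius_of_gyration.conformer <- function(x, weights = NULL) {
  ca <- ca_xyz(x)
  if (nrow(ca) < 2L) stop("need >= 2 residues for a radius of gyration")
  sqrt(mean(rowSums(sweep(ca, 2L, colMeans(ca))^2)))
}

#' @export
radius_of_gyration.ensemble <- function(x, weights = NULL) {
  if (is.null(weights)) weights <- x$weights
  weights <- check_weights(weights, length(x))
  rg2 <- vapply(x$conformers, function(cf) radius_of_gyration(cf)^2, numeric(1L))
  sqrt(sum(weights * rg2))
}

## Weighted mean CA-CA distance matrix (n_res x n_res) over an ensemble.
mean_dist_matrix <- function(ens, weights) {
  n <- length(unique(ens$conformers[[1L]]$resno))
  acc <- matrix(0, n, n)
  for (i in seq_along(ens$conformers)) {
    ca <- ca_xyz(ens$conformers[[i]])
    acc <- acc + weights[i] * as.matrix(stats::dist(ca))
  }
  acc
}

#' Inter-residue scaling map
#'
#' Ensemble-averaged CA-CA distances for every residue pair, normalized by
#' the corresponding averages in a reference ensemble (typically a random
#' coil): `D_ij = <r_ij>_ens / <r_ij>_ref`. Values above 1 indicate local
#' expansion relative to the reference, below 1 compaction. The diagonal is
#' `NA`.
#'
#' @param ens an [ensemble()].
#' @param weights conformer weights (default the ensemble's own).
#' @param ref reference [ensemble()] with the same sequence length.
#' @param ref_weights reference weights (default the reference's own).
#' @return Symmetric matrix of class `scaling_map`.
#' @export
scaling_map <- function(ens, weights = NULL, ref, ref_weights = NULL) {
  if (is.null(weights)) weights <- ens$weights
  if (is.null(ref_weights)) ref_weights <- ref$weights
  n1 <- length(unique(ens$conformers[[1L]]$resno))
  n2 <- length(unique(ref$conformers[[1L]]$resno))
  if (n1 != n2) stop("ensemble and reference differ in sequence length")
  weights <- check_weights(weights, length(ens))
  ref_weights <- check_weights(ref_weights, length(ref))
  D <- mean_dist_matrix(ens, weights) / mean_dist_matrix(ref, ref_weights)
  diag(D) <- NA_real_
  class(D) <- c("scaling_map", class(D))
  D
}

#' Per-residue 3-class secondary-structure propensities
#'
#' Weighted fraction of conformers assigning each residue to helix,
#' extended or coil ([dssp3()]); the three classes sum to 1 per residue.
#' With `B > 1`, weighted-bootstrap standard deviations are attached.
#'
#' @param ens an [ensemble()].
#' @param weights conformer weights (default the ensemble's own).
#' @param B bootstrap replicates (0 or 1 to skip).
#' @param seed RNG seed for the bootstrap.
#' @param ss optional precomputed matrix of [dssp3()] classes
#'   (conformers x residues).
#' @return list with `propensity` (residues x 3 matrix) and `sd` (same shape
#'   or NULL).
#' @export
ss_propensity <- function(ens, weights = NULL, B = 0, seed = 1, ss = NULL) {
  if (is.null(weights)) weights <- ens$weights
  weights <- check_weights(weights, length(ens))
  if (is.null(ss))
    ss <- t(vapply(ens$conformers, dssp3,
                   character(length(unique(ens$conformers[[1L]]$resno)))))
  classes <- c("helix", "extended", "coil")
  prop <- vapply(classes, function(cl) as.numeric(crossprod(weights, ss == cl)),
                 numeric(ncol(ss)))
  rownames(prop) <- unique(ens$conformers[[1L]]$resno)
  sd <- NULL
  if (B > 1L) {
    ind <- do.call(cbind, lapply(classes, function(cl) (ss == cl) * 1))
    sdv <- bootstrap_sd_values(ind, weights, B = B, seed = seed)
    sd <- matrix(sdv, ncol = 3L, dimnames = dimnames(prop))
  }
  list(propensity = prop, sd = sd)
}

#' Weighted-bootstrap standard deviation of an ensemble statistic
#'
#' Draws `B` resamples of size `N` (with replacement, probabilities equal to
#' the weights), evaluates the statistic on each resampled ensemble with
#' uniform weights, and returns the standard deviation across resamples.
#'
#' @param statistic function taking an [ensemble()] and returning a numeric
#'   scalar or vector.
#' @param ens an [ensemble()].
#' @param weights resampling probabilities (default the ensemble's own
#'   weights).
#' @param B number of bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @return Standard deviation(s) of the statistic across replicates.
#' @export
bootstrap_sd <- function(statistic, ens, weights = NULL, B = 1000, seed = 1) {
  if (B < 2L) stop("B must be >= 2")
  if (is.null(weights)) weights <- ens$weights
  weights <- check_weights(weights, length(ens))
  n <- length(ens)
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE, prob = weights)
    as.numeric(statistic(ensemble(ens$conformers[idx])))
  }, numeric(length(statistic(ens))))
  if (is.matrix(reps)) apply(reps, 1L, stats::sd) else stats::sd(reps)
}

#' @rdname bootstrap_sd
#' @param values matrix of per-conformer feature values (conformers x
#'   features); fast path for statistics that are weighted means of
#'   per-conformer features, resampling rows instead of rebuilding
#'   ensembles.
#' @export
bootstrap_sd_values <- function(values, weights, B = 1000, seed = 1) {
  if (B < 2L) stop("B must be >= 2")
  values <- as.matrix(values)
  n <- nrow(values)
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE, prob = weights)
    colMeans(values[idx, , drop = FALSE])
  }, numeric(ncol(values)))
  if (is.matrix(reps)) apply(reps, 1L, stats::sd) else stats::sd(reps)
}
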