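# Planar pi-contact detection and hydrogen-bond statistics over ensembles.

## Planar group atom definitions per residue type (side chains); the
## backbone amide plane (C_i, O_i, N_{i+1}) is always available.
.sc_planes <- list(
  ARG = c("NE", "CZ", "NH1", "NH2"),
  ASN = c("CG", "OD1", "ND2"),
  GLN = c("CD", "OE1", "NE2"),
  ASP = c("CG", "OD1", "OD2"),
  GLU = c("CD", "OE1", "OE2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

## Enumerate planar groups of a conformer: list of (residue, class, normal,
## center). Degenerate (collinear) groups are skipped with a warning.
planar_groups <- function(conf) {
  ures <- unique(conf$resno)
  n <- length(ures)
  groups <- list()
  ## backbone amide planes for peptide bonds i -> i+1, assigned to residue i
  C <- atom_xyz(conf, "C"); O <- atom_xyz(conf, "O"); N <- atom_xyz(conf, "N")
  for (i in seq_len(n - 1L)) {
    if (ures[i + 1L] != ures[i] + 1L) next   # peptide bond requires consecutive residues
    v1 <- O[i, ] - C[i, ]; v2 <- N[i + 1L, ] - C[i, ]
    nv <- cross3(v1, v2)
    if (vnorm(nv) < 1e-8) {
      warning("degenerate backbone plane at residue ", ures[i])
      next
    }
    groups[[length(groups) + 1L]] <-
      list(res = ures[i], class = "bb", normal = nv / vnorm(nv),
           center = (C[i, ] + O[i, ] + N[i + 1L, ]) / 3)
  }
  ## side-chain planes where the atoms are present
  for (i in seq_len(n)) {
    rn <- conf$resid[match(ures[i], conf$resno)]
    ats <- .sc_planes[[rn]]
    if (is.null(ats)) next
    sel <- conf$resno == ures[i] & conf$elety %in% ats
    if (sum(sel) < length(ats)) next
    pl <- tryCatch(fit_plane(conf$xyz[sel, , drop = FALSE]),
                   degenerate_plane = function(e) {
                     warning("degenerate side-chain plane at residue ", ures[i]); NULL
                   })
    if (!is.null(pl))
      groups[[length(groups) + 1L]] <-
        list(res = ures[i], class = "sc", normal = pl$normal, center = pl$center)
  }
  groups
}

#' Planar pi-contact counts for a single conformer
#'
#' Two planar groups are in contact when their centres are within `d_max`
#' and the angle between their plane normals (folded to `[0, 90]` degrees)
#' is at most `a_max`. Groups are backbone amide planes (always available)
#' and side-chain planes of R, N, Q, D, E, H, F, Y, W when those atoms are
#' present. Only pairs with residue separation `|i - j| > min_separation`
#' are counted, and contacts are classified by group provenance.
#'
#' @param conf a [conformer()].
#' @param d_max centre-centre distance cutoff, nm.
#' @param a_max normal-normal angle cutoff, degrees.
#' @param min_separation minimum residue separation.
#' @return Named integer vector with counts `sc_sc`, `bb_bb`, `sc_bb`.
#' @export
pi_contacts <- function(conf, d_max = 0.49, a_max = 40, min_separation = 10) {
  groups <- planar_groups(conf)
  out <- c(sc_sc = 0L, bb_bb = 0L, sc_bb = 0L)
  ng <- length(groups)
  if (ng < 2L) return(out)
  res <- vapply(groups, `[[`, numeric(1L), "res")
  cls <- vapply(groups, `[[`, character(1L), "class")
  ctr <- t(vapply(groups, `[[`, numeric(3L), "center"))
  nrm <- t(vapply(groups, `[[`, numeric(3L), "normal"))
  D <- cdist(ctr, ctr)
  cosang <- pmin(abs(tcrossprod(nrm)), 1)      # normals folded to [0, 90] deg
  sep <- abs(outer(res, res, "-"))
  hit <- upper.tri(D) & sep > min_separation & D <= d_max &
    rad2deg(acos(cosang)) <= a_max
  idx <- which(hit, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    a <- idx[k, 1L]; b <- idx[k, 2L]
    key <- if (cls[a] == cls[b]) paste0(cls[a], "_", cls[b]) else "sc_bb"
    out[key] <- out[key] + 1L
  }
  out
}

#' Weighted PMF of long-range hydrogen-bond counts per conformer
#'
#' Counts backbone H-bonds with sequence separation `|i - j| >
#' min_separation` per conformer ([hbond_assign()]), then accumulates the
#' conformer weights into a probability mass function over counts.
#'
#' @param ens an [ensemble()].
#' @param weights conformer weights (default the ensemble's own).
#' @param min_separation residue separation filter.
#' @param counts optional precomputed per-conformer counts.
#' @return list with `pmf` (named numeric, names are counts `0..kmax`) and
#'   `mean` (weighted mean count).
#' @export
hbond_pmf <- function(ens, weights = NULL, min_separation = 10, counts = NULL) {
  if (is.null(weights)) weights <- ens$weights
  weights <- check_weights(weights, length(ens))
  if (is.null(counts))
    counts <- vapply(ens$conformers,
                     function(cf) nrow(hbond_assign(cf, min_separation)),
                     integer(1L))
  kmax <- max(counts)
  pmf <- vapply(0:kmax, function(k) sum(weights[counts == k]), numeric(1L))
  names(pmf) <- 0:kmax
  list(pmf = pmf, mean = sum(weights * counts))
}

#' Weighted contact summary of an ensemble
#'
#' Weighted means (and, when `B > 1`, weighted-bootstrap standard
#' deviations) of the long-range hydrogen-bond count and of each planar
#' pi-contact class per conformer, plus the H-bond PMF.
#'
#' @param ens an [ensemble()].
#' @param weights conformer weights (default the ensemble's own).
#' @param min_separation residue separation filter.
#' @param B bootstrap replicates (0 or 1 to skip).
#' @param seed RNG seed for the bootstrap.
#' @return list with `hbond` (`pmf`, `mean`, `sd`) and `pi` (data.frame with
#'   class, mean, sd).
#' @export
contact_summary <- function(ens, weights = NULL, min_separation = 10,
                            B = 1000, seed = 1) {
  if (is.null(weights)) weights <- ens$weights
  weights <- check_weights(weights, length(ens))
  hb <- vapply(ens$conformers,
               function(cf) nrow(hbond_assign(cf, min_separation)), integer(1L))
  pc <- t(vapply(ens$conformers, pi_contacts, c(sc_sc = 0L, bb_bb = 0L, sc_bb = 0L),
                 min_separation = min_separation))
  feats <- cbind(hbond = hb, pc)
  sds <- rep(NA_real_, ncol(feats))
  if (B > 1L) sds <- bootstrap_sd_values(feats, weights, B = B, seed = seed)
  list(
    hbond = c(hbond_pmf(ens, weights, min_separation, counts = hb),
              list(sd = sds[1L])),
    pi = data.frame(class = colnames(pc),
                    mean = as.numeric(crossprod(weights, pc)),
                    sd = sds[-1L])
  )
}
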