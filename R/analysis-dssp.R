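# Backbone hydrogen-bond detection and reduced 3-class DSSP assignment.

## Amide H positions; reconstructed geometrically when absent (bisector of
## C(i-1)->N and CA->N directions, 0.1 nm bond).
amide_h_xyz <- function(conf) {
  H <- atom_xyz(conf, "H")
  miss <- is.na(H[, 1L])
  if (any(miss)) {
    N <- atom_xyz(conf, "N"); CA <- ca_xyz(conf); C <- atom_xyz(conf, "C")
    for (i in which(miss)) {
      if (i == 1L) {
        H[i, ] <- N[i, ] + 0.1 * unitv(N[i, ] - CA[i, ])
      } else {
        H[i, ] <- N[i, ] + 0.1 * unitv(-(unitv(C[i - 1L, ] - N[i, ]) +
                                           unitv(CA[i, ] - N[i, ])))
      }
    }
  }
  H
}

## Kabsch-Sander H-bond matrix: hb[a, d] TRUE when the NH of residue d
## donates to the C=O of residue a. Electrostatic energy (kcal/mol, with
## distances in Angstrom): E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN),
## bond when E < -0.5. Pairs with |a - d| <= 1 are excluded.
ks_hbond_matrix <- function(conf) {
  N <- atom_xyz(conf, "N") * 10
  C <- atom_xyz(conf, "C") * 10
  O <- atom_xyz(conf, "O") * 10
  H <- amide_h_xyz(conf) * 10
  E <- 0.084 * 332 * (1 / cdist(O, N) + 1 / cdist(C, H) -
                        1 / cdist(O, H) - 1 / cdist(C, N))
  hb <- E < -0.5
  n <- nrow(N)
  near <- abs(outer(seq_len(n), seq_len(n), "-")) <= 1L
  hb[near] <- FALSE
  hb
}

#' Reduced 3-class DSSP secondary-structure assignment
#'
#' Kabsch-Sander backbone H-bond energies define n-turns (CO of residue i
#' accepting from NH of residue i+n, n = 3, 4, 5) and beta bridges. Two
#' consecutive n-turns mark the spanned residues helical; parallel or
#' antiparallel bridge patterns mark residues extended; everything else is
#' coil. The 8-state alphabet is collapsed to the standard 3 classes
#' (helical; strand/extended; loop/coil).
#'
#' @param conf a [conformer()].
#' @return Character vector per residue: `"helix"`, `"extended"`, `"coil"`.
#' @export
dssp3 <- function(conf) {
  n <- length(unique(conf$resno))
  cls <- rep("coil", n)
  if (n < 3L) return(cls)
  hb <- ks_hbond_matrix(conf)
  ## n-turns: turn_n[i] <- CO(i) accepts from NH(i+n)
  for (tn in c(4L, 3L, 5L)) {
    if (n < tn + 2L) next
    turn <- logical(n)
    idx <- seq_len(n - tn)
    turn[idx] <- hb[cbind(idx, idx + tn)]
    two <- which(turn[-length(turn)] & turn[-1L])  # consecutive turns at i, i+1
    for (i in two) cls[(i + 1L):(i + tn)] <- "helix"
  }
  ## beta bridges (minimal rules, no bulges)
  hbond <- function(a, d) {            # CO(a) <- NH(d), with bounds check
    ok <- a >= 1L & a <= n & d >= 1L & d <= n
    out <- logical(length(a)); out[ok] <- hb[cbind(a[ok], d[ok])]
    out
  }
  pr <- expand.grid(i = seq_len(n), j = seq_len(n))
  pr <- pr[abs(pr$i - pr$j) > 2L, ]
  i <- pr$i; j <- pr$j
  par <- (hbond(i - 1L, j) & hbond(j, i + 1L)) | (hbond(j - 1L, i) & hbond(i, j + 1L))
  anti <- (hbond(i, j) & hbond(j, i)) | (hbond(i - 1L, j + 1L) & hbond(j - 1L, i + 1L))
  bridged <- unique(c(i[par | anti], j[par | anti]))
  cls[bridged[cls[bridged] != "helix"]] <- "extended"
  cls
}

#' Geometric backbone hydrogen-bond assignment
#'
#' A donor-acceptor pair is a hydrogen bond when the H...O distance is below
#' `dist_cutoff` and the N-H...O angle exceeds `angle_cutoff`. Only pairs
#' with sequence separation `|i - j| > min_separation` are reported
#' (`min_separation = 0` disables the long-range filter).
#'
#' @param conf a [conformer()].
#' @param min_separation minimum |donor - acceptor| residue separation.
#' @param dist_cutoff H...acceptor distance cutoff, nm.
#' @param angle_cutoff donor-H...acceptor angle cutoff, degrees.
#' @return data.frame with `donor` and `acceptor` residue numbers.
#' @export
hbond_assign <- function(conf, min_separation = 10, dist_cutoff = 0.25,
                         angle_cutoff = 120) {
  N <- atom_xyz(conf, "N")
  O <- atom_xyz(conf, "O")
  H <- amide_h_xyz(conf)
  n <- nrow(N)
  ures <- unique(conf$resno)
  dHO <- cdist(H, O)                  # rows donors, cols acceptors
  sep <- abs(outer(ures, ures, "-"))
  cand <- which(dHO < dist_cutoff & sep > min_separation, arr.ind = TRUE)
  if (!nrow(cand)) return(data.frame(donor = integer(), acceptor = integer()))
  keep <- vapply(seq_len(nrow(cand)), function(k) {
    d <- cand[k, 1L]; a <- cand[k, 2L]
    rad2deg(vec_angle(N[d, ], H[d, ], O[a, ])) > angle_cutoff
  }, logical(1L))
  ures <- unique(conf$resno)
  data.frame(donor = ures[cand[keep, 1L]], acceptor = ures[cand[keep, 2L]])
}
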