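# Internal-coordinate chain growth with ideal peptide geometry.
#
# Backbone atoms N, H, CA, C, O (+ CB for non-glycine) are placed from
# sampled (phi, psi) torsions with fixed trans peptide bonds (omega = 180).
# Bond lengths/angles are the standard Engh-Huber values. Self-avoidance is
# enforced on CA atoms: any nonadjacent CA-CA pair closer than `clash_nm`
# rejects the step; the residue's torsions are resampled and, failing that,
# the whole chain is re-grown.

.geom <- list(
  b_NCA = 0.1458, b_CAC = 0.1525, b_CN = 0.1329,
  b_NH = 0.100, b_CO = 0.1231, b_CACB = 0.1530,
  ang_NCAC = 111.2, ang_CACN = 116.2, ang_CNCA = 121.7,
  ang_CACO = 120.8, ang_CACCB = 110.1, tor_CB = 122.55,
  omega = 180
)

#' Build one self-avoiding conformer from sampled backbone torsions
#'
#' @param sequence one-letter amino-acid string (length >= 2).
#' @param phi_psi_sampler function of the residue index returning
#'   `c(phi, psi)` in degrees. See [sampler_fixed()] and [sampler_basin()].
#' @param seed optional integer seed (sets the RNG; samplers that do not draw
#'   random numbers are unaffected).
#' @param clash_nm CA-CA self-avoidance threshold in nm.
#' @param max_resample per-residue torsion resampling attempts before the
#'   chain is re-grown from scratch.
#' @param max_restarts chain re-growth attempts before a generation error.
#' @return A [conformer()].
#' @export
build_chain <- function(sequence, phi_psi_sampler, seed = NULL,
                        clash_nm = 0.4, max_resample = 50L, max_restarts = 200L) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(aa)
  if (n < 2L) stop("sequence length must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  for (restart in seq_len(max_restarts)) {
    cf <- try_grow_chain(aa, phi_psi_sampler, clash_nm, max_resample)
    if (!is.null(cf)) return(cf)
  }
  stop("generation error: failed to place a self-avoiding chain after ",
       max_restarts, " restarts")
}

try_grow_chain <- function(aa, sampler, clash_nm, max_resample) {
  g <- .geom
  n <- length(aa)
  N <- CA <- C <- matrix(NA_real_, n, 3L)
  phi <- psi <- numeric(n)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_NCA, 0, 0)
  C[1L, ] <- place_atom(c(0, 1, 0), N[1L, ], CA[1L, ], g$b_CAC,
                        deg2rad(g$ang_NCAC), deg2rad(0))
  pp <- sampler(1L)
  phi[1L] <- pp[1L]; psi[1L] <- pp[2L]
  for (i in seq_len(n - 1L)) {
    ok <- FALSE
    for (attempt in seq_len(max_resample)) {
      Ni1 <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_CN,
                        deg2rad(g$ang_CACN), deg2rad(psi[i]))
      CAi1 <- place_atom(CA[i, ], C[i, ], Ni1, g$b_NCA,
                         deg2rad(g$ang_CNCA), deg2rad(g$omega))
      clash <- FALSE
      if (i >= 2L) {
        prev <- CA[seq_len(i - 1L), , drop = FALSE]
        d2 <- rowSums(sweep(prev, 2L, CAi1)^2)
        clash <- any(d2 < clash_nm^2)
      }
      if (!clash) {
        pp <- sampler(i + 1L)
        phi[i + 1L] <- pp[1L]; psi[i + 1L] <- pp[2L]
        N[i + 1L, ] <- Ni1
        CA[i + 1L, ] <- CAi1
        C[i + 1L, ] <- place_atom(C[i, ], Ni1, CAi1, g$b_CAC,
                                  deg2rad(g$ang_NCAC), deg2rad(phi[i + 1L]))
        ok <- TRUE
        break
      }
      ## resample this residue's torsions and retry
      pp <- sampler(i)
      phi[i] <- pp[1L]; psi[i] <- pp[2L]
      if (i >= 2L) {
        ## phi(i) moves C(i); rebuild it before retrying psi(i)
        C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ], g$b_CAC,
                             deg2rad(g$ang_NCAC), deg2rad(phi[i]))
      }
    }
    if (!ok) return(NULL)
  }
  assemble_conformer(aa, N, CA, C, psi)
}

## Derived atoms (O, H, CB) and topology assembly from backbone traces.
assemble_conformer <- function(aa, N, CA, C, psi) {
  g <- .geom
  n <- length(aa)
  aa3 <- bio3d::aa123(aa)
  nat_res <- ifelse(aa == "G", 5L, 6L)
  xyz <- matrix(NA_real_, sum(nat_res), 3L)
  elety <- character(sum(nat_res))
  resno <- rep(seq_len(n), nat_res)
  at <- 0L
  for (i in seq_len(n)) {
    O <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_CO,
                    deg2rad(g$ang_CACO), deg2rad(psi[i] + 180))
    if (i == 1L) {
      H <- place_atom(C[1L, ], CA[1L, ], N[1L, ], g$b_NH,
                      deg2rad(118), deg2rad(180))
    } else {
      hdir <- -(unitv(C[i - 1L, ] - N[i, ]) + unitv(CA[i, ] - N[i, ]))
      H <- N[i, ] + g$b_NH * unitv(hdir)
    }
    k <- nat_res[i]
    rows <- at + seq_len(k)
    xyz[rows[1L], ] <- N[i, ]; xyz[rows[2L], ] <- H
    xyz[rows[3L], ] <- CA[i, ]; xyz[rows[4L], ] <- C[i, ]
    xyz[rows[5L], ] <- O
    elety[rows] <- c("N", "H", "CA", "C", "O", "CB")[seq_len(k)]
    if (k == 6L)
      xyz[rows[6L], ] <- place_atom(N[i, ], C[i, ], CA[i, ], g$b_CACB,
                                    deg2rad(g$ang_CACCB), deg2rad(g$tor_CB))
    at <- at + k
  }
  conformer(xyz, resno, rep(aa3, nat_res), elety)
}

#' Torsion samplers for chain growth
#'
#' `sampler_fixed` always returns the same (phi, psi). `sampler_basin` draws
#' from a 3-basin discrete library (helical, extended/polyproline-II,
#' left-handed) with Gaussian jitter, the statistical-coil model used for
#' prior generation.
#'
#' @param phi,psi torsions in degrees.
#' @return A function of the residue index returning `c(phi, psi)` degrees.
#' @export
sampler_fixed <- function(phi, psi) {
  force(phi); force(psi)
  function(i) c(phi, psi)
}

## Basin centres (degrees): helical, extended/PPII, left-handed helical.
.basins <- matrix(c(-63, -43,
                    -120, 135,
                    60, 45), ncol = 2L, byrow = TRUE,
                  dimnames = list(c("helix", "extended", "left"), c("phi", "psi")))

#' @rdname sampler_fixed
#' @param probs basin probabilities `c(helix, extended, left)`; normalized.
#' @param jitter_sd Gaussian jitter around the basin centre, degrees.
#' @export
sampler_basin <- function(probs = c(helix = 0.30, extended = 0.60, left = 0.10),
                          jitter_sd = 12) {
  probs <- probs / sum(probs)
  function(i) {
    b <- sample.int(3L, 1L, prob = probs)
    .basins[b, ] + stats::rnorm(2L, 0, jitter_sd)
  }
}
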