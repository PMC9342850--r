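#' Conformer objects
#'
#' A conformer is one all-backbone structure of the chain: coordinates in
#' nanometres plus a per-atom topology. The minimal atom set per residue is
#' N, CA, C, O (plus CB for non-glycine); an amide H is carried when built by
#' the chain generator and reconstructed geometrically otherwise.
#'
#' @param xyz numeric matrix, one row per atom, columns x/y/z in nm.
#' @param resno integer vector of PDB residue numbers per atom.
#' @param resid character vector of 3-letter residue names per atom.
#' @param elety character vector of atom names per atom (N, H, CA, C, O, CB, ...).
#' @param validate logical; check the structural invariants (default TRUE).
#'
#' @return An object of class `conformer` with fields `xyz`, `resno`,
#'   `resid`, `elety`, `sequence` (one-letter string) and `res_index`
#'   (0-based internal residue index per atom).
#' @export
conformer <- function(xyz, resno, resid, elety, validate = TRUE) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  n <- nrow(xyz)
  if (length(resno) != n || length(resid) != n || length(elety) != n)
    stop("topology vectors must match number of atoms")
  ures <- unique(resno)
  obj <- structure(list(
    xyz = xyz,
    resno = as.integer(resno),
    resid = as.character(resid),
    elety = as.character(elety),
    res_index = match(resno, ures) - 1L,
    sequence = paste(bio3d::aa321(resid[match(ures, resno)]), collapse = "")
  ), class = "conformer")
  if (validate) validate_conformer(obj)
  obj
}

validate_conformer <- function(x) {
  if (!all(is.finite(x$xyz))) stop("conformer coordinates must be finite")
  ures <- unique(x$resno)
  for (r in ures) {
    at <- x$elety[x$resno == r]
    need <- c("N", "CA", "C", "O")
    if (!all(need %in% at))
      stop("topology error: residue ", r, " missing backbone atom(s): ",
           paste(setdiff(need, at), collapse = ","))
    rn <- x$resid[x$resno == r][1L]
    if (rn != "GLY" && !("CB" %in% at))
      stop("topology error: residue ", r, " (", rn, ") missing CB")
  }
  ca <- ca_xyz(x)
  if (nrow(ca) >= 2L) {
    d <- sqrt(rowSums((ca[-1L, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
    if (any(d <= 0.2 | d >= 0.6))
      stop("consecutive CA-CA distance outside (0.2, 0.6) nm: broken chain?")
  }
  invisible(x)
}

#' @export
print.conformer <- function(x, ...) {
  cat("conformer:", nlevels(factor(x$resno)), "residues,", nrow(x$xyz),
      "atoms, sequence", substr(x$sequence, 1, 20),
      if (nchar(x$sequence) > 20) "..." else "", "\n")
  invisible(x)
}

## CA coordinates of a conformer, in residue order (matrix n_res x 3, nm).
ca_xyz <- function(conf) conf$xyz[conf$elety == "CA", , drop = FALSE]

## Coordinates of one named atom per residue; NA rows where absent.
atom_xyz <- function(conf, name) {
  sel <- conf$elety == name
  out <- matrix(NA_real_, max(conf$res_index) + 1L, 3L)
  out[conf$res_index[sel] + 1L, ] <- conf$xyz[sel, , drop = FALSE]
  out
}

## CB coordinates with CA fallback for glycine (the spin-label convention).
cb_or_ca_xyz <- function(conf) {
  cb <- atom_xyz(conf, "CB")
  ca <- ca_xyz(conf)
  miss <- is.na(cb[, 1L])
  cb[miss, ] <- ca[miss, ]
  cb
}

#' Conformational ensembles
#'
#' An ensemble is an ordered set of conformers sharing one topology, plus
#' per-conformer prior weights on the probability simplex.
#'
#' @param conformers list of [conformer()] objects with identical topology.
#' @param weights numeric prior weights; default uniform `1/N`.
#' @return Object of class `ensemble` with fields `conformers` and `weights`.
#' @export
ensemble <- function(conformers, weights = NULL) {
  if (!length(conformers)) stop("empty ensemble")
  ref <- conformers[[1L]]
  for (cf in conformers) {
    if (nrow(cf$xyz) != nrow(ref$xyz) || !identical(cf$elety, ref$elety) ||
        !identical(cf$resno, ref$resno))
      stop("format error: conformers differ in atom count or ordering")
  }
  n <- length(conformers)
  if (is.null(weights)) weights <- rep(1 / n, n)
  weights <- check_weights(weights, n)
  structure(list(conformers = conformers, weights = weights), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble of", length(x$conformers), "conformers,",
      nchar(x$conformers[[1L]]$sequence), "residues\n")
  invisible(x)
}

#' @export
length.ensemble <- function(x) length(x$conformers)

#' Validate a weight vector on the probability simplex
#'
#' @param w numeric vector of weights.
#' @param n expected length (optional).
#' @return `w`, normalized metadata untouched; errors if not a simplex point.
#' @export
check_weights <- function(w, n = NULL) {
  w <- as.numeric(w)
  if (!is.null(n) && length(w) != n) stop("weight vector has wrong length")
  if (any(!is.finite(w)) || any(w < -1e-12)) stop("weights must be finite and >= 0")
  w[w < 0] <- 0
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1 (got ", sum(w), ")")
  w
}

#' Load a conformer ensemble from a multi-model PDB file
#'
#' Models become conformers with uniform prior weights; coordinates are
#' converted from Angstrom to nm.
#'
#' @param path multi-model PDB file (MODEL/ENDMDL records).
#' @return An [ensemble()].
#' @export
load_ensemble <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("format error reading PDB: ",
                                           conditionMessage(e)))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nat <- nrow(pdb$atom)
  if (ncol(xyz) != 3L * nat)
    stop("format error: inconsistent atom count across models")
  confs <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE) / 10  # Angstrom -> nm
    conformer(m, pdb$atom$resno, pdb$atom$resid, pdb$atom$elety)
  })
  ensemble(confs)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens an [ensemble()]; weights are not stored in the PDB
#'   (see [write_weights()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  ref <- ens$conformers[[1L]]
  nat <- nrow(ref$xyz)
  elefmt <- ifelse(nchar(ref$elety) < 4L,
                   sprintf(" %-3s", ref$elety), sprintf("%-4s", ref$elety))
  out <- vector("list", 2L * length(ens) + 1L)
  for (m in seq_along(ens$conformers)) {
    a <- ens$conformers[[m]]$xyz * 10   # nm -> Angstrom
    lines <- sprintf("ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                     seq_len(nat), elefmt, ref$resid, ref$resno,
                     a[, 1L], a[, 2L], a[, 3L])
    out[[2L * m - 1L]] <- sprintf("MODEL     %4d", m)
    out[[2L * m]] <- c(lines, "ENDMDL")
  }
  out[[2L * length(ens) + 1L]] <- "END"
  writeLines(unlist(out), path)
  invisible(path)
}

#' Subsample an ensemble with a fixed stride
#'
#' Keeps conformers at indices 1, 1+stride, 1+2*stride, ... (the convention
#' used when thinning correlated trajectory frames) and resets weights to
#' uniform.
#'
#' @param ens an [ensemble()].
#' @param stride positive integer < number of conformers.
#' @return The thinned [ensemble()].
#' @export
subsample_stride <- function(ens, stride) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  n <- length(ens)
  if (stride >= n && n > 1L || (n == 1L && stride > 1L))
    stop("stride (", stride, ") must be smaller than ensemble size (", n, ")")
  keep <- seq.int(1L, n, by = stride)
  ensemble(ens$conformers[keep])
}
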