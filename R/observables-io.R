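#' Experimental observable sets
#'
#' Container for one experiment type's measured values, uncertainties and
#' kind-specific metadata:
#' * `SAXS`: `meta$q` scattering vector in 1/nm;
#' * `CS`: `meta$resid` (PDB numbering) and `meta$atom` (`"CA"`/`"CB"`);
#' * `FRET`: `meta$site_a`, `meta$site_b` (residue numbers), `meta$R0_nm`;
#' * `PRE`: `meta$label_site` (spin-label residue number), `meta$resid`.
#'
#' @param kind one of `"SAXS"`, `"CS"`, `"FRET"`, `"PRE"`.
#' @param values numeric vector of measured values.
#' @param sigmas positive numeric vector of uncertainties, same length.
#' @param meta data.frame of per-point metadata, same number of rows.
#' @return Object of class `observable_set`.
#' @export
observable_set <- function(kind, values, sigmas, meta) {
  kind <- match.arg(kind, c("SAXS", "CS", "FRET", "PRE"))
  values <- as.numeric(values)
  sigmas <- as.numeric(sigmas)
  meta <- as.data.frame(meta)
  if (length(values) != length(sigmas) || nrow(meta) != length(values))
    stop("values, sigmas and meta must have equal length")
  if (any(!is.finite(sigmas)) || any(sigmas <= 0))
    stop("validation error: sigmas must be positive")
  structure(list(kind = kind, values = values, sigmas = sigmas, meta = meta),
            class = "observable_set")
}

#' @export
print.observable_set <- function(x, ...) {
  cat(x$kind, "observable set:", length(x$values), "points\n")
  invisible(x)
}

#' @export
length.observable_set <- function(x) length(x$values)

obs_columns <- list(
  SAXS = c("q_nm^-1", "I", "sigma"),
  CS   = c("resid", "atom", "shift_ppm", "sigma"),
  FRET = c("site_a", "site_b", "R0_nm", "E", "sigma"),
  PRE  = c("label_site", "resid", "ratio", "sigma")
)

#' Read an observable table from TSV
#'
#' Column layouts (tab-separated, header row): SAXS `q_nm^-1, I, sigma`;
#' CS `resid, atom, shift_ppm, sigma`; FRET `site_a, site_b, R0_nm, E,
#' sigma`; PRE `label_site, resid, ratio, sigma`.
#'
#' @param path TSV file.
#' @param kind experiment kind (see [observable_set()]).
#' @return An [observable_set()].
#' @export
read_observables <- function(path, kind) {
  kind <- match.arg(kind, c("SAXS", "CS", "FRET", "PRE"))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  cols <- obs_columns[[kind]]
  if (!all(cols %in% names(tab)))
    stop("missing columns for ", kind, ": ",
         paste(setdiff(cols, names(tab)), collapse = ","))
  val_col <- cols[length(cols) - 1L]
  meta <- tab[cols[seq_len(length(cols) - 2L)]]
  if (kind == "SAXS") names(meta) <- "q"
  observable_set(kind, tab[[val_col]], tab$sigma, meta)
}

#' Write an observable table to TSV
#'
#' @param obs an [observable_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_observables <- function(obs, path) {
  cols <- obs_columns[[obs$kind]]
  meta <- obs$meta
  if (obs$kind == "SAXS") names(meta) <- "q_nm^-1"
  tab <- cbind(meta, value = obs$values, sigma = obs$sigmas)
  names(tab)[ncol(tab) - 1L] <- cols[length(cols) - 1L]
  utils::write.table(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write conformer weights as TSV
#'
#' Two columns: `conformer_index` (1-based) and `weight`.
#'
#' @param w numeric weight vector on the simplex.
#' @param path TSV file.
#' @return `read_weights`: the weight vector; `write_weights`: `path`.
#' @export
write_weights <- function(w, path) {
  w <- check_weights(w)
  tab <- data.frame(conformer_index = seq_along(w),
                    weight = format(w, digits = 17, scientific = TRUE, trim = TRUE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  check_weights(tab$weight[order(tab$conformer_index)])
}
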