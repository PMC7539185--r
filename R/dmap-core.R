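# Distance-map core: data types, real-space <-> training-space mappings,
# symmetrisation, and selection of the informative 4-16 Angstrom band.

DMAP_BAND <- c(4, 16)       # informative distance band (Angstrom)
RESTRAINT_DELTA <- 0.4      # half-width of exported distance restraints
TS_CLAMP <- 1 - 1e-7        # training-space clamp before atanh

#' Construct and validate a distance map
#'
#' A distance map is an L x L symmetric matrix of pairwise inter-residue
#' distances in Angstrom ("real space"), zero on the diagonal.
#'
#' @param values square numeric matrix of distances
#' @param tol symmetry tolerance
#' @return a `dmap` object (matrix with class attribute)
#' @export
dmap <- function(values, tol = 1e-9) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance map must be square")
  bad <- which(!is.finite(values))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(values))
    stop(sprintf("non-finite distance at (%d, %d)", ij[1], ij[2]))
  }
  if (any(values < 0)) stop("distances must be non-negative")
  if (max(abs(values - t(values))) > tol) stop("distance map is not symmetric")
  if (any(abs(diag(values)) > 0)) stop("distance map diagonal must be zero")
  structure(values, class = c("dmap", "matrix", "array"))
}

#' @export
print.dmap <- function(x, ...) {
  cat(sprintf("<dmap> %d residues, distances %.2f-%.2f A\n",
              nrow(x), min(x[upper.tri(x)]), max(x)))
  invisible(x)
}

#' Map real-space distances to training space
#'
#' Applies the label mapping `V_TS = tanh((5 V_RS - 50) / 12)`. The inner
#' linear transform sends the informative band 4-16 Angstrom onto
#' `[-2.5, 2.5]`, where tanh has its largest derivatives, so the band is
#' spread over most of `(-1, 1)` while all distances remain representable.
#'
#' @param d numeric matrix (or vector) of distances in Angstrom
#' @return object of the same shape with entries in `(-1, 1)`
#' @seealso [unmap_label()] for the inverse
#' @export
map_label <- function(d) {
  bad <- which(!is.finite(d))
  if (length(bad)) stop("non-finite distance at index ", bad[1])
  out <- tanh((5 * unclass(d) - 50) / 12)
  out
}

#' Map training-space values back to distances
#'
#' Inverse of [map_label()]. Values are clamped to
#' `[-1 + 1e-7, 1 - 1e-7]` before `atanh`: a generator's bounded output
#' activation can saturate arbitrarily close to +/-1 and the inverse must stay
#' finite and deterministic.
#'
#' @param m numeric matrix (or vector) in training space
#' @param clamp_tol entries may exceed 1 in magnitude by at most this much
#'   before being treated as an error
#' @return distances in Angstrom, same shape as `m`
#' @export
unmap_label <- function(m, clamp_tol = 1e-6) {
  bad <- which(abs(m) >= 1 + clamp_tol)
  if (length(bad)) stop("training-space value out of (-1, 1) at index ", bad[1])
  mm <- pmin(pmax(unclass(m), -TS_CLAMP), TS_CLAMP)
  out <- (12 * atanh(mm) + 50) / 5
  if (is.matrix(m)) dim(out) <- dim(m)
  out
}

#' Min-max map a feature channel to [-1, 1]
#'
#' Linear map `V_TS = (2 V_RS - Max - Min) / (Max - Min)` with Max/Min taken
#' over the supplied values (one channel of one protein). A constant channel
#' (Max = Min) maps to all zeros with a warning rather than an error, because
#' broadcast scalar channels such as protein length are constant over the grid
#' by construction.
#'
#' @param values numeric array of channel values in real space
#' @param stats optional `c(min, max)` to use instead of the observed range
#' @return same shape, values in `[-1, 1]`
#' @export
map_feature_channel <- function(values, stats = NULL) {
  if (is.null(stats)) stats <- range(values)
  mn <- stats[1]; mx <- stats[2]
  if (mx <= mn) {
    if (mx < mn) stop("invalid channel stats: max < min")
    warning("constant feature channel mapped to zeros")
    return(values * 0)
  }
  # algebraically identical form whose endpoints are exact in floating point
  pmin(pmax(2 * ((values - mn) / (mx - mn)) - 1, -1), 1)
}

#' Symmetrise a raw network output
#'
#' The final prediction for a residue pair is the average of the upper- and
#' lower-triangle outputs: `out[i,j] = (raw[i,j] + raw[j,i]) / 2`.
#'
#' @param raw square numeric matrix
#' @return symmetric matrix of the same size
#' @export
symmetrize <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) != ncol(raw)) stop("symmetrize expects a square matrix")
  (raw + t(raw)) / 2
}

#' Construct a restraint set
#'
#' @param entries data.frame with columns `i`, `j` (1-based residue indices,
#'   `i < j`), `center`, `lower`, `upper` (Angstrom)
#' @return a `restraint_set` object
#' @export
restraint_set <- function(entries) {
  entries <- as.data.frame(entries)
  need <- c("i", "j", "center", "lower", "upper")
  if (!all(need %in% names(entries))) stop("restraint set needs columns ", paste(need, collapse = ", "))
  if (nrow(entries)) {
    if (any(entries$i >= entries$j)) stop("restraints require i < j")
    if (anyDuplicated(entries[c("i", "j")])) stop("duplicate residue pair in restraint set")
    if (any(entries$lower <= 0)) stop("restraint lower bound must be positive")
    if (max(abs(entries$lower - (entries$center - RESTRAINT_DELTA)),
            abs(entries$upper - (entries$center + RESTRAINT_DELTA))) > 1e-9)
      stop(sprintf("restraint bounds must be center +/- %.1f", RESTRAINT_DELTA))
    if (any(entries$center < DMAP_BAND[1] - 1e-9) || any(entries$center > DMAP_BAND[2] + 1e-9))
      stop(sprintf("restraint centers must lie in [%g, %g] A", DMAP_BAND[1], DMAP_BAND[2]))
  }
  structure(entries[order(entries$i, entries$j), , drop = FALSE],
            class = c("restraint_set", "data.frame"))
}

#' Select distance restraints from a predicted map
#'
#' Collects every residue pair `i < j` with `|i - j| >= min_sep` whose
#' predicted distance lies in the informative band (4-16 Angstrom) and turns
#' it into a restraint `center +/- 0.4` Angstrom for a CNS/CONFOLD-style
#' folding run. Residue indices in the result are 1-based.
#'
#' @param pred symmetric numeric matrix of predicted distances (Angstrom)
#' @param min_sep minimum sequence separation; default 2 excludes self and
#'   adjacent pairs, which the 4 Angstrom floor would mostly remove anyway
#' @param band numeric length-2, the distance band to keep
#' @param delta half-width of each restraint
#' @return a [restraint_set()]
#' @export
select_restraints <- function(pred, min_sep = 2L, band = DMAP_BAND,
                              delta = RESTRAINT_DELTA) {
  pred <- as.matrix(pred)
  L <- nrow(pred)
  idx <- which(upper.tri(pred), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1]) >= min_sep
  idx <- idx[keep, , drop = FALSE]
  d <- pred[idx]
  inband <- d >= band[1] & d <= band[2]
  entries <- data.frame(i = idx[inband, 1], j = idx[inband, 2],
                        center = d[inband])
  entries$lower <- entries$center - delta
  entries$upper <- entries$center + delta
  restraint_set(entries)
}

# --- serialization ----------------------------------------------------------

#' Write a distance map as a plain-text square matrix
#' @param d matrix of distances
#' @param path output file
#' @export
write_dmap_text <- function(d, path) {
  utils::write.table(format(as.matrix(unclass(d)), digits = 10, trim = TRUE,
                            scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text distance map written by [write_dmap_text()]
#' @param path input file
#' @return a validated [dmap()]
#' @export
read_dmap_text <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  dmap(m, tol = 1e-6)
}

#' Write a distance map in the compact binary container
#'
#' Layout: magic "DMAP", int32 length L, then L*L little-endian doubles in
#' column-major order.
#' @param d matrix of distances
#' @param path output file
#' @export
write_dmap_bin <- function(d, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("DMAP", con, 4, eos = NULL)
  writeBin(as.integer(nrow(d)), con, size = 4L, endian = "little")
  writeBin(as.numeric(unclass(d)), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a binary distance map container; validates invariants
#' @param path input file
#' @return a validated [dmap()]
#' @export
read_dmap_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "DMAP")) stop("not a DMAP container: ", path)
  L <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  vals <- readBin(con, numeric(), L * L, size = 8L, endian = "little")
  dmap(matrix(vals, L, L))
}
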