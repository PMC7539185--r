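# Assembly of the 130-channel training-space input grid and the Neff
# effective-alignment-depth statistic.

STACK_CHANNELS <- c(zero_d = 2L, one_d_row = 62L, one_d_col = 62L, two_d = 4L)

#' Assemble a 130-channel training-space feature stack
#'
#' Broadcasts a raw per-protein feature bundle onto the pair grid: the 2
#' scalar (0D) features become constant L x L planes; each of the 62
#' per-residue (1D) features is broadcast twice, horizontally (channel value
#' `f1[c, i]` at grid point `(i, j)`) and vertically (`f1[c, j]`), giving 124
#' channels; the 4 per-pair (2D) features pass through. Every channel is then
#' min-max mapped to `[-1, 1]` with [map_feature_channel()], using that
#' channel's own range over the grid of this protein. Total: 2 + 124 + 4 =
#' 130 channels.
#'
#' @param bundle list with `f0` (length 2), `f1` (62 x L matrix), `f2`
#'   (4 x L x L array), as produced by [synth_features()]
#' @return `feature_stack`: L x L x 130 array in `[-1, 1]` with per-channel
#'   provenance tags in attribute `provenance`
#' @export
assemble_stack <- function(bundle) {
  if (length(bundle$f0) != 2L)
    stop("0D feature group must have exactly 2 scalars")
  if (!is.matrix(bundle$f1) || nrow(bundle$f1) != 62L)
    stop("1D feature group must be a 62 x L matrix")
  L <- ncol(bundle$f1)
  if (length(dim(bundle$f2)) != 3L || !all(dim(bundle$f2) == c(4L, L, L)))
    stop("2D feature group must be a 4 x L x L array")

  n_tot <- sum(STACK_CHANNELS)
  stack <- array(0, dim = c(L, L, n_tot))
  prov <- rep(names(STACK_CHANNELS), times = STACK_CHANNELS)
  ch <- 0L
  for (s in 1:2) {
    ch <- ch + 1L
    stack[, , ch] <- matrix(bundle$f0[s], L, L)
  }
  for (c_ in 1:62) {
    ch <- ch + 1L
    stack[, , ch] <- matrix(bundle$f1[c_, ], L, L)        # row broadcast: value of residue i
  }
  for (c_ in 1:62) {
    ch <- ch + 1L
    stack[, , ch] <- matrix(bundle$f1[c_, ], L, L, byrow = TRUE)  # column broadcast
  }
  for (c_ in 1:4) {
    ch <- ch + 1L
    stack[, , ch] <- bundle$f2[c_, , ]
  }
  for (k in seq_len(n_tot)) {
    stack[, , k] <- suppressWarnings(map_feature_channel(stack[, , k]))
  }
  structure(stack, provenance = prov, class = c("feature_stack", "array"))
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d x %d x %d (training space)\n",
              dim(x)[1], dim(x)[2], dim(x)[3]))
  invisible(x)
}

#' Pairwise sequence identity matrix of an alignment
#'
#' Identity is the fraction of exactly matching alignment columns; gap
#' characters count as mismatches unless both sequences share the same gap.
#' @param seqs character vector of equal-length aligned sequences
#' @return N x N matrix of identities in `[0, 1]`
#' @export
pairwise_identity <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length")
  chars <- do.call(cbind, strsplit(seqs, ""))   # length x N
  N <- length(seqs)
  pid <- matrix(1, N, N)
  if (N > 1) for (a in 1:(N - 1)) for (b in (a + 1):N) {
    pid[a, b] <- pid[b, a] <- mean(chars[, a] == chars[, b])
  }
  pid
}

#' Effective alignment depth (Neff)
#'
#' `Neff = sum_i 1 / S_i`, where `S_i` counts the sequences (including
#' sequence i itself, which is 100% identical to itself) whose identity to
#' sequence i is at least `threshold`. A stack of N identical sequences has
#' Neff 1; N mutually dissimilar sequences have Neff N, so
#' `1 <= Neff <= N` always.
#'
#' @param seqs character vector of aligned sequences (N >= 1)
#' @param threshold identity threshold, default 0.75
#' @return scalar Neff
#' @export
neff <- function(seqs, threshold = 0.75) {
  if (length(seqs) < 1) stop("need at least one sequence")
  pid <- pairwise_identity(seqs)
  s_i <- rowSums(pid >= threshold)
  sum(1 / s_i)
}

#' Read / write aligned FASTA for toy MSAs
#' @param seqs character vector of aligned sequences
#' @param path file path
#' @return `write_msa_fasta`: the path; `read_msa_fasta`: character vector
#' @export
write_msa_fasta <- function(seqs, path) {
  nm <- names(seqs)
  if (is.null(nm)) nm <- sprintf("seq%03d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", nm), seqs)), path)
  invisible(path)
}

#' @rdname write_msa_fasta
#' @export
read_msa_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1), collapse = "")
  names(seqs) <- sub("^>", "", lines[hdr])
  seqs
}

#' Write / read a feature stack in the compact binary container
#'
#' Layout: magic "FSTK", int32 L, int32 channel count, provenance tags as a
#' newline-separated string block, then the array values as little-endian
#' doubles.
#' @param stack a `feature_stack`
#' @param path file path
#' @export
write_stack_bin <- function(stack, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("FSTK", con, 4, eos = NULL)
  d <- dim(stack)
  writeBin(as.integer(c(d[1], d[3])), con, size = 4L, endian = "little")
  prov <- paste(attr(stack, "provenance"), collapse = "\n")
  writeBin(nchar(prov), con, size = 4L, endian = "little")
  writeChar(prov, con, nchar(prov), eos = NULL)
  writeBin(as.numeric(stack), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_stack_bin
#' @export
read_stack_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "FSTK")) stop("not a FSTK container: ", path)
  hd <- readBin(con, integer(), 2L, size = 4L, endian = "little")
  np <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  prov <- strsplit(readChar(con, np), "\n")[[1]]
  vals <- readBin(con, numeric(), hd[1] * hd[1] * hd[2], size = 8L, endian = "little")
  structure(array(vals, dim = c(hd[1], hd[1], hd[2])), provenance = prov,
            class = c("feature_stack", "array"))
}
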