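# Restraint export, contact lists, a distance-geometry embedder and
# superposition metrics: the geometric back end that turns predicted maps
# into something a folding engine (or a validity check) can consume.

#' Write a restraint set as CNS/CONFOLD-style assign statements
#'
#' One line per restraint:
#' `assign (resid I and name cb) (resid J and name cb) CENTER 0.40 0.40`,
#' i.e. the allowed range is `center - delta` to `center + delta`. Residue
#' numbering is 1-based, rows ordered by (i, j). Centers are printed with 4
#' decimals; the bundled parser reads the file back at that precision and
#' re-writing a parsed file is byte-identical.
#'
#' @param r a [restraint_set()]
#' @param path output file
#' @param atom_name atom field emitted for both residues; the trace-atom
#'   convention of the synthetic backbones is a single "cb" name
#' @return the path, invisibly
#' @export
write_cns_restraints <- function(r, path, atom_name = "cb") {
  hdr <- c("! distance restraints (CNS/CONFOLD assign format)",
           sprintf("! %d restraints, bounds are center +/- %.2f A",
                   nrow(r), RESTRAINT_DELTA))
  lines <- if (nrow(r)) {
    sprintf("assign (resid %d and name %s) (resid %d and name %s) %.4f %.2f %.2f",
            r$i, atom_name, r$j, atom_name, r$center,
            r$center - r$lower, r$upper - r$center)
  } else character(0)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Parse a restraint file written by [write_cns_restraints()]
#' @param path input file
#' @return a [restraint_set()]
#' @export
read_cns_restraints <- function(path) {
  lines <- grep("^assign", readLines(path), value = TRUE)
  pat <- paste0("^assign \\(resid ([0-9]+) and name [^)]+\\) ",
                "\\(resid ([0-9]+) and name [^)]+\\) ",
                "([0-9.]+) ([0-9.]+) ([0-9.]+)$")
  m <- regmatches(lines, regexec(pat, lines))
  bad <- lengths(m) != 6L
  if (any(bad)) stop("unparseable restraint line: ", lines[which(bad)[1]])
  f <- function(k) as.numeric(vapply(m, `[`, character(1), k))
  center <- f(4)
  restraint_set(data.frame(i = f(2), j = f(3), center = center,
                           lower = center - f(5), upper = center + f(6)))
}

#' Contact list from a distance map or a score matrix
#'
#' In `threshold` mode, every pair `i < j` with `|i - j| >= min_sep` and
#' distance at most `cutoff` (8 Angstrom, the CASP convention for C-beta
#' contacts) is a contact, scored by `-distance`. In `top2L` mode the `2L`
#' highest-scoring pairs are kept, the standard budget handed to
#' contact-based folding protocols.
#'
#' @param d symmetric distance matrix (threshold mode), or any symmetric
#'   score matrix with larger = more likely in `top2L` mode
#' @param mode `"threshold"` or `"top2L"`
#' @param cutoff contact cutoff in Angstrom
#' @param min_sep minimum sequence separation
#' @return `contact_list`: data.frame (i, j, score) sorted by descending score
#' @export
contacts_from_dmap <- function(d, mode = c("threshold", "top2L"), cutoff = 8,
                               min_sep = 6L) {
  mode <- match.arg(mode)
  d <- as.matrix(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  idx <- idx[(idx[, 2] - idx[, 1]) >= min_sep, , drop = FALSE]
  score <- if (mode == "threshold") -d[idx] else d[idx]
  keep <- if (mode == "threshold") d[idx] <= cutoff else {
    rank(-score, ties.method = "first") <= 2L * nrow(d)
  }
  out <- data.frame(i = idx[keep, 1], j = idx[keep, 2], score = score[keep])
  out <- out[order(-out$score, out$i, out$j), ]
  rownames(out) <- NULL
  structure(out, class = c("contact_list", "data.frame"))
}

#' Write contacts in CASP RR-like text (i j d_lo d_hi score)
#' @param contacts a `contact_list`
#' @param path output file
#' @param range allowed distance range written with each pair; `[3.5, 8]` is
#'   the conventional setting for contact-based folding
#' @export
write_contacts_rr <- function(contacts, path, range = c(3.5, 8)) {
  writeLines(sprintf("%d %d %.1f %.1f %.4f", contacts$i, contacts$j,
                     range[1], range[2], contacts$score), path)
  invisible(path)
}

#' Embed a distance map into 3D coordinates (classical MDS)
#'
#' Double-centres the squared-distance matrix and takes the top three
#' eigenpairs. Distances alone cannot fix chirality, so both the embedding
#' and its mirror image are returned, ranked by a local-chain-geometry
#' heuristic: the mean sign of consecutive-quadruple torsion angles is
#' compared with the right-handed helix convention of the synthetic
#' backbones. A map that is substantially non-Euclidean (large negative
#' eigenvalues) is flagged and a best-effort embedding returned.
#'
#' @param d symmetric distance matrix (possibly noisy)
#' @return list with `coords` (preferred L x 3), `mirror` (the other
#'   chirality), `eigenvalues` (top of the spectrum), and `non_euclidean`
#'   flag
#' @export
embed_dmap <- function(d) {
  d <- as.matrix(d)
  L <- nrow(d)
  J <- diag(L) - 1 / L
  B <- -0.5 * J %*% (d^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- eg$values
  non_euclidean <- any(ev < -1e-6 * max(abs(ev)) * L)
  top <- pmax(ev[1:3], 0)
  X <- eg$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(top), 3)
  Xm <- X %*% diag(c(-1, 1, 1))
  if (mean_torsion_sign(X) >= mean_torsion_sign(Xm)) {
    out <- list(coords = X, mirror = Xm)
  } else {
    out <- list(coords = Xm, mirror = X)
  }
  c(out, list(eigenvalues = ev[1:min(6, L)], non_euclidean = non_euclidean))
}

# mean torsion *sine* over consecutive atom quadruples; the synthetic helix
# convention is a positive (right-handed) twist. Using sin rather than the
# raw angle makes near-planar (trans, ~180 degree) strand quadruples — whose
# angle sign is numerically arbitrary — contribute nothing, so helix content
# dominates the chirality vote.
mean_torsion_sign <- function(xyz) {
  L <- nrow(xyz)
  if (L < 4) return(0)
  s <- 0
  for (i in 1:(L - 3)) {
    b1 <- xyz[i + 1, ] - xyz[i, ]
    b2 <- xyz[i + 2, ] - xyz[i + 1, ]
    b3 <- xyz[i + 3, ] - xyz[i + 2, ]
    n1 <- pracma_cross(b1, b2)
    n2 <- pracma_cross(b2, b3)
    y <- sum(pracma_cross(n1, n2) * b2) / sqrt(sum(b2^2))
    den <- sqrt(sum(n1^2) * sum(n2^2))
    if (den <= 1e-12) next
    # helix-like quadruples (i to i+3 about 5 A apart) carry the chirality
    # convention; extended or loop quadruples get only a token vote
    d13 <- sqrt(sum((xyz[i + 3, ] - xyz[i, ])^2))
    w <- if (d13 < 7) 1 else 0.05
    s <- s + w * y / den
  }
  s / (L - 3)
}

#' Optimal rigid superposition and RMSD (Kabsch)
#'
#' Least-squares superposition of `b` onto `a` with a proper rotation only
#' (no reflection), via SVD of the cross-covariance.
#' @param a,b L x 3 coordinate matrices in correspondence
#' @return list with `rotation` (3 x 3), `translation` (length 3, applied to
#'   `b` after rotation), and `rmsd` in Angstrom
#' @export
superpose_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets must have equal size")
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  s <- svd(crossprod(B, A))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Bf <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((A - Bf)^2)))
  list(rotation = R, translation = ca - drop(R %*% cb), rmsd = rmsd)
}
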