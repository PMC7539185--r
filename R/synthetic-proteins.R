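# Synthetic-protein factory: toy backbones, conformational jitter ensembles,
# partially informative feature bundles, and toy alignments. These stand in
# statistically for the real training corpus (PDB chains, MD snapshots,
# MSA-derived feature extractors), so the learning and evaluation machinery is
# exercisable with no external data.

CLASH_MIN <- 3.0        # Angstrom floor between non-adjacent trace atoms
BOND_RANGE <- c(3.0, 4.2)

helix_template <- function(n) {
  t <- 0:n
  r <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
  cbind(r * cos(twist * t), r * sin(twist * t), rise * t)
}

strand_template <- function(n) {
  t <- 0:n
  cbind(0.8 * (-1)^t, 0, 3.3 * t)
}

loop_template <- function(n) {
  # persistent random walk, step 3.8 A
  dirs <- matrix(stats::rnorm(3 * (n + 1)), ncol = 3)
  out <- matrix(0, n + 1, 3)
  d <- c(0, 0, 1)
  for (i in seq_len(n) + 1L) {
    d <- d + 0.9 * dirs[i, ]
    d <- d / sqrt(sum(d^2))
    out[i, ] <- out[i - 1, ] + 3.8 * d
  }
  out
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q %*% diag(c(1, 1, det(Q)))
}

rotation_onto <- function(target) {
  # proper rotation taking +z to `target`, with random spin about it
  target <- target / sqrt(sum(target^2))
  spin <- random_rotation()
  z <- spin %*% c(0, 0, 1)
  v <- pracma_cross(z, target)
  s <- sqrt(sum(v^2)); cth <- sum(z * target)
  if (s < 1e-12) R <- diag(3) * sign(cth) else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  R %*% spin
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

draw_segments <- function(length, ss_composition) {
  types <- names(ss_composition)
  segs <- list(); placed <- 0L
  while (placed < length) {
    ty <- sample(types, 1, prob = ss_composition)
    n <- switch(ty,
      helix = 6L + stats::rpois(1, 4),
      strand = 4L + stats::rpois(1, 2),
      loop = 2L + stats::rpois(1, 2))
    n <- min(n, length - placed)
    segs[[length(segs) + 1L]] <- list(type = ty, n = n)
    placed <- placed + n
  }
  segs
}

#' Generate a clash-free synthetic protein backbone
#'
#' Builds a single-trace-atom backbone from ideal-geometry secondary-structure
#' segments (helix: 1.5 Angstrom rise per residue on a 100-degree twist;
#' strand: 3.3 Angstrom rise with a small zigzag; loop: persistent random
#' walk), joined with randomly oriented segment placement, a soft confinement
#' bias toward a globular radius, and rejection sampling until the chain is
#' clash-free (no two non-adjacent atoms closer than 3 Angstrom).
#'
#' @param length residue count, at least 10
#' @param ss_composition named numeric, sampling weights for segment types
#'   `helix`, `strand`, `loop`; must sum to 1
#' @param seed integer seed; identical seeds give identical proteins
#' @param max_tries global rebuild attempts before giving up
#' @return a `synthetic_protein`: list with `length`, `coords` (L x 3),
#'   `ss_labels`, `seed`
#' @export
generate_backbone <- function(length,
                              ss_composition = c(helix = 0.4, strand = 0.25, loop = 0.35),
                              seed = 1L, max_tries = 40L) {
  if (length < 10) stop("length must be at least 10")
  if (abs(sum(ss_composition) - 1) > 1e-9) stop("ss_composition must sum to 1")
  set.seed(seed)
  r_conf <- 3.4 * length^(1 / 3)
  margin <- CLASH_MIN + 0.2   # build margin so jitter has headroom

  for (try_ in seq_len(max_tries)) {
    segs <- draw_segments(length, ss_composition)
    coords <- matrix(0, 0, 3)
    labels <- character(0)
    ok <- TRUE
    for (sg in segs) {
      placed <- FALSE
      for (attempt in 1:30) {
        tmpl <- switch(sg$type,
          helix = helix_template(sg$n),
          strand = strand_template(sg$n),
          loop = loop_template(sg$n))
        tmpl <- sweep(tmpl, 2, tmpl[1, ])   # anchor first template atom at origin
        if (nrow(coords) == 0L) {
          seg <- tmpl[-1, , drop = FALSE] %*% t(random_rotation())
          seg <- rbind(c(0, 0, 0), seg)[seq_len(sg$n), , drop = FALSE]
        } else {
          p_end <- coords[nrow(coords), ]
          u <- if (nrow(coords) > 1) p_end - coords[nrow(coords) - 1, ] else stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          inward <- -p_end
          ni <- sqrt(sum(inward^2))
          w_in <- max(0, ni / r_conf - 0.55)
          dirv <- u + (if (ni > 1e-9) w_in * inward / ni else 0) + 0.7 * stats::rnorm(3)
          R <- rotation_onto(dirv)
          seg <- sweep(tmpl %*% t(R), 2, -p_end, "-")[-1, , drop = FALSE]
        }
        cand <- rbind(coords, seg)
        if (nrow(cand) > 2 &&
            cpp_min_nonadjacent_dist(cand, 2L) < margin) next
        coords <- cand
        labels <- c(labels, rep(sg$type, sg$n))
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok && nrow(coords) == length) {
      coords <- sweep(coords, 2, colMeans(coords))
      p <- list(length = length, coords = coords, ss_labels = labels, seed = seed)
      class(p) <- "synthetic_protein"
      return(p)
    }
  }
  stop(sprintf("failed to build a clash-free backbone for seed %d after %d tries",
               seed, max_tries))
}

#' @export
print.synthetic_protein <- function(x, ...) {
  cat(sprintf("<synthetic_protein> L=%d (%s), seed=%d\n", x$length,
              paste(sprintf("%s %d", names(table(x$ss_labels)), table(x$ss_labels)),
                    collapse = ", "), x$seed))
  invisible(x)
}

#' Pairwise distance map of a synthetic protein
#' @param p a `synthetic_protein` (or bare L x 3 coordinate matrix)
#' @return a validated [dmap()] of Euclidean trace-atom distances
#' @export
coords_to_dmap <- function(p) {
  xyz <- if (is.list(p)) p$coords else p
  dmap(as.matrix(stats::dist(xyz)))
}

#' Conformational jitter ensemble (label-augmentation stand-in)
#'
#' Emulates the role of an equilibrium molecular-dynamics trajectory for label
#' augmentation: snapshots are produced by cumulative seeded Gaussian
#' perturbation of the coordinates with bond lengths re-projected to their
#' initial values after every step, so structures drift away from the start
#' while remaining chain-like and clash-free. Only the snapshot count/timing
#' contract (`total_steps / save_every` snapshots, e.g. 2,500,000 / 5,000 =
#' 500) and the qualitative drift are modelled; there is no force field.
#'
#' @param p a `synthetic_protein`
#' @param total_steps,save_every abstract step schedule; `save_every` must
#'   divide `total_steps`
#' @param amplitude per-coordinate Gaussian step (Angstrom) per saved snapshot
#' @param seed integer seed
#' @return a `jitter_ensemble`: list with `snapshots` (list of L x 3
#'   matrices), `schedule`
#' @export
jitter_ensemble <- function(p, total_steps = 2500000, save_every = 5000,
                            amplitude = 0.1, seed = 1L) {
  if (amplitude <= 0) stop("amplitude must be positive")
  if (total_steps %% save_every != 0) stop("save_every must divide total_steps")
  n_snap <- total_steps %/% save_every
  set.seed(seed)
  x <- p$coords
  L <- nrow(x)
  d0 <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-L, , drop = FALSE])^2))
  snaps <- vector("list", n_snap)
  for (t in seq_len(n_snap)) {
    accepted <- FALSE
    for (k in 1:20) {
      y <- x + amplitude * matrix(stats::rnorm(3 * L), L, 3)
      # re-project bond lengths sequentially from the first atom
      for (i in 2:L) {
        v <- y[i, ] - y[i - 1, ]
        y[i, ] <- y[i - 1, ] + v * (d0[i - 1] / sqrt(sum(v^2)))
      }
      if (cpp_min_nonadjacent_dist(y, 2L) >= CLASH_MIN) { accepted <- TRUE; break }
    }
    if (accepted) x <- y   # otherwise the drift pauses for this snapshot
    snaps[[t]] <- x
  }
  structure(list(snapshots = snaps,
                 schedule = c(total_steps = total_steps, save_every = save_every)),
            class = "jitter_ensemble")
}

# separable Gaussian blur with edge renormalisation (sigma in grid units)
gaussian_blur <- function(m, sigma = 1.5) {
  r <- ceiling(2 * sigma)
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  L <- nrow(m)
  K <- matrix(0, L, L)
  for (o in -r:r) {
    idx <- seq_len(L) + o
    ok <- idx >= 1 & idx <= L
    K[cbind(which(ok), idx[ok])] <- w[o + r + 1]
  }
  K <- K / rowSums(K)
  K %*% m %*% t(K)
}

#' Synthesise a raw feature bundle for one protein
#'
#' Emulates the statistical role of real sequence-derived feature extractors.
#' Real 2D features (evolutionary couplings, mutual information) are
#' informative about the coarse contact pattern but spatially diffuse: they
#' do not carry the pixel-level texture of the true map. The synthetic 2D
#' channels therefore degrade with `noise_level` in two ways at once — they
#' blend toward a Gaussian-blurred version of the true map and acquire
#' spatially smooth symmetric noise — so the coarse stripes survive while
#' high frequencies disappear. At `noise_level = 0` the first channel equals
#' the map exactly. The fourth channel is the deterministic
#' sequence-separation grid. The 1D block carries one-hot secondary
#' structure, residue position and seeded noise padded to 62 rows; the 0D
#' block is (protein length, pseudo alignment depth).
#'
#' @param d a distance map (Angstrom)
#' @param ss_labels character vector of per-residue labels
#'   in `helix`/`strand`/`loop`
#' @param noise_level non-negative degradation scale (0 = perfect features)
#' @param seed integer seed
#' @return list with `f0` (length 2), `f1` (62 x L), `f2` (4 x L x L array)
#' @export
synth_features <- function(d, ss_labels, noise_level = 0.3, seed = 1L) {
  if (noise_level < 0) stop("noise_level must be non-negative")
  d <- as.matrix(unclass(d))
  L <- nrow(d)
  set.seed(seed)
  f0 <- c(length = L, align_depth = round(stats::runif(1, 50, 5000)))

  f1 <- matrix(stats::rnorm(62 * L), 62, L)
  ss_idx <- match(ss_labels, c("helix", "strand", "loop"))
  f1[1:3, ] <- 0
  f1[cbind(ss_idx, seq_len(L))] <- 1
  f1[4, ] <- seq_len(L) / L

  smooth_noise <- function() {
    e <- matrix(stats::rnorm(L * L), L, L)
    e <- gaussian_blur((e + t(e)) / sqrt(2))
    e / max(stats::sd(e), 1e-12)
  }
  degrade <- function(m) {
    a <- min(1, noise_level)
    (1 - a) * m + a * gaussian_blur(m) +
      noise_level * stats::sd(m) * smooth_noise()
  }
  f2 <- array(0, dim = c(4, L, L))
  f2[1, , ] <- degrade(d)
  f2[2, , ] <- degrade(exp(-d / 8))
  f2[3, , ] <- degrade(1 / (1 + (d / 8)^2))
  f2[4, , ] <- abs(outer(seq_len(L), seq_len(L), "-")) / L
  list(f0 = f0, f1 = f1, f2 = f2)
}

#' Generate a toy multiple sequence alignment with identity clusters
#'
#' Sequences are built around `n_clusters` mutually divergent centre
#' sequences; members of a cluster are light mutations of their centre so
#' that intra-cluster identity is at least 75% and inter-cluster identity is
#' below 75%. The construction is verified and re-drawn until it satisfies
#' both constraints.
#'
#' @param n_seq number of sequences
#' @param length alignment length
#' @param n_clusters identity clusters; members are assigned round-robin
#' @param seed integer seed
#' @param threshold identity threshold the clusters are built around
#' @return character vector of aligned sequences, with cluster assignment in
#'   attribute `cluster`
#' @export
toy_msa <- function(n_seq, length = 60L, n_clusters = 1L, seed = 1L,
                    threshold = 0.75) {
  if (n_seq < 1) stop("n_seq must be at least 1")
  if (n_clusters > n_seq) stop("more clusters than sequences")
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  assign <- rep(seq_len(n_clusters), length.out = n_seq)
  mut_rate <- min(0.08, (1 - threshold) / 3)
  for (try_ in 1:50) {
    centers <- replicate(n_clusters, sample(aa, length, replace = TRUE),
                         simplify = FALSE)
    seqs <- lapply(assign, function(k) {
      s <- centers[[k]]
      mut <- stats::runif(length) < mut_rate
      s[mut] <- sample(aa, sum(mut), replace = TRUE)
      paste(s, collapse = "")
    })
    seqs <- unlist(seqs)
    pid <- pairwise_identity(seqs)
    same <- outer(assign, assign, "==")
    ok_in <- all(pid[same] >= threshold)
    ok_out <- n_clusters == 1L || all(pid[!same] < threshold)
    if (ok_in && ok_out) return(structure(seqs, cluster = assign))
  }
  stop("could not satisfy the identity-cluster constraints; ",
       "alignment length ", length, " is likely too short")
}

#' Write a synthetic protein as a minimal PDB coordinate file
#'
#' Trace atoms are emitted as CA ATOM records (GLY residues) for visual
#' inspection in standard structure viewers.
#' @param p a `synthetic_protein` or L x 3 coordinate matrix
#' @param path output file
#' @export
write_pdb_trace <- function(p, path) {
  xyz <- if (is.list(p)) p$coords else p
  lines <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(xyz)), seq_len(nrow(xyz)), xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
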