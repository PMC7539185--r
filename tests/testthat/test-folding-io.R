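# Restraint export/parse, contact lists, the MDS embedder and superposition.

test_that("restraint writer emits the documented assign format", {
  r <- restraint_set(data.frame(i = 3, j = 9, center = 10,
                                lower = 9.6, upper = 10.4))
  tf <- tempfile(fileext = ".tbl")
  write_cns_restraints(r, tf)
  lines <- readLines(tf)
  expect_equal(lines[3],
               "assign (resid 3 and name cb) (resid 9 and name cb) 10.0000 0.40 0.40")
  # empty set: header-only file
  r0 <- restraint_set(data.frame(i = integer(), j = integer(),
                                 center = numeric(), lower = numeric(),
                                 upper = numeric()))
  tf0 <- tempfile()
  write_cns_restraints(r0, tf0)
  expect_true(all(grepl("^!", readLines(tf0))))
})

test_that("write -> parse -> write round trips", {
  set.seed(401)
  raw <- matrix(runif(225, 3, 20), 15, 15)
  pred <- (raw + t(raw)) / 2; diag(pred) <- 0
  r <- select_restraints(pred)
  t1 <- tempfile(); t2 <- tempfile()
  write_cns_restraints(r, t1)
  back <- read_cns_restraints(t1)
  # parse-after-write reproduces the set at the printed precision
  expect_equal(back$i, r$i); expect_equal(back$j, r$j)
  expect_equal(back$center, r$center, tolerance = 1e-4)
  # and re-writing the parsed set is byte-identical
  write_cns_restraints(back, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("contact extraction agrees with brute-force threshold scans", {
  set.seed(402)
  p <- generate_backbone(30, seed = 402)
  d <- unclass(coords_to_dmap(p))
  ct <- contacts_from_dmap(d, min_sep = 6L)
  n_brute <- 0L
  for (i in 1:29) for (j in (i + 1):30) {
    if (j - i >= 6 && d[i, j] <= 8) n_brute <- n_brute + 1L
  }
  expect_equal(nrow(ct), n_brute)
  expect_true(all(diff(ct$score) <= 0))

  # exactly three qualifying long-range pairs
  m <- matrix(20, 10, 10); diag(m) <- 0
  for (pr in list(c(1, 8), c(2, 9), c(3, 10))) {
    m[pr[1], pr[2]] <- m[pr[2], pr[1]] <- 6
  }
  expect_equal(nrow(contacts_from_dmap(m, min_sep = 6L)), 3L)

  # top-2L budget
  sc <- matrix(runif(400), 20, 20); sc <- (sc + t(sc)) / 2
  top <- contacts_from_dmap(sc, mode = "top2L", min_sep = 1L)
  expect_lte(nrow(top), 40L)
})

test_that("contact lists export in RR-like text", {
  m <- matrix(20, 10, 10); diag(m) <- 0
  m[1, 9] <- m[9, 1] <- 5
  ct <- contacts_from_dmap(m, min_sep = 6L)
  tf <- tempfile()
  write_contacts_rr(ct, tf)
  expect_match(readLines(tf)[1], "^1 9 3.5 8.0 ")
})

test_that("the MDS embedder reconstructs noise-free backbones", {
  p <- generate_backbone(30, seed = 403)
  d <- coords_to_dmap(p)
  em <- embed_dmap(d)
  expect_false(em$non_euclidean)
  expect_lt(superpose_rmsd(p$coords, em$coords)$rmsd, 0.1)

  # collinear points give a rank-1 embedding
  line <- cbind(seq(0, 9, by = 3), 0, 0)
  em2 <- embed_dmap(as.matrix(dist(line)))
  expect_lt(abs(em2$eigenvalues[2]), 1e-6 * em2$eigenvalues[1])
  expect_lt(abs(em2$eigenvalues[3]), 1e-6 * em2$eigenvalues[1])
})

test_that("moderate symmetric noise degrades but preserves the topology", {
  set.seed(404)
  p <- generate_backbone(30, seed = 404)
  d <- unclass(coords_to_dmap(p))
  e <- matrix(rnorm(900, sd = 0.2), 30, 30)
  noisy <- pmax(d + (e + t(e)) / 2, 0); diag(noisy) <- 0
  em <- embed_dmap(noisy)
  rmsd <- superpose_rmsd(p$coords, em$coords)$rmsd
  expect_gt(rmsd, 1e-4)
  expect_lt(rmsd, 2)
})

test_that("superposition is exact on rigid copies and symmetric", {
  set.seed(405)
  a <- matrix(rnorm(45), 15, 3)
  expect_equal(superpose_rmsd(a, a)$rmsd, 0, tolerance = 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  b <- a %*% t(R) + matrix(c(3, -2, 8), 15, 3, byrow = TRUE)
  expect_lt(superpose_rmsd(a, b)$rmsd, 1e-9)
  # rotation returned is proper
  expect_equal(det(superpose_rmsd(a, b)$rotation), 1, tolerance = 1e-9)
  # symmetry and joint-rotation invariance
  b2 <- a + matrix(rnorm(45, sd = 0.5), 15, 3)
  expect_equal(superpose_rmsd(a, b2)$rmsd, superpose_rmsd(b2, a)$rmsd,
               tolerance = 1e-9)
  expect_equal(superpose_rmsd(a %*% t(R), b2 %*% t(R))$rmsd,
               superpose_rmsd(a, b2)$rmsd, tolerance = 1e-9)
})

test_that("superposition matches an exhaustive rotation-grid oracle", {
  set.seed(406)
  a <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  b <- a + matrix(rnorm(12, sd = 0.4), 4, 3)
  expect_equal(superpose_rmsd(a, b)$rmsd, grid_superpose_rmsd(a, b),
               tolerance = 1e-3)
})

test_that("superposition agrees with an established structural-biology tool", {
  skip_if_not_installed("bio3d")
  set.seed(407)
  a <- matrix(rnorm(60), 20, 3)
  b <- a %*% t(qr.Q(qr(matrix(rnorm(9), 3)))) + 2 +
    matrix(rnorm(60, sd = 0.3), 20, 3)
  ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  expect_equal(superpose_rmsd(a, b)$rmsd, ref, tolerance = 1e-3)
})

test_that("evaluation reports the documented fields", {
  p <- generate_backbone(20, seed = 408)
  d <- coords_to_dmap(p)
  rep <- evaluate_prediction(d, d, coords_true = p$coords)
  expect_equal(rep$band_l1, 0)
  expect_lt(rep$embed_rmsd, 0.1)
  expect_equal(rep$contact_precision, 1)
  expect_named(rep, c("band_l1", "sharpness_pred", "sharpness_true",
                      "embed_rmsd", "contact_precision", "n_band_pairs"))

  # band-L1 by hand on a 4x4 toy map
  tru <- matrix(c(0, 5, 9, 20,
                  5, 0, 6, 10,
                  9, 6, 0, 7,
                  20, 10, 7, 0), 4, 4)
  prd <- tru + 1; diag(prd) <- 0
  # pairs with sep >= 2 and predicted value in [4, 16]: (1,3)=10, (2,4)=11
  rep2 <- evaluate_prediction(prd, dmap(tru), min_sep = 2L)
  expect_equal(rep2$n_band_pairs, 2L)
  expect_equal(rep2$band_l1, 1)
})
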