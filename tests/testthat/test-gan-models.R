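# Architecture contracts: generator shapes and bounds, attention behavior,
# patch and SPP discriminators, receptive fields, checkpoints.

test_that("Swish is zero at zero and configs validate", {
  sw <- distgan:::nn_swish(1.0)
  expect_equal(sw$forward(array(0, c(1, 1, 1)))[1], 0)
  expect_error(generator_config(kernel = 4L), "odd")
  expect_error(generator_config(n_conv_layers = 2L), "at least")
  expect_error(generator_config(activation = "gelu"), "activation")
})

test_that("generator is fully convolutional with bounded outputs", {
  set.seed(200)
  cfg <- tiny_gen_cfg(attention = TRUE)
  gen <- build_generator(cfg)
  cfg130 <- generator_config(n_conv_layers = 5L, block_size = 3L, kernel = 3L,
                             channels = 6L, attention = FALSE)
  gen130 <- build_generator(cfg130)
  out <- generator_forward(gen130, array(rnorm(24 * 24 * 130), c(24, 24, 130)))
  expect_true(all(out > -1 & out < 1))
  for (L in c(16, 32, 48)) {
    x <- array(rnorm(L * L * 130), c(L, L, 130))
    o <- generator_forward(gen130, x)
    expect_equal(dim(o), c(L, L))
  }
  expect_error(gen130$forward(array(0, c(16, 16, 7))), "channels")
})

test_that("generator layer count follows the block layout rule", {
  count_convs <- function(cfg) {
    n <- sum(vapply(distgan:::nn_layers(build_generator(cfg)),
                    function(l) inherits(l, "nn_conv2d"), logical(1)))
    # subtract the attention module's pixel-attention convolution if present
    if (cfg$attention) n - 1L else n
  }
  expect_equal(count_convs(generator_config(n_conv_layers = 12, channels = 4,
                                            kernel = 3, attention = FALSE)), 12L)
  expect_equal(count_convs(generator_config(n_conv_layers = 8, channels = 4,
                                            kernel = 3, attention = TRUE)), 8L)
})

test_that("generator is translation-covariant in the interior", {
  set.seed(201)
  cfg <- generator_config(n_conv_layers = 5L, block_size = 3L, kernel = 3L,
                          channels = 6L, attention = FALSE, batchnorm = FALSE,
                          in_channels = 4L)
  gen <- build_generator(cfg)
  L <- 30; s <- 4
  x <- array(0, c(L, L, 4))
  x[9:20, 9:20, ] <- rnorm(12 * 12 * 4)
  xs <- array(0, c(L, L, 4))
  xs[(9 + s):(20 + s), (9 + s):(20 + s), ] <- x[9:20, 9:20, ]
  o <- generator_forward(gen, x)
  os <- generator_forward(gen, xs)
  expect_equal(os[(9 + s):(20 + s), (9 + s):(20 + s)], o[9:20, 9:20],
               tolerance = 1e-9)
})

test_that("attention weights are in (0,1), shrink the stack, and can saturate to identity", {
  set.seed(202)
  att <- nn_attention(130L)
  x <- array(rnorm(12 * 12 * 130), c(12, 12, 130))
  w <- attention_weights(att, x)
  expect_length(w$caf, 130L)
  expect_equal(dim(w$paf), c(12L, 12L))
  expect_true(all(w$caf > 0 & w$caf < 1))
  expect_true(all(w$paf > 0 & w$paf < 1))
  out <- att$forward(x, train = FALSE)
  expect_true(all(abs(out) <= abs(x)))
  expect_error(att$forward(array(0, c(5, 5, 7))), "channels")

  # saturating both sigmoid biases forces the module toward the identity
  ls_ <- distgan:::nn_layers(att)
  ls_[[2]]$b <- ls_[[2]]$b + 50     # channel-attention output bias
  ls_[[3]]$b <- ls_[[3]]$b + 50     # pixel-attention convolution bias
  expect_equal(att$forward(x, train = FALSE), x, tolerance = 1e-6)
})

test_that("patch discriminator follows the published sizing rule", {
  cfg <- patch_disc_config(n_layers = 4L, first_width = 128L)
  expect_equal(cfg$widths, c(128L, 256L, 512L, 1L))
  expect_equal(cfg$strides, c(2L, 2L, 1L, 1L))
  expect_equal(cfg$kernels, rep(4L, 4L))
  expect_error(patch_disc_config(n_layers = 2L), "at least 3")
  expect_error(build_patch_discriminator(2), "at least 3")
})

test_that("patch discriminator outputs per-patch probabilities on a contracted grid", {
  set.seed(203)
  cfg <- patch_disc_config(n_layers = 4L, first_width = 4L, in_channels = 6L)
  disc <- build_patch_discriminator(cfg)
  for (L in c(34, 70, 100)) {
    st <- array(rnorm(L * L * 5), c(L, L, 5))
    mp <- matrix(rnorm(L * L), L, L)
    p <- discriminator_forward(disc, st, mp)
    expect_true(all(p > 0 & p < 1))
    side <- L
    for (i in seq_len(cfg$n_layers)) side <- (side + 2 - 4) %/% cfg$strides[i] + 1
    expect_equal(dim(p)[1:2], c(side, side))
  }
})

test_that("receptive field formula matches the published patch sizes", {
  expect_equal(receptive_field(c(4, 4, 4, 4), c(2, 2, 1, 1)), 34L)
  expect_equal(receptive_field(c(4, 4, 4, 4, 4), c(2, 2, 2, 1, 1)), 70L)
  expect_equal(receptive_field(1, 1), 1L)
  expect_error(receptive_field(integer(0), integer(0)), "non-empty")
  expect_error(receptive_field(c(3, 3), 1), "same length")
})

test_that("receptive field agrees with the gradient-probe oracle", {
  set.seed(204)
  expect_equal(probe_receptive_field(c(4, 4, 4, 4), c(2, 2, 1, 1)), 34L)
  for (rep in 1:6) {
    depth <- sample(2:4, 1)
    ks <- sample(c(3, 4, 7), depth, replace = TRUE)
    ss <- sample(1:2, depth, replace = TRUE)
    expect_equal(probe_receptive_field(ks, ss), receptive_field(ks, ss),
                 info = paste("k:", paste(ks, collapse = ","),
                              "s:", paste(ss, collapse = ",")))
  }
})

test_that("SPP discriminator pools to a fixed-length vector for any size", {
  set.seed(205)
  spp <- build_spp_discriminator(in_channels = 4L, width = 6L,
                                 mlp_hidden = c(16L, 8L))
  expect_equal(spp$cfg$vec_len, 6L * 84L)
  for (L in c(16, 33, 64)) {
    st <- array(rnorm(L * L * 3), c(L, L, 3))
    mp <- matrix(rnorm(L * L), L, L)
    p <- discriminator_forward(spp, st, mp)
    expect_length(p, 1L)
    expect_true(p > 0 && p < 1)
  }
  expect_error(spp$forward(array(0, c(6, 6, 4))), ">= 8")
  # the published width gives the 64 x (64 + 16 + 4) = 5376 pooled vector
  expect_equal(build_spp_discriminator(width = 64L)$cfg$vec_len, 5376L)
})

test_that("max pooling is invariant to permutations within one patch", {
  set.seed(206)
  pool <- distgan:::nn_adaptive_maxpool(2L)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  o1 <- pool$forward(x, train = FALSE)
  xp <- x
  xp[1:4, 1:4, ] <- x[sample(4), sample(4), ]   # shuffle inside patch (1,1)
  o2 <- pool$forward(xp, train = FALSE)
  expect_equal(o1, o2)
})

test_that("checkpoints round trip and reject architecture mismatches", {
  set.seed(207)
  cfg <- tiny_gen_cfg()
  gen <- build_generator(cfg)
  x <- array(rnorm(14 * 14 * 130), c(14, 14, 130))
  o1 <- generator_forward(gen, x)
  tf <- tempfile(fileext = ".rds")
  save_checkpoint(gen, tf)
  gen2 <- load_checkpoint(tf, build_generator)
  expect_equal(generator_forward(gen2, x), o1, tolerance = 1e-12)

  ck <- readRDS(tf)
  ck$cfg$channels <- 32L   # tampered config no longer matches fingerprint
  tf2 <- tempfile(fileext = ".rds")
  saveRDS(ck, tf2)
  expect_error(load_checkpoint(tf2, build_generator), "fingerprint")

  # same fingerprint but state sized for another net is refused
  ck3 <- readRDS(tf)
  ck3$cfg <- unclass(generator_config(n_conv_layers = 8L, channels = 4L, kernel = 3L))
  class(ck3$cfg) <- "generator_config"
  ck3$fingerprint <- config_fingerprint(ck3$cfg)
  tf3 <- tempfile(fileext = ".rds")
  saveRDS(ck3, tf3)
  expect_error(load_checkpoint(tf3, build_generator), "size|missing")
})
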