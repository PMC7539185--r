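# Generator and discriminator architectures.
#
# The generator is a fully convolutional residual network: stem convolution,
# residual blocks of `block_size` convolutions (conv -> activation -> batch
# norm), and a 1-channel head bounded by tanh so outputs live in the training
# space. The discriminators are (a) a patch-classifier FCN that scores local
# map patches, and (b) the preliminary spatial-pyramid-pooling classifier that
# scores the whole map with one scalar.

#' Generator architecture description
#'
#' @param n_conv_layers total convolution layers (stem + blocks + head). The
#'   published capacity split is 77 layers ("Model X", routed to chains up to
#'   350 residues) and 52 layers ("Model L", for longer chains); the default
#'   here is the 40-layer preliminary setting. Layers beyond the stem/head
#'   are grouped into residual blocks of `block_size`; a remainder is placed
#'   as plain convolution layers before the head.
#' @param block_size convolutions per residual block (3 outperformed 2)
#' @param kernel odd spatial kernel size (7 was the published choice)
#' @param channels internal channel width
#' @param activation one of `swish`, `relu`, `leaky_relu`
#' @param attention logical: apply the two-stage channel/pixel attention
#'   module to the input stack
#' @param batchnorm logical: batch normalisation after each activation
#' @param swish_beta_init initial value of the learnable Swish beta (one per
#'   layer)
#' @param in_channels input channel count (130-channel feature stack)
#' @return a `generator_config` list
#' @export
generator_config <- function(n_conv_layers = 40L, block_size = 3L, kernel = 7L,
                             channels = 64L, activation = "swish",
                             attention = TRUE, batchnorm = TRUE,
                             swish_beta_init = 1.0, in_channels = 130L) {
  if (kernel %% 2 != 1) stop("kernel size must be odd")
  if (n_conv_layers < 3) stop("need at least stem, one body layer, and head")
  if (!activation %in% c("swish", "relu", "leaky_relu"))
    stop("unsupported activation: ", activation)
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 block_size = as.integer(block_size),
                 kernel = as.integer(kernel), channels = as.integer(channels),
                 activation = activation, attention = attention,
                 batchnorm = batchnorm, swish_beta_init = swish_beta_init,
                 in_channels = as.integer(in_channels)),
            class = "generator_config")
}

#' Model X / Model L presets (77 and 52 convolution layers)
#' @param ... overrides passed to [generator_config()]
#' @export
generator_config_model_x <- function(...) {
  do.call(generator_config, utils::modifyList(list(n_conv_layers = 77L), list(...)))
}

#' @rdname generator_config_model_x
#' @export
generator_config_model_l <- function(...) {
  do.call(generator_config, utils::modifyList(list(n_conv_layers = 52L, channels = 48L),
                                              list(...)))
}

act_layer <- function(cfg) {
  switch(cfg$activation,
    swish = nn_swish(cfg$swish_beta_init),
    relu = nn_activation("relu"),
    leaky_relu = nn_activation("leaky_relu"))
}

conv_unit <- function(cfg, in_ch, out_ch) {
  ls_ <- list(nn_conv2d(in_ch, out_ch, cfg$kernel), act_layer(cfg))
  if (cfg$batchnorm) ls_ <- c(ls_, list(nn_batchnorm2d(out_ch)))
  ls_
}

#' Build a generator network from a configuration
#'
#' The network maps a 130 x L x L training-space feature stack to a 1 x L x L
#' training-space map for any L; it is fully convolutional, so L is free.
#' Weights are drawn from the current RNG state.
#'
#' @param cfg a [generator_config()]
#' @return a `generator` object (layer environment with `$cfg`)
#' @export
build_generator <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  body_layers <- cfg$n_conv_layers - 2L
  n_blocks <- body_layers %/% cfg$block_size
  n_extra <- body_layers %% cfg$block_size
  layers <- list()
  if (cfg$attention) layers <- c(layers, list(nn_attention(cfg$in_channels)))
  layers <- c(layers, conv_unit(cfg, cfg$in_channels, cfg$channels))
  for (b in seq_len(n_blocks)) {
    body <- do.call(c, lapply(seq_len(cfg$block_size), function(i)
      conv_unit(cfg, cfg$channels, cfg$channels)))
    layers <- c(layers, list(nn_residual(nn_sequential(body))))
  }
  for (e in seq_len(n_extra)) {
    layers <- c(layers, conv_unit(cfg, cfg$channels, cfg$channels))
  }
  layers <- c(layers, list(nn_conv2d(cfg$channels, 1L, cfg$kernel),
                           nn_activation("tanh")))
  net <- nn_sequential(layers)
  net$cfg <- cfg
  class(net) <- c("generator", class(net))
  net
}

#' Run a generator on a feature stack
#' @param gen a generator from [build_generator()]
#' @param stack L x L x 130 array in training space
#' @param train logical; training mode uses batch statistics and keeps caches
#' @return L x L matrix in training space (raw, not yet symmetrised)
#' @export
generator_forward <- function(gen, stack, train = FALSE) {
  out <- gen$forward(unclass(stack), train = train)
  matrix(out, dim(out)[1], dim(out)[2])
}

#' Predict a real-space distance map from a feature stack
#'
#' Forward pass in inference mode, upper/lower-triangle averaging of the raw
#' output, inverse label mapping back to Angstrom, and zeroing of the
#' diagonal.
#' @inheritParams generator_forward
#' @return a validated [dmap()]
#' @export
predict_dmap <- function(gen, stack) {
  raw <- generator_forward(gen, stack, train = FALSE)
  m <- symmetrize(raw)
  d <- unmap_label(m)
  diag(d) <- 0
  dmap(pmax(d, 0) * (1 - diag(nrow(d))))
}

# --- attention --------------------------------------------------------------

#' Two-stage channel/pixel attention module
#'
#' Stage 1 (CAF, channel attention): a 130-75-130 bottleneck perceptron (ReLU
#' hidden, sigmoid output) processes the sum of global average and global max
#' pooling of each channel, producing per-channel weights in (0, 1). Stage 2
#' (PAF, pixel attention): a single 7 x 7 stride-1 convolution scans the
#' 2-channel concatenation of the per-pixel channel average and channel max of
#' the channel-reweighted stack, sigmoid-activated to per-pixel weights. The
#' output is `(Raw * CAF(Raw)) * PAF(Raw * CAF(Raw))`.
#'
#' @param n_ch input channel count (130 for the standard stack)
#' @param bottleneck hidden width of the channel-attention perceptron
#' @param paf_kernel pixel-attention kernel size
#' @return an attention layer usable inside a generator
#' @export
nn_attention <- function(n_ch = 130L, bottleneck = 75L, paf_kernel = 7L) {
  mlp1 <- nn_dense(n_ch, bottleneck)
  mlp2 <- nn_dense(bottleneck, n_ch)
  paf_conv <- nn_conv2d(2L, 1L, paf_kernel)
  self <- new_layer("nn_attention", children = list(mlp1, mlp2, paf_conv))
  self$n_ch <- n_ch

  self$forward <- function(x, train = TRUE) {
    d <- dim(x)
    if (d[3] != self$n_ch)
      stop(sprintf("attention expects %d channels, got %d", self$n_ch, d[3]))
    hw <- d[1] * d[2]
    xm <- matrix(x, hw, d[3])
    arg_c <- max.col(t(xm), ties.method = "first")       # argmax pixel per channel
    ca_in <- colMeans(xm) + xm[cbind(arg_c, seq_len(d[3]))]
    h1 <- mlp1$forward(ca_in, train)
    r1 <- pmax(h1, 0)
    caf <- sigmoid_(mlp2$forward(r1, train))
    xm1 <- sweep(xm, 2, caf, "*")
    arg_p <- max.col(xm1, ties.method = "first")         # argmax channel per pixel
    pa_in <- array(c(rowMeans(xm1), xm1[cbind(seq_len(hw), arg_p)]),
                   dim = c(d[1], d[2], 2))
    pz <- paf_conv$forward(pa_in, train)
    paf <- sigmoid_(as.vector(pz))
    out <- sweep(xm1, 1, paf, "*")
    if (train) {
      self$cache <- list(d = d, xm = xm, xm1 = xm1, caf = caf, paf = paf,
                         h1 = h1, arg_c = arg_c, arg_p = arg_p)
    }
    array(out, dim = d)
  }

  self$backward <- function(g) {
    cc <- self$cache
    d <- cc$d; hw <- d[1] * d[2]
    gm <- matrix(g, hw, d[3])
    g_x1 <- sweep(gm, 1, cc$paf, "*")
    g_paf <- rowSums(gm * cc$xm1)
    g_pz <- g_paf * cc$paf * (1 - cc$paf)
    g_pa_in <- paf_conv$backward(array(g_pz, dim = c(d[1], d[2], 1)))
    g_pa <- matrix(g_pa_in, hw, 2)
    g_x1 <- g_x1 + g_pa[, 1] / d[3]
    idx_p <- cbind(seq_len(hw), cc$arg_p)
    g_x1[idx_p] <- g_x1[idx_p] + g_pa[, 2]
    g_x <- sweep(g_x1, 2, cc$caf, "*")
    g_caf <- colSums(g_x1 * cc$xm)
    g_z <- g_caf * cc$caf * (1 - cc$caf)
    g_r1 <- mlp2$backward(g_z)
    g_h1 <- g_r1 * (cc$h1 > 0)
    g_ca <- mlp1$backward(g_h1)
    g_x <- sweep(g_x, 2, g_ca / hw, "+")
    idx_c <- cbind(cc$arg_c, seq_len(d[3]))
    g_x[idx_c] <- g_x[idx_c] + g_ca
    array(g_x, dim = d)
  }
  self
}

#' Channel and pixel attention weights for a stack (diagnostic)
#' @param att an [nn_attention()] layer
#' @param stack L x L x C array
#' @return list with `caf` (length C) and `paf` (L x L matrix), both in (0, 1)
#' @export
attention_weights <- function(att, stack) {
  out <- att$forward(unclass(stack), train = TRUE)
  d <- dim(out)
  list(caf = att$cache$caf, paf = matrix(att$cache$paf, d[1], d[2]))
}

# --- discriminators ---------------------------------------------------------

#' Patch-classifier discriminator configuration
#'
#' Fully convolutional classifier over 4 x 4 kernels: all but the last two
#' layers have stride 2 (to grow the receptive field quickly), the last two
#' stride 1; the first layer has `first_width` channels, doubling each layer,
#' and the final layer has a single sigmoid channel giving the probability
#' that each patch is real. With 4 layers and `first_width = 128` the widths
#' are (128, 256, 512, 1) and the patch size is 34; with 5 layers it is 70.
#'
#' @param n_layers at least 3 (the last-two-stride-1 rule needs 3 layers)
#' @param first_width channels of the first convolution (128 published;
#'   smaller widths suit desk-scale experiments)
#' @param in_channels conditioning stack channels + 1 judged map channel
#' @param batchnorm logical; normalisation on the interior layers
#' @return a `patch_disc_config`
#' @export
patch_disc_config <- function(n_layers = 4L, first_width = 128L,
                              in_channels = 131L, batchnorm = TRUE) {
  if (n_layers < 3) stop("patch discriminator needs at least 3 layers")
  n_layers <- as.integer(n_layers)
  widths <- c(first_width * 2L^(seq_len(n_layers - 1L) - 1L), 1L)
  strides <- c(rep(2L, n_layers - 2L), 1L, 1L)
  structure(list(variant = "patch_fcn", n_layers = n_layers,
                 kernels = rep(4L, n_layers), strides = strides,
                 widths = widths, in_channels = as.integer(in_channels),
                 batchnorm = batchnorm),
            class = "patch_disc_config")
}

#' Build the patch-classifier discriminator
#'
#' Input is the channel-wise concatenation of the conditioning feature stack
#' and the judged map (real label or generator output); output is a grid of
#' per-patch probabilities in (0, 1).
#'
#' @param cfg a [patch_disc_config()], or an integer layer count
#' @return a `discriminator` layer environment
#' @export
build_patch_discriminator <- function(cfg = patch_disc_config()) {
  if (is.numeric(cfg)) cfg <- patch_disc_config(n_layers = cfg)
  layers <- list()
  in_ch <- cfg$in_channels
  for (i in seq_len(cfg$n_layers)) {
    layers <- c(layers, list(nn_conv2d(in_ch, cfg$widths[i], cfg$kernels[i],
                                       stride = cfg$strides[i], pad = 1L)))
    if (i < cfg$n_layers) {
      layers <- c(layers, list(nn_activation("leaky_relu", slope = 0.2)))
      if (cfg$batchnorm && i > 1L)
        layers <- c(layers, list(nn_batchnorm2d(cfg$widths[i])))
    } else {
      layers <- c(layers, list(nn_activation("sigmoid")))
    }
    in_ch <- cfg$widths[i]
  }
  net <- nn_sequential(layers)
  net$cfg <- cfg
  class(net) <- c("discriminator", class(net))
  net
}

#' Score a map with a discriminator under its conditioning stack
#' @param disc discriminator network
#' @param stack L x L x C conditioning feature stack
#' @param map L x L matrix in training space (label or generator output)
#' @param train logical
#' @return array of patch probabilities (or scalar for the SPP variant)
#' @export
discriminator_forward <- function(disc, stack, map, train = FALSE) {
  d <- dim(stack)
  x <- array(c(unclass(stack), map), dim = c(d[1], d[2], d[3] + 1L))
  disc$forward(x, train = train)
}

#' Analytic receptive-field (patch) size of a stacked convolutional network
#'
#' `RF = 1 + sum_i (k_i - 1) * prod_{j < i} s_j`. For the patch discriminator
#' this is the side length of the input patch a single output probability
#' looks at.
#'
#' @param kernels integer vector of kernel sizes, outermost first
#' @param strides integer vector of strides, same length
#' @return integer patch side length
#' @export
receptive_field <- function(kernels, strides) {
  if (length(kernels) == 0 || length(kernels) != length(strides))
    stop("kernels and strides must be non-empty and the same length")
  jumps <- cumprod(c(1, strides[-length(strides)]))
  as.integer(1 + sum((kernels - 1) * jumps))
}

#' Spatial-pyramid-pooling discriminator configuration (preliminary variant)
#' @inheritParams build_spp_discriminator
#' @return an `spp_disc_config`
#' @export
spp_disc_config <- function(in_channels = 131L, width = 64L,
                            mlp_hidden = c(256L, 64L)) {
  structure(list(variant = "spp", in_channels = as.integer(in_channels),
                 width = as.integer(width), mlp_hidden = as.integer(mlp_hidden)),
            class = "spp_disc_config")
}

#' Build a discriminator from either configuration flavour
#' @param cfg a [patch_disc_config()] or [spp_disc_config()]
#' @return a `discriminator` layer environment
#' @export
build_discriminator <- function(cfg) {
  if (inherits(cfg, "patch_disc_config")) return(build_patch_discriminator(cfg))
  if (inherits(cfg, "spp_disc_config")) {
    return(build_spp_discriminator(cfg$in_channels, cfg$width, cfg$mlp_hidden))
  }
  stop("unknown discriminator configuration")
}

#' Build the preliminary spatial-pyramid-pooling discriminator
#'
#' Three 3 x 3 convolution layers of `width` filters, then max pooling over
#' 8 x 8, 4 x 4 and 2 x 2 partitions of the feature map, concatenated to a
#' fixed-length vector (width x 84) regardless of input size, and a 3-layer
#' perceptron ending in a single sigmoid probability.
#'
#' @param in_channels conditioning channels + judged map
#' @param width convolution width (64 in the preliminary setting)
#' @param mlp_hidden hidden sizes of the perceptron's first two layers
#' @return a `discriminator` layer environment; inputs need side length >= 8
#' @export
build_spp_discriminator <- function(in_channels = 131L, width = 64L,
                                    mlp_hidden = c(256L, 64L)) {
  convs <- nn_sequential(
    nn_conv2d(in_channels, width, 3L), nn_activation("leaky_relu"),
    nn_conv2d(width, width, 3L), nn_activation("leaky_relu"),
    nn_conv2d(width, width, 3L), nn_activation("leaky_relu"))
  pools <- list(nn_adaptive_maxpool(8L), nn_adaptive_maxpool(4L),
                nn_adaptive_maxpool(2L))
  vec_len <- width * (64L + 16L + 4L)
  mlp <- nn_sequential(
    nn_dense(vec_len, mlp_hidden[1]), nn_activation("leaky_relu"),
    nn_dense(mlp_hidden[1], mlp_hidden[2]), nn_activation("leaky_relu"),
    nn_dense(mlp_hidden[2], 1L), nn_activation("sigmoid"))
  self <- new_layer("nn_spp_disc", children = c(list(convs), pools, list(mlp)))
  self$cfg <- list(variant = "spp", in_channels = in_channels, width = width,
                   pyramid = c(8L, 4L, 2L), vec_len = vec_len)
  self$forward <- function(x, train = TRUE) {
    if (min(dim(x)[1:2]) < 8) stop("SPP discriminator needs input side >= 8")
    h <- convs$forward(x, train)
    parts <- lapply(pools, function(p) as.numeric(p$forward(h, train)))
    self$cache_sizes <- lengths(parts)
    v <- unlist(parts)
    mlp$forward(v, train)
  }
  self$backward <- function(g) {
    gv <- mlp$backward(g)
    sz <- self$cache_sizes
    off <- cumsum(c(0, sz))
    gh <- 0
    for (i in seq_along(pools)) {
      n <- pools[[i]]$n
      gpart <- array(gv[(off[i] + 1):off[i + 1]],
                     dim = c(n, n, sz[i] / (n * n)))
      gh <- gh + pools[[i]]$backward(gpart)
    }
    convs$backward(gh)
  }
  class(self) <- c("discriminator", class(self))
  self
}

# --- checkpoints ------------------------------------------------------------

#' Fingerprint of an architecture/loss configuration
#'
#' MD5 over the deparsed configuration; stored in checkpoints and verified on
#' load so weights can never be restored into a mismatched architecture.
#' @param cfg any configuration list
#' @return hex string
#' @export
config_fingerprint <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(cfg[order(names(unclass(cfg)))]), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

#' Save / load network checkpoints with architecture fingerprints
#' @param net a generator or discriminator with a `$cfg`
#' @param path checkpoint file
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(fingerprint = config_fingerprint(net$cfg), cfg = net$cfg,
               state = nn_state_dict(net)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param builder function turning the stored config into a fresh network
#' @export
load_checkpoint <- function(path, builder) {
  ck <- readRDS(path)
  if (!identical(ck$fingerprint, config_fingerprint(ck$cfg)))
    stop("checkpoint fingerprint mismatch: refusing to load")
  net <- builder(ck$cfg)
  nn_load_state(net, ck$state)
  net
}
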