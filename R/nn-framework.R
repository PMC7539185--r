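#' @useDynLib distgan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal convolutional-network engine with manual reverse-mode gradients.
#
# Tensors are plain R arrays with dim = c(H, W, C); a single protein is a
# minibatch of one. Layers are environments exposing forward()/backward();
# backward() ACCUMULATES parameter gradients (g_<name>) so a loss with several
# terms, or a discriminator seeing real and fake inputs, can sum contributions
# before one optimiser step. Gradient correctness is enforced by
# finite-difference checks in the test suite.
# ---------------------------------------------------------------------------

new_layer <- function(class, children = list(), param_names = character()) {
  self <- new.env(parent = emptyenv())
  self$children <- children
  self$param_names <- param_names
  class(self) <- c(class, "nn_layer")
  self
}

#' @export
print.nn_layer <- function(x, ...) {
  np <- sum(vapply(nn_layers(x), function(l) {
    sum(vapply(l$param_names, function(p) length(l[[p]]), numeric(1)))
  }, numeric(1)))
  cat(sprintf("<%s> %d trainable parameters\n", class(x)[1], np))
  invisible(x)
}

#' List all leaf layers of a network (depth-first)
#' @param net a layer or composite layer
#' @return list of layer environments owning parameters or caches
#' @keywords internal
nn_layers <- function(net) {
  if (length(net$children) == 0L) return(list(net))
  out <- list()
  for (ch in net$children) out <- c(out, nn_layers(ch))
  out
}

#' Zero accumulated gradients of every parameter in a network
#' @param net a layer
#' @return the network, invisibly
#' @keywords internal
nn_zero_grads <- function(net) {
  for (l in nn_layers(net)) {
    for (p in l$param_names) l[[paste0("g_", p)]] <- l[[p]] * 0
  }
  invisible(net)
}

#' Extract all parameters of a network as a named list
#' @param net a layer
#' @return named list of numeric arrays (names encode layer index and slot)
#' @export
nn_state_dict <- function(net) {
  out <- list()
  ls_ <- nn_layers(net)
  for (i in seq_along(ls_)) {
    for (p in ls_[[i]]$param_names) {
      out[[sprintf("L%03d.%s", i, p)]] <- ls_[[i]][[p]]
    }
    if (inherits(ls_[[i]], "nn_batchnorm2d")) {
      out[[sprintf("L%03d.run_mean", i)]] <- ls_[[i]]$run_mean
      out[[sprintf("L%03d.run_var", i)]] <- ls_[[i]]$run_var
    }
  }
  out
}

#' Load parameters produced by [nn_state_dict()] into a structurally
#' identical network
#' @param net a layer
#' @param state named list from [nn_state_dict()]
#' @return the network, invisibly
#' @export
nn_load_state <- function(net, state) {
  ls_ <- nn_layers(net)
  for (i in seq_along(ls_)) {
    for (p in ls_[[i]]$param_names) {
      key <- sprintf("L%03d.%s", i, p)
      if (is.null(state[[key]])) stop("state is missing parameter ", key)
      if (length(state[[key]]) != length(ls_[[i]][[p]]))
        stop("parameter ", key, " has wrong size: architecture mismatch")
      ls_[[i]][[p]] <- state[[key]]
    }
    if (inherits(ls_[[i]], "nn_batchnorm2d")) {
      ls_[[i]]$run_mean <- state[[sprintf("L%03d.run_mean", i)]]
      ls_[[i]]$run_var <- state[[sprintf("L%03d.run_var", i)]]
    }
  }
  invisible(net)
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))

# --- 2D convolution ---------------------------------------------------------

#' 2D convolution layer (zero padding, square kernel)
#'
#' Weights use He initialisation from the current RNG state; callers control
#' reproducibility with `set.seed()`.
#'
#' @param in_ch,out_ch channel counts
#' @param k odd kernel side
#' @param stride integer stride
#' @param pad zero padding on each side; default keeps "same" size at stride 1
#' @return a layer environment
#' @keywords internal
nn_conv2d <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  self <- new_layer("nn_conv2d", param_names = c("W", "b"))
  fan_in <- in_ch * k * k
  self$W <- matrix(stats::rnorm(out_ch * fan_in, sd = sqrt(2 / fan_in)),
                   out_ch, fan_in)
  self$b <- numeric(out_ch)
  self$in_ch <- in_ch; self$out_ch <- out_ch
  self$k <- as.integer(k); self$stride <- as.integer(stride)
  self$pad <- as.integer(pad)

  self$forward <- function(x, train = TRUE) {
    d <- dim(x)
    if (d[3] != self$in_ch)
      stop(sprintf("conv2d expected %d input channels, got %d", self$in_ch, d[3]))
    fw <- cpp_conv_fwd(x, self$W, self$b, self$k, self$stride, self$pad, train)
    if (train) {
      self$cache_col <- fw$col
      self$cache_dim <- d
    }
    fw$out
  }
  self$backward <- function(g) {
    d <- self$cache_dim
    bw <- cpp_conv_bwd(self$cache_col, self$W, g, d[1], d[2], self$in_ch,
                       self$k, self$stride, self$pad)
    self$g_W <- self$g_W + bw$gW
    self$g_b <- self$g_b + as.numeric(bw$gb)
    bw$gin
  }
  self
}

# --- batch normalisation ----------------------------------------------------

#' Per-channel batch normalisation over the spatial grid
#'
#' With one protein per minibatch this normalises each channel over its H x W
#' grid. Running moments are tracked for inference mode.
#' @param n_ch channel count
#' @param eps variance floor
#' @param momentum running-statistics update rate
#' @keywords internal
nn_batchnorm2d <- function(n_ch, eps = 1e-5, momentum = 0.1) {
  self <- new_layer("nn_batchnorm2d", param_names = c("gamma", "beta"))
  self$gamma <- rep(1, n_ch); self$beta <- rep(0, n_ch)
  self$run_mean <- rep(0, n_ch); self$run_var <- rep(1, n_ch)
  self$n_ch <- n_ch; self$eps <- eps; self$momentum <- momentum

  self$forward <- function(x, train = TRUE) {
    d <- dim(x); m <- d[1] * d[2]
    xm <- matrix(x, m, d[3])
    if (train) {
      mu <- colMeans(xm)
      va <- colMeans(xm^2) - mu^2
      self$run_mean <- (1 - self$momentum) * self$run_mean + self$momentum * mu
      self$run_var <- (1 - self$momentum) * self$run_var + self$momentum * va
    } else {
      mu <- self$run_mean; va <- self$run_var
    }
    istd <- 1 / sqrt(va + self$eps)
    xhat <- sweep(sweep(xm, 2, mu, "-"), 2, istd, "*")
    y <- sweep(sweep(xhat, 2, self$gamma, "*"), 2, self$beta, "+")
    if (train) {
      self$cache_xhat <- xhat; self$cache_istd <- istd; self$cache_dim <- d
    }
    array(y, dim = d)
  }
  self$backward <- function(g) {
    d <- self$cache_dim; m <- d[1] * d[2]
    gm <- matrix(g, m, d[3])
    xhat <- self$cache_xhat
    self$g_gamma <- self$g_gamma + colSums(gm * xhat)
    self$g_beta <- self$g_beta + colSums(gm)
    dxhat <- sweep(gm, 2, self$gamma, "*")
    s1 <- colSums(dxhat); s2 <- colSums(dxhat * xhat)
    gx <- sweep(dxhat, 2, s1 / m, "-") - sweep(xhat, 2, s2 / m, "*")
    gx <- sweep(gx, 2, self$cache_istd, "*")
    array(gx, dim = d)
  }
  self
}

# --- activations ------------------------------------------------------------

#' Swish activation x * sigmoid(beta * x) with one learnable beta per layer
#' @param beta_init initial slope parameter
#' @keywords internal
nn_swish <- function(beta_init = 1.0) {
  self <- new_layer("nn_swish", param_names = "beta")
  self$beta <- beta_init
  self$forward <- function(x, train = TRUE) {
    s <- sigmoid_(self$beta * x)
    if (train) { self$cache_x <- x; self$cache_s <- s }
    x * s
  }
  self$backward <- function(g) {
    x <- self$cache_x; s <- self$cache_s
    sp <- s * (1 - s)
    self$g_beta <- self$g_beta + sum(g * x * x * sp)
    g * (s + self$beta * x * sp)
  }
  self
}

nn_activation <- function(kind = c("leaky_relu", "relu", "sigmoid", "tanh"),
                          slope = 0.2) {
  kind <- match.arg(kind)
  self <- new_layer(paste0("nn_", kind))
  self$kind <- kind; self$slope <- slope
  self$forward <- function(x, train = TRUE) {
    y <- switch(kind,
      leaky_relu = ifelse(x > 0, x, slope * x),
      relu = pmax(x, 0),
      sigmoid = sigmoid_(x),
      tanh = tanh(x))
    if (is.array(x)) dim(y) <- dim(x)
    if (train) {
      self$cache <- switch(kind, leaky_relu = , relu = x, y)
    }
    y
  }
  self$backward <- function(g) {
    switch(kind,
      leaky_relu = g * ifelse(self$cache > 0, 1, slope),
      relu = g * (self$cache > 0),
      sigmoid = g * self$cache * (1 - self$cache),
      tanh = g * (1 - self$cache^2))
  }
  self
}

# --- dense ------------------------------------------------------------------

#' Fully connected layer on flat vectors
#' @param n_in,n_out sizes
#' @keywords internal
nn_dense <- function(n_in, n_out) {
  self <- new_layer("nn_dense", param_names = c("W", "b"))
  self$W <- matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
  self$b <- numeric(n_out)
  self$forward <- function(x, train = TRUE) {
    x <- as.numeric(x)
    if (train) self$cache_x <- x
    drop(self$W %*% x) + self$b
  }
  self$backward <- function(g) {
    g <- as.numeric(g)
    self$g_W <- self$g_W + outer(g, self$cache_x)
    self$g_b <- self$g_b + g
    drop(crossprod(self$W, g))
  }
  self
}

# --- composites -------------------------------------------------------------

#' Sequential container
#' @param ... layers applied in order
#' @keywords internal
nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "nn_layer")) layers <- layers[[1]]
  self <- new_layer("nn_sequential", children = layers)
  self$forward <- function(x, train = TRUE) {
    for (l in self$children) x <- l$forward(x, train)
    x
  }
  self$backward <- function(g) {
    for (l in rev(self$children)) g <- l$backward(g)
    g
  }
  self
}

#' Residual block: out = x + body(x)
#' @param body a layer (typically a sequential stack of convolutions)
#' @keywords internal
nn_residual <- function(body) {
  self <- new_layer("nn_residual", children = list(body))
  self$forward <- function(x, train = TRUE) x + self$children[[1]]$forward(x, train)
  self$backward <- function(g) g + self$children[[1]]$backward(g)
  self
}

# --- pooling (used by the SPP discriminator) --------------------------------

#' Adaptive max pooling to an n x n partition grid
#'
#' Bin b of axis length H covers rows floor((b-1)H/n)+1 .. floor(bH/n).
#' @param n partition count per side
#' @keywords internal
nn_adaptive_maxpool <- function(n) {
  self <- new_layer("nn_adaptive_maxpool")
  self$n <- as.integer(n)
  self$forward <- function(x, train = TRUE) {
    d <- dim(x); n <- self$n
    if (d[1] < n || d[2] < n)
      stop(sprintf("input side %d too small for %dx%d pooling", min(d[1], d[2]), n, n))
    hb <- floor(seq_len(n) * d[1] / n); hb0 <- c(0L, hb[-n]) + 1L
    wb <- floor(seq_len(n) * d[2] / n); wb0 <- c(0L, wb[-n]) + 1L
    out <- array(0, dim = c(n, n, d[3]))
    arg <- array(0L, dim = c(n, n, d[3]))
    for (c_ in seq_len(d[3])) {
      sl <- x[, , c_]
      for (j in seq_len(n)) for (i in seq_len(n)) {
        blk <- sl[hb0[i]:hb[i], wb0[j]:wb[j], drop = FALSE]
        w <- which.max(blk)
        out[i, j, c_] <- blk[w]
        bi <- (w - 1L) %% nrow(blk) + hb0[i]
        bj <- (w - 1L) %/% nrow(blk) + wb0[j]
        arg[i, j, c_] <- bi + (bj - 1L) * d[1]
      }
    }
    if (train) { self$cache_arg <- arg; self$cache_dim <- d }
    out
  }
  self$backward <- function(g) {
    d <- self$cache_dim
    gx <- array(0, dim = d)
    n <- self$n
    for (c_ in seq_len(d[3])) {
      sl <- matrix(0, d[1], d[2])
      idx <- self$cache_arg[, , c_]
      sl[as.vector(idx)] <- sl[as.vector(idx)] + as.vector(g[, , c_])
      gx[, , c_] <- sl
    }
    gx
  }
  self
}
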