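# Adam optimiser over the parameters of a layer tree.

#' Create an Adam optimiser bound to a network
#'
#' Moment buffers live in the returned environment; `adam_step()` consumes the
#' gradients accumulated by `backward()` calls since the last
#' [nn_zero_grads()].
#'
#' @param net a layer (see `nn_layers()`)
#' @param lr learning rate
#' @param beta1,beta2 Adam moment decay rates; 0.5/0.999 by default, the
#'   customary setting for adversarial training
#' @param eps numerical floor
#' @return an optimiser environment
#' @export
adam_new <- function(net, lr = 1e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$net <- net
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- list(); opt$v <- list()
  ls_ <- nn_layers(net)
  for (i in seq_along(ls_)) {
    for (p in ls_[[i]]$param_names) {
      key <- sprintf("L%03d.%s", i, p)
      opt$m[[key]] <- ls_[[i]][[p]] * 0
      opt$v[[key]] <- ls_[[i]][[p]] * 0
    }
  }
  opt
}

#' Apply one Adam update from accumulated gradients
#' @param opt optimiser from [adam_new()]
#' @param lr optional learning-rate override for this step
#' @return the optimiser, invisibly
#' @export
adam_step <- function(opt, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  ls_ <- nn_layers(opt$net)
  for (i in seq_along(ls_)) {
    for (p in ls_[[i]]$param_names) {
      key <- sprintf("L%03d.%s", i, p)
      g <- ls_[[i]][[paste0("g_", p)]]
      if (is.null(g)) next
      opt$m[[key]] <- b1 * opt$m[[key]] + (1 - b1) * g
      opt$v[[key]] <- b2 * opt$v[[key]] + (1 - b2) * g * g
      mhat <- opt$m[[key]] / corr1
      vhat <- opt$v[[key]] / corr2
      ls_[[i]][[p]] <- ls_[[i]][[p]] - lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  invisible(opt)
}
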