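# Loss functions, schedules, routing, and the training loops.

eps <- 1e-7

test_that("discriminator cross-entropy matches its closed forms", {
  # perfect discriminator limit
  expect_lt(loss_d_plain(1 - eps, eps), 1e-5)
  # maximally uncertain: -2 log(1/2) = 2 ln 2
  expect_equal(loss_d_plain(0.5, 0.5), 2 * log(2), tolerance = 1e-12)
  # symmetric degradation: loss(a, 1 - a) = -2 log a
  for (a in c(0.6, 0.8)) {
    expect_equal(loss_d_plain(a, 1 - a), -2 * log(a), tolerance = 1e-12)
  }
  # patch grids are averaged
  expect_equal(loss_d_plain(c(0.5, 0.5, 0.5, 0.5), matrix(0.5, 2, 2)),
               2 * log(2), tolerance = 1e-12)
})

test_that("clipped discriminator loss filters realistic-looking fakes", {
  # fully rejected fakes contribute -log(0.9)
  expect_equal(loss_d_clipped(1 - eps, 0), -log(0.9), tolerance = 1e-5)
  # a fake patch judged "real" (above the ceiling) hits the epsilon floor,
  # i.e. the clip argument is 0 and the patch carries no useful gradient
  v <- loss_d_clipped(1 - eps, 0.95)
  expect_equal(v, -log(1e-7), tolerance = 1e-4)
  g <- distgan:::loss_d_grad_fake(0.95, loss_config())
  expect_equal(g$g_fake, 0)
  expect_equal(g$n_clamped, 1L)
  # the clip argument is monotone non-increasing in d_fake on [0, 0.9]
  dgrid <- seq(0, 0.9, by = 0.05)
  clip_arg <- pmin(pmax(0.9 - dgrid, 0), 0.9)
  expect_true(all(diff(clip_arg) <= 0))
})

test_that("clipped and unclipped fake terms coincide when the clip is inactive", {
  # in the open overlap region the CLIP is the identity, so the clipped loss
  # equals the same expression with no clamping at all
  d_real <- c(0.7, 0.8)
  d_fake <- c(0.2, 0.5, 0.85)
  expect_equal(loss_d_clipped(d_real, d_fake),
               -(mean(log(d_real)) + mean(log(0.9 - d_fake))),
               tolerance = 1e-12)
})

test_that("generator loss combines adversarial and weighted L1 terms", {
  p <- matrix(0.3, 4, 4); tr <- p
  # perfect prediction accepted by D: both terms vanish
  expect_lt(loss_g(1 - eps, p, tr, loss_config()), 1e-5)
  # pure adversarial term at d_fake = 1/2 is ln 2
  expect_equal(loss_g(0.5, p, tr, loss_config()), log(2), tolerance = 1e-10)
  # lambda scaling on a unit L1 error
  tr2 <- p + 1
  expect_equal(loss_g(1 - eps, p, tr2, loss_config(lambda = 158)), 158,
               tolerance = 1e-4)
  # saturating variant at d_fake = 1/2: log(1 - 1/2) = -ln 2
  expect_equal(loss_g(0.5, p, tr, loss_config(g_loss_variant = "saturating")),
               -log(2), tolerance = 1e-10)
  expect_error(loss_g(0.5, p, matrix(0, 3, 3)), "shape")
})

test_that("multiplying lambda by c scales the regression term exactly by c", {
  set.seed(301)
  p <- matrix(runif(36, -1, 1), 6, 6)
  tr <- matrix(runif(36, -1, 1), 6, 6)
  d_fake <- 0.37
  base <- loss_g(d_fake, p, tr, loss_config(lambda = 50))
  adv <- loss_g(d_fake, p, p, loss_config(lambda = 50))
  for (c_ in c(2, 7.5)) {
    scaled <- loss_g(d_fake, p, tr, loss_config(lambda = 50 * c_))
    expect_equal(scaled - adv, c_ * (base - adv), tolerance = 1e-12)
  }
})

test_that("control loss is the lambda-weighted mean absolute error", {
  p <- matrix(0.2, 5, 5)
  expect_equal(loss_control(p, p), 0)
  expect_equal(loss_control(p, p + 0.3, lambda = 158), 158 * 0.3,
               tolerance = 1e-10)
  set.seed(302)
  a <- matrix(rnorm(49), 7, 7); b <- matrix(rnorm(49), 7, 7)
  expect_equal(loss_control(a, b, lambda = 3.5), 3.5 * mean(abs(a - b)))
})

test_that("a constant discriminator is optimal at the real fraction", {
  # balanced real/fake batches: scan constant outputs, optimum at 1/2
  grid <- seq(0.05, 0.95, by = 0.005)
  losses <- vapply(grid, function(d) loss_d_plain(d, d), numeric(1))
  expect_equal(grid[which.min(losses)], 0.5, tolerance = 0.006)
})

test_that("length routing follows the 350-residue threshold", {
  expect_equal(route_model(350), "model_x")
  expect_equal(route_model(351), "model_l")
  expect_equal(route_model(42), "model_x")
})

test_that("the staged learning-rate schedule follows its fractions", {
  sched <- lr_schedule_staged(c(1e-4, 1e-5, 1e-6), c(0.2, 0.3, 0.5))
  got <- vapply(1:100, sched, numeric(1), n_epochs = 100)
  expect_equal(got[1:20], rep(1e-4, 20))
  expect_equal(got[21:50], rep(1e-5, 30))
  expect_equal(got[51:100], rep(1e-6, 50))
  expect_error(lr_schedule_staged(1, c(0.4, 0.4)), "sum to 1")
})

test_that("loss configuration validates its fields", {
  expect_error(loss_config(lambda = 0), "positive")
  expect_error(loss_config(clip_lo = 0.5, clip_hi = 0.3), "clip")
  expect_error(loss_config(reg_loss = "L2"), "L1")
})

test_that("GAN training reduces the smoothed regression loss deterministically", {
  ds <- tiny_dataset()
  fit <- train_gan(ds, tiny_gen_cfg(), tiny_disc_cfg(), loss_config(),
                   epochs = 4, lr_schedule = desk_lr_schedule(), seed = 11)
  expect_lt(tail(fit$log$ema_g_l1, 1), fit$log$ema_g_l1[1])
  expect_true(all(is.finite(fit$log$loss_d)))
  # identical seed reproduces the loss trajectory bitwise
  fit2 <- train_gan(ds, tiny_gen_cfg(), tiny_disc_cfg(), loss_config(),
                    epochs = 4, lr_schedule = desk_lr_schedule(), seed = 11)
  expect_identical(fit$log, fit2$log)
  expect_error(train_gan(list(list(stack = 1, labels_ts = list())),
                         tiny_gen_cfg(), tiny_disc_cfg()), "empty label")
})

test_that("the control path shows monotone decreasing smoothed L1", {
  ds <- tiny_dataset()
  fit <- train_control(ds, tiny_gen_cfg(), lambda = 158, epochs = 5,
                       lr_schedule = desk_lr_schedule(), seed = 12)
  expect_true(all(diff(fit$log$ema_g_l1) < 0))
  g <- glance(fit)
  expect_equal(g$kind, "control")
  expect_equal(nrow(tidy(fit)), 5L)
})

test_that("the desk-scale discriminator separates real maps from fakes", {
  # discriminator-only training against a frozen random generator: the
  # premise of the adversarial experiment is that D can learn at this scale
  set.seed(31)
  ds <- tiny_dataset()
  gen <- build_generator(tiny_gen_cfg())
  disc <- build_patch_discriminator(
    patch_disc_config(n_layers = 4L, first_width = 32L, batchnorm = FALSE))
  opt <- adam_new(disc, lr = 1e-3)
  lc <- loss_config()
  for (step in 1:80) {
    b <- ds[[(step %% length(ds)) + 1]]
    y <- b$labels_ts[[1]]
    fake <- generator_forward(gen, b$stack, train = FALSE)
    distgan:::nn_zero_grads(disc)
    pr <- discriminator_forward(disc, b$stack, y, train = TRUE)
    disc$backward(array(distgan:::loss_d_grad_real(pr), dim = dim(pr)))
    pf <- discriminator_forward(disc, b$stack, fake, train = TRUE)
    gdf <- distgan:::loss_d_grad_fake(pf, lc)
    disc$backward(array(gdf$g_fake, dim = dim(pf)))
    adam_step(opt)
  }
  margin <- mean(vapply(ds, function(b) {
    fake <- generator_forward(gen, b$stack, train = FALSE)
    mean(discriminator_forward(disc, b$stack, b$labels_ts[[1]])) -
      mean(discriminator_forward(disc, b$stack, fake))
  }, numeric(1)))
  expect_gt(margin, 0.2)
})

test_that("the preliminary SPP-discriminator variant trains end to end", {
  ds <- tiny_dataset()
  fit <- train_gan(ds[1:2], tiny_gen_cfg(),
                   spp_disc_config(in_channels = 131L, width = 6L,
                                   mlp_hidden = c(16L, 8L)),
                   loss_config(lambda = 258, d_loss_variant = "plain",
                               g_loss_variant = "saturating"),
                   epochs = 1, lr_schedule = desk_lr_schedule(), seed = 21,
                   n_truths = 2L)
  expect_true(all(is.finite(fit$log$loss_d)))
  expect_s3_class(fit$discriminator, "discriminator")
})

test_that("predicted maps are symmetric validated distance maps", {
  ds <- tiny_dataset()
  fit <- train_control(ds[1:2], tiny_gen_cfg(), epochs = 1, seed = 13,
                       lr_schedule = desk_lr_schedule())
  pred <- predict_dmap(fit$generator, ds[[3]]$stack)
  expect_s3_class(pred, "dmap")
  expect_true(isSymmetric(unclass(pred)))
})
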