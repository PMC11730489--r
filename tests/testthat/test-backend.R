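test_that("materialized networks carry exactly the counted parameters", {
  nets <- tiny_gan()
  for (spec in nets) {
    pc <- count_parameters(spec)
    nm <- network_numel(build_network(spec, seed = 1))
    expect_identical(nm$total, pc$total)
    expect_identical(nm$trainable, pc$trainable)
    expect_identical(nm$non_trainable, pc$non_trainable)
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  gen <- generator_spec(latent_dim = 4, image_size = 16, seed_spatial = 8,
                        seed_channels = 2, kernel_size = 3)
  disc <- discriminator_spec(image_shape = c(16, 16, 1), base_channels = 2,
                             kernel_size = 3)
  gn <- build_network(gen, seed = 1)
  dn <- build_network(disc, seed = 2)
  z <- matrix(rnorm(3 * 4), 3, 4)
  loss_of <- function(gn, dn) {
    fake <- ganstop:::network_forward(gn, z, training = TRUE)$out
    generator_loss(ganstop:::network_forward(dn, fake, training = TRUE)$out)
  }
  gf <- ganstop:::network_forward(gn, z, training = TRUE, grad = TRUE)
  df <- ganstop:::network_forward(dn, gf$out, training = TRUE, grad = TRUE)
  p <- df$out
  dg <- (-1 / ganstop:::clip_prob(p)) / length(p)
  bd <- ganstop:::network_backward(dn, df$caches, array(dg, dim(p)))
  bg <- ganstop:::network_backward(gn, gf$caches, bd$dx)

  eps <- 1e-6
  cases <- list(list("g", 1L, "W", 5L), list("g", 2L, "gamma", 3L),
                list("g", 5L, "W", 7L), list("d", 1L, "W", 3L),
                list("d", 3L, "W", 2L))
  for (cs in cases) {
    net <- cs[[1]]; li <- cs[[2]]; pn <- cs[[3]]; idx <- cs[[4]]
    analytic <- if (net == "g") bg$grads[[li]][[pn]][idx] else
      bd$grads[[li]][[pn]][idx]
    gn2 <- gn; dn2 <- dn
    bump <- function(d) {
      if (net == "g") gn2$layers[[li]][[pn]][idx] <<-
          gn$layers[[li]][[pn]][idx] + d
      else dn2$layers[[li]][[pn]][idx] <<- dn$layers[[li]][[pn]][idx] + d
    }
    bump(eps); up <- loss_of(gn2, dn2)
    bump(-eps); dn_ <- loss_of(gn2, dn2)
    fd <- (up - dn_) / (2 * eps)
    expect_equal(analytic, fd, tolerance = 1e-3)
  }
})

test_that("forward output shapes follow the inferred shape chain", {
  nets <- tiny_gan()
  gn <- build_network(nets$gen, seed = 0)
  z <- matrix(rnorm(2 * 16), 2, 16)
  out <- ganstop:::network_forward(gn, z, training = FALSE)$out
  expect_equal(dim(out), c(2, 32, 32, 1))
  expect_true(all(abs(out) <= 1))

  dn <- build_network(nets$disc, seed = 0)
  p <- ganstop:::network_forward(dn, out, training = FALSE)$out
  expect_equal(dim(p), c(2, 16))
  expect_true(all(p > 0 & p < 1))
})

test_that("image generation is deterministic, bounded and validated", {
  nets <- tiny_gan()
  gn <- build_network(nets$gen, seed = 3)
  a <- generate_images(gn, n = 4, rng_seed = 11)
  b <- generate_images(gn, n = 4, rng_seed = 11)
  expect_identical(a, b)
  expect_equal(dim(a), c(4, 32, 32, 1))
  expect_true(all(a >= -1 & a <= 1))
  expect_false(identical(a, generate_images(gn, n = 4, rng_seed = 12)))
  expect_error(generate_images(gn, n = 0), class = "ganstop_config_error")
})

test_that("the full-scale generator emits a bounded 256x256 grayscale image", {
  gn <- build_network(generator_spec(), seed = 0)
  img <- generate_images(gn, n = 1, rng_seed = 1)
  expect_equal(dim(img), c(1, 256, 256, 1))
  expect_true(all(img >= -1 & img <= 1))
})

test_that("training rejects images that do not match the discriminator input", {
  nets <- tiny_gan()
  bad <- synthesize_images(4, 16, rng_seed = 1)
  expect_error(
    gan_train(bad, nets$gen, nets$disc,
              training_config(epochs = 1, batch_size = 2, latent_dim = 16,
                              image_size = 32)),
    class = "ganstop_config_error"
  )
})

test_that("training records per-epoch losses, checkpoints and reproduces itself", {
  nets <- tiny_gan()
  imgs <- synthesize_images(12, 32, rng_seed = 1)
  cfg <- training_config(epochs = 2, batch_size = 4, latent_dim = 16,
                         image_size = 32, checkpoint_every = 1, rng_seed = 5)
  withr::with_tempdir({
    fit <- gan_train(imgs, nets$gen, nets$disc, cfg, out_dir = "run")
    expect_s3_class(fit$history, "loss_history")
    expect_equal(nrow(fit$history), 2)
    expect_true(all(is.finite(fit$history$g_loss)))
    # checkpoint_every 1, epochs 2 -> exactly 2 generator/discriminator pairs
    expect_length(fit$checkpoints, 4)
    expect_true(all(file.exists(fit$checkpoints)))
    expect_true(file.exists("run/loss_history.csv"))
    expect_true(file.exists("run/config.yaml"))

    fit2 <- gan_train(imgs, nets$gen, nets$disc, cfg)
    expect_equal(fit$history, fit2$history)

    # zero-epoch run: empty history, no checkpoints, no error
    fit0 <- gan_train(imgs, nets$gen, nets$disc,
                      training_config(epochs = 0, batch_size = 4,
                                      latent_dim = 16, image_size = 32))
    expect_equal(nrow(fit0$history), 0)
    expect_length(fit0$checkpoints, 0)
  })
})
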