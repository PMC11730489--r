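#' Training hyperparameter configuration
#'
#' Bundles the DCGAN training hyperparameters. The defaults are the published
#' 256x256 grayscale setup: 500 epochs, batch size 32, latent dimension 128,
#' kernel size 5, Adam with learning rate 1e-5 and beta1 0.5 for both
#' networks, real labels smoothed by 0.1, checkpoints every 50 epochs and
#' monitoring plots every 10 iterations.
#'
#' @param epochs Number of passes over the dataset.
#' @param batch_size Images per gradient step.
#' @param latent_dim Length of the generator's input noise vector.
#' @param kernel_size Convolution kernel side.
#' @param learning_rate,beta1 Adam optimizer settings (both networks).
#' @param smooth Real-label smoothing factor in `[0, 0.5)`.
#' @param checkpoint_every Epoch interval between weight checkpoints.
#' @param plot_every Iteration interval for the live monitoring callback.
#' @param rng_seed Seed controlling weight init, noise and batch shuffling.
#' @param image_size Image side in pixels.
#' @param latent_dist Noise distribution: `"normal"` (standard normal, the
#'   default) or `"uniform"` (uniform on `[-1, 1]`).
#' @param record Loss recording granularity: `"epoch"` (mean of batch losses,
#'   the default) or `"batch"`.
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 500, batch_size = 32, latent_dim = 128,
                            kernel_size = 5, learning_rate = 1e-5,
                            beta1 = 0.5, smooth = 0.1, checkpoint_every = 50,
                            plot_every = 10, rng_seed = 0, image_size = 256,
                            latent_dist = c("normal", "uniform"),
                            record = c("epoch", "batch")) {
  if (epochs < 0 || batch_size < 1) {
    abort_config("epochs must be >= 0 and batch_size >= 1")
  }
  if (smooth < 0 || smooth >= 0.5) {
    abort_config("smooth must lie in [0, 0.5)")
  }
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    latent_dim = as.integer(latent_dim), kernel_size = as.integer(kernel_size),
    learning_rate = learning_rate, beta1 = beta1, smooth = smooth,
    checkpoint_every = as.integer(checkpoint_every),
    plot_every = as.integer(plot_every), rng_seed = as.integer(rng_seed),
    image_size = as.integer(image_size),
    latent_dist = match.arg(latent_dist), record = match.arg(record),
    bn_epsilon = BN_EPS, bn_momentum = BN_MOMENTUM, leaky_slope = 0.2
  ), class = "training_config")
}

sample_latent <- function(n, latent_dim, dist = "normal") {
  z <- if (dist == "uniform") stats::runif(n * latent_dim, -1, 1)
  else stats::rnorm(n * latent_dim)
  matrix(z, n, latent_dim)
}

as_image_array <- function(images) {
  if (is.list(images)) images <- simplify2array(images)
  d <- dim(images)
  if (is.null(d) || !length(d) %in% c(3, 4)) {
    abort_config("images must be an (N, H, W) or (N, H, W, 1) array")
  }
  if (length(d) == 3) images <- array(images, c(d, 1))
  images
}

#' Train a DCGAN at any scale
#'
#' Runs alternating adversarial training of a generator/discriminator pair
#' realized from their [network_spec]s: per batch, the discriminator takes an
#' Adam step on the summed real (smoothed-label) and fake binary
#' cross-entropy, then the generator takes an Adam step on the all-ones-target
#' cross-entropy of the discriminator's output for fresh fakes. Losses are
#' recorded per epoch (mean over batches, the default) or per batch; weights
#' are checkpointed every `checkpoint_every` epochs and at the final epoch.
#' The run is reproducible from `config$rng_seed`.
#'
#' @param images Real images: `(N, H, W)` or `(N, H, W, 1)` array with values
#'   in `[-1, 1]`, H and W matching the discriminator input.
#' @param gen_spec,disc_spec [network_spec]s for the two networks.
#' @param config A [training_config()].
#' @param out_dir Optional run directory: receives `config.yaml`,
#'   `loss_history.csv`, `checkpoints/` and `samples/`.
#' @param callbacks Optional list with functions `on_iteration(iter, g, d)`
#'   (called every `plot_every` iterations) and `on_epoch(epoch, g, d)`.
#' @return A `gan_fit` list: `history` (loss-history tibble), `generator` and
#'   `discriminator` (`gan_network`s), `checkpoints` (file paths), `config`.
#' @export
gan_train <- function(images, gen_spec, disc_spec, config = training_config(),
                      out_dir = NULL, callbacks = NULL) {
  images <- as_image_array(images)
  d <- dim(images)
  shp <- attr(disc_spec, "input")$image_shape
  if (d[2] != shp[1] || d[3] != shp[2] || d[4] != shp[3]) {
    abort_config(sprintf(
      "image shape (%d, %d, %d) does not match discriminator input (%d, %d, %d)",
      d[2], d[3], d[4], shp[1], shp[2], shp[3]
    ))
  }
  latent_dim <- attr(gen_spec, "input")$latent_dim

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "checkpoints"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "samples"), showWarnings = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  gen <- build_network(gen_spec, seed = config$rng_seed)
  disc <- build_network(disc_spec, seed = config$rng_seed + 1L)
  set.seed(config$rng_seed + 2L)
  g_state <- adam_init(gen)
  d_state <- adam_init(disc)

  n <- d[1]
  rows <- list()
  checkpoints <- character(0)
  iter <- 0L
  t_g <- t_d <- 0L

  save_checkpoint <- function(epoch) {
    if (is.null(out_dir)) return(invisible(NULL))
    gp <- file.path(out_dir, "checkpoints",
                    sprintf("generator_epoch%04d.rds", epoch))
    dp <- file.path(out_dir, "checkpoints",
                    sprintf("discriminator_epoch%04d.rds", epoch))
    saveRDS(gen$layers, gp)
    saveRDS(disc$layers, dp)
    checkpoints <<- c(checkpoints, gp, dp)
    invisible(NULL)
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    g_batch <- d_batch <- numeric(0)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1, n)]
      real <- images[idx, , , , drop = FALSE]
      nb <- length(idx)
      iter <- iter + 1L

      # --- discriminator step
      z <- sample_latent(nb, latent_dim, config$latent_dist)
      fake <- network_forward(gen, z, training = TRUE)$out
      fr <- network_forward(disc, real, grad = TRUE)
      ff <- network_forward(disc, fake, grad = TRUE)
      p_r <- fr$out; p_f <- ff$out
      d_loss <- discriminator_loss(p_r, p_f, config$smooth)
      m_out <- length(p_r)
      pc_r <- clip_prob(p_r); pc_f <- clip_prob(p_f)
      dd_r <- -((1 - config$smooth) / pc_r - config$smooth / (1 - pc_r)) / m_out
      dd_f <- (1 / (1 - pc_f)) / length(p_f)
      br <- network_backward(disc, fr$caches, array(dd_r, dim(p_r)))
      bf <- network_backward(disc, ff$caches, array(dd_f, dim(p_f)))
      grads <- purrr::map2(br$grads, bf$grads, function(a, b) {
        if (is.null(a)) return(NULL)
        purrr::map2(a, b, function(x, y) if (is.null(x)) NULL else x + y)
      })
      t_d <- t_d + 1L
      upd <- adam_step(disc, grads, d_state, config$learning_rate,
                       config$beta1, t = t_d)
      disc <- upd$net; d_state <- upd$state
      disc <- update_moving_stats(disc, fr$caches)

      # --- generator step
      z <- sample_latent(nb, latent_dim, config$latent_dist)
      gf <- network_forward(gen, z, training = TRUE, grad = TRUE)
      df <- network_forward(disc, gf$out, grad = TRUE)
      p <- df$out
      g_loss <- generator_loss(p)
      pc <- clip_prob(p)
      dg <- (-1 / pc) / length(p)
      bd <- network_backward(disc, df$caches, array(dg, dim(p)))
      bg <- network_backward(gen, gf$caches, bd$dx)
      t_g <- t_g + 1L
      upd <- adam_step(gen, bg$grads, g_state, config$learning_rate,
                       config$beta1, t = t_g)
      gen <- upd$net; g_state <- upd$state
      gen <- update_moving_stats(gen, gf$caches)

      g_batch <- c(g_batch, g_loss)
      d_batch <- c(d_batch, d_loss)
      if (!is.null(callbacks$on_iteration) && iter %% config$plot_every == 0) {
        callbacks$on_iteration(iter, g_loss, d_loss)
      }
    }
    g_epoch <- mean(g_batch); d_epoch <- mean(d_batch)
    rows[[epoch]] <- if (config$record == "batch") {
      tibble::tibble(epoch = epoch - 1L, batch = seq_along(g_batch) - 1L,
                     g_loss = g_batch, d_loss = d_batch)
    } else {
      tibble::tibble(epoch = epoch - 1L, g_loss = g_epoch, d_loss = d_epoch)
    }
    if (!is.null(callbacks$on_epoch)) callbacks$on_epoch(epoch, g_epoch, d_epoch)
    if (epoch %% config$checkpoint_every == 0 || epoch == config$epochs) {
      save_checkpoint(epoch)
    }
    if (!is.null(out_dir)) {
      imgs <- generate_images(gen, n = 1, rng_seed = config$rng_seed + epoch)
      write_images_png(imgs, file.path(out_dir, "samples"),
                       prefix = sprintf("epoch%d", epoch))
    }
  }

  history <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(epoch = integer(0), g_loss = numeric(0), d_loss = numeric(0))
  if (config$record == "epoch") history <- as_loss_history(history)
  if (!is.null(out_dir) && config$record == "epoch") {
    write_loss_history(history, file.path(out_dir, "loss_history.csv"))
  }
  structure(list(history = history, generator = gen, discriminator = disc,
                 checkpoints = checkpoints, config = config),
            class = "gan_fit")
}

#' Generate images from a (trained) generator
#'
#' Draws `n` latent vectors from the configured noise distribution under
#' `rng_seed` and maps them through the generator. Outputs are
#' `image_size x image_size x 1` with every pixel in `[-1, 1]` (tanh range);
#' identical seeds give bitwise-identical arrays (batch statistics are not
#' used: batch norm runs in inference mode on its moving statistics).
#'
#' @param generator A `gan_network` (or a `gan_fit`, whose generator is used),
#'   or a checkpoint `.rds` path together with `spec`.
#' @param n Number of images (>= 1).
#' @param rng_seed Seed for the latent draws.
#' @param latent_dist `"normal"` or `"uniform"`.
#' @param spec Generator [network_spec], required when `generator` is a
#'   checkpoint path.
#' @return An `(n, H, W, 1)` array in `[-1, 1]`.
#' @export
generate_images <- function(generator, n, rng_seed = 0,
                            latent_dist = "normal", spec = NULL) {
  if (n <= 0) abort_config("n must be a positive integer")
  if (inherits(generator, "gan_fit")) generator <- generator$generator
  if (is.character(generator)) {
    if (is.null(spec)) abort_config("loading weights from file requires `spec`")
    net <- build_network(spec, seed = 0)
    net$layers <- readRDS(generator)
    generator <- net
  }
  stopifnot(inherits(generator, "gan_network"))
  latent_dim <- generator$input$latent_dim
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  z <- sample_latent(n, latent_dim, latent_dist)
  network_forward(generator, z, training = FALSE)$out
}

#' Write images to PNG files
#'
#' Maps pixel values from `[-1, 1]` to `[0, 255]` linearly and writes one
#' grayscale PNG per image.
#'
#' @param images `(N, H, W, 1)` or `(N, H, W)` array in `[-1, 1]`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix; files are `<prefix>_<i>.png` (or
#'   `<prefix>.png` for a single image).
#' @return Paths of the written files, invisibly.
#' @export
write_images_png <- function(images, dir, prefix = "image") {
  images <- as_image_array(images)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(images)[1]
  paths <- character(n)
  for (i in seq_len(n)) {
    img <- (images[i, , , 1] + 1) / 2
    img <- pmin(pmax(img, 0), 1)
    paths[i] <- file.path(dir, if (n == 1) paste0(prefix, ".png")
                          else sprintf("%s_%03d.png", prefix, i))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}
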