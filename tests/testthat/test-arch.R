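test_that("default generator and discriminator reproduce the published layer table", {
  gen <- generator_spec()
  disc <- discriminator_spec()

  pg <- count_parameters(gen)
  expect_identical(pg$total, 26129728)
  expect_identical(pg$trainable, 25996736)
  expect_identical(pg$non_trainable, 132992)

  pd <- count_parameters(disc)
  expect_identical(pd$total, 4369440)
  expect_identical(pd$trainable, 4367520)
  expect_identical(pd$non_trainable, 1920)

  # per-layer spot checks: dense projection, first transposed conv,
  # first discriminator conv (hand arithmetic 128*65536+65536, 5*5*1024*512,
  # 5*5*1*32)
  expect_equal(tidy(pg)$params[1], 8454144)
  expect_equal(tidy(pg)$params[5], 13107200)
  expect_equal(tidy(pd)$params[1], 800)

  # glance view matches
  expect_equal(glance(pg)$total, 26129728)
  expect_equal(glance(pd)$non_trainable, 1920)
})

test_that("generator layer sequence and shape chain follow the DCGAN layout", {
  gen <- generator_spec()
  expect_equal(
    gen$kind,
    c("dense", "batch_norm", "relu", "reshape",
      rep(c("transposed_conv", "batch_norm", "relu"), 4),
      "transposed_conv", "activation")
  )
  expect_equal(gen$units[gen$kind == "transposed_conv"], c(512L, 256L, 128L, 64L, 1L))
  expect_true(all(!gen$use_bias[gen$kind == "transposed_conv"]))
  expect_true(gen$use_bias[1])
  expect_equal(gen$activation[nrow(gen)], "tanh")

  sh <- infer_shapes(gen)
  spatial <- sh[!is.na(sh$height), c("height", "channels")]
  expect_equal(unique(paste(spatial$height, spatial$channels)),
               c("8 1024", "16 512", "32 256", "64 128", "128 64", "256 1"))
  expect_equal(unlist(sh[nrow(sh), c("height", "width", "channels")],
                      use.names = FALSE), c(256L, 256L, 1L))
})

test_that("discriminator downsamples to 16 sigmoid logits with no dense head", {
  disc <- discriminator_spec()
  expect_false("dense" %in% disc$kind)
  expect_equal(disc$units[disc$kind == "conv"], c(32L, 64L, 128L, 256L, 512L, 1L))
  expect_equal(disc$activation[nrow(disc)], "sigmoid")

  sh <- infer_shapes(disc)
  expect_true(any(sh$height == 64 & sh$channels == 64, na.rm = TRUE))
  expect_true(any(sh$height == 16 & sh$channels == 256, na.rm = TRUE))
  pre_flatten <- sh[max(which(!is.na(sh$height))), ]
  expect_equal(unlist(pre_flatten[c("height", "width", "channels")],
                      use.names = FALSE), c(4L, 4L, 1L))
  expect_equal(sh$flat[sh$kind == "flatten"], 16L)
})

test_that("minimal configurations build and degenerate ones are rejected", {
  g <- generator_spec(latent_dim = 4, image_size = 16, seed_spatial = 8,
                      seed_channels = 2, kernel_size = 1)
  expect_s3_class(g, "network_spec")
  expect_equal(sum(g$kind == "transposed_conv"), 1L)

  d <- discriminator_spec(image_shape = c(8, 8, 1), base_channels = 1,
                          kernel_size = 1)
  expect_equal(sum(d$kind == "conv"), 2L)

  expect_error(generator_spec(image_size = 96), class = "ganstop_config_error")
  expect_error(generator_spec(image_size = 8, seed_spatial = 8),
               class = "ganstop_config_error")
  expect_error(discriminator_spec(image_shape = c(256, 128, 1)),
               class = "ganstop_config_error")
  expect_error(discriminator_spec(image_shape = c(96, 96, 1)),
               class = "ganstop_config_error")
})

test_that("reshape volume mismatches raise a shape error naming the layer", {
  rows <- dplyr::bind_rows(
    ganstop:::layer_row("dense", units = 65536L, use_bias = TRUE),
    ganstop:::layer_row("reshape", target_h = 8L, target_w = 8L,
                        target_c = 1000L)
  )
  bad <- ganstop:::new_network_spec(rows, input = list(latent_dim = 128L),
                                    role = "generator")
  err <- expect_error(infer_shapes(bad), class = "ganstop_shape_error")
  expect_match(conditionMessage(err), "layer 2")

  rows$target_c[2] <- 1024L
  ok <- ganstop:::new_network_spec(rows, input = list(latent_dim = 128L),
                                   role = "generator")
  sh <- infer_shapes(ok)
  expect_equal(sh$channels[2], 1024L)
})

test_that("an empty specification counts zero parameters", {
  empty <- ganstop:::new_network_spec(ganstop:::layer_row("relu")[0, ],
                                      input = list(latent_dim = 1L),
                                      role = "generator")
  pc <- count_parameters(empty)
  expect_equal(c(pc$total, pc$trainable, pc$non_trainable), c(0, 0, 0))
})

test_that("parameter accounting identities hold across generator sizes", {
  for (size in c(32, 64, 256)) {
    gen <- generator_spec(image_size = size)
    pc <- count_parameters(gen)
    expect_identical(pc$total, pc$trainable + pc$non_trainable)
    expect_identical(pc$total, sum(pc$per_layer$params))
    # non-trainable = 2 x sum of batch-norm channels
    sh <- infer_shapes(gen)
    bn_ch <- ifelse(is.na(sh$channels), sh$flat, sh$channels)[sh$kind == "batch_norm"]
    expect_identical(pc$non_trainable, 2 * sum(bn_ch))
    final <- sh[nrow(sh), ]
    expect_equal(unlist(final[c("height", "width", "channels")],
                        use.names = FALSE), c(size, size, 1L))
  }
  disc <- discriminator_spec()
  pcd <- count_parameters(disc)
  expect_identical(pcd$non_trainable, 2 * sum(c(64, 128, 256, 512)))
})

test_that("network specifications round-trip through YAML", {
  withr::with_tempfile("tf", fileext = ".yaml", {
    gen <- generator_spec(latent_dim = 16, image_size = 32, seed_spatial = 8,
                          seed_channels = 16)
    write_network_spec(gen, tf)
    back <- read_network_spec(tf)
    expect_equal(back$kind, gen$kind)
    expect_equal(back$units, gen$units)
    expect_equal(attr(back, "input"), attr(gen, "input"))
    expect_equal(count_parameters(back)$total, count_parameters(gen)$total)
  })
})

test_that("the layer-table renderer prints shapes and totals", {
  out <- capture.output(print(discriminator_spec()))
  expect_true(any(grepl("(None, 128, 128, 32)", out, fixed = TRUE)))
  expect_true(any(grepl("4,369,440", out, fixed = TRUE)))
})
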