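test_that("noise-free backbones are exactly piecewise linear", {
  p <- archetype_params("A2", g_sd = 0, spike_rate = 0, d_sd = 0)
  h <- simulate_loss_history(p)

  expect_equal(h$g_loss[h$epoch == p$plateau_start], p$plateau_level)
  expect_equal(h$g_loss[h$epoch == p$n_epochs - 1],
               p$plateau_level + p$plateau_drift * (p$n_epochs - 1 - p$plateau_start))
  expect_equal(h$g_loss[h$epoch == p$peak_epoch], p$peak_height)
  expect_equal(h$g_loss[1], p$g_base)

  # single-piece fits recover the generating slopes to machine precision
  rise <- fit_loss_line(h, "g_loss", 0, p$peak_epoch)
  expect_equal(rise$slope, (p$peak_height - p$g_base) / p$peak_epoch,
               tolerance = 1e-12)
  fall <- fit_loss_line(h, "g_loss", p$peak_epoch, p$plateau_start)
  expect_equal(fall$slope,
               (p$plateau_level - p$peak_height) / (p$plateau_start - p$peak_epoch),
               tolerance = 1e-12)

  # divergent variant adds a linear ramp after onset
  p3 <- archetype_params("A3", g_sd = 0, spike_rate = 0, d_sd = 0)
  h3 <- simulate_loss_history(p3)
  late <- fit_loss_line(h3, "g_loss", 420, 499)
  expect_equal(late$slope, p3$plateau_drift + p3$divergence_rate,
               tolerance = 1e-12)
})

test_that("simulated histories are reproducible, valid and calibrated", {
  p <- archetype_params("A1")
  h1 <- simulate_loss_history(p, rng_seed = 4)
  h2 <- simulate_loss_history(p, rng_seed = 4)
  expect_identical(h1, h2)
  expect_false(identical(h1, simulate_loss_history(p, rng_seed = 5)))
  expect_s3_class(h1, "loss_history")
  expect_true(all(h1$g_loss >= 0 & h1$d_loss >= 0))
  expect_equal(attr(h1, "ground_truth")$name, "A1_fluctuating")

  # fluctuating-archetype moments track the generating base level
  s <- loss_summary(simulate_loss_history(p, rng_seed = 0), "g_loss")
  expect_equal(s$mean, 3.001, tolerance = 0.06 / 3.001)

  # long-run convergence of mean and sd (law of large numbers)
  pl <- archetype_params("A1", n_epochs = 10000L, spike_rate = 0)
  sl <- loss_summary(simulate_loss_history(pl, rng_seed = 1), "g_loss")
  expect_equal(sl$mean, 3.001, tolerance = 0.03 / 3.001)
  expect_equal(sl$sd, 0.624, tolerance = 0.03 / 0.624)
})

test_that("archetype invariants are enforced", {
  expect_error(archetype_params("A2", plateau_start = 100L),
               class = "ganstop_config_error")
  expect_error(archetype_params("A3", divergence_onset = 120L),
               class = "ganstop_config_error")
  expect_error(archetype_params("A1", g_sd = -1),
               class = "ganstop_config_error")
  expect_error(archetype_params("A2", n_epochs = 150L),
               class = "ganstop_config_error")
  expect_error(archetype_params("A2", bogus = 1),
               class = "ganstop_config_error")
})

test_that("chest-like image fixtures are bounded, distinct and deterministic", {
  imgs <- synthesize_images(30, 32, rng_seed = 1)
  expect_equal(dim(imgs), c(30, 32, 32, 1))
  expect_true(all(imgs >= -1 & imgs <= 1))
  # every image spans the full dynamic range
  rng <- apply(imgs, 1, range)
  expect_true(all(rng[1, ] == -1 & rng[2, ] == 1))
  # images are pairwise distinct
  flat <- matrix(imgs, 30)
  expect_equal(nrow(unique(flat)), 30)

  expect_identical(imgs, synthesize_images(30, 32, rng_seed = 1))
  expect_false(identical(imgs[1, , , ], synthesize_images(1, 32, rng_seed = 2)[1, , , ]))

  expect_silent(synthesize_images(1, 16, rng_seed = 0))
  expect_error(synthesize_images(0, 32), class = "ganstop_config_error")
  expect_error(synthesize_images(5, 48), class = "ganstop_config_error")
  expect_error(synthesize_images(5, 8), class = "ganstop_config_error")
})

test_that("archetypes are separable by the detectors across seeds", {
  seeds <- 0:14
  a2_stop <- vapply(seeds, function(s) {
    r <- recommend_stop(simulate_loss_history(archetype_params("A2"), s))
    !is.na(r$stop_epoch)
  }, logical(1))
  a3_div <- vapply(seeds, function(s) {
    detect_divergence(simulate_loss_history(archetype_params("A3"), s))$diverged
  }, logical(1))
  a2_fp <- vapply(seeds, function(s) {
    detect_divergence(simulate_loss_history(archetype_params("A2"), s))$diverged
  }, logical(1))
  expect_gte(mean(a2_stop), 0.9)
  expect_gte(mean(a3_div), 0.9)
  expect_lte(mean(a2_fp), 0.05)
})
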