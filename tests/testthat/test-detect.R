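test_that("stable-segment detection finds the plateau onset on clean curves", {
  # noiseless peak-then-plateau backbone: rise to 110, plateau from 150
  p <- archetype_params("A2", g_sd = 0, spike_rate = 0, d_sd = 0)
  h <- simulate_loss_history(p)
  start <- detect_stable_start(h)
  expect_gte(start, 140)
  expect_lte(start, 170)

  # flat noiseless series settles immediately
  expect_equal(detect_stable_start(make_history(rep(3, 200))), 0L)

  # strictly increasing series never flattens
  res <- detect_stable_start(linear_history(200, 0.05, 1))
  expect_true(is.na(res))
  expect_equal(attr(res, "reason"), "no_stable_segment")

  # override bypasses detection entirely
  expect_equal(detect_stable_start(h, override = 150), 150L)

  expect_error(detect_stable_start(make_history(rep(3, 50))),
               class = "ganstop_config_error")
})

test_that("the stop rule follows the slope-sign transition and plateau paths", {
  # constant history: flat-stable from the anchor, no negative phase
  rec <- recommend_stop(make_history(rep(3, 200)))
  expect_equal(rec$rationale, "plateau_stability")
  expect_equal(rec$stop_epoch, rec$stable_start + 25L)

  # strictly decreasing series: slope never leaves the negative regime
  dec <- recommend_stop(linear_history(300, -0.02, 9))
  expect_true(is.na(dec$stop_epoch))

  # peak-then-plateau run: negative-to-flat transition after the plateau
  h <- simulate_loss_history(archetype_params("A2"), rng_seed = 7)
  rec2 <- recommend_stop(h)
  expect_equal(rec2$rationale, "slope_sign_transition")
  expect_gte(rec2$stop_epoch, rec2$stable_start)
  expect_gte(rec2$slope_at_stop, -0.005)
})

test_that("stop recommendations land after the plateau across seeds", {
  stops <- vapply(0:19, function(s) {
    h <- simulate_loss_history(archetype_params("A2"), rng_seed = s)
    r <- recommend_stop(h)
    if (is.na(r$stop_epoch)) NA_real_ else as.numeric(r$stop_epoch)
  }, numeric(1))
  expect_true(all(!is.na(stops)))
  expect_true(all(stops >= 150))
  expect_gte(median(stops), 200)
  expect_lte(median(stops), 320)
})

test_that("divergence detection flags late rises and spares healthy plateaus", {
  h3 <- simulate_loss_history(archetype_params("A3"), rng_seed = 3)
  rep3 <- detect_divergence(h3)
  expect_true(rep3$diverged)
  expect_gte(rep3$onset_epoch, 375)
  expect_lte(rep3$onset_epoch, 425)

  h2 <- simulate_loss_history(archetype_params("A2"), rng_seed = 3)
  expect_false(detect_divergence(h2)$diverged)

  # linearly rising series: flagged within the first rolling window
  lin <- detect_divergence(linear_history(300, 0.05, 1))
  expect_true(lin$diverged)
  expect_lte(lin$onset_epoch, 50)
  expect_gt(lin$trailing_slope, 0.01)

  expect_error(detect_divergence(make_history(rep(3, 40))),
               class = "ganstop_config_error")
})

test_that("stop and divergence decisions ignore discriminator-channel scaling", {
  h <- simulate_loss_history(archetype_params("A3"), rng_seed = 9)
  scaled <- make_history(h$g_loss, h$d_loss * 5, h$epoch)
  r1 <- recommend_stop(h); r2 <- recommend_stop(scaled)
  expect_equal(r1$stop_epoch, r2$stop_epoch)
  d1 <- detect_divergence(h); d2 <- detect_divergence(scaled)
  expect_equal(d1$onset_epoch, d2$onset_epoch)
})

test_that("plateau drift is recovered exactly without noise and within error with", {
  p0 <- archetype_params("A2", g_sd = 0, spike_rate = 0, d_sd = 0)
  h0 <- simulate_loss_history(p0)
  fit0 <- fit_loss_line(h0, "g_loss", 150, 499)
  expect_equal(fit0$slope, 0.0016, tolerance = 1e-12)

  covered <- vapply(0:39, function(s) {
    h <- simulate_loss_history(archetype_params("A2", spike_rate = 0),
                               rng_seed = s)
    fit <- fit_loss_line(h, "g_loss", 150, 499)
    abs(fit$slope - 0.0016) <= 2 * fit$std_error
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("full analysis assembles every component and guards tiny inputs", {
  h <- simulate_loss_history(archetype_params("A2"), rng_seed = 7)
  an <- analyze_history(h)
  expect_s3_class(an, "gan_analysis")
  expect_equal(nrow(an$summaries), 2)
  expect_named(an$regressions, c("g_full", "d_full", "g_stable", "d_stable"))
  expect_false(an$divergence$diverged)
  expect_false(is.na(an$stop$stop_epoch))

  err <- tryCatch(analyze_history(make_history(c(1, 2, 3, 2))),
                  error = conditionMessage)
  expect_match(err, "5 epochs")
})
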