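# Shared fixtures and independent oracles for the test suite.

# closed-form OLS via the sum formulas -- the independent oracle against
# which the QR-based implementation is checked
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  list(slope = slope, intercept = (sy - slope * sx) / n)
}

make_history <- function(g, d = rep(0.5, length(g)), epochs = seq_along(g) - 1) {
  as_loss_history(tibble::tibble(epoch = epochs, g_loss = g, d_loss = d))
}

linear_history <- function(n, slope, intercept, d = 0.5) {
  e <- seq_len(n) - 1
  make_history(pmax(intercept + slope * e, 0), rep(d, n), e)
}

# scaled-down spec pair used by training smoke tests
tiny_gan <- function(image_size = 32) {
  list(
    gen = generator_spec(latent_dim = 16, image_size = image_size,
                         seed_spatial = 8,
                         seed_channels = if (image_size > 16) 16 else 8,
                         kernel_size = 5),
    disc = discriminator_spec(image_shape = c(image_size, image_size, 1),
                              base_channels = 4, kernel_size = 5)
  )
}
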