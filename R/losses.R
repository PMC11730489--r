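#' Adversarial binary cross-entropy losses
#'
#' The generator loss is the binary cross-entropy between all-ones targets and
#' the discriminator's probabilities on generated images: low when fakes fool
#' the discriminator. The discriminator loss is the sum of a real half (targets
#' one, optionally label-smoothed to `1 - smooth` to avoid overconfidence) and
#' a fake half (targets zero), each half a mean over the discriminator's
#' outputs. Probabilities are clipped into `[1e-7, 1 - 1e-7]` before taking
#' logs so losses stay finite. All losses are in nats.
#'
#' @param disc_out_fake,disc_out_real Numeric vectors of discriminator output
#'   probabilities in `(0, 1)` (any shape, flattened).
#' @param smooth Label-smoothing factor in `[0, 0.5)` applied to the real
#'   targets (default 0.1).
#' @return A single non-negative number (nats).
#' @examples
#' generator_loss(c(0.5, 1))              # (log 2)/2
#' discriminator_loss(0.5, 0.5, smooth = 0)  # 2 log 2
#' @export
generator_loss <- function(disc_out_fake) {
  p <- clip_prob(disc_out_fake)
  -mean(log(p))
}

#' @rdname generator_loss
#' @export
discriminator_loss <- function(disc_out_real, disc_out_fake, smooth = 0.1) {
  if (!is.numeric(smooth) || length(smooth) != 1 || smooth < 0 || smooth >= 0.5) {
    rlang::abort("smooth must be a single value in [0, 0.5)",
                 class = "ganstop_config_error")
  }
  bce(1 - smooth, clip_prob(disc_out_real)) + bce(0, clip_prob(disc_out_fake))
}

clip_prob <- function(p, eps = 1e-7) {
  if (length(p) == 0) {
    rlang::abort("probability vector must be non-empty",
                 class = "ganstop_config_error")
  }
  pmin(pmax(as.numeric(p), eps), 1 - eps)
}

# mean BCE of predictions p against a scalar target t (already clipped)
bce <- function(t, p) {
  -mean(t * log(p) + (1 - t) * log1p(-p))
}
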