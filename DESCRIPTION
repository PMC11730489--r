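Package: ganstop
Title: Regression-Slope Monitoring and Early Stopping for DCGAN Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding when to stop training a deep convolutional
    generative adversarial network (DCGAN) and for flagging failed (divergent)
    runs, by ordinary-least-squares regression over generator/discriminator
    loss histories. Provides declarative DCGAN architecture specifications
    with exact parameter accounting and shape inference, a compact CPU
    reference trainer with loss recording, checkpointing and plotting
    callbacks, cumulative and rolling slope-series analysis with a stop-epoch
    recommendation and divergence detector, and simulators for archetypal
    loss histories and chest-radiograph-like grayscale image fixtures so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
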