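#' Declarative DCGAN architecture specifications
#'
#' A `network_spec` is a tibble with one row per layer and the attributes
#' `input` (either a latent dimension or an image shape) and `role`
#' (`"generator"` or `"discriminator"`). Layer kinds follow the usual DCGAN
#' vocabulary: `dense`, `batch_norm`, `relu`, `leaky_relu`, `reshape`,
#' `transposed_conv`, `conv`, `flatten`, `activation`. Shapes and parameter
#' counts are computed from the table alone, so an architecture can be audited
#' against a framework model summary without any training backend.
#'
#' @name network_spec
NULL

LAYER_KINDS <- c(
  "dense", "batch_norm", "relu", "leaky_relu", "reshape",
  "transposed_conv", "conv", "flatten", "activation"
)
CONV_KINDS <- c("conv", "transposed_conv")
PARAM_KINDS <- c("dense", "conv", "transposed_conv")

layer_row <- function(kind, units = NA_integer_, kernel = NA_integer_,
                      stride = NA_integer_, use_bias = NA,
                      activation = NA_character_,
                      target_h = NA_integer_, target_w = NA_integer_,
                      target_c = NA_integer_) {
  tibble::tibble(
    kind = kind, units = as.integer(units), kernel = as.integer(kernel),
    stride = as.integer(stride), use_bias = use_bias, activation = activation,
    target_h = as.integer(target_h), target_w = as.integer(target_w),
    target_c = as.integer(target_c)
  )
}

new_network_spec <- function(layers, input, role) {
  spec <- tibble::new_tibble(layers, class = "network_spec", nrow = nrow(layers))
  attr(spec, "input") <- input
  attr(spec, "role") <- role
  spec
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "ganstop_config_error")
}

abort_shape <- function(msg, layer = NULL) {
  rlang::abort(msg, class = "ganstop_shape_error", layer = layer)
}

validate_network_spec <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  if (!all(spec$kind %in% LAYER_KINDS)) {
    abort_config(paste0(
      "unknown layer kind(s): ",
      paste(setdiff(spec$kind, LAYER_KINDS), collapse = ", ")
    ))
  }
  non_conv <- !spec$kind %in% CONV_KINDS
  if (any(non_conv & (!is.na(spec$kernel) | !is.na(spec$stride)))) {
    abort_config("kernel_size and stride must be absent for non-convolutional layers")
  }
  needs_units <- spec$kind %in% PARAM_KINDS
  if (any(needs_units & (is.na(spec$units) | spec$units <= 0L))) {
    abort_config("dense/conv/transposed_conv layers need a positive unit/channel count")
  }
  if (any(spec$kind %in% CONV_KINDS &
            (is.na(spec$kernel) | spec$kernel < 1L |
               is.na(spec$stride) | !spec$stride %in% c(1L, 2L)))) {
    abort_config("convolutional layers need kernel_size >= 1 and stride in {1, 2}")
  }
  invisible(infer_shapes(spec))
}

is_pow2 <- function(x) {
  x >= 1 && abs(log2(x) - round(log2(x))) < 1e-9
}

#' Build the generator architecture specification
#'
#' Constructs the layer table of a DCGAN generator: a biased dense projection
#' of the latent vector, batch normalisation and ReLU, a reshape to a
#' `seed_spatial x seed_spatial x seed_channels` tensor, a chain of stride-2
#' transposed convolutions (each followed by batch norm + ReLU, channel count
#' halving per block) up to a final stride-2 transposed convolution producing
#' one channel, and a tanh output activation. Convolutions carry no bias; the
#' dense projection does. With the defaults this reproduces the 256x256
#' grayscale generator with 26,129,728 parameters.
#'
#' @param latent_dim Length of the input noise vector (default 128).
#' @param image_size Output height = width in pixels; must equal
#'   `seed_spatial * 2^k` for an integer `k >= 1` (default 256).
#' @param seed_spatial Spatial side of the first feature map (default 8).
#' @param seed_channels Channel count of the first feature map (default 1024);
#'   halved at every intermediate upsampling block, so it must be divisible by
#'   `2^(k-1)`.
#' @param kernel_size Square kernel side for every transposed convolution
#'   (default 5).
#' @return A [network_spec] tibble (one row per layer).
#' @examples
#' gen <- generator_spec()
#' count_parameters(gen)
#' @export
generator_spec <- function(latent_dim = 128, image_size = 256,
                           seed_spatial = 8, seed_channels = 1024,
                           kernel_size = 5) {
  args <- c(latent_dim = latent_dim, image_size = image_size,
            seed_spatial = seed_spatial, seed_channels = seed_channels,
            kernel_size = kernel_size)
  if (any(args <= 0) || any(args != round(args))) {
    abort_config("all generator_spec arguments must be positive integers")
  }
  ratio <- image_size / seed_spatial
  if (!is_pow2(ratio) || ratio < 2) {
    abort_config(sprintf(
      "image_size (%d) must be seed_spatial (%d) times 2^k with k >= 1",
      image_size, seed_spatial
    ))
  }
  k <- as.integer(round(log2(ratio)))
  inner <- if (k > 1) seed_channels / 2^seq_len(k - 1) else integer(0)
  if (length(inner) && any(inner != round(inner) | inner < 1)) {
    abort_config("seed_channels must be divisible by 2^(k-1) so block channels stay integral")
  }

  rows <- list(
    layer_row("dense", units = seed_spatial^2 * seed_channels, use_bias = TRUE),
    layer_row("batch_norm"),
    layer_row("relu"),
    layer_row("reshape", target_h = seed_spatial, target_w = seed_spatial,
              target_c = seed_channels)
  )
  for (ch in inner) {
    rows <- c(rows, list(
      layer_row("transposed_conv", units = ch, kernel = kernel_size,
                stride = 2L, use_bias = FALSE),
      layer_row("batch_norm"),
      layer_row("relu")
    ))
  }
  rows <- c(rows, list(
    layer_row("transposed_conv", units = 1L, kernel = kernel_size,
              stride = 2L, use_bias = FALSE),
    layer_row("activation", activation = "tanh")
  ))
  spec <- new_network_spec(dplyr::bind_rows(rows),
                           input = list(latent_dim = as.integer(latent_dim)),
                           role = "generator")
  validate_network_spec(spec)
  spec
}

#' Build the discriminator architecture specification
#'
#' Constructs the layer table of a DCGAN discriminator: a stride-2 convolution
#' to `base_channels` followed by LeakyReLU, then stride-2 convolution blocks
#' (conv + batch norm + LeakyReLU, channels doubling) down to a 4x4 map at the
#' default size, a final stride-2 convolution to one channel, a flatten, and a
#' sigmoid activation over the flattened logits. There is no dense head and no
#' convolution bias. With the defaults this reproduces the 256x256 grayscale
#' discriminator with 4,369,440 parameters and 16 sigmoid outputs.
#'
#' @param image_shape Integer vector `(H, W, C)`; `H` must equal `W` and be a
#'   power of two (default `c(256, 256, 1)`).
#' @param base_channels Channels of the first convolution (default 32),
#'   doubled at each subsequent block.
#' @param kernel_size Square kernel side for every convolution (default 5).
#' @return A [network_spec] tibble (one row per layer).
#' @examples
#' disc <- discriminator_spec()
#' infer_shapes(disc)
#' @export
discriminator_spec <- function(image_shape = c(256, 256, 1),
                               base_channels = 32, kernel_size = 5) {
  if (length(image_shape) != 3 || any(image_shape <= 0) ||
        any(image_shape != round(image_shape))) {
    abort_config("image_shape must be three positive integers (H, W, C)")
  }
  if (image_shape[1] != image_shape[2]) {
    abort_config("discriminator input must be square (H = W)")
  }
  if (!is_pow2(image_shape[1])) {
    abort_config("discriminator input side must be a power of two")
  }
  if (base_channels < 1 || kernel_size < 1) {
    abort_config("base_channels and kernel_size must be positive")
  }
  side <- image_shape[1]
  n_convs <- max(2L, as.integer(round(log2(side))) - 2L)
  inner <- if (n_convs > 2) base_channels * 2^seq_len(n_convs - 2) else integer(0)

  rows <- list(
    layer_row("conv", units = base_channels, kernel = kernel_size,
              stride = 2L, use_bias = FALSE),
    layer_row("leaky_relu")
  )
  for (ch in inner) {
    rows <- c(rows, list(
      layer_row("conv", units = ch, kernel = kernel_size, stride = 2L,
                use_bias = FALSE),
      layer_row("batch_norm"),
      layer_row("leaky_relu")
    ))
  }
  rows <- c(rows, list(
    layer_row("conv", units = 1L, kernel = kernel_size, stride = 2L,
              use_bias = FALSE),
    layer_row("flatten"),
    layer_row("activation", activation = "sigmoid")
  ))
  spec <- new_network_spec(dplyr::bind_rows(rows),
                           input = list(image_shape = as.integer(image_shape)),
                           role = "discriminator")
  validate_network_spec(spec)
  spec
}

input_shape_state <- function(spec) {
  input <- attr(spec, "input")
  if (!is.null(input$latent_dim)) {
    list(flat = as.integer(input$latent_dim), hwc = NULL)
  } else {
    list(flat = NULL, hwc = as.integer(input$image_shape))
  }
}

#' Infer per-layer output shapes of a network specification
#'
#' Chains shapes through the layer table under the same-padding stride-2
#' convention: a stride-2 convolution halves height and width, a stride-2
#' transposed convolution doubles them; dense, reshape and flatten transform
#' as declared; elementwise layers preserve shape. Fails with a shape error
#' naming the offending layer when the chain is inconsistent (e.g. a reshape
#' that does not preserve volume).
#'
#' @param spec A [network_spec].
#' @return A tibble with one row per layer: `layer` (index), `kind`, `height`,
#'   `width`, `channels` (NA for flat outputs) and `flat` (flattened length,
#'   NA for spatial outputs).
#' @export
infer_shapes <- function(spec) {
  if (!inherits(spec, "network_spec")) {
    abort_config("infer_shapes expects a network_spec")
  }
  if (nrow(spec) == 0) {
    return(tibble::tibble(layer = integer(0), kind = character(0),
                          height = integer(0), width = integer(0),
                          channels = integer(0), flat = integer(0)))
  }
  state <- input_shape_state(spec)
  out <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    l <- spec[i, ]
    state <- switch(
      l$kind,
      dense = {
        if (is.null(state$flat)) {
          abort_shape(sprintf("layer %d (dense) needs a flat input", i), i)
        }
        list(flat = l$units, hwc = NULL)
      },
      reshape = {
        if (is.null(state$flat)) {
          abort_shape(sprintf("layer %d (reshape) needs a flat input", i), i)
        }
        vol <- as.double(l$target_h) * l$target_w * l$target_c
        if (vol != state$flat) {
          abort_shape(sprintf(
            "layer %d (reshape): target volume %dx%dx%d = %.0f != input length %d",
            i, l$target_h, l$target_w, l$target_c, vol, state$flat
          ), i)
        }
        list(flat = NULL, hwc = c(l$target_h, l$target_w, l$target_c))
      },
      transposed_conv = {
        if (is.null(state$hwc)) {
          abort_shape(sprintf("layer %d (transposed_conv) needs a spatial input", i), i)
        }
        list(flat = NULL,
             hwc = c(state$hwc[1] * l$stride, state$hwc[2] * l$stride, l$units))
      },
      conv = {
        if (is.null(state$hwc)) {
          abort_shape(sprintf("layer %d (conv) needs a spatial input", i), i)
        }
        list(flat = NULL,
             hwc = c(as.integer(ceiling(state$hwc[1] / l$stride)),
                     as.integer(ceiling(state$hwc[2] / l$stride)), l$units))
      },
      flatten = {
        if (is.null(state$hwc)) {
          abort_shape(sprintf("layer %d (flatten) needs a spatial input", i), i)
        }
        list(flat = as.integer(prod(state$hwc)), hwc = NULL)
      },
      # batch_norm / relu / leaky_relu / activation preserve shape
      state
    )
    out[[i]] <- tibble::tibble(
      layer = i, kind = l$kind,
      height = if (is.null(state$hwc)) NA_integer_ else state$hwc[1],
      width = if (is.null(state$hwc)) NA_integer_ else state$hwc[2],
      channels = if (is.null(state$hwc)) NA_integer_ else state$hwc[3],
      flat = if (is.null(state$flat)) NA_integer_ else state$flat
    )
  }
  dplyr::bind_rows(out)
}

#' Count parameters of a network specification
#'
#' Applies the standard bookkeeping: a dense layer contributes
#' `in * out (+ out if biased)`; a convolution or transposed convolution
#' `k * k * in_channels * out_channels (+ out_channels if biased)`; a batch
#' normalisation layer `4 * channels`, of which the scale/offset pair
#' (`2 * channels`) is trainable and the moving mean/variance pair
#' (`2 * channels`) is not. All other layer kinds are parameter-free.
#'
#' @param spec A [network_spec].
#' @return A `param_count` object: list with `total`, `trainable`,
#'   `non_trainable` and `per_layer` (a tibble aligned with the layers).
#'   `tidy()` returns the per-layer table, `glance()` the totals.
#' @examples
#' glance(count_parameters(generator_spec()))
#' @export
count_parameters <- function(spec) {
  shapes <- infer_shapes(spec)
  state <- input_shape_state(spec)
  fan_in <- function(i) {
    if (i == 1) {
      if (!is.null(state$flat)) c(flat = state$flat) else c(channels = state$hwc[3])
    } else if (!is.na(shapes$flat[i - 1])) {
      c(flat = shapes$flat[i - 1])
    } else {
      c(channels = shapes$channels[i - 1])
    }
  }
  n <- nrow(spec)
  params <- trainable <- numeric(n)
  for (i in seq_len(n)) {
    l <- spec[i, ]
    fi <- fan_in(i)
    p <- switch(
      l$kind,
      dense = as.double(fi[["flat"]]) * l$units +
        if (isTRUE(l$use_bias)) l$units else 0,
      conv = ,
      transposed_conv = as.double(l$kernel)^2 * fi[["channels"]] * l$units +
        if (isTRUE(l$use_bias)) l$units else 0,
      batch_norm = 4 * as.double(fi[[1]]),  # channel axis; flat width when 1-D
      0
    )
    params[i] <- p
    trainable[i] <- if (l$kind == "batch_norm") p / 2 else p
  }
  structure(
    list(
      total = sum(params),
      trainable = sum(trainable),
      non_trainable = sum(params) - sum(trainable),
      per_layer = tibble::tibble(
        layer = seq_len(n), kind = spec$kind, params = params,
        trainable = trainable, non_trainable = params - trainable
      )
    ),
    class = "param_count"
  )
}

#' @export
print.param_count <- function(x, ...) {
  cat(sprintf(
    "Total params: %s. Trainable params: %s. Non-trainable params: %s\n",
    format(x$total, big.mark = ","), format(x$trainable, big.mark = ","),
    format(x$non_trainable, big.mark = ",")
  ))
  invisible(x)
}

format_shape <- function(h, w, c, flat) {
  if (!is.na(flat)) sprintf("(None, %d)", flat)
  else sprintf("(None, %d, %d, %d)", h, w, c)
}

#' @export
print.network_spec <- function(x, ...) {
  role <- attr(x, "role")
  cat(sprintf("<network_spec: %s, %d layers>\n", role, nrow(x)))
  if (nrow(x) == 0) return(invisible(x))
  shapes <- infer_shapes(x)
  pc <- count_parameters(x)
  tab <- tibble::tibble(
    `Layer (type)` = x$kind,
    `Output shape` = purrr::pmap_chr(
      list(shapes$height, shapes$width, shapes$channels, shapes$flat),
      format_shape
    ),
    `Param #` = format(pc$per_layer$params, big.mark = ",", trim = TRUE)
  )
  print(as.data.frame(tab), right = FALSE, row.names = FALSE)
  print(pc)
  invisible(x)
}

#' Write / read a network specification as YAML
#'
#' Round-trips a [network_spec] through a plain YAML architecture file (role,
#' input descriptor, one mapping per layer with NA fields dropped).
#'
#' @param spec A [network_spec].
#' @param path File path.
#' @return `write_network_spec()` returns `path` invisibly;
#'   `read_network_spec()` returns the reconstructed [network_spec].
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  layers <- purrr::map(seq_len(nrow(spec)), function(i) {
    row <- as.list(spec[i, ])
    row[!purrr::map_lgl(row, is.na)]
  })
  yaml::write_yaml(
    list(role = attr(spec, "role"), input = attr(spec, "input"),
         layers = layers),
    path
  )
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  rows <- purrr::map(obj$layers, function(l) do.call(layer_row, l))
  input <- obj$input
  input[[1]] <- as.integer(input[[1]])
  spec <- new_network_spec(dplyr::bind_rows(rows), input = input,
                           role = obj$role)
  validate_network_spec(spec)
  spec
}
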