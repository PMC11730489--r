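# Compact CPU engine that realizes a network_spec as numeric weight arrays
# and provides forward/backward passes and Adam updates. Activations are
# (N, H, W, C) arrays or (N, units) matrices; convolutions use im2col with
# same-padding, and the stride-2 transposed convolution is implemented as the
# exact adjoint of the matching stride-2 convolution, so shape doubling/
# halving mirrors the spec's shape chain by construction.

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99

pad_amounts <- function(h, k, s) {
  hout <- as.integer(ceiling(h / s))
  pt <- max((hout - 1L) * s + k - h, 0L)
  list(hout = hout, beg = pt %/% 2L, total = pt)
}

pad_spatial <- function(x, beg, total) {
  if (total == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + total, d[3] + total, d[4]))
  xp[, beg + seq_len(d[2]), beg + seq_len(d[3]), ] <- x
  xp
}

crop_spatial <- function(xp, beg, h, w) {
  xp[, beg + seq_len(h), beg + seq_len(w), , drop = FALSE]
}

im2col <- function(xp, k, s, hout, wout) {
  d <- dim(xp)
  n <- d[1]; ch <- d[4]
  cols <- matrix(0, n * hout * wout, k * k * ch)
  off <- 0L
  for (dj in 0:(k - 1)) {
    for (di in 0:(k - 1)) {
      rows <- seq(1L + di, by = s, length.out = hout)
      cls <- seq(1L + dj, by = s, length.out = wout)
      cols[, off + seq_len(ch)] <-
        matrix(xp[, rows, cls, , drop = FALSE], n * hout * wout, ch)
      off <- off + ch
    }
  }
  cols
}

col2im <- function(cols, n, hp, wp, ch, k, s, hout, wout) {
  xp <- array(0, c(n, hp, wp, ch))
  off <- 0L
  for (dj in 0:(k - 1)) {
    for (di in 0:(k - 1)) {
      rows <- seq(1L + di, by = s, length.out = hout)
      cls <- seq(1L + dj, by = s, length.out = wout)
      xp[, rows, cls, ] <- xp[, rows, cls, , drop = FALSE] +
        array(cols[, off + seq_len(ch)], c(n, hout, wout, ch))
      off <- off + ch
    }
  }
  xp
}

#' Materialize a network specification into weight arrays
#'
#' Realizes a [network_spec] in the package's CPU engine: every dense /
#' convolution / batch-norm layer gets concrete parameter arrays (Gaussian
#' init, sd 0.02, the DCGAN convention; batch-norm scale 1 / offset 0 with
#' zero moving mean and unit moving variance). The element counts of the
#' realized network are exactly those reported by [count_parameters()], which
#' [network_numel()] exposes for parity checks.
#'
#' @param spec A [network_spec].
#' @param seed Integer seed for the weight initialisation.
#' @return A `gan_network` object (list of per-layer parameter arrays plus
#'   static shape metadata).
#' @export
build_network <- function(spec, seed = 0) {
  shapes <- infer_shapes(spec)
  state <- input_shape_state(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  layers <- vector("list", nrow(spec))
  meta <- vector("list", nrow(spec))
  cur_flat <- state$flat
  cur_hwc <- state$hwc
  for (i in seq_len(nrow(spec))) {
    l <- spec[i, ]
    if (l$kind == "dense") {
      layers[[i]] <- list(
        W = matrix(stats::rnorm(cur_flat * l$units, sd = 0.02), cur_flat, l$units),
        b = if (isTRUE(l$use_bias)) numeric(l$units) else NULL
      )
      meta[[i]] <- list(kind = "dense")
    } else if (l$kind == "batch_norm") {
      ch <- if (is.null(cur_hwc)) cur_flat else cur_hwc[3]
      layers[[i]] <- list(gamma = rep(1, ch), beta = numeric(ch),
                          moving_mean = numeric(ch), moving_var = rep(1, ch))
      meta[[i]] <- list(kind = "batch_norm", channels = ch)
    } else if (l$kind == "conv") {
      cin <- cur_hwc[3]
      pads <- pad_amounts(cur_hwc[1], l$kernel, l$stride)
      layers[[i]] <- list(
        W = matrix(stats::rnorm(l$kernel^2 * cin * l$units, sd = 0.02),
                   l$kernel^2 * cin, l$units)
      )
      meta[[i]] <- list(kind = "conv", k = l$kernel, s = l$stride,
                        cin = cin, cout = l$units,
                        hin = cur_hwc[1], win = cur_hwc[2],
                        hout = pads$hout, wout = pads$hout,
                        beg = pads$beg, total = pads$total)
    } else if (l$kind == "transposed_conv") {
      cin <- cur_hwc[3]
      hout <- cur_hwc[1] * l$stride
      # adjoint conv maps (hout, cout) -> (hin, cin)
      pads <- pad_amounts(hout, l$kernel, l$stride)
      layers[[i]] <- list(
        W = matrix(stats::rnorm(l$kernel^2 * l$units * cin, sd = 0.02),
                   l$kernel^2 * l$units, cin)
      )
      meta[[i]] <- list(kind = "transposed_conv", k = l$kernel, s = l$stride,
                        cin = cin, cout = l$units,
                        hin = cur_hwc[1], win = cur_hwc[2],
                        hout = hout, wout = cur_hwc[2] * l$stride,
                        beg = pads$beg, total = pads$total)
    } else {
      meta[[i]] <- list(kind = l$kind, activation = l$activation,
                        target = c(l$target_h, l$target_w, l$target_c))
    }
    cur_flat <- if (is.na(shapes$flat[i])) NULL else shapes$flat[i]
    cur_hwc <- if (is.na(shapes$height[i])) NULL else
      c(shapes$height[i], shapes$width[i], shapes$channels[i])
  }
  structure(list(spec = spec, layers = layers, meta = meta,
                 role = attr(spec, "role"),
                 input = attr(spec, "input")),
            class = "gan_network")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Element counts of a materialized network
#'
#' @param net A `gan_network` from [build_network()].
#' @return A list with `total`, `trainable` and `non_trainable` element
#'   counts summed over all realized parameter arrays.
#' @export
network_numel <- function(net) {
  stopifnot(inherits(net, "gan_network"))
  total <- trainable <- 0
  for (p in net$layers) {
    if (is.null(p)) next
    for (nm in names(p)) {
      if (is.null(p[[nm]])) next
      n <- length(p[[nm]])
      total <- total + n
      if (!nm %in% c("moving_mean", "moving_var")) trainable <- trainable + n
    }
  }
  list(total = total, trainable = trainable, non_trainable = total - trainable)
}

# forward pass; returns list(out, caches) when grad = TRUE
network_forward <- function(net, x, training = TRUE, grad = FALSE) {
  caches <- if (grad) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    m <- net$meta[[i]]
    p <- net$layers[[i]]
    if (m$kind == "dense") {
      inx <- x
      x <- inx %*% p$W
      if (!is.null(p$b)) x <- sweep(x, 2, p$b, "+")
      if (grad) caches[[i]] <- list(x = inx)
    } else if (m$kind == "batch_norm") {
      d <- dim(x)
      flatin <- is.matrix(x)
      xm <- if (flatin) x else matrix(x, prod(d[1:3]), d[4])
      if (training) {
        mu <- colMeans(xm)
        xc <- sweep(xm, 2, mu)
        v <- colMeans(xc^2)
      } else {
        mu <- p$moving_mean
        v <- p$moving_var
        xc <- sweep(xm, 2, mu)
      }
      inv_std <- 1 / sqrt(v + BN_EPS)
      xhat <- sweep(xc, 2, inv_std, "*")
      ym <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
      x <- if (flatin) ym else array(ym, d)
      if (grad) caches[[i]] <- list(xhat = xhat, inv_std = inv_std, dims = d,
                                    flatin = flatin, mu = mu, v = v)
    } else if (m$kind == "relu") {
      mask <- x > 0
      x <- x * mask
      if (grad) caches[[i]] <- list(mask = mask)
    } else if (m$kind == "leaky_relu") {
      mask <- x > 0
      x <- ifelse(mask, x, 0.2 * x)
      if (grad) caches[[i]] <- list(mask = mask)
    } else if (m$kind == "reshape") {
      n <- nrow(x)
      x <- array(x, c(n, m$target))
      if (grad) caches[[i]] <- list(n = n)
    } else if (m$kind == "flatten") {
      d <- dim(x)
      x <- matrix(x, d[1], prod(d[-1]))
      if (grad) caches[[i]] <- list(dims = d)
    } else if (m$kind == "conv") {
      xp <- pad_spatial(x, m$beg, m$total)
      cols <- im2col(xp, m$k, m$s, m$hout, m$wout)
      y <- cols %*% p$W
      n <- dim(x)[1]
      x <- array(y, c(n, m$hout, m$wout, m$cout))
      if (grad) caches[[i]] <- list(cols = cols, n = n, dp = dim(xp))
    } else if (m$kind == "transposed_conv") {
      n <- dim(x)[1]
      xmat <- matrix(x, n * m$hin * m$win, m$cin)
      colsT <- xmat %*% t(p$W)
      yp <- col2im(colsT, n, m$hout + m$total, m$wout + m$total, m$cout,
                   m$k, m$s, m$hin, m$win)
      x <- crop_spatial(yp, m$beg, m$hout, m$wout)
      if (grad) caches[[i]] <- list(xmat = xmat, n = n)
    } else if (m$kind == "activation") {
      x <- switch(m$activation, tanh = tanh(x), sigmoid = stats::plogis(x), x)
      if (grad) caches[[i]] <- list(y = x)
    }
  }
  if (grad) list(out = x, caches = caches) else list(out = x)
}

# batch-norm forward recomputation is avoided by updating moving stats in a
# dedicated pass: network_forward with training = TRUE leaves moving stats
# untouched (a functional engine); update_moving_stats applies the EMA.
update_moving_stats <- function(net, caches) {
  for (i in seq_along(net$layers)) {
    if (net$meta[[i]]$kind == "batch_norm" && !is.null(caches[[i]])) {
      c_ <- caches[[i]]
      net$layers[[i]]$moving_mean <-
        BN_MOMENTUM * net$layers[[i]]$moving_mean + (1 - BN_MOMENTUM) * c_$mu
      net$layers[[i]]$moving_var <-
        BN_MOMENTUM * net$layers[[i]]$moving_var + (1 - BN_MOMENTUM) * c_$v
    }
  }
  net
}

# backward pass: dout has the shape of the network output; returns
# list(dx, grads) with grads aligned to layers
network_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  dx <- dout
  for (i in rev(seq_along(net$layers))) {
    m <- net$meta[[i]]
    p <- net$layers[[i]]
    c_ <- caches[[i]]
    if (m$kind == "dense") {
      grads[[i]] <- list(W = crossprod(c_$x, dx),
                         b = if (!is.null(p$b)) colSums(dx) else NULL)
      dx <- tcrossprod(dx, p$W)
    } else if (m$kind == "batch_norm") {
      d <- c_$dims
      dym <- if (c_$flatin) dx else matrix(dx, prod(d[1:3]), d[4])
      mrows <- nrow(dym)
      dgamma <- colSums(dym * c_$xhat)
      dbeta <- colSums(dym)
      t1 <- sweep(dym, 2, dbeta / mrows)
      t2 <- sweep(c_$xhat, 2, dgamma / mrows, "*")
      dxm <- sweep(t1 - t2, 2, p$gamma * c_$inv_std, "*")
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      dx <- if (c_$flatin) dxm else array(dxm, d)
    } else if (m$kind == "relu") {
      dx <- dx * c_$mask
    } else if (m$kind == "leaky_relu") {
      dx <- ifelse(c_$mask, dx, 0.2 * dx)
    } else if (m$kind == "reshape") {
      dx <- matrix(dx, c_$n, prod(m$target))
    } else if (m$kind == "flatten") {
      dx <- array(dx, c_$dims)
    } else if (m$kind == "conv") {
      dymat <- matrix(dx, c_$n * m$hout * m$wout, m$cout)
      grads[[i]] <- list(W = crossprod(c_$cols, dymat))
      dxp <- col2im(tcrossprod(dymat, p$W), c_$n, c_$dp[2], c_$dp[3], m$cin,
                    m$k, m$s, m$hout, m$wout)
      dx <- crop_spatial(dxp, m$beg, m$hin, m$win)
    } else if (m$kind == "transposed_conv") {
      dyp <- pad_spatial(dx, m$beg, m$total)
      cols_dy <- im2col(dyp, m$k, m$s, m$hin, m$win)
      grads[[i]] <- list(W = crossprod(cols_dy, c_$xmat))
      dx <- array(cols_dy %*% p$W, c(c_$n, m$hin, m$win, m$cin))
    } else if (m$kind == "activation") {
      dx <- switch(m$activation,
                   tanh = dx * (1 - c_$y^2),
                   sigmoid = dx * c_$y * (1 - c_$y),
                   dx)
    }
  }
  list(dx = dx, grads = grads)
}

adam_init <- function(net) {
  purrr::map(net$layers, function(p) {
    if (is.null(p)) return(NULL)
    nm <- setdiff(names(p), c("moving_mean", "moving_var"))
    stats_ <- purrr::map(p[nm], function(w) {
      if (is.null(w)) NULL else list(m = w * 0, v = w * 0)
    })
    stats_
  })
}

adam_step <- function(net, grads, state, lr, beta1, beta2 = 0.999,
                      eps = 1e-8, t = 1) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      if (is.null(g[[nm]])) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$layers[[i]][[nm]] <- net$layers[[i]][[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}
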