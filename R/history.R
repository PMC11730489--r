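#' Loss-history objects
#'
#' A loss history is a tibble with one row per epoch and columns `epoch`
#' (0-based, strictly increasing integers), `g_loss` and `d_loss` (finite,
#' non-negative, in nats). It is the central analysis object: every slope /
#' stop / divergence operation consumes it, and it round-trips through the
#' `epoch,g_loss,d_loss` CSV interchange format, so histories logged by any
#' GAN trainer can be analyzed.
#'
#' @param x A data frame with columns `epoch`, `g_loss`, `d_loss`.
#' @return A `loss_history` tibble.
#' @export
as_loss_history <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("epoch", "g_loss", "d_loss")
  if (!all(req %in% names(x))) {
    abort_config("a loss history needs columns epoch, g_loss and d_loss")
  }
  x <- x[req]
  if (nrow(x) > 0) {
    if (any(!is.finite(x$epoch)) || any(x$epoch != round(x$epoch)) ||
          any(diff(x$epoch) <= 0)) {
      abort_config("epoch must be strictly increasing integers")
    }
    if (any(!is.finite(x$g_loss)) || any(!is.finite(x$d_loss)) ||
          any(x$g_loss < 0) || any(x$d_loss < 0)) {
      abort_config("losses must be finite and non-negative")
    }
  }
  x$epoch <- as.integer(x$epoch)
  class(x) <- c("loss_history", class(tibble::tibble()))
  x
}

#' Read / write the loss-history CSV interchange format
#'
#' The file format is `epoch,g_loss,d_loss` with a header row, one row per
#' epoch, UTF-8, `.` decimal separator. Reading validates the header, the
#' numeric cells and epoch monotonicity, and reports the offending line
#' number on failure; writing uses 10 significant digits so histories
#' round-trip value-identically at that precision.
#'
#' @param path CSV file path.
#' @param history A [as_loss_history()] tibble (or plain data frame).
#' @return `read_loss_history()` returns a `loss_history` tibble;
#'   `write_loss_history()` returns `path` invisibly.
#' @export
read_loss_history <- function(path) {
  abort_parse <- function(msg) {
    rlang::abort(paste0(path, ": ", msg), class = "ganstop_parse_error")
  }
  if (!file.exists(path)) abort_parse("file does not exist")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_parse("empty file")
  header <- trimws(strsplit(lines[1], ",")[[1]])
  if (!identical(header, c("epoch", "g_loss", "d_loss"))) {
    abort_parse("line 1: expected header 'epoch,g_loss,d_loss'")
  }
  n <- length(lines) - 1L
  epoch <- integer(n); g <- numeric(n); d <- numeric(n)
  prev <- -Inf
  for (i in seq_len(n)) {
    cells <- strsplit(lines[i + 1], ",")[[1]]
    if (length(cells) != 3) {
      abort_parse(sprintf("line %d: expected 3 comma-separated cells, got %d",
                          i + 1, length(cells)))
    }
    vals <- suppressWarnings(as.numeric(trimws(cells)))
    if (any(is.na(vals))) {
      abort_parse(sprintf("line %d: non-numeric cell '%s'",
                          i + 1, trimws(cells[which(is.na(vals))[1]])))
    }
    if (vals[1] != round(vals[1]) || vals[1] <= prev) {
      abort_parse(sprintf(
        "line %d: epochs must be strictly increasing integers (got %s after %s)",
        i + 1, format(vals[1]), format(prev)))
    }
    prev <- vals[1]
    epoch[i] <- as.integer(vals[1]); g[i] <- vals[2]; d[i] <- vals[3]
  }
  as_loss_history(tibble::tibble(epoch = epoch, g_loss = g, d_loss = d))
}

#' @rdname read_loss_history
#' @export
write_loss_history <- function(history, path) {
  history <- as_loss_history(history)
  fmt <- function(x) formatC(x, digits = 10, format = "g")
  lines <- c("epoch,g_loss,d_loss",
             sprintf("%d,%s,%s", history$epoch, fmt(history$g_loss),
                     fmt(history$d_loss)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Descriptive statistics of a loss channel
#'
#' Mean, median, standard deviation (n-1 denominator), minimum and maximum of
#' one or both loss channels — the summary printed for each training outcome.
#' A single-point series reports `sd = 0` and raises a warning.
#'
#' @param history A loss history (data frame with `epoch,g_loss,d_loss`).
#' @param channel `"g_loss"`, `"d_loss"` or `"both"` (default).
#' @return A tibble with columns `channel`, `n`, `mean`, `median`, `sd`,
#'   `min`, `max`.
#' @examples
#' h <- simulate_loss_history(archetype_params("A1_fluctuating"))
#' loss_summary(h)
#' @export
loss_summary <- function(history, channel = c("both", "g_loss", "d_loss")) {
  channel <- match.arg(channel)
  history <- as_loss_history(history)
  if (nrow(history) == 0) abort_config("loss history is empty")
  chans <- if (channel == "both") c("g_loss", "d_loss") else channel
  purrr::map_dfr(chans, function(ch) {
    y <- history[[ch]]
    s <- if (length(y) == 1) {
      rlang::warn("single-point series: sd reported as 0",
                  class = "ganstop_single_point_sd")
      0
    } else stats::sd(y)
    tibble::tibble(channel = ch, n = length(y), mean = mean(y),
                   median = stats::median(y), sd = s,
                   min = min(y), max = max(y))
  })
}
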