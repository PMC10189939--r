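#' Random convolutional kernel transform
#'
#' The transform convolves a large bank of random kernels over the padded
#' multichannel residue representation and summarizes each kernel's output
#' series by two statistics: the proportion of positive values (PPV, strict
#' `> 0`) and the maximum. A bank of 10,000 kernels therefore yields 20,000
#' features per peptide, which feed an L2-regularized logistic regression.
#'
#' Kernel sampling follows the standard recipe for this family of
#' transforms: length uniform over \{7, 9, 11\}; weights standard normal,
#' mean-centered per kernel; bias uniform on \[-1, 1\]; dilation `floor(2^a)`
#' with `a` uniform on `[0, log2((input_length - 1) / (length - 1))]` so the
#' dilated span never exceeds the input; "same" zero-padding on a fair coin.
#' Multichannel inputs use a random channel subset per kernel (subset size
#' log-uniform on \[1, n_channels\], channels drawn without replacement);
#' an all-channels mode is available for sensitivity analysis.
#'
#' @name rocket
NULL

#' Generate a random kernel bank
#'
#' Deterministic under `seed`: the same (seed, n_kernels, input_length,
#' n_channels) regenerate a bit-identical bank.
#'
#' @param n_kernels Number of kernels (>= 0).
#' @param input_length Series length the bank will be applied to (the padded
#'   residue count, usually 50); must be at least 11, the largest kernel
#'   length at dilation 1.
#' @param n_channels Number of input channels.
#' @param seed Integer RNG seed.
#' @param channel_mode `"subset"` (default, random channel subsets) or
#'   `"all"` (every kernel sees all channels).
#' @return A `kernel_bank` object: list of kernels (each with `length`,
#'   `channels`, `weights` |channels| x length, `bias`, `dilation`,
#'   `padding`) plus the generation parameters.
#' @export
generate_kernels <- function(n_kernels, input_length, n_channels, seed,
                             channel_mode = c("subset", "all")) {
  channel_mode <- match.arg(channel_mode)
  if (n_channels <= 0L) stop("n_channels must be positive", call. = FALSE)
  if (n_kernels < 0L) stop("n_kernels must be >= 0", call. = FALSE)
  if (input_length < 11L) {
    stop("input_length must be >= 11 (largest kernel span at dilation 1)", call. = FALSE)
  }
  kernels <- with_seed(seed, lapply(seq_len(n_kernels), function(i) {
    len <- sample(c(7L, 9L, 11L), 1L)
    if (channel_mode == "all") {
      ch <- seq_len(n_channels)
    } else {
      n_ch <- max(1L, min(n_channels, as.integer(floor(2^runif(1, 0, log2(n_channels + 1))))))
      ch <- sort(sample.int(n_channels, n_ch))
    }
    w <- matrix(rnorm(length(ch) * len), nrow = length(ch))
    w <- w - mean(w)
    bias <- runif(1, -1, 1)
    a_max <- log2((input_length - 1) / (len - 1))
    dilation <- max(1L, as.integer(floor(2^runif(1, 0, a_max))))
    padding <- runif(1) < 0.5
    list(length = len, channels = ch, weights = w, bias = bias,
         dilation = dilation, padding = padding)
  }))
  structure(list(kernels = kernels, n_kernels = as.integer(n_kernels),
                 seed = as.integer(seed), input_length = as.integer(input_length),
                 n_channels = as.integer(n_channels), channel_mode = channel_mode),
            class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("Kernel bank: %d kernels over %d channels x %d positions (seed %d, %s channels)\n",
              x$n_kernels, x$n_channels, x$input_length, x$seed, x$channel_mode))
  invisible(x)
}

#' Apply one kernel to one padded representation (reference implementation)
#'
#' Plain-R dilated convolution along the residue axis, summed over the
#' kernel's channel subset; with `padding` the series is zero-extended by
#' `(length - 1) * dilation / 2` on both sides. This naive loop is the
#' reference the vectorized [rocket_transform()] is tested against.
#'
#' @param x Numeric L x C matrix (a padded tensor; pad rows are ordinary
#'   zeros to the convolution).
#' @param k A kernel from a [generate_kernels()] bank.
#' @return Named numeric vector `c(ppv = ..., max = ...)`; PPV counts output
#'   entries strictly greater than zero.
#' @export
apply_kernel <- function(x, k) {
  L <- nrow(x)
  span <- (k$length - 1L) * k$dilation
  pad <- if (k$padding) span %/% 2L else 0L
  t0 <- 1L - pad
  t1 <- L + pad - span
  if (t1 < t0) stop("kernel span exceeds input length", call. = FALSE)
  out <- numeric(t1 - t0 + 1L)
  for (t in t0:t1) {
    s <- k$bias
    for (j in seq_len(k$length)) {
      idx <- t + (j - 1L) * k$dilation
      if (idx >= 1L && idx <= L) {
        s <- s + sum(k$weights[, j] * x[idx, k$channels])
      }
    }
    out[t - t0 + 1L] <- s
  }
  c(ppv = mean(out > 0), max = max(out))
}

#' Transform padded representations with a kernel bank
#'
#' Produces the n_samples x (2 * n_kernels) feature matrix: for each kernel,
#' in bank order, its PPV then its maximum. Computation is done in compiled
#' code; it matches the naive [apply_kernel()] loop exactly.
#'
#' @param samples List of numeric `input_length` x `n_channels` matrices
#'   (e.g. from [pad_to()]), or a single such matrix.
#' @param bank A [generate_kernels()] bank.
#' @return Numeric matrix with `attr(, "provenance")`: data.frame (`kernel`,
#'   `stat`) describing each column.
#' @export
rocket_transform <- function(samples, bank) {
  stopifnot(inherits(bank, "kernel_bank"))
  if (is.matrix(samples)) samples <- list(samples)
  for (i in seq_along(samples)) {
    d <- dim(samples[[i]])
    if (d[1] != bank$input_length || d[2] != bank$n_channels) {
      stop(sprintf("sample %d is %d x %d; bank expects %d x %d",
                   i, d[1], d[2], bank$input_length, bank$n_channels), call. = FALSE)
    }
  }
  X <- array(unlist(samples, use.names = FALSE),
             dim = c(bank$input_length, bank$n_channels, length(samples)))
  out <- rocket_transform_cpp(X, bank$kernels)
  prov <- data.frame(kernel = rep(seq_len(bank$n_kernels), each = 2L),
                     stat = rep(c("ppv", "max"), times = bank$n_kernels))
  if (bank$n_kernels > 0L) {
    colnames(out) <- paste0("k", prov$kernel, "_", prov$stat)
  }
  attr(out, "provenance") <- prov
  out
}

fmt_dbl <- function(x) sprintf("%.17g", x)

#' Serialize a kernel bank to JSON
#'
#' Doubles are written as 17-significant-digit strings so the round trip is
#' bit-exact, allowing a frozen transform to be reused across sessions.
#'
#' @param bank A `kernel_bank`.
#' @param path Output JSON path.
#' @export
write_kernel_bank <- function(bank, path) {
  ser <- list(
    n_kernels = bank$n_kernels, seed = bank$seed,
    input_length = bank$input_length, n_channels = bank$n_channels,
    channel_mode = bank$channel_mode,
    kernels = lapply(bank$kernels, function(k) list(
      length = k$length, channels = k$channels,
      weights = fmt_dbl(k$weights), n_rows = nrow(k$weights),
      bias = fmt_dbl(k$bias), dilation = k$dilation, padding = k$padding
    ))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a kernel bank written by [write_kernel_bank()]
#' @param path JSON path.
#' @return A `kernel_bank` identical (bit-exact) to the one written.
#' @export
read_kernel_bank <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  kernels <- lapply(seq_len(ser$n_kernels), function(i) {
    k <- if (is.data.frame(ser$kernels)) lapply(ser$kernels, `[[`, i) else ser$kernels[[i]]
    list(length = as.integer(k$length),
         channels = as.integer(unlist(k$channels)),
         weights = matrix(as.numeric(unlist(k$weights)), nrow = as.integer(k$n_rows)),
         bias = as.numeric(k$bias),
         dilation = as.integer(k$dilation),
         padding = as.logical(k$padding))
  })
  structure(list(kernels = kernels, n_kernels = as.integer(ser$n_kernels),
                 seed = as.integer(ser$seed), input_length = as.integer(ser$input_length),
                 n_channels = as.integer(ser$n_channels),
                 channel_mode = ser$channel_mode %||% "subset"),
            class = "kernel_bank")
}
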