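#' Supported spectral window kinds
#'
#' @return Character vector of the sixteen window-function names accepted by
#'   [stft_window()].
#' @export
window_kinds <- function() {
  c("bartlett_hann", "bartlett", "blackman", "blackman_harris", "bohman",
    "chebyshev", "flat_top", "gaussian", "hamming", "hann", "kaiser",
    "nuttall", "parzen", "rectangular", "tukey", "triangular")
}

# cosine-sum window, symmetric over k = 0..L-1
cosine_sum_window <- function(L, a) {
  k <- seq_len(L) - 1
  m <- L - 1
  w <- rep(a[1], L)
  for (j in seq_along(a)[-1]) {
    w <- w + (-1)^(j - 1) * a[j] * cos(2 * pi * (j - 1) * k / m)
  }
  w
}

#' Generate a symmetric spectral window
#'
#' Returns the symmetric form of the requested window, length `L`, following
#' the classic signal-processing definitions (cosine-sum coefficients and
#' shape-parameter conventions as in mainstream DSP toolboxes). Windows whose
#' canonical definition peaks at 1 do so here.
#'
#' @param kind One of [window_kinds()]. `"tukey"` is the tapered cosine.
#' @param length Window length in samples (>= 2).
#' @param shape_param Optional shape parameter: reciprocal standard deviation
#'   `alpha` for `"gaussian"` (default 2.5), `beta` for `"kaiser"` (default
#'   0.5), sidelobe attenuation in dB for `"chebyshev"` (default 100), taper
#'   ratio for `"tukey"` (default 0.5). Ignored by the other kinds.
#' @return Numeric vector of length `length`.
#' @export
stft_window <- function(kind, length = 100, shape_param = NULL) {
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% window_kinds())) {
    stop("unsupported window kind: ", paste(kind, collapse = ", "),
         "; see window_kinds()", call. = FALSE)
  }
  L <- as.integer(length)
  if (L < 2L) stop("window length must be >= 2", call. = FALSE)
  k <- seq_len(L) - 1
  m <- L - 1
  w <- switch(kind,
    rectangular = rep(1, L),
    bartlett = as.numeric(signal::bartlett(L)),
    triangular = as.numeric(signal::triang(L)),
    hamming = as.numeric(signal::hamming(L)),
    hann = as.numeric(signal::hanning(L)),
    blackman = as.numeric(signal::blackman(L)),
    kaiser = as.numeric(signal::kaiser(L, beta = shape_param %||% 0.5)),
    chebyshev = as.numeric(signal::chebwin(L, at = shape_param %||% 100)),
    bartlett_hann = 0.62 - 0.48 * abs(k / m - 0.5) +
      0.38 * cos(2 * pi * (k / m - 0.5)),
    blackman_harris = cosine_sum_window(L, c(0.35875, 0.48829, 0.14128,
                                             0.01168)),
    nuttall = cosine_sum_window(L, c(0.3635819, 0.4891775, 0.1365995,
                                     0.0106411)),
    flat_top = cosine_sum_window(L, c(0.21557895, 0.41663158, 0.277263158,
                                      0.083578947, 0.006947368)),
    bohman = {
      x <- abs(2 * k / m - 1)
      (1 - x) * cos(pi * x) + sin(pi * x) / pi
    },
    gaussian = {
      alpha <- shape_param %||% 2.5
      n <- k - m / 2
      exp(-0.5 * (alpha * n / (m / 2))^2)
    },
    parzen = {
      n <- k - m / 2
      x <- abs(n) / (L / 2)
      ifelse(x <= 0.5, 1 - 6 * x^2 + 6 * x^3, 2 * (1 - x)^3)
    },
    tukey = {
      r <- shape_param %||% 0.5
      if (r <= 0) {
        rep(1, L)
      } else if (r >= 1) {
        0.5 * (1 + cos(pi * (2 * k / m - 1)))
      } else {
        x <- k / m
        w <- rep(1, L)
        lo <- x < r / 2
        hi <- x > 1 - r / 2
        w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / r - 1)))
        w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / r - 2 / r + 1)))
        w
      }
    }
  )
  as.numeric(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
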