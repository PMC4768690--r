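#' Band-limited Fourier resampling of a periodic signal
#'
#' Resamples a sequence to length `n` by trigonometric (FFT) interpolation,
#' treating the input as one period of a periodic signal: forward FFT,
#' symmetric truncation or zero-padding of the spectrum to `n` bins with the
#' Nyquist bin folded (downsampling) or split (upsampling), inverse FFT, and
#' amplitude rescaling by `n / length(x)`. This is the natural interpolation
#' for a closed-contour radius signal.
#'
#' @param x Numeric vector (a `"contour_signal"` is accepted; its radii are
#'   used), length >= 4.
#' @param n Output length, default 1000.
#' @return Numeric vector of length `n`.
#' @export
resample_fft <- function(x, n = 1000) {
  if (inherits(x, "contour_signal")) x <- x$radii
  if (!is.numeric(x) || length(x) < 4L) {
    stop("x must be a numeric vector of length >= 4", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("x contains non-finite values", call. = FALSE)
  n <- as.integer(n)
  if (n < 4L) stop("n must be >= 4", call. = FALSE)
  nx <- length(x)
  if (n == nx) return(as.numeric(x))
  X <- stats::fft(x)
  Y <- complex(n)
  nkeep <- min(n, nx)
  nyq <- nkeep %/% 2L + 1L
  Y[seq_len(nyq)] <- X[seq_len(nyq)]
  ntail <- nkeep - nyq
  if (ntail > 0L) {
    Y[(n - ntail + 1L):n] <- X[(nx - ntail + 1L):nx]
  }
  if (nkeep %% 2L == 0L) {
    h <- nkeep %/% 2L
    if (n < nx) {
      # fold the conjugate negative-Nyquist energy into the retained bin
      Y[h + 1L] <- Y[h + 1L] + X[nx - h + 1L]
    } else {
      # split the Nyquist bin between positive and negative frequencies
      Y[h + 1L] <- 0.5 * Y[h + 1L]
      Y[n - h + 1L] <- Y[h + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / nx
}

#' Short-time Fourier transform
#'
#' Splits a signal into overlapping segments, applies a window, and computes
#' a length-`nfft` DFT of each segment, keeping the one-sided spectrum
#' (bins `0..nfft/2`). Segment `s` covers samples
#' `[(s-1)*hop + 1, (s-1)*hop + L]` with `hop = L - overlap`; trailing
#' samples that do not fill a window are discarded, giving
#' `S = floor((N - overlap) / hop)` segments.
#'
#' @param x Numeric signal of length `N` (e.g. from [resample_fft()]).
#' @param window Either a numeric window vector, or a window kind name passed
#'   to [stft_window()]. Default: Gaussian window of length 100.
#' @param length Window length `L` when `window` is a kind name.
#' @param overlap Number of overlapping samples between consecutive
#'   segments, `0 <= overlap < L`. Default 40.
#' @param nfft DFT length, `>= L`. Default (`NULL`) is
#'   `max(256, 2^ceiling(log2(L)))`, which yields 129 one-sided frequency
#'   bins for the standard 100-sample window.
#' @param shape_param Optional window shape parameter, see [stft_window()].
#' @param fs Sampling frequency recorded for axis labelling only; the
#'   default `2*pi` gives normalised angular frequency.
#' @return Object of class `"stft_spectrogram"`: list with `coeffs`
#'   (complex `S x F` matrix), `nfft`, `fs`, `window` (the window vector),
#'   `overlap`, `hop` and `n` (input length).
#' @export
stft <- function(x, window = "gaussian", length = 100, overlap = 40,
                 nfft = NULL, shape_param = NULL, fs = 2 * pi) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("x must be a finite numeric vector", call. = FALSE)
  }
  if (is.character(window)) {
    w <- stft_window(window, length, shape_param)
  } else {
    w <- as.numeric(window)
  }
  L <- base::length(w)
  N <- base::length(x)
  if (L > N) {
    stop("window length (", L, ") exceeds signal length (", N, ")",
         call. = FALSE)
  }
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= L) {
    stop("overlap must satisfy 0 <= overlap < window length", call. = FALSE)
  }
  if (is.null(nfft)) {
    nfft <- max(256L, 2L^ceiling(log2(L)))
  }
  nfft <- as.integer(nfft)
  if (nfft < L) stop("nfft must be >= window length", call. = FALSE)
  hop <- L - overlap
  S <- (N - overlap) %/% hop
  if (S < 1L) stop("signal too short for one full segment", call. = FALSE)
  Fbins <- nfft %/% 2L + 1L
  coeffs <- matrix(complex(1), nrow = S, ncol = Fbins)
  for (s in seq_len(S)) {
    seg <- x[((s - 1L) * hop + 1L):((s - 1L) * hop + L)] * w
    X <- stats::fft(c(seg, rep(0, nfft - L)))
    coeffs[s, ] <- X[seq_len(Fbins)]
  }
  structure(
    list(coeffs = coeffs, nfft = nfft, fs = fs, window = w,
         overlap = overlap, hop = hop, n = N),
    class = "stft_spectrogram"
  )
}

#' @export
print.stft_spectrogram <- function(x, ...) {
  cat("STFT spectrogram: ", nrow(x$coeffs), " segments x ", ncol(x$coeffs),
      " one-sided frequency bins (nfft = ", x$nfft, ", window length ",
      base::length(x$window), ", overlap ", x$overlap, ")\n", sep = "")
  invisible(x)
}

#' @export
plot.stft_spectrogram <- function(x, ...) {
  psd <- 10 * log10(pmax(Mod(t(x$coeffs))^2, .Machine$double.eps))
  graphics::image(
    x = seq_len(nrow(x$coeffs)), y = seq(0, x$fs / 2, length.out = ncol(x$coeffs)),
    z = t(psd), xlab = "segment", ylab = "normalised frequency",
    col = grDevices::hcl.colors(64, "viridis"), ...
  )
  invisible(x)
}

#' Per-segment spectral maxima features
#'
#' For each STFT segment, the magnitudes of the one-sided frequency
#' components are z-scored across bins and their maximum recorded
#' (`MAX_ABS`); likewise for the principal-value phase angles (`MAX_ANG`).
#' With the standard 16-segment configuration this yields the 32-element
#' shape descriptor used by the STFT-DA classifier.
#'
#' @param spectrogram An `"stft_spectrogram"` object.
#' @param ddof Degrees-of-freedom correction for the z-score standard
#'   deviation: 1 (sample sd, default) or 0 (population sd).
#' @return Object of class `"stftda_features"`: list with numeric vectors
#'   `max_abs`, `max_ang` (length `S` each) and `combined` (length `2*S`,
#'   named `MAX_ABS_01..`, `MAX_ANG_01..`).
#' @export
extract_features <- function(spectrogram, ddof = 1) {
  if (!inherits(spectrogram, "stft_spectrogram")) {
    stop("spectrogram must be an 'stft_spectrogram' object", call. = FALSE)
  }
  co <- spectrogram$coeffs
  S <- nrow(co)
  Fbins <- ncol(co)
  if (Fbins < 2L) stop("need at least 2 frequency bins", call. = FALSE)
  zmax <- function(v, what, s) {
    mu <- mean(v)
    sd2 <- sum((v - mu)^2) / (base::length(v) - ddof)
    if (sd2 <= 0) {
      stop("degenerate spectrum: zero-variance ", what, " in segment ", s,
           call. = FALSE)
    }
    max((v - mu) / sqrt(sd2))
  }
  max_abs <- numeric(S)
  max_ang <- numeric(S)
  for (s in seq_len(S)) {
    max_abs[s] <- zmax(Mod(co[s, ]), "magnitudes", s)
    max_ang[s] <- zmax(Arg(co[s, ]), "phase angles", s)
  }
  combined <- c(max_abs, max_ang)
  names(combined) <- c(sprintf("MAX_ABS_%02d", seq_len(S)),
                       sprintf("MAX_ANG_%02d", seq_len(S)))
  structure(list(max_abs = max_abs, max_ang = max_ang, combined = combined),
            class = "stftda_features")
}

#' @export
print.stftda_features <- function(x, ...) {
  cat("STFT-DA features: ", base::length(x$combined), " values (",
      base::length(x$max_abs), " MAX_ABS + ", base::length(x$max_ang),
      " MAX_ANG)\n", sep = "")
  invisible(x)
}

#' Contour signal to feature vector
#'
#' Resamples a contour signal to `resample_n` points and extracts the
#' STFT spectral-maxima features.
#'
#' @param sig A `"contour_signal"` object or numeric radius vector.
#' @param resample_n Resampled signal length, default 1000.
#' @inheritParams stft
#' @inheritParams extract_features
#' @return An `"stftda_features"` object.
#' @export
signal_to_features <- function(sig, resample_n = 1000, window = "gaussian",
                               length = 100, overlap = 40, nfft = NULL,
                               shape_param = NULL, ddof = 1) {
  x <- resample_fft(sig, resample_n)
  sp <- stft(x, window = window, length = length, overlap = overlap,
             nfft = nfft, shape_param = shape_param)
  extract_features(sp, ddof = ddof)
}
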