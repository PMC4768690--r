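# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (no stats::fft for the DFT oracle, no solve()
# for the discriminant oracle).

# Naive windowed DFT: direct evaluation of
#   sum_k w[k] x[s*hop + k] exp(-2 pi i f k / nfft)
# for every segment s and one-sided bin f.
naive_stft <- function(x, w, overlap, nfft) {
  L <- length(w)
  hop <- L - overlap
  S <- (length(x) - overlap) %/% hop
  Fbins <- nfft %/% 2 + 1
  k <- 0:(L - 1)
  E <- exp(-2i * pi * outer(0:(nfft %/% 2), k) / nfft)  # F x L DFT kernel
  out <- matrix(complex(1), S, Fbins)
  for (s in seq_len(S)) {
    seg <- x[((s - 1) * hop + 1):((s - 1) * hop + L)]
    out[s, ] <- as.vector(E %*% (w * seg))
  }
  out
}

# Plain Gaussian elimination with partial pivoting; solves A x = b.
gauss_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (j in seq_len(n)) {
    p <- which.max(abs(M[j:n, j])) + j - 1
    if (p != j) M[c(j, p), ] <- M[c(p, j), ]
    M[j, ] <- M[j, ] / M[j, j]
    for (i in seq_len(n)[-j]) {
      M[i, ] <- M[i, ] - M[i, j] * M[j, ]
    }
  }
  M[, -seq_len(n), drop = FALSE]
}

# Closed-form linear discriminant scores using gauss_solve for the
# covariance systems.
oracle_da_scores <- function(x, means, S, priors) {
  K <- nrow(means)
  a <- gauss_solve(S, t(means))          # d x K, columns S^-1 mu_k
  sc <- matrix(0, nrow(x), K)
  for (k in seq_len(K)) {
    sc[, k] <- x %*% a[, k] - 0.5 * sum(means[k, ] * a[, k]) + log(priors[k])
  }
  sc
}

# Rasterise a disk (optionally radial function) for contour tests without
# going through the package's render_image().
raster_shape <- function(rfun, h, w, cr, cc, fg = 0.9, bg = 0.02) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- sqrt((rows - cr)^2 + (cols - cc)^2)
  th <- atan2(-(rows - cr), cols - cc)
  img <- matrix(bg, h, w)
  img[d < rfun(th)] <- fg
  img
}

# Small, fast three-species configuration reused by several tests.
small_specs <- function(seed = 11, noise = 0.01, orders = c(2, 3, 5),
                        amplitude = 0.15, n_specimens = 20) {
  stats::setNames(lapply(seq_along(orders), function(i) {
    species_shape_spec(base_radius = 70,
                       harmonics = list(c(orders[i], amplitude, 0)),
                       radial_noise_sd = noise, n_specimens = n_specimens,
                       seed = seed + i)
  }), sprintf("k%d", orders))
}

small_config <- function(...) {
  stftda_config(min_area = 5000, ...)
}
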