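#' Specification of a synthetic otolith-like species shape
#'
#' A species is a star-convex closed contour: a base radius modulated by a
#' small number of fixed low-order harmonics (the species signature) plus
#' smooth seeded radial noise (specimen-to-specimen biological variation).
#'
#' @param base_radius Base radius in pixels.
#' @param harmonics List of species harmonics, each `c(order, amplitude,
#'   phase)` with integer order >= 2 and amplitude expressed as a fraction
#'   of the base radius. The amplitudes (plus 3 standard deviations of the
#'   noise) must sum to less than 0.5 so the radius stays positive and the
#'   shape star-convex.
#' @param radial_noise_sd Standard deviation of the smooth radial noise, as
#'   a fraction of the base radius.
#' @param n_specimens Number of distinct specimens the spec can generate.
#' @param seed Integer seed; together with the specimen index it fully
#'   determines each shape.
#' @param label Optional species label.
#' @return Object of class `"species_shape_spec"`.
#' @export
species_shape_spec <- function(base_radius = 150, harmonics = list(),
                               radial_noise_sd = 0.01, n_specimens = 30,
                               seed = 1, label = NULL) {
  if (base_radius <= 0) stop("base_radius must be positive", call. = FALSE)
  for (h in harmonics) {
    if (length(h) != 3L || h[1] < 2 || h[1] != round(h[1]) || h[2] < 0) {
      stop("each harmonic must be c(order >= 2, amplitude >= 0, phase)",
           call. = FALSE)
    }
  }
  amp_sum <- sum(vapply(harmonics, `[`, numeric(1), 2L))
  if (amp_sum + 3 * radial_noise_sd >= 0.5) {
    stop("harmonic amplitudes + 3*noise sd must sum below 0.5 ",
         "(shape must stay star-convex with positive radius)", call. = FALSE)
  }
  structure(
    list(base_radius = base_radius, harmonics = harmonics,
         radial_noise_sd = radial_noise_sd,
         n_specimens = as.integer(n_specimens),
         seed = as.integer(seed), label = label),
    class = "species_shape_spec"
  )
}

#' @export
print.species_shape_spec <- function(x, ...) {
  hh <- if (length(x$harmonics)) {
    paste(vapply(x$harmonics, function(h) {
      sprintf("k=%d a=%.3g phi=%.3g", as.integer(h[1]), h[2], h[3])
    }, character(1)), collapse = "; ")
  } else "none"
  cat("Species shape spec", if (!is.null(x$label)) paste0(" '", x$label, "'"),
      ": R=", x$base_radius, " px, harmonics [", hh, "], noise sd ",
      x$radial_noise_sd, ", ", x$n_specimens, " specimens, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# derive a 31-bit stream seed from (seed, specimen_index)
specimen_seed <- function(seed, specimen_index) {
  as.integer((as.double(seed) * 1000003 + as.double(specimen_index) * 7919 +
                12345) %% 2147483647)
}

#' Generate one specimen's radial function
#'
#' Returns the continuous radial function
#' `r(theta) = R * (1 + sum_k a_k cos(k theta + phi_k) + eps(theta))`
#' where `eps` is smooth seeded noise built from random low-order harmonics
#' (orders 2-13) scaled to standard deviation `radial_noise_sd` over the
#' circle. Deterministic given `(spec$seed, specimen_index)`.
#'
#' @param spec A `"species_shape_spec"`.
#' @param specimen_index Positive integer specimen identifier.
#' @return A vectorised function `r(theta)` returning radii in pixels.
#' @export
generate_shape <- function(spec, specimen_index = 1) {
  if (!inherits(spec, "species_shape_spec")) {
    stop("spec must be a 'species_shape_spec'", call. = FALSE)
  }
  rs <- local_rng(specimen_seed(spec$seed, specimen_index))
  on.exit(restore_rng(rs))
  noise_orders <- 2:13
  b <- stats::rnorm(length(noise_orders))
  psi <- stats::runif(length(noise_orders), 0, 2 * pi)
  if (spec$radial_noise_sd > 0) {
    # sd over theta of sum b_j cos(j theta + psi_j) is sqrt(sum b_j^2 / 2)
    b <- b * spec$radial_noise_sd / sqrt(sum(b^2) / 2)
  } else {
    b <- b * 0
  }
  R <- spec$base_radius
  harmonics <- spec$harmonics
  function(theta) {
    mod <- rep(1, length(theta))
    for (h in harmonics) {
      mod <- mod + h[2] * cos(h[1] * theta + h[3])
    }
    for (j in seq_along(noise_orders)) {
      mod <- mod + b[j] * cos(noise_orders[j] * theta + psi[j])
    }
    R * mod
  }
}

#' Rasterise a radial function onto a grayscale canvas
#'
#' A pixel is set to `fg` iff its centre lies strictly inside the contour
#' (distance to `center` less than `r(theta)` at the pixel's polar angle in
#' the y-up frame); everything else is `bg`.
#'
#' @param r Radial function from [generate_shape()] (or any vectorised
#'   function of angle).
#' @param canvas `(height, width)` in pixels.
#' @param center `(row, col)` of the shape centre; default canvas centre.
#' @param fg,bg Foreground and background intensities; defaults 0.9 / 0.02
#'   sit on opposite sides of the standard 0.1 threshold.
#' @param margin Minimum clearance to the canvas border in pixels.
#' @return Numeric intensity matrix (`canvas[1] x canvas[2]`).
#' @export
render_image <- function(r, canvas = c(512, 512), center = NULL,
                         fg = 0.9, bg = 0.02, margin = 2) {
  h <- canvas[1]; w <- canvas[2]
  if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)
  th <- seq(0, 2 * pi, length.out = 2048L)
  rmax <- max(r(th))
  if (center[1] - rmax < margin || center[1] + rmax > h - margin + 1 ||
      center[2] - rmax < margin || center[2] + rmax > w - margin + 1) {
    stop("shape does not fit inside the canvas with a ", margin,
         "-pixel margin (max radius ", round(rmax, 1), " px)", call. = FALSE)
  }
  rows <- matrix(seq_len(h), nrow = h, ncol = w)
  cols <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
  dy <- -(rows - center[1])   # y-up frame
  dx <- cols - center[2]
  dist <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  img <- matrix(bg, h, w)
  img[dist < r(theta)] <- fg
  img
}

#' Generate a labelled synthetic train/test image set
#'
#' For each species spec, specimens `1..n_train` form the training split and
#' `n_train+1 .. n_train+n_test` the test split (disjoint by construction,
#' deterministic given the specs' seeds). Images are kept in memory; when
#' `dir` is given they are also written as PNG files with a manifest CSV
#' (`image_path, species, split`).
#'
#' @param specs Named list of `"species_shape_spec"` objects (names are the
#'   species labels; an unnamed list uses the specs' `label` fields).
#' @param n_train,n_test Specimens per species in each split.
#' @param canvas,fg,bg Passed to [render_image()].
#' @param dir Optional output directory for PNGs and `manifest.csv`.
#' @return List with `images` (list of intensity matrices) and `manifest`
#'   (data frame: `image_id, species, split, specimen, path`).
#' @export
make_dataset <- function(specs, n_train, n_test, canvas = c(512, 512),
                         fg = 0.9, bg = 0.02, dir = NULL) {
  labels <- names(specs)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(specs, function(s) s$label %||% "", character(1))
  }
  if (any(!nzchar(labels)) || anyDuplicated(labels)) {
    stop("specs must have unique species labels", call. = FALSE)
  }
  for (s in specs) {
    if (n_train + n_test > s$n_specimens) {
      stop("invalid split: n_train + n_test (", n_train + n_test,
           ") exceeds n_specimens (", s$n_specimens, ")", call. = FALSE)
    }
  }
  images <- list()
  rows <- list()
  i <- 0L
  for (si in seq_along(specs)) {
    for (j in seq_len(n_train + n_test)) {
      i <- i + 1L
      rfun <- generate_shape(specs[[si]], j)
      img <- render_image(rfun, canvas = canvas, fg = fg, bg = bg)
      id <- sprintf("%s_%02d", labels[si], j)
      images[[id]] <- img
      rows[[i]] <- data.frame(
        image_id = id, species = labels[si],
        split = if (j <= n_train) "train" else "test",
        specimen = j, path = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(nrow(manifest))) {
      p <- file.path(dir, paste0(manifest$image_id[k], ".png"))
      png::writePNG(images[[manifest$image_id[k]]], p)
      manifest$path[k] <- p
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(images = images, manifest = manifest)
}

#' Run a full synthetic-recovery experiment
#'
#' Generates a synthetic dataset, extracts STFT features from every image,
#' trains the discriminant model on the training split and evaluates it on
#' the test split.
#'
#' @inheritParams make_dataset
#' @param config Pipeline configuration from [stftda_config()].
#' @return List with `model`, `confusion`, `accuracy`, `accuracy_pct`,
#'   `features` (full feature data frame with species and split columns).
#' @export
synthetic_experiment <- function(specs, n_train, n_test,
                                 canvas = c(512, 512),
                                 config = stftda_config()) {
  ds <- make_dataset(specs, n_train, n_test, canvas = canvas)
  feats <- features_from_images(ds$images, config = config)
  df <- cbind(ds$manifest[match(feats$image_id, ds$manifest$image_id),
                          c("species", "split")], feats)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  tr <- df[df$split == "train", ]
  te <- df[df$split == "test", ]
  model <- stftda.default(as.matrix(tr[, fcols]), tr$species,
                          prior = config$prior, ridge = config$ridge)
  ev <- evaluate(model, as.matrix(te[, fcols]), te$species)
  list(model = model, confusion = ev$confusion, accuracy = ev$accuracy,
       accuracy_pct = ev$accuracy_pct, features = df)
}
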