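#' Read a grayscale otolith image
#'
#' Reads a PNG, TIFF or JPEG image and returns a numeric matrix of
#' intensities in `[0, 1]`, rows running down the image and columns across.
#' RGB images are converted to luminance; 8- and 16-bit integer images are
#' rescaled by their type maximum.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return Numeric matrix of intensities in `[0, 1]` (rows x cols).
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) == EBImage::Color) {
    img <- EBImage::channel(img, "luminance")
  }
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) > 2L) {
    dat <- dat[, , 1L]
  }
  # EBImage stores images as [x, y]; transpose to [row, col]
  m <- t(dat)
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

#' Threshold a grayscale image to a binary mask
#'
#' A pixel is foreground when its intensity strictly exceeds `threshold`
#' on the `[0, 1]` scale. Integer-valued matrices are first rescaled by
#' their type maximum (255 or 65535).
#'
#' @param img Numeric matrix of intensities in `[0, 1]` (or an integer
#'   matrix, which is rescaled first).
#' @param threshold Scalar in (0, 1); foreground is `intensity > threshold`.
#'   The default 0.1 accommodates otoliths over a wide range of transparency.
#' @return Logical matrix of the same shape, `TRUE` for foreground.
#' @export
binarize <- function(img, threshold = 0.1) {
  if (!is.matrix(img) || !is.numeric(c(img[1]))) {
    stop("img must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(img))) {
    stop("img contains non-finite intensities", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a scalar in (0, 1)", call. = FALSE)
  }
  if (is.integer(img)) {
    tymax <- if (max(img) > 255L) 65535 else 255
    img <- img / tymax
  }
  if (min(img) < 0 || max(img) > 1) {
    stop("intensities must lie in [0, 1]", call. = FALSE)
  }
  img > threshold
}

# 8-connected component labelling built on EBImage's 4-connected bwlabel:
# labels that touch diagonally are merged with a union-find pass.
label_components <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  nlab <- max(lab)
  if (nlab <= 1L) {
    return(lab)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) {
    return(lab)
  }
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Clean a binary mask for outline extraction
#'
#' Applies, in order: (1) removal of any foreground component touching the
#' image border, (2) filling of background holes fully enclosed by
#' foreground, (3) removal of components with fewer than `min_area` pixels.
#' Components use 8-connectivity. The result may legitimately be empty.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param min_area Minimum component area in pixels; the default 50000
#'   corresponds to otoliths photographed at 6.3x magnification. Lower it
#'   for smaller rasters.
#' @return Logical matrix of the same shape.
#' @export
clean_mask <- function(mask, min_area = 50000) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  mask <- mask != 0
  lab <- label_components(mask)
  nlab <- max(lab)
  if (nlab == 0L) return(mask & FALSE)
  # (1) clear components touching the border
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  if (length(border)) {
    mask[lab %in% border] <- FALSE
  }
  # (2) fill enclosed holes
  mask <- EBImage::imageData(EBImage::fillHull(mask * 1)) > 0
  # (3) drop small components
  lab <- label_components(mask)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    small <- which(areas < min_area)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  mask
}

# Moore-neighbour boundary tracing (8-connectivity). `mask` is logical and
# `start` its first foreground pixel in row-major (row, then col) scan order,
# so the west/north neighbours of `start` are background. Stops when the
# start -> second-pixel transition repeats (Jacob's criterion). Returns an
# n x 2 matrix of (row, col), oriented counterclockwise in a y-up frame.
trace_boundary <- function(mask, start) {
  # clockwise Moore neighbourhood offsets, starting west
  offs <- rbind(
    c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
    c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L)
  )
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- function(p) {
    p[1] >= 1L && p[1] <= nr && p[2] >= 1L && p[2] <= nc && mask[p[1], p[2]]
  }
  pts <- matrix(0L, nrow = 256L, ncol = 2L)
  pts[1L, ] <- start
  n <- 1L
  cur <- start
  bdir <- 1L  # backtrack direction index (entered start from the west)
  second <- NULL
  max_steps <- 8L * sum(mask) + 16L
  steps <- 0L
  repeat {
    cand <- NULL
    for (i in 1:8) {
      d <- ((bdir - 1L + i) %% 8L) + 1L
      p <- cur + offs[d, ]
      if (fg(p)) {
        cand <- p
        # backtrack for the next step: the (background) neighbour examined
        # just before cand, expressed as an offset index from cand
        prevd <- ((d - 2L) %% 8L) + 1L
        rel <- cur + offs[prevd, ] - cand
        bnext <- which(offs[, 1] == rel[1] & offs[, 2] == rel[2])
        break
      }
    }
    if (is.null(cand)) break  # isolated pixel
    if (!is.null(second) && all(cur == start) && all(cand == second)) break
    if (is.null(second)) second <- cand
    n <- n + 1L
    if (n > nrow(pts)) {
      pts <- rbind(pts, matrix(0L, nrow = nrow(pts), ncol = 2L))
    }
    pts[n, ] <- cand
    cur <- cand
    bdir <- bnext
    steps <- steps + 1L
    if (steps > max_steps) break
  }
  if (n > 1L && all(pts[n, ] == start)) n <- n - 1L
  b <- pts[seq_len(n), , drop = FALSE]
  # orient counterclockwise in y-up coordinates (x = col, y = -row)
  if (nrow(b) >= 3L) {
    x <- b[, 2]; y <- -b[, 1]
    area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
    if (area2 < 0) b <- b[c(1L, rev(seq_len(nrow(b))[-1L])), , drop = FALSE]
  }
  b
}

#' Extract the external outline and centre of gravity
#'
#' Traces the external boundary (Moore neighbourhood, 8-connectivity) of the
#' largest foreground component and computes the component's centre of
#' gravity as the mean (row, col) of its pixels. The boundary is oriented
#' counterclockwise in a y-up frame.
#'
#' @param mask Logical (or 0/1) matrix with at least one foreground pixel.
#' @return An object of class `"otolith_outline"`: a list with `boundary`
#'   (n x 2 integer matrix of (row, col)), `centroid` (length-2 numeric,
#'   (row, col)) and `area` (pixel count of the component).
#' @export
extract_outline <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  mask <- mask != 0
  lab <- label_components(mask)
  if (max(lab) == 0L) {
    stop("no foreground object in mask (image failed preprocessing)",
         call. = FALSE)
  }
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which.max(areas)
  comp <- lab == keep
  idx <- which(comp, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  # first foreground pixel in row-major (row, then col) order
  ord <- order(idx[, 1], idx[, 2])
  start <- idx[ord[1L], ]
  boundary <- trace_boundary(comp, as.integer(start))
  structure(
    list(boundary = boundary, centroid = centroid, area = areas[keep]),
    class = "otolith_outline"
  )
}

#' @export
print.otolith_outline <- function(x, ...) {
  cat("Otolith outline: ", nrow(x$boundary), " boundary pixels, area ",
      x$area, " px, centroid (", sprintf("%.2f", x$centroid[1]), ", ",
      sprintf("%.2f", x$centroid[2]), ")\n", sep = "")
  invisible(x)
}

#' Polar radius signal of an outline
#'
#' For every boundary pixel, computes the Euclidean distance to the centre
#' of gravity and the polar angle in a y-up frame (angle 0 along the
#' positive x-axis, counterclockwise, mapped to `[0, 2*pi)`). The sequence
#' starts at the boundary point whose angle is closest to 0 and proceeds
#' counterclockwise.
#'
#' @param outline An `"otolith_outline"` object from [extract_outline()].
#' @param ordering `"traversal"` keeps boundary-trace order (approximately
#'   uniform arc-length spacing, the default); `"angle_sorted"` sorts by
#'   ascending angle (ties broken by traversal order).
#' @return An object of class `"contour_signal"`: list with numeric vectors
#'   `radii` and `angles` of equal length.
#' @export
radius_signal <- function(outline, ordering = c("traversal", "angle_sorted")) {
  ordering <- match.arg(ordering)
  if (!inherits(outline, "otolith_outline")) {
    stop("outline must be an 'otolith_outline' object", call. = FALSE)
  }
  b <- outline$boundary
  dr <- b[, 1] - outline$centroid[1]
  dc <- b[, 2] - outline$centroid[2]
  radii <- sqrt(dr^2 + dc^2)
  if (any(radii == 0)) {
    stop("degenerate shape: centroid coincides with a boundary pixel",
         call. = FALSE)
  }
  # y-up frame: rows increase downward, so y = -dr
  angles <- atan2(-dr, dc) %% (2 * pi)
  if (ordering == "angle_sorted") {
    ord <- order(angles, seq_along(angles))
  } else {
    # rotate the traversal so it starts at the angle closest to 0
    dist0 <- pmin(angles, 2 * pi - angles)
    s <- which.min(dist0)
    n <- length(angles)
    ord <- c(s:n, if (s > 1L) 1:(s - 1L))
  }
  structure(list(radii = radii[ord], angles = angles[ord]),
            class = "contour_signal")
}

#' @export
print.contour_signal <- function(x, ...) {
  cat("Contour signal: ", length(x$radii), " samples, radius range [",
      sprintf("%.1f", min(x$radii)), ", ", sprintf("%.1f", max(x$radii)),
      "] px\n", sep = "")
  invisible(x)
}

#' @export
plot.contour_signal <- function(x, ...) {
  graphics::plot(x$angles, x$radii, type = "p", pch = 16, cex = 0.3,
                 xlab = "angle (rad)", ylab = "radius (px)", ...)
  invisible(x)
}

#' Grayscale image to contour signal
#'
#' Convenience wrapper chaining [binarize()], [clean_mask()],
#' [extract_outline()] and [radius_signal()].
#'
#' @param img Numeric intensity matrix in `[0, 1]`.
#' @param threshold Binarization threshold, see [binarize()].
#' @param min_area Minimum object area in pixels, see [clean_mask()].
#' @param ordering Sample ordering, see [radius_signal()].
#' @return A `"contour_signal"` object.
#' @export
image_to_signal <- function(img, threshold = 0.1, min_area = 50000,
                            ordering = "traversal") {
  mask <- clean_mask(binarize(img, threshold), min_area)
  radius_signal(extract_outline(mask), ordering)
}
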