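#' Read and write gray images
#'
#' Thin wrappers around `EBImage` I/O using the package's row-by-column,
#' 0--255 integer convention. Color files are reduced to grayscale with
#' [to_grayscale()]. Masks are single-channel images where any nonzero pixel
#' counts as inside the region.
#'
#' @param path Image file (PNG, TIFF or JPEG).
#' @return `read_gray_image()`: integer matrix in \[0, 255\];
#'   `read_mask()`: logical matrix.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop_domain("no such image file: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) {
    arr <- aperm(dat[, , 1:min(3, dim(dat)[3]), drop = FALSE] * 255,
                 c(2, 1, 3))
    to_grayscale(round(arr))
  } else {
    m <- t(dat) * 255
    to_grayscale(round(m))
  }
}

#' @rdname read_gray_image
#' @param img Integer gray-image matrix.
#' @export
write_gray_image <- function(img, path) {
  check_gray_image(img)
  EBImage::writeImage(EBImage::Image(t(img) / 255), path)
  invisible(path)
}

#' @rdname read_gray_image
#' @export
read_mask <- function(path) {
  read_gray_image(path) > 0
}

#' Reduce an image to grayscale
#'
#' Three-channel input is reduced by standard luminance weighting
#' (0.299 R + 0.587 G + 0.114 B), rounded to integers; single-channel input
#' passes through unchanged. Constant RGB `(v, v, v)` maps to gray `v` since
#' the weights sum to 1.
#'
#' @param x 2-D matrix or rows-by-cols-by-3 array of intensities in \[0, 255\].
#' @return Integer gray-image matrix.
#' @export
to_grayscale <- function(x) {
  if (is.matrix(x)) {
    return(check_gray_image(structure(as.integer(round(x)), dim = dim(x))))
  }
  if (!is.array(x) || length(dim(x)) != 3 || dim(x)[3] != 3) {
    stop_domain("expected a 2-D matrix or a rows x cols x 3 array")
  }
  g <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  g <- pmin(pmax(round(g), 0), 255)
  check_gray_image(structure(as.integer(g), dim = dim(x)[1:2]))
}

#' Perona-Malik anisotropic diffusion
#'
#' Edge-preserving denoising: each explicit time step moves a pixel toward its
#' four neighbors proportionally to the conductance
#' `exp(-(grad / kappa)^2)`, so diffusion is suppressed across strong edges.
#' Borders are reflecting (Neumann), which conserves total intensity, and the
#' scheme is a contraction in range for `dt <= 0.25`: every intermediate value
#' stays within the input's min--max before the final rounding back to
#' integers.
#'
#' @param img Gray-image matrix.
#' @param iterations Number of diffusion steps (>= 0); 0 returns the input.
#' @param kappa Gray-level edge scale (> 0). Default 30.
#' @param dt Time step in (0, 0.25]. Default 0.2.
#' @return Gray-image matrix of the same shape.
#' @export
anisotropic_diffusion <- function(img, iterations = 10, kappa = 30, dt = 0.2) {
  check_gray_image(img)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0) stop_domain("iterations must be >= 0")
  if (!is.numeric(kappa) || kappa <= 0) stop_domain("kappa must be > 0")
  if (!is.numeric(dt) || dt <= 0 || dt > 0.25) {
    stop_domain("dt must lie in (0, 0.25]")
  }
  if (iterations == 0) return(img)
  u <- img * 1.0
  nr <- nrow(u); nc <- ncol(u)
  for (i in seq_len(iterations)) {
    gn <- rbind(u[1, , drop = FALSE], u[-nr, , drop = FALSE]) - u
    gs <- rbind(u[-1, , drop = FALSE], u[nr, , drop = FALSE]) - u
    gw <- cbind(u[, 1, drop = FALSE], u[, -nc, drop = FALSE]) - u
    ge <- cbind(u[, -1, drop = FALSE], u[, nc, drop = FALSE]) - u
    u <- u + dt * (exp(-(gn / kappa)^2) * gn + exp(-(gs / kappa)^2) * gs +
                   exp(-(gw / kappa)^2) * gw + exp(-(ge / kappa)^2) * ge)
  }
  structure(as.integer(pmin(pmax(round(u), 0), 255)), dim = dim(img))
}

#' Fill boundary-connected white edges with black
#'
#' Sets to zero every pixel at or above `white_threshold` that is connected to
#' the image boundary through a 4-connected path of equally bright pixels —
#' the irregular white frame some scanners leave around a scan. Bright regions
#' strictly interior to the image are untouched.
#'
#' @param img Gray-image matrix.
#' @param white_threshold Gray level in \[1, 255\]; default 250.
#' @return Gray-image matrix of the same shape.
#' @export
fill_white_border <- function(img, white_threshold = 250) {
  check_gray_image(img)
  if (white_threshold < 1 || white_threshold > 255) {
    stop_domain("white_threshold must lie in [1, 255]")
  }
  bright <- img >= white_threshold
  if (!any(bright)) return(img)
  visited <- matrix(FALSE, nrow(img), ncol(img))
  visited[1, ] <- bright[1, ]; visited[nrow(img), ] <- bright[nrow(img), ]
  visited[, 1] <- bright[, 1]; visited[, ncol(img)] <- bright[, ncol(img)]
  repeat {
    grown <- shift_or(visited) & bright
    if (!any(grown & !visited)) break
    visited <- visited | grown
  }
  img[visited] <- 0L
  img
}

# OR of a logical matrix with its four 4-neighbor shifts (zero padded).
shift_or <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, , drop = FALSE]
  out[-nr, ] <- out[-nr, ] | m[-1, , drop = FALSE]
  out[, -1] <- out[, -1] | m[, -nc, drop = FALSE]
  out[, -nc] <- out[, -nc] | m[, -1, drop = FALSE]
  out
}

# Orientation (degrees, in (-90, 90]) of the maximum Feret diameter of a
# logical mask: the farthest pair of mask points, found on the convex hull.
feret_angle <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) stop_domain("mask is empty")
  if (nrow(pts) == 1) return(0)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[hull, , drop = FALSE]
  d <- as.matrix(stats::dist(hp))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  dy <- hp[ij[2], 1] - hp[ij[1], 1]   # rows
  dx <- hp[ij[2], 2] - hp[ij[1], 2]   # cols
  ang <- atan2(dy, dx) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Rotate so the region's longest diameter is horizontal
#'
#' Computes the orientation of the mask's maximum Feret diameter (the farthest
#' pair of boundary points) and rotates image and mask by its negative, so the
#' longest diameter ends up horizontal. The image is interpolated bilinearly;
#' the mask uses nearest-neighbor so it stays binary. The canvas expands to
#' hold the rotated content, padded with zeros.
#'
#' @param img Gray-image matrix.
#' @param mask Logical matrix, same shape as `img`, with at least one `TRUE`.
#' @return List with `image`, `mask` and the applied `angle` (degrees).
#' @export
rotate_longest_diameter_horizontal <- function(img, mask) {
  check_gray_image(img)
  if (!is.logical(mask) || !identical(dim(mask), dim(img))) {
    stop_domain("mask must be a logical matrix with the image's shape")
  }
  if (!any(mask)) stop_domain("mask is empty")
  ang <- feret_angle(mask)
  if (abs(ang) < 1e-9) {
    return(list(image = img, mask = mask, angle = 0))
  }
  ie <- EBImage::rotate(EBImage::Image(t(img) / 255), -ang,
                        filter = "bilinear", bg.col = 0)
  me <- EBImage::rotate(EBImage::Image(t(mask) * 1), -ang,
                        filter = "none", bg.col = 0)
  out_img <- structure(
    as.integer(pmin(pmax(round(t(EBImage::imageData(ie)) * 255), 0), 255)),
    dim = rev(dim(EBImage::imageData(ie)))
  )
  out_mask <- t(EBImage::imageData(me)) > 0.5
  list(image = out_img, mask = out_mask, angle = -ang)
}
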