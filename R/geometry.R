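# Rotation geometry. Convention: 0-based pixel coordinates, x = column,
# y = row, origin top-left, y increasing downward. The hair axis at angle
# theta = atan2(dy, dx) is brought to the horizontal by rotating the frame
# by -theta about the image centre; the canvas is enlarged to hold the full
# rotated footprint and the out-of-frame fill value is 0.

# snap near-quarter-turn angles so those paths are bit-exact
snap_angle <- function(theta) {
  k <- round(theta / (pi / 2))
  if (abs(theta - k * pi / 2) < 1e-9) k * pi / 2 else theta
}

rotation_map <- function(dims, theta) {
  H <- dims[1L]; W <- dims[2L]
  theta <- snap_angle(theta)
  quarter <- (theta %% (pi / 2)) == 0
  cth <- if (quarter) round(cos(theta)) else cos(theta)
  sth <- if (quarter) round(sin(theta)) else sin(theta)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  fwd0 <- function(x, y) {
    list(x = cth * (x - cx) + sth * (y - cy),
         y = -sth * (x - cx) + cth * (y - cy))
  }
  corners <- fwd0(c(0, W - 1, 0, W - 1), c(0, 0, H - 1, H - 1))
  tx <- -min(corners$x); ty <- -min(corners$y)
  out_w <- as.integer(ceiling(max(corners$x) - min(corners$x) - 1e-9)) + 1L
  out_h <- as.integer(ceiling(max(corners$y) - min(corners$y) - 1e-9)) + 1L
  list(
    theta = theta, quarter = quarter, cth = cth, sth = sth,
    cx = cx, cy = cy, tx = tx, ty = ty, dims_out = c(out_h, out_w),
    forward = function(x, y) {
      p <- fwd0(x, y)
      list(x = p$x + tx, y = p$y + ty)
    },
    inverse = function(x, y) {
      list(x = cth * (x - tx) - sth * (y - ty) + cx,
           y = sth * (x - tx) + cth * (y - ty) + cy)
    }
  )
}

sample_at <- function(pixels, x, y) {
  H <- nrow(pixels); W <- ncol(pixels)
  v <- numeric(length(x))
  ok <- x >= 0 & x <= W - 1 & y >= 0 & y <= H - 1
  v[ok] <- pixels[cbind(y[ok] + 1L, x[ok] + 1L)]
  v
}

rotate_pixels <- function(pixels, theta) {
  m <- rotation_map(dim(pixels), theta)
  if (m$theta == 0) return(pixels)
  out_h <- m$dims_out[1L]; out_w <- m$dims_out[2L]
  qx <- matrix(rep(0:(out_w - 1L), each = out_h), nrow = out_h)
  qy <- matrix(rep(0:(out_h - 1L), times = out_w), nrow = out_h)
  p <- m$inverse(as.vector(qx), as.vector(qy))
  if (m$quarter) {
    # exact index permutation: inverse map lands on integers
    v <- sample_at(pixels, round(p$x), round(p$y))
  } else {
    x0 <- floor(p$x); y0 <- floor(p$y)
    fx <- p$x - x0; fy <- p$y - y0
    v <- (1 - fx) * (1 - fy) * sample_at(pixels, x0, y0) +
      fx * (1 - fy) * sample_at(pixels, x0 + 1, y0) +
      (1 - fx) * fy * sample_at(pixels, x0, y0 + 1) +
      fx * fy * sample_at(pixels, x0 + 1, y0 + 1)
    v <- pmin(pmax(v, 0), 255)
  }
  matrix(v, nrow = out_h, ncol = out_w)
}

#' Rotate an image so the hair axis is horizontal
#'
#' Rotates by minus the axis angle `atan2(dy, dx)` about the image centre.
#' The canvas is enlarged to contain the whole rotated frame; pixels falling
#' outside the original footprint are 0. Resampling is bilinear (clamped to
#' \[0, 255\]) except at quarter-turn angles, where the rotation is an exact
#' index permutation, and at angle 0, where the input is returned unchanged.
#'
#' @param img a [gray_image()].
#' @param axis an axis [line_annotation()].
#' @return A [gray_image()] in the rotated frame.
#' @seealso [map_to_rotated()] to carry point coordinates into the same frame.
#' @export
rotate_to_axis <- function(img, axis) {
  d <- axis$p2 - axis$p1
  theta <- atan2(d[2], d[1])
  gray_image(rotate_pixels(img$pixels, theta),
             magnification = img$magnification, id = img$id)
}

#' Map image coordinates into the rotated frame
#'
#' Applies to arbitrary points exactly the coordinate transform that
#' [rotate_to_axis()] applies to the pixel grid, so annotations drawn in the
#' original frame can be re-expressed in the rotated frame.
#'
#' @param img the *unrotated* [gray_image()] (its dimensions fix the canvas).
#' @param axis the axis [line_annotation()] given to [rotate_to_axis()].
#' @param pts numeric n x 2 matrix of 0-based `(x, y)` coordinates.
#' @return An n x 2 matrix of coordinates in the rotated frame.
#' @export
map_to_rotated <- function(img, axis, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  d <- axis$p2 - axis$p1
  m <- rotation_map(dim(img$pixels), atan2(d[2], d[1]))
  q <- m$forward(pts[, 1L], pts[, 2L])
  cbind(x = q$x, y = q$y)
}

#' Region of interest of a rotated hair segment
#'
#' Given the diagonal line spanning the segment's bounding corners in the
#' rotated image, the ROI is the centred rectangle covering 3/4 of the
#' segment extent in each direction — hence 9/16 (56%) of the bounding-box
#' area — which excludes the abnormally bright bands along the segment edges.
#' With `xmin, xmax, ymin, ymax` the coordinate extremes of the diagonal:
#' origin `(floor((7*xmin + xmax)/8), floor((7*ymin + ymax)/8))`,
#' length `l = floor(3/4 * (xmax - xmin))`, width `w = floor(3/4 * (ymax - ymin))`.
#' Fractional bounds are floored for determinism.
#'
#' @param img the rotated [gray_image()].
#' @param diagonal a diagonal [line_annotation()] in the rotated frame; its
#'   endpoints must differ in both coordinates.
#' @return An object of class `roi`: list with `origin` (0-based `(x, y)`),
#'   `length`, `width` and the `width x length` pixel matrix.
#' @export
define_roi <- function(img, diagonal) {
  xs <- c(diagonal$p1[1], diagonal$p2[1])
  ys <- c(diagonal$p1[2], diagonal$p2[2])
  if (xs[1] == xs[2] || ys[1] == ys[2]) {
    stop("degenerate diagonal: endpoints must differ in both x and y", call. = FALSE)
  }
  xmin <- min(xs); xmax <- max(xs); ymin <- min(ys); ymax <- max(ys)
  xlh <- floor((7 * xmin + xmax) / 8)
  ylh <- floor((7 * ymin + ymax) / 8)
  l <- floor(3 / 4 * (xmax - xmin))
  w <- floor(3 / 4 * (ymax - ymin))
  if (l < 2 || w < 2) stop("diagonal too short: ROI smaller than 2 x 2", call. = FALSE)
  H <- nrow(img$pixels); W <- ncol(img$pixels)
  x0 <- xlh; y0 <- ylh; x1 <- xlh + l - 1; y1 <- ylh + w - 1
  if (x0 < 0 || y0 < 0 || x1 > W - 1 || y1 > H - 1) {
    warning("ROI exceeds image bounds; clipping", call. = FALSE)
    x0 <- max(x0, 0); y0 <- max(y0, 0)
    x1 <- min(x1, W - 1); y1 <- min(y1, H - 1)
    l <- x1 - x0 + 1; w <- y1 - y0 + 1
  }
  structure(
    list(origin = c(x = x0, y = y0), length = l, width = w,
         pixels = img$pixels[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]),
    class = "roi"
  )
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> origin (%g, %g), length %d x width %d px\n",
              x$origin[1], x$origin[2], x$length, x$width))
  invisible(x)
}

roi_pixels <- function(x) {
  if (inherits(x, c("roi", "normalized_roi"))) x$pixels
  else if (inherits(x, "gray_image")) x$pixels
  else if (is.matrix(x)) x
  else stop("expected an roi, normalized_roi, gray_image or matrix", call. = FALSE)
}
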