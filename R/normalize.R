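# Row-wise brightness normalization. A "row" is the direction along the hair
# length: in the rotated ROI, row j is the horizontal line of l pixels at
# vertical position j. Normalization (i) rescales each row so its mean is the
# dark-grey centring value 109 — undamaged cuticle occupies most of a segment,
# so its brightness is pinned between images — and (ii) min-max rescales the
# upper half of each row so the row maximum reaches 255, preserving ratios
# below the centre. 109 is 43% of the 8-bit maximum; the rescale span
# 146 = 255 - 109.

#' Centre each row's mean brightness
#'
#' Multiplies every pixel of row j by `center / mean(row j)`, so each row mean
#' becomes exactly `center` in real arithmetic. This removes the brightness
#' gradient across the width of the tube-shaped segment.
#'
#' @param roi an `roi` (or brightness matrix, rows = across-width position j,
#'   columns = along-length position i).
#' @param center target row mean, default 109.
#' @return Numeric matrix of row-normalized brightness (not yet rescaled).
#' @export
normalize_rows <- function(roi, center = 109) {
  px <- roi_pixels(roi)
  mu <- rowMeans(px)
  bad <- which(mu <= 0)
  if (length(bad)) {
    stop("cannot normalize: row(s) with non-positive mean brightness: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  px * (center / mu)
}

#' Min-max rescale the upper half of each row
#'
#' For each row with maximum `M > center + tol`, pixels above `center` map to
#' `(max_brightness - center) * (p - center) / (M - center) + center`, so the
#' row maximum becomes `max_brightness`; pixels at or below `center` are
#' unchanged. Rows whose maximum is within `tol` of `center` are left alone —
#' a near-degenerate denominator would only amplify noise.
#'
#' @param grid matrix produced by [normalize_rows()].
#' @param center centring value, default 109.
#' @param max_brightness full scale, default 255.
#' @param tol degenerate-row tolerance in brightness units, default 1.
#' @return An object of class `normalized_roi`: list with real-valued `pixels`
#'   (quantization to 8-bit happens only on export / histogram binning),
#'   `center_value` and `span = max_brightness - center`.
#' @export
rescale_rows <- function(grid, center = 109, max_brightness = 255, tol = 1) {
  px <- roi_pixels(grid)
  M <- apply(px, 1L, max)
  span <- max_brightness - center
  for (j in which(M > center + tol)) {
    row <- px[j, ]
    hi <- row > center
    row[hi] <- span * (row[hi] - center) / (M[j] - center) + center
    px[j, ] <- row
  }
  structure(
    list(pixels = px, center_value = center, span = span),
    class = "normalized_roi"
  )
}

#' Normalize an ROI (row centring + upper-half rescale)
#'
#' Composition of [normalize_rows()] and [rescale_rows()], recording per-row
#' means and maxima in a provenance table.
#'
#' @inheritParams normalize_rows
#' @inheritParams rescale_rows
#' @param intermediate_rounding if `TRUE`, quantize to 8-bit integers between
#'   the two stages (off by default: real values are carried through to avoid
#'   double-rounding artefacts).
#' @return A `normalized_roi` with attribute `provenance`, a data frame with
#'   columns `row`, `mean_raw`, `mean_norm`, `max_norm`.
#' @export
normalize <- function(roi, center = 109, max_brightness = 255, tol = 1,
                      intermediate_rounding = FALSE) {
  px <- roi_pixels(roi)
  grid <- normalize_rows(px, center = center)
  if (intermediate_rounding) grid <- quantize8(grid)
  out <- rescale_rows(grid, center = center, max_brightness = max_brightness, tol = tol)
  attr(out, "provenance") <- data.frame(
    row = seq_len(nrow(px)),
    mean_raw = rowMeans(px),
    mean_norm = rowMeans(grid),
    max_norm = apply(out$pixels, 1L, max)
  )
  out
}

#' @export
print.normalized_roi <- function(x, ...) {
  cat(sprintf("<normalized_roi> %d x %d px, centre %g, span %g\n",
              nrow(x$pixels), ncol(x$pixels), x$center_value, x$span))
  invisible(x)
}
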