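# Pixel-brightness damage metrics on a normalized ROI: mean brightness,
# polyline roughness of along-length brightness profiles, and the tailing
# factor of the pixel-brightness histogram. Damage features (lifted or torn
# cuticle scales, holes, debris) are brighter than the dark-grey undamaged
# surface, so they add mass to the right tail of the histogram; the tailing
# factor — full width over twice the leading half-width at a small fraction f
# of the peak height, as in chromatographic peak-shape analysis — scores that
# asymmetry (1 = symmetric peak, > 1 = right-tailed).

#' Mean ROI brightness
#'
#' @param roi a `normalized_roi`, `roi` or brightness matrix.
#' @return Scalar mean of all pixel values.
#' @export
mean_brightness <- function(roi) {
  mean(roi_pixels(roi))
}

#' Average image roughness of brightness profiles
#'
#' Each row (along-length brightness profile) is divided into `n` sections of
#' width `s = floor(l/n)` pixels; brightness is sampled at single pixels
#' `1, s+1, 2s+1, ...` and at the row end `l`. Row roughness is the polyline
#' arc length `sum(sqrt(dI^2 + run^2))` over consecutive samples — the
#' distance formula applied to the brightness profile — divided by `l`, and
#' the image roughness `r_bar` is the mean over rows. A perfectly flat
#' profile has roughness exactly 1.
#'
#' @param roi a `normalized_roi`, `roi` or brightness matrix (rows = profiles).
#' @param n requested section count, `1 <= n <= l`; default 100.
#' @param rule how many sections to realize when `s` does not divide `l`:
#'   `"cover"` (default) uses `n_actual = ceiling(l/s)` full sections plus a
#'   final partial run ending at `l`; `"exact-n"` keeps exactly `n` sections
#'   and lets the final run `l - s*(n-1)` absorb the remainder.
#' @return An object of class `roughness_result`: list with `n`, `s`,
#'   `n_actual` and `r_bar` (dimensionless, `>= 1`).
#' @export
roughness <- function(roi, n = 100, rule = c("cover", "exact-n")) {
  rule <- match.arg(rule)
  px <- roi_pixels(roi)
  l <- ncol(px)
  if (n < 1 || n > l) stop("`n` must satisfy 1 <= n <= ROI length", call. = FALSE)
  s <- floor(l / n)
  n_actual <- if (rule == "cover") {
    if (l %% s == 0) l %/% s else ceiling(l / s)
  } else {
    n
  }
  pos <- s * (0:(n_actual - 1L)) + 1L   # sampled pixel positions, 1-based
  samp <- px[, pos, drop = FALSE]
  total <- numeric(nrow(px))
  if (n_actual > 1L) {
    dI <- samp[, -1L, drop = FALSE] - samp[, -n_actual, drop = FALSE]
    total <- rowSums(sqrt(dI^2 + s^2))
  }
  last_run <- l - s * (n_actual - 1L)
  total <- total + sqrt((px[, l] - samp[, n_actual])^2 + last_run^2)
  structure(
    list(n = n, s = s, n_actual = n_actual, r_bar = mean(total / l)),
    class = "roughness_result"
  )
}

#' Pixel-brightness histogram of an ROI
#'
#' Pixels are quantized round-half-up to integers and counted over the 256
#' unit bins 0-255. The apex is the lowest brightness attaining the maximum
#' count (undamaged dark-grey mass dominates; a tie is reported).
#'
#' @param roi a `normalized_roi`, `roi` or brightness matrix.
#' @return An object of class `brightness_histogram`: list with `counts`
#'   (length 256, bin i+1 = brightness i), peak height `H`, apex brightness
#'   `I_H`, and `total = l*w`.
#' @export
build_histogram <- function(roi) {
  px <- roi_pixels(roi)
  q <- quantize8(px)
  counts <- tabulate(as.integer(q) + 1L, nbins = 256L)
  H <- max(counts)
  modes <- which(counts == H) - 1L
  if (length(modes) > 1L) {
    message("histogram has ", length(modes),
            " modes; apex taken at the lowest brightness (", modes[1L], ")")
  }
  structure(
    list(counts = counts, H = H, I_H = modes[1L], total = sum(counts)),
    class = "brightness_histogram"
  )
}

# Crossing of the count profile with `level`, scanning outward from the apex.
# Returns the (possibly fractional) brightness where counts first fall below
# `level`, linearly interpolated between the bracketing integer bins; clamps
# to 0/255 with a warning when the profile never falls below `level`.
histogram_crossing <- function(counts, apex, level, side = c("lead", "lag")) {
  side <- match.arg(side)
  c_at <- function(i) counts[i + 1L]
  step <- if (side == "lead") -1L else 1L
  bound <- if (side == "lead") 0L else 255L
  i <- apex
  while (i != bound && c_at(i + step) >= level) i <- i + step
  if (i == bound) {
    warning("histogram never falls below ", signif(level, 4), " on the ",
            side, " side; crossing clamped to ", bound, call. = FALSE)
    return(as.numeric(bound))
  }
  inner <- i           # count >= level
  outer <- i + step    # first count < level
  frac <- (c_at(inner) - level) / (c_at(inner) - c_at(outer))
  inner + step * frac
}

#' Redefine the histogram peak apex within the FWHM window
#'
#' To remove skew from secondary peaks, the apex is re-estimated as the
#' count-weighted mean brightness over the integer bins inside the full width
#' at half maximum. If that mean `I_Hbar` is within 3 brightness units of the
#' mode `I_H`, the mode is kept (`I_h = I_H`); otherwise the weighted mean is
#' adopted (`I_h = I_Hbar`).
#'
#' @param h a [build_histogram()] result.
#' @return List with `I_Hbar`, `I_h`, and the half-height crossings
#'   `I_lead_halfH`, `I_lag_halfH`.
#' @export
apex_brightness <- function(h) {
  if (h$H <= 0) stop("empty histogram: peak height is zero", call. = FALSE)
  level <- h$H / 2
  lead <- histogram_crossing(h$counts, h$I_H, level, "lead")
  lag <- histogram_crossing(h$counts, h$I_H, level, "lag")
  bins <- ceiling(lead):floor(lag)
  cts <- h$counts[bins + 1L]
  I_Hbar <- sum(bins * cts) / sum(cts)
  I_h <- if (abs(I_Hbar - h$I_H) <= 3) h$I_H else I_Hbar
  list(I_Hbar = I_Hbar, I_h = I_h, I_lead_halfH = lead, I_lag_halfH = lag)
}

#' Tailing factor of a pixel-brightness histogram
#'
#' With `I_lead_fH` and `I_lag_fH` the leading and lagging crossings of the
#' count profile at the fraction `f` of the peak height, and `I_h` the
#' (possibly redefined) apex brightness from [apex_brightness()]:
#' \deqn{t_f = (I_{lag,fH} - I_{lead,fH}) / (2 (I_h - I_{lead,fH}))}
#' A symmetric histogram gives exactly 1; bright-tailed histograms give more.
#' The default `f = 0.02` (2% of peak height) maximizes correlation with the
#' ordinal SEM damage grade; chromatography conventionally uses 5%.
#'
#' @param h a [build_histogram()] result.
#' @param f fraction of peak height, `0 < f < 0.5`; default 0.02.
#' @return An object of class `tailing_result`: list with `f`, crossings at
#'   `f*H` and `0.5*H`, `I_Hbar`, `I_h` and the tailing factor `t_f`.
#' @export
tailing_factor <- function(h, f = 0.02) {
  if (f <= 0 || f >= 0.5) stop("`f` must lie in (0, 0.5)", call. = FALSE)
  apex <- apex_brightness(h)
  level <- f * h$H
  lead <- histogram_crossing(h$counts, h$I_H, level, "lead")
  lag <- histogram_crossing(h$counts, h$I_H, level, "lag")
  denom <- 2 * (apex$I_h - lead)
  if (denom <= 0) {
    stop("degenerate peak: apex does not exceed the leading crossing", call. = FALSE)
  }
  structure(
    list(f = f, I_lead_fH = lead, I_lag_fH = lag,
         I_lead_halfH = apex$I_lead_halfH, I_lag_halfH = apex$I_lag_halfH,
         I_Hbar = apex$I_Hbar, I_h = apex$I_h,
         t_f = (lag - lead) / denom),
    class = "tailing_result"
  )
}

#' @export
print.tailing_result <- function(x, ...) {
  cat(sprintf("<tailing_result> t_f = %.4f at f = %g (apex %g, crossings %.2f / %.2f)\n",
              x$t_f, x$f, x$I_h, x$I_lead_fH, x$I_lag_fH))
  invisible(x)
}

#' Score a single micrograph end to end
#'
#' Runs the full pipeline: rotate to the axis, carve the ROI from the
#' diagonal (drawn in the rotated frame), normalize, and compute all three
#' metrics. Deterministic for fixed inputs.
#'
#' @param img a [gray_image()].
#' @param axis axis [line_annotation()] in the original frame.
#' @param diagonal diagonal [line_annotation()] in the rotated frame.
#' @param center row-centring value, default 109.
#' @param f tailing-factor peak-height fraction, default 0.02.
#' @param n roughness section count, default 100.
#' @return One-row data frame: `image_id`, `magnification`, `mean_brightness`,
#'   `roughness`, `tailing_factor`, `f`, `n_sections`.
#' @export
score_image <- function(img, axis, diagonal, center = 109, f = 0.02, n = 100) {
  rot <- rotate_to_axis(img, axis)
  roi <- define_roi(rot, diagonal)
  nroi <- normalize(roi, center = center)
  r <- roughness(nroi, n = min(n, roi$length))
  tf <- tailing_factor(build_histogram(nroi), f = f)
  data.frame(
    image_id = img$id,
    magnification = img$magnification,
    mean_brightness = mean_brightness(nroi),
    roughness = r$r_bar,
    tailing_factor = tf$t_f,
    f = f,
    n_sections = r$n,
    stringsAsFactors = FALSE
  )
}

#' Score a set of micrographs
#'
#' @param images list of [gray_image()].
#' @param annotations named list as from [read_annotations()], keyed by image
#'   id, each with `axis` and `diagonal`.
#' @param ... passed to [score_image()].
#' @return Data frame with one row per image, as in [score_image()].
#' @export
score_images <- function(images, annotations, ...) {
  rows <- lapply(images, function(img) {
    a <- annotations[[img$id]]
    if (is.null(a)) stop("no annotations for image '", img$id, "'", call. = FALSE)
    score_image(img, a$axis, a$diagonal, ...)
  })
  do.call(rbind, rows)
}
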