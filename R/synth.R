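# Synthetic SEM-like micrographs of single hair segments. The generator
# renders the brightness statistics the pipeline consumes — a dark-grey
# tube with a gradient across its width, bright edge bands, overlapping
# cuticle scale edges, and bright damage features — with simple parametric
# shapes (Gaussian blobs for lifted cuticle, annuli for holes, near-white
# specks for debris). No electron-optics modelling is attempted: shape
# realism is irrelevant to histogram- and profile-based metrics.

#' Damage-grade thresholds on the damage-area fraction
#'
#' Config constants mapping the fraction of tube-interior area covered by
#' bright damage features to an ordinal grade. They exist to give synthetic
#' cohorts a meaningful ground truth, not to reproduce any visual grading
#' criteria.
#'
#' @return Named numeric vector of upper fraction bounds for Scu 1-3 (Scu 4
#'   is everything above).
#' @export
damage_grade_thresholds <- function() {
  c("Scu 1" = 0.004, "Scu 2" = 0.015, "Scu 3" = 0.05)
}

# smooth unit-variance random field: bilinear upsampling of a coarse
# standard-normal grid with correlation length `scale` pixels
smooth_noise <- function(H, W, scale = 8) {
  hc <- ceiling(H / scale) + 2L
  wc <- ceiling(W / scale) + 2L
  g <- matrix(stats::rnorm(hc * wc), hc, wc)
  yi <- (0:(H - 1)) / scale + 1
  xi <- (0:(W - 1)) / scale + 1
  y0 <- floor(yi); x0 <- floor(xi)
  fy <- yi - y0; fx <- xi - x0
  tex <- outer(1 - fy, 1 - fx) * g[y0, x0] +
    outer(1 - fy, fx) * g[y0, x0 + 1] +
    outer(fy, 1 - fx) * g[y0 + 1, x0] +
    outer(fy, fx) * g[y0 + 1, x0 + 1]
  tex / stats::sd(tex)
}

grade_from_fraction <- function(fraction) {
  th <- damage_grade_thresholds()
  if (fraction < th[1L]) "Scu 1"
  else if (fraction < th[2L]) "Scu 2"
  else if (fraction < th[3L]) "Scu 3"
  else "Scu 4"
}

#' Specification of a synthetic hair-segment micrograph
#'
#' @param height,width canvas size in pixels (default 480 x 640, a typical
#'   SEM export aspect).
#' @param angle tube axis angle in degrees (0 = horizontal).
#' @param tube_width_frac tube width as a fraction of the smaller canvas
#'   dimension, default 0.6.
#' @param base_brightness in-tube dark-grey level, default 109.
#' @param background_brightness off-tube level, default 30.
#' @param gradient_amplitude amplitude of the linear across-width brightness
#'   gradient, default 25.
#' @param edge_band_frac fraction of the tube half-width beyond which the
#'   bright edge band starts, default 0.82.
#' @param edge_boost brightness boost inside the edge band, default 80.
#' @param scale_edge_density cuticle scale edges per 100 px of tube length,
#'   default 1.5.
#' @param n_clusters,n_rings,n_specks counts of bright clusters (lifted
#'   cuticle), concentric rings (holes) and near-white specks (debris).
#' @param texture_sd standard deviation of the smooth cuticle-texture field
#'   inside the tube, default 12 (real cuticle topography gives undamaged
#'   regions a broad brightness distribution, not a pixel-noise spike).
#' @param texture_scale correlation length of the texture field in pixels,
#'   default 8.
#' @param noise_sd additive Gaussian pixel noise standard deviation, default 4.
#' @param magnification magnification recorded on the image, default 2000.
#' @param seed integer seed; the fixture is a deterministic function of it.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(height = 480, width = 640, angle = 0,
                         tube_width_frac = 0.6, base_brightness = 109,
                         background_brightness = 30, gradient_amplitude = 25,
                         edge_band_frac = 0.82, edge_boost = 80,
                         scale_edge_density = 1.5,
                         n_clusters = 0, n_rings = 0, n_specks = 0,
                         texture_sd = 12, texture_scale = 8,
                         noise_sd = 4, magnification = 2000, seed = 1) {
  if (min(n_clusters, n_rings, n_specks, scale_edge_density, noise_sd) < 0) {
    stop("densities and noise sd must be non-negative", call. = FALSE)
  }
  structure(as.list(environment()), class = "fixture_spec")
}

#' Render a synthetic micrograph with annotations and ground truth
#'
#' Renders the fixture described by `spec` and returns the image together
#' with the two line annotations the pipeline needs — the axis along the tube
#' (original frame) and the diagonal spanning the segment corners, expressed
#' in the rotated frame exactly as [rotate_to_axis()]/[map_to_rotated()]
#' produce it — plus the damage-area fraction and the grade it implies under
#' [damage_grade_thresholds()]. Bit-exact for a fixed seed.
#'
#' @param spec a [fixture_spec()].
#' @return List with `image` ([gray_image()]), `axis`, `diagonal`
#'   ([line_annotation()]), `grade`, `damage_fraction`, and `masks` (logical
#'   H x W matrices `tube` and `edge_band` in the original frame).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, render_fixture(spec))
}

render_fixture <- function(spec) {
  H <- spec$height; W <- spec$width
  th <- spec$angle * pi / 180
  cth <- cos(th); sth <- sin(th)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  X <- matrix(rep(0:(W - 1L), each = H), nrow = H)
  Y <- matrix(rep(0:(H - 1L), times = W), nrow = H)
  U <- (X - cx) * cth + (Y - cy) * sth     # along-axis coordinate
  V <- -(X - cx) * sth + (Y - cy) * cth    # across-width coordinate
  hw <- spec$tube_width_frac * min(H, W) / 2
  half_w <- (W - 1) / 2 - 2; half_h <- (H - 1) / 2 - 2
  a <- min(
    if (abs(cth) > 1e-9) (half_w - hw * abs(sth)) / abs(cth) else Inf,
    if (abs(sth) > 1e-9) (half_h - hw * abs(cth)) / abs(sth) else Inf
  )
  if (!is.finite(a) || a <= hw) {
    stop("tube does not fit the canvas at this angle/width", call. = FALSE)
  }
  tube <- abs(U) <= a & abs(V) <= hw
  edge_band <- tube & abs(V) > spec$edge_band_frac * hw

  img <- matrix(spec$background_brightness, H, W)
  img[tube] <- spec$base_brightness + spec$gradient_amplitude * (V[tube] / hw)
  if (spec$texture_sd > 0) {
    tex <- smooth_noise(H, W, spec$texture_scale)
    img[tube] <- img[tube] + spec$texture_sd * tex[tube]
  }
  img[edge_band] <- img[edge_band] + spec$edge_boost

  # overlapping cuticle scale edges: bright curved lines across the tube.
  # Real scale edges are genuinely bright (SEM edge effect); rows need such
  # structure so the upper-half min-max rescale is not dominated by noise.
  n_edges <- round(spec$scale_edge_density * (2 * a) / 100)
  if (n_edges > 0) {
    u_k <- stats::runif(n_edges, -a, a)
    amp_k <- stats::runif(n_edges, 50, 90)
    for (e in seq_len(n_edges)) {
      band <- tube & abs(U - (u_k[e] + 0.15 * V^2 / hw)) < 1
      img[band] <- img[band] + amp_k[e]
    }
  }

  # damage features; placed away from the edge bands so they land in the ROI.
  # Lifted/torn cuticle patches are contiguous regions of roughly uniform
  # light-grey-to-white brightness, so clusters are rendered as flat-top
  # plateaus with a narrow soft skirt rather than smooth Gaussians.
  bright <- matrix(0, H, W)
  place <- function() c(stats::runif(1, -0.85 * a, 0.85 * a),
                        stats::runif(1, -0.65 * hw, 0.65 * hw))
  for (i in seq_len(spec$n_clusters)) {
    p <- place(); rc <- stats::runif(1, 4, 10); amp <- stats::runif(1, 60, 110)
    d <- sqrt((U - p[1])^2 + (V - p[2])^2)
    bright <- bright + amp * exp(-pmax(d - rc, 0)^2 / (2 * 3^2))
  }
  dark <- matrix(0, H, W)
  for (i in seq_len(spec$n_rings)) {
    p <- place(); rr <- stats::runif(1, 4, 9)
    d <- sqrt((U - p[1])^2 + (V - p[2])^2)
    bright <- bright + 70 * (abs(d - rr) < 1.5)
    dark <- dark + 30 * (d < rr - 1.5)
  }
  for (i in seq_len(spec$n_specks)) {
    p <- place(); amp <- stats::runif(1, 120, 160)
    d2 <- (U - p[1])^2 + (V - p[2])^2
    bright <- bright + amp * (d2 < 3)
  }
  img <- img + bright - dark
  if (spec$noise_sd > 0) img <- img + stats::rnorm(H * W, sd = spec$noise_sd)
  px <- quantize8(img)

  interior <- abs(V) <= 0.75 * hw & abs(U) <= 0.75 * a
  damage_fraction <- sum(bright > 20 & interior) / sum(interior)

  id <- sprintf("synth-%d", spec$seed)
  image <- gray_image(px, magnification = spec$magnification, id = id)
  dir <- c(cth, sth)
  axis <- line_annotation(round(c(cx, cy) - 0.9 * a * dir),
                          round(c(cx, cy) + 0.9 * a * dir), "axis")
  perp <- c(-sth, cth)
  corners <- rbind(
    c(cx, cy) - a * dir - hw * perp, c(cx, cy) + a * dir - hw * perp,
    c(cx, cy) - a * dir + hw * perp, c(cx, cy) + a * dir + hw * perp
  )
  rc <- map_to_rotated(image, axis, corners)
  diagonal <- line_annotation(
    c(ceiling(min(rc[, 1])) + 1, ceiling(min(rc[, 2])) + 1),
    c(floor(max(rc[, 1])) - 1, floor(max(rc[, 2])) - 1), "diagonal"
  )
  list(image = image, axis = axis, diagonal = diagonal,
       grade = grade_from_fraction(damage_fraction),
       damage_fraction = damage_fraction,
       masks = list(tube = tube, edge_band = edge_band))
}

# per-grade damage-feature counts for the default 240 x 320 cohort canvas;
# scaled by canvas area for other sizes
cohort_regimes <- function(area_factor = 1) {
  base <- list(
    "Scu 1" = c(clusters = 0, rings = 0, specks = 2),
    "Scu 2" = c(clusters = 10, rings = 3, specks = 15),
    "Scu 3" = c(clusters = 20, rings = 6, specks = 30),
    "Scu 4" = c(clusters = 35, rings = 12, specks = 60)
  )
  lapply(base, function(v) round(v * area_factor))
}

#' Generate a labelled synthetic cohort
#'
#' Renders `n_per_grade` fixtures for each requested grade regime, assigning
#' images round-robin to `samples_per_grade` synthetic hair samples per grade.
#' Grade Scu 1 regimes are labelled `control`, higher regimes `exploded`, so a
#' two-grade cohort is balanced across conditions. Record grades are the
#' regime labels (ground truth by construction); each fixture also carries the
#' grade its realized damage fraction implies.
#'
#' @param n_per_grade images per grade, default 8.
#' @param grades character vector of regimes to render, default
#'   `c("Scu 1", "Scu 2")`.
#' @param seed master seed; all per-image seeds derive from it.
#' @param height,width canvas size, default 240 x 320 (downsampled frames keep
#'   cohort studies fast; metric behaviour is resolution-stable).
#' @param angle tube axis angle in degrees, default 0.
#' @param samples_per_grade synthetic hairs per grade, default 2.
#' @return List with `records` (data frame: `image_id`, `sample_id`,
#'   `condition`, `grade`) and `fixtures` (named list of
#'   [generate_fixture()] outputs).
#' @export
generate_cohort <- function(n_per_grade = 8, grades = c("Scu 1", "Scu 2"),
                            seed = 1, height = 240, width = 320, angle = 0,
                            samples_per_grade = 2) {
  stopifnot(n_per_grade >= 1, all(grades %in% scu_grades()))
  regimes <- cohort_regimes(area_factor = (height * width) / (240 * 320))
  n_total <- n_per_grade * length(grades)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_total))
  fixtures <- list()
  records <- vector("list", n_total)
  idx <- 0L
  for (gi in seq_along(grades)) {
    g <- grades[gi]
    counts <- regimes[[g]]
    for (i in seq_len(n_per_grade)) {
      idx <- idx + 1L
      # small count jitter within the regime, never crossing into another
      jit <- with_seed(seeds[idx] %% 1000003L, sample(-1:1, 3, replace = TRUE))
      cc <- pmax(counts + jit * (counts > 0), 0)
      sp <- fixture_spec(
        height = height, width = width, angle = angle,
        n_clusters = cc[["clusters"]], n_rings = cc[["rings"]],
        n_specks = cc[["specks"]], seed = seeds[idx]
      )
      fx <- generate_fixture(sp)
      fx$image$id <- sprintf("img-%s-%02d", gsub(" ", "", g), i)
      fixtures[[fx$image$id]] <- fx
      records[[idx]] <- data.frame(
        image_id = fx$image$id,
        sample_id = sprintf("%s-H%d", gsub(" ", "", g), (i - 1L) %% samples_per_grade + 1L),
        condition = if (g == "Scu 1") "control" else "exploded",
        grade = g,
        stringsAsFactors = FALSE
      )
    }
  }
  list(records = do.call(rbind, records), fixtures = fixtures)
}

#' Score every fixture of a synthetic cohort
#'
#' Runs [score_image()] on each fixture and joins the metrics onto the cohort
#' records.
#'
#' @param cohort a [generate_cohort()] result.
#' @param ... passed to [score_image()].
#' @return The cohort `records` data frame extended with `mean_brightness`,
#'   `roughness`, `tailing_factor`, `f`, `n_sections`.
#' @export
score_cohort <- function(cohort, ...) {
  scores <- do.call(rbind, lapply(cohort$fixtures, function(fx) {
    score_image(fx$image, fx$axis, fx$diagonal, ...)
  }))
  merge(cohort$records, scores, by = "image_id", sort = FALSE)
}
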