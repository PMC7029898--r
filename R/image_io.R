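#' Greyscale SEM image container
#'
#' An 8-bit greyscale image: an H x W numeric matrix of brightness values in
#' \[0, 255\] (row = image row y, column = image column x, origin top-left),
#' plus optional acquisition magnification and an identifier.
#'
#' @param pixels numeric matrix, H x W, values in \[0, 255\], H >= 2, W >= 2.
#' @param magnification positive scalar magnification (e.g. 2000 for 2000x),
#'   or `NA` when unknown.
#' @param id opaque image identifier string.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, magnification = NA_real_, id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("image must be at least 2 x 2 pixels", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  if (!is.na(magnification) && magnification <= 0) {
    stop("`magnification` must be positive", call. = FALSE)
  }
  structure(
    list(pixels = pixels, magnification = as.numeric(magnification), id = as.character(id)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image '%s'> %d x %d px, magnification %s\n",
    x$id, nrow(x$pixels), ncol(x$pixels),
    if (is.na(x$magnification)) "unknown" else paste0(x$magnification, "x")
  ))
  invisible(x)
}

#' Line annotation in image pixel space
#'
#' A user-drawn line: either the axis line along the hair segment or the
#' diagonal line spanning the segment's bounding corners. Coordinates are
#' 0-based pixel indices, x = column, y = row, origin top-left.
#'
#' @param p1,p2 numeric length-2 vectors `c(x, y)`; must differ.
#' @param kind `"axis"` or `"diagonal"`.
#' @return An object of class `line_annotation`.
#' @export
line_annotation <- function(p1, p2, kind = c("axis", "diagonal")) {
  kind <- match.arg(kind)
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 2L || length(p2) != 2L || anyNA(c(p1, p2))) {
    stop("endpoints must be numeric (x, y) pairs", call. = FALSE)
  }
  if (all(p1 == p2)) stop("line endpoints must be distinct", call. = FALSE)
  structure(list(p1 = p1, p2 = p2, kind = kind), class = "line_annotation")
}

png_bit_depth <- function(path) {
  # IHDR layout: 8-byte signature, 4-byte length, "IHDR", width, height, depth
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stop("not a valid PNG file: ", path, call. = FALSE)
  as.integer(hdr[25L])
}

#' Read an 8-bit greyscale image
#'
#' Reads a PNG or TIFF micrograph into a [gray_image()]. Multi-channel rasters
#' are collapsed to grey by the unweighted channel mean (with a message, since
#' SEM exports are often RGB-encoded greys). Bit depths above 8 are rejected
#' rather than silently rescaled.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param magnification optional magnification to attach.
#' @param id image identifier; defaults to the file name without extension.
#' @return A [gray_image()].
#' @export
read_image <- function(path, magnification = NA_real_, id = NULL) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (png_bit_depth(path) > 8L) {
      stop("unsupported bit depth (> 8 bits per sample): ", path, call. = FALSE)
    }
    arr <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(arr, "bits.per.sample")
    if (!is.null(bps) && any(bps > 8)) {
      stop("unsupported bit depth (> 8 bits per sample): ", path, call. = FALSE)
    }
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)", call. = FALSE)
  }
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    # drop a pure alpha channel before averaging colour planes
    if (nch %in% c(2L, 4L)) arr <- arr[, , -nch, drop = FALSE]
    message("multi-channel image collapsed to grey by channel mean: ", path)
    arr <- apply(arr, c(1L, 2L), mean)
  }
  px <- quantize8(arr * 255)
  gray_image(px, magnification = magnification,
             id = if (is.null(id)) tools::file_path_sans_ext(basename(path)) else id)
}

#' Write an 8-bit greyscale image
#'
#' Quantizes brightness round-half-up to integers, clamps to \[0, 255\] and
#' writes a single-channel PNG or TIFF. `read_image(write_image(x))` is the
#' identity on valid 8-bit grids.
#'
#' @param img a [gray_image()] or numeric brightness matrix.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  v <- quantize8(px) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(v, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)", call. = FALSE)
  }
  invisible(path)
}

annotation_entry <- function(rows) {
  need <- function(kind) {
    r <- rows[rows$kind == kind, , drop = FALSE]
    if (nrow(r) == 0L) {
      stop("missing ", kind, " annotation for image '", rows$image_id[1L], "'", call. = FALSE)
    }
    r[1L, ]
  }
  ax <- need("axis"); dg <- need("diagonal")
  mag <- suppressWarnings(as.numeric(c(ax$magnification, dg$magnification)))
  mag <- mag[!is.na(mag)]
  list(
    axis = line_annotation(c(ax$x1, ax$y1), c(ax$x2, ax$y2), "axis"),
    diagonal = line_annotation(c(dg$x1, dg$y1), c(dg$x2, dg$y2), "diagonal"),
    magnification = if (length(mag)) mag[1L] else NA_real_
  )
}

#' Read an annotation sidecar
#'
#' Parses the CSV or JSON sidecar that replaces interactive line drawing.
#' CSV header: `image_id,kind,x1,y1,x2,y2,magnification` with
#' `kind` in `{axis, diagonal}`; magnification may be blank. The JSON dialect
#' is a list of objects with the same keys. Coordinates are 0-based pixel
#' indices (x = column, y = row).
#'
#' @param path path to a `.csv` or `.json` sidecar.
#' @param image_ids optional character vector of known image ids; annotation
#'   rows referencing other ids are skipped with a warning.
#' @return Named list keyed by image id; each element has `axis`, `diagonal`
#'   (both [line_annotation()]) and `magnification` (`NA` when absent).
#' @export
read_annotations <- function(path, image_ids = NULL) {
  if (!file.exists(path)) stop("annotation sidecar not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(image_id = "character"))
  } else if (ext == "json") {
    df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (is.null(df$magnification)) df$magnification <- NA_real_
  } else {
    stop("unsupported sidecar format: .", ext, " (use CSV or JSON)", call. = FALSE)
  }
  required <- c("image_id", "kind", "x1", "y1", "x2", "y2")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("annotation sidecar is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(df$kind %in% c("axis", "diagonal"))) {
    stop("annotation kind must be 'axis' or 'diagonal'", call. = FALSE)
  }
  if (!is.null(image_ids)) {
    unknown <- !(df$image_id %in% image_ids)
    if (any(unknown)) {
      warning("skipping annotation(s) for unknown image id(s): ",
              paste(unique(df$image_id[unknown]), collapse = ", "), call. = FALSE)
      df <- df[!unknown, , drop = FALSE]
    }
  }
  out <- lapply(split(df, df$image_id), annotation_entry)
  out[unique(df$image_id)]
}

#' Write an annotation sidecar CSV
#'
#' @param annotations named list as returned by [read_annotations()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  rows <- do.call(rbind, lapply(names(annotations), function(id) {
    a <- annotations[[id]]
    data.frame(
      image_id = id,
      kind = c("axis", "diagonal"),
      x1 = c(a$axis$p1[1], a$diagonal$p1[1]),
      y1 = c(a$axis$p1[2], a$diagonal$p1[2]),
      x2 = c(a$axis$p2[1], a$diagonal$p2[1]),
      y2 = c(a$axis$p2[2], a$diagonal$p2[2]),
      magnification = c(a$magnification, NA_real_),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Filter images by acquisition magnification
#'
#' Partitions a list of images into those acquired within a magnification
#' window and those outside it. The default window of 1000x-4000x is the
#' range over which mean image brightness is uncorrelated with magnification,
#' so images remain directly comparable. Images with unknown magnification
#' are excluded (with a message).
#'
#' @param images list of [gray_image()] objects.
#' @param lo,hi inclusive magnification bounds, `lo <= hi`.
#' @return List with elements `retained` and `excluded`, each a list of
#'   [gray_image()]; `length(retained) + length(excluded) == length(images)`.
#' @export
filter_by_magnification <- function(images, lo = 1000, hi = 4000) {
  if (lo > hi) stop("`lo` must not exceed `hi`", call. = FALSE)
  mags <- vapply(images, function(im) im$magnification, numeric(1))
  keep <- !is.na(mags) & mags >= lo & mags <= hi
  if (any(is.na(mags))) {
    message(sum(is.na(mags)), " image(s) excluded: magnification unknown")
  }
  list(retained = images[keep], excluded = images[!keep])
}
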