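# Frame input/output: image-sequence and multi-page TIFF readers, luminance
# conversion, lossless PNG writers, and the results CSV writer.
#
# Internal conventions: frames are H x W x 3 arrays of doubles in [0, 1], RGB
# channel order, frame indices 0-based (source-video numbering), boxes in
# pixel coordinates with origin top-left and half-open extents.

#' Construct a color frame
#'
#' @param pixels H x W x 3 numeric array in `[0, 1]`, RGB order.
#' @param index 0-based frame number in the source video.
#' @return an object of class `color_frame`.
#' @export
color_frame <- function(pixels, index) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 8L || dim(pixels)[2] < 8L)
    stop("frames must be at least 8 x 8 pixels", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  index <- as.integer(index)
  if (is.na(index) || index < 0L) stop("`index` must be >= 0", call. = FALSE)
  structure(list(pixels = pixels, index = index), class = "color_frame")
}

#' Construct a luminance plane
#'
#' @param pixels H x W numeric matrix in `[0, 1]`.
#' @param index 0-based source frame number.
#' @return an object of class `luminance_plane`.
#' @export
luminance_plane <- function(pixels, index) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("luminance values must lie in [0, 1]", call. = FALSE)
  structure(list(pixels = pixels, index = as.integer(index)),
            class = "luminance_plane")
}

#' Construct a frame stream
#'
#' A frame stream is an ordered sequence of [color_frame()]s whose source
#' indices increase by exactly `frame_skip`.
#'
#' @param frames list of `color_frame` objects.
#' @param fps frames per second of the source video (before skipping).
#' @param frame_skip the skip factor `k` used when the stream was read.
#' @return an object of class `frame_stream`.
#' @export
frame_stream <- function(frames, fps = 30, frame_skip = 1L) {
  if (length(frames) == 0L) stop("frame stream must be non-empty", call. = FALSE)
  idx <- vapply(frames, function(f) f$index, integer(1))
  k <- as.integer(frame_skip)
  if (length(idx) > 1L && !all(diff(idx) == k))
    stop("frame indices must increase by exactly `frame_skip`", call. = FALSE)
  stopifnot_scalar_number(fps, "fps", lower = 1e-9)
  structure(list(frames = frames, fps = fps, frame_skip = k),
            class = "frame_stream")
}

#' @export
length.frame_stream <- function(x) length(x$frames)

#' @export
print.frame_stream <- function(x, ...) {
  d <- dim(x$frames[[1]]$pixels)
  cat(sprintf("<frame_stream> %d frames, %d x %d px, fps %g, frame_skip %d\n",
              length(x$frames), d[2], d[1], x$fps, x$frame_skip))
  invisible(x)
}

frame_dims <- function(stream) dim(stream$frames[[1]]$pixels)[1:2]

#' Read video frames from disk
#'
#' Reads either a directory of image frames (PNG or TIFF, ordered by
#' filename) or a single multi-page TIFF stack, returning every `frame_skip`-th
#' frame with its original source index. Grayscale and RGBA inputs are
#' normalized to 3-channel RGB; all values are scaled to `[0, 1]`.
#'
#' @param path directory of images, or a `.tif`/`.tiff` stack.
#' @param frame_skip keep every k-th source frame (k >= 1).
#' @param fps frames per second to record on the stream; image containers
#'   carry no rate metadata, so this defaults to 30.
#' @return a [frame_stream()].
#' @export
read_frames <- function(path, frame_skip = 1L, fps = 30) {
  k <- as.integer(frame_skip)
  if (is.na(k) || k < 1L) stop("`frame_skip` must be an integer >= 1", call. = FALSE)
  if (!file.exists(path)) stop(sprintf("input not found: %s", path), call. = FALSE)

  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- files[order(basename(files))]
    if (length(files) == 0L)
      stop(sprintf("no decodable frames in %s", path), call. = FALSE)
    keep <- seq(1L, length(files), by = k)
    frames <- lapply(keep, function(i) {
      color_frame(read_image_rgb(files[i]), index = i - 1L)
    })
  } else {
    if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
      stop(sprintf("unsupported container (use a TIFF stack or image directory): %s",
                   path), call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 0L)
      stop(sprintf("no decodable frames in %s", path), call. = FALSE)
    keep <- seq(1L, length(pages), by = k)
    frames <- lapply(keep, function(i) {
      color_frame(normalize_rgb(pages[[i]]), index = i - 1L)
    })
  }
  frame_stream(frames, fps = fps, frame_skip = k)
}

read_image_rgb <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- switch(ext,
    png  = png::readPNG(file),
    tif  = ,
    tiff = tiff::readTIFF(file),
    stop(sprintf("unsupported image format: %s", file), call. = FALSE)
  )
  normalize_rgb(img)
}

normalize_rgb <- function(img) {
  if (is.matrix(img)) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3] == 4L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3] == 2L) {  # gray + alpha
    img <- array(rep(img[, , 1L], 3L), dim = c(dim(img)[1:2], 3L))
  }
  clip01(img)
}

#' Convert a color frame to luminance
#'
#' Rec.601 luma weights (0.299 R, 0.587 G, 0.114 B), the conventional default
#' for video-derived material; alternative weights may be supplied.
#'
#' @param frame a [color_frame()] (or motion frame).
#' @param weights length-3 RGB weights summing to 1.
#' @return a [luminance_plane()] with the frame's source index.
#' @export
to_luminance <- function(frame, weights = c(0.299, 0.587, 0.114)) {
  px <- frame$pixels
  L <- weights[1] * px[, , 1] + weights[2] * px[, , 2] + weights[3] * px[, , 3]
  luminance_plane(clip01(L), index = frame$index)
}

#' Quantize pixels to the 8-bit grid
#'
#' Snaps values to multiples of 1/255, the representable set of an 8-bit PNG,
#' so that written dataset images round-trip bit-exactly.
#'
#' @param pixels numeric array in `[0, 1]`.
#' @return quantized array.
#' @export
quantize8 <- function(pixels) {
  round(clip01(pixels) * 255) / 255
}

#' Write a frame as a lossless PNG
#'
#' Values are quantized to the 8-bit grid on write; reading the file back
#' yields the quantized array exactly.
#'
#' @param pixels H x W x 3 array (or H x W matrix) in `[0, 1]`.
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_png <- function(pixels, path) {
  dir_create_for(path)
  ok <- tryCatch({
    png::writePNG(clip01(pixels), target = path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write image: %s", path), call. = FALSE)
  invisible(path)
}

#' Write frames as a multi-page TIFF stack
#'
#' The package's lossless video container: one page per frame, float storage.
#'
#' @param frames a [frame_stream()] or list of frame objects with `$pixels`.
#' @param path destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_video <- function(frames, path) {
  if (inherits(frames, "frame_stream")) frames <- frames$frames
  dir_create_for(path)
  pages <- lapply(frames, function(f) clip01(f$pixels))
  ok <- tryCatch({
    tiff::writeTIFF(pages, where = path, bits.per.sample = 8L)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write video: %s", path), call. = FALSE)
  invisible(path)
}

#' Write the tracking results table
#'
#' Comma-separated, UTF-8, header row, reals at fixed 6-decimal precision —
#' byte-deterministic for identical inputs.
#'
#' @param rows a results data.frame (see [process_video()]).
#' @param path destination `.csv` path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(rows, path) {
  dir_create_for(path)
  cols <- c("video", "frame", "track_id", "primary_class", "primary_confidence",
            "secondary_class", "secondary_confidence", "cx", "cy", "source")
  lines <- paste(cols, collapse = ",")
  if (nrow(rows) > 0) {
    fmt6 <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
    body <- paste(
      rows$video, rows$frame, rows$track_id, rows$primary_class,
      fmt6(rows$primary_confidence),
      ifelse(is.na(rows$secondary_class), "", rows$secondary_class),
      fmt6(rows$secondary_confidence),
      fmt6(rows$cx), fmt6(rows$cy), rows$source,
      sep = ","
    )
    lines <- c(lines, body)
  }
  con <- tryCatch(file(path, open = "wb"), error = function(e) NULL)
  if (is.null(con)) stop(sprintf("cannot write CSV: %s", path), call. = FALSE)
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

dir_create_for <- function(path) {
  d <- dirname(path)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(d)) stop(sprintf("cannot create directory: %s", d), call. = FALSE)
  invisible(d)
}
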