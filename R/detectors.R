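# Pluggable detector interface.
#
# A primary detector is any function
#     detector(pixels, stream, frame_index, video_id) -> detection data.frame
# returning columns frame, x0, y0, x1, y1, class_name, confidence, source.
# A secondary classifier is any function (crop, group) -> list(label,
# confidence). Real CNN backends (e.g., an external YOLO process) plug in
# through the same signatures; the package ships a ground-truth oracle used
# for testing, simulation studies and pipeline validation.

#' Ground-truth oracle detector
#'
#' Builds a detector from [render_scene()] ground truth. Each truth label is
#' routed to a stream and class via `class_map`; by default every label is
#' reported on the motion stream under its own name. Imperfection can be
#' injected for robustness studies: seeded box dropout (false negatives),
#' centroid jitter, and uniform false positives. All randomness is
#' counter-based on `(seed, video, frame, stream)`, so detections for one
#' frame never depend on which other frames were queried.
#'
#' @param truth ground-truth data.frame (`frame, object_id, x0, y0, x1, y1,
#'   label, ...`); an optional `video_id` column scopes rows to one video in
#'   multi-video batches.
#' @param class_map optional named list mapping a truth label to
#'   `list(stream, class)`; labels absent from the map are reported on the
#'   motion stream under the truth label.
#' @param dropout probability of dropping each true box.
#' @param jitter_sd Gaussian jitter (px) added to box corners.
#' @param fp_rate expected number of false-positive boxes per frame.
#' @param frame_size `c(width, height)`, needed when `fp_rate > 0`.
#' @param confidence reported confidence for true boxes.
#' @param seed integer seed for the imperfection draws.
#' @return a detector function.
#' @export
oracle_detector <- function(truth, class_map = NULL,
                            dropout = 0, jitter_sd = 0, fp_rate = 0,
                            frame_size = NULL, confidence = 1, seed = 0L) {
  if (fp_rate > 0 && is.null(frame_size))
    stop("`frame_size` is required when `fp_rate` > 0", call. = FALSE)
  force(truth)

  function(pixels, stream, frame_index, video_id = "video") {
    rows <- truth[truth$frame == frame_index, , drop = FALSE]
    if (!is.null(rows$video_id))
      rows <- rows[rows$video_id == video_id, , drop = FALSE]
    out <- det_frame()
    if (nrow(rows) > 0) {
      route <- lapply(rows$label, function(lb) {
        class_map[[lb]] %||% list(stream = "motion", class = lb)
      })
      keep <- vapply(route, function(r) identical(r$stream, stream), logical(1))
      rows <- rows[keep, , drop = FALSE]
      route <- route[keep]
      if (nrow(rows) > 0) {
        if (dropout > 0) {
          u <- with_seed(derive_seed(seed, "drop", video_id, frame_index, stream),
                         stats::runif(nrow(rows)))
          rows <- rows[u >= dropout, , drop = FALSE]
          route <- route[u >= dropout]
        }
        if (nrow(rows) > 0) {
          b <- as.matrix(rows[, c("x0", "y0", "x1", "y1")])
          if (jitter_sd > 0) {
            b <- b + with_seed(derive_seed(seed, "jit", video_id, frame_index, stream),
                               matrix(stats::rnorm(length(b), 0, jitter_sd),
                                      nrow(b), 4))
            bad <- b[, 1] >= b[, 3] | b[, 2] >= b[, 4]
            b[bad, ] <- as.matrix(rows[bad, c("x0", "y0", "x1", "y1")])
          }
          out <- det_frame(frame = rows$frame,
                           x0 = b[, 1], y0 = b[, 2], x1 = b[, 3], y1 = b[, 4],
                           class_name = vapply(route, function(r) r$class,
                                               character(1)),
                           confidence = rep(confidence, nrow(rows)),
                           source = rep(stream, nrow(rows)))
        }
      }
    }
    if (fp_rate > 0) {
      nfp <- with_seed(derive_seed(seed, "fpn", video_id, frame_index, stream),
                       stats::rpois(1, fp_rate))
      if (nfp > 0) {
        classes <- schema_pool <- unique(truth$label)
        fp <- with_seed(derive_seed(seed, "fp", video_id, frame_index, stream), {
          x0 <- stats::runif(nfp, 0, frame_size[1] - 6)
          y0 <- stats::runif(nfp, 0, frame_size[2] - 6)
          w <- stats::runif(nfp, 3, 8); h <- stats::runif(nfp, 3, 8)
          cls <- sample(classes, nfp, replace = TRUE)
          det_frame(frame = rep(frame_index, nfp),
                    x0 = x0, y0 = y0,
                    x1 = pmin(x0 + w, frame_size[1]),
                    y1 = pmin(y0 + h, frame_size[2]),
                    class_name = cls,
                    confidence = stats::runif(nfp, 0.3, 0.7),
                    source = rep(stream, nfp))
        })
        out <- rbind(out, fp)
      }
    }
    out
  }
}

#' Ground-truth oracle secondary classifier
#'
#' Returns the truth label of the object whose box best matches the crop's
#' source detection. Because the crop itself carries no identity, the oracle
#' is constructed per use with a lookup from group to label; in tests it is
#' usually a closure over the scene's truth.
#'
#' @param label_fn function `(crop, group) -> character` giving the truth
#'   label (or a constant label).
#' @param confidence reported confidence.
#' @return a secondary-classifier function `(crop, group) -> list(label,
#'   confidence)`.
#' @export
oracle_secondary <- function(label_fn, confidence = 1) {
  if (!is.function(label_fn)) {
    lbl <- label_fn
    label_fn <- function(crop, group) lbl
  }
  function(crop, group) {
    list(label = label_fn(crop, group), confidence = confidence)
  }
}
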