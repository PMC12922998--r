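# Batch processing: encode -> detect -> merge -> track -> secondary dispatch,
# with overlay video and CSV results output.

#' Bundle a full run configuration
#'
#' @param encoder an [encoder_config()].
#' @param tracker a [tracker_config()]; its `dominant_source` is overridden
#'   by the schema's.
#' @param schema a [class_schema()].
#' @param seed global seed forwarded to seeded components.
#' @return an object of class `run_config`.
#' @export
run_config <- function(encoder = encoder_config(),
                       tracker = tracker_config(),
                       schema = class_schema(),
                       seed = 1L) {
  tracker$dominant_source <- schema$dominant_source
  structure(list(encoder = encoder, tracker = tracker, schema = schema,
                 seed = as.integer(seed)),
            class = "run_config")
}

result_row_df <- function() {
  data.frame(video = character(), frame = integer(), track_id = integer(),
             primary_class = character(), primary_confidence = numeric(),
             secondary_class = character(), secondary_confidence = numeric(),
             cx = numeric(), cy = numeric(), source = character(),
             stringsAsFactors = FALSE)
}

#' Process one video through the full pipeline
#'
#' Per frame: encode the motion stream, run the primary detector on each
#' stream that has primary classes, merge duplicate detections across
#' streams, advance the Kalman tracker, and dispatch secondary classification
#' on confirmed detections. One result row is emitted per confirmed-track
#' observation; tentative and lost tracks produce no rows. Deterministic for
#' a deterministic detector.
#'
#' @param video a [frame_stream()] or path readable by [read_frames()].
#' @param config a [run_config()].
#' @param detector primary detector function (see [oracle_detector()]).
#' @param secondary_classifier optional secondary classifier function.
#' @param video_id identifier written into the rows.
#' @param overlay if `TRUE`, also return frames with track boxes drawn in.
#' @return `list(rows = data.frame, overlay = list of frames or NULL,
#'   skipped = integer, degraded = logical)`.
#' @export
process_video <- function(video, config, detector,
                          secondary_classifier = NULL,
                          video_id = "video", overlay = FALSE) {
  stream <- if (inherits(video, "frame_stream")) video else
    read_frames(video, frame_skip = config$encoder$frame_skip)
  schema <- config$schema
  motion_frames <- encode_stream(stream, config$encoder)
  tracker <- new_tracker(config$tracker)
  rows <- list()
  overlay_frames <- if (overlay) vector("list", length(stream$frames)) else NULL
  skipped <- 0L

  for (pos in seq_along(stream$frames)) {
    f <- stream$frames[[pos]]
    mf <- motion_frames[[pos]]

    dets <- det_frame()
    ok <- TRUE
    for (sname in c("static", "motion")) {
      if (length(schema_classes(schema, sname)) == 0) next
      if (sname == "motion" && mf$warm_up) next  # warm-up: no motion detections
      px <- if (sname == "static") f$pixels else mf$pixels
      d <- tryCatch(detector(px, sname, f$index, video_id),
                    error = function(e) {
                      warning(sprintf("detector failed on %s frame %d: %s",
                                      video_id, f$index, conditionMessage(e)))
                      NULL
                    })
      if (is.null(d)) { ok <- FALSE; break }
      if (nrow(d) > 0) dets <- rbind(dets, d)
    }
    if (!ok) {
      skipped <- skipped + 1L
      if (overlay) overlay_frames[[pos]] <- f
      next
    }

    merged <- merge_detections(dets, config$tracker)
    stepped <- step_tracker(tracker, merged)
    tracker <- stepped$state
    asg <- stepped$assignments

    if (nrow(asg) > 0) for (k in seq_len(nrow(asg))) {
      if (!asg$confirmed[k]) next
      det <- merged[asg$det[k], , drop = FALSE]
      cen <- box_centroid(as.numeric(det[c("x0", "y0", "x1", "y1")]))
      sec_label <- NA_character_; sec_conf <- NA_real_
      if (!is.null(secondary_classifier) && length(schema$secondary) > 0) {
        res <- dispatch_secondary(det, f$pixels, mf$pixels, schema,
                                  secondary_classifier)
        if (is.null(res$skipped)) {
          sec_label <- res$label; sec_conf <- res$confidence
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        video = video_id, frame = f$index, track_id = asg$track_id[k],
        primary_class = det$class_name,
        primary_confidence = det$confidence,
        secondary_class = sec_label, secondary_confidence = sec_conf,
        cx = cen[1], cy = cen[2], source = det$source,
        stringsAsFactors = FALSE)
    }

    if (overlay) {
      px <- f$pixels
      if (nrow(asg) > 0) for (k in seq_len(nrow(asg))) {
        if (!asg$confirmed[k]) next
        det <- merged[asg$det[k], , drop = FALSE]
        px <- draw_box(px, as.numeric(det[c("x0", "y0", "x1", "y1")]),
                       color = class_color(det$class_name))
      }
      overlay_frames[[pos]] <- color_frame(px, f$index)
    }
  }

  rows_df <- if (length(rows)) do.call(rbind, rows) else result_row_df()
  if (config$tracker$min_track_length > 0 && nrow(rows_df) > 0) {
    len <- table(rows_df$track_id)
    keep <- names(len)[len >= config$tracker$min_track_length]
    rows_df <- rows_df[rows_df$track_id %in% as.integer(keep), , drop = FALSE]
  }
  rownames(rows_df) <- NULL
  n_frames <- length(stream$frames)
  list(rows = rows_df,
       overlay = overlay_frames,
       skipped = skipped,
       degraded = skipped > 0.1 * n_frames)
}

#' Batch-process every video in a directory
#'
#' Each entry of `input_dir` (a multi-page TIFF stack or a sub-directory of
#' frames) is processed with [process_video()]; per-video CSV and overlay
#' outputs are written next to a run manifest recording the configuration
#' snapshot, encoder hash and per-video status.
#'
#' @param input_dir directory of input videos.
#' @param config a [run_config()].
#' @param detector primary detector function.
#' @param output_dir destination directory.
#' @param secondary_classifier optional secondary classifier.
#' @param overlay write overlay videos (default `TRUE`).
#' @return the manifest, invisibly.
#' @export
batch_process <- function(input_dir, config, detector, output_dir,
                          secondary_classifier = NULL, overlay = TRUE) {
  entries <- c(list.files(input_dir, pattern = "\\.tiff?$", full.names = TRUE),
               list.dirs(input_dir, recursive = FALSE))
  entries <- sort(unique(entries))
  if (length(entries) == 0)
    stop(sprintf("no input videos in %s", input_dir), call. = FALSE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  status <- list()
  for (path in entries) {
    vid <- sub("\\.tiff?$", "", basename(path))
    res <- tryCatch({
      out <- process_video(path, config, detector,
                           secondary_classifier = secondary_classifier,
                           video_id = vid, overlay = overlay)
      write_result_csv(out$rows, file.path(output_dir, paste0(vid, ".csv")))
      if (overlay)
        write_video(out$overlay, file.path(output_dir, paste0(vid, "_overlay.tif")))
      list(status = if (out$degraded) "degraded" else "ok",
           frames_skipped = out$skipped, rows = nrow(out$rows))
    }, error = function(e) list(status = "failed", error = conditionMessage(e)))
    status[[vid]] <- res
  }

  manifest <- list(
    encoder_hash = encoder_hash(config$encoder),
    config = list(
      encoder = yaml::yaml.load(encoder_config_yaml(config$encoder)),
      tracker = unclass(config$tracker),
      schema = unclass(config$schema),
      seed = config$seed),
    videos = status)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# ---- overlay drawing -----------------------------------------------------

class_color <- function(class_name) {
  palette <- list(c(1, 0.2, 0.2), c(0.2, 1, 0.2), c(0.2, 0.4, 1),
                  c(1, 1, 0.2), c(1, 0.2, 1), c(0.2, 1, 1))
  idx <- (utf8ToInt(substr(class_name, 1, 1)) %% length(palette)) + 1L
  palette[[idx]]
}

draw_box <- function(pixels, box, color = c(1, 1, 0.2), thickness = 1L) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  b <- box_clip(box, w, h)
  if (is.null(b)) return(pixels)
  rows <- box_px_range(b[2], b[4], h)
  cols <- box_px_range(b[1], b[3], w)
  t <- seq_len(min(thickness, length(rows), length(cols)))
  edge_r <- unique(c(rows[t], rows[length(rows) + 1L - t]))
  edge_c <- unique(c(cols[t], cols[length(cols) + 1L - t]))
  for (c in 1:3) {
    pixels[edge_r, cols, c] <- color[c]
    pixels[rows, edge_c, c] <- color[c]
  }
  pixels
}
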