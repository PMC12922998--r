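# Dual-stream annotation datasets in YOLO darknet layout.
#
# Annotations are rows of a data.frame (the JSON-lines store is the source
# of truth; the on-disk YOLO tree is a compiled artifact):
#   video_id, frame, stream ("static"/"motion"), class_name, x0, y0, x1, y1,
#   kind ("label"/"shield"), confidence (NA for manual), provenance
#   ("manual"/"auto")
# Boxes are pixel coordinates, half-open, origin top-left. Shields carry no
# class; a frame may mix labels and shields.

#' Construct an annotation table
#'
#' @param video_id,frame,stream,class_name,x0,y0,x1,y1,kind,confidence,provenance
#'   vectors, recycled to a common length.
#' @return annotation data.frame.
#' @export
annotations <- function(video_id, frame, stream, class_name,
                        x0, y0, x1, y1, kind = "label",
                        confidence = NA_real_, provenance = "manual") {
  data.frame(video_id = video_id, frame = as.integer(frame), stream = stream,
             class_name = class_name, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
             kind = kind, confidence = confidence, provenance = provenance,
             stringsAsFactors = FALSE)
}

empty_annotations <- function() {
  annotations(character(), integer(), character(), character(),
              numeric(), numeric(), numeric(), numeric(),
              character(), numeric(), character())
}

#' Class schema for the dual-stream classifier hierarchy
#'
#' Primary classes are detected per stream over whole frames; secondary
#' groups classify crops of primary detections (e.g., sexing individuals).
#'
#' @param primary_static,primary_motion character vectors of class names,
#'   unique within each stream.
#' @param secondary named list of groups, each
#'   `list(classes = c(...), stream = "static"|"motion",
#'   primary_classes = NULL or c(...))`; `primary_classes = NULL` means the
#'   group applies to every primary class not ignored.
#' @param motion_blocks_static if `TRUE`, every motion-labeled box is
#'   gray-shielded out of the static training images so the static model only
#'   ever sees truly stationary appearances.
#' @param ignore_secondary primary classes for which secondary dispatch is
#'   skipped.
#' @param dominant_source class-priority rule for merged detections
#'   (`"motion"`, `"static"` or `"confidence"`).
#' @return an object of class `class_schema`.
#' @export
class_schema <- function(primary_static = character(),
                         primary_motion = character(),
                         secondary = list(),
                         motion_blocks_static = FALSE,
                         ignore_secondary = character(),
                         dominant_source = c("confidence", "motion", "static")) {
  dominant_source <- match.arg(dominant_source)
  if (anyDuplicated(primary_static) || anyDuplicated(primary_motion))
    stop("class names must be unique within a stream", call. = FALSE)
  known <- c(primary_static, primary_motion)
  if (!all(ignore_secondary %in% known))
    stop("`ignore_secondary` must be a subset of the primary classes", call. = FALSE)
  structure(list(primary_static = primary_static,
                 primary_motion = primary_motion,
                 secondary = secondary,
                 motion_blocks_static = isTRUE(motion_blocks_static),
                 ignore_secondary = ignore_secondary,
                 dominant_source = dominant_source),
            class = "class_schema")
}

schema_classes <- function(schema, stream) {
  if (stream == "static") schema$primary_static else schema$primary_motion
}

#' Assign a frame to the training or validation split
#'
#' Deterministic: the side is a pure function of `(seed, video_id, frame)`
#' through a SHA-256 hash, so adding videos or re-running a build never
#' migrates existing frames. In `exclusive_videos` mode the hash ignores the
#' frame, sending whole videos to one side (validation and training material
#' then come from mutually exclusive videos).
#'
#' @param video_id,frame vectors identifying the frames.
#' @param seed integer split seed.
#' @param p_val validation probability in `(0, 1)`.
#' @param mode `"per_frame"` (default) or `"exclusive_videos"`.
#' @return character vector of `"train"` / `"val"`.
#' @export
assign_split <- function(video_id, frame, seed, p_val = 0.2,
                         mode = c("per_frame", "exclusive_videos")) {
  mode <- match.arg(mode)
  if (!is.numeric(p_val) || p_val <= 0 || p_val >= 1)
    stop("`p_val` must lie strictly between 0 and 1", call. = FALSE)
  key <- if (mode == "per_frame") {
    sprintf("split|%d|%s|%d", as.integer(seed), video_id, as.integer(frame))
  } else {
    sprintf("split|%d|%s|video", as.integer(seed), video_id)
  }
  ifelse(hash_unit(key) < p_val, "val", "train")
}

# ---- YOLO darknet label format ------------------------------------------

yolo_encode <- function(ann, class_names, width, height) {
  idx <- match(ann$class_name, class_names) - 1L
  if (anyNA(idx))
    stop(sprintf("class not in schema: %s",
                 paste(unique(ann$class_name[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  cx <- (ann$x0 + ann$x1) / 2 / width
  cy <- (ann$y0 + ann$y1) / 2 / height
  bw <- (ann$x1 - ann$x0) / width
  bh <- (ann$y1 - ann$y0) / height
  sprintf("%d %.6f %.6f %.6f %.6f", idx, cx, cy, bw, bh)
}

#' Write YOLO darknet label files
#'
#' One text file per image with lines `class_index cx cy w h`, box center and
#' size normalized by the image dimensions, fixed 6-decimal format.
#' Background frames (no label annotations) get an empty file.
#'
#' @param ann annotation data.frame for one image (labels only; shields are
#'   not written).
#' @param path destination `.txt` path.
#' @param class_names ordered class list defining the indices.
#' @param width,height image dimensions in pixels.
#' @return `path`, invisibly.
#' @export
write_labels <- function(ann, path, class_names, width, height) {
  dir_create_for(path)
  ann <- ann[ann$kind == "label", , drop = FALSE]
  lines <- if (nrow(ann) > 0) yolo_encode(ann, class_names, width, height)
           else character()
  writeLines(lines, path)
  invisible(path)
}

#' Parse a YOLO darknet label file back to pixel boxes
#'
#' @param path label `.txt` path.
#' @param class_names ordered class list.
#' @param width,height image dimensions.
#' @return data.frame with `class_name, x0, y0, x1, y1`.
#' @export
read_labels <- function(path, class_names, width, height) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(class_name = character(), x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  cx <- parts[, 2] * width; cy <- parts[, 3] * height
  bw <- parts[, 4] * width; bh <- parts[, 5] * height
  data.frame(class_name = class_names[parts[, 1] + 1],
             x0 = cx - bw / 2, y0 = cy - bh / 2,
             x1 = cx + bw / 2, y1 = cy + bh / 2,
             stringsAsFactors = FALSE)
}

#' Gray-shield regions of a frame
#'
#' Sets every pixel inside each shield box to mid-gray 0.5 in all channels.
#' Used on written dataset images only — the source video is never modified.
#' Boxes reaching outside the frame are clipped with a warning.
#'
#' @param pixels H x W x 3 array.
#' @param shields data.frame (or list) of boxes with `x0, y0, x1, y1`.
#' @return the shielded array.
#' @export
apply_shields <- function(pixels, shields) {
  if (is.null(shields) || NROW(shields) == 0) return(pixels)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  for (i in seq_len(NROW(shields))) {
    b <- as.numeric(shields[i, c("x0", "y0", "x1", "y1")])
    if (b[1] < 0 || b[2] < 0 || b[3] > w || b[4] > h) {
      warning(sprintf("shield box [%g,%g,%g,%g] clipped to frame bounds",
                      b[1], b[2], b[3], b[4]))
    }
    bc <- box_clip(b, w, h)
    if (is.null(bc)) next
    rows <- box_px_range(bc[2], bc[4], h)
    cols <- box_px_range(bc[1], bc[3], w)
    pixels[rows, cols, ] <- 0.5
  }
  pixels
}

#' Hide motion-labeled instances from the static stream
#'
#' When `motion_blocks_static` is enabled, every motion-stream labeled box on
#' a frame is gray-shielded in the static training image, and static labels
#' whose centers fall inside a blocked region are dropped with a warning —
#' the static model must never train on appearances that the motion model
#' owns (e.g., walking flies that look like resting ones).
#'
#' @param static_pixels H x W x 3 static image.
#' @param motion_labels data.frame of motion-stream label boxes for the frame.
#' @param static_labels data.frame of static-stream labels for the frame.
#' @return `list(pixels, labels)` — the shielded image and surviving labels.
#' @export
apply_motion_blocks_static <- function(static_pixels, motion_labels,
                                       static_labels = NULL) {
  if (NROW(motion_labels) == 0)
    return(list(pixels = static_pixels, labels = static_labels))
  pixels <- apply_shields(static_pixels, motion_labels)
  labels <- static_labels
  if (NROW(static_labels) > 0) {
    cx <- (static_labels$x0 + static_labels$x1) / 2
    cy <- (static_labels$y0 + static_labels$y1) / 2
    blocked <- rep(FALSE, nrow(static_labels))
    for (i in seq_len(nrow(motion_labels))) {
      b <- as.numeric(motion_labels[i, c("x0", "y0", "x1", "y1")])
      blocked <- blocked | (cx >= b[1] & cx < b[3] & cy >= b[2] & cy < b[4])
    }
    if (any(blocked)) {
      warning(sprintf("%d static label(s) dropped: inside motion-blocked regions",
                      sum(blocked)))
      labels <- static_labels[!blocked, , drop = FALSE]
    }
  }
  list(pixels = pixels, labels = labels)
}

image_basename <- function(video_id, frame) sprintf("%s_f%06d", video_id, frame)

#' Compile a dual-stream YOLO dataset
#'
#' Renders static images from raw frames and motion images through the
#' encoder, applies gray-box shields and (optionally) motion-blocks-static
#' masking, splits frames into train/val with [assign_split()], writes
#' normalized label files, exports secondary-classifier crops per class, and
#' records metadata including the encoder-configuration hash used for
#' rebuild detection. Annotations on warm-up motion frames are excluded with
#' a warning.
#'
#' @param videos named list mapping `video_id` to a [frame_stream()] (or a
#'   path readable by [read_frames()]).
#' @param ann annotation data.frame (see [annotations()]).
#' @param schema a [class_schema()].
#' @param encoder an [encoder_config()].
#' @param seed split seed.
#' @param p_val validation probability (default 0.2).
#' @param root destination directory.
#' @param split_mode `"per_frame"` or `"exclusive_videos"`.
#' @return the dataset root path, invisibly; the tree layout is
#'   `root/{static,motion}/{images,labels}/{train,val}`,
#'   `root/secondary/<group>/<class>/`, plus `root/<stream>/data.yaml` and
#'   `root/metadata.json`.
#' @export
build_dataset <- function(videos, ann, schema, encoder, seed, p_val = 0.2,
                          root, split_mode = "per_frame") {
  videos <- lapply(videos, function(v) {
    if (inherits(v, "frame_stream")) v else read_frames(v, frame_skip = encoder$frame_skip)
  })
  missing <- setdiff(unique(ann$video_id), names(videos))
  if (length(missing) > 0)
    stop(sprintf("annotations reference missing video(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)

  for (stream in c("static", "motion")) for (part in c("images", "labels"))
    for (side in c("train", "val"))
      dir.create(file.path(root, stream, part, side), recursive = TRUE,
                 showWarnings = FALSE)

  crop_counter <- 0L
  for (vid in names(videos)) {
    vann <- ann[ann$video_id == vid, , drop = FALSE]
    if (nrow(vann) == 0) next
    stream <- videos[[vid]]
    dims <- frame_dims(stream)
    motion_frames <- encode_stream(stream, encoder)
    idx_of <- stats::setNames(seq_along(stream$frames),
                              vapply(stream$frames, function(f) f$index, integer(1)))

    for (fr in sort(unique(vann$frame))) {
      pos <- idx_of[as.character(fr)]
      if (is.na(pos))
        stop(sprintf("annotation references missing frame %d of video %s",
                     fr, vid), call. = FALSE)
      fann <- vann[vann$frame == fr, , drop = FALSE]
      mf <- motion_frames[[pos]]
      if (mf$warm_up) {
        warning(sprintf("video %s frame %d is a warm-up motion frame; excluded",
                        vid, fr))
        next
      }
      side <- assign_split(vid, fr, seed, p_val, mode = split_mode)
      base <- image_basename(vid, fr)

      static_px <- stream$frames[[pos]]$pixels
      motion_px <- mf$pixels
      s_lab <- fann[fann$stream == "static" & fann$kind == "label", , drop = FALSE]
      m_lab <- fann[fann$stream == "motion" & fann$kind == "label", , drop = FALSE]
      s_shl <- fann[fann$stream == "static" & fann$kind == "shield", , drop = FALSE]
      m_shl <- fann[fann$stream == "motion" & fann$kind == "shield", , drop = FALSE]

      static_px <- apply_shields(static_px, s_shl)
      motion_px <- apply_shields(motion_px, m_shl)
      if (schema$motion_blocks_static) {
        mb <- apply_motion_blocks_static(static_px, m_lab, s_lab)
        static_px <- mb$pixels
        s_lab <- mb$labels
      }

      write_png(quantize8(static_px),
                file.path(root, "static", "images", side, paste0(base, ".png")))
      write_png(quantize8(motion_px),
                file.path(root, "motion", "images", side, paste0(base, ".png")))
      write_labels(s_lab, file.path(root, "static", "labels", side,
                                    paste0(base, ".txt")),
                   schema$primary_static, dims[2], dims[1])
      write_labels(m_lab, file.path(root, "motion", "labels", side,
                                    paste0(base, ".txt")),
                   schema$primary_motion, dims[2], dims[1])

      # secondary-classifier crops: one per labeled box carrying a class of
      # a secondary group, cropped from the group's stream
      for (gname in names(schema$secondary)) {
        grp <- schema$secondary[[gname]]
        src_px <- if (identical(grp$stream, "motion")) motion_px else static_px
        sec_ann <- fann[fann$kind == "label" & fann$class_name %in% grp$classes, ,
                        drop = FALSE]
        if (nrow(sec_ann) == 0) next
        for (k in seq_len(nrow(sec_ann))) {
          b <- box_clip(as.numeric(sec_ann[k, c("x0", "y0", "x1", "y1")]),
                        dims[2], dims[1])
          if (is.null(b)) next
          rows <- box_px_range(b[2], b[4], dims[1])
          cols <- box_px_range(b[1], b[3], dims[2])
          crop_counter <- crop_counter + 1L
          write_png(quantize8(src_px[rows, cols, , drop = FALSE]),
                    file.path(root, "secondary", gname, sec_ann$class_name[k],
                              sprintf("%s_%03d.png", base, crop_counter)))
        }
      }
    }
  }

  for (stream in c("static", "motion")) {
    writeLines(yaml::as.yaml(list(
      path = ".",  # relative to this file's directory
      train = "images/train", val = "images/val",
      names = as.list(schema_classes(schema, stream))
    )), file.path(root, stream, "data.yaml"))
  }
  meta <- list(encoder_hash = encoder_hash(encoder),
               encoder = yaml::yaml.load(encoder_config_yaml(encoder)),
               seed = as.integer(seed), p_val = p_val,
               split_mode = split_mode,
               videos = names(videos))
  jsonlite::write_json(meta, file.path(root, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(root)
}

#' Rebuild the motion images of a dataset under new encoder settings
#'
#' A change in motion-encoding settings is detected by comparing SHA-256
#' configuration hashes; when they differ, every motion image in the tree is
#' regenerated from its source video under the new settings while label
#' files, split assignments and static images are left byte-identical. A
#' rebuild with an unchanged configuration is a no-op.
#'
#' @param root dataset root produced by [build_dataset()].
#' @param videos named list of source [frame_stream()]s (or paths).
#' @param new_encoder the new [encoder_config()].
#' @return `TRUE` if a rebuild happened, `FALSE` for the no-op, invisibly.
#' @export
rebuild_motion <- function(root, videos, new_encoder) {
  meta_path <- file.path(root, "metadata.json")
  meta <- jsonlite::read_json(meta_path)
  new_hash <- encoder_hash(new_encoder)
  if (identical(meta$encoder_hash, new_hash)) return(invisible(FALSE))

  videos <- lapply(videos, function(v) {
    if (inherits(v, "frame_stream")) v else
      read_frames(v, frame_skip = new_encoder$frame_skip)
  })

  img_files <- list.files(file.path(root, "motion", "images"), recursive = TRUE,
                          pattern = "\\.png$", full.names = TRUE)
  wanted <- data.frame(path = img_files,
                       base = sub("\\.png$", "", basename(img_files)),
                       stringsAsFactors = FALSE)
  wanted$video_id <- sub("_f[0-9]{6}$", "", wanted$base)
  wanted$frame <- as.integer(sub("^.*_f", "", wanted$base))

  missing <- setdiff(unique(wanted$video_id), names(videos))
  if (length(missing) > 0)
    stop(sprintf("cannot rebuild: source video(s) unavailable: %s (frames %s)",
                 paste(missing, collapse = ", "),
                 paste(wanted$frame[wanted$video_id %in% missing], collapse = ",")),
         call. = FALSE)

  for (vid in unique(wanted$video_id)) {
    stream <- videos[[vid]]
    motion_frames <- encode_stream(stream, new_encoder)
    idx_of <- stats::setNames(seq_along(stream$frames),
                              vapply(stream$frames, function(f) f$index, integer(1)))
    rows <- wanted[wanted$video_id == vid, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      pos <- idx_of[as.character(rows$frame[k])]
      if (is.na(pos))
        stop(sprintf("cannot rebuild: frame %d of video %s unavailable",
                     rows$frame[k], vid), call. = FALSE)
      write_png(quantize8(motion_frames[[pos]]$pixels), rows$path[k])
    }
  }
  meta$encoder_hash <- new_hash
  meta$encoder <- yaml::yaml.load(encoder_config_yaml(new_encoder))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(TRUE)
}

#' Predict annotations with a trained detector
#'
#' Runs the detector over both streams of each video and converts detections
#' at or above `conf_min` into annotation records marked `provenance =
#' "auto"` (carrying the detector confidence); detections below the threshold
#' are returned separately as low-confidence suggestions for human review.
#' Frames that already carry manual annotations for a stream are skipped —
#' auto-annotation never overwrites manual work. Detector errors skip the
#' frame with a warning.
#'
#' @param videos named list of [frame_stream()]s.
#' @param detector function `(pixels, stream, frame_index, video_id) ->
#'   detection data.frame` (see [oracle_detector()]).
#' @param conf_min confidence threshold for acceptance.
#' @param encoder an [encoder_config()] used to produce the motion stream.
#' @param existing manual annotation data.frame to protect (optional).
#' @return `list(annotations, suggestions)`, both annotation data.frames.
#' @export
auto_annotate <- function(videos, detector, conf_min, encoder = encoder_config(),
                          existing = NULL) {
  acc <- list(); sug <- list()
  for (vid in names(videos)) {
    stream <- videos[[vid]]
    motion_frames <- encode_stream(stream, encoder)
    for (pos in seq_along(stream$frames)) {
      f <- stream$frames[[pos]]
      for (sname in c("static", "motion")) {
        if (!is.null(existing) && nrow(existing) > 0) {
          manual <- existing[existing$video_id == vid &
                             existing$frame == f$index &
                             existing$stream == sname &
                             existing$provenance == "manual", , drop = FALSE]
          if (nrow(manual) > 0) next
        }
        if (sname == "motion" && motion_frames[[pos]]$warm_up) next
        px <- if (sname == "static") f$pixels else motion_frames[[pos]]$pixels
        dets <- tryCatch(detector(px, sname, f$index, vid),
                         error = function(e) {
                           warning(sprintf("detector failed on %s frame %d (%s): skipped",
                                           vid, f$index, conditionMessage(e)))
                           NULL
                         })
        if (is.null(dets) || nrow(dets) == 0) next
        rec <- annotations(vid, f$index, sname, dets$class_name,
                           dets$x0, dets$y0, dets$x1, dets$y1,
                           kind = "label", confidence = dets$confidence,
                           provenance = "auto")
        keep <- rec$confidence >= conf_min
        if (any(keep)) acc[[length(acc) + 1L]] <- rec[keep, , drop = FALSE]
        if (any(!keep)) sug[[length(sug) + 1L]] <- rec[!keep, , drop = FALSE]
      }
    }
  }
  list(annotations = if (length(acc)) do.call(rbind, acc) else empty_annotations(),
       suggestions = if (length(sug)) do.call(rbind, sug) else empty_annotations())
}

#' Read / write the annotation store (JSON lines)
#'
#' The versioned store is the source of truth for annotations; the YOLO tree
#' is compiled from it.
#'
#' @param ann annotation data.frame.
#' @param path destination `.jsonl` path.
#' @return path (write) / annotation data.frame (read).
#' @export
write_annotation_store <- function(ann, path) {
  dir_create_for(path)
  lines <- vapply(seq_len(nrow(ann)), function(i) {
    jsonlite::toJSON(as.list(ann[i, ]), auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotation_store
#' @export
read_annotation_store <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_annotations())
  rows <- lapply(lines, function(l) {
    v <- jsonlite::fromJSON(l)
    v$confidence <- v$confidence %||% NA_real_
    as.data.frame(v, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
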