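# Duplicate-detection merging, class resolution across streams, and
# Kalman-filtered multi-object tracking with stable identities.
#
# Detections are rows of a data.frame with columns
#   frame, x0, y0, x1, y1, class_name, confidence, source
# (source is "static" or "motion"; merged clusters report "merged" when the
# members span both streams). The same object is routinely found by both the
# static and the motion detector; clusters of mutually close / overlapping
# boxes are replaced by one detection whose class is chosen by the
# dominant-source rule, while every member record is retained for output.

#' Intersection-over-union of two boxes
#'
#' @param a,b boxes `c(x0, y0, x1, y1)`.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @export
box_iou <- function(a, b) {
  ix <- min(a[3], b[3]) - max(a[1], b[1])
  iy <- min(a[4], b[4]) - max(a[2], b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (box_area(a) + box_area(b) - inter)
}

#' Tracker configuration
#'
#' @param theta_iou overlap threshold for linking duplicate detections.
#' @param theta_dist centroid-distance threshold for linking, as a fraction
#'   of the mean diagonal of the pair of boxes.
#' @param gate association gate in pixels; `NULL` selects an adaptive gate of
#'   `3 * sqrt(position covariance trace) + mean box diagonal` per track.
#' @param n_confirm detections needed before a track is confirmed.
#' @param max_misses consecutive missed frames before a track is lost.
#' @param q process-noise intensity (white-acceleration model), px^2/frame^4.
#' @param r measurement-noise variance, px^2.
#' @param dominant_source `"motion"`, `"static"` or `"confidence"` — which
#'   stream's class wins for merged detections.
#' @param min_track_length optional post-hoc filter: confirmed tracks shorter
#'   than this many observations are dropped from results (0 = keep all).
#' @return an object of class `tracker_config`.
#' @export
tracker_config <- function(theta_iou = 0.5, theta_dist = 0.5, gate = NULL,
                           n_confirm = 2L, max_misses = 15L,
                           q = 0.01, r = 1,
                           dominant_source = c("confidence", "motion", "static"),
                           min_track_length = 0L) {
  dominant_source <- match.arg(dominant_source)
  stopifnot(theta_iou > 0, theta_dist > 0, q >= 0, r > 0,
            n_confirm >= 1, max_misses >= 0)
  structure(list(theta_iou = theta_iou, theta_dist = theta_dist, gate = gate,
                 n_confirm = as.integer(n_confirm),
                 max_misses = as.integer(max_misses),
                 q = q, r = r, dominant_source = dominant_source,
                 min_track_length = as.integer(min_track_length)),
            class = "tracker_config")
}

det_frame <- function(frame = integer(), x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric(),
                      class_name = character(), confidence = numeric(),
                      source = character()) {
  data.frame(frame = frame, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
             class_name = class_name, confidence = confidence,
             source = source, stringsAsFactors = FALSE)
}

# pairwise link rule: overlap above theta_iou OR centroids closer than
# theta_dist times the mean diagonal of the pair
dets_linked <- function(bi, bj, cfg) {
  if (box_iou(bi, bj) > cfg$theta_iou) return(TRUE)
  d <- box_centroid(bi) - box_centroid(bj)
  sqrt(sum(d^2)) < cfg$theta_dist * (box_diag(bi) + box_diag(bj)) / 2
}

#' Merge duplicate detections within one frame
#'
#' Clusters detections by the transitive closure of the pairwise link rule
#' (IoU above `theta_iou`, or centroid distance below `theta_dist` times the
#' pair's mean box diagonal), iterated until the clustering is a fixed point,
#' so merging the output again changes nothing. Each cluster is replaced by
#' a single detection with the union box and the class/confidence given by
#' [resolve_class()]; the member records are retained in a `members`
#' list-column so both streams survive into the output.
#'
#' @param dets detection data.frame (one frame).
#' @param cfg a [tracker_config()].
#' @return detection data.frame with a `members` list-column.
#' @export
merge_detections <- function(dets, cfg = tracker_config()) {
  n <- nrow(dets)
  members <- if (is.null(dets$members)) {
    lapply(seq_len(n), function(i) dets[i, setdiff(names(dets), "members"), drop = FALSE])
  } else dets$members
  if (n <= 1L) {
    dets$members <- members
    return(dets)
  }
  boxes <- lapply(seq_len(n), function(i) as.numeric(dets[i, c("x0", "y0", "x1", "y1")]))

  repeat {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    linked_any <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (dets_linked(boxes[[i]], boxes[[j]], cfg)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) { parent[rj] <- ri; linked_any <- TRUE }
      }
    }
    if (!linked_any) break
    roots <- vapply(seq_len(n), find, integer(1))
    groups <- split(seq_len(n), roots)
    new_rows <- list(); new_boxes <- list(); new_members <- list()
    for (g in groups) {
      mem <- do.call(rbind, members[g])
      ub <- Reduce(box_union, boxes[g])
      res <- resolve_class(mem, cfg$dominant_source)
      src <- if (length(unique(mem$source)) > 1L) "merged" else mem$source[1]
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        frame = mem$frame[1], x0 = ub[1], y0 = ub[2], x1 = ub[3], y1 = ub[4],
        class_name = res$class_name, confidence = res$confidence,
        source = src, stringsAsFactors = FALSE)
      new_boxes[[length(new_boxes) + 1L]] <- ub
      new_members[[length(new_members) + 1L]] <- mem
    }
    dets <- do.call(rbind, new_rows)
    boxes <- new_boxes
    members <- new_members
    n <- nrow(dets)
    if (n <= 1L) break
  }
  dets$members <- members
  rownames(dets) <- NULL
  dets
}

#' Resolve the class of a merged detection cluster
#'
#' `mode = "motion"`: the highest-confidence motion-stream member wins,
#' falling back to static when the cluster has no motion member;
#' `mode = "static"` is the mirror image; `mode = "confidence"` takes the
#' globally highest confidence. Ties break to motion first, then first
#' occurrence (lowest class index).
#'
#' @param cluster data.frame of member detections.
#' @param mode `"motion"`, `"static"` or `"confidence"`.
#' @return `list(class_name, confidence)`.
#' @export
resolve_class <- function(cluster, mode = c("confidence", "motion", "static")) {
  mode <- match.arg(mode)
  stopifnot(nrow(cluster) >= 1L)
  pick_best <- function(df) {
    ord <- order(-df$confidence, match(df$source, c("motion", "static")),
                 seq_len(nrow(df)))
    df[ord[1], , drop = FALSE]
  }
  sub <- switch(mode,
    motion = if (any(cluster$source == "motion"))
      cluster[cluster$source == "motion", , drop = FALSE] else cluster,
    static = if (any(cluster$source == "static"))
      cluster[cluster$source == "static", , drop = FALSE] else cluster,
    confidence = cluster
  )
  best <- pick_best(sub)
  list(class_name = best$class_name, confidence = best$confidence)
}

#' Constant-velocity Kalman model
#'
#' State `x = (cx, cy, vx, vy)` with unit time step; position-only
#' measurements. Process noise follows the discrete white-acceleration model
#' `Q = q * G` with per-axis block `[[1/4, 1/2], [1/2, 1]]`.
#'
#' @param q process-noise intensity.
#' @param r measurement-noise variance (isotropic).
#' @return list with matrices `F`, `H`, `Q`, `R`.
#' @export
kalman_model <- function(q = 0.01, r = 1) {
  F <- diag(4); F[1, 3] <- 1; F[2, 4] <- 1
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  Q <- q * matrix(c(1/4, 0, 1/2, 0,
                    0, 1/4, 0, 1/2,
                    1/2, 0, 1, 0,
                    0, 1/2, 0, 1), 4, 4, byrow = TRUE)
  R <- r * diag(2)
  list(F = F, H = H, Q = Q, R = R)
}

new_track <- function(id, det, model) {
  cen <- box_centroid(as.numeric(det[c("x0", "y0", "x1", "y1")]))
  P <- diag(c(model$R[1, 1], model$R[1, 1], 25, 25))
  list(id = id,
       x = c(cen, 0, 0),
       P = P,
       size = c(det$x1 - det$x0, det$y1 - det$y0),
       status = "tentative",
       hits = 1L, misses = 0L,
       class_history = list(list(frame = det$frame, class_name = det$class_name,
                                 confidence = det$confidence,
                                 source = det$source)),
       secondary = NULL)
}

#' Kalman predict step
#'
#' `x <- F x`, `P <- F P F' + Q`, with symmetrization of `P` for numerical
#' stability.
#'
#' @param track a track (list with `x`, `P`).
#' @param model a [kalman_model()].
#' @return the predicted track.
#' @export
kf_predict <- function(track, model) {
  track$x <- as.numeric(model$F %*% track$x)
  P <- model$F %*% track$P %*% t(model$F) + model$Q
  track$P <- (P + t(P)) / 2
  track
}

#' Kalman update step
#'
#' Standard gain-form update with innovation `y = z - H x`; the posterior
#' covariance is symmetrized after `(I - K H) P`.
#'
#' @param track a predicted track.
#' @param z measurement `c(cx, cy)`.
#' @param model a [kalman_model()].
#' @return the updated track.
#' @export
kf_update <- function(track, z, model) {
  y <- z - as.numeric(model$H %*% track$x)
  S <- model$H %*% track$P %*% t(model$H) + model$R
  K <- track$P %*% t(model$H) %*% solve(S)
  track$x <- track$x + as.numeric(K %*% y)
  P <- (diag(4) - K %*% model$H) %*% track$P
  track$P <- (P + t(P)) / 2
  track
}

track_gate <- function(track, cfg) {
  cfg$gate %||%
    (3 * sqrt(track$P[1, 1] + track$P[2, 2]) + sqrt(sum(track$size^2)))
}

#' Associate detections with predicted tracks
#'
#' One-to-one assignment minimizing summed centroid distance (Hungarian
#' algorithm), with pairs beyond a track's gate excluded.
#'
#' @param tracks list of predicted tracks.
#' @param dets detection data.frame.
#' @param cfg a [tracker_config()].
#' @return `list(matches = 2-column matrix (track index, det index),
#'   unmatched_tracks, unmatched_dets)`.
#' @export
associate_detections <- function(tracks, dets, cfg = tracker_config()) {
  nt <- length(tracks); nd <- nrow(dets)
  if (nt == 0L || nd == 0L) {
    return(list(matches = matrix(integer(), 0, 2),
                unmatched_tracks = seq_len(nt),
                unmatched_dets = seq_len(nd)))
  }
  cen <- t(vapply(seq_len(nd), function(j) {
    box_centroid(as.numeric(dets[j, c("x0", "y0", "x1", "y1")]))
  }, numeric(2)))
  big <- 1e9
  cost <- matrix(big, nt, nd)
  for (i in seq_len(nt)) {
    g <- track_gate(tracks[[i]], cfg)
    p <- tracks[[i]]$x[1:2]
    d <- sqrt((cen[, 1] - p[1])^2 + (cen[, 2] - p[2])^2)
    cost[i, d <= g] <- d[d <= g]
  }
  # pad to square for the LSAP solver
  n <- max(nt, nd)
  cm <- matrix(big, n, n)
  cm[seq_len(nt), seq_len(nd)] <- cost
  sol <- as.integer(clue::solve_LSAP(cm))
  matches <- matrix(integer(), 0, 2)
  for (i in seq_len(nt)) {
    j <- sol[i]
    if (j <= nd && cost[i, j] < big) matches <- rbind(matches, c(i, j))
  }
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(nt), matches[, 1]),
       unmatched_dets = setdiff(seq_len(nd), matches[, 2]))
}

#' Create an empty tracker state
#'
#' @param cfg a [tracker_config()].
#' @param model a [kalman_model()]; defaults to one built from `cfg$q`,
#'   `cfg$r`.
#' @return an object of class `tracker_state`.
#' @export
new_tracker <- function(cfg = tracker_config(), model = NULL) {
  structure(list(tracks = list(), next_id = 1L, cfg = cfg,
                 model = model %||% kalman_model(cfg$q, cfg$r)),
            class = "tracker_state")
}

#' Advance the tracker by one frame
#'
#' Predict all live tracks, associate merged detections, update matched
#' tracks (confirming at `n_confirm` hits), age unmatched tracks (lost after
#' `max_misses` consecutive misses), and spawn tentative tracks from
#' unmatched detections. IDs increase strictly and are never reused.
#'
#' @param state a `tracker_state`.
#' @param dets merged detection data.frame for this frame (see
#'   [merge_detections()]).
#' @return `list(state, assignments)` where `assignments` maps detection rows
#'   to track ids (`NA` while a track is tentative it is still recorded, with
#'   `confirmed` flag).
#' @export
step_tracker <- function(state, dets) {
  cfg <- state$cfg; model <- state$model
  state$tracks <- lapply(state$tracks, kf_predict, model = model)
  assoc <- associate_detections(state$tracks, dets, cfg)

  assignments <- if (nrow(dets) > 0) {
    data.frame(det = seq_len(nrow(dets)), track_id = NA_integer_,
               confirmed = FALSE)
  } else data.frame(det = integer(), track_id = integer(), confirmed = logical())

  if (nrow(assoc$matches) > 0) for (k in seq_len(nrow(assoc$matches))) {
    i <- assoc$matches[k, 1]; j <- assoc$matches[k, 2]
    tr <- state$tracks[[i]]
    cen <- box_centroid(as.numeric(dets[j, c("x0", "y0", "x1", "y1")]))
    tr <- kf_update(tr, cen, model)
    tr$hits <- tr$hits + 1L; tr$misses <- 0L
    tr$size <- 0.7 * tr$size + 0.3 * c(dets$x1[j] - dets$x0[j],
                                       dets$y1[j] - dets$y0[j])
    if (tr$status == "tentative" && tr$hits >= cfg$n_confirm)
      tr$status <- "confirmed"
    tr$class_history[[length(tr$class_history) + 1L]] <-
      list(frame = dets$frame[j], class_name = dets$class_name[j],
           confidence = dets$confidence[j], source = dets$source[j])
    state$tracks[[i]] <- tr
    assignments$track_id[j] <- tr$id
    assignments$confirmed[j] <- tr$status == "confirmed"
  }

  for (i in assoc$unmatched_tracks) {
    tr <- state$tracks[[i]]
    tr$misses <- tr$misses + 1L
    if (tr$misses > cfg$max_misses) tr$status <- "lost"
    state$tracks[[i]] <- tr
  }
  state$tracks <- Filter(function(tr) tr$status != "lost", state$tracks)

  for (j in assoc$unmatched_dets) {
    tr <- new_track(state$next_id, dets[j, , drop = FALSE], model)
    if (cfg$n_confirm <= 1L) tr$status <- "confirmed"
    state$next_id <- state$next_id + 1L
    state$tracks[[length(state$tracks) + 1L]] <- tr
    assignments$track_id[j] <- tr$id
    assignments$confirmed[j] <- tr$status == "confirmed"
  }

  list(state = state, assignments = assignments)
}

#' Crop a detection and run the secondary classifier
#'
#' Implements the hierarchical primary/secondary dispatch: a detection whose
#' class belongs to a secondary group's primaries is cropped from the group's
#' configured stream and passed to the per-object classifier. Detections of
#' classes in `schema$ignore_secondary` are skipped with the reason recorded
#' (e.g., sexing a fly is pointless while its wing markings are blurred in
#' flight).
#'
#' @param det one detection row.
#' @param static_frame,motion_frame pixel arrays for the current frame.
#' @param schema a [class_schema()].
#' @param secondary_classifier function `(crop, group) -> list(label,
#'   confidence)`.
#' @return `list(group, label, confidence)` or `list(skipped = reason)`.
#' @export
dispatch_secondary <- function(det, static_frame, motion_frame, schema,
                               secondary_classifier) {
  if (det$class_name %in% schema$ignore_secondary)
    return(list(skipped = sprintf("class '%s' in ignore_secondary", det$class_name)))
  for (gname in names(schema$secondary)) {
    grp <- schema$secondary[[gname]]
    applies <- is.null(grp$primary_classes) ||
      det$class_name %in% grp$primary_classes
    if (!applies) next
    src <- if (identical(grp$stream, "motion")) motion_frame else static_frame
    h <- dim(src)[1]; w <- dim(src)[2]
    b <- box_clip(as.numeric(det[c("x0", "y0", "x1", "y1")]), w, h)
    if (is.null(b))
      return(list(skipped = "degenerate crop after clipping"))
    rows <- box_px_range(b[2], b[4], h)
    cols <- box_px_range(b[1], b[3], w)
    if (length(rows) == 0 || length(cols) == 0)
      return(list(skipped = "degenerate crop after clipping"))
    crop <- src[rows, cols, , drop = FALSE]
    res <- secondary_classifier(crop, gname)
    return(list(group = gname, label = res$label, confidence = res$confidence))
  }
  list(skipped = "no secondary group configured for this class")
}
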