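# Synthetic test scenes with exact ground truth.
#
# Emulates the situations the encoder and tracker are meant for: small
# targets moving over textured backgrounds with constant-velocity,
# accelerating, decelerating, turning or stationary kinematics; background
# distractor motion (swaying-vegetation style row drift); additive sensor
# noise; and camouflaged targets that are a perfect sub-sample of their
# surrounds and hence invisible until they move. Every frame comes with
# ground-truth boxes, centroids, velocities and track IDs, so downstream
# modules are testable without any real footage.

#' Specify one moving object
#'
#' Kinematics follow `p(t) = p0 + v0 t + a t^2 / 2` (positions in pixels,
#' time in frames); a nonzero `heading_turn` rotates the velocity by that many
#' degrees each frame, integrated stepwise.
#'
#' @param shape `"disc"`, `"square"` or `"triangle"`.
#' @param size object diameter (disc), side (square) or circumdiameter
#'   (triangle), in pixels; `>= 1`.
#' @param appearance either `list(type = "solid", gray = g)` for a uniform
#'   gray-level target, or `list(type = "background_patch")` for a camouflaged
#'   target whose pixels are sampled from the background at its starting
#'   footprint (pixel-identical to the background while it has not moved).
#' @param x0,y0 starting position (pixel coordinates, origin top-left).
#' @param v0 initial velocity `c(vx, vy)` in px/frame.
#' @param a acceleration `c(ax, ay)` in px/frame^2.
#' @param heading_turn degrees/frame of heading rotation (positive =
#'   clockwise in image coordinates).
#' @param t_start,t_end active half-open frame interval `[t_start, t_end)`;
#'   `t_end = Inf` means active to the end of the scene.
#' @param label class name recorded in the ground truth.
#' @return an object of class `object_spec`.
#' @export
object_spec <- function(shape = c("disc", "square", "triangle"),
                        size = 6,
                        appearance = list(type = "solid", gray = 1),
                        x0, y0, v0 = c(0, 0), a = c(0, 0),
                        heading_turn = 0,
                        t_start = 0L, t_end = Inf,
                        label = "object") {
  shape <- match.arg(shape)
  if (size < 1) stop("`size` must be >= 1 pixel", call. = FALSE)
  if (!is.list(appearance) || !appearance$type %in% c("solid", "background_patch"))
    stop("`appearance$type` must be \"solid\" or \"background_patch\"", call. = FALSE)
  structure(list(shape = shape, size = size, appearance = appearance,
                 p0 = c(x0, y0), v0 = as.numeric(v0), a = as.numeric(a),
                 heading_turn = as.numeric(heading_turn),
                 t_start = t_start, t_end = t_end, label = label),
            class = "object_spec")
}

#' Specify a scene
#'
#' @param width,height frame size in pixels (>= 8).
#' @param n_frames number of frames to render.
#' @param background one of `list(type = "uniform", gray = g)`,
#'   `list(type = "texture")` (static value-noise texture), or
#'   `list(type = "drifting_texture", amplitude = px)` (textured background
#'   with sinusoidal per-row horizontal drift, emulating swaying vegetation).
#' @param objects list of [object_spec()]s.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (`>= 0`), applied per frame after compositing.
#' @param seed integer scene seed; all randomness (texture, noise) derives
#'   from it through keyed substreams, so rendering is fully deterministic and
#'   adding an object never perturbs existing pixels' noise.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(width, height, n_frames,
                       background = list(type = "uniform", gray = 0.5),
                       objects = list(),
                       noise_sd = 0,
                       seed = 1L) {
  if (width < 8 || height < 8) stop("scene must be at least 8 x 8", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!background$type %in% c("uniform", "texture", "drifting_texture"))
    stop("unknown background type", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames), background = background,
                 objects = objects, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Object position at a frame
#'
#' Closed form `p0 + v0 t + a t^2 / 2` when `heading_turn == 0`; otherwise
#' stepwise integration with the velocity rotated each frame.
#'
#' @param obj an [object_spec()].
#' @param t frame index (must lie in the object's active interval).
#' @return `c(x, y)` in pixels.
#' @export
kinematics_position <- function(obj, t) {
  if (t < obj$t_start || t >= obj$t_end)
    stop(sprintf("frame %s outside active interval [%s, %s)", t,
                 obj$t_start, obj$t_end), call. = FALSE)
  kinematics_state(obj, t)$p
}

#' Object velocity at a frame
#'
#' @inheritParams kinematics_position
#' @return `c(vx, vy)` in px/frame.
#' @export
kinematics_velocity <- function(obj, t) {
  kinematics_state(obj, t)$v
}

kinematics_state <- function(obj, t) {
  tt <- t - obj$t_start
  if (obj$heading_turn == 0) {
    return(list(p = obj$p0 + obj$v0 * tt + obj$a * tt^2 / 2,
                v = obj$v0 + obj$a * tt))
  }
  th <- obj$heading_turn * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p <- obj$p0; v <- obj$v0
  if (tt > 0) {
    for (s in seq_len(tt)) {
      p <- p + v + obj$a / 2
      v <- as.numeric(rot %*% (v + obj$a))
    }
  }
  list(p = p, v = v)
}

# Anti-aliased coverage mask of a shape at a sub-pixel center position,
# by 4x4 supersampling within a local window. Returns a full-frame matrix.
render_mask <- function(shape, size, center, height, width, ss = 4L) {
  r <- size / 2
  mask <- matrix(0, height, width)
  cols <- box_px_range(center[1] - r - 1.5, center[1] + r + 1.5, width)
  rows <- box_px_range(center[2] - r - 1.5, center[2] + r + 1.5, height)
  if (length(cols) == 0 || length(rows) == 0) return(mask)
  off <- (seq_len(ss) - 0.5) / ss
  sx <- rep(off, times = ss); sy <- rep(off, each = ss)
  for (i in rows) {
    for (j in cols) {
      x <- (j - 1) + sx - center[1]
      y <- (i - 1) + sy - center[2]
      inside <- switch(shape,
        disc = (x^2 + y^2) <= r^2,
        square = (abs(x) <= r) & (abs(y) <= r),
        triangle = point_in_triangle(x, y, r)
      )
      mask[i, j] <- mean(inside)
    }
  }
  mask
}

# Equilateral triangle, apex up, circumradius r, centered at origin.
point_in_triangle <- function(x, y, r) {
  v <- list(c(0, -r),
            c(r * sin(2 * pi / 3), -r * cos(2 * pi / 3)),
            c(r * sin(4 * pi / 3), -r * cos(4 * pi / 3)))
  inside <- rep(TRUE, length(x))
  for (k in 1:3) {
    a <- v[[k]]; b <- v[[(k %% 3) + 1]]
    cross <- (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
    inside <- inside & (cross >= 0)
  }
  inside
}

# Value-noise texture: coarse uniform grid, bilinearly interpolated.
value_noise_texture <- function(height, width, seed, cell = 8L,
                                lo = 0.25, hi = 0.75) {
  gh <- ceiling(height / cell) + 2L
  gw <- ceiling(width / cell) + 2L
  grid <- with_seed(seed, matrix(stats::runif(gh * gw, lo, hi), gh, gw))
  ys <- (seq_len(height) - 0.5) / cell + 1
  xs <- (seq_len(width) - 0.5) / cell + 1
  bilinear_grid(grid, ys, xs)
}

bilinear_grid <- function(grid, ys, xs) {
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  g <- function(i, j) grid[cbind(pmin(pmax(i, 1), nrow(grid)),
                                 pmin(pmax(j, 1), ncol(grid)))]
  out <- matrix(0, length(ys), length(xs))
  for (jj in seq_along(xs)) {
    c00 <- g(y0, rep(x0[jj], length(ys)))
    c10 <- g(y0 + 1, rep(x0[jj], length(ys)))
    c01 <- g(y0, rep(x0[jj] + 1, length(ys)))
    c11 <- g(y0 + 1, rep(x0[jj] + 1, length(ys)))
    out[, jj] <- (1 - fy) * ((1 - fx[jj]) * c00 + fx[jj] * c01) +
      fy * ((1 - fx[jj]) * c10 + fx[jj] * c11)
  }
  out
}

# Horizontal per-row sinusoidal displacement of a texture, wrap-around,
# linear interpolation between columns.
drift_texture <- function(base, t, amplitude, row_period = 16, frame_period = 24) {
  h <- nrow(base); w <- ncol(base)
  out <- base
  for (i in seq_len(h)) {
    dx <- amplitude * sin(2 * pi * (i / row_period + t / frame_period))
    pos <- (seq_len(w) - 1 - dx) %% w
    j0 <- floor(pos); f <- pos - j0
    out[i, ] <- (1 - f) * base[i, (j0 %% w) + 1] + f * base[i, ((j0 + 1) %% w) + 1]
  }
  out
}

# Sample a matrix at real-valued (y, x) positions with clamped bilinear interp.
sample_bilinear <- function(m, ys, xs) {
  h <- nrow(m); w <- ncol(m)
  ys <- pmin(pmax(ys, 0.5), h - 0.5) + 0.5
  xs <- pmin(pmax(xs, 0.5), w - 0.5) + 0.5
  y0 <- pmin(floor(ys), h - 1); x0 <- pmin(floor(xs), w - 1)
  fy <- ys - y0; fx <- xs - x0
  idx <- function(i, j) m[cbind(pmin(pmax(i, 1), h), pmin(pmax(j, 1), w))]
  (1 - fy) * ((1 - fx) * idx(y0, x0) + fx * idx(y0, x0 + 1)) +
    fy * ((1 - fx) * idx(y0 + 1, x0) + fx * idx(y0 + 1, x0 + 1))
}

#' Render a scene and its ground truth
#'
#' Deterministic given the scene seed. Camouflaged (`background_patch`)
#' objects carry the background texture of their starting footprint with
#' them: while stationary at the start position they are pixel-identical to
#' the background (zero static contrast, zero motion energy); the first
#' movement displaces the patch and creates frame differences.
#'
#' @param spec a [scene_spec()].
#' @param quantize snap rendered frames to the 8-bit grid (the representable
#'   values of ordinary video); default `TRUE`.
#' @return `list(stream = frame_stream, truth = data.frame)` where `truth`
#'   has columns `frame, object_id, x0, y0, x1, y1, cx, cy, vx, vy, label`
#'   (boxes are tight integer bounds of the coverage mask at threshold 0.5).
#' @export
render_scene <- function(spec, quantize = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width
  bg <- spec$background
  base <- switch(bg$type,
    uniform = matrix(bg$gray %||% 0.5, h, w),
    texture = value_noise_texture(h, w, derive_seed(spec$seed, "background")),
    drifting_texture = value_noise_texture(h, w, derive_seed(spec$seed, "background"))
  )

  # pre-sample camouflage patches from the undrifted base texture
  patches <- lapply(spec$objects, function(obj) {
    if (obj$appearance$type != "background_patch") return(NULL)
    base
  })

  frames <- vector("list", spec$n_frames)
  truth <- list()
  for (t in seq_len(spec$n_frames) - 1L) {
    bgt <- if (bg$type == "drifting_texture") {
      drift_texture(base, t, bg$amplitude %||% 1)
    } else base
    px <- array(rep(bgt, 3L), dim = c(h, w, 3L))

    for (oi in seq_along(spec$objects)) {
      obj <- spec$objects[[oi]]
      if (t < obj$t_start || t >= obj$t_end) next
      st <- kinematics_state(obj, t)
      r <- obj$size / 2
      if (st$p[1] - r < 0 || st$p[2] - r < 0 ||
          st$p[1] + r > w || st$p[2] + r > h)
        stop(sprintf("object %d (%s) leaves the frame at frame %d",
                     oi, obj$label, t), call. = FALSE)
      mask <- render_mask(obj$shape, obj$size, st$p, h, w)
      cover <- mask >= 0.5
      if (!any(cover))
        stop(sprintf("object %d (%s) has no visible pixels at frame %d",
                     oi, obj$label, t), call. = FALSE)
      rr <- range(which(rowSums(cover) > 0))
      cc <- range(which(colSums(cover) > 0))
      bbox <- c(cc[1] - 1, rr[1] - 1, cc[2], rr[2])  # half-open px box

      if (obj$appearance$type == "solid") {
        val <- matrix(obj$appearance$gray, h, w)
      } else {
        # translate the starting-footprint patch with the object
        off <- st$p - obj$p0
        ii <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
        jj <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
        val <- matrix(sample_bilinear(patches[[oi]],
                                      as.vector(ii - off[2]),
                                      as.vector(jj - off[1])), h, w)
      }
      for (c in 1:3) px[, , c] <- (1 - mask) * px[, , c] + mask * val

      mtot <- sum(mask)
      cxy <- c(sum(matrix(rep(seq_len(w) - 0.5, each = h), h, w) * mask),
               sum(matrix(rep(seq_len(h) - 0.5, times = w), h, w) * mask)) / mtot
      truth[[length(truth) + 1L]] <- data.frame(
        frame = t, object_id = oi,
        x0 = bbox[1], y0 = bbox[2], x1 = bbox[3], y1 = bbox[4],
        cx = cxy[1], cy = cxy[2], vx = st$v[1], vy = st$v[2],
        label = obj$label, stringsAsFactors = FALSE)
    }

    if (spec$noise_sd > 0) {
      noise <- with_seed(derive_seed(spec$seed, "noise", t),
                         array(stats::rnorm(h * w * 3, 0, spec$noise_sd),
                               dim = c(h, w, 3L)))
      px <- px + noise
    }
    px <- clip01(px)
    if (quantize) px <- quantize8(px)
    frames[[t + 1L]] <- color_frame(px, index = t)
  }

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(frame = integer(), object_id = integer(),
               x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
               cx = numeric(), cy = numeric(), vx = numeric(), vy = numeric(),
               label = character(), stringsAsFactors = FALSE)
  list(stream = frame_stream(frames, fps = 30, frame_skip = 1L),
       truth = truth_df)
}

#' Write / read ground-truth records as CSV
#'
#' @param truth ground-truth data.frame from [render_scene()].
#' @param path destination `.csv`.
#' @return the path (write) or the data.frame (read).
#' @export
write_truth_csv <- function(truth, path) {
  dir_create_for(path)
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
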