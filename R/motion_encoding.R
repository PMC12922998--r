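# Color-from-motion encoding.
#
# The motion stream maps inter-frame luminance change into color so that the
# hue of a trail encodes time-since-motion: the absolute difference between
# successive luminance planes is smoothed over three timescales, the shortest
# feeding the blue channel and the longest the red. A moving object therefore
# leaves a tail fading white -> blue -> green -> red, whose length encodes
# speed and whose color gradient along the path encodes acceleration
# (an accelerating object outruns its red tail, a decelerating one is caught
# by it).
#
# Exponential strategy, per channel c with persistence weight w_c:
#     D_t   = |L_t - L_{t-1}|
#     M_c,t = w_c * M_c,t-1 + (1 - w_c) * D_t
#     O_c   = clip01(D_t + M_c,t)        (default)
#     O_c   = clip01(M_c,t)              (chromatic tails only)
# so M_c,t = sum_tau (1 - w_c) w_c^tau D_{t-tau}: w_c is the memory length.
#
# Sequential strategy: discrete lags instead of smoothing. With differences
# d_j = |L_{t-j+1} - L_{t-j}|, the newest difference d_1 enters every channel
# (rendering as white) and each older lag occupies exactly one channel,
# bluest = most recent:
#     O_B = clip01(d_1 + d_2), O_G = clip01(d_1 + d_3), O_R = clip01(d_1 + d_4)
#
# Either output may finally be blended with the current luminance plane,
# O'_c = (1 - beta) O_c + beta L, to restore spatial context.

#' Motion-encoder configuration
#'
#' @param strategy `"exponential"` (per-channel exponential smoothing of the
#'   frame difference) or `"sequential"` (discrete recent lags, one per
#'   channel).
#' @param weights persistence weights `(w_B, w_G, w_R)` in `[0, 1)`, strictly
#'   increasing: blue has the shortest memory, red the longest. Larger weights
#'   reach further back in time. Defaults separate the channel peaks over
#'   roughly 1-60 frames.
#' @param tails_only if `TRUE`, omit the raw (white) current difference and
#'   show the chromatic tails alone (exponential strategy only).
#' @param blend luminance blending proportion `beta` in `[0, 1]`; the output is
#'   `(1 - beta) * motion + beta * luminance`.
#' @param frame_skip encode every k-th source frame, extending the temporal
#'   window at no extra cost.
#' @param seq_depth number of chromatic lags for the sequential strategy
#'   (default 3: blue, green, red behind the white current difference).
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(strategy = c("exponential", "sequential"),
                           weights = c(0.5, 0.8, 0.95),
                           tails_only = FALSE,
                           blend = 0,
                           frame_skip = 1L,
                           seq_depth = 3L) {
  strategy <- match.arg(strategy)
  if (length(weights) != 3L || any(weights < 0) || any(weights >= 1) ||
      !(weights[1] < weights[2] && weights[2] < weights[3]))
    stop("`weights` must satisfy 0 <= w_B < w_G < w_R < 1", call. = FALSE)
  stopifnot_scalar_number(blend, "blend", 0, 1)
  frame_skip <- as.integer(frame_skip)
  if (is.na(frame_skip) || frame_skip < 1L)
    stop("`frame_skip` must be an integer >= 1", call. = FALSE)
  seq_depth <- as.integer(seq_depth)
  if (is.na(seq_depth) || seq_depth < 2L)
    stop("`seq_depth` must be an integer >= 2", call. = FALSE)
  structure(list(strategy = strategy,
                 weights = as.numeric(weights),
                 tails_only = isTRUE(tails_only),
                 blend = as.numeric(blend),
                 frame_skip = frame_skip,
                 seq_depth = seq_depth),
            class = "encoder_config")
}

#' SHA-256 fingerprint of an encoder configuration
#'
#' Stored in dataset metadata so that a change in motion settings is detected
#' and the motion images rebuilt (labels and splits untouched).
#'
#' @param config an [encoder_config()].
#' @return 64-character lowercase hex string.
#' @export
encoder_hash <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  stable_hash(encoder_config_yaml(config))
}

#' Serialize / deserialize an encoder configuration as YAML
#'
#' @param config an [encoder_config()].
#' @return `encoder_config_yaml()`: a YAML string; `encoder_config_from_yaml()`:
#'   an [encoder_config()].
#' @export
encoder_config_yaml <- function(config) {
  yaml::as.yaml(list(strategy = config$strategy,
                     weights = config$weights,
                     tails_only = config$tails_only,
                     blend = config$blend,
                     frame_skip = config$frame_skip,
                     seq_depth = config$seq_depth))
}

#' @rdname encoder_config_yaml
#' @param text YAML produced by `encoder_config_yaml()`.
#' @export
encoder_config_from_yaml <- function(text) {
  v <- yaml::yaml.load(text)
  encoder_config(strategy = v$strategy, weights = unlist(v$weights),
                 tails_only = v$tails_only, blend = v$blend,
                 frame_skip = v$frame_skip, seq_depth = v$seq_depth)
}

#' Initialize encoder state
#'
#' Accumulators start at zero; the ring buffer of recent luminance planes
#' (sequential strategy) starts empty.
#'
#' @param height,width frame dimensions in pixels.
#' @param config an [encoder_config()].
#' @return an object of class `encoder_state`.
#' @export
encoder_state <- function(height, width, config) {
  zero <- matrix(0, height, width)
  structure(list(M = list(B = zero, G = zero, R = zero),
                 prev = NULL,
                 ring = list(),
                 frames_seen = 0L,
                 config = config),
            class = "encoder_state")
}

#' Absolute luminance difference between two planes
#'
#' @param curr,prev [luminance_plane()]s of identical dimensions.
#' @return H x W matrix of `|curr - prev|` (class `diff_plane` attributes are
#'   not needed; the plain matrix is in `[0, 1]` by construction).
#' @export
frame_diff <- function(curr, prev) {
  a <- if (inherits(curr, "luminance_plane")) curr$pixels else curr
  b <- if (inherits(prev, "luminance_plane")) prev$pixels else prev
  if (!identical(dim(a), dim(b)))
    stop("luminance planes have mismatched dimensions", call. = FALSE)
  abs(a - b)
}

#' Update the exponential accumulators with a new difference plane
#'
#' Elementwise, for each channel `c`: `M_c <- w_c * M_c + (1 - w_c) * D`.
#' Accumulators are kept exact (no clipping); they remain in `[0, 1]` because
#' the recurrence is a convex combination of values in `[0, 1]`.
#'
#' @param state an [encoder_state()].
#' @param D difference matrix from [frame_diff()].
#' @param config an [encoder_config()] (exponential strategy).
#' @return the updated state.
#' @export
ema_update <- function(state, D, config = state$config) {
  if (!identical(dim(D), dim(state$M$B)))
    stop("difference plane does not match encoder state dimensions", call. = FALSE)
  w <- config$weights
  state$M$B <- w[1] * state$M$B + (1 - w[1]) * D
  state$M$G <- w[2] * state$M$G + (1 - w[2]) * D
  state$M$R <- w[3] * state$M$R + (1 - w[3]) * D
  state$frames_seen <- state$frames_seen + 1L
  state
}

motion_frame <- function(pixels, index, warm_up = FALSE) {
  structure(list(pixels = pixels, index = as.integer(index),
                 warm_up = isTRUE(warm_up)),
            class = "motion_frame")
}

#' Compose the exponential-strategy motion frame
#'
#' Default mode adds the current (white) difference to every channel's
#' accumulator; chromatic-tails-only mode shows the accumulators alone,
#' preserving more static luminance detail when blended.
#'
#' @param D current difference matrix.
#' @param state an [encoder_state()] already updated for this frame.
#' @param config an [encoder_config()].
#' @param index source frame number for the output.
#' @return a `motion_frame` (RGB array in `[0, 1]`), unblended.
#' @export
compose_exponential <- function(D, state, config = state$config, index = 0L) {
  h <- nrow(D); w <- ncol(D)
  out <- array(0, dim = c(h, w, 3L))
  if (config$tails_only) {
    out[, , 1] <- clip01(state$M$R)
    out[, , 2] <- clip01(state$M$G)
    out[, , 3] <- clip01(state$M$B)
  } else {
    out[, , 1] <- clip01(D + state$M$R)
    out[, , 2] <- clip01(D + state$M$G)
    out[, , 3] <- clip01(D + state$M$B)
  }
  motion_frame(out, index)
}

#' Compose the sequential-strategy motion frame
#'
#' With luminance planes `L_t, L_{t-1}, ...` in the ring (newest first) and
#' `d_j = |L_{t-j+1} - L_{t-j}|`, the newest difference `d_1` enters all three
#' channels (white) and lags `d_2 .. d_{seq_depth+1}` occupy blue, green, red
#' in order of age. With `seq_depth > 3` the extra, oldest lags are summed
#' into red.
#'
#' @param ring list of luminance matrices, newest first, length
#'   `>= seq_depth + 2` for a full composition.
#' @param config an [encoder_config()].
#' @param index source frame number for the output.
#' @return a `motion_frame`; all-black with `warm_up = TRUE` while the ring is
#'   still filling.
#' @export
compose_sequential <- function(ring, config, index = 0L) {
  need <- config$seq_depth + 2L
  if (length(ring) < need) {
    d <- dim(ring[[1]])
    return(motion_frame(array(0, dim = c(d[1], d[2], 3L)), index, warm_up = TRUE))
  }
  diffs <- lapply(seq_len(config$seq_depth + 1L), function(j) {
    abs(ring[[j]] - ring[[j + 1L]])
  })
  d1 <- diffs[[1]]
  h <- nrow(d1); w <- ncol(d1)
  chan <- list(B = 0, G = 0, R = 0)
  lag_channel <- rep(c("B", "G", "R"), c(1L, 1L, config$seq_depth - 2L))
  for (j in seq_len(config$seq_depth)) {
    ch <- lag_channel[j]
    chan[[ch]] <- chan[[ch]] + diffs[[j + 1L]]
  }
  out <- array(0, dim = c(h, w, 3L))
  out[, , 1] <- clip01(d1 + chan$R)
  out[, , 2] <- clip01(d1 + chan$G)
  out[, , 3] <- clip01(d1 + chan$B)
  motion_frame(out, index)
}

#' Blend a motion frame with the current luminance plane
#'
#' Convex combination `(1 - beta) * motion + beta * L` per channel; `beta = 0`
#' returns the motion frame unchanged, `beta = 1` the grayscale frame.
#'
#' @param motion a `motion_frame`.
#' @param L the current [luminance_plane()].
#' @param beta blending proportion in `[0, 1]`.
#' @return the blended `motion_frame`.
#' @export
blend_luminance <- function(motion, L, beta) {
  stopifnot_scalar_number(beta, "beta", 0, 1)
  if (beta == 0) return(motion)
  Lp <- if (inherits(L, "luminance_plane")) L$pixels else L
  if (!identical(dim(Lp), dim(motion$pixels)[1:2]))
    stop("luminance plane does not match motion frame dimensions", call. = FALSE)
  px <- motion$pixels
  for (c in 1:3) px[, , c] <- clip01((1 - beta) * px[, , c] + beta * Lp)
  motion$pixels <- px
  motion
}

#' Encode a frame stream into motion frames
#'
#' Runs the configured strategy over the whole stream, threading encoder state
#' internally. Output is index-aligned with the input: warm-up frames (before
#' the encoder has enough history — 1 frame for the exponential strategy,
#' `seq_depth + 1` for the sequential) are emitted all-black and flagged
#' `warm_up = TRUE`, never dropped. The function is pure: identical input and
#' configuration give bit-identical output.
#'
#' @param stream a [frame_stream()].
#' @param config an [encoder_config()].
#' @return list of `motion_frame` objects, one per input frame.
#' @export
encode_stream <- function(stream, config) {
  stopifnot(inherits(stream, "frame_stream"), inherits(config, "encoder_config"))
  dims <- frame_dims(stream)
  state <- encoder_state(dims[1], dims[2], config)
  out <- vector("list", length(stream$frames))
  for (i in seq_along(stream$frames)) {
    f <- stream$frames[[i]]
    L <- to_luminance(f)
    if (config$strategy == "exponential") {
      if (is.null(state$prev)) {
        mf <- motion_frame(array(0, dim = c(dims[1], dims[2], 3L)),
                           f$index, warm_up = TRUE)
      } else {
        D <- frame_diff(L$pixels, state$prev)
        state <- ema_update(state, D, config)
        mf <- compose_exponential(D, state, config, index = f$index)
      }
      state$prev <- L$pixels
    } else {
      state$ring <- c(list(L$pixels), state$ring)
      keep <- min(length(state$ring), config$seq_depth + 2L)
      state$ring <- state$ring[seq_len(keep)]
      mf <- compose_sequential(state$ring, config, index = f$index)
    }
    if (!mf$warm_up && config$blend > 0) {
      mf <- blend_luminance(mf, L, config$blend)
    }
    out[[i]] <- mf
  }
  out
}
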