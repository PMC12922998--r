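# Shared fixture builders: synthetic scenes, detection tables and small
# random streams, all generated in code at test time.

make_stream <- function(frames_px, fps = 30, frame_skip = 1L) {
  frames <- lapply(seq_along(frames_px), function(i) {
    color_frame(frames_px[[i]], index = (i - 1L) * frame_skip)
  })
  frame_stream(frames, fps = fps, frame_skip = frame_skip)
}

gray_frame <- function(g, h = 16, w = 16) array(g, dim = c(h, w, 3L))

# deterministic pseudo-random frame sequence in [0,1]
random_stream <- function(n, h = 12, w = 12, seed = 1) {
  set.seed(seed)
  make_stream(lapply(seq_len(n), function(i) {
    array(runif(h * w * 3), dim = c(h, w, 3L))
  }))
}

# constant-velocity disc on a uniform background
disc_scene <- function(n_frames = 40, size = c(64, 64), v = c(1.3, 0),
                       start = c(8, 32), disc_size = 6, seed = 5,
                       gray = 0.2, a = c(0, 0)) {
  obj <- object_spec("disc", size = disc_size,
                     appearance = list(type = "solid", gray = 1),
                     x0 = start[1], y0 = start[2], v0 = v, a = a,
                     label = "move")
  render_scene(scene_spec(size[1], size[2], n_frames,
                          background = list(type = "uniform", gray = gray),
                          objects = list(obj), seed = seed))
}

three_object_scene <- function(n_frames = 50, seed = 7) {
  objs <- list(
    object_spec("disc", 5, list(type = "solid", gray = 1),
                x0 = 10, y0 = 10, v0 = c(1, 0.3), label = "walk"),
    object_spec("square", 5, list(type = "solid", gray = 0.9),
                x0 = 10, y0 = 40, v0 = c(1, -0.2), label = "fly"),
    object_spec("disc", 5, list(type = "solid", gray = 0.8),
                x0 = 50, y0 = 55, v0 = c(-0.5, 0), label = "display"))
  render_scene(scene_spec(80, 72, n_frames,
                          background = list(type = "uniform", gray = 0.2),
                          objects = objs, seed = seed))
}

make_dets <- function(frame, x0, y0, x1, y1, class_name = "obj",
                      confidence = 1, source = "motion") {
  if (length(frame) == 0) {
    class_name <- character(0); confidence <- numeric(0); source <- character(0)
  }
  data.frame(frame = frame, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
             class_name = class_name, confidence = confidence,
             source = source, stringsAsFactors = FALSE)
}

random_det_set <- function(seed, n_max = 7, extent = 60) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  x0 <- runif(n, 0, extent); y0 <- runif(n, 0, extent)
  w <- runif(n, 4, 14); h <- runif(n, 4, 14)
  make_dets(0L, x0, y0, x0 + w, y0 + h,
            class_name = sample(c("a", "b"), n, replace = TRUE),
            confidence = runif(n, 0.4, 1),
            source = sample(c("static", "motion"), n, replace = TRUE))
}

# Independent clustering oracle: the transitive closure of the pairwise link
# rule, taken round by round — each round builds the full link graph among
# current cluster boxes (independently coded predicate), takes connected
# components by breadth-first search (a different algorithm than the
# implementation's union-find), replaces each component by its union box,
# and repeats until no links remain.
brute_force_clusters <- function(dets, cfg) {
  link <- function(a, b) {
    ia <- min(a[3], b[3]) - max(a[1], b[1])
    iy <- min(a[4], b[4]) - max(a[2], b[2])
    iou <- if (ia <= 0 || iy <= 0) 0 else {
      inter <- ia * iy
      inter / ((a[3]-a[1])*(a[4]-a[2]) + (b[3]-b[1])*(b[4]-b[2]) - inter)
    }
    if (iou > cfg$theta_iou) return(TRUE)
    ca <- c((a[1]+a[3])/2, (a[2]+a[4])/2); cb <- c((b[1]+b[3])/2, (b[2]+b[4])/2)
    diag_m <- (sqrt((a[3]-a[1])^2+(a[4]-a[2])^2) +
               sqrt((b[3]-b[1])^2+(b[4]-b[2])^2)) / 2
    sqrt(sum((ca - cb)^2)) < cfg$theta_dist * diag_m
  }
  clusters <- lapply(seq_len(nrow(dets)), function(i) i)
  boxes <- lapply(seq_len(nrow(dets)), function(i)
    as.numeric(dets[i, c("x0", "y0", "x1", "y1")]))
  repeat {
    n <- length(clusters)
    if (n <= 1) break
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      adj[i, j] <- adj[j, i] <- link(boxes[[i]], boxes[[j]])
    if (!any(adj)) break
    comp <- rep(NA_integer_, n); ncomp <- 0
    for (s in 1:n) {
      if (!is.na(comp[s])) next
      ncomp <- ncomp + 1
      queue <- s
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- ncomp
        queue <- c(queue, which(adj[v, ] & is.na(comp)))
      }
    }
    clusters <- lapply(split(seq_len(n), comp), function(idx)
      unlist(clusters[idx]))
    boxes <- lapply(split(seq_len(n), comp), function(idx) {
      bs <- boxes[idx]
      c(min(vapply(bs, `[`, 0, 1)), min(vapply(bs, `[`, 0, 2)),
        max(vapply(bs, `[`, 0, 3)), max(vapply(bs, `[`, 0, 4)))
    })
  }
  canonical_partition(clusters)
}

canonical_partition <- function(clusters) {
  parts <- lapply(unname(clusters), function(x) sort(unname(unlist(x))))
  parts[order(vapply(parts, min, numeric(1)))]
}

# Two straight constant-speed trajectories crossing at a given angle; returns
# per-frame noisy detection tables plus true positions.
crossing_scenario <- function(seed, n = 40, speed = 3, angle_deg = 60,
                              noise_sd = 1, box = 6) {
  th <- (angle_deg / 2) * pi / 180
  posA <- function(t) c(60, 40) + (t - n / 2) * speed * c(cos(th), sin(th))
  posB <- function(t) c(60, 40) + (t - n / 2) * speed * c(cos(-th), sin(-th))
  set.seed(seed)
  frames <- lapply(0:(n - 1), function(t) {
    pa <- posA(t); pb <- posB(t)
    za <- pa + rnorm(2, 0, noise_sd); zb <- pb + rnorm(2, 0, noise_sd)
    list(truth = rbind(pa, pb),
         dets = make_dets(t, c(za[1], zb[1]) - box / 2, c(za[2], zb[2]) - box / 2,
                          c(za[1], zb[1]) + box / 2, c(za[2], zb[2]) + box / 2))
  })
  frames
}

# Run the tracker over a crossing scenario; count identity swaps over frames
# where the two objects are separated by more than one box width (where
# identity is observable), and the post-convergence position RMSE.
run_crossing <- function(frames, q = 0.01, r = 1) {
  st <- new_tracker(tracker_config(q = q, r = r))
  maps <- list(); errs <- c()
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    out <- step_tracker(st, fr$dets)
    st <- out$state
    a <- out$assignments
    sepd <- sqrt(sum((fr$truth[1, ] - fr$truth[2, ])^2))
    if (k > 3 && sepd > 6) maps[[length(maps) + 1]] <- a$track_id
    if (k > 10) {
      for (tr in st$tracks) {
        j <- which(a$track_id == tr$id)
        if (length(j) == 1) errs <- c(errs, sum((tr$x[1:2] - fr$truth[j, ])^2))
      }
    }
  }
  m <- do.call(rbind, maps)
  swaps <- sum(apply(diff(m), 1, function(d) any(d != 0)))
  list(swaps = swaps, rmse = sqrt(mean(errs)))
}
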