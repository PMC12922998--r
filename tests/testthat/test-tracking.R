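test_that("IoU matches hand-computed overlaps and is symmetric and bounded", {
  a <- c(0, 0, 10, 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, c(20, 20, 30, 30)), 0)
  expect_equal(box_iou(a, c(5, 0, 15, 10)), 1 / 3)
  set.seed(51)
  for (i in 1:50) {
    b1 <- c(runif(2, 0, 20), 0, 0); b1[3:4] <- b1[1:2] + runif(2, 1, 10)
    b2 <- c(runif(2, 0, 20), 0, 0); b2[3:4] <- b2[1:2] + runif(2, 1, 10)
    v <- box_iou(b1, b2)
    expect_identical(v, box_iou(b2, b1))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("duplicate static+motion detections merge into one with both members", {
  dets <- make_dets(0L, c(10, 10), c(10, 10), c(20, 20), c(20, 20),
                    class_name = c("rest", "walk"), confidence = c(0.9, 0.6),
                    source = c("static", "motion"))
  m <- merge_detections(dets, tracker_config(dominant_source = "motion"))
  expect_equal(nrow(m), 1)
  expect_equal(m$source, "merged")
  expect_equal(nrow(m$members[[1]]), 2)
  expect_setequal(m$members[[1]]$source, c("static", "motion"))
  # motion-dominant resolution picks the motion class despite lower confidence
  expect_equal(m$class_name, "walk")
  expect_equal(m$confidence, 0.6)

  far <- make_dets(0L, c(0, 50), c(0, 50), c(5, 55), c(5, 55))
  m2 <- merge_detections(far, tracker_config())
  expect_equal(nrow(m2), 2)
  expect_equal(m2[, names(far)], far, ignore_attr = TRUE)
})

test_that("merging is transitive and idempotent", {
  # A~B, B~C but A and C disjoint: one cluster of three
  chain <- make_dets(0L, c(0, 6, 12), c(0, 0, 0), c(10, 16, 22), c(10, 10, 10))
  m <- merge_detections(chain, tracker_config())
  expect_equal(nrow(m), 1)
  expect_equal(as.numeric(m[1, c("x0", "y0", "x1", "y1")]), c(0, 0, 22, 10))
  expect_equal(nrow(m$members[[1]]), 3)

  set.seed(52)
  for (rep in 1:25) {
    dets <- random_det_set(rep + 100)
    cfg <- tracker_config()
    once <- merge_detections(dets, cfg)
    twice <- merge_detections(once, cfg)
    expect_equal(nrow(twice), nrow(once))
    expect_equal(twice[, c("x0", "y0", "x1", "y1")],
                 once[, c("x0", "y0", "x1", "y1")], ignore_attr = TRUE)
  }
})

test_that("merge clustering equals an independent iterated closure", {
  cfg <- tracker_config()
  for (seed in 1:60) {
    dets <- random_det_set(seed)
    m <- merge_detections(dets, cfg)
    got <- canonical_partition(lapply(m$members, function(mm)
      match(paste(mm$x0, mm$y0), paste(dets$x0, dets$y0))))
    want <- brute_force_clusters(dets, cfg)
    expect_identical(got, want)
  }
})

test_that("class resolution follows the dominant-source rule", {
  cluster <- data.frame(
    frame = 0L, x0 = 0, y0 = 0, x1 = 5, y1 = 5,
    class_name = c("rest", "walk"), confidence = c(0.9, 0.6),
    source = c("static", "motion"), stringsAsFactors = FALSE)
  expect_equal(resolve_class(cluster, "motion"),
               list(class_name = "walk", confidence = 0.6))
  expect_equal(resolve_class(cluster, "static"),
               list(class_name = "rest", confidence = 0.9))
  expect_equal(resolve_class(cluster, "confidence"),
               list(class_name = "rest", confidence = 0.9))
  # fallback when the preferred stream is absent
  only_static <- cluster[1, ]
  expect_equal(resolve_class(only_static, "motion")$class_name, "rest")
  # singleton under any mode
  for (mode in c("motion", "static", "confidence"))
    expect_equal(resolve_class(cluster[2, ], mode)$class_name, "walk")
})

test_that("Kalman predict advances linearly and inflates covariance", {
  model <- kalman_model(q = 0, r = 1)
  tr <- list(x = c(10, 10, 2, 0), P = diag(4))
  expect_equal(kf_predict(tr, model)$x, c(12, 10, 2, 0))
  tr2 <- list(x = c(0, 0, 1, 1), P = diag(4))
  expect_equal(kf_predict(kf_predict(tr2, model), model)$x[1:2], c(2, 2))

  model_q <- kalman_model(q = 0.5, r = 1)
  trq <- list(x = rep(0, 4), P = diag(4))
  p1 <- kf_predict(trq, model_q)
  expect_gt(sum(diag(p1$P)), sum(diag(trq$P)))
})

test_that("Kalman update honors the measurement and its noise limit", {
  model <- kalman_model(q = 0.01, r = 1)
  tr <- list(x = c(5, 5, 1, 0), P = diag(4))
  up <- kf_update(tr, c(5, 5), model)
  expect_equal(up$x[1:2], c(5, 5))
  expect_lt(sum(diag(up$P[1:2, 1:2])), sum(diag(tr$P[1:2, 1:2])))

  tiny_r <- kalman_model(q = 0.01, r = 1e-12)
  up2 <- kf_update(tr, c(7.3, 4.1), tiny_r)
  expect_equal(up2$x[1:2], c(7.3, 4.1), tolerance = 1e-6)
})

test_that("velocity estimates converge on noiseless constant-velocity truth", {
  model <- kalman_model(q = 0.01, r = 0.01)
  tr <- list(x = c(0, 0, 0, 0), P = diag(c(1, 1, 25, 25)))
  v <- c(1.7, -0.6)
  for (t in 1:20) {
    tr <- kf_predict(tr, model)
    tr <- kf_update(tr, v * t, model)
  }
  expect_lt(max(abs(tr$x[3:4] - v) / abs(v)), 0.01)
})

test_that("covariance stays symmetric positive-definite over 10^4 cycles", {
  model <- kalman_model(q = 0.05, r = 0.5)
  tr <- list(x = rep(0, 4), P = diag(4))
  set.seed(53)
  for (i in 1:10000) {
    tr <- kf_predict(tr, model)
    tr <- kf_update(tr, rnorm(2), model)
  }
  expect_equal(tr$P, t(tr$P))
  expect_true(all(eigen(tr$P, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("association matches within the gate and spawns outside it", {
  cfg <- tracker_config(gate = 10)
  st <- new_tracker(cfg)
  out <- step_tracker(st, make_dets(0L, 10, 10, 16, 16))
  st <- out$state
  expect_equal(length(st$tracks), 1)
  # detection near the prediction is matched to the same track
  out2 <- step_tracker(st, make_dets(1L, 11, 11, 17, 17))
  expect_equal(out2$assignments$track_id, st$tracks[[1]]$id)
  # detection far outside every gate spawns a new track id
  out3 <- step_tracker(out2$state, make_dets(2L, 60, 60, 66, 66))
  expect_equal(length(out3$state$tracks), 2)
  expect_gt(out3$assignments$track_id, st$tracks[[1]]$id)
})

test_that("starved tracks are lost after max_misses frames", {
  cfg <- tracker_config(max_misses = 3)
  st <- new_tracker(cfg)
  st <- step_tracker(st, make_dets(0L, 10, 10, 16, 16))$state
  for (t in 1:4) st <- step_tracker(st, make_dets(integer(0), numeric(0),
                                                  numeric(0), numeric(0),
                                                  numeric(0)))$state
  expect_equal(length(st$tracks), 0)
})

test_that("three separated objects yield a per-frame truth-to-track bijection", {
  sc <- three_object_scene(n_frames = 50)
  det <- oracle_detector(sc$truth)
  st <- new_tracker(tracker_config())
  id_map <- list()
  for (t in 0:49) {
    dets <- det(NULL, "motion", t)
    out <- step_tracker(st, merge_detections(dets, st$cfg))
    st <- out$state
    if (t >= 2) {
      a <- out$assignments
      expect_true(all(a$confirmed))
      truth_t <- sc$truth[sc$truth$frame == t, ]
      for (k in seq_len(nrow(a))) {
        cen <- c((dets$x0[k] + dets$x1[k]) / 2, (dets$y0[k] + dets$y1[k]) / 2)
        j <- which.min((truth_t$cx - cen[1])^2 + (truth_t$cy - cen[2])^2)
        key <- as.character(truth_t$object_id[j])
        if (is.null(id_map[[key]])) id_map[[key]] <- a$track_id[k]
        expect_equal(a$track_id[k], id_map[[key]])
      }
    }
  }
  expect_equal(length(unique(unlist(id_map))), 3)
})

test_that("a short occlusion resumes the same identity", {
  cfg <- tracker_config(max_misses = 10)
  st <- new_tracker(cfg)
  id <- NULL
  for (t in 0:19) {
    if (t %in% 8:10) {
      st <- step_tracker(st, make_dets(integer(0), numeric(0), numeric(0),
                                       numeric(0), numeric(0)))$state
      next
    }
    x <- 10 + 2 * t
    out <- step_tracker(st, make_dets(t, x - 3, 17, x + 3, 23))
    st <- out$state
    if (t == 5) id <- out$assignments$track_id
    if (t > 10) expect_equal(out$assignments$track_id, id)
  }
})

test_that("crossing trajectories keep identities and beat raw measurement noise", {
  res <- lapply(1:10, function(seed) run_crossing(crossing_scenario(seed)))
  swaps <- vapply(res, function(r) r$swaps, numeric(1))
  rmse <- vapply(res, function(r) r$rmse, numeric(1))
  expect_gte(sum(swaps == 0), 9)
  expect_lt(mean(rmse), 1)
})

test_that("secondary dispatch crops the configured stream and honors skips", {
  schema <- class_schema(
    primary_static = "rest", primary_motion = c("walk", "fly", "display"),
    secondary = list(sex = list(classes = c("male", "female"),
                                stream = "static")),
    ignore_secondary = c("display", "fly"),
    dominant_source = "motion")
  static_px <- array(0.3, c(40, 40, 3)); static_px[11:20, 11:20, 1] <- 0.9
  motion_px <- array(0, c(40, 40, 3))
  seen <- new.env()
  clf <- function(crop, group) {
    seen$dims <- dim(crop); seen$group <- group
    list(label = "male", confidence = 0.95)
  }
  det <- data.frame(frame = 1L, x0 = 10, y0 = 10, x1 = 20, y1 = 20,
                    class_name = "walk", confidence = 0.8, source = "motion",
                    stringsAsFactors = FALSE)
  res <- dispatch_secondary(det, static_px, motion_px, schema, clf)
  expect_equal(res$label, "male")
  expect_equal(seen$group, "sex")
  expect_equal(seen$dims, c(10, 10, 3))

  det_fly <- det; det_fly$class_name <- "fly"
  res2 <- dispatch_secondary(det_fly, static_px, motion_px, schema, clf)
  expect_match(res2$skipped, "ignore_secondary")

  det_out <- det; det_out$x0 <- -30; det_out$x1 <- -10
  res3 <- dispatch_secondary(det_out, static_px, motion_px, schema, clf)
  expect_match(res3$skipped, "degenerate")
})
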