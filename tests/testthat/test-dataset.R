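test_that("split assignment is a stable pure function with the right rate", {
  s1 <- assign_split("vid1", 0:499, seed = 4, p_val = 0.2)
  s2 <- assign_split("vid1", 0:499, seed = 4, p_val = 0.2)
  expect_identical(s1, s2)
  # different seed reshuffles
  s3 <- assign_split("vid1", 0:499, seed = 5, p_val = 0.2)
  expect_false(identical(s1, s3))
  # binomial plausibility at n = 2000
  frac <- mean(assign_split("v", 0:1999, seed = 1, p_val = 0.2) == "val")
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
  expect_error(assign_split("v", 1, seed = 1, p_val = 1.2), "p_val")
})

test_that("exclusive-videos mode partitions whole videos", {
  vids <- rep(sprintf("v%02d", 1:20), each = 25)
  frames <- rep(0:24, times = 20)
  side <- assign_split(vids, frames, seed = 2, p_val = 0.3,
                       mode = "exclusive_videos")
  tab <- table(vids, side)
  # each video entirely on one side
  expect_true(all(apply(tab > 0, 1, sum) == 1))
  expect_true(all(c("train", "val") %in% side))
})

test_that("YOLO labels round-trip within 0.5 px and full-frame boxes normalize", {
  classes <- c("walk", "fly", "rest")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "img.txt")

  full <- annotations("v", 0, "motion", "fly", 0, 0, 80, 60)
  write_labels(full, path, classes, 80, 60)
  expect_identical(readLines(path), "1 0.500000 0.500000 1.000000 1.000000")

  set.seed(41)
  n <- 25
  x0 <- runif(n, 0, 70); y0 <- runif(n, 0, 50)
  ann <- annotations("v", 0, "motion", sample(classes, n, replace = TRUE),
                     x0, y0, x0 + runif(n, 2, 10), y0 + runif(n, 2, 10))
  write_labels(ann, path, classes, 80, 60)
  back <- read_labels(path, classes, 80, 60)
  expect_identical(back$class_name, ann$class_name)
  for (col in c("x0", "y0", "x1", "y1"))
    expect_lt(max(abs(back[[col]] - ann[[col]])), 0.5)

  # a frame holding only shields compiles to an empty label file
  shields <- annotations("v", 0, "motion", NA_character_, 5, 5, 15, 15,
                         kind = "shield")
  write_labels(shields, path, classes, 80, 60)
  expect_identical(readLines(path), character(0))

  expect_error(write_labels(annotations("v", 0, "motion", "unknown", 0, 0, 5, 5),
                            path, classes, 80, 60), "class not in schema")
})

test_that("gray shields paint exactly 0.5 inside each box and nothing else", {
  px <- array(runif(40 * 40 * 3), c(40, 40, 3))
  expect_identical(apply_shields(px, NULL), px)

  whole <- apply_shields(px, data.frame(x0 = 0, y0 = 0, x1 = 40, y1 = 40))
  expect_true(all(whole == 0.5))

  one <- apply_shields(px, data.frame(x0 = 10, y0 = 5, x1 = 20, y1 = 15))
  expect_true(all(one[6:15, 11:20, ] == 0.5))
  mask <- array(TRUE, dim(px)); mask[6:15, 11:20, ] <- FALSE
  expect_identical(one[mask], px[mask])

  expect_warning(apply_shields(px, data.frame(x0 = -5, y0 = 0, x1 = 10, y1 = 10)),
                 "clipped")
})

test_that("motion_blocks_static shields motion boxes and drops conflicting labels", {
  px <- array(0.8, c(30, 30, 3))
  m_lab <- data.frame(x0 = 5, y0 = 5, x1 = 15, y1 = 15)

  off <- apply_motion_blocks_static(px, m_lab[0, ], NULL)
  expect_identical(off$pixels, px)

  on <- apply_motion_blocks_static(px, m_lab, NULL)
  expect_true(all(on$pixels[6:15, 6:15, ] == 0.5))
  expect_true(all(on$pixels[16:30, , ] == 0.8))

  s_lab <- annotations("v", 0, "static", c("rest", "rest"),
                       c(7, 20), c(7, 20), c(12, 25), c(12, 25))
  expect_warning(
    res <- apply_motion_blocks_static(px, m_lab, s_lab),
    "dropped")
  expect_equal(nrow(res$labels), 1)
  expect_equal(res$labels$x0, 20)
})

test_that("compiled datasets pair every image with a label file and crops per class", {
  sc <- three_object_scene(n_frames = 12)
  schema <- class_schema(
    primary_static = "rest",
    primary_motion = c("walk", "fly", "display"),
    secondary = list(sex = list(classes = c("male", "female"),
                                stream = "static")),
    dominant_source = "motion")
  tr <- sc$truth
  lab <- tr[tr$frame %in% c(3, 5, 7, 9), ]
  ann <- annotations("vidA", lab$frame, "motion", lab$label,
                     lab$x0, lab$y0, lab$x1, lab$y1)
  sexes <- c(walk = "male", fly = "male", display = "female")
  sec <- annotations("vidA", lab$frame, "static", unname(sexes[lab$label]),
                     lab$x0, lab$y0, lab$x1, lab$y1)
  ann <- rbind(ann, sec)

  root <- withr::local_tempdir()
  # secondary classes are labels for crops, not primary label files: restrict
  schema2 <- class_schema(
    primary_static = c("rest", "male", "female"),
    primary_motion = c("walk", "fly", "display"),
    secondary = list(sex = list(classes = c("male", "female"),
                                stream = "static")),
    dominant_source = "motion")
  build_dataset(list(vidA = sc$stream), ann, schema2, encoder_config(),
                seed = 3, p_val = 0.2, root = root)

  for (stream in c("static", "motion")) for (side in c("train", "val")) {
    imgs <- list.files(file.path(root, stream, "images", side))
    labs <- list.files(file.path(root, stream, "labels", side))
    expect_identical(sub("\\.png$", "", imgs), sub("\\.txt$", "", labs))
  }
  # 4 frames x 3 objects = 12 secondary boxes; counts split male/female 8/4
  males <- list.files(file.path(root, "secondary", "sex", "male"))
  females <- list.files(file.path(root, "secondary", "sex", "female"))
  expect_equal(length(males), 8)
  expect_equal(length(females), 4)
  meta <- jsonlite::read_json(file.path(root, "metadata.json"))
  expect_identical(meta$encoder_hash, encoder_hash(encoder_config()))
})

test_that("rebuilding is deterministic, config-gated, and touches motion images only", {
  sc <- disc_scene(n_frames = 10)
  tr <- sc$truth[sc$truth$frame %in% c(2, 4, 6), ]
  ann <- annotations("v1", tr$frame, "motion", "move",
                     tr$x0, tr$y0, tr$x1, tr$y1)
  schema <- class_schema(primary_motion = "move")
  cfg <- encoder_config()

  root1 <- withr::local_tempdir(); root2 <- withr::local_tempdir()
  build_dataset(list(v1 = sc$stream), ann, schema, cfg, 1, 0.2, root1)
  build_dataset(list(v1 = sc$stream), ann, schema, cfg, 1, 0.2, root2)
  tree_bytes <- function(root) {
    files <- sort(list.files(root, recursive = TRUE, full.names = FALSE))
    lapply(files, function(f) readBin(file.path(root, f), "raw",
                                      file.size(file.path(root, f))))
  }
  expect_identical(tree_bytes(root1), tree_bytes(root2))

  # no-op rebuild with the identical config
  snapshot <- tree_bytes(root1)
  expect_false(rebuild_motion(root1, list(v1 = sc$stream), cfg))
  expect_identical(tree_bytes(root1), snapshot)

  # strategy change rewrites motion images, leaves labels byte-identical
  cfg2 <- encoder_config(strategy = "sequential")
  expect_true(rebuild_motion(root1, list(v1 = sc$stream), cfg2))
  lab_files <- function(root) {
    f <- sort(list.files(file.path(root, c("static", "motion")),
                         recursive = TRUE, full.names = TRUE, pattern = "\\.txt$"))
    lapply(f, readLines)
  }
  expect_identical(lab_files(root1), lab_files(root2))
  m1 <- sort(list.files(file.path(root1, "motion", "images"), recursive = TRUE,
                        full.names = TRUE))
  m2 <- sort(list.files(file.path(root2, "motion", "images"), recursive = TRUE,
                        full.names = TRUE))
  changed <- mapply(function(a, b) !identical(readBin(a, "raw", file.size(a)),
                                              readBin(b, "raw", file.size(b))),
                    m1, m2)
  expect_true(any(changed))
  # static images untouched
  s1 <- sort(list.files(file.path(root1, "static", "images"), recursive = TRUE,
                        full.names = TRUE))
  s2 <- sort(list.files(file.path(root2, "static", "images"), recursive = TRUE,
                        full.names = TRUE))
  same <- mapply(function(a, b) identical(readBin(a, "raw", file.size(a)),
                                          readBin(b, "raw", file.size(b))),
                 s1, s2)
  expect_true(all(same))
  expect_identical(jsonlite::read_json(file.path(root1, "metadata.json"))$encoder_hash,
                   encoder_hash(cfg2))

  # missing source video names the video
  expect_error(rebuild_motion(root1, list(other = sc$stream), cfg),
               "v1")
})

test_that("annotations on warm-up motion frames are excluded with a warning", {
  sc <- disc_scene(n_frames = 8)
  tr0 <- sc$truth[sc$truth$frame == 0, ]
  ann <- annotations("v1", 0, "motion", "move", tr0$x0, tr0$y0, tr0$x1, tr0$y1)
  root <- withr::local_tempdir()
  expect_warning(
    build_dataset(list(v1 = sc$stream), ann, class_schema(primary_motion = "move"),
                  encoder_config(), 1, 0.2, root),
    "warm-up")
  expect_length(list.files(file.path(root, "motion", "images"),
                           recursive = TRUE), 0)
})

test_that("auto-annotation recovers oracle truth and respects the threshold", {
  sc <- disc_scene(n_frames = 10)
  det <- oracle_detector(sc$truth)
  res <- auto_annotate(list(v1 = sc$stream), det, conf_min = 0.5)
  got <- res$annotations
  expect_true(all(got$provenance == "auto"))
  expect_true(all(got$stream == "motion"))
  # warm-up frame 0 excluded; frames 1..9 each contribute the truth box
  expect_equal(sort(unique(got$frame)), 1:9)
  for (fr in 1:9) {
    truth_row <- sc$truth[sc$truth$frame == fr, ]
    got_row <- got[got$frame == fr, ]
    expect_equal(nrow(got_row), 1)
    expect_equal(as.numeric(got_row[c("x0", "y0", "x1", "y1")]),
                 as.numeric(truth_row[c("x0", "y0", "x1", "y1")]))
  }
  # impossible threshold accepts nothing
  res2 <- auto_annotate(list(v1 = sc$stream), det, conf_min = 1.01)
  expect_equal(nrow(res2$annotations), 0)
  expect_gt(nrow(res2$suggestions), 0)
  # manual annotations are never overwritten
  manual <- annotations("v1", 5, "motion", "move", 1, 1, 5, 5)
  res3 <- auto_annotate(list(v1 = sc$stream), det, conf_min = 0.5,
                        existing = manual)
  expect_false(5 %in% res3$annotations$frame)
})

test_that("the annotation store round-trips through JSON lines", {
  ann <- annotations(c("a", "a", "b"), c(0, 1, 4), c("motion", "static", "motion"),
                     c("walk", "rest", "fly"), 1, 2, 7.5, 9.25,
                     kind = c("label", "label", "shield"),
                     confidence = c(NA, 0.8, NA),
                     provenance = c("manual", "auto", "manual"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_annotation_store(ann, path)
  back <- read_annotation_store(path)
  expect_equal(back$video_id, ann$video_id)
  expect_equal(back$x1, ann$x1)
  expect_equal(back$confidence, ann$confidence)
  expect_equal(back$kind, ann$kind)
})
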