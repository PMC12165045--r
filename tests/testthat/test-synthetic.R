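test_that("plain elliptical shapes have the analytic area", {
  p <- shape_params(5, 2.5, bump_amp = 0, bump_width = 0.5)
  expect_lt(abs(polygon_area(generate_shape(p)) - pi * 12.5) / (pi * 12.5),
            0.01)
})

test_that("shape generation is deterministic and rotation is rigid", {
  p0 <- shape_params(5, 2.5, bump_amp = 0.15, bend = 0.1, orientation = 0)
  s0 <- generate_shape(p0)
  expect_identical(s0, generate_shape(p0))
  th <- 0.8
  p1 <- shape_params(5, 2.5, bump_amp = 0.15, bend = 0.1, orientation = th)
  s1 <- generate_shape(p1)
  ctr <- colMeans(s0)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rotated <- sweep(sweep(s0, 2, ctr) %*% t(R), 2, ctr, "+")
  expect_equal(unname(s1), unname(rotated), tolerance = 1e-12)
})

test_that("projection scales with position and preserves the centroid", {
  cam <- camera_model(96, 96, px_per_unit = 1, s_min = 1, s_max = 1)
  poly <- generate_shape(shape_params(5, 2.5))
  proj <- project_to_image(poly, c(48, 48), cam)
  shifted <- sweep(poly, 2, colMeans(poly)) + 48
  expect_equal(unname(proj), unname(shifted), tolerance = 1e-12)
  # apparent-area ratio between two scales follows similarity scaling
  cam2 <- camera_model(96, 96, px_per_unit = 3, s_min = 0.9, s_max = 1.1)
  center_pos <- c(48, 48)                       # scale s_max = 1.1
  corner_pos <- c(96, 96)                       # image corner: scale s_min
  a1 <- polygon_area(project_to_image(poly, center_pos, cam2))
  a2 <- polygon_area(project_to_image(poly, corner_pos, cam2))
  expect_equal(a2 / a1, (0.9 / 1.1)^2, tolerance = 1e-6)
  expect_equal(colMeans(project_to_image(poly, c(30, 60), cam2)), c(30, 60),
               tolerance = 1e-9)
})

test_that("weights are deterministic in world geometry at zero noise", {
  p <- shape_params(5, 2.5, bump_amp = 0)
  area <- polygon_area(generate_shape(p))
  wm <- weight_model(k = 2, p = 1, sigma = 0)
  expect_equal(assign_weight(p, wm), 2 * area)
  # position does not enter the weight: the model sees world geometry only
  expect_equal(assign_weight(p, wm), assign_weight(p, wm))
})

test_that("weight noise has the stated spread", {
  set.seed(8)
  p <- shape_params(5, 2.5)
  wm <- weight_model(k = 1.35, p = 1, sigma = 0.05)
  draws <- replicate(4000, assign_weight(p, wm))
  mu <- 1.35 * polygon_area(generate_shape(p))
  expect_lt(abs(sd(draws) - 0.05 * mu) / (0.05 * mu), 0.05)
})

test_that("datasets split exactly, stratify by animal, and reproduce", {
  ds <- make_dataset(40, seed = 7, render = FALSE)
  expect_equal(vapply(ds, length, 1L),
               c(train = 24L, val = 8L, test = 8L))
  animal_ids <- lapply(ds, function(s)
    unique(unlist(lapply(s, function(r)
      vapply(r$instances, function(i) i$animal_id, 1L)))))
  expect_length(intersect(animal_ids$train, animal_ids$test), 0)
  expect_length(intersect(animal_ids$train, animal_ids$val), 0)
  inst_ids <- unlist(lapply(unlist(ds, recursive = FALSE), function(r)
    vapply(r$instances, function(i) i$instance_id, 1L)))
  expect_false(any(duplicated(inst_ids)))
  expect_identical(ds, make_dataset(40, seed = 7, render = FALSE))
})

test_that("written datasets are byte-identical under the same seed", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  make_dataset(6, seed = 3, out_dir = d1, n_animals = 6)
  make_dataset(6, seed = 3, out_dir = d2, n_animals = 6)
  j1 <- readLines(file.path(d1, "train_coco.json"))
  j2 <- readLines(file.path(d2, "train_coco.json"))
  expect_identical(j1, j2)
  w1 <- read.csv(file.path(d1, "weights.csv"))
  expect_true(all(c("image_id", "instance_id", "animal_id", "weight_kg")
                  %in% names(w1)))
  # COCO annotations round-trip through the reader
  back <- read_coco(file.path(d1, "train_coco.json"))
  expect_gt(length(back$annotations), 0)
  expect_equal(ncol(back$annotations[[1]]$polygon), 2)
})

test_that("projected polygons rasterize consistently across resolutions", {
  cam <- camera_model(96, 96)
  poly <- generate_shape(shape_params(5.5, 2.8, bump_amp = 0.12))
  proj <- project_to_image(poly, c(48, 50), cam)
  m1 <- rasterize_contour(proj, 96, 96)
  # reference raster at 4x resolution, block-averaged back down
  m4 <- rasterize_contour(proj * 4 + 1.5, 384, 384)
  blk <- matrix(0, 96, 96)
  for (i in 1:96) {
    for (j in 1:96) {
      blk[i, j] <- mean(m4[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j)])
    }
  }
  hi <- (blk >= 0.5) * 1L
  inter <- sum(m1 & hi); un <- sum(m1 | hi)
  expect_gte(inter / un, 0.99)
})
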