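test_that("backbone emits the stride-4/8/16/32 pyramid", {
  cfg <- cien_config("desk")
  model <- cien_build(cfg, seed = 1)
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  bb <- extract_backbone_features(model, img)
  expect_equal(dim(bb$o1)[1:2], c(24, 24))
  expect_equal(dim(bb$o2)[1:2], c(12, 12))
  expect_equal(dim(bb$o3)[1:2], c(6, 6))
  expect_equal(dim(bb$o4)[1:2], c(3, 3))
  # determinism with fixed weights
  expect_identical(extract_backbone_features(model, img)$o4, bb$o4)
  expect_error(extract_backbone_features(model,
                                         array(0, c(50, 96, 3))),
               "divisible by 32")
})

test_that("the full-scale preset constructs and strides 768 x 576 inputs", {
  cfg <- cien_config("paper")
  expect_equal(cfg$n_vertices, 128)
  expect_equal(cfg$fprime_channels + 2, 256)
  expect_equal(cfg$heads, 8)
  expect_equal(cfg$csa_blocks, 2)
  model <- cien_build(cfg, seed = 1)
  img <- array(0.5, c(576, 768, 3))
  bb <- extract_backbone_features(model, img)
  expect_equal(dim(bb$o1)[1:2], c(144, 192))   # 576/4, 768/4
  expect_equal(dim(bb$o4)[1:2], c(18, 24))
})

test_that("deep aggregation follows the recursion and output contract", {
  cfg <- cien_config("desk")
  model <- cien_build(cfg, seed = 1)
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  bb <- extract_backbone_features(model, img)
  F <- ida_aggregate(model, list(bb$o1, bb$o2, bb$o3, bb$o4))
  expect_equal(dim(F), c(24, 24, 24))
  # a single-element series returns its (projected) input: no fusion nodes
  F1 <- ida_aggregate(model, list(bb$o1))
  p1 <- contourweight:::conv_fwd(model$ida$proj1, bb$o1)$Y
  expect_equal(F1, p1)
  # the n = 3 recursion is node(node(o1, o2), o3): dropping o4 must equal
  # re-running the explicit two-node composition
  F3 <- ida_aggregate(model, list(bb$o1, bb$o2, bb$o3))
  v2 <- contourweight:::upsample2_fwd(
    contourweight:::conv_fwd(model$ida$proj2, bb$o2)$Y)
  x1 <- contourweight:::conv_relu_fwd(model$ida$fuse1, p1 + v2)$Y
  v3 <- contourweight:::upsample2_fwd(contourweight:::upsample2_fwd(
    contourweight:::conv_fwd(model$ida$proj3, bb$o3)$Y))
  x2 <- contourweight:::conv_relu_fwd(model$ida$fuse2, x1 + v3)$Y
  expect_equal(F3, x2)
})

test_that("center heads have the contracted shapes and ranges", {
  cfg <- cien_config("desk")
  model <- cien_build(cfg, seed = 2)
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  bb <- extract_backbone_features(model, img)
  F <- ida_aggregate(model, list(bb$o1, bb$o2, bb$o3, bb$o4))
  heads <- predict_center_and_regression(model, F)
  expect_equal(dim(heads$heatmap), c(24, 24))
  expect_equal(dim(heads$reg), c(24, 24, 2 * cfg$n_vertices))
  expect_true(all(heads$heatmap > 0 & heads$heatmap < 1))
  # zeroed head weights: sigmoid(0) = 0.5 everywhere
  z <- model
  z$heat$c2$W[] <- 0; z$heat$c2$b[] <- 0
  hz <- predict_center_and_regression(z, F)
  expect_true(all(hz$heatmap == 0.5))
})

test_that("contour initialization adds offsets to the center cell", {
  reg <- array(0, c(8, 8, 12))                # N = 6 vertices
  init <- initialize_contours(rbind(c(3, 5)), reg)
  expect_length(init, 1)
  expect_equal(init[[1]], matrix(rep(c(3, 5), each = 6), 6, 2))
  offs <- matrix(seq(-0.6, 0.5, length.out = 12), 6, 2)
  reg[6, 4, ] <- as.vector(offs)              # cell (y=5, x=3), 1-indexed
  init2 <- initialize_contours(rbind(c(3, 5)), reg)
  expect_equal(init2[[1]], sweep(offs, 2, c(3, 5), "+"))
  expect_warning(initialize_contours(rbind(c(40, 2)), reg), "clamped")
})

test_that("positional embedding is the box normalization of the contour", {
  ct <- rbind(c(0, 0), c(2, 0), c(2, 4), c(0, 4))
  expect_equal(contour_positional_embedding(ct), box_normalize(ct))
})

test_that("a freshly built CSA block is the identity on contours", {
  cfg <- cien_config("desk")
  model <- cien_build(cfg, seed = 3)
  Fp <- array(rnorm(24 * 24 * cfg$fprime_channels),
              c(24, 24, cfg$fprime_channels))
  ct <- cbind(runif(cfg$n_vertices, 4, 20), runif(cfg$n_vertices, 4, 20))
  r <- csa_refine(model, ct, Fp, block = 1)
  expect_equal(r$refined, ct)                 # zero-initialized offset head
  expect_equal(dim(r$offsets), c(cfg$n_vertices, 2))
  # point-feature width is F' channels + 2 positional channels
  expect_equal(model$csa[[1]]$mhsa$d, cfg$fprime_channels + 2)
})

test_that("focal loss matches a hand-evaluated tiny heatmap", {
  tgt <- matrix(c(1, 0.5, 0.2, 0), 2, 2)
  p <- matrix(0.5, 2, 2)
  by_hand <- -( (1 - 0.5)^2 * log(0.5) +
                  (1 - 0.5)^4 * 0.25 * log(0.5) +
                  (1 - 0.2)^4 * 0.25 * log(0.5) +
                  (1 - 0)^4 * 0.25 * log(0.5) ) / 1
  r <- focal_heatmap_loss(p, tgt)
  expect_equal(r$loss, by_hand, tolerance = 1e-12)
  # near-perfect prediction drives the loss toward zero
  good <- ifelse(tgt >= 1, 1 - 1e-7, 1e-7)
  expect_lt(focal_heatmap_loss(good, tgt)$loss, 1e-5)
  # duplicating objects doubles the sum but the per-object loss is stable
  tgt2 <- cbind(tgt, tgt)
  p2 <- cbind(p, p)
  expect_equal(focal_heatmap_loss(p2, tgt2)$loss, r$loss, tolerance = 1e-12)
  expect_warning(focal_heatmap_loss(p, matrix(0, 2, 2)), "no objects")
})

test_that("focal gradient matches finite differences", {
  set.seed(6)
  tgt <- matrix(runif(16), 4, 4)^2
  tgt[2, 3] <- 1
  logits <- matrix(rnorm(16), 4, 4)
  p <- 1 / (1 + exp(-logits))
  r <- focal_heatmap_loss(p, tgt)
  h <- 1e-6
  for (idx in list(c(2, 3), c(1, 1), c(4, 2))) {
    l1 <- logits; l1[idx[1], idx[2]] <- l1[idx[1], idx[2]] + h
    l2 <- logits; l2[idx[1], idx[2]] <- l2[idx[1], idx[2]] - h
    num <- (focal_heatmap_loss(1 / (1 + exp(-l1)), tgt)$loss -
              focal_heatmap_loss(1 / (1 + exp(-l2)), tgt)$loss) / (2 * h)
    expect_equal(r$grad_logits[idx[1], idx[2]], num, tolerance = 1e-4)
  }
})

test_that("the total loss uses the 1 / 0.5 / 0.5 / 1 stage weights", {
  expect_equal(cien_total_loss(1, 1, 1, 1), 3)
  expect_equal(cien_total_loss(0, 0, 0, 0), 0)
  expect_equal(cien_total_loss(0.2, 0.4, 0.6, 0.8), 1.5)
})

test_that("a short training run is deterministic and reduces the loss", {
  ds <- tiny_scene_dataset(24, seed = 7)
  cfg <- cien_config("desk", epochs = 4)
  t1 <- train_cien(ds$train, cfg, seed = 11)
  expect_true(all(is.finite(t1$history$total)))
  expect_lt(t1$history$total[4], t1$history$total[1])
  cfg1 <- cien_config("desk", epochs = 1)
  a <- train_cien(ds$train, cfg1, seed = 11)
  b <- train_cien(ds$train, cfg1, seed = 11)
  expect_identical(a$history$total[1], b$history$total[1])
  # vertex count is conserved through initialization and both CSA blocks
  dets <- cien_infer(t1$model, ds$train[[1]]$image, threshold = 0.05)
  if (length(dets) > 0)
    expect_true(all(vapply(dets, function(d) nrow(d$contour), 1) ==
                      cfg$n_vertices))
  expect_error(train_cien(list(), cfg), "empty")
})

test_that("the hard-assignment supervision variant trains through the same loop", {
  ds <- tiny_scene_dataset(16, seed = 8)
  cfg <- cien_config("desk", epochs = 2, supervision = "km")
  t1 <- train_cien(ds$train, cfg, seed = 12)
  expect_true(all(is.finite(t1$history$total)))
})
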