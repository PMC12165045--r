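test_that("arc-length resampling spaces points uniformly and preserves corners", {
  sq <- unit_square()
  s8 <- sample_contour_points(sq, 8)
  gaps <- sqrt(rowSums((s8[c(2:8, 1), ] - s8)^2))
  expect_true(all(abs(gaps - 0.5) < 1e-9 * 4))
  # starting at a corner with count 4 recovers the corners in order
  expect_equal(unname(sample_contour_points(sq, 4)), unname(sq),
               tolerance = 1e-12)
})

test_that("N-point sample nests exactly inside the 4N-point sample at phase 0", {
  set.seed(42)
  for (rep in 1:5) {
    n_v <- sample(5:12, 1)
    poly <- random_convex(n_v, seed = rep)$points * 10
    a <- sample_contour_points(poly, 16, phase = 0)
    b <- sample_contour_points(poly, 64, phase = 0)
    expect_equal(unname(a), unname(b[seq(1, 64, by = 4), ]))
  }
})

test_that("degenerate polygons are rejected", {
  degenerate <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_error(sample_contour_points(degenerate, 8), "degenerate contour")
})

test_that("box normalization maps extrema to the unit square", {
  r <- box_normalize(rbind(c(0, 0), c(2, 0), c(2, 4), c(0, 4)))
  expect_equal(unname(r), unname(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
  # identity on points already spanning [0,1]^2
  p <- rbind(c(0, 0), c(1, 0.3), c(0.4, 1), c(0.2, 0.6))
  expect_equal(unname(box_normalize(p)), unname(p))
  set.seed(1)
  q <- box_normalize(matrix(rnorm(256), ncol = 2))
  expect_equal(range(q[, 1]), c(0, 1))
  expect_equal(range(q[, 2]), c(0, 1))
  expect_error(box_normalize(cbind(rep(1, 5), 1:5)), "degenerate box")
})

test_that("greedy multi-start TSP recovers the square perimeter", {
  sq <- unit_square()[c(3, 1, 4, 2), ]
  r <- order_points_tsp(sq)
  expect_equal(r$length, 4)
  expect_error(order_points_tsp(sq[1:2, ]), "at least 3")
})

test_that("TSP ordering matches the brute-force shortest tour on convex sets", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:7, 1)
    cfg <- random_convex(n, seed = s + 100)
    r <- order_points_tsp(cfg$shuffled)
    expect_equal(r$length, brute_force_tour_length(cfg$points),
                 tolerance = 1e-9)
  }
})

test_that("TSP never returns a longer tour than the input ordering", {
  set.seed(9)
  for (rep in 1:5) {
    pts <- random_convex(8, seed = rep + 200)$points
    d <- as.matrix(stats::dist(pts))
    input_len <- sum(d[cbind(1:8, c(2:8, 1))])
    expect_lte(order_points_tsp(pts)$length, input_len + 1e-12)
  }
  # duplicate points are allowed
  expect_silent(order_points_tsp(rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1))))
})

test_that("rasterization reproduces analytic areas", {
  sq <- rbind(c(10, 10), c(60, 10), c(60, 60), c(10, 60))
  m <- rasterize_contour(sq, 256, 256)
  expect_lt(abs(sum(m) - 2500) / 2500, 0.01)
  # entirely outside the image
  far <- sq + 1000
  expect_equal(sum(rasterize_contour(far, 256, 256)), 0)
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  el <- cbind(128 + 40 * cos(th), 128 + 20 * sin(th))
  expect_lt(abs(sum(rasterize_contour(el, 256, 256)) - pi * 800) / (pi * 800),
            0.02)
  bow <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_warning(rasterize_contour(bow, 16, 16), "self-intersecting")
})

test_that("rasterize -> boundary re-extraction -> rasterize is stable", {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  el <- cbind(48 + 20 * cos(th), 40 + 12 * sin(th))
  m1 <- rasterize_contour(el, 96, 96)
  # boundary pixels: mask cells with a 4-neighbour background cell
  pad <- matrix(0L, 98, 98)
  pad[2:97, 2:97] <- m1
  interior <- pad[1:96, 2:97] & pad[3:98, 2:97] &
    pad[2:97, 1:96] & pad[2:97, 3:98]
  bd <- which(m1 == 1L & !interior, arr.ind = TRUE)
  pts <- cbind(bd[, 2] - 1, bd[, 1] - 1)
  m2 <- rasterize_contour(order_points_tsp(pts)$contour, 96, 96,
                          check_simple = FALSE)
  perim <- sum(m1 == 1L & !interior)
  expect_lt(abs(sum(m2) - sum(m1)), perim)
})

test_that("mask AP follows the COCO matching conventions", {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  mk <- function(cx, cy, r) rasterize_contour(
    cbind(cx + r * cos(th), cy + r * sin(th)), 96, 96)
  a <- mk(30, 30, 12); b <- mk(70, 60, 15)
  perfect <- mask_ap(list(list(mask = a, score = 0.9),
                          list(mask = b, score = 0.4)),
                     list(list(mask = a), list(mask = b)))
  expect_equal(perfect$ap, 1)
  expect_equal(perfect$ap50, 1)
  expect_equal(perfect$ap75, 1)
  disjoint <- mask_ap(list(list(mask = a, score = 0.9)),
                      list(list(mask = mk(70, 60, 10))))
  expect_equal(disjoint$ap, 0)
  # a prediction at IoU 0.6: counts at the 0.5 threshold, not at 0.75
  sq <- function(x0, w) rasterize_contour(
    rbind(c(x0, 10), c(x0 + w, 10), c(x0 + w, 40), c(x0, 40)), 96, 96)
  p <- sq(10, 40); t <- sq(20, 40)  # overlap 30/union 50 = 0.6
  one <- mask_ap(list(list(mask = p, score = 1)), list(list(mask = t)))
  expect_equal(one$ap50, 1)
  expect_equal(one$ap75, 0)
  # empty-truth conventions
  expect_equal(mask_ap(list(list(mask = a, score = 1)), list())$ap, 0)
  expect_true(mask_ap(list(), list())$skipped)
})

test_that("regression metrics match hand arithmetic", {
  exact <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(exact$mae, 0)
  expect_equal(exact$r2, 1)
  one <- regression_metrics(110, 100)
  expect_equal(one$mae, 10)
  expect_equal(one$mse, 100)
  expect_equal(one$mape, 10)
  two <- regression_metrics(c(60, 90), c(50, 100))
  expect_equal(two$mae, 10)
  expect_equal(two$mse, 100)
  expect_equal(two$mape, 15)
  expect_equal(two$r2, 1 - 200 / 1250)
  expect_error(regression_metrics(1, 0), "MAPE")
  expect_true(is.nan(regression_metrics(c(1, 2), c(5, 5))$r2))
})

test_that("COCO files round-trip through the reader", {
  tmp <- tempfile(fileext = ".json")
  poly <- rbind(c(3, 4), c(20, 5), c(18, 30), c(2, 28))
  images <- data.frame(id = 1L, file_name = "x.png", height = 96, width = 96)
  write_coco(images, list(list(id = 7L, image_id = 1L, polygon = poly)), tmp)
  back <- read_coco(tmp)
  expect_equal(back$images$file_name, "x.png")
  expect_equal(unname(back$annotations[[1]]$polygon), unname(poly))
  expect_equal(back$annotations[[1]]$id, 7L)
})
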