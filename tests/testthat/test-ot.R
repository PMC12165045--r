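test_that("cost matrices are plain Euclidean distances", {
  p <- matrix(runif(10), 5, 2)
  C <- build_cost_matrix(p, p)
  expect_equal(diag(C), rep(0, 5))
  expect_equal(build_cost_matrix(matrix(c(0, 0), 1),
                                 matrix(c(3, 4), 1))[1, 1], 5)
  set.seed(2)
  a <- matrix(runif(8), 4, 2); b <- matrix(runif(8), 4, 2)
  loop <- outer(1:4, 1:4, Vectorize(function(i, j)
    sqrt(sum((a[i, ] - b[j, ])^2))))
  expect_equal(build_cost_matrix(a, b), loop)
  expect_error(build_cost_matrix(matrix(0, 0, 2), b), "empty")
})

test_that("regularized OT equals the distance for single atoms", {
  a <- discrete_measure(matrix(c(0, 0), 1))
  b <- discrete_measure(matrix(c(3, 4), 1))
  expect_equal(sinkhorn_ot(a, b)$value, 5, tolerance = 1e-9)
  expect_equal(debiased_divergence(a, b), 5, tolerance = 1e-9)
})

test_that("regularized OT does not vanish for identical measures", {
  m <- random_measure(6, seed = 10)
  expect_gt(sinkhorn_ot(m, m)$value, 0)
})

test_that("annealed Sinkhorn approaches the exact assignment cost", {
  cfg <- sinkhorn_config(epsilon_target = 1e-3)
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:8, 1)
    P <- matrix(runif(2 * n), n, 2); Q <- matrix(runif(2 * n), n, 2)
    v <- sinkhorn_ot(discrete_measure(P), discrete_measure(Q), cfg)$value
    exact <- exact_ot_uniform(P, Q)
    expect_lt(abs(v - exact) / exact, 0.02)
  }
})

test_that("value decreases monotonically toward exact OT as epsilon shrinks", {
  set.seed(30)
  P <- matrix(runif(12), 6, 2); Q <- matrix(runif(12), 6, 2)
  am <- discrete_measure(P); bm <- discrete_measure(Q)
  vals <- vapply(c(0.5, 0.1, 0.02, 4e-3, 1e-3), function(e)
    sinkhorn_ot(am, bm, sinkhorn_config(epsilon_target = e))$value, 1)
  expect_true(all(diff(vals) < 1e-6))
  expect_lt(abs(vals[5] - exact_ot_uniform(P, Q)), 0.02 * vals[5])
})

test_that("debiased divergence is zero at identity, symmetric, nonnegative", {
  for (s in 1:25) {
    am <- random_measure(8, seed = s)
    bm <- random_measure(8, seed = s + 1000)
    lab <- debiased_divergence(am, bm)
    lba <- debiased_divergence(bm, am)
    expect_gte(lab, -1e-9)
    expect_lt(abs(lab - lba), 1e-9)
    diam <- max(build_cost_matrix(am$locations, am$locations))
    expect_lt(abs(debiased_divergence(am, am)), 1e-6 * max(diam, 1e-3))
  }
})

test_that("transport plan satisfies its marginals at convergence", {
  am <- random_measure(8, seed = 77)
  bm <- random_measure(8, seed = 78)
  sol <- sinkhorn_ot(am, bm, sinkhorn_config(tol = 1e-12, max_iters = 20000))
  gam <- transport_plan(am, bm, sol)
  expect_true(all(gam >= 0))
  expect_lt(max(abs(rowSums(gam) - am$weights)), 1e-6)
  expect_lt(max(abs(colSums(gam) - bm$weights)), 1e-6)
})

test_that("analytic gradients vanish at identity and point along the cost", {
  m <- random_measure(6, seed = 21)
  cfg <- sinkhorn_config(tol = 1e-12, max_iters = 5000)
  du <- debiased_divergence(m, m, cfg, with_duals = TRUE)
  g0 <- ot_gradient(m, m, du)
  expect_lt(max(abs(g0)), 1e-8)
  a <- discrete_measure(matrix(c(0, 0), 1))
  b <- discrete_measure(matrix(c(3, 4), 1))
  du1 <- debiased_divergence(a, b, cfg, with_duals = TRUE)
  expect_equal(ot_gradient(a, b, du1)[1, ], c(-0.6, -0.8), tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  set.seed(3)
  P <- matrix(runif(12), 6, 2); Q <- matrix(runif(12), 6, 2)
  am <- discrete_measure(P); bm <- discrete_measure(Q)
  cfg <- sinkhorn_config(tol = 1e-12, max_iters = 5000)
  du <- debiased_divergence(am, bm, cfg, with_duals = TRUE)
  gr <- ot_gradient(am, bm, du)
  h <- 1e-5
  fd <- matrix(0, 6, 2)
  for (i in 1:6) {
    for (k in 1:2) {
      Pp <- P; Pp[i, k] <- Pp[i, k] + h
      Pm <- P; Pm[i, k] <- Pm[i, k] - h
      fd[i, k] <- (debiased_divergence(discrete_measure(Pp), bm, cfg) -
                     debiased_divergence(discrete_measure(Pm), bm, cfg)) /
        (2 * h)
    }
  }
  expect_lt(max(abs(gr - fd)) / max(abs(fd)), 1e-3)
})

test_that("Kuhn-Munkres matches brute force and handles crossings", {
  p5 <- matrix(runif(10), 5, 2)
  ident <- km_hard_assign(p5, p5)
  expect_equal(ident$permutation, 1:5)
  expect_equal(ident$loss, 0)
  # two points where the crossed matching is cheaper
  pred <- rbind(c(0, 0), c(10, 0))
  truth <- rbind(c(11, 0), c(1, 0))
  km <- km_hard_assign(pred, truth)
  expect_equal(km$permutation, c(2L, 1L))
  for (s in 1:30) {
    set.seed(s)
    n <- sample(2:7, 1)
    pred <- matrix(runif(2 * n), n, 2)
    truth <- matrix(runif(2 * n), n, 2)
    km <- km_hard_assign(pred, truth)
    expect_equal(km$matched_cost,
                 brute_force_assignment_cost(build_cost_matrix(pred, truth)),
                 tolerance = 1e-9)
  }
  expect_error(km_hard_assign(matrix(0, 3, 2), matrix(0, 4, 2)), "equal")
})
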