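# Shared fixture builders. Everything is generated in code at test time.

unit_square <- function() rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

# n points on a random convex polygon (circle with jittered radii, sorted
# angles), returned shuffled together with the hull order
random_convex <- function(n, seed) {
  set.seed(seed)
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- 1 + stats::runif(n, -0.05, 0.05)
  pts <- cbind(r * cos(ang), r * sin(ang))
  sh <- sample.int(n)
  list(points = pts, shuffled = pts[sh, , drop = FALSE], perm = sh)
}

# shortest closed tour by brute force over all (n-1)!/2 tours
brute_force_tour_length <- function(pts) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  perms <- contourweight:::permutations_all(n - 1)
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    ord <- c(1L, perms[i, ] + 1L)
    len <- sum(d[cbind(ord, ord[c(2:n, 1)])])
    best <- min(best, len)
  }
  best
}

brute_force_assignment_cost <- function(C) {
  n <- nrow(C)
  perms <- contourweight:::permutations_all(n)
  min(apply(perms, 1, function(p) sum(C[cbind(seq_len(n), p)])))
}

random_measure <- function(n, seed) {
  set.seed(seed)
  discrete_measure(matrix(stats::runif(2 * n), n, 2))
}

# flatten scene records into per-instance contour/weight records
as_contour_records <- function(scenes) {
  out <- list()
  for (r in scenes) {
    for (i in r$instances)
      out[[length(out) + 1]] <- list(polygon = i$polygon, width = r$width,
                                     height = r$height, weight = i$weight)
  }
  out
}

tiny_scene_dataset <- function(n_scenes = 24, seed = 7) {
  make_dataset(n_scenes, seed = seed, split = c(0.5, 0.25, 0.25))
}
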