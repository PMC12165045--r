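# Deterministic generator of overhead "pen" scenes: smooth animal-shaped
# blobs (ellipse body, cosine head bump, gentle bend) placed without
# overlap on a textured floor, imaged through a position-dependent scale
# factor that mimics perspective (the same animal appears larger or
# smaller depending on where it stands), and liveweights that are a
# deterministic function of the TRUE world-space dorsal area plus
# multiplicative Gaussian noise. Because weight depends on pre-projection
# geometry, an estimator working on image contours can only recover it by
# exploiting image-position information -- exactly the property the
# contour-based weight regressor is designed to have.

#' Shape parameters for one synthetic animal outline
#'
#' @param a,b body semi-axes in world units (a > b > 0).
#' @param bump_amp head-bump amplitude as a fraction of local radius.
#' @param bump_width angular width (radians) of the head bump.
#' @param bend bending coefficient (dimensionless, signed).
#' @param orientation rotation about the shape centroid, radians.
#' @export
shape_params <- function(a, b, bump_amp = 0.12, bump_width = 0.5,
                         bend = 0, orientation = 0) {
  if (!(a > b && b > 0)) stop("need a > b > 0")
  if (bump_amp < 0 || bump_width <= 0) stop("invalid head bump")
  list(a = a, b = b, bump_amp = bump_amp, bump_width = bump_width,
       bend = bend, orientation = orientation)
}

#' Generate a world-space animal outline polygon
#'
#' Ellipse base with a cosine-windowed head bump at the +x pole and a
#' quadratic bend, rotated by `orientation` about the shape centroid.
#' Deterministic given its parameters.
#'
#' @param params from [shape_params()].
#' @param n_vertices outline resolution.
#' @return n_vertices x 2 polygon centered near the origin.
#' @export
generate_shape <- function(params, n_vertices = 256) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  x <- params$a * cos(th)
  y <- params$b * sin(th)
  # head bump: radial swell within +-bump_width of theta = 0
  wrap <- atan2(sin(th), cos(th))
  g <- exp(-wrap^2 / (2 * params$bump_width^2))
  x <- x * (1 + params$bump_amp * g)
  y <- y * (1 + params$bump_amp * g)
  # gentle spine bend
  y <- y + params$bend * (x / params$a)^2 * params$b
  poly <- cbind(x, y)
  ctr <- colMeans(poly)
  ang <- params$orientation
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  sweep(sweep(poly, 2, ctr) %*% t(R), 2, ctr, "+")
}

#' Camera model linking image position to apparent scale
#'
#' Scale varies linearly with normalized distance from the image center:
#' s = s_max at the center, s_min at the corners. `px_per_unit` converts
#' world units to pixels at scale 1.
#'
#' @param width,height image size in pixels.
#' @param px_per_unit pixels per world unit.
#' @param s_min,s_max apparent-scale range.
#' @export
camera_model <- function(width, height, px_per_unit = 3,
                         s_min = 0.85, s_max = 1.15) {
  list(width = width, height = height, px_per_unit = px_per_unit,
       s_min = s_min, s_max = s_max)
}

camera_scale <- function(camera, position) {
  dx <- (position[1] - camera$width / 2) / (camera$width / 2)
  dy <- (position[2] - camera$height / 2) / (camera$height / 2)
  d <- sqrt(dx^2 + dy^2) / sqrt(2)
  camera$s_max - (camera$s_max - camera$s_min) * min(d, 1)
}

#' Project a world polygon into the image
#'
#' Scales the centered shape by `px_per_unit * s(position)` and translates
#' its centroid to `position`. The same world shape at two positions thus
#' has projected areas in ratio s1^2 : s2^2.
#'
#' @param polygon world-space polygon.
#' @param position length-2 pixel position of the projected centroid.
#' @param camera from [camera_model()].
#' @return pixel-space polygon.
#' @export
project_to_image <- function(polygon, position, camera) {
  s <- camera_scale(camera, position)
  ctr <- colMeans(as.matrix(polygon))
  sweep(sweep(as.matrix(polygon), 2, ctr) * (camera$px_per_unit * s),
        2, position, "+")
}

#' Liveweight model: weight from world geometry
#'
#' weight = k * area^p * (1 + e), e ~ N(0, sigma^2). Area is the WORLD
#' (pre-projection) outline area, so two sightings of the same animal at
#' different image positions have the same expected weight.
#'
#' @param k kg per world-area unit (to the power p).
#' @param p allometric exponent.
#' @param sigma relative noise standard deviation.
#' @export
weight_model <- function(k = 1.35, p = 1, sigma = 0.02) {
  stopifnot(k > 0, p > 0, sigma >= 0)
  list(k = k, p = p, sigma = sigma)
}

#' @rdname weight_model
#' @param params shape parameters of the animal.
#' @param model from [weight_model()].
#' @export
assign_weight <- function(params, model = weight_model()) {
  area <- polygon_area(generate_shape(params))
  noise <- if (model$sigma > 0) stats::rnorm(1, 0, model$sigma) else 0
  model$k * area^model$p * (1 + noise)
}

render_scene <- function(polys, camera, rng_noise = 0.02) {
  H <- camera$height; W <- camera$width
  img <- array(0.30, dim = c(H, W, 3))
  img[, , 1] <- img[, , 1] + 0.02
  base_cols <- list(c(0.80, 0.62, 0.58), c(0.75, 0.58, 0.52),
                    c(0.83, 0.66, 0.60), c(0.78, 0.60, 0.56))
  for (i in seq_along(polys)) {
    m <- rasterize_contour(polys[[i]], H, W, check_simple = FALSE)
    col <- base_cols[[(i - 1) %% length(base_cols) + 1]]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m == 1] <- col[ch]
      img[, , ch] <- plane
    }
  }
  img <- img + array(stats::rnorm(length(img), 0, rng_noise), dim = dim(img))
  pmin(pmax(img, 0), 1)
}

new_animal <- function(id, wmodel) {
  a <- stats::runif(1, 4.0, 6.8)
  b <- a * stats::runif(1, 0.42, 0.58)
  list(id = id, a = a, b = b,
       bump_amp = stats::runif(1, 0.08, 0.18),
       bump_width = stats::runif(1, 0.4, 0.6))
}

#' Generate a stratified synthetic dataset of annotated scenes
#'
#' A pool of synthetic animals (persistent body geometry) is split by
#' animal id into train/validation/test; scenes are then generated within
#' each split, so no animal leaks across splits. Each scene places 1 to
#' `max_instances` animals without overlap, projects them through the
#' camera model, renders an RGB image, and records per-instance polygons
#' and liveweights.
#'
#' @param n_scenes total number of scenes.
#' @param seed RNG seed; the full dataset is reproducible from it.
#' @param camera from [camera_model()].
#' @param wmodel from [weight_model()].
#' @param split train/val/test fractions summing to 1.
#' @param max_instances maximum animals per scene.
#' @param n_animals size of the animal pool.
#' @param render if FALSE, skip image rendering (annotation-only records).
#' @param out_dir optional directory: writes PNG frames, COCO JSON per
#'   split, and a weight CSV.
#' @return list of splits, each a list of scene records with fields
#'   `image`, `instances` (polygon/weight/ids), `width`, `height`.
#' @export
make_dataset <- function(n_scenes, seed = 1, camera = camera_model(96, 96),
                         wmodel = weight_model(), split = c(0.6, 0.2, 0.2),
                         max_instances = 2, n_animals = 16, render = TRUE,
                         out_dir = NULL) {
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  set.seed(seed)
  animals <- lapply(seq_len(n_animals), new_animal, wmodel = wmodel)
  split_of_animal <- sample(rep(1:3, times = round(split * n_animals))[
    seq_len(n_animals)])
  counts <- round(split * n_scenes)
  counts[1] <- n_scenes - sum(counts[-1])
  out <- list(train = list(), val = list(), test = list())
  names(counts) <- names(out)
  inst_id <- 0L
  attempt_scene <- function(pool) {
    k <- sample.int(min(max_instances, length(pool)), 1)
    ids <- if (length(pool) == 1) pool else sample(pool, k)
    polys <- list(); insts <- list()
    centers <- matrix(0, 0, 2); radii <- numeric(0)
    for (aid in ids) {
      an <- animals[[aid]]
      params <- shape_params(an$a, an$b, an$bump_amp, an$bump_width,
                             bend = stats::runif(1, -0.2, 0.2),
                             orientation = stats::runif(1, 0, 2 * pi))
      world <- generate_shape(params)
      r_px <- an$a * (1 + an$bump_amp) * camera$px_per_unit * camera$s_max
      placed <- FALSE
      for (try in 1:40) {
        pos <- c(stats::runif(1, r_px + 1, camera$width - r_px - 2),
                 stats::runif(1, r_px + 1, camera$height - r_px - 2))
        if (nrow(centers) == 0 ||
            all(sqrt(rowSums(sweep(centers, 2, pos)^2)) >
                0.95 * (radii + r_px))) {
          placed <- TRUE
          break
        }
      }
      if (!placed) next
      proj <- project_to_image(world, pos, camera)
      if (any(proj[, 1] < 1) || any(proj[, 1] > camera$width - 2) ||
          any(proj[, 2] < 1) || any(proj[, 2] > camera$height - 2)) next
      centers <- rbind(centers, pos); radii <- c(radii, r_px)
      inst_id <<- inst_id + 1L
      noise <- if (wmodel$sigma > 0) stats::rnorm(1, 0, wmodel$sigma) else 0
      w_true <- wmodel$k * polygon_area(world)^wmodel$p * (1 + noise)
      polys[[length(polys) + 1]] <- proj
      insts[[length(insts) + 1]] <- list(
        instance_id = inst_id, animal_id = an$id,
        polygon = proj, world_polygon = world, weight = w_true)
    }
    list(polys = polys, insts = insts)
  }
  for (sp in 1:3) {
    pool <- which(split_of_animal == sp)
    if (length(pool) == 0) pool <- seq_len(n_animals)
    for (sc in seq_len(counts[sp])) {
      for (redo in 1:20) {
        sc_try <- attempt_scene(pool)
        if (length(sc_try$insts) > 0) break
      }
      img <- if (render) render_scene(sc_try$polys, camera) else NULL
      rec <- list(image = img, instances = sc_try$insts,
                  width = camera$width, height = camera$height,
                  scene_id = sprintf("s%d_%03d", sp, sc))
      out[[sp]] <- c(out[[sp]], list(rec))
    }
  }
  if (!is.null(out_dir)) write_dataset(out, out_dir)
  out
}

write_dataset <- function(splits, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wrows <- list()
  for (sp in names(splits)) {
    imgs <- list(); anns <- list()
    for (i in seq_along(splits[[sp]])) {
      rec <- splits[[sp]][[i]]
      fn <- paste0(rec$scene_id, ".png")
      if (!is.null(rec$image))
        write_image_png(rec$image, file.path(out_dir, fn))
      imgs[[i]] <- data.frame(id = i, file_name = fn,
                              height = rec$height, width = rec$width,
                              stringsAsFactors = FALSE)
      for (inst in rec$instances) {
        anns[[length(anns) + 1]] <- list(id = inst$instance_id,
                                         image_id = i,
                                         polygon = inst$polygon)
        wrows[[length(wrows) + 1]] <- data.frame(
          split = sp, image_id = i, instance_id = inst$instance_id,
          animal_id = inst$animal_id, weight_kg = inst$weight,
          stringsAsFactors = FALSE)
      }
    }
    write_coco(do.call(rbind, imgs), anns,
               file.path(out_dir, paste0(sp, "_coco.json")))
  }
  utils::write.csv(do.call(rbind, wrows),
                   file.path(out_dir, "weights.csv"), row.names = FALSE)
  invisible(out_dir)
}
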