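#' @keywords internal
"_PACKAGE"

# Contours are plain numeric matrices with two columns (x, y) in pixel
# coordinates, 0-based, pixel-center convention. Polygons are implicitly
# closed: the last vertex connects back to the first.

as_contour <- function(points) {
  m <- as.matrix(points)
  if (!is.numeric(m) || ncol(m) != 2L)
    stop("contour must be an N x 2 numeric matrix")
  if (nrow(m) < 3L) stop("contour needs at least 3 points")
  if (!all(is.finite(m))) stop("contour coordinates must be finite")
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param polygon N x 2 matrix of vertices, implicitly closed.
#' @return Absolute enclosed area in squared coordinate units.
#' @export
polygon_area <- function(polygon) {
  p <- as_contour(polygon)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_perimeter <- function(polygon) {
  p <- as_contour(polygon)
  d <- p[c(2:nrow(p), 1), , drop = FALSE] - p
  sum(sqrt(rowSums(d^2)))
}

polygon_centroid <- function(polygon) {
  p <- as_contour(polygon)
  colMeans(p)
}

#' Uniform arc-length resampling of a closed polygon
#'
#' Places `count` points equally spaced by arc length along the closed
#' polygon boundary, starting at the fractional perimeter offset `phase`.
#' Orientation of the input is preserved. This is the sampling used to turn
#' an annotated boundary into a fixed-length vertex sequence for training.
#'
#' @param polygon N x 2 vertex matrix, implicitly closed.
#' @param count number of points to place (>= 3).
#' @param phase fraction of the perimeter at which the first sample sits.
#' @return `count` x 2 matrix of resampled points.
#' @export
sample_contour_points <- function(polygon, count, phase = 0) {
  p <- as_contour(polygon)
  if (count < 3L) stop("count must be >= 3")
  n <- nrow(p)
  nxt <- c(2:n, 1)
  seg <- p[nxt, , drop = FALSE] - p
  len <- sqrt(rowSums(seg^2))
  per <- sum(len)
  if (per <= 0) stop("degenerate contour")
  # cumulative arc length at the start of each edge
  cum <- c(0, cumsum(len))
  pos <- ((0:(count - 1)) / count + phase) %% 1 * per
  idx <- findInterval(pos, cum, rightmost.closed = FALSE)
  idx[idx > n] <- n
  t <- (pos - cum[idx]) / len[idx]
  t[!is.finite(t)] <- 0
  p[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * t
}

#' Bounding-box normalization of a point set to the unit square
#'
#' Maps x to (x - x_min) / (x_max - x_min) and likewise for y, with the
#' extrema taken over all input points, so each output axis spans exactly
#' [0, 1]. Used as the contour positional embedding: it gives every vertex
#' awareness of where it sits within its own instance, independent of image
#' position and apparent size.
#'
#' @param points N x 2 matrix.
#' @return N x 2 matrix with per-axis minimum 0 and maximum 1.
#' @export
box_normalize <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 2L) stop("need at least 2 points")
  rng_x <- range(p[, 1]); rng_y <- range(p[, 2])
  if (diff(rng_x) <= 0 || diff(rng_y) <= 0) stop("degenerate box")
  cbind((p[, 1] - rng_x[1]) / diff(rng_x),
        (p[, 2] - rng_y[1]) / diff(rng_y))
}

#' Order an unordered point set into a polygon via greedy multi-start TSP
#'
#' Networks supervised with an optimal-transport point-set loss emit
#' unordered boundary points; to build a mask they must first be connected
#' into a simple polygon. The shortest closed tour through the points is a
#' good ordering, and it is approximated by nearest-neighbour greedy tours
#' started from every point. The input order itself is added as a candidate
#' tour, and the shortest closed tour wins (ties broken by earlier start
#' index; nearest-neighbour ties by lowest point index).
#'
#' @param points N x 2 matrix (N >= 3), possibly with duplicates.
#' @return list with `order` (integer permutation), `contour` (reordered
#'   points) and `length` (closed tour length).
#' @export
order_points_tsp <- function(points) {
  p <- as.matrix(points)
  n <- nrow(p)
  if (n < 3L) stop("need at least 3 points")
  if (!all(is.finite(p))) stop("points must be finite")
  d <- as.matrix(stats::dist(p))
  tour_len <- function(ord) {
    sum(d[cbind(ord, ord[c(2:n, 1)])])
  }
  best_ord <- seq_len(n)           # identity candidate
  best_len <- tour_len(best_ord)
  for (s in seq_len(n)) {
    ord <- integer(n)
    ord[1] <- s
    left <- rep(TRUE, n)
    left[s] <- FALSE
    cur <- s
    for (k in 2:n) {
      cand <- d[cur, ]
      cand[!left] <- Inf
      nxt <- which.min(cand)      # which.min takes lowest index on ties
      ord[k] <- nxt
      left[nxt] <- FALSE
      cur <- nxt
    }
    len <- tour_len(ord)
    if (len < best_len - 1e-12) {
      best_len <- len
      best_ord <- ord
    }
  }
  list(order = best_ord, contour = p[best_ord, , drop = FALSE],
       length = best_len)
}

segments_intersect <- function(p1, p2, p3, p4) {
  o <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  (o1 != o2) && (o3 != o4)
}

polygon_self_intersects <- function(p) {
  n <- nrow(p)
  nxt <- c(2:n, 1)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    js <- setdiff(seq.int(i + 2L, jmax), i)
    for (j in js) {
      if (segments_intersect(p[i, ], p[nxt[i], ], p[j, ], p[nxt[j], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Rasterize a closed polygon to a binary mask
#'
#' Even-odd scanline fill at pixel centers, clipped to the image rectangle.
#' Pixel (row r, column c) of the output covers the point
#' (x = c - 1, y = r - 1) in the 0-based pixel-center convention.
#' Self-intersecting polygons are filled even-odd with a warning.
#'
#' @param contour N x 2 vertex matrix, implicitly closed.
#' @param height,width mask dimensions in pixels.
#' @param check_simple if TRUE, warn when the polygon self-intersects.
#' @return height x width binary (0/1) matrix.
#' @export
rasterize_contour <- function(contour, height, width, check_simple = TRUE) {
  p <- as_contour(contour)
  if (height < 1 || width < 1) stop("mask dimensions must be >= 1")
  if (check_simple && nrow(p) <= 512 && polygon_self_intersects(p))
    warning("self-intersecting polygon rasterized with even-odd rule")
  mask <- matrix(0L, nrow = height, ncol = width)
  n <- nrow(p)
  nxt <- c(2:n, 1)
  x1 <- p[, 1]; y1 <- p[, 2]
  x2 <- p[nxt, 1]; y2 <- p[nxt, 2]
  for (r in seq_len(height)) {
    yc <- r - 1
    # half-open rule [ymin, ymax) avoids double-counting shared vertices
    cross <- ((y1 <= yc) & (y2 > yc)) | ((y2 <= yc) & (y1 > yc))
    if (!any(cross)) next
    xi <- x1[cross] + (yc - y1[cross]) / (y2[cross] - y1[cross]) *
      (x2[cross] - x1[cross])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      lo <- ceiling(xi[k])          # first pixel center >= entry
      hi <- ceiling(xi[k + 1]) - 1  # last pixel center < exit
      lo <- max(lo, 0); hi <- min(hi, width - 1)
      if (lo <= hi) mask[r, (lo + 1):(hi + 1)] <- 1L
    }
  }
  mask
}

mask_iou <- function(a, b) {
  inter <- sum(a & b)
  un <- sum(a | b)
  if (un == 0) return(0)
  inter / un
}

#' COCO-style mask average precision
#'
#' Greedy score-ordered matching of predicted masks to ground-truth masks,
#' one match per truth, evaluated at IoU thresholds 0.50:0.05:0.95 with
#' 101-point interpolated precision. Accepts predictions from several
#' images at once via the `image_id` fields.
#'
#' @param predicted list of lists with elements `mask` (binary matrix),
#'   `score` (numeric in `[0,1]`) and optional `image_id`.
#' @param truth list of lists with elements `mask` and optional `image_id`.
#' @param iou_thresholds IoU thresholds; default COCO 0.50:0.05:0.95.
#' @return list with `ap`, `ap50`, `ap75`, and `per_threshold`.
#' @export
mask_ap <- function(predicted, truth,
                    iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  get_id <- function(x) if (is.null(x$image_id)) 1L else x$image_id
  if (length(truth) == 0L) {
    if (length(predicted) == 0L)
      return(list(ap = NA_real_, ap50 = NA_real_, ap75 = NA_real_,
                  per_threshold = rep(NA_real_, length(iou_thresholds)),
                  skipped = TRUE))
    z <- rep(0, length(iou_thresholds))
    return(list(ap = 0, ap50 = 0, ap75 = 0, per_threshold = z,
                skipped = FALSE))
  }
  pred_ids <- vapply(predicted, get_id, 1L)
  truth_ids <- vapply(truth, get_id, 1L)
  scores <- vapply(predicted, function(x) x$score, 1)
  ord <- order(scores, decreasing = TRUE)
  n_truth <- length(truth)
  # precompute IoUs between co-imaged pairs
  iou_tab <- matrix(0, nrow = length(predicted), ncol = n_truth)
  for (i in seq_along(predicted)) {
    for (j in seq_len(n_truth)) {
      if (pred_ids[i] == truth_ids[j])
        iou_tab[i, j] <- mask_iou(predicted[[i]]$mask, truth[[j]]$mask)
    }
  }
  recall_grid <- seq(0, 1, length.out = 101)
  ap_at <- vapply(iou_thresholds, function(thr) {
    matched <- logical(n_truth)
    tp <- fp <- numeric(length(predicted))
    for (k in seq_along(ord)) {
      i <- ord[k]
      cand <- which(!matched & iou_tab[i, ] >= thr)
      if (length(cand) > 0) {
        j <- cand[which.max(iou_tab[i, cand])]
        matched[j] <- TRUE
        tp[k] <- 1
      } else fp[k] <- 1
    }
    ctp <- cumsum(tp); cfp <- cumsum(fp)
    rec <- ctp / n_truth
    prec <- ctp / pmax(ctp + cfp, 1e-12)
    # monotone non-increasing interpolated precision
    for (k in rev(seq_along(prec))[-1]) prec[k] <- max(prec[k], prec[k + 1])
    mean(vapply(recall_grid, function(r) {
      ok <- rec >= r
      if (any(ok)) max(prec[ok]) else 0
    }, 1))
  }, 1)
  list(ap = mean(ap_at),
       ap50 = ap_at[which.min(abs(iou_thresholds - 0.5))],
       ap75 = ap_at[which.min(abs(iou_thresholds - 0.75))],
       per_threshold = ap_at, skipped = FALSE)
}

#' Regression metrics for liveweight prediction
#'
#' @param predicted,truth equal-length numeric vectors (kg); truths must be
#'   strictly positive for MAPE.
#' @return list with `mae` (kg), `mse` (kg^2), `mape` (percent), `r2`.
#' @export
regression_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0)
    stop("predicted and truth must have equal nonzero length")
  if (any(truth == 0)) stop("MAPE undefined for zero truth values")
  err <- predicted - truth
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot == 0) NaN else 1 - sum(err^2) / ss_tot
  list(mae = mean(abs(err)),
       mse = mean(err^2),
       mape = 100 * mean(abs(err) / abs(truth)),
       r2 = r2)
}
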