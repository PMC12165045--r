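# Perceptual-hash (pHash) near-duplicate frame filtering, as used to prune
# a 13 fps overhead video stream before annotation: grayscale, resize to
# 32 x 32, 2-D DCT, threshold the 8 x 8 low-frequency block against its
# mean to get a 64-bit signature, and drop frames whose Hamming distance to
# the previous retained frame is at most tau.

# orthonormal type-II DCT matrix of order n
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  m <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

rgb_to_gray <- function(image) {
  if (length(dim(image)) == 2L) return(image)
  # ITU-R BT.601 luma
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# separable bilinear resize (align-corners = FALSE convention)
resize_bilinear <- function(gray, out_h, out_w) {
  in_h <- nrow(gray); in_w <- ncol(gray)
  axis_weights <- function(n_in, n_out) {
    src <- ((0:(n_out - 1)) + 0.5) * n_in / n_out - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    lo <- floor(src)
    hi <- pmin(lo + 1, n_in - 1)
    w <- src - lo
    list(lo = lo + 1, hi = hi + 1, w = w)
  }
  ry <- axis_weights(in_h, out_h)
  rx <- axis_weights(in_w, out_w)
  rows <- gray[ry$lo, , drop = FALSE] * (1 - ry$w) +
    gray[ry$hi, , drop = FALSE] * ry$w
  rows[, rx$lo, drop = FALSE] * rep(1 - rx$w, each = out_h) +
    rows[, rx$hi, drop = FALSE] * rep(rx$w, each = out_h)
}

#' 64-bit perceptual hash of an image
#'
#' Grayscale conversion (BT.601 luma), bilinear resize to 32 x 32,
#' orthonormal 2-D type-II DCT, then the top-left 8 x 8 low-frequency
#' coefficient block is thresholded against its own mean: bit = 1 where the
#' coefficient strictly exceeds the mean, else 0. Bits are returned
#' row-major over the 8 x 8 block.
#'
#' @param image H x W x 3 array or H x W matrix, values in `[0, 1]`.
#' @return integer vector of 64 bits (0/1).
#' @export
compute_phash <- function(image) {
  if (length(image) == 0) stop("empty image")
  g <- rgb_to_gray(image)
  if (nrow(g) < 1 || ncol(g) < 1) stop("empty image")
  small <- resize_bilinear(g, 32, 32)
  D <- dct_matrix(32)
  coef <- D %*% small %*% t(D)
  block <- coef[1:8, 1:8]
  mu <- mean(block)
  bits <- ifelse(t(block) > mu, 1L, 0L)  # row-major order
  as.integer(bits)
}

#' Hamming distance between two 64-bit hashes
#'
#' @param h1,h2 integer vectors of 64 bits.
#' @return integer count of differing positions, in `[0, 64]`.
#' @export
hamming_distance <- function(h1, h2) {
  if (length(h1) != length(h2)) stop("hash length mismatch")
  sum(h1 != h2)
}

#' Drop near-duplicate frames from an ordered stream
#'
#' Each incoming frame's hash is compared to the hash of the most recently
#' retained frame (default), or to the immediately preceding raw frame when
#' `compare_to = "adjacent"`. Frames at Hamming distance <= tau are dropped
#' as similar; the first frame is always retained.
#'
#' @param frames list of images, or list of precomputed 64-bit hashes when
#'   `hashed = TRUE`.
#' @param tau similarity threshold in `[0, 64]`; frames with distance
#'   <= tau are dropped (the dataset-production default is 15).
#' @param compare_to "retained" (default) or "adjacent".
#' @param hashed set TRUE when `frames` already contains hash vectors.
#' @return list with `keep` (logical vector), `kept` (indices retained) and
#'   `n_dropped`.
#' @export
filter_similar_frames <- function(frames, tau = 15,
                                  compare_to = c("retained", "adjacent"),
                                  hashed = FALSE) {
  compare_to <- match.arg(compare_to)
  if (tau < 0 || tau > 64) stop("tau must be in [0, 64]")
  n <- length(frames)
  if (n == 0) return(list(keep = logical(0), kept = integer(0), n_dropped = 0L))
  hashes <- if (hashed) frames else lapply(frames, compute_phash)
  keep <- logical(n)
  keep[1] <- TRUE
  ref <- hashes[[1]]
  for (i in seq_len(n)[-1]) {
    base <- if (compare_to == "retained") ref else hashes[[i - 1]]
    if (hamming_distance(hashes[[i]], base) > tau) {
      keep[i] <- TRUE
      if (compare_to == "retained") ref <- hashes[[i]]
    }
  }
  list(keep = keep, kept = which(keep), n_dropped = sum(!keep))
}
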