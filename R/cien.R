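# Contour information extraction network (CIEN). Three parts:
#   1. feature extraction: a strided conv backbone emitting maps at
#      strides 4/8/16/32, fused top-down by iterative deep aggregation
#      (IDA) into a stride-4 map F with 24 channels;
#   2. contour initialization: a sigmoid center heatmap plus a regression
#      map holding, at every cell, N vertex offsets relative to the
#      center, so one lookup yields a whole initial contour;
#   3. contour evolution: CSA blocks that sample per-vertex features from
#      a refined map F', append the box-normalized vertex coordinates
#      (contour positional embedding), run multi-head self-attention, and
#      regress per-vertex offsets.
# Supervision: penalty-reduced focal loss on the heatmap plus a point-set
# loss per contour stage -- either the debiased Sinkhorn divergence
# ("SoftAssign") or Kuhn-Munkres matching with smooth-L1 ("HardAssign").
# Total loss: L = L_focal + 0.5 L_init + 0.5 L_csa1 + 1.0 L_csa2.

#' CIEN configuration
#'
#' The "paper" preset mirrors the full-scale experiment (768 x 576 inputs,
#' N = 128 vertices, F' with 254 channels, 8 heads, 2 CSA blocks, 300
#' epochs, Adam at 1e-4 halved at 50/100/150/200/250/270); the "desk"
#' preset is a width-reduced variant sized for CPU runs (96 x 96 inputs,
#' 32 vertices, 30-channel F', 4 heads).
#'
#' @param preset "desk" or "paper".
#' @param ... overrides of individual fields.
#' @export
cien_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "paper") {
    list(input_size = c(576, 768), n_vertices = 128, csa_blocks = 2,
         fprime_channels = 254, heads = 8, widths = c(24, 32, 96, 320),
         head_width = 64, heatmap_threshold = 0.3,
         epochs = 300, lr = 1e-4, batch_size = 24,
         lr_milestones = c(50, 100, 150, 200, 250, 270), lr_decay = 0.5,
         augment_flip = TRUE)
  } else {
    list(input_size = c(96, 96), n_vertices = 32, csa_blocks = 2,
         fprime_channels = 30, heads = 4, widths = c(16, 24, 32, 48),
         head_width = 32, heatmap_threshold = 0.3,
         epochs = 14, lr = 1e-3, batch_size = 1,
         lr_milestones = c(8, 12), lr_decay = 0.3,
         augment_flip = TRUE)
  }
  cfg$supervision <- "ot"
  cfg$use_csa <- TRUE
  cfg$ot_config <- sinkhorn_config(epsilon_target = 0.05,
                                   scaling_ratio = 0.5,
                                   max_iters = 120, tol = 1e-5)
  over <- list(...)
  cfg[names(over)] <- over
  cfg$d_csa <- cfg$fprime_channels + 2
  stopifnot(cfg$d_csa %% cfg$heads == 0)
  cfg
}

#' Construct an untrained CIEN
#'
#' @param config from [cien_config()].
#' @param seed RNG seed for initialization.
#' @export
cien_build <- function(config = cien_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- config$widths
  N <- config$n_vertices
  model <- list(
    backbone = list(
      s1a = conv_init(3, w[1], k = 3, stride = 2),
      s1b = conv_init(w[1], w[1], k = 3, stride = 2),
      s2 = conv_init(w[1], w[2], k = 3, stride = 2),
      s3 = conv_init(w[2], w[3], k = 3, stride = 2),
      s4 = conv_init(w[3], w[4], k = 3, stride = 2)),
    ida = list(
      proj1 = conv_init(w[1], 24, k = 1, pad = 0),
      proj2 = conv_init(w[2], 24, k = 1, pad = 0),
      proj3 = conv_init(w[3], 24, k = 1, pad = 0),
      proj4 = conv_init(w[4], 24, k = 1, pad = 0),
      fuse1 = conv_init(24, 24, k = 3),
      fuse2 = conv_init(24, 24, k = 3),
      fuse3 = conv_init(24, 24, k = 3)),
    heat = list(c1 = conv_init(24, config$head_width, k = 3),
                c2 = conv_init(config$head_width, 1, k = 1, pad = 0)),
    reg = list(c1 = conv_init(24, config$head_width, k = 3),
               c2 = conv_init(config$head_width, 2 * N, k = 1, pad = 0)),
    fprime = list(c1 = conv_init(24, config$head_width, k = 3),
                  c2 = conv_init(config$head_width,
                                 config$fprime_channels, k = 3)),
    csa = lapply(seq_len(config$csa_blocks), function(i) {
      blk <- list(mhsa = mhsa_init(config$d_csa, config$heads),
                  offset = linear_init(config$d_csa, 2, bias = TRUE))
      blk$offset$W[] <- 0   # zero offsets at init: refinement starts as identity
      blk
    }),
    config = config
  )
  # bias the heatmap towards background so focal loss starts stable
  model$heat$c2$b[] <- -2.19
  model
}

conv_relu_fwd <- function(layer, X) {
  r <- conv_fwd(layer, X)
  list(Y = relu(r$Y), pre = r$Y, cache = r$cache)
}

conv_relu_bwd <- function(layer, fw, gY) {
  conv_bwd(layer, fw$cache, gY * (fw$pre > 0))
}

#' Backbone feature pyramid at strides 4, 8, 16, 32
#'
#' @param model from [cien_build()].
#' @param image H x W x 3 array with H, W divisible by 32.
#' @return list of four feature maps `o1`..`o4` (and caches when
#'   `keep_cache = TRUE`).
#' @param keep_cache retain intermediate activations for backprop.
#' @export
extract_backbone_features <- function(model, image, keep_cache = FALSE) {
  d <- dim(image)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stop("image dimensions must be divisible by 32")
  b <- model$backbone
  f1 <- conv_relu_fwd(b$s1a, image)
  f2 <- conv_relu_fwd(b$s1b, f1$Y)       # stride 4
  f3 <- conv_relu_fwd(b$s2, f2$Y)        # stride 8
  f4 <- conv_relu_fwd(b$s3, f3$Y)        # stride 16
  f5 <- conv_relu_fwd(b$s4, f4$Y)        # stride 32
  out <- list(o1 = f2$Y, o2 = f3$Y, o3 = f4$Y, o4 = f5$Y)
  if (keep_cache) out$cache <- list(f1 = f1, f2 = f2, f3 = f3, f4 = f4,
                                    f5 = f5)
  out
}

backbone_bwd <- function(model, image, cache, g_o) {
  b <- model$backbone
  g <- list()
  r5 <- conv_relu_bwd(b$s4, cache$f5, g_o$o4)
  g$s4 <- r5$grads
  r4 <- conv_relu_bwd(b$s3, cache$f4, g_o$o3 + r5$gX)
  g$s3 <- r4$grads
  r3 <- conv_relu_bwd(b$s2, cache$f3, g_o$o2 + r4$gX)
  g$s2 <- r3$grads
  r2 <- conv_relu_bwd(b$s1b, cache$f2, g_o$o1 + r3$gX)
  g$s1b <- r2$grads
  r1 <- conv_relu_bwd(b$s1a, cache$f1, r2$gX)
  g$s1a <- r1$grads
  g
}

upsample_pow2 <- function(X, times) {
  for (i in seq_len(times)) X <- upsample2_fwd(X)
  X
}

downsample_pow2_grad <- function(g, times) {
  for (i in seq_len(times)) g <- upsample2_bwd(g)
  g
}

#' Iterative deep aggregation of the backbone pyramid
#'
#' Recursive pairwise fusion T(o1, ..., on) = T(N(o1, o2), o3, ..., on):
#' each aggregation node projects both inputs to 24 channels, upsamples
#' the deeper map to stride 4, sums, and applies a 3x3 conv + ReLU. A
#' single-map series returns its (projected) input.
#'
#' @param model CIEN model.
#' @param series list of feature maps at increasing downsampling.
#' @param keep_cache retain activations for backprop.
#' @return stride-4 aggregated map F with 24 channels.
#' @export
ida_aggregate <- function(model, series, keep_cache = FALSE) {
  a <- model$ida
  projs <- list(a$proj1, a$proj2, a$proj3, a$proj4)
  fuses <- list(a$fuse1, a$fuse2, a$fuse3)
  p1 <- conv_fwd(projs[[1]], series[[1]])
  x <- p1$Y
  caches <- list(p = list(p1), f = list(), up_times = integer(0))
  if (length(series) > 1) {
    for (i in 2:length(series)) {
      pi_ <- conv_fwd(projs[[i]], series[[i]])
      up_t <- i - 1L
      v <- upsample_pow2(pi_$Y, up_t)
      fw <- conv_relu_fwd(fuses[[i - 1]], x + v)
      caches$p[[i]] <- pi_
      caches$f[[i - 1]] <- fw
      caches$up_times <- c(caches$up_times, up_t)
      x <- fw$Y
    }
  }
  if (keep_cache) list(F = x, cache = caches) else x
}

ida_bwd <- function(model, series, cache, gF) {
  a <- model$ida
  projs <- list(a$proj1, a$proj2, a$proj3, a$proj4)
  fuses <- list(a$fuse1, a$fuse2, a$fuse3)
  g <- list()
  g_o <- vector("list", length(series))
  gx <- gF
  n <- length(series)
  if (n > 1) {
    for (i in n:2) {
      fb <- conv_relu_bwd(fuses[[i - 1]], cache$f[[i - 1]], gx)
      g[[paste0("fuse", i - 1)]] <- fb$grads
      g_sum <- fb$gX
      gv <- downsample_pow2_grad(g_sum, cache$up_times[i - 1])
      pb <- conv_bwd(projs[[i]], cache$p[[i]]$cache, gv)
      g[[paste0("proj", i)]] <- pb$grads
      g_o[[i]] <- pb$gX
      gx <- g_sum
    }
  }
  pb1 <- conv_bwd(projs[[1]], cache$p[[1]]$cache, gx)
  g$proj1 <- pb1$grads
  g_o[[1]] <- pb1$gX
  list(grads = g, g_o = g_o)
}

#' Center heatmap and vertex-regression maps from the aggregated features
#'
#' @param model CIEN model.
#' @param F stride-4 aggregated feature map.
#' @param keep_cache retain activations for backprop.
#' @return list with `heatmap` (sigmoid, Hf x Wf), `logits`, `reg`
#'   (Hf x Wf x 2N).
#' @export
predict_center_and_regression <- function(model, F, keep_cache = FALSE) {
  h1 <- conv_relu_fwd(model$heat$c1, F)
  h2 <- conv_fwd(model$heat$c2, h1$Y)
  r1 <- conv_relu_fwd(model$reg$c1, F)
  r2 <- conv_fwd(model$reg$c2, r1$Y)
  out <- list(heatmap = sigmoid(h2$Y[, , 1]), logits = h2$Y[, , 1],
              reg = r2$Y)
  if (keep_cache) out$cache <- list(h1 = h1, h2 = h2, r1 = r1, r2 = r2)
  out
}

fprime_fwd <- function(model, F, keep_cache = FALSE) {
  c1 <- conv_relu_fwd(model$fprime$c1, F)
  c2 <- conv_relu_fwd(model$fprime$c2, c1$Y)
  out <- list(Fp = c2$Y)
  if (keep_cache) out$cache <- list(c1 = c1, c2 = c2)
  out
}

#' Initial contours from centers and the regression map
#'
#' For each center (feature-map coordinates), reads the N x 2 offset
#' vector stored at its cell and adds it to the center location.
#'
#' @param centers n x 2 matrix of center positions (feature-map coords,
#'   0-based).
#' @param reg Hf x Wf x 2N regression map.
#' @return list of N x 2 contours in feature-map coordinates.
#' @export
initialize_contours <- function(centers, reg) {
  d <- dim(reg)
  N <- d[3] / 2
  lapply(seq_len(nrow(centers)), function(p) {
    cx <- centers[p, 1]; cy <- centers[p, 2]
    cxi <- min(max(round(cx), 0), d[2] - 1)
    cyi <- min(max(round(cy), 0), d[1] - 1)
    if (cxi != round(cx) || cyi != round(cy))
      warning("center clamped into feature grid")
    off <- matrix(reg[cyi + 1, cxi + 1, ], N, 2)
    sweep(off, 2, c(cxi, cyi), "+")
  })
}

#' Contour positional embedding
#'
#' Box-normalized vertex coordinates in the unit square; delegates to
#' [box_normalize()].
#' @param contour N x 2 matrix.
#' @export
contour_positional_embedding <- function(contour) {
  box_normalize(contour)
}

csa_fwd <- function(blk, contour, Fp, keep_cache = FALSE) {
  samp <- bilinear_sample(Fp, contour)
  cpe <- box_normalize(contour)
  P <- cbind(samp$features, cpe)
  mh <- mhsa_fwd(blk$mhsa, P)
  off <- linear_fwd(blk$offset, mh$out)
  refined <- contour + off
  out <- list(refined = refined, offsets = off)
  if (keep_cache) out$cache <- list(samp = samp, P = P, mh = mh$cache,
                                    mh_out = mh$out)
  out
}

csa_bwd <- function(blk, cache, g_refined_extra, g_offsets) {
  # g_offsets: gradient arriving at the offsets (= gradient at refined
  # vertices); g_refined_extra is already included by the caller.
  lb <- linear_bwd(blk$offset, cache$mh_out, g_offsets)
  mb <- mhsa_bwd(blk$mhsa, cache$mh, lb$gX)
  C <- ncol(cache$samp$features)
  gFeat <- mb$gP[, seq_len(C), drop = FALSE]
  gFp <- bilinear_sample_bwd(cache$samp$cache, gFeat)
  list(grads = list(offset = lb$grads, mhsa = mb$grads), gFp = gFp)
}

#' One CSA refinement applied to a contour
#'
#' Samples per-vertex features from F', appends the contour positional
#' embedding, runs the attention block, and adds the predicted offsets.
#'
#' @param model CIEN model; `block` index selects the CSA block.
#' @param contour N x 2 feature-map coordinates.
#' @param Fp refined feature map F'.
#' @param block block index.
#' @return list with `refined` contour and `offsets`.
#' @export
csa_refine <- function(model, contour, Fp, block = 1) {
  csa_fwd(model$csa[[block]], contour, Fp)
}

## ---- focal loss ------------------------------------------------------

gaussian_splat <- function(hf, wf, centers, sigmas) {
  tgt <- matrix(0, hf, wf)
  xs <- matrix(0:(wf - 1), hf, wf, byrow = TRUE)
  ys <- matrix(0:(hf - 1), hf, wf)
  for (i in seq_len(nrow(centers))) {
    g <- exp(-((xs - centers[i, 1])^2 + (ys - centers[i, 2])^2) /
               (2 * sigmas[i]^2))
    tgt <- pmax(tgt, g)
  }
  tgt
}

#' Penalty-reduced pixel-wise focal loss for center heatmaps
#'
#' Peak pixels (target exactly 1) contribute (1-p)^2 log p; all others
#' are penalty-reduced by (1-t)^4 and contribute p^2 log(1-p). The sum is
#' normalized by the number of objects.
#'
#' @param heatmap predicted sigmoid heatmap.
#' @param target splatted Gaussian target with exact 1 at centers.
#' @param n_objects normalizer (defaults to the count of exact-1 pixels).
#' @return list with `loss` and `grad_logits` (same shape as heatmap).
#' @export
focal_heatmap_loss <- function(heatmap, target, n_objects = NULL) {
  if (is.null(n_objects)) n_objects <- sum(target >= 1)
  if (n_objects == 0) {
    warning("no objects in focal target; loss 0")
    return(list(loss = 0, grad_logits = heatmap * 0))
  }
  p <- pmin(pmax(heatmap, 1e-7), 1 - 1e-7)
  pos <- target >= 1
  loss_pos <- (1 - p)^2 * log(p)
  loss_neg <- (1 - target)^4 * p^2 * log(1 - p)
  loss <- -(sum(loss_pos[pos]) + sum(loss_neg[!pos])) / n_objects
  # d loss / d p
  dpos <- -(-2 * (1 - p) * log(p) + (1 - p)^2 / p)
  dneg <- -((1 - target)^4 * (2 * p * log(1 - p) - p^2 / (1 - p)))
  dp <- ifelse(pos, dpos, dneg) / n_objects
  list(loss = loss, grad_logits = dp * p * (1 - p))
}

#' Total CIEN training loss
#'
#' L = L_focal + 0.5 L_init + 0.5 L_csa1 + 1.0 L_csa2 (stages beyond the
#' available CSA blocks contribute 0).
#'
#' @param l_focal,l_init,l_csa1,l_csa2 component losses.
#' @export
cien_total_loss <- function(l_focal, l_init, l_csa1 = 0, l_csa2 = 0) {
  l_focal + 0.5 * l_init + 0.5 * l_csa1 + 1.0 * l_csa2
}

stage_weights <- function(n_blocks) {
  if (n_blocks >= 2) c(0.5, 0.5, rep(1, n_blocks - 1))[seq_len(n_blocks + 1)]
  else if (n_blocks == 1) c(0.5, 1)
  else 1
}
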