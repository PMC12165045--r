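# CIEN training loop and inference. Contours live in feature-map
# coordinates during training (stride 4 relative to the input) and are
# scaled back to pixels at inference. For the optimal-transport loss both
# point sets are normalized by the feature-map size so that the entropic
# epsilon = 0.05 has a consistent scale across image sizes; gradients are
# chained back through that normalization.

# point-set loss between predicted and target contours (feature coords).
# Returns loss value and d loss / d pred.
contour_stage_loss <- function(pred, target, config, bb_value = NULL) {
  if (config$supervision == "ot") {
    S <- c(config$map_w, config$map_h)
    pn <- cbind(pred[, 1] / S[1], pred[, 2] / S[2])
    tn <- cbind(target[, 1] / S[1], target[, 2] / S[2])
    am <- discrete_measure(pn)
    bm <- discrete_measure(tn)
    ab <- sinkhorn_ot(am, bm, config$ot_config)
    aa <- sinkhorn_self_potential(am, config$ot_config)
    if (is.null(bb_value))
      bb_value <- sinkhorn_self_potential(bm, config$ot_config)$value
    du <- list(value = ab$value - 0.5 * aa$value - 0.5 * bb_value,
               g_ab = ab$g, f_aa = aa$f, epsilon = ab$epsilon)
    g <- ot_gradient(am, bm, du)
    # express the divergence in feature-pixel units (the coordinates were
    # shrunk by S for a scale-free epsilon), so both supervision
    # strategies share the fixed loss weights on a common cost scale
    s_iso <- mean(S)
    list(loss = du$value * s_iso,
         grad = cbind(g[, 1] * s_iso / S[1], g[, 2] * s_iso / S[2]),
         bb_value = bb_value)
  } else {
    km <- km_hard_assign(pred, target, beta = 1)
    list(loss = km$loss, grad = km$gradient, bb_value = NULL)
  }
}

# forward + backward for one image; returns loss components and gradients
cien_train_step <- function(model, rec, config, phase_rng = TRUE) {
  hf <- config$map_h; wf <- config$map_w
  N <- config$n_vertices
  bb <- extract_backbone_features(model, rec$image, keep_cache = TRUE)
  series <- list(bb$o1, bb$o2, bb$o3, bb$o4)
  ida <- ida_aggregate(model, series, keep_cache = TRUE)
  heads <- predict_center_and_regression(model, ida$F, keep_cache = TRUE)
  use_csa <- config$use_csa && config$csa_blocks > 0
  fp <- if (use_csa) fprime_fwd(model, ida$F, keep_cache = TRUE) else NULL

  centers <- t(vapply(rec$instances, function(inst)
    polygon_centroid(inst$polygon) / 4, numeric(2)))
  centers[, 1] <- pmin(pmax(centers[, 1], 0), wf - 1)
  centers[, 2] <- pmin(pmax(centers[, 2], 0), hf - 1)
  sigmas <- vapply(rec$instances, function(inst)
    max(1, sqrt(polygon_area(inst$polygon) / 16 / pi) / 3), 1)
  target_hm <- gaussian_splat(hf, wf, round(centers), sigmas)
  idx_pos <- cbind(round(centers[, 2]) + 1, round(centers[, 1]) + 1)
  target_hm[idx_pos] <- 1
  fl <- focal_heatmap_loss(heads$heatmap, target_hm)

  w_st <- stage_weights(if (use_csa) config$csa_blocks else 0)
  g_reg <- array(0, dim = dim(heads$reg))
  gFp <- if (use_csa) fp$Fp * 0 else NULL
  g_csa <- NULL
  stage_losses <- numeric(length(w_st))
  inits <- initialize_contours(centers, heads$reg)
  for (p in seq_along(rec$instances)) {
    gt_poly <- rec$instances[[p]]$polygon / 4
    phase <- if (phase_rng) stats::runif(1) else 0
    target <- sample_contour_points(gt_poly, N, phase = phase)
    contour <- inits[[p]]
    # forward through stages, caching
    stage_caches <- list()
    contours <- list(contour)
    if (use_csa) {
      for (b in seq_len(config$csa_blocks)) {
        r <- csa_fwd(model$csa[[b]], contours[[b]], fp$Fp, keep_cache = TRUE)
        stage_caches[[b]] <- r$cache
        contours[[b + 1]] <- r$refined
      }
    }
    # per-stage losses and gradients at each stage's output; the target
    # self-transport term is shared across stages
    g_at <- vector("list", length(contours))
    bb_value <- NULL
    for (s in seq_along(contours)) {
      sl <- contour_stage_loss(contours[[s]], target, config, bb_value)
      bb_value <- sl$bb_value
      stage_losses[s] <- stage_losses[s] + sl$loss
      g_at[[s]] <- sl$grad * w_st[s]
    }
    # backward: accumulate down the identity chain
    g_down <- g_at[[length(contours)]]
    if (use_csa) {
      for (b in config$csa_blocks:1) {
        cb <- csa_bwd(model$csa[[b]], stage_caches[[b]], NULL, g_down)
        g_csa[[b]] <- grads_add(if (is.null(g_csa)) NULL else g_csa[[b]],
                                cb$grads)
        gFp <- gFp + cb$gFp
        g_down <- g_down + g_at[[b]]    # pass-through + this stage's loss
      }
    }
    # g_down is now d loss / d initial contour -> regression map cell
    cxi <- min(max(round(centers[p, 1]), 0), wf - 1)
    cyi <- min(max(round(centers[p, 2]), 0), hf - 1)
    g_reg[cyi + 1, cxi + 1, ] <- g_reg[cyi + 1, cxi + 1, ] +
      as.vector(g_down)
  }
  n_inst <- length(rec$instances)
  stage_losses <- stage_losses / n_inst
  g_reg <- g_reg / n_inst
  if (use_csa) {
    gFp <- gFp / n_inst
    g_csa <- lapply(g_csa, function(g) grads_scale(g, 1 / n_inst))
  }

  # ---- backward through the heads into F and the backbone
  grads <- list()
  hb2 <- conv_bwd(model$heat$c2, heads$cache$h2$cache,
                  array(fl$grad_logits, dim = c(hf, wf, 1)))
  hb1 <- conv_relu_bwd(model$heat$c1, heads$cache$h1, hb2$gX)
  grads$heat <- list(c1 = hb1$grads, c2 = hb2$grads)
  gF <- hb1$gX
  rb2 <- conv_bwd(model$reg$c2, heads$cache$r2$cache, g_reg)
  rb1 <- conv_relu_bwd(model$reg$c1, heads$cache$r1, rb2$gX)
  grads$reg <- list(c1 = rb1$grads, c2 = rb2$grads)
  gF <- gF + rb1$gX
  if (use_csa) {
    fb2 <- conv_relu_bwd(model$fprime$c2, fp$cache$c2, gFp)
    fb1 <- conv_relu_bwd(model$fprime$c1, fp$cache$c1, fb2$gX)
    grads$fprime <- list(c1 = fb1$grads, c2 = fb2$grads)
    gF <- gF + fb1$gX
    grads$csa <- g_csa
  }
  ib <- ida_bwd(model, series, ida$cache, gF)
  grads$ida <- ib$grads
  g_o <- list(o1 = ib$g_o[[1]], o2 = ib$g_o[[2]], o3 = ib$g_o[[3]],
              o4 = ib$g_o[[4]])
  grads$backbone <- backbone_bwd(model, rec$image, bb$cache, g_o)

  n_stages <- length(w_st)
  list(grads = grads,
       loss = list(focal = fl$loss,
                   stages = stage_losses,
                   total = fl$loss + sum(w_st * stage_losses)))
}

hflip_record <- function(rec) {
  W <- rec$width
  rec$image <- rec$image[, W:1, , drop = FALSE]
  rec$instances <- lapply(rec$instances, function(inst) {
    inst$polygon[, 1] <- W - 1 - inst$polygon[, 1]
    inst
  })
  rec
}

#' Train a CIEN on annotated scene records
#'
#' Optimizes the focal + per-stage point-set loss with Adam and the
#' configured milestone learning-rate schedule; ground-truth centers are
#' used during training. Supervision is either the debiased Sinkhorn
#' divergence (`supervision = "ot"`) or Kuhn-Munkres matching
#' (`supervision = "km"`).
#'
#' @param records list of scene records (fields `image`, `instances`,
#'   `width`, `height`), e.g. a split from [make_dataset()].
#' @param config from [cien_config()].
#' @param seed RNG seed covering initialization, data order, sampling
#'   phases and augmentation.
#' @param verbose print epoch losses.
#' @return list with `model` and `history` (data.frame of per-epoch mean
#'   loss components).
#' @export
train_cien <- function(records, config = cien_config(), seed = 1,
                       verbose = FALSE) {
  if (length(records) == 0) stop("empty dataset")
  set.seed(seed)
  config$map_h <- config$input_size[1] / 4
  config$map_w <- config$input_size[2] / 4
  model <- cien_build(config)
  trainable <- c("backbone", "ida", "heat", "reg", "fprime", "csa")
  opt <- adam_state(model[trainable])
  n <- length(records)
  hist <- data.frame(epoch = seq_len(config$epochs), focal = NA_real_,
                     contour = NA_real_, total = NA_real_)
  for (ep in seq_len(config$epochs)) {
    lr <- config$lr * config$lr_decay^sum(ep > config$lr_milestones)
    ord <- sample.int(n)
    ep_f <- ep_c <- ep_t <- 0
    b_count <- 0
    grads <- NULL
    for (ii in seq_along(ord)) {
      rec <- records[[ord[ii]]]
      if (config$augment_flip && stats::runif(1) < 0.5)
        rec <- hflip_record(rec)
      st <- cien_train_step(model, rec, config)
      grads <- grads_add(grads, st$grads)
      b_count <- b_count + 1
      ep_f <- ep_f + st$loss$focal
      ep_c <- ep_c + sum(st$loss$stages)
      ep_t <- ep_t + st$loss$total
      if (b_count == config$batch_size || ii == length(ord)) {
        grads <- grads_scale(grads, 1 / b_count)
        stp <- adam_step(model[trainable], grads, opt, lr)
        model[trainable] <- stp$params
        opt <- stp$state
        grads <- NULL
        b_count <- 0
      }
    }
    hist$focal[ep] <- ep_f / n
    hist$contour[ep] <- ep_c / n
    hist$total[ep] <- ep_t / n
    if (verbose)
      message(sprintf("epoch %3d  focal %.4f  contour %.4f  total %.4f",
                      ep, hist$focal[ep], hist$contour[ep], hist$total[ep]))
  }
  model$config <- config
  list(model = model, history = hist)
}

heatmap_peaks <- function(hm, threshold, max_peaks = 16) {
  H <- nrow(hm); W <- ncol(hm)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- hm
  is_max <- hm >= threshold
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1 && dj == 1) next
    is_max <- is_max & (hm >= pad[(1 + di):(H + di), (1 + dj):(W + dj)])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(0, 0, 3))
  sc <- hm[idx]
  ord <- order(sc, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; sc <- sc[ord]
  keep <- seq_len(min(length(sc), max_peaks))
  cbind(x = idx[keep, 2] - 1, y = idx[keep, 1] - 1, score = sc[keep])
}

#' Contour inference on one image
#'
#' Thresholded 3x3 local maxima of the center heatmap become instance
#' centers; each center's regression vector initializes a contour, which
#' the CSA blocks refine; output contours are scaled to input-image
#' pixels with the peak value as confidence score.
#'
#' @param model trained CIEN (from [train_cien()]).
#' @param image H x W x 3 array.
#' @param threshold heatmap threshold (default from the config).
#' @return list of lists with `contour` (N x 2, pixels) and `score`.
#' @export
cien_infer <- function(model, image, threshold = NULL) {
  config <- model$config
  if (is.null(threshold)) threshold <- config$heatmap_threshold
  bb <- extract_backbone_features(model, image)
  F <- ida_aggregate(model, list(bb$o1, bb$o2, bb$o3, bb$o4))
  heads <- predict_center_and_regression(model, F)
  peaks <- heatmap_peaks(heads$heatmap, threshold)
  if (nrow(peaks) == 0) return(list())
  use_csa <- config$use_csa && config$csa_blocks > 0
  Fp <- if (use_csa) fprime_fwd(model, F)$Fp else NULL
  contours <- initialize_contours(peaks[, 1:2, drop = FALSE], heads$reg)
  lapply(seq_along(contours), function(i) {
    ct <- contours[[i]]
    if (use_csa) {
      for (b in seq_len(config$csa_blocks))
        ct <- csa_fwd(model$csa[[b]], ct, Fp)$refined
    }
    list(contour = ct * 4, score = unname(peaks[i, 3]))
  })
}

#' Mask AP of a trained CIEN on a held-out split
#'
#' Runs inference on every record, orders each predicted point set with
#' the greedy multi-start TSP, rasterizes predictions and ground truth,
#' and scores COCO-style AP. Images with no detection are reported in
#' `skipped`.
#'
#' @param model trained CIEN.
#' @param records held-out scene records.
#' @param threshold optional heatmap threshold override.
#' @return list with `metrics` (from [mask_ap()]), `n_images`, `skipped`.
#' @export
evaluate_cien <- function(model, records, threshold = NULL) {
  preds <- list(); truths <- list(); skipped <- character(0)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    dets <- cien_infer(model, rec$image, threshold)
    if (length(dets) == 0) skipped <- c(skipped, rec$scene_id)
    for (d in dets) {
      ordered <- order_points_tsp(d$contour)$contour
      preds[[length(preds) + 1]] <- list(
        mask = rasterize_contour(ordered, rec$height, rec$width,
                                 check_simple = FALSE),
        score = d$score, image_id = i)
    }
    for (inst in rec$instances) {
      truths[[length(truths) + 1]] <- list(
        mask = rasterize_contour(inst$polygon, rec$height, rec$width,
                                 check_simple = FALSE),
        image_id = i)
    }
  }
  list(metrics = mask_ap(preds, truths), n_images = length(records),
       skipped = skipped)
}
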