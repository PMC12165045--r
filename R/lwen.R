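# Liveweight estimation network (LWEN): regresses body weight in kg
# directly from N normalized contour coordinates. Architecture: linear
# projection of the N x 4 normalized sequence to d_hide channels, one (or
# more) multi-head self-attention blocks, mean pooling over the N
# positions, and a two-layer regression head. After normalization the
# prediction needs only a handful of matrix products, which is what makes
# the network fast; mean pooling over attention outputs also makes the
# prediction invariant to the input point order, so ordered and unordered
# contour extractors feed it equally well.

#' LWEN configuration
#'
#' Defaults reproduce the full-size network: 128 input points, hidden
#' width 512, 8 attention heads, one attention block, feed-forward
#' expansion 4x, and a 512 -> 128 -> 1 regression head. The Wide variant
#' raises `d_hide` to 1024; the Deep variant raises `mhsa_layers` to 6.
#'
#' @param n_points number of contour points N.
#' @param d_hide hidden width after linear projection.
#' @param heads attention head count (must divide d_hide).
#' @param mhsa_layers number of stacked attention blocks.
#' @param d_fc width of the regression head's hidden layer.
#' @param img_norm "printed" maps image coordinates to `[-1, 0]` via
#'   (x - W)/W; "centered" uses (x - W/2)/(W/2) instead.
#' @param epochs,lr,weight_decay,batch_size,warmup_epochs,warmup_factor,
#'   lr_milestones,lr_decay training schedule (defaults follow the
#'   full-scale protocol: 400 epochs, lr 1e-3, weight decay 5e-4, ten
#'   warm-up epochs at 0.1x, decay 10x at 80/160/240/320, batch 32).
#' @param noise_sd coordinate jitter augmentation, in pixels.
#' @export
lwen_config <- function(n_points = 128, d_hide = 512, heads = 8,
                        mhsa_layers = 1, d_fc = 128,
                        img_norm = c("printed", "centered"),
                        epochs = 400, lr = 1e-3, weight_decay = 5e-4,
                        batch_size = 32, warmup_epochs = 10,
                        warmup_factor = 0.1,
                        lr_milestones = c(80, 160, 240, 320),
                        lr_decay = 0.1, noise_sd = 0.5) {
  stopifnot(d_hide %% heads == 0, n_points >= 3)
  list(n_points = n_points, d_hide = d_hide, heads = heads,
       mhsa_layers = mhsa_layers, d_fc = d_fc,
       img_norm = match.arg(img_norm), epochs = epochs, lr = lr,
       weight_decay = weight_decay, batch_size = batch_size,
       warmup_epochs = warmup_epochs, warmup_factor = warmup_factor,
       lr_milestones = lr_milestones, lr_decay = lr_decay,
       noise_sd = noise_sd)
}

#' Wide and Deep LWEN variants
#'
#' @param base a [lwen_config()] to modify.
#' @return modified config: Wide sets d_hide = 1024, Deep sets 6 attention
#'   blocks.
#' @export
lwen_config_wide <- function(base = lwen_config()) {
  base$d_hide <- 1024L
  base
}

#' @rdname lwen_config_wide
#' @export
lwen_config_deep <- function(base = lwen_config()) {
  base$mhsa_layers <- 6L
  base
}

#' Desk-scale LWEN configuration for CPU runs
#'
#' Width-reduced variant used by the synthetic benchmark: 48 input points,
#' hidden width 64, 4 heads, 32-wide regression head, 40 epochs with
#' 4 warm-up epochs and decay at 20/32.
#' @export
lwen_config_desk <- function() {
  lwen_config(n_points = 48, d_hide = 64, heads = 4, d_fc = 32,
              epochs = 40, warmup_epochs = 4, lr_milestones = c(20, 32),
              batch_size = 32, noise_sd = 0.5)
}

#' Normalize a contour for liveweight regression
#'
#' Concatenates image normalization and bounding-box normalization into an
#' N x 4 sequence. Image normalization (columns 1-2) is (x - W)/W and
#' (y - H)/H, mapping coordinates into `[-1, 0]`; box normalization
#' (columns 3-4) rescales the contour to its own bounding box and acts as
#' the positional embedding. The image columns carry absolute position and
#' apparent size, the box columns carry pure shape.
#'
#' @param contour N x 2 pixel-coordinate matrix.
#' @param width,height image dimensions in pixels.
#' @param img_norm see [lwen_config()].
#' @return N x 4 matrix.
#' @export
lwen_normalize <- function(contour, width, height, img_norm = "printed") {
  p <- as.matrix(contour)
  if (width <= 0 || height <= 0) stop("image dimensions must be positive")
  img <- if (img_norm == "printed") {
    cbind((p[, 1] - width) / width, (p[, 2] - height) / height)
  } else {
    cbind((p[, 1] - width / 2) / (width / 2),
          (p[, 2] - height / 2) / (height / 2))
  }
  cbind(img, box_normalize(p))
}

#' Construct an untrained LWEN
#'
#' @param config from [lwen_config()].
#' @param seed RNG seed for weight initialization.
#' @return model list with parameter matrices and the config.
#' @export
lwen_build <- function(config = lwen_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- config$d_hide
  model <- list(
    lp = linear_init(4, d, bias = TRUE),
    blocks = lapply(seq_len(config$mhsa_layers), function(i)
      mhsa_init(d, config$heads)),
    fc1 = linear_init(d, config$d_fc, bias = TRUE),
    fc2 = linear_init(config$d_fc, 1, bias = TRUE),
    config = config,
    target_center = 0, target_scale = 1
  )
  model
}

lwen_fwd <- function(model, X_norm, keep_attention = FALSE) {
  Xlp <- linear_fwd(model$lp, X_norm)
  caches <- vector("list", length(model$blocks))
  X <- Xlp
  for (i in seq_along(model$blocks)) {
    r <- mhsa_fwd(model$blocks[[i]], X, keep_attention = keep_attention)
    caches[[i]] <- r$cache
    X <- r$out
  }
  Xf <- colMeans(X)
  z1 <- drop(Xf %*% model$fc1$W) + model$fc1$b
  h1 <- leaky_relu(z1)
  lw_raw <- drop(h1 %*% model$fc2$W) + model$fc2$b
  lw <- lw_raw * model$target_scale + model$target_center
  list(lw = lw, cache = list(X_norm = X_norm, Xlp = Xlp, blocks = caches,
                             Xm = X, Xf = Xf, z1 = z1, h1 = h1))
}

lwen_bwd <- function(model, cache, g_lw) {
  g_raw <- g_lw * model$target_scale
  g <- list()
  g$fc2 <- list(W = cbind(cache$h1) * g_raw, b = g_raw)
  gh1 <- drop(model$fc2$W) * g_raw
  gz1 <- gh1 * leaky_relu_grad(cache$z1)
  g$fc1 <- list(W = tcrossprod(cache$Xf, gz1), b = gz1)
  gXf <- drop(model$fc1$W %*% gz1)
  n <- nrow(cache$Xm)
  gX <- matrix(rep(gXf / n, each = n), n)
  g$blocks <- vector("list", length(model$blocks))
  for (i in rev(seq_along(model$blocks))) {
    r <- mhsa_bwd(model$blocks[[i]], cache$blocks[[i]], gX)
    g$blocks[[i]] <- r$grads
    gX <- r$gP
  }
  lb <- linear_bwd(model$lp, cache$X_norm, gX)
  g$lp <- lb$grads
  g
}

#' Predict liveweight from a contour
#'
#' @param model trained model from [train_lwen()] or [lwen_build()].
#' @param contour N x 2 pixel coordinates (order-free).
#' @param width,height image dimensions.
#' @return predicted liveweight in kg.
#' @export
lwen_forward <- function(model, contour, width, height) {
  Xn <- lwen_normalize(contour, width, height, model$config$img_norm)
  lwen_fwd(model, Xn)$lw
}

#' Smooth-L1 (Huber-type) loss on a liveweight prediction
#'
#' Quadratic for |error| < beta, linear beyond.
#' @param predicted,truth scalars (kg).
#' @param beta transition point.
#' @export
lwen_loss <- function(predicted, truth, beta = 1) {
  mean(smooth_l1(predicted - truth, beta))
}

#' Count trainable parameters of a model
#'
#' @param model model list whose numeric leaves (excluding config entries)
#'   are trainable arrays.
#' @return list with `count` and `label` ("X.XM" formatted).
#' @export
count_parameters <- function(model) {
  count_leaf <- function(x, nm) {
    if (identical(nm, "config")) return(0)
    if (is.list(x)) {
      nms <- names(x)
      if (is.null(nms)) nms <- rep("", length(x))
      return(sum(vapply(seq_along(x),
                        function(i) count_leaf(x[[i]], nms[i]), 1)))
    }
    if (is.numeric(x) && nm %in% c("W", "b", "WQ", "WK", "WV", "WO",
                                   "Wz1", "Wz2")) return(length(x))
    0
  }
  n <- count_leaf(model, "")
  list(count = n, label = sprintf("%.1fM", n / 1e6))
}

#' Train an LWEN on (contour, image dims, weight) records
#'
#' Training contours are uniformly resampled from the annotated ground
#' truth each epoch (random phase over a 4x oversampled boundary) and
#' jittered with Gaussian coordinate noise; smooth-L1 supervision with the
#' warm-up + milestone learning-rate schedule from the config. Targets are
#' standardized internally for optimization and mapped back to kg in the
#' model's output layer.
#'
#' @param records list of lists with `polygon` (ground-truth boundary,
#'   pixel coords), `width`, `height`, `weight`.
#' @param config from [lwen_config()].
#' @param seed RNG seed (weights, sampling phases, noise, batch order).
#' @param verbose print per-epoch losses.
#' @return list with `model` and `history` (mean training loss per epoch).
#' @export
train_lwen <- function(records, config = lwen_config(), seed = 1,
                       verbose = FALSE) {
  if (length(records) == 0) stop("empty dataset")
  set.seed(seed)
  model <- lwen_build(config)
  ws <- vapply(records, function(r) r$weight, 1)
  model$target_center <- mean(ws)
  model$target_scale <- max(stats::sd(ws), 1e-8)
  opt <- adam_state(model[c("lp", "blocks", "fc1", "fc2")])
  n <- length(records)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    lr <- config$lr *
      config$lr_decay^sum(ep > config$lr_milestones) *
      (if (ep <= config$warmup_epochs) config$warmup_factor else 1)
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      grads <- NULL
      for (i in idx) {
        r <- records[[i]]
        ct <- sample_contour_points(r$polygon, 4 * config$n_points,
                                    phase = stats::runif(1))
        ct <- ct[seq(1, 4 * config$n_points, by = 4), , drop = FALSE]
        if (stats::runif(1) < 0.5)            # horizontal flip
          ct[, 1] <- r$width - 1 - ct[, 1]
        if (config$noise_sd > 0)
          ct <- ct + matrix(stats::rnorm(length(ct), 0, config$noise_sd),
                            ncol = 2)
        Xn <- lwen_normalize(ct, r$width, r$height, config$img_norm)
        fw <- lwen_fwd(model, Xn)
        err <- (fw$lw - r$weight) / model$target_scale
        ep_loss <- ep_loss + smooth_l1(err)
        g_lw <- smooth_l1_grad(err) / model$target_scale
        grads <- grads_add(grads, lwen_bwd(model, fw$cache, g_lw))
      }
      grads <- grads_scale(grads, 1 / length(idx))
      st <- adam_step(model[c("lp", "blocks", "fc1", "fc2")], grads, opt,
                      lr, weight_decay = config$weight_decay)
      model[c("lp", "blocks", "fc1", "fc2")] <- st$params
      opt <- st$state
    }
    history[ep] <- ep_loss / n
    if (verbose && (ep %% 10 == 0 || ep == 1))
      message(sprintf("epoch %d loss %.4f lr %.2g", ep, history[ep], lr))
  }
  list(model = model, history = history)
}

#' Export per-head attention maps from a fitted LWEN
#'
#' Runs the network on one contour and returns each head's N x N attention
#' matrix from the first attention block, normalized to `[0, 1]` per head,
#' with values below `mask_below` zeroed for display. Raw (pre-
#' normalization) rows are softmax distributions summing to 1.
#'
#' @param model trained LWEN.
#' @param contour N x 2 pixel coordinates.
#' @param width,height image dimensions.
#' @param mask_below display mask threshold.
#' @return list with `normalized` (list of masked maps), `raw` (softmax
#'   attention), and `prediction`.
#' @export
export_attention <- function(model, contour, width, height,
                             mask_below = 0.1) {
  Xn <- lwen_normalize(contour, width, height, model$config$img_norm)
  fw <- lwen_fwd(model, Xn, keep_attention = TRUE)
  raw <- fw$cache$blocks[[1]]$attention
  normalized <- lapply(raw, function(A) {
    A <- (A - min(A)) / max(max(A) - min(A), 1e-12)
    A[A < mask_below] <- 0
    A
  })
  list(normalized = normalized, raw = raw, prediction = fw$lw)
}
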