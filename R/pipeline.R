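# End-to-end orchestration: synthetic dataset -> contour network training
# -> contour extraction -> liveweight network training -> evaluation
# reports, plus the supervision/refinement ablation grid. One seed
# reproduces the whole chain.

#' Run configuration for the end-to-end pipeline
#'
#' @param preset "desk" (CPU-scale defaults: 96 x 96 scenes, 100/50/50
#'   split, width-reduced networks) or "paper" (the full-scale schedules).
#' @param seed global seed; every stage derives its randomness from it.
#' @param n_scenes total scene count.
#' @param cien,lwen component configs (defaults follow the preset).
#' @param camera,wmodel synthetic-scene generation models.
#' @export
run_config <- function(preset = c("desk", "paper"), seed = 1,
                       n_scenes = 200, cien = NULL, lwen = NULL,
                       camera = NULL, wmodel = weight_model()) {
  preset <- match.arg(preset)
  if (is.null(cien)) cien <- cien_config(preset)
  if (is.null(lwen))
    lwen <- if (preset == "desk") lwen_config_desk() else lwen_config()
  if (is.null(camera)) {
    camera <- if (preset == "desk") camera_model(96, 96)
              else camera_model(768, 576, px_per_unit = 24)
  }
  list(preset = preset, seed = seed, n_scenes = n_scenes, cien = cien,
       lwen = lwen, camera = camera, wmodel = wmodel,
       split = c(0.5, 0.25, 0.25))
}

contour_records <- function(scenes) {
  out <- list()
  for (r in scenes) {
    for (i in r$instances)
      out[[length(out) + 1]] <- list(polygon = i$polygon, width = r$width,
                                     height = r$height, weight = i$weight,
                                     instance_id = i$instance_id)
  }
  out
}

#' Train and evaluate the full dual-network pipeline
#'
#' Generates a synthetic dataset, trains the contour network (OT
#' supervision) and the liveweight network (ground-truth contour
#' sampling), then evaluates on the held-out test split: segmentation AP
#' from rasterized predicted contours, and weight-regression metrics on
#' liveweights predicted from the CIEN-extracted contours (matched to
#' ground-truth instances by mask IoU >= 0.5). Images without any
#' detection are reported, not silently dropped.
#'
#' @param config from [run_config()].
#' @param verbose print training progress.
#' @return list with `segmentation` (AP metrics), `regression` (weight
#'   metrics or NULL when nothing matched), `predictions` (per-instance
#'   table), `skipped` (scene ids with no detection), `models`.
#' @export
run_end_to_end <- function(config = run_config(), verbose = FALSE) {
  ds <- make_dataset(config$n_scenes, seed = config$seed,
                     camera = config$camera, wmodel = config$wmodel,
                     split = config$split)
  cien_fit <- train_cien(ds$train, config$cien, seed = config$seed + 1,
                         verbose = verbose)
  lwen_fit <- train_lwen(contour_records(ds$train), config$lwen,
                         seed = config$seed + 2, verbose = verbose)
  seg <- evaluate_cien(cien_fit$model, ds$test)
  rows <- list()
  for (i in seq_along(ds$test)) {
    rec <- ds$test[[i]]
    dets <- cien_infer(cien_fit$model, rec$image)
    truth_masks <- lapply(rec$instances, function(inst)
      rasterize_contour(inst$polygon, rec$height, rec$width,
                        check_simple = FALSE))
    for (d in dets) {
      ordered <- order_points_tsp(d$contour)$contour
      resampled <- sample_contour_points(ordered, config$lwen$n_points)
      lw <- lwen_forward(lwen_fit$model, resampled, rec$width, rec$height)
      pm <- rasterize_contour(ordered, rec$height, rec$width,
                              check_simple = FALSE)
      ious <- vapply(truth_masks, function(tm) mask_iou(pm, tm), 1)
      j <- which.max(ious)
      rows[[length(rows) + 1]] <- data.frame(
        scene_id = rec$scene_id, score = d$score,
        predicted_kg = lw,
        matched_instance = if (ious[j] >= 0.5)
          rec$instances[[j]]$instance_id else NA_integer_,
        truth_kg = if (ious[j] >= 0.5) rec$instances[[j]]$weight
          else NA_real_,
        iou = ious[j], stringsAsFactors = FALSE)
    }
  }
  predictions <- if (length(rows)) do.call(rbind, rows) else NULL
  regression <- NULL
  if (!is.null(predictions)) {
    ok <- !is.na(predictions$truth_kg)
    if (any(ok))
      regression <- regression_metrics(predictions$predicted_kg[ok],
                                       predictions$truth_kg[ok])
  }
  list(segmentation = seg$metrics, regression = regression,
       predictions = predictions, skipped = seg$skipped,
       models = list(cien = cien_fit$model, lwen = lwen_fit$model),
       history = list(cien = cien_fit$history, lwen = lwen_fit$history))
}

#' Supervision x refinement ablation grid
#'
#' Trains {no-refinement baseline, CSA refinement} x {OT, KM} variants at
#' equal budget and fixed seed on the same dataset and reports mask AP
#' per cell.
#'
#' @param config from [run_config()]; the CIEN config supplies the budget.
#' @param verbose print progress.
#' @return data.frame with columns refinement, supervision, ap, ap50.
#' @export
run_ablation <- function(config = run_config(), verbose = FALSE) {
  ds <- make_dataset(config$n_scenes, seed = config$seed,
                     camera = config$camera, wmodel = config$wmodel,
                     split = config$split)
  grid <- expand.grid(refinement = c("none", "csa"),
                      supervision = c("km", "ot"),
                      stringsAsFactors = FALSE)
  grid$ap <- grid$ap50 <- NA_real_
  for (g in seq_len(nrow(grid))) {
    cfg <- config$cien
    cfg$use_csa <- grid$refinement[g] == "csa"
    cfg$supervision <- grid$supervision[g]
    fit <- train_cien(ds$train, cfg, seed = config$seed + 1,
                      verbose = verbose)
    ev <- evaluate_cien(fit$model, ds$test)
    grid$ap[g] <- ev$metrics$ap
    grid$ap50[g] <- ev$metrics$ap50
    if (verbose)
      message(sprintf("%s + %s: AP %.3f AP50 %.3f", grid$refinement[g],
                      grid$supervision[g], grid$ap[g], grid$ap50[g]))
  }
  grid
}

#' Predict liveweights for a batch of contours
#'
#' @param model trained LWEN.
#' @param contours list of N x 2 matrices (any point count; resampled to
#'   the model's configured count), or a single matrix.
#' @param width,height image dimensions.
#' @return data.frame with instance index and predicted kg.
#' @export
predict_weights <- function(model, contours, width, height) {
  if (is.matrix(contours)) contours <- list(contours)
  n_pts <- model$config$n_points
  kg <- vapply(contours, function(ct) {
    if (nrow(ct) != n_pts) ct <- sample_contour_points(ct, n_pts)
    lwen_forward(model, ct, width, height)
  }, 1)
  data.frame(instance = seq_along(contours), predicted_kg = kg)
}
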