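# OKS-based evaluation of keypoint predictions.

#' OKS evaluation configuration
#'
#' @param sigmas Per-landmark normalization constants (labeling-noise
#'   standard deviations); one value per canonical landmark.
#' @param thresholds Strictly increasing OKS threshold grid in (0, 1).
#' @param area_convention "sqrt_area" uses s = sqrt(bbox area), the
#'   standard dimensionally consistent scale; "raw_area" uses s = bbox area
#'   literally.
#' @return List of class `oks_config`.
#' @export
oks_config <- function(sigmas = rep(0.05, 6),
                       thresholds = seq(0.50, 0.95, by = 0.05),
                       area_convention = c("sqrt_area", "raw_area")) {
  area_convention <- match.arg(area_convention)
  if (any(sigmas <= 0)) stop_bovi("sigmas must be positive", class = "eval_error")
  if (length(sigmas) != length(keypoint_names()))
    stop_bovi("need one sigma per canonical landmark", class = "eval_error")
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0) || any(thresholds >= 1))
    stop_bovi("thresholds must be strictly increasing within (0, 1)", class = "eval_error")
  structure(list(sigmas = sigmas, thresholds = thresholds,
                 area_convention = area_convention), class = "oks_config")
}

oks_scale <- function(bbox_area, config) {
  switch(config$area_convention,
         sqrt_area = sqrt(bbox_area),
         raw_area = bbox_area)
}

# Per-keypoint Gaussian similarity terms for visible ground-truth
# landmarks: exp(-d_i^2 / (2 s^2 sigma_i^2)).
oks_terms <- function(pred, gt, config) {
  pk <- pred$keypoints; gk <- gt$keypoints
  vis <- gk$visibility > 0L
  if (!any(vis))
    stop_bovi("OKS undefined: ground truth has no visible keypoints",
              class = "undefined_oks_error")
  if (gt$bbox_area <= 0)
    stop_bovi("OKS undefined: non-positive bounding-box area", class = "undefined_oks_error")
  s <- oks_scale(gt$bbox_area, config)
  d2 <- (pk$u - gk$u)^2 + (pk$v - gk$v)^2
  d2[is.na(d2)] <- Inf  # invisible/missing prediction for a visible gt keypoint
  terms <- exp(-d2 / (2 * s^2 * config$sigmas^2))
  list(terms = terms[vis], which = which(vis))
}

#' Object keypoint similarity between a prediction and ground truth
#'
#' Mean over visible ground-truth keypoints of
#' exp(-d_i^2 / (2 s^2 sigma_i^2)), where d_i is the pixel distance between
#' predicted and true landmark i and s is the object scale from the
#' bounding-box area.
#'
#' @param pred,gt `keypoint_set` objects.
#' @param config `oks_config`.
#' @return OKS value in [0, 1].
#' @export
oks <- function(pred, gt, config = oks_config()) {
  mean(oks_terms(pred, gt, config)$terms)
}

#' Average precision at one OKS threshold
#'
#' The fraction of instances whose OKS strictly exceeds the threshold
#' (indicator form; ties at the threshold do not count).
#'
#' @param oks_values Non-empty numeric vector of per-instance OKS values.
#' @param T Threshold in (0, 1).
#' @return AP in [0, 1].
#' @export
ap_at_threshold <- function(oks_values, T) {
  if (!length(oks_values)) stop_bovi("empty OKS list", class = "eval_error")
  mean(oks_values > T)
}

#' Mean average precision
#'
#' Arithmetic mean of per-category (or per-threshold) AP values.
#'
#' @param per_category_ap Non-empty numeric vector.
#' @return mAP.
#' @export
mean_ap <- function(per_category_ap) {
  if (!length(per_category_ap)) stop_bovi("empty AP list", class = "eval_error")
  mean(per_category_ap)
}

#' Precision and recall from detection counts
#'
#' P = TP / (TP + FP), R = TP / (TP + FN); 0/0 is defined as 0 and flagged.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return List with `precision`, `recall` and logical `degenerate` flags.
#' @export
precision_recall <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop_bovi("counts must be non-negative", class = "eval_error")
  p_deg <- (tp + fp) == 0
  r_deg <- (tp + fn) == 0
  list(precision = if (p_deg) 0 else tp / (tp + fp),
       recall = if (r_deg) 0 else tp / (tp + fn),
       degenerate = c(precision = p_deg, recall = r_deg))
}

#' Match predicted keypoint sets to ground-truth sets
#'
#' Greedy one-to-one matching: predictions are visited in descending mean
#' confidence and each takes the unmatched ground truth with the highest
#' OKS. Unmatched predictions count as false-positive instances and
#' unmatched ground truths as false negatives. Keypoint-level TP requires
#' the per-keypoint OKS term to exceed `decision_threshold`.
#'
#' @param preds,gts Lists of `keypoint_set`.
#' @param config `oks_config`.
#' @param decision_threshold OKS term threshold for keypoint-level TP.
#' @return List: `oks` (per matched instance), `matches` (pred, gt index
#'   pairs), keypoint-level `tp`, `fp`, `fn`, and instance-level
#'   `unmatched_pred` / `unmatched_gt` counts.
#' @export
match_predictions <- function(preds, gts, config = oks_config(),
                              decision_threshold = 0.5) {
  conf <- vapply(preds, function(p) {
    k <- p$keypoints; v <- k$visibility > 0L
    if (any(v)) mean(k$confidence[v]) else 0
  }, numeric(1))
  order_pred <- order(conf, decreasing = TRUE)
  taken <- rep(FALSE, length(gts))
  matches <- NULL
  oks_list <- numeric(0)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (pi in order_pred) {
    best <- 0; best_gi <- NA_integer_; best_terms <- NULL
    for (gi in seq_along(gts)) {
      if (taken[gi]) next
      ot <- tryCatch(oks_terms(preds[[pi]], gts[[gi]], config),
                     undefined_oks_error = function(e) NULL)
      if (is.null(ot)) next
      val <- mean(ot$terms)
      if (is.na(best_gi) || val > best) { best <- val; best_gi <- gi; best_terms <- ot }
    }
    if (!is.na(best_gi)) {
      taken[best_gi] <- TRUE
      matches <- rbind(matches, c(pred = pi, gt = best_gi))
      oks_list <- c(oks_list, best)
      hit <- best_terms$terms > decision_threshold
      tp <- tp + sum(hit)
      fn <- fn + sum(!hit)
      # predicted-visible keypoints aimed at invisible gt landmarks
      pk <- preds[[pi]]$keypoints; gk <- gts[[best_gi]]$keypoints
      fp <- fp + sum(pk$visibility > 0L & gk$visibility == 0L) + sum(!hit)
    } else {
      fp <- fp + sum(preds[[pi]]$keypoints$visibility > 0L)
    }
  }
  for (gi in which(!taken))
    fn <- fn + sum(gts[[gi]]$keypoints$visibility > 0L)
  list(oks = oks_list, matches = matches, tp = tp, fp = fp, fn = fn,
       unmatched_pred = length(preds) - length(oks_list),
       unmatched_gt = sum(!taken))
}

#' Summarize keypoint-detection performance
#'
#' Matches predictions to ground truth, then reports AP on the threshold
#' grid, mAP over the grid, AP@0.5, precision, recall and the TP/FP/FN
#' counts.
#'
#' @inheritParams match_predictions
#' @return List of class `eval_summary`.
#' @export
evaluate_keypoints <- function(preds, gts, config = oks_config(),
                               decision_threshold = 0.5) {
  m <- match_predictions(preds, gts, config, decision_threshold)
  n_gt <- length(gts)
  # false-negative instances enter the AP pool with OKS 0
  pool <- c(m$oks, rep(0, m$unmatched_gt))
  ap <- vapply(config$thresholds, function(T) ap_at_threshold(pool, T), numeric(1))
  names(ap) <- sprintf("AP@%.2f", config$thresholds)
  pr <- precision_recall(m$tp, m$fp, m$fn)
  structure(list(ap = ap,
                 ap50 = unname(ap[which.min(abs(config$thresholds - 0.5))]),
                 map = mean_ap(ap),
                 precision = pr$precision, recall = pr$recall,
                 tp = m$tp, fp = m$fp, fn = m$fn,
                 n_instances = n_gt, oks = m$oks),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("Keypoint evaluation over %d instance(s):\n", x$n_instances))
  cat(sprintf("  AP@0.50          %.4f\n", x$ap50))
  cat(sprintf("  AP@[0.50:0.95]   %.4f\n", x$map))
  cat(sprintf("  precision %.4f  recall %.4f  (TP %d, FP %d, FN %d)\n",
              x$precision, x$recall, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Absolute AP improvement in percentage points
#'
#' @param ap_new,ap_ref AP values on the [0, 1] scale.
#' @return (ap_new - ap_ref) * 100, in percentage points.
#' @export
ap_improvement <- function(ap_new, ap_ref) {
  (ap_new - ap_ref) * 100
}

#' Dataset split sizes under a ratio with rounding
#'
#' Train and validation counts are the rounded fractions; the test set
#' takes the remainder so the three parts always sum to `n`.
#'
#' @param n Total number of images.
#' @param ratios Length-3 split proportions (normalized internally).
#' @return Named integer vector (train, validation, test).
#' @export
split_counts <- function(n, ratios = c(7, 2, 1)) {
  stopifnot(length(ratios) == 3L, all(ratios > 0), n >= 0)
  p <- ratios / sum(ratios)
  train <- round(n * p[1])
  validation <- round(n * p[2])
  c(train = train, validation = validation, test = n - train - validation)
}
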