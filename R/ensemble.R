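#' Predict a binary segmentation mask for one case
#'
#' Runs the model slice-wise over a channel stack and thresholds the
#' per-pixel probabilities. A probability exactly equal to the threshold is
#' included (>= rule).
#'
#' @param model A trained `unet_model`.
#' @param stack A `channel_stack` from [assemble_channels()].
#' @param prob_threshold Binarization threshold (default 0.5).
#' @param out_shape Optional (nx, ny) of the native grid; when given, the
#'   thresholded slices are resampled back to it (nearest neighbour).
#' @param spacing Voxel spacing recorded in the returned mask.
#' @return A `seg_mask`.
#' @export
predict_mask <- function(model, stack, prob_threshold = 0.5,
                         out_shape = NULL, spacing = c(1, 1, 1)) {
  if (!inherits(model, "unet_model")) abort("`model` must be a unet_model.")
  d <- dim(stack)
  if (length(d) != 4 || d[3] != 3) abort("`stack` must be (H, W, 3, slices).")
  if (d[1] != model$config$input_size) {
    abort("Slice size of `stack` does not match the model input size.")
  }
  prob <- predict_prob_array(model$params, model$state, unclass(stack),
                             model$config)
  bin <- array(as.integer(prob[, , 1, ] >= prob_threshold), c(d[1], d[2], d[4]))
  if (!is.null(out_shape)) {
    out <- array(0L, c(out_shape[1], out_shape[2], d[4]))
    for (z in seq_len(d[4])) {
      sl <- EBImage::resize(bin[, , z], w = out_shape[1], h = out_shape[2],
                            filter = "none")
      out[, , z] <- as.integer(round(as.numeric(sl)))
    }
    bin <- out
  }
  new_seg_mask(bin, spacing)
}

#' Majority-vote fusion of ensemble member masks
#'
#' A voxel is labeled positive when at least `min_votes` of the member
#' masks label it positive (default: 3 of 5).
#'
#' @param member_masks List of binary arrays or `seg_mask`s of one shape.
#' @param min_votes Minimum number of positive votes (default 3).
#' @return A `seg_mask` consensus.
#' @export
majority_vote <- function(member_masks, min_votes = 3) {
  if (length(member_masks) < 1) abort("Need at least one member mask.")
  vox <- lapply(member_masks, function(m) if (inherits(m, "seg_mask")) m$voxels else m)
  spacing <- if (inherits(member_masks[[1]], "seg_mask")) {
    member_masks[[1]]$spacing
  } else {
    c(1, 1, 1)
  }
  d <- dim(vox[[1]])
  for (m in vox) {
    if (!identical(dim(m), d)) abort("Member masks differ in shape.")
    if (!is_binary_array(m)) abort("Member masks must be binary.")
  }
  votes <- Reduce(`+`, vox)
  new_seg_mask(array(as.integer(votes >= min_votes), d), spacing)
}

#' Dice similarity coefficient between two binary masks
#'
#' `DSC = 2 |T intersect P| / (|T| + |P|)`. Symmetric and in \[0, 1\]. By
#' documented convention two empty masks give 1.0 and exactly one empty
#' mask gives 0.0 (never `NaN`).
#'
#' @param truth,pred Binary arrays or `seg_mask`s of identical shape.
#' @return DSC value.
#' @export
dice_coefficient <- function(truth, pred) {
  t_vox <- if (inherits(truth, "seg_mask")) truth$voxels else truth
  p_vox <- if (inherits(pred, "seg_mask")) pred$voxels else pred
  if (!identical(dim(t_vox), dim(p_vox))) abort("Masks differ in shape.")
  if (!is_binary_array(t_vox) || !is_binary_array(p_vox)) {
    abort("Masks must be binary.")
  }
  st <- sum(t_vox); sp <- sum(p_vox)
  if (st + sp == 0) return(1)
  2 * sum(t_vox * p_vox) / (st + sp)
}

#' Ensemble prediction for one case
#'
#' Applies every cross-validation model to the case and fuses the member
#' masks by majority vote.
#'
#' @param models List of trained `unet_model`s (typically the 5 CV models).
#' @param case A `patient_case`.
#' @param channel_mode Input mode used at training time.
#' @param min_votes Vote threshold (default 3).
#' @param prob_threshold Member binarization threshold (default 0.5).
#' @param native Resample the consensus back to the case's native grid.
#' @return List with `consensus` (`seg_mask`) and `members` (list of
#'   `seg_mask`s). Class `ensemble_prediction`.
#' @export
ensemble_predict <- function(models, case, channel_mode = "multi",
                             min_votes = 3, prob_threshold = 0.5,
                             native = FALSE) {
  size <- models[[1]]$config$input_size
  stack <- assemble_channels(case, channel_mode, size)
  out_shape <- if (native) dim(case$b0)[1:2]
  members <- lapply(models, predict_mask, stack = stack,
                    prob_threshold = prob_threshold, out_shape = out_shape,
                    spacing = case$spacing)
  structure(
    list(consensus = majority_vote(members, min_votes), members = members,
         vote_threshold = min_votes, case_id = case$case_id),
    class = "ensemble_prediction"
  )
}

#' Summarize cross-validation DSC values (mean and range)
#'
#' @param per_fold_dsc Numeric vector of per-fold DSC values.
#' @return Tibble with `mean_dsc`, `min_dsc`, `max_dsc`.
#' @export
summarize_cv <- function(per_fold_dsc) {
  if (length(per_fold_dsc) == 0) abort("No DSC values supplied.")
  tibble::tibble(mean_dsc = mean(per_fold_dsc),
                 min_dsc = min(per_fold_dsc),
                 max_dsc = max(per_fold_dsc))
}

#' Summarize test-set DSC values (median and interquartile range)
#'
#' Quartiles use linear interpolation (R type 7), fixed for
#' reproducibility.
#'
#' @param per_case_dsc Numeric vector of per-case DSC values.
#' @return Tibble with `median_dsc`, `q1_dsc`, `q3_dsc`.
#' @export
summarize_test <- function(per_case_dsc) {
  if (length(per_case_dsc) == 0) abort("No DSC values supplied.")
  q <- q13(per_case_dsc)
  tibble::tibble(median_dsc = median(per_case_dsc),
                 q1_dsc = q[1], q3_dsc = q[2])
}

#' Per-case DSC report for an evaluated set
#'
#' @param per_case Named numeric vector or tibble (case_id, dsc).
#' @param style `"test"` (median + IQR) or `"cv"` (mean + range).
#' @return A `dsc_report`: tibble of per-case values with the aggregate in
#'   attribute `aggregate`.
#' @export
dsc_report <- function(per_case, style = c("test", "cv")) {
  style <- match.arg(style)
  tbl <- if (is.data.frame(per_case)) {
    tibble::as_tibble(per_case)
  } else {
    tibble::tibble(case_id = names(per_case) %||%
                     paste0("case_", seq_along(per_case)),
                   dsc = as.numeric(per_case))
  }
  if (any(tbl$dsc < 0 | tbl$dsc > 1)) abort("DSC values must lie in [0, 1].")
  agg <- if (style == "test") summarize_test(tbl$dsc) else summarize_cv(tbl$dsc)
  structure(tbl, aggregate = agg, style = style,
            class = c("dsc_report", class(tbl)))
}
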