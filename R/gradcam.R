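# Grad-CAM explanation volumes.
#
# The target layer is the last transformer block's output token grid,
# reshaped to (g, g, g) x embed_dim. Channel weights are the spatial means of
# the gradient of the chosen class logit; the CAM is the ReLU of the weighted
# channel sum, upsampled (nearest-neighbor) to patch resolution and
# normalized to [0, 1].

upsample_nearest <- function(vol, factor) {
  d <- dim(vol)
  idx1 <- rep(seq_len(d[1L]), each = factor)
  idx2 <- rep(seq_len(d[2L]), each = factor)
  idx3 <- rep(seq_len(d[3L]), each = factor)
  vol[idx1, idx2, idx3]
}

#' Grad-CAM attention volume
#'
#' @param ckpt a [train()] checkpoint (or a list with `model` and
#'   `std_stats`).
#' @param subject one subject (patch-sized, or croppable via
#'   [extract_patch()]).
#' @param task `"idh"` or `"grade"`.
#' @param target `"predicted"` (default), `"class1"` or `"class0"`: the logit
#'   whose gradient drives the map.
#' @return list of class `gradcam_map`: `map` (3D array in `[0, 1]` at patch
#'   resolution), `flagged_zero` (`TRUE` when every gradient vanished),
#'   `task`, `class_index`.
#' @export
gradcam <- function(ckpt, subject, task = c("idh", "grade"),
                    target = c("predicted", "class1", "class0")) {
  task <- match.arg(task)
  target <- match.arg(target)
  model <- ckpt$model
  input_size <- model$cfg$input_size
  if (!identical(dim(subject$roi_mask), rep(input_size, 3L))) {
    subject <- extract_patch(subject, input_size)
  }
  x_hc <- if (!is.null(ckpt$std_stats)) {
    as.numeric(apply_std(matrix(subject$features, nrow = 1L),
                         ckpt$std_stats))
  } else {
    as.numeric(subject$features)
  }
  cfg <- ckpt$cfg
  out <- model_fwd_ag(model, subject$volumes, x_hc, training = FALSE,
                      bypass_mfeb = isTRUE(cfg$bypass_mfeb),
                      use_adapters = !isFALSE(cfg$use_adapters))
  logits <- nn_linear_fwd(model$heads[[task]], out$feature)
  cls <- switch(target,
                predicted = which.max(logits$value[, 1L]),
                class1 = 2L, class0 = 1L)
  z <- ag_pick(logits, cls)
  ag_backward(z)
  A <- out$tokens$value                      # [E, N]
  dA <- out$tokens$grad
  if (is.null(dA) || all(dA == 0)) {
    return(structure(list(map = array(0, rep(input_size, 3L)),
                          flagged_zero = TRUE, task = task,
                          class_index = cls - 1L), class = "gradcam_map"))
  }
  w <- rowMeans(dA)
  cam <- pmax(as.vector(crossprod(A, matrix(w, ncol = 1L))), 0)  # [N]
  g <- out$grid
  cam_vol <- array(cam, g)
  cam_full <- upsample_nearest(cam_vol, input_size %/% g[1L])
  m <- max(cam_full)
  flagged <- m <= 0
  if (m > 0) cam_full <- cam_full / m
  structure(list(map = cam_full, flagged_zero = flagged, task = task,
                 class_index = cls - 1L), class = "gradcam_map")
}
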