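# Training and evaluation orchestration.

#' Training configuration
#'
#' Reference settings follow the published recipe: Ranger optimizer, initial
#' learning rate 2e-5 with decay, batch size 4, 80/20 train/test split with
#' 15% of the training data for validation. The scaled-down defaults used in
#' tests are set through the arguments, not by editing the reference values.
#'
#' @param encoder an [encoder_config()].
#' @param learning_rate initial learning rate.
#' @param batch_size gradient-accumulation batch size.
#' @param epochs training epochs.
#' @param seed master seed: controls splitting, initialization, shuffling,
#'   dropout and augmentation.
#' @param optimizer `"ranger"` or `"adam"`.
#' @param schedule `"cosine"` (decay to 0) or `"constant"`.
#' @param augmentation named logical list: `flip`, `rotate`, `noise`,
#'   `intensity`, `shift`.
#' @param loss a [loss_config()]; its `alpha` is replaced per task by the
#'   training-split negative/positive ratio.
#' @param test_fraction,val_fraction held-out test fraction and validation
#'   fraction of the remaining training data.
#' @param tasks character subset of `c("idh", "grade")` (ablation hook).
#' @param bypass_mfeb replace the learned mismatch map by plain subtraction
#'   (ablation hook).
#' @param use_adapters disable to train with the plain backbone (ablation
#'   hook).
#' @param mfeb_width internal channel width of the mismatch block.
#' @return list of class `train_config`.
#' @export
train_config <- function(encoder = encoder_config(),
                         learning_rate = 2e-5, batch_size = 4L, epochs = 10L,
                         seed = 1L, optimizer = c("ranger", "adam"),
                         schedule = c("cosine", "constant"),
                         augmentation = list(flip = TRUE, rotate = TRUE,
                                             noise = TRUE, intensity = TRUE,
                                             shift = TRUE),
                         loss = loss_config(),
                         test_fraction = 0.2, val_fraction = 0.15,
                         tasks = c("idh", "grade"), bypass_mfeb = FALSE,
                         use_adapters = TRUE, mfeb_width = 8L) {
  optimizer <- match.arg(optimizer)
  schedule <- match.arg(schedule)
  tasks <- match.arg(tasks, c("idh", "grade"), several.ok = TRUE)
  if (test_fraction < 0 || test_fraction >= 1 || val_fraction < 0 ||
      val_fraction >= 1) {
    stop("split fractions must lie in [0, 1)")
  }
  structure(list(encoder = encoder, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 optimizer = optimizer, schedule = schedule,
                 augmentation = augmentation, loss = loss,
                 test_fraction = test_fraction, val_fraction = val_fraction,
                 tasks = tasks, bypass_mfeb = isTRUE(bypass_mfeb),
                 use_adapters = isTRUE(use_adapters),
                 mfeb_width = as.integer(mfeb_width)),
            class = "train_config")
}

# ---- augmentation -----------------------------------------------------------

flip3d <- function(vol, axis) {
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- rev(seq_len(dim(vol)[axis]))
  do.call(`[`, c(list(vol), idx))
}

rot90_3d <- function(vol, axes, k) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    perm <- seq_len(3L)
    perm[axes] <- rev(axes)
    vol <- flip3d(aperm(vol, perm), axes[1L])
  }
  vol
}

shift3d <- function(vol, by) {
  d <- dim(vol)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s <- by[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) {
      src[[a]] <- 1:(d[a] - s); dst[[a]] <- (1 + s):d[a]
    } else {
      src[[a]] <- (1 - s):d[a]; dst[[a]] <- 1:(d[a] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

#' Augment one subject patch
#'
#' Geometric transforms (axis flips, 90-degree rotations, integer voxel
#' shifts) are applied congruently to all modalities and the mask; intensity
#' transforms (Gaussian noise, scale/shift) touch the volumes only. With all
#' toggles off the subject is returned unchanged; a fixed `seed` makes the
#' augmentation deterministic.
#'
#' @param subject a `phantom_subject` (volumes + roi_mask).
#' @param toggles named logical list (see [train_config()]).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return the augmented subject.
#' @export
augment <- function(subject, toggles = list(), seed = NULL) {
  run <- function() {
    vols <- subject$volumes
    mask <- subject$roi_mask
    if (isTRUE(toggles$flip)) {
      for (a in 1:3) {
        if (stats::runif(1) < 0.5) {
          vols <- lapply(vols, flip3d, axis = a)
          mask <- flip3d(mask, a)
        }
      }
    }
    if (isTRUE(toggles$rotate)) {
      axes <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))[[sample.int(3L, 1L)]]
      k <- sample.int(4L, 1L) - 1L
      vols <- lapply(vols, rot90_3d, axes = axes, k = k)
      mask <- rot90_3d(mask, axes, k)
    }
    if (isTRUE(toggles$shift)) {
      s <- max(1L, round(0.05 * dim(mask)[1L]))
      by <- sample(seq(-s, s), 3L, replace = TRUE)
      vols <- lapply(vols, shift3d, by = by)
      mask <- shift3d(mask, by)
      storage.mode(mask) <- "integer"
    }
    if (isTRUE(toggles$intensity)) {
      sc <- stats::runif(1, 0.9, 1.1)
      sh <- stats::runif(1, -0.1, 0.1)
      vols <- lapply(vols, function(v) v * sc + sh)
    }
    if (isTRUE(toggles$noise)) {
      vols <- lapply(vols, function(v) {
        v + array(stats::rnorm(length(v), sd = 0.05), dim(v))
      })
    }
    subject$volumes <- vols
    storage.mode(mask) <- "integer"
    subject$roi_mask <- mask
    subject
  }
  if (is.null(seed)) run() else with_rng(seed, run())
}

# ---- splitting --------------------------------------------------------------

# stratified by the joint (idh, grade) label; deterministic under the RNG
split_indices <- function(idh, grade, fraction) {
  strata <- interaction(idh, grade, drop = TRUE)
  held <- integer(0)
  for (s in levels(strata)) {
    idx <- sample(which(strata == s))
    k <- round(length(idx) * fraction)
    held <- c(held, idx[seq_len(k)])
  }
  sort(held)
}

subject_labels <- function(cohort) {
  list(idh = vapply(cohort, function(s) s$idh_label, integer(1)),
       grade = vapply(cohort, function(s) s$grade_label, integer(1)))
}

cohort_features <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) s$features))
}

# ---- training ---------------------------------------------------------------

#' Train the multi-task model
#'
#' Splits the cohort (stratified jointly on both labels) into test /
#' validation / training parts, standardizes tabular features on the training
#' rows only, sets each task's class weight alpha to the training-split
#' negative/positive ratio, and optimizes the uncertainty-weighted joint loss
#' with gradient accumulation. The best-validation parameter state is
#' retained.
#'
#' @param cohort a `phantom_cohort` (or list of subjects with volumes, mask,
#'   labels, features).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return list of class `mtg_checkpoint`: `model` (best-validation state),
#'   `history` (per-epoch train/val losses and the gamma_i trajectory),
#'   `std_stats`, index vectors `train_idx`, `val_idx`, `test_idx`, `alpha`,
#'   and the config.
#' @export
train <- function(cohort, cfg, verbose = FALSE) {
  lab <- subject_labels(cohort)
  n <- length(cohort)
  with_rng(cfg$seed, {
    test_idx <- if (cfg$test_fraction > 0) {
      split_indices(lab$idh, lab$grade, cfg$test_fraction)
    } else integer(0)
    rest <- setdiff(seq_len(n), test_idx)
    val_rel <- if (cfg$val_fraction > 0) {
      split_indices(lab$idh[rest], lab$grade[rest], cfg$val_fraction)
    } else integer(0)
    val_idx <- rest[val_rel]
    train_idx <- setdiff(rest, val_idx)
    for (task in c("idh", "grade")) {
      y <- lab[[task]][train_idx]
      if (length(unique(y)) < 2L) {
        stop("class absent from the training split for task '", task,
             "'; use a larger cohort")
      }
    }
    if (length(val_idx) > 0L) {
      for (task in c("idh", "grade")) {
        if (length(unique(lab[[task]][val_idx])) < 2L &&
            length(val_idx) < 2L) {
          stop("validation split degenerate; use a larger cohort")
        }
      }
    }

    feats <- cohort_features(cohort)
    std <- standardize(feats, fit_rows = train_idx)
    Z <- std$matrix

    # alpha per task: negative/positive ratio on the training split,
    # applied to positive-class samples
    alpha <- vapply(c("idh", "grade"), function(task) {
      y <- lab[[task]][train_idx]
      sum(y == 0L) / sum(y == 1L)
    }, numeric(1))

    input_size <- cfg$encoder$input_size
    prep <- lapply(cohort, function(s) {
      if (!identical(dim(s$roi_mask), rep(input_size, 3L))) {
        extract_patch(s, input_size)
      } else s
    })

    model <- model_init(cfg$encoder, mfeb_width = cfg$mfeb_width,
                        seed = cfg$seed + 1L)
    params <- nn_trainable(list(mfeb = model$mfeb, encoder = model$encoder,
                                heads = model$heads, uw = model$uw))
    opt <- make_optimizer(params, type = cfg$optimizer,
                          lr = cfg$learning_rate)
    total_steps <- max(1L, cfg$epochs *
                         ceiling(length(train_idx) / cfg$batch_size))
    step <- 0L

    sample_loss <- function(i, training) {
      s <- prep[[i]]
      if (training && length(cfg$augmentation) > 0L) {
        s <- augment(s, cfg$augmentation)
      }
      out <- model_fwd_ag(model, s$volumes, Z[i, ], training = training,
                          bypass_mfeb = cfg$bypass_mfeb,
                          use_adapters = cfg$use_adapters)
      task_loss <- list()
      for (task in cfg$tasks) {
        y <- lab[[task]][i]
        p <- if (task == "idh") out$p_idh else out$p_grade
        p_true <- if (y == 1L) p else {
          ag_sub(ag_tensor(matrix(1, 1, 1)), p)
        }
        a <- if (y == 1L) alpha[[task]] else 1
        task_loss[[task]] <- ag_weighted_ce(p_true, a, cfg$loss$gamma,
                                            cfg$loss$beta, cfg$loss$epsilon,
                                            cfg$loss$form)
      }
      if (length(cfg$tasks) == 2L) {
        ag_joint_loss(task_loss$idh, task_loss$grade, model$uw)
      } else {
        task_loss[[1L]]
      }
    }

    history <- data.frame()
    best_val <- Inf
    best_state <- model_get_values(model)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(train_idx)
      opt$zero()
      epoch_loss <- 0
      n_in_batch <- 0L
      for (i in ord) {
        L <- sample_loss(i, training = TRUE)
        epoch_loss <- epoch_loss + L$value[1L]
        ag_backward(L)
        n_in_batch <- n_in_batch + 1L
        if (n_in_batch == cfg$batch_size || i == ord[length(ord)]) {
          for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / n_in_batch
          step <- step + 1L
          scale <- if (cfg$schedule == "cosine") {
            lr_cosine(step, total_steps)
          } else 1
          opt$step(scale)
          opt$zero()
          n_in_batch <- 0L
        }
      }
      train_loss <- epoch_loss / length(ord)
      val_loss <- if (length(val_idx) > 0L) {
        mean(vapply(val_idx, function(i) {
          sample_loss(i, training = FALSE)$value[1L]
        }, numeric(1)))
      } else train_loss
      gam <- uw_values(model$uw)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = train_loss, val_loss = val_loss,
        gamma_idh = gam[1L], gamma_grade = gam[2L]))
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f gamma=(%.3f, %.3f)",
                        epoch, train_loss, val_loss, gam[1L], gam[2L]))
      }
      if (val_loss <= best_val) {
        best_val <- val_loss
        best_state <- model_get_values(model)
      }
    }
    model_set_values(model, best_state)
    structure(list(model = model, history = history,
                   std_stats = std$standardization_stats,
                   train_idx = train_idx, val_idx = val_idx,
                   test_idx = test_idx, alpha = alpha, cfg = cfg),
              class = "mtg_checkpoint")
  })
}

# apply stored standardization stats to a feature matrix
apply_std <- function(feats, stats_list) {
  mu <- as.numeric(stats_list$mean)
  sdv <- as.numeric(stats_list$sd)
  sweep(sweep(feats, 2L, mu), 2L, ifelse(sdv > 0, sdv, 1), `/`)
}

#' Evaluate a checkpoint on a test cohort
#'
#' AUC by rank statistic, ACC and F1 from confusion counts at threshold 0.5,
#' with percentile-bootstrap 95% confidence intervals over subjects.
#'
#' @param ckpt a [train()] checkpoint (or [load_checkpoint()] result with a
#'   `model` element plus `std_stats` and `cfg`).
#' @param cohort test subjects, disjoint from the training rows.
#' @param n_boot bootstrap resamples (reference: 2000).
#' @param seed bootstrap seed.
#' @return list of class `eval_report`: per task `AUC`, `ACC`, `F1` with CI
#'   bounds, confusion counts, and the raw scores.
#' @export
evaluate <- function(ckpt, cohort, n_boot = 2000L, seed = 1L) {
  model <- ckpt$model
  cfg <- ckpt$cfg
  input_size <- model$cfg$input_size
  lab <- subject_labels(cohort)
  Z <- apply_std(cohort_features(cohort), ckpt$std_stats)
  scores <- t(vapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    if (!identical(dim(s$roi_mask), rep(input_size, 3L))) {
      s <- extract_patch(s, input_size)
    }
    model_predict(model, s, Z[i, ],
                  bypass_mfeb = isTRUE(cfg$bypass_mfeb),
                  use_adapters = !isFALSE(cfg$use_adapters))
  }, numeric(2)))
  report <- with_rng(seed, {
    lapply(c(idh = "idh", grade = "grade"), function(task) {
      y <- lab[[task]]
      if (length(unique(y)) < 2L) {
        return(list(point = c(AUC = NA_real_,
                              ACC = accuracy_from_counts(
                                confusion_counts(scores[, task], y)),
                              F1 = f1_from_counts(
                                confusion_counts(scores[, task], y))),
                    lower = NULL, upper = NULL,
                    counts = confusion_counts(scores[, task], y),
                    note = "single-class test set: AUC undefined"))
      }
      boot_metrics(scores[, task], y, n_boot)
    })
  })
  structure(list(idh = report$idh, grade = report$grade, scores = scores,
                 labels = lab, n_boot = n_boot), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  for (task in c("idh", "grade")) {
    r <- x[[task]]
    cat(sprintf("%-6s", task))
    for (m in c("AUC", "ACC", "F1")) {
      if (is.null(r$lower)) {
        cat(sprintf("  %s %.3f", m, r$point[m]))
      } else {
        cat(sprintf("  %s %.3f [%.3f-%.3f]", m, r$point[m], r$lower[m],
                    r$upper[m]))
      }
    }
    cat("\n")
    if (!is.null(r$note)) cat("  note:", r$note, "\n")
  }
  invisible(x)
}
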