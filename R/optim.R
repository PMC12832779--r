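# Optimizers. The reference settings name the Ranger optimizer; Ranger is
# RAdam (rectified Adam) wrapped in Lookahead (k = 6, alpha = 0.5), and both
# pieces are implemented here directly. Plain Adam is the fallback.

#' Create an optimizer over a flat list of trainable tensors
#'
#' @param params named list of `ag_tensor` parameters (see the internal
#'   `nn_trainable()`); only tensors with `requires_grad = TRUE` are updated.
#' @param type `"ranger"` (RAdam + Lookahead) or `"adam"`.
#' @param lr learning rate.
#' @param betas Adam moment decay rates.
#' @param eps numerical stabilizer.
#' @param lookahead_k,lookahead_alpha Lookahead sync period and step size
#'   (ranger only).
#' @return environment with `$step(lr_scale)` and `$zero()`.
#' @export
make_optimizer <- function(params, type = c("ranger", "adam"), lr = 2e-5,
                           betas = c(0.9, 0.999), eps = 1e-8,
                           lookahead_k = 6L, lookahead_alpha = 0.5) {
  type <- match.arg(type)
  params <- params[vapply(params, function(p) p$requires_grad, logical(1))]
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L
  opt$m <- lapply(params, function(p) array(0, dim(p$value)))
  opt$v <- lapply(params, function(p) array(0, dim(p$value)))
  opt$slow <- if (type == "ranger") lapply(params, function(p) p$value) else NULL
  b1 <- betas[1]; b2 <- betas[2]
  rho_inf <- 2 / (1 - b2) - 1

  opt$zero <- function() ag_zero_grad(params)

  opt$step <- function(lr_scale = 1) {
    opt$t <- opt$t + 1L
    t <- opt$t
    lrt <- lr * lr_scale
    for (i in seq_along(params)) {
      p <- params[[i]]
      g <- p$grad
      if (is.null(g)) next
      opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
      opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
      mhat <- opt$m[[i]] / (1 - b1^t)
      if (type == "adam") {
        vhat <- opt$v[[i]] / (1 - b2^t)
        p$value <- p$value - lrt * mhat / (sqrt(vhat) + eps)
      } else {
        rho_t <- rho_inf - 2 * t * b2^t / (1 - b2^t)
        if (rho_t > 4) {
          vhat <- sqrt(opt$v[[i]] / (1 - b2^t))
          rect <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                         ((rho_inf - 4) * (rho_inf - 2) * rho_t))
          p$value <- p$value - lrt * rect * mhat / (vhat + eps)
        } else {
          p$value <- p$value - lrt * mhat
        }
      }
    }
    if (type == "ranger" && opt$t %% lookahead_k == 0L) {
      for (i in seq_along(params)) {
        opt$slow[[i]] <- opt$slow[[i]] +
          lookahead_alpha * (params[[i]]$value - opt$slow[[i]])
        params[[i]]$value <- opt$slow[[i]]
      }
    }
    invisible(NULL)
  }
  opt
}

# cosine decay to zero over total steps
lr_cosine <- function(step, total) 0.5 * (1 + cos(pi * min(step, total) / total))
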