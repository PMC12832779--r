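# Task heads and loss functions.
#
# Per task (IDH genotype, grade) the loss on the predicted true-class
# probability y_t is a focal-style class-weighted term plus a
# beta-scaled entropy term, exactly as printed in the method:
#   L(y_t) = -alpha (1-y_t)^gamma log(y_t) + beta * H(y_t),
#   H(y_t) = -y_t log(y_t) - (1-y_t) log(1-y_t).
# The entropy form of the regularizer is unusual (it is the entropy of the
# predicted probability, not a label-conditioned cross-entropy); a
# `form = "conventional"` switch replaces H(y_t) by -log(y_t).
# The two task losses are combined by trainable uncertainty weights:
#   L_joint = sum_i L_i / (2 gamma_i^2) + sum_i log(gamma_i),
# with gamma_i parameterized internally as log(gamma_i) so positivity is
# structural.

#' Loss configuration
#'
#' @param alpha class-ratio scaling factor (> 0); during training it is set
#'   per task to the training-split negative/positive count ratio and applied
#'   to positive-class samples.
#' @param gamma focusing exponent (default 2).
#' @param beta weight of the entropy/cross-entropy regularization term.
#' @param epsilon probability clamp.
#' @param form `"as_printed"` (entropy regularizer, default) or
#'   `"conventional"` (`-log(y_t)` regularizer).
#' @return list of class `loss_config`.
#' @export
loss_config <- function(alpha = 1, gamma = 2, beta = 1, epsilon = 1e-7,
                        form = c("as_printed", "conventional")) {
  form <- match.arg(form)
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (beta < 0) stop("beta must be >= 0")
  structure(list(alpha = as.numeric(alpha), gamma = as.numeric(gamma),
                 beta = as.numeric(beta), epsilon = as.numeric(epsilon),
                 form = form), class = "loss_config")
}

#' Focal-style class-weighted cross-entropy of the true-class probability
#'
#' @param y_t predicted probability of the true class (vectorized); values
#'   outside `(0, 1)` are clamped to `[epsilon, 1 - epsilon]` with a warning.
#' @param cfg a [loss_config()].
#' @return numeric loss value(s).
#' @export
weighted_ce <- function(y_t, cfg = loss_config()) {
  eps <- cfg$epsilon
  if (any(y_t <= 0 | y_t >= 1)) {
    warning("y_t outside (0,1); clamping to [", eps, ", ", 1 - eps, "]")
  }
  y <- pmin(pmax(y_t, eps), 1 - eps)
  focal <- -cfg$alpha * (1 - y)^cfg$gamma * log(y)
  reg <- if (cfg$form == "as_printed") {
    -y * log(y) - (1 - y) * log(1 - y)
  } else {
    -log(y)
  }
  focal + cfg$beta * reg
}

#' Trainable per-task uncertainty weights
#'
#' @param gamma_i positive initial weights, one per task (default `c(1, 1)`).
#' @return list of class `uncertainty_weights` holding the log-parameterized
#'   trainable tensor.
#' @export
uncertainty_weights <- function(gamma_i = c(1, 1)) {
  if (any(gamma_i <= 0)) stop("gamma_i must be strictly positive")
  structure(list(log_gamma = nn_param(matrix(log(gamma_i), ncol = 1L))),
            class = "uncertainty_weights")
}

uw_values <- function(w) {
  if (inherits(w, "uncertainty_weights")) exp(w$log_gamma$value[, 1L]) else w
}

#' Uncertainty-weighted joint loss
#'
#' `sum_i L_i / (2 gamma_i^2) + sum_i log(gamma_i)`. At the initialization
#' `gamma = (1, 1)` this is the plain mean of the two losses.
#'
#' @param L1,L2 nonnegative per-task losses.
#' @param w an [uncertainty_weights()] object or a positive numeric vector of
#'   length 2.
#' @return scalar joint loss.
#' @export
joint_loss <- function(L1, L2, w = uncertainty_weights()) {
  g <- uw_values(w)
  if (any(g <= 0)) stop("gamma_i must be strictly positive")
  sum(c(L1, L2) / (2 * g^2)) + sum(log(g))
}

# ---- heads ------------------------------------------------------------------

#' Initialize the two task heads
#'
#' @param embed_dim deep-feature width.
#' @return list of class `mtg_heads` with one affine 2-class head per task.
#' @export
heads_init <- function(embed_dim) {
  structure(list(idh = nn_linear(embed_dim, 2L),
                 grade = nn_linear(embed_dim, 2L)), class = "mtg_heads")
}

#' Per-task class probabilities from a deep feature vector
#'
#' @param feature numeric vector (length `embed_dim`).
#' @param heads a [heads_init()] parameter set.
#' @return 2 x 2 matrix of probabilities, rows `idh` and `grade`, columns
#'   class 0 and class 1; each row sums to 1.
#' @export
predict_heads <- function(feature, heads) {
  f <- ag_tensor(matrix(feature, ncol = 1L))
  out <- sapply(c("idh", "grade"), function(task) {
    z <- nn_linear_fwd(heads[[task]], f)$value[, 1L]
    e <- exp(z - max(z))
    e / sum(e)
  })
  t(out) # rows = tasks
}

# ---- tape versions used during training -------------------------------------

ag_softmax_col <- function(z) {
  zv <- z$value[, 1L]
  e <- exp(zv - max(zv))
  sm <- matrix(e / sum(e), ncol = 1L)
  ag_op(sm, list(z), function(g, need) list((g - sum(g * sm)) * sm))
}

# softmax head -> scalar probability of the true class
ag_head_prob <- function(head, feature, label) {
  s <- ag_softmax_col(nn_linear_fwd(head, feature))
  ag_pick(s, label + 1L)
}

ag_weighted_ce <- function(p_true, alpha, gamma, beta, eps = 1e-7,
                           form = "as_printed") {
  # clamp on the tape: values are sane in practice, clamp guards the logs
  pv <- p_true$value[1L]
  if (pv < eps || pv > 1 - eps) {
    p_true <- ag_op(matrix(min(max(pv, eps), 1 - eps), 1, 1), list(p_true),
                    function(g, need) list(g))
  }
  one <- ag_tensor(matrix(1, 1, 1))
  om <- ag_sub(one, p_true)
  focal <- ag_smul(ag_mul(ag_pow_const(om, gamma), ag_log(p_true)), -alpha)
  reg <- if (form == "as_printed") {
    ag_neg(ag_add(ag_mul(p_true, ag_log(p_true)),
                  ag_mul(om, ag_log(om))))
  } else {
    ag_neg(ag_log(p_true))
  }
  ag_add(focal, ag_smul(reg, beta))
}

ag_pow_const <- function(x, p) {
  xv <- x$value
  ag_op(xv^p, list(x), function(g, need) list(g * p * xv^(p - 1)))
}

ag_joint_loss <- function(L1, L2, uw) {
  lg <- uw$log_gamma
  w1 <- ag_exp(ag_smul(ag_pick(lg, 1L), -2))    # 1/gamma_1^2
  w2 <- ag_exp(ag_smul(ag_pick(lg, 2L), -2))
  ag_add(ag_add(ag_smul(ag_mul(L1, w1), 0.5), ag_smul(ag_mul(L2, w2), 0.5)),
         ag_sum(lg))
}
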