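# Module constructors. A module is a plain named list whose leaves are
# ag_tensor parameters (plus environments for batch-norm running moments);
# forward functions live next to the constructors. Initialization draws from
# the session RNG, so callers control determinism with set.seed().

nn_param <- function(value) ag_tensor(value, requires_grad = TRUE)

nn_he <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

nn_linear <- function(d_in, d_out, gain = 2) {
  list(W = nn_param(matrix(stats::rnorm(d_out * d_in,
                                        sd = sqrt(gain / d_in)), d_out, d_in)),
       b = nn_param(matrix(0, d_out, 1L)))
}

nn_linear_fwd <- function(mod, x) ag_linear(x, mod$W, mod$b)

nn_bilinear <- function(ha, hb, d_out) {
  list(W = nn_param(matrix(stats::rnorm(d_out * ha * hb,
                                        sd = sqrt(1 / (ha * hb))),
                           d_out, ha * hb)),
       b = nn_param(matrix(0, d_out, 1L)))
}

nn_bilinear_fwd <- function(mod, a, b) ag_bilinear(a, b, mod$W, mod$b)

nn_conv3d <- function(c_in, c_out, k, stride = 1L, dilation = 1L,
                      groups = 1L, pad = NULL) {
  if (k %% 2L == 0L && is.null(pad)) {
    stop("conv3d kernel size must be odd for same padding; got ", k)
  }
  if (is.null(pad)) pad <- (k - 1L) * dilation / 2L
  fan_in <- (c_in / groups) * k^3
  list(W = nn_param(nn_he(c_out, fan_in, fan_in)),
       b = nn_param(matrix(0, c_out, 1L)),
       k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), dilation = as.integer(dilation),
       groups = as.integer(groups), c_in = c_in, c_out = c_out)
}

nn_conv3d_fwd <- function(mod, x, dims) {
  ag_conv3d(x, mod$W, mod$b, dims, mod$k, mod$stride, mod$pad,
            mod$dilation, mod$groups)
}

nn_convT3d <- function(c_in, c_out, k = 2L, stride = 2L) {
  fan_in <- c_in * k^3
  list(W = nn_param(nn_he(c_out * k^3, c_in, fan_in)),
       b = nn_param(matrix(0, c_out, 1L)),
       k = as.integer(k), stride = as.integer(stride),
       c_in = c_in, c_out = c_out)
}

nn_convT3d_fwd <- function(mod, x, dims_in) {
  ag_conv_transpose3d(x, mod$W, mod$b, dims_in, mod$k, mod$stride)
}

nn_batchnorm <- function(C) {
  list(gamma = nn_param(matrix(1, C, 1L)),
       beta = nn_param(matrix(0, C, 1L)),
       state = new.env(parent = emptyenv()))
}

nn_batchnorm_fwd <- function(mod, x, training) {
  ag_batchnorm(x, mod$gamma, mod$beta, mod$state, training)
}

nn_layernorm <- function(C) {
  list(gamma = nn_param(matrix(1, C, 1L)),
       beta = nn_param(matrix(0, C, 1L)))
}

nn_layernorm_fwd <- function(mod, x) ag_layernorm(x, mod$gamma, mod$beta)

# ---- parameter bookkeeping --------------------------------------------------

# walk a nested module list and return a flat named list of ag_tensors
nn_params <- function(mod, prefix = "") {
  out <- list()
  if (is_ag(mod)) {
    out[[prefix]] <- mod
    return(out)
  }
  if (!is.list(mod)) return(out)
  nm <- names(mod)
  for (i in seq_along(mod)) {
    key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
    child <- mod[[i]]
    if (is_ag(child) || is.list(child)) {
      p <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
      out <- c(out, nn_params(child, p))
    }
  }
  out
}

nn_trainable <- function(mod) {
  ps <- nn_params(mod)
  ps[vapply(ps, function(p) p$requires_grad, logical(1))]
}

nn_set_requires_grad <- function(mod, value) {
  for (p in nn_params(mod)) p$requires_grad <- p$needs <- value
  invisible(mod)
}

# walk and collect batch-norm state environments (running moments)
nn_bn_states <- function(mod, prefix = "") {
  out <- list()
  if (!is.list(mod) || is_ag(mod)) return(out)
  nm <- names(mod)
  for (i in seq_along(mod)) {
    key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
    child <- mod[[i]]
    p <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (is.environment(child) && identical(key, "state")) {
      out[[p]] <- child
    } else if (is.list(child) && !is_ag(child)) {
      out <- c(out, nn_bn_states(child, p))
    }
  }
  out
}
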