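# Customized 3D vision-transformer encoder.
#
# A stand-in for a pretrained 3D segmentation foundation-model encoder:
# strided-conv patch embedding (expanded from 1 to 5 input channels: 4 MRI
# modalities + the mismatch map), learned positional embeddings, pre-LN
# transformer blocks. Fine-tuning is parameter-efficient: each block carries a
# multi-view adapter (MVAdapter) that gates the block's input token grid by a
# bilinear combination of pooled image features and tabular features, a
# multi-scale dilated group convolution branch (DGCB) that lifts the gated
# grid to query/key/value width, and the result is added to that block's QKV
# tensor. With the backbone frozen, gradients reach only the patch embedding,
# the adapters and the task heads.

#' Encoder configuration
#'
#' Reference scale follows the published architecture: 128^3 input, patch 16,
#' embedding 384 (so an (8,8,8) token grid), adapter bottleneck
#' `embed_dim / adapter_reduction = 48`, QKV width `3 * embed_dim = 1152`.
#'
#' @param input_size cubic input edge length in voxels.
#' @param patch_size patch-embedding stride/kernel; must divide `input_size`.
#' @param embed_dim token channel count; must be divisible by `n_heads` and by
#'   `group_div`.
#' @param n_blocks,n_heads transformer depth and attention head count.
#' @param adapter_reduction bottleneck divisor of the adapter (default 8).
#' @param tabular_dim width of the tabular feature vector (99 radiomic-like +
#'   age + sex = 101).
#' @param qkv_dim width of the fused adapter output; defaults to
#'   `3 * embed_dim` so it can be added to the query/key/value tensor.
#' @param mlp_ratio hidden expansion of the transformer MLP.
#' @param group_div `embed_dim / group_div` groups are used in the DGCB
#'   grouped convolutions.
#' @param in_channels input channels (4 MRI + 1 mismatch map).
#' @param freeze_backbone if `TRUE` (default) only patch embedding, adapters
#'   and heads receive gradients.
#' @param dropout_rate,slope regularization / LeakyReLU slope shared with the
#'   conv blocks.
#' @return A validated list of class `encoder_config`.
#' @export
encoder_config <- function(input_size = 128L, patch_size = 16L,
                           embed_dim = 384L, n_blocks = 12L, n_heads = 6L,
                           adapter_reduction = 8L, tabular_dim = 101L,
                           qkv_dim = NULL, mlp_ratio = 4L, group_div = 8L,
                           in_channels = 5L, freeze_backbone = TRUE,
                           dropout_rate = 0.1, slope = 0.01) {
  input_size <- as.integer(input_size); patch_size <- as.integer(patch_size)
  embed_dim <- as.integer(embed_dim)
  if (input_size %% patch_size != 0L) {
    stop("input_size (", input_size, ") must be divisible by patch_size (",
         patch_size, ")")
  }
  if (embed_dim %% n_heads != 0L) {
    stop("embed_dim must be divisible by n_heads")
  }
  if (embed_dim %% adapter_reduction != 0L) {
    stop("embed_dim must be divisible by adapter_reduction")
  }
  if (embed_dim %% group_div != 0L) {
    stop("embed_dim must be divisible by group_div")
  }
  if (is.null(qkv_dim)) qkv_dim <- 3L * embed_dim
  structure(list(
    input_size = input_size, patch_size = patch_size, embed_dim = embed_dim,
    n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
    adapter_reduction = as.integer(adapter_reduction),
    adapter_hidden = embed_dim %/% as.integer(adapter_reduction),
    tabular_dim = as.integer(tabular_dim), qkv_dim = as.integer(qkv_dim),
    mlp_ratio = as.integer(mlp_ratio), group_div = as.integer(group_div),
    in_channels = as.integer(in_channels),
    freeze_backbone = isTRUE(freeze_backbone),
    dropout_rate = dropout_rate, slope = slope,
    grid = input_size %/% patch_size), class = "encoder_config")
}

#' Expand a single-channel patch-embedding kernel to five channels
#'
#' The kernel is replicated across the five input channels and scaled by 1/5,
#' so an input whose five channels are all equal to `v` reproduces the
#' original single-channel response on `v`.
#'
#' @param base_weights matrix `[embed_dim, k^3]` (one input channel) or a 5D
#'   array `c(embed_dim, 1, k, k, k)`.
#' @param n_channels target channel count (default 5).
#' @return matrix `[embed_dim, n_channels * k^3]` in the package's
#'   channel-major tap layout.
#' @export
expand_patch_embed <- function(base_weights, n_channels = 5L) {
  if (is.array(base_weights) && length(dim(base_weights)) == 5L) {
    d <- dim(base_weights)
    if (d[2L] != 1L) {
      stop("base kernel already has ", d[2L], " input channels; expected 1")
    }
    base_weights <- matrix(base_weights, d[1L], prod(d[3:5]))
  }
  if (!is.matrix(base_weights)) stop("base_weights must be a matrix or 5D array")
  do.call(cbind, rep(list(base_weights / n_channels), n_channels))
}

# ---- construction -----------------------------------------------------------

mvadapter_init <- function(cfg) {
  E <- cfg$embed_dim; h <- cfg$adapter_hidden
  list(fc_img = nn_linear(E, h),
       fc_tab = nn_linear(cfg$tabular_dim, h),
       bil = nn_bilinear(h, h, E),
       fc_fm = nn_linear(E, E))
}

dgcb_init <- function(cfg) {
  E <- cfg$embed_dim
  groups <- E %/% cfg$group_div
  br <- function(k) {
    list(dconv = nn_conv3d(E, E, k, dilation = 3L, groups = groups),
         gconv = nn_conv3d(E, E, k, dilation = 1L, groups = groups))
  }
  list(b7 = br(7L), b5 = br(5L), b3 = br(3L),
       bn = nn_batchnorm(E),
       pc = nn_linear(E, cfg$qkv_dim))
}

block_init <- function(cfg) {
  E <- cfg$embed_dim
  list(ln1 = nn_layernorm(E),
       qkv = nn_linear(E, 3L * E),
       proj = nn_linear(E, E),
       ln2 = nn_layernorm(E),
       mlp1 = nn_linear(E, cfg$mlp_ratio * E),
       mlp2 = nn_linear(cfg$mlp_ratio * E, E))
}

#' Initialize the encoder
#'
#' Random (seed-controlled) initialization; use [load_pretrained()] to load
#' backbone weights from a checkpoint instead. When `cfg$freeze_backbone` is
#' `TRUE`, the transformer blocks and positional embeddings are frozen.
#'
#' @param cfg an [encoder_config()].
#' @return A parameter list of class `mtg_encoder`.
#' @export
encoder_init <- function(cfg) {
  E <- cfg$embed_dim; g <- cfg$grid; p <- cfg$patch_size
  fan_in <- cfg$in_channels * p^3
  enc <- list(
    cfg = cfg,
    patch_embed = list(W = nn_param(nn_he(E, fan_in, fan_in)),
                       b = nn_param(matrix(0, E, 1L))),
    pos = nn_param(matrix(stats::rnorm(E * g^3, sd = 0.02), E, g^3)),
    blocks = lapply(seq_len(cfg$n_blocks), function(i) block_init(cfg)),
    adapters = lapply(seq_len(cfg$n_blocks), function(i) {
      list(mv = mvadapter_init(cfg), dgcb = dgcb_init(cfg))
    }))
  class(enc) <- "mtg_encoder"
  if (cfg$freeze_backbone) {
    nn_set_requires_grad(enc$blocks, FALSE)
    enc$pos$requires_grad <- enc$pos$needs <- FALSE
  }
  enc
}

#' Zero all adapter parameters in place
#'
#' Reproduces the "without MVAdapter" ablation: with every adapter parameter
#' zero, the fused injection is exactly zero and the encoder output equals the
#' plain backbone output.
#'
#' @param enc an encoder from [encoder_init()].
#' @return The encoder, invisibly (modified in place).
#' @export
zero_adapters <- function(enc) {
  for (p in nn_params(enc$adapters)) p$value[] <- 0
  invisible(enc)
}

# ---- forward pieces ---------------------------------------------------------

#' Patch-embed a 5-channel volume into a token grid
#'
#' @param patch 4D array `c(in_channels, s, s, s)` with `s` divisible by the
#'   configured patch size.
#' @param enc encoder from [encoder_init()].
#' @return An object of class `token_grid`: list with `data`
#'   (`[embed_dim, g^3]` matrix, tokens in column-major grid order) and `grid`.
#' @export
patch_embed <- function(patch, enc) {
  cfg <- enc$cfg
  d <- dim(patch)
  if (length(d) != 4L || d[1L] != cfg$in_channels) {
    stop("expected c(", cfg$in_channels, ", s, s, s) input")
  }
  dims <- as.integer(d[2:4])
  if (any(dims %% cfg$patch_size != 0L)) {
    stop("spatial dims ", paste(dims, collapse = "x"),
         " not divisible by patch_size ", cfg$patch_size)
  }
  x <- ag_tensor(matrix(as.vector(patch), nrow = d[1L]))
  tok <- ag_conv3d(x, enc$patch_embed$W, enc$patch_embed$b, dims,
                   k = cfg$patch_size, stride = cfg$patch_size, pad = 0L)
  structure(list(data = tok$value, grid = dims %/% cfg$patch_size),
            class = "token_grid")
}

mvadapter_fuse_ag <- function(mv, x_fm, x_hc) {
  pooled <- ag_rowmeans(x_fm)                   # [E, 1] global avg over grid
  a <- nn_linear_fwd(mv$fc_img, pooled)         # [E/8, 1]
  b <- nn_linear_fwd(mv$fc_tab, x_hc)           # [E/8, 1]
  gate <- ag_sigmoid(nn_bilinear_fwd(mv$bil, a, b))   # [E, 1] in (0,1)
  ag_mul_colvec(nn_linear_fwd(mv$fc_fm, x_fm), gate)
}

#' Multi-view adapter gating
#'
#' Pools the token grid to a channel vector, bottlenecks it and the tabular
#' vector to `embed_dim / 8` features each, combines them bilinearly into one
#' gate logit per channel and applies the sigmoid gate channel-wise to a
#' width-preserving linear transform of the token grid.
#'
#' @param x_fm a [patch_embed()] token grid (or a bare `[embed_dim, n]`
#'   matrix).
#' @param x_hc standardized tabular feature vector of length
#'   `cfg$tabular_dim`.
#' @param adapter one element of `enc$adapters` (uses its `$mv` part) or the
#'   `$mv` list itself.
#' @return list of class `gated_token_grid` with `data` (same shape as input)
#'   and `gate` (the per-channel gate values).
#' @export
mvadapter_fuse <- function(x_fm, x_hc, adapter) {
  mv <- if (!is.null(adapter$mv)) adapter$mv else adapter
  xm <- if (inherits(x_fm, "token_grid")) x_fm$data else x_fm
  if (length(x_hc) != ncol(mv$fc_tab$W$value)) {
    stop("tabular width ", length(x_hc), " != configured ",
         ncol(mv$fc_tab$W$value))
  }
  x <- ag_tensor(xm)
  hc <- ag_tensor(matrix(x_hc, ncol = 1L))
  pooled <- ag_rowmeans(x)
  a <- nn_linear_fwd(mv$fc_img, pooled)
  b <- nn_linear_fwd(mv$fc_tab, hc)
  gate <- ag_sigmoid(nn_bilinear_fwd(mv$bil, a, b))
  out <- ag_mul_colvec(nn_linear_fwd(mv$fc_fm, x), gate)
  structure(list(data = out$value, gate = gate$value[, 1L],
                 bottleneck = c(img = nrow(a$value), tab = nrow(b$value))),
            class = "gated_token_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dgcb_fwd_ag <- function(dg, x, grid_dims, training, slope = 0.01) {
  br <- function(b) {
    nn_conv3d_fwd(b$gconv, ag_leaky_relu(nn_conv3d_fwd(b$dconv, x, grid_dims),
                                         slope), grid_dims)
  }
  s <- ag_add(ag_add(br(dg$b7), br(dg$b5)), br(dg$b3))
  s <- nn_batchnorm_fwd(dg$bn, s, training)
  s <- ag_leaky_relu(s, slope)
  nn_linear_fwd(dg$pc, s)
}

#' Dilated group convolution branch
#'
#' Three parallel branches (kernels 7, 5, 3; dilated grouped conv ->
#' LeakyReLU -> grouped conv) are summed, batch-normalized, activated, and a
#' pointwise convolution lifts the channels to QKV width.
#'
#' @param x_fmw a gated token grid ([mvadapter_fuse()] output, `token_grid`,
#'   or a `[embed_dim, g^3]` matrix).
#' @param adapter one element of `enc$adapters` (uses `$dgcb`) or the `$dgcb`
#'   list itself.
#' @param grid spatial grid dims (length-3 integer); required when `x_fmw` is
#'   a bare matrix with a non-cubic token count.
#' @param training logical.
#' @return list of class `fused_features` with `data` (`[qkv_dim, g^3]`).
#' @export
dgcb <- function(x_fmw, adapter, grid = NULL, training = FALSE) {
  dg <- if (!is.null(adapter$dgcb)) adapter$dgcb else adapter
  xm <- if (is.list(x_fmw)) x_fmw$data else x_fmw
  if (is.null(grid)) {
    g <- round(ncol(xm)^(1 / 3))
    if (g^3 != ncol(xm)) stop("token count is not a cube; pass `grid`")
    grid <- rep(as.integer(g), 3L)
  }
  out <- dgcb_fwd_ag(dg, ag_tensor(xm), as.integer(grid), training)
  structure(list(data = out$value, grid = as.integer(grid)),
            class = "fused_features")
}

#' Add fused adapter features to a QKV tensor
#'
#' @param x_fusion `[qkv_dim, n_tokens]` matrix (or `fused_features`).
#' @param x_qkv matrix of the same shape produced inside a transformer block.
#' @return matrix `x_qkv + x_fusion`.
#' @export
inject_qkv <- function(x_fusion, x_qkv) {
  xf <- if (is.list(x_fusion)) x_fusion$data else x_fusion
  if (!identical(dim(xf), dim(x_qkv))) {
    stop("shape mismatch: fusion ", paste(dim(xf), collapse = "x"),
         " vs qkv ", paste(dim(x_qkv), collapse = "x"))
  }
  x_qkv + xf
}

# ---- full forward -----------------------------------------------------------

attention_ag <- function(blk, x, cfg, x_fusion = NULL) {
  E <- cfg$embed_dim; H <- cfg$n_heads; dh <- E %/% H
  h <- nn_layernorm_fwd(blk$ln1, x)
  qkv <- nn_linear_fwd(blk$qkv, h)              # [3E, N]
  if (!is.null(x_fusion)) qkv <- ag_add(qkv, x_fusion)
  heads <- vector("list", H)
  for (i in seq_len(H)) {
    rows <- ((i - 1L) * dh + 1L):(i * dh)
    q <- ag_rows(qkv, rows)
    k <- ag_rows(qkv, E + rows)
    v <- ag_rows(qkv, 2L * E + rows)
    scores <- ag_smul(ag_matmul(ag_t(q), k), 1 / sqrt(dh))  # [N, N]
    a <- ag_softmax_rows(scores)
    heads[[i]] <- ag_matmul(v, ag_t(a))
  }
  out <- nn_linear_fwd(blk$proj, ag_rbind(heads))
  ag_add(x, out)
}

block_fwd_ag <- function(blk, adapter, x, x_hc, cfg, grid_dims, training,
                         use_adapter = TRUE) {
  x_fusion <- NULL
  if (use_adapter && !is.null(adapter)) {
    x_fmw <- mvadapter_fuse_ag(adapter$mv, x, x_hc)
    x_fusion <- dgcb_fwd_ag(adapter$dgcb, x_fmw, grid_dims, training,
                            cfg$slope)
  }
  x <- attention_ag(blk, x, cfg, x_fusion)
  h <- nn_layernorm_fwd(blk$ln2, x)
  h <- nn_linear_fwd(blk$mlp2, ag_gelu(nn_linear_fwd(blk$mlp1, h)))
  ag_add(x, h)
}

# internal tape forward; returns list(feature, tokens_node, token_dims)
encode_ag <- function(enc, patch_ag, x_hc_ag, dims, training = FALSE,
                      use_adapters = TRUE) {
  cfg <- enc$cfg
  if (cfg$qkv_dim != 3L * cfg$embed_dim && use_adapters) {
    stop("QKV injection requires qkv_dim == 3*embed_dim (got ", cfg$qkv_dim,
         "); the alternative printed width is available through dgcb() only")
  }
  tok <- ag_conv3d(patch_ag, enc$patch_embed$W, enc$patch_embed$b, dims,
                   k = cfg$patch_size, stride = cfg$patch_size, pad = 0L)
  grid_dims <- as.integer(dims) %/% cfg$patch_size
  n_tok <- prod(grid_dims)
  pos <- enc$pos
  if (n_tok != ncol(pos$value)) {
    # nearest-grid interpolation of learned positional embeddings
    g0 <- round(ncol(pos$value)^(1 / 3))
    idx <- pos_interp_index(g0, grid_dims)
    pos <- ag_op(pos$value[, idx, drop = FALSE], list(pos), function(g, need) {
      dp <- matrix(0, nrow(g), g0^3)
      for (j in seq_along(idx)) dp[, idx[j]] <- dp[, idx[j]] + g[, j]
      list(dp)
    })
  }
  x <- ag_add(tok, pos)
  for (i in seq_len(cfg$n_blocks)) {
    x <- block_fwd_ag(enc$blocks[[i]],
                      if (use_adapters) enc$adapters[[i]] else NULL,
                      x, x_hc_ag, cfg, grid_dims, training, use_adapters)
  }
  list(feature = ag_rowmeans(x), tokens = x, grid = grid_dims)
}

pos_interp_index <- function(g0, grid_dims) {
  ax <- lapply(grid_dims, function(g) {
    pmin(g0, pmax(1L, as.integer(round((seq_len(g) - 0.5) / g * g0 + 0.5))))
  })
  as.vector(outer(outer(ax[[1L]], (ax[[2L]] - 1L) * g0, `+`),
                  (ax[[3L]] - 1L) * g0 * g0, `+`))
}

#' Encode a 5-channel patch into a deep feature vector
#'
#' Runs patch embedding, all transformer blocks with per-block adapter
#' injection, and global average pooling over tokens.
#'
#' @param patch 4D array `c(in_channels, s, s, s)`.
#' @param x_hc standardized tabular feature vector (length `cfg$tabular_dim`).
#' @param enc encoder from [encoder_init()].
#' @param use_adapters set `FALSE` to run the plain backbone.
#' @return numeric vector of length `embed_dim`.
#' @export
encode <- function(patch, x_hc, enc, use_adapters = TRUE) {
  d <- dim(patch)
  dims <- as.integer(d[2:4])
  x <- ag_tensor(matrix(as.vector(patch), nrow = d[1L]))
  hc <- ag_tensor(matrix(x_hc, ncol = 1L))
  out <- encode_ag(enc, x, hc, dims, training = FALSE,
                   use_adapters = use_adapters)
  out$feature$value[, 1L]
}
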