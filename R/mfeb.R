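# T2-FLAIR mismatch feature extraction block (MFEB).
#
# The block first forms a pooled two-channel "overview" of a modality at half
# resolution (average + max pooling, window/stride 2), passes it through a
# chain of shared-weight multi-scale dilated blocks (kernels 7 -> 5 -> 3,
# dilation 3), restores full resolution with a transposed convolution and
# squashes to a per-voxel weight in (0,1). The mismatch map is the difference
# of the two weighted modalities, x_tf = w(t2)*t2 - w(flair)*flair. One
# parameter set serves both branches, so identical inputs produce identical
# weight maps and the map is antisymmetric under input swap.

# ---- small representation helpers -------------------------------------------

vol_dims <- function(vol) {
  d <- dim(vol)
  if (is.null(d) || length(d) != 3L) stop("expected a 3D array")
  as.integer(d)
}

chan_mat <- function(vol) matrix(as.vector(vol), nrow = 1L)

mat_vol <- function(mat, dims) array(as.vector(mat), dim = dims)

#' Pooled two-channel overview of one modality
#'
#' Concatenates average-pooled and max-pooled copies of a volume (window and
#' stride 2), halving the resolution. Channel 1 is the average, channel 2 the
#' max, so channel 2 >= channel 1 voxelwise.
#'
#' @param volume 3D numeric array with even dimensions.
#' @param source_modality optional label, `"t2"` or `"flair"`.
#' @return An object of class `pooled_pair`: a list with `data` (4D array
#'   `c(2, dims/2)`), `dims` (the half-resolution spatial dims) and
#'   `source_modality`.
#' @export
pool_concat <- function(volume, source_modality = NULL) {
  dims <- vol_dims(volume)
  if (any(dims %% 2L != 0L)) {
    stop("pool_concat requires even spatial dims; got ",
         paste(dims, collapse = "x"), " (pad the input first)")
  }
  x <- ag_tensor(chan_mat(volume))
  avg <- ag_avgpool2(x, dims)
  mx <- ag_maxpool2(x, dims)
  half <- dims %/% 2L
  structure(list(data = array(rbind(avg$value, mx$value), c(2L, half)),
                 dims = half, source_modality = source_modality),
            class = "pooled_pair")
}

# ---- dilated block (DB) -----------------------------------------------------

#' Configuration of one dilated block
#'
#' @param kernel_size odd convolution kernel size.
#' @param dilation dilation rate of the leading dilated convolution.
#' @param width internal channel count.
#' @param dropout_rate dropout probability between the two detail convolutions.
#' @param slope negative slope of the LeakyReLU activations.
#' @return A list of class `db_config`.
#' @export
db_config <- function(kernel_size, dilation = 3L, width = 8L,
                      dropout_rate = 0.1, slope = 0.01) {
  if (kernel_size %% 2L != 1L) stop("kernel_size must be odd, got ", kernel_size)
  if (dilation < 1L) stop("dilation must be >= 1")
  structure(list(kernel_size = as.integer(kernel_size),
                 dilation = as.integer(dilation), width = as.integer(width),
                 dropout_rate = dropout_rate, slope = slope),
            class = "db_config")
}

db_init <- function(c_in, cfg) {
  w <- cfg$width
  k <- cfg$kernel_size
  list(fd = nn_conv3d(c_in, w, k, dilation = cfg$dilation),
       bn = nn_batchnorm(w),
       fc1 = nn_conv3d(w, w, k),
       fc2 = nn_conv3d(w, w, k),
       ffn1 = nn_linear(w, 2L * w),
       ffn2 = nn_linear(2L * w, w),
       cfg = cfg)
}

# operator order exactly as specified:
# dilated conv -> LeakyReLU -> BatchNorm -> conv -> LeakyReLU -> dropout ->
# conv -> FFN (pointwise, LeakyReLU, pointwise)
db_fwd <- function(db, x, dims, training) {
  s <- db$cfg$slope
  y <- nn_conv3d_fwd(db$fd, x, dims)
  y <- ag_leaky_relu(y, s)
  y <- nn_batchnorm_fwd(db$bn, y, training)
  y <- nn_conv3d_fwd(db$fc1, y, dims)
  y <- ag_leaky_relu(y, s)
  y <- ag_dropout(y, db$cfg$dropout_rate, training)
  y <- nn_conv3d_fwd(db$fc2, y, dims)
  y <- nn_linear_fwd(db$ffn1, y)
  y <- ag_leaky_relu(y, s)
  nn_linear_fwd(db$ffn2, y)
}

#' Apply one dilated block
#'
#' Spatial shape is preserved (same padding). In evaluation mode
#' (`training = FALSE`) dropout is inactive, so repeated calls are identical.
#'
#' @param x 4D numeric array `c(channels, d1, d2, d3)`.
#' @param block a block created by [mfeb_init()] (elements of `$db`) or
#'   directly by the internal constructor.
#' @param training logical; enables dropout and batch-norm batch statistics.
#' @return 4D array with `block$cfg$width` channels and unchanged spatial dims.
#' @export
dilated_block <- function(x, block, training = FALSE) {
  d <- dim(x)
  if (length(d) != 4L) stop("expected a 4D array c(channels, d1, d2, d3)")
  dims <- as.integer(d[2:4])
  xm <- ag_tensor(matrix(as.vector(x), nrow = d[1L]))
  y <- db_fwd(block, xm, dims, training)
  array(y$value, c(nrow(y$value), dims))
}

# ---- the full block ---------------------------------------------------------

#' Initialize MFEB parameters
#'
#' @param width internal channel count of the dilated blocks.
#' @param dropout_rate dropout probability inside each dilated block.
#' @param slope LeakyReLU negative slope.
#' @return A parameter list of class `mfeb`, with one shared dilated-block
#'   chain (kernels 7, 5, 3) serving both the T2 and the FLAIR branch, and a
#'   transposed convolution (kernel 2, stride 2) restoring full resolution.
#' @export
mfeb_init <- function(width = 8L, dropout_rate = 0.1, slope = 0.01) {
  structure(list(
    db = list(db7 = db_init(2L, db_config(7L, 3L, width, dropout_rate, slope)),
              db5 = db_init(width, db_config(5L, 3L, width, dropout_rate, slope)),
              db3 = db_init(width, db_config(3L, 3L, width, dropout_rate, slope))),
    tc = nn_convT3d(width, 1L, k = 2L, stride = 2L),
    width = as.integer(width)), class = "mfeb")
}

# shared-weight head: pooled pair -> full-resolution weight map in (0,1)
mfeb_weight_ag <- function(params, pooled_mat, half_dims, training) {
  y <- db_fwd(params$db$db7, pooled_mat, half_dims, training)
  y <- db_fwd(params$db$db5, y, half_dims, training)
  y <- db_fwd(params$db$db3, y, half_dims, training)
  y <- nn_convT3d_fwd(params$tc, y, half_dims)
  ag_sigmoid(y)
}

mfeb_pool_ag <- function(x, dims) {
  ag_rbind(list(ag_avgpool2(x, dims), ag_maxpool2(x, dims)))
}

# full mismatch forward on the tape; t2/flair are [1, V] ag tensors
mfeb_fwd_ag <- function(params, t2, flair, dims, training = FALSE,
                        bypass = FALSE) {
  if (bypass) return(ag_sub(t2, flair))
  half <- dims %/% 2L
  w_t2 <- mfeb_weight_ag(params, mfeb_pool_ag(t2, dims), half, training)
  w_fl <- mfeb_weight_ag(params, mfeb_pool_ag(flair, dims), half, training)
  ag_sub(ag_mul(w_t2, t2), ag_mul(w_fl, flair))
}

#' Per-voxel modality weight map
#'
#' Runs the shared dilated-block chain on a pooled pair and restores full
#' resolution; values are strictly inside (0,1) (sigmoid output).
#'
#' @param pooled a [pool_concat()] result.
#' @param params an [mfeb_init()] parameter set.
#' @param bypass if `TRUE`, return an all-ones map (test/ablation hook).
#' @return 3D array at full input resolution.
#' @export
compute_weight_map <- function(pooled, params, bypass = FALSE) {
  stopifnot(inherits(pooled, "pooled_pair"))
  full <- pooled$dims * 2L
  if (bypass) return(array(1, full))
  x <- ag_tensor(matrix(as.vector(pooled$data), nrow = 2L))
  w <- mfeb_weight_ag(params, x, pooled$dims, training = FALSE)
  mat_vol(w$value, full)
}

#' T2-FLAIR mismatch map
#'
#' Computes `x_tf = w(t2)*t2 - w(flair)*flair` with a single shared weight
#' head for both modalities. With `bypass = TRUE` the map is the plain
#' difference `t2 - flair` (the "without MFEB" ablation), bit-exactly.
#'
#' @param t2,flair 3D numeric arrays of identical shape with even dims.
#' @param params an [mfeb_init()] parameter set.
#' @param bypass logical ablation hook.
#' @return An object of class `mismatch_map`: list with `data` (3D array at
#'   full input resolution).
#' @export
mismatch_map <- function(t2, flair, params, bypass = FALSE) {
  dims <- vol_dims(t2)
  if (!identical(dims, vol_dims(flair))) {
    stop("t2 and flair shapes differ: ", paste(dim(t2), collapse = "x"),
         " vs ", paste(dim(flair), collapse = "x"))
  }
  out <- mfeb_fwd_ag(params, ag_tensor(chan_mat(t2)),
                     ag_tensor(chan_mat(flair)), dims,
                     training = FALSE, bypass = bypass)
  structure(list(data = mat_vol(out$value, dims)), class = "mismatch_map")
}
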