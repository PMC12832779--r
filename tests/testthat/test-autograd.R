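# Gradient correctness of the autodiff engine, checked against central
# differences on random inputs.

test_that("elementwise, linear-algebra and activation ops backpropagate", {
  set.seed(1)
  gradcheck(function(p) {
    y <- ns$ag_matmul(p[[1]], p[[2]])
    y <- ns$ag_add_bias(y, p[[3]])
    y <- ns$ag_leaky_relu(y, 0.01)
    ns$ag_mean(ns$ag_mul(y, y))
  }, list(rmat(3, 4), rmat(4, 5), rmat(3, 1)))

  gradcheck(function(p) {
    s <- ns$ag_sigmoid(p[[1]])
    g <- ns$ag_gelu(p[[2]])
    ns$ag_sum(ns$ag_mul(s, g))
  }, list(rmat(4, 4), rmat(4, 4)))

  gradcheck(function(p) {
    sm <- ns$ag_softmax_rows(p[[1]])
    ns$ag_mean(ns$ag_mul(sm, p[[2]]))
  }, list(rmat(3, 6), rmat(3, 6)))

  gradcheck(function(p) {
    ns$ag_sum(ns$ag_mul_colvec(p[[1]], p[[2]]))
  }, list(rmat(4, 7), rmat(4, 1)))

  gradcheck(function(p) {
    a <- ns$ag_rows(p[[1]], 2:3)
    b <- ns$ag_rbind(list(a, ns$ag_rows(p[[1]], c(1L, 4L))))
    s1 <- ns$ag_sum(ns$ag_pow_const(b, 2))
    s2 <- ns$ag_sum(ns$ag_t(ns$ag_smul(ns$ag_rowmeans(p[[1]]), 2)))
    ns$ag_add(s1, s2)
  }, list(rmat(5, 3)))
})

test_that("normalization layers backpropagate", {
  set.seed(2)
  gradcheck(function(p) {
    y <- ns$ag_layernorm(p[[1]], p[[2]], p[[3]])
    ns$ag_mean(ns$ag_mul(y, y))
  }, list(rmat(6, 5), rmat(6, 1), rmat(6, 1)), tol = 1e-3)

  st <- new.env()
  gradcheck(function(p) {
    y <- ns$ag_batchnorm(p[[1]], p[[2]], p[[3]], st, training = TRUE)
    ns$ag_mean(ns$ag_mul(y, y))
  }, list(rmat(4, 9), rmat(4, 1), rmat(4, 1)), tol = 1e-3)
})

test_that("bilinear form backpropagates", {
  set.seed(3)
  gradcheck(function(p) {
    z <- ns$ag_bilinear(p[[1]], p[[2]], p[[3]], p[[4]])
    ns$ag_sum(ns$ag_sigmoid(z))
  }, list(rmat(3, 1), rmat(4, 1), rmat(5, 12), rmat(5, 1)))
})

test_that("conv3d backpropagates (plain, dilated, grouped, strided)", {
  set.seed(4)
  dims <- c(6L, 6L, 6L)
  # plain same-padded k=3
  gradcheck(function(p) {
    y <- ns$ag_conv3d(p[[1]], p[[2]], p[[3]], dims, k = 3L, pad = 1L)
    ns$ag_mean(ns$ag_mul(y, y))
  }, list(rmat(2, 216), rmat(3, 2 * 27), rmat(3, 1)))
  # dilated k=3, dilation 2, same padding
  gradcheck(function(p) {
    y <- ns$ag_conv3d(p[[1]], p[[2]], NULL, dims, k = 3L, pad = 2L,
                      dilation = 2L)
    ns$ag_sum(ns$ag_pow_const(y, 2))
  }, list(rmat(1, 216), rmat(2, 27)))
  # grouped: 4 channels, 2 groups
  gradcheck(function(p) {
    y <- ns$ag_conv3d(p[[1]], p[[2]], p[[3]], dims, k = 3L, pad = 1L,
                      groups = 2L)
    ns$ag_mean(ns$ag_mul(y, y))
  }, list(rmat(4, 216), rmat(4, 2 * 27), rmat(4, 1)))
  # strided patch-embedding style: k = stride = 3, no pad
  gradcheck(function(p) {
    y <- ns$ag_conv3d(p[[1]], p[[2]], p[[3]], dims, k = 3L, stride = 3L,
                      pad = 0L)
    ns$ag_mean(ns$ag_mul(y, y))
  }, list(rmat(2, 216), rmat(3, 2 * 27), rmat(3, 1)))
})

test_that("transposed convolution and pooling backpropagate", {
  set.seed(5)
  dims <- c(4L, 4L, 4L)
  gradcheck(function(p) {
    y <- ns$ag_conv_transpose3d(p[[1]], p[[2]], p[[3]], dims, k = 2L,
                                stride = 2L)
    ns$ag_mean(ns$ag_mul(y, y))
  }, list(rmat(3, 64), rmat(1 * 8, 3), rmat(1, 1)))

  dims <- c(6L, 6L, 6L)
  gradcheck(function(p) {
    ns$ag_sum(ns$ag_pow_const(ns$ag_avgpool2(p[[1]], dims), 2))
  }, list(rmat(2, 216)))
  gradcheck(function(p) {
    ns$ag_sum(ns$ag_pow_const(ns$ag_maxpool2(p[[1]], dims), 2))
  }, list(rmat(2, 216)))
})

test_that("conv3d forward matches a direct dense computation", {
  # independent oracle: brute-force triple loop for a tiny configuration
  set.seed(6)
  d <- c(4L, 4L, 4L)
  x <- array(rnorm(prod(d)), d)
  W <- array(rnorm(27), c(3, 3, 3))
  xm <- matrix(as.vector(x), 1)
  Wm <- matrix(as.vector(W), 1)
  y <- ns$ag_conv3d(ns$ag_tensor(xm), ns$ag_tensor(Wm), NULL, d, k = 3L,
                    pad = 1L)$value
  ref <- array(0, d)
  xp <- array(0, d + 2L)
  xp[2:5, 2:5, 2:5] <- x
  for (i in 1:4) for (j in 1:4) for (l in 1:4) {
    ref[i, j, l] <- sum(xp[i:(i + 2), j:(j + 2), l:(l + 2)] * W)
  }
  expect_equal(as.vector(y), as.vector(ref), tolerance = 1e-12)
})

test_that("composite model gradients are correct at tiny scale", {
  # end-to-end: MFEB + encoder + head on a 8^3 patch, 2 tokens wide
  set.seed(7)
  cfg <- encoder_config(input_size = 8L, patch_size = 4L, embed_dim = 8L,
                        n_blocks = 1L, n_heads = 2L, tabular_dim = 5L,
                        freeze_backbone = FALSE, dropout_rate = 0)
  model <- model_init(cfg, mfeb_width = 2L, seed = 11L)
  vols <- lapply(1:4, function(i) array(rnorm(512), c(8, 8, 8)))
  names(vols) <- c("t1", "t1ce", "t2", "flair")
  x_hc <- rnorm(5)
  fwd <- function() {
    out <- ns$model_fwd_ag(model, vols, x_hc, training = FALSE)
    L1 <- ns$ag_weighted_ce(out$p_idh, 1.5, 2, 1)
    L2 <- ns$ag_weighted_ce(out$p_grade, 1, 2, 0.5)
    ns$ag_joint_loss(L1, L2, model$uw)
  }
  root <- fwd()
  params <- ns$nn_trainable(list(m = model$mfeb, e = model$encoder,
                                 h = model$heads, u = model$uw))
  ns$ag_backward(root)
  # check a sample of parameters across all components
  picks <- c("m.db.db7.fd.W", "m.db.db3.ffn2.W", "m.tc.W",
             "e.patch_embed.W", "e.blocks.1.qkv.W", "e.blocks.1.mlp1.W",
             "e.adapters.1.mv.bil.W", "e.adapters.1.dgcb.b5.dconv.W",
             "e.adapters.1.dgcb.pc.W", "h.idh.W", "u.log_gamma")
  h <- 1e-5
  set.seed(8)
  for (nm in picks) {
    p <- params[[nm]]
    expect_false(is.null(p), label = paste("param", nm, "exists"))
    i <- sample.int(length(p$value), 1L)
    v0 <- p$value[i]
    p$value[i] <- v0 + h; fp <- fwd()$value[1L]
    p$value[i] <- v0 - h; fm <- fwd()$value[1L]
    p$value[i] <- v0
    num <- (fp - fm) / (2 * h)
    ana <- if (is.null(p$grad)) 0 else p$grad[i]
    expect_equal(ana, num, tolerance = 5e-3,
                 label = paste("analytic grad of", nm))
  }
})
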