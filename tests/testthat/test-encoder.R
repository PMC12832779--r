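# Encoder: patch-embed expansion, token-grid shapes, adapter contracts,
# QKV injection and the zero-adapter equivalence.

test_that("expand_patch_embed replicates and rescales correctly", {
  set.seed(1)
  E <- 6L; k <- 3L
  base <- array(rnorm(E * k^3), c(E, 1L, k, k, k))
  W5 <- expand_patch_embed(base)
  expect_identical(dim(W5), as.integer(c(E, 5 * k^3)))
  # five identical channels reproduce the single-channel response
  v <- rnorm(k^3)
  resp1 <- matrix(base, E, k^3) %*% v
  resp5 <- W5 %*% rep(v, 5L)
  expect_equal(resp5, resp1, tolerance = 1e-12)
  # zero input: response zero before and after (bias is handled outside)
  expect_equal(as.vector(W5 %*% numeric(5 * k^3)), numeric(E))
  expect_error(expand_patch_embed(array(0, c(E, 2L, k, k, k))), "expected 1")
})

test_that("patch embedding yields the contracted token grid at test scale", {
  set.seed(2)
  cfg <- encoder_config(input_size = 32L, patch_size = 4L, embed_dim = 48L,
                        n_blocks = 1L, n_heads = 6L)
  enc <- encoder_init(cfg)
  patch <- array(rnorm(5 * 32^3), c(5, 32, 32, 32))
  tg <- patch_embed(patch, enc)
  expect_identical(tg$grid, rep(8L, 3L))
  expect_identical(dim(tg$data), c(48L, 512L))   # 8^3 = 512 tokens
  expect_error(patch_embed(array(0, c(5, 30, 30, 30)), enc), "divisible")
  expect_error(encoder_config(input_size = 30L, patch_size = 4L), "divisible")
})

test_that("MVAdapter bottlenecks, gates in (0,1), and width preservation", {
  set.seed(3)
  cfg <- encoder_config(input_size = 32L, patch_size = 4L, embed_dim = 48L,
                        n_blocks = 1L, n_heads = 6L)
  enc <- encoder_init(cfg)
  x_fm <- matrix(rnorm(48 * 512), 48, 512)
  x_hc <- rnorm(101)
  g <- mvadapter_fuse(x_fm, x_hc, enc$adapters[[1]])
  expect_identical(dim(g$data), dim(x_fm))
  expect_true(all(g$gate > 0 & g$gate < 1))
  expect_identical(unname(g$bottleneck), c(6L, 6L))  # embed/8 at test scale
  expect_error(mvadapter_fuse(x_fm, rnorm(50), enc$adapters[[1]]),
               "tabular width")
})

test_that("DGCB output width is 3x embed and constant on zero input", {
  set.seed(4)
  cfg <- encoder_config(input_size = 32L, patch_size = 4L, embed_dim = 48L,
                        n_blocks = 1L, n_heads = 6L)
  enc <- encoder_init(cfg)
  z <- dgcb(matrix(0, 48, 512), enc$adapters[[1]])
  expect_identical(dim(z$data), c(144L, 512L))   # 3 * 48
  # translation invariance: all tokens identical on a constant input
  expect_true(all(abs(z$data - z$data[, 1L]) < 1e-12))
})

test_that("reference-scale shape contracts hold", {
  # (8,8,8) x 384 token grid, 48-wide bottlenecks, 1152-wide fusion
  set.seed(5)
  cfg <- encoder_config(n_blocks = 1L)   # reference dims, shallow for speed
  expect_identical(cfg$grid, 8L)
  expect_identical(cfg$embed_dim, 384L)
  expect_identical(cfg$adapter_hidden, 48L)
  expect_identical(cfg$qkv_dim, 1152L)
  enc <- encoder_init(cfg)
  expect_identical(dim(enc$patch_embed$W$value), as.integer(c(384, 5 * 16^3)))
  patch <- array(rnorm(5 * 128^3, sd = 0.1), c(5, 128, 128, 128))
  tg <- patch_embed(patch, enc)
  expect_identical(tg$grid, rep(8L, 3L))
  expect_identical(dim(tg$data), c(384L, 512L))
  ad <- mvadapter_fuse(tg, rnorm(101), enc$adapters[[1]])
  expect_identical(unname(ad$bottleneck), c(48L, 48L))
  fused <- dgcb(ad, enc$adapters[[1]])
  expect_identical(dim(fused$data), c(1152L, 512L))
})

test_that("inject_qkv is exact addition with shape checking", {
  set.seed(6)
  q <- matrix(rnorm(24 * 8), 24, 8)
  f <- matrix(rnorm(24 * 8), 24, 8)
  expect_identical(inject_qkv(matrix(0, 24, 8), q), q)
  expect_equal(inject_qkv(f, q) - q, f, tolerance = 1e-15)
  expect_error(inject_qkv(matrix(0, 24, 9), q), "mismatch")
})

test_that("zero-adapter equivalence: zeroed adapters reproduce the backbone", {
  set.seed(7)
  cfg <- encoder_config(input_size = 16L, patch_size = 4L, embed_dim = 16L,
                        n_blocks = 2L, n_heads = 2L, tabular_dim = 7L)
  enc <- encoder_init(cfg)
  patch <- array(rnorm(5 * 16^3), c(5, 16, 16, 16))
  x_hc <- rnorm(7)
  plain <- encode(patch, x_hc, enc, use_adapters = FALSE)
  withadp <- encode(patch, x_hc, enc, use_adapters = TRUE)
  expect_gt(max(abs(withadp - plain)), 1e-6)   # adapters do something
  zero_adapters(enc)
  zeroed <- encode(patch, x_hc, enc, use_adapters = TRUE)
  expect_equal(zeroed, plain, tolerance = 1e-12)
  expect_length(plain, 16L)
})

test_that("encode is deterministic in eval mode and freeze contract holds", {
  set.seed(8)
  cfg <- encoder_config(input_size = 16L, patch_size = 4L, embed_dim = 16L,
                        n_blocks = 1L, n_heads = 2L, tabular_dim = 7L,
                        freeze_backbone = TRUE)
  model <- model_init(cfg, mfeb_width = 2L, seed = 9L)
  vols <- lapply(1:4, function(i) array(rnorm(16^3), c(16, 16, 16)))
  names(vols) <- c("t1", "t1ce", "t2", "flair")
  # determinism with identical inputs
  x_hc <- rnorm(7)
  p <- array(rnorm(5 * 16^3), c(5, 16, 16, 16))
  expect_identical(encode(p, x_hc, model$encoder), encode(p, x_hc, model$encoder))

  # freeze: one optimizer step leaves backbone bit-identical
  backbone_before <- lapply(ns$nn_params(model$encoder$blocks),
                            function(p) p$value)
  pos_before <- model$encoder$pos$value
  out <- ns$model_fwd_ag(model, vols, x_hc, training = TRUE)
  L <- ns$ag_weighted_ce(out$p_idh, 1, 2, 1)
  ns$ag_backward(L)
  params <- ns$nn_trainable(list(m = model$mfeb, e = model$encoder,
                                 h = model$heads))
  opt <- make_optimizer(params, "adam", lr = 1e-2)
  opt$step()
  backbone_after <- lapply(ns$nn_params(model$encoder$blocks),
                           function(p) p$value)
  expect_identical(backbone_before, backbone_after)
  expect_identical(pos_before, model$encoder$pos$value)
  # while trainable parts moved
  expect_gt(max(abs(model$encoder$patch_embed$W$grad)), 0)
})

test_that("gate monotonicity: raising a gate logit raises channel magnitude", {
  set.seed(9)
  cfg <- encoder_config(input_size = 16L, patch_size = 4L, embed_dim = 16L,
                        n_blocks = 1L, n_heads = 2L, tabular_dim = 7L)
  enc <- encoder_init(cfg)
  x_fm <- matrix(rnorm(16 * 64), 16, 64)
  x_hc <- rnorm(7)
  ad <- enc$adapters[[1L]]
  base <- mvadapter_fuse(x_fm, x_hc, ad)
  for (ch in c(1L, 5L, 16L)) {
    ad$mv$bil$b$value[ch] <- ad$mv$bil$b$value[ch] + 0.5
    up <- mvadapter_fuse(x_fm, x_hc, ad)
    expect_gt(mean(abs(up$data[ch, ])), mean(abs(base$data[ch, ])))
    expect_gt(up$gate[ch], base$gate[ch])
    ad$mv$bil$b$value[ch] <- ad$mv$bil$b$value[ch] - 0.5
    base2 <- mvadapter_fuse(x_fm, x_hc, ad)
    expect_equal(base2$gate, base$gate, tolerance = 1e-12)
  }
})

test_that("load_pretrained expands 1-channel kernels and rejects mismatches", {
  set.seed(10)
  cfg <- encoder_config(input_size = 16L, patch_size = 4L, embed_dim = 16L,
                        n_blocks = 1L, n_heads = 2L, tabular_dim = 7L)
  # no checkpoint: random init, seed-controlled
  e1 <- load_pretrained(NULL, cfg, seed = 3L)
  e2 <- load_pretrained(NULL, cfg, seed = 3L)
  expect_identical(e1$patch_embed$W$value, e2$patch_embed$W$value)

  # forge a "pretrained" archive with a 1-channel patch embed
  src <- encoder_init(cfg)
  src$patch_embed$W <- ns$nn_param(matrix(rnorm(16 * 4^3), 16, 4^3))
  tmp <- tempfile()
  save_checkpoint(structure(list(cfg = cfg, mfeb = mfeb_init(2L),
                                 encoder = src, heads = heads_init(16L),
                                 uw = uncertainty_weights(),
                                 class = "x"), class = "mtg_model"), tmp)
  loaded <- load_pretrained(tmp, cfg, seed = 4L)
  expect_identical(dim(loaded$patch_embed$W$value), c(16L, 5L * 64L))
  expect_equal(loaded$patch_embed$W$value,
               expand_patch_embed(src$patch_embed$W$value), tolerance = 1e-12)
  # model accepts 5-channel input after expansion
  f <- encode(array(rnorm(5 * 16^3), c(5, 16, 16, 16)), rnorm(7), loaded)
  expect_length(f, 16L)

  # mismatched embed_dim: explicit failure naming tensors
  cfg2 <- encoder_config(input_size = 16L, patch_size = 4L, embed_dim = 32L,
                         n_blocks = 1L, n_heads = 2L, tabular_dim = 7L)
  expect_error(load_pretrained(tmp, cfg2, seed = 4L), "mismatch")
  unlink(tmp, recursive = TRUE)
})

abind_vols <- function(vols) {
  d <- dim(vols[[1]])
  out <- array(0, c(4L, d))
  for (i in 1:4) out[i, , , ] <- vols[[i]]
  # pad a fifth zero channel for direct encode() calls in tests
  out2 <- array(0, c(5L, d))
  out2[1:4, , , ] <- out
  out2
}
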