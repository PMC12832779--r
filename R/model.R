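# Full model assembly: MFEB -> 5-channel concat -> adapter-tuned encoder ->
# global average pooling -> two task heads, with trainable per-task
# uncertainty weights.

#' Initialize a full multi-task model
#'
#' @param enc_cfg an [encoder_config()].
#' @param mfeb_width internal channel width of the mismatch block.
#' @param seed RNG seed for the (random, seed-controlled) initialization.
#' @return list of class `mtg_model` with `mfeb`, `encoder`, `heads`, `uw`.
#' @export
model_init <- function(enc_cfg, mfeb_width = 8L, seed = 1L) {
  with_rng(seed, {
    structure(list(cfg = enc_cfg,
                   mfeb = mfeb_init(width = mfeb_width,
                                    dropout_rate = enc_cfg$dropout_rate,
                                    slope = enc_cfg$slope),
                   encoder = encoder_init(enc_cfg),
                   heads = heads_init(enc_cfg$embed_dim),
                   uw = uncertainty_weights(c(1, 1))), class = "mtg_model")
  })
}

# one subject forward on the tape
# returns list(p_idh, p_grade [ag scalars of class-1 prob], feature, tokens)
model_fwd_ag <- function(model, volumes, x_hc, training = FALSE,
                         bypass_mfeb = FALSE, use_adapters = TRUE) {
  dims <- vol_dims(volumes$t1)
  vt <- lapply(volumes, function(v) ag_tensor(chan_mat(v)))
  xtf <- mfeb_fwd_ag(model$mfeb, vt$t2, vt$flair, dims,
                     training = training, bypass = bypass_mfeb)
  x5 <- ag_rbind(list(vt$t1, vt$t1ce, vt$t2, vt$flair, xtf))
  hc <- ag_tensor(matrix(x_hc, ncol = 1L))
  enc <- encode_ag(model$encoder, x5, hc, dims, training = training,
                   use_adapters = use_adapters)
  p1 <- ag_pick(ag_softmax_col(nn_linear_fwd(model$heads$idh, enc$feature)), 2L)
  p2 <- ag_pick(ag_softmax_col(nn_linear_fwd(model$heads$grade, enc$feature)), 2L)
  list(p_idh = p1, p_grade = p2, feature = enc$feature, tokens = enc$tokens,
       grid = enc$grid, mismatch = xtf)
}

# plain-value prediction: class-1 probabilities per task
model_predict <- function(model, subject, x_hc, bypass_mfeb = FALSE,
                          use_adapters = TRUE) {
  out <- model_fwd_ag(model, subject$volumes, x_hc, training = FALSE,
                      bypass_mfeb = bypass_mfeb, use_adapters = use_adapters)
  c(idh = out$p_idh$value[1L], grade = out$p_grade$value[1L])
}

model_params <- function(model) {
  nn_params(list(mfeb = model$mfeb, encoder = model$encoder,
                 heads = model$heads, uw = model$uw))
}

model_get_values <- function(model) lapply(model_params(model), function(p) p$value)

model_set_values <- function(model, values) {
  ps <- model_params(model)
  for (nm in names(values)) {
    if (!is.null(ps[[nm]])) ps[[nm]]$value <- values[[nm]]
  }
  invisible(model)
}

# ---- checkpoints: flat named-tensor archive + JSON sidecar ------------------

#' Save a trained checkpoint
#'
#' Writes a directory with `params.bin` (all tensors concatenated as
#' little-endian doubles), `manifest.json` (tensor names, shapes, offsets,
#' trainability, batch-norm running moments) and `config.json`.
#'
#' @param ckpt a [train()] result (or a bare `mtg_model`).
#' @param path directory to create.
#' @export
save_checkpoint <- function(ckpt, path) {
  model <- if (inherits(ckpt, "mtg_model")) ckpt else ckpt$model
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ps <- model_params(model)
  # batch-norm running moments and (for full checkpoints) standardization
  # statistics ride in the same binary archive so round trips are bit-exact
  bn <- nn_bn_states(list(mfeb = model$mfeb, encoder = model$encoder))
  extra <- list()
  for (nm in names(bn)) {
    if (!is.null(bn[[nm]]$mean)) {
      extra[[paste0("bn::", nm, "::mean")]] <-
        list(value = matrix(bn[[nm]]$mean, ncol = 1L), requires_grad = FALSE)
      extra[[paste0("bn::", nm, "::var")]] <-
        list(value = matrix(bn[[nm]]$var, ncol = 1L), requires_grad = FALSE)
    }
  }
  if (!inherits(ckpt, "mtg_model") && !is.null(ckpt$std_stats)) {
    extra[["std::mean"]] <- list(value = matrix(ckpt$std_stats$mean, ncol = 1L),
                                 requires_grad = FALSE)
    extra[["std::sd"]] <- list(value = matrix(ckpt$std_stats$sd, ncol = 1L),
                               requires_grad = FALSE)
  }
  all_t <- c(lapply(ps, function(p) {
    list(value = p$value, requires_grad = p$requires_grad)
  }), extra)
  sizes <- vapply(all_t, function(p) length(p$value), numeric(1))
  offsets <- cumsum(c(0, sizes))[seq_along(sizes)]
  con <- file(file.path(path, "params.bin"), "wb")
  for (p in all_t) writeBin(as.vector(p$value), con, size = 8L,
                            endian = "little")
  close(con)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mtglioma")),
    tensors = lapply(seq_along(all_t), function(i) {
      list(name = names(all_t)[i], dim = dim(all_t[[i]]$value),
           offset = offsets[i], length = sizes[i],
           requires_grad = all_t[[i]]$requires_grad)
    }))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  cfginfo <- list(encoder = unclass(model$cfg))
  if (!inherits(ckpt, "mtg_model")) {
    cfginfo$train <- serialize_cfg(ckpt$cfg)
    cfginfo$mfeb_width <- model$mfeb$width
    if (!is.null(ckpt$history)) {
      data.table::fwrite(ckpt$history, file.path(path, "history.csv"))
    }
  } else {
    cfginfo$mfeb_width <- model$mfeb$width
  }
  jsonlite::write_json(cfginfo, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_tensor_archive <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  raw <- readBin(file.path(path, "params.bin"), "double",
                 n = file.size(file.path(path, "params.bin")) / 8L,
                 size = 8L, endian = "little")
  tens <- manifest$tensors
  out <- list()
  for (i in seq_len(nrow(tens))) {
    len <- tens$length[i]
    v <- raw[(tens$offset[i] + 1L):(tens$offset[i] + len)]
    d <- tens$dim[[i]]
    out[[tens$name[i]]] <- list(value = matrix(v, d[1L], d[2L]),
                                requires_grad = tens$requires_grad[i])
  }
  list(tensors = out, manifest = manifest)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path checkpoint directory.
#' @return list with `model`, `cfg` (train config if present), `std_stats`,
#'   `history`.
#' @export
load_checkpoint <- function(path) {
  arch <- read_tensor_archive(path)
  cfginfo <- jsonlite::read_json(file.path(path, "config.json"),
                                 simplifyVector = TRUE)
  enc_cfg <- do.call(encoder_config,
                     cfginfo$encoder[setdiff(names(cfginfo$encoder),
                                             c("adapter_hidden", "grid"))])
  model <- model_init(enc_cfg, mfeb_width = cfginfo$mfeb_width %||% 8L,
                      seed = 1L)
  ps <- model_params(model)
  bn <- nn_bn_states(list(mfeb = model$mfeb, encoder = model$encoder))
  std_stats <- NULL
  for (nm in names(arch$tensors)) {
    t <- arch$tensors[[nm]]
    if (startsWith(nm, "bn::")) {
      parts <- strsplit(nm, "::", fixed = TRUE)[[1L]]
      if (!is.null(bn[[parts[2L]]])) {
        bn[[parts[2L]]][[parts[3L]]] <- t$value[, 1L]
      }
      next
    }
    if (startsWith(nm, "std::")) {
      std_stats[[sub("^std::", "", nm)]] <- t$value[, 1L]
      next
    }
    if (is.null(ps[[nm]])) stop("unknown tensor in checkpoint: ", nm)
    if (!identical(dim(ps[[nm]]$value), dim(t$value))) {
      stop("dimension mismatch for ", nm)
    }
    ps[[nm]]$value <- t$value
    ps[[nm]]$requires_grad <- ps[[nm]]$needs <- isTRUE(t$requires_grad)
  }
  hist_path <- file.path(path, "history.csv")
  list(model = model,
       cfg = if (!is.null(cfginfo$train)) deserialize_cfg(cfginfo$train),
       std_stats = std_stats,
       history = if (file.exists(hist_path)) {
         as.data.frame(data.table::fread(hist_path))
       })
}

#' Load pretrained backbone weights into a fresh encoder
#'
#' Backbone tensors are matched by name; a single-channel patch-embedding
#' kernel is expanded to the configured channel count via
#' [expand_patch_embed()]. With `path = NULL` the encoder is randomly
#' initialized (seed-controlled) — the documented behavior when no
#' checkpoint is available.
#'
#' @param path checkpoint directory (a flat named-tensor archive), or `NULL`.
#' @param cfg an [encoder_config()].
#' @param seed seed for random initialization.
#' @return an encoder parameter list.
#' @export
load_pretrained <- function(path, cfg, seed = 1L) {
  enc <- with_rng(seed, encoder_init(cfg))
  if (is.null(path)) return(enc)
  arch <- read_tensor_archive(path)
  ps <- nn_params(enc)
  bad <- character(0)
  for (nm in names(arch$tensors)) {
    key <- sub("^encoder\\.", "", nm)
    if (is.null(ps[[key]])) next
    v <- arch$tensors[[nm]]$value
    if (key == "patch_embed.W" && ncol(v) * cfg$in_channels ==
        ncol(ps[[key]]$value)) {
      v <- expand_patch_embed(v, cfg$in_channels)
    }
    if (!identical(dim(ps[[key]]$value), dim(v))) {
      bad <- c(bad, sprintf("%s: checkpoint %s vs model %s", key,
                            paste(dim(v), collapse = "x"),
                            paste(dim(ps[[key]]$value), collapse = "x")))
      next
    }
    ps[[key]]$value <- v
  }
  if (length(bad) > 0L) {
    stop("dimension mismatch for tensors:\n  ", paste(bad, collapse = "\n  "))
  }
  enc
}

serialize_cfg <- function(cfg) {
  out <- unclass(cfg)
  out$encoder <- NULL
  out$loss <- if (!is.null(cfg$loss)) unclass(cfg$loss)
  out
}

deserialize_cfg <- function(lst) {
  if (!is.null(lst$loss)) lst$loss <- do.call(loss_config, lst$loss)
  lst
}
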