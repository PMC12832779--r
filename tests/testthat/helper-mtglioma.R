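# Shared test helpers. Fixtures are built in code; nothing binary on disk.

ns <- asNamespace("mtglioma")

# central-difference gradient check for a scalar-valued tape function.
# f: function(list of ag_tensors) -> ag scalar. Checks up to `n_per` entries
# per tensor against the analytic gradient.
gradcheck <- function(f, values, n_per = 4L, h = 1e-5, tol = 1e-4,
                      seed = 42L) {
  set.seed(seed)
  tensors <- lapply(values, function(v) ns$ag_tensor(v, requires_grad = TRUE))
  out <- f(tensors)
  ns$ag_backward(out)
  for (ti in seq_along(tensors)) {
    te <- tensors[[ti]]
    n <- length(te$value)
    idx <- if (n <= n_per) seq_len(n) else sample.int(n, n_per)
    for (i in idx) {
      v0 <- te$value[i]
      te$value[i] <- v0 + h
      fp <- f(tensors)$value[1L]
      te$value[i] <- v0 - h
      fm <- f(tensors)$value[1L]
      te$value[i] <- v0
      num <- (fp - fm) / (2 * h)
      ana <- if (is.null(te$grad)) 0 else te$grad[i]
      expect_equal(ana, num, tolerance = tol,
                   label = sprintf("tensor %d entry %d analytic", ti, i),
                   expected.label = "numeric")
    }
  }
  invisible(NULL)
}

rmat <- function(nr, nc, sd = 1) matrix(rnorm(nr * nc, sd = sd), nr, nc)

with_seed_local <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# small standard phantom cohorts, cached across test files
cohort_cache <- new.env()
get_cohort <- function(n = 20, grid = 16, seed = 1, ...) {
  key <- paste(n, grid, seed, paste(unlist(list(...)), collapse = "_"),
               sep = "_")
  if (is.null(cohort_cache[[key]])) {
    cohort_cache[[key]] <- generate_cohort(
      phantom_spec(n_subjects = n, grid_size = grid, seed = seed, ...))
  }
  cohort_cache[[key]]
}

scaled_encoder_config <- function(input = 16L, patch = 4L, embed = 16L,
                                  blocks = 1L, heads = 2L, ...) {
  encoder_config(input_size = input, patch_size = patch, embed_dim = embed,
                 n_blocks = blocks, n_heads = heads, ...)
}
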