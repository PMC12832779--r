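# Phantom generator: stratification, determinism, mask geometry, planted
# signals, patch extraction and the feature table.

tumor_interior_diff <- function(s) {
  interior <- s$roi_mask == 1L | s$roi_mask == 2L
  mean(s$volumes$t2[interior] - s$volumes$flair[interior])
}

test_that("cohort stratification is exact and deterministic", {
  co <- generate_cohort(phantom_spec(20, grid_size = 16, seed = 1,
                                     idh_mutant_fraction = 0.2))
  idh <- vapply(co, function(s) s$idh_label, integer(1))
  expect_identical(sum(idh), 4L)        # round(20 * 0.2)
  expect_identical(sum(idh == 0L), 16L)
  gr <- vapply(co, function(s) s$grade_label, integer(1))
  expect_identical(sum(gr), 16L)        # round(20 * 0.8)
  # wildtype co-occurs with higher grade (coupling direction)
  expect_gt(mean(gr[idh == 0L]), mean(gr[idh == 1L]))

  co2 <- generate_cohort(phantom_spec(20, grid_size = 16, seed = 1,
                                      idh_mutant_fraction = 0.2))
  expect_identical(co[[3]]$volumes$t2, co2[[3]]$volumes$t2)
  expect_identical(co[[7]]$roi_mask, co2[[7]]$roi_mask)
  expect_identical(co[[5]]$features, co2[[5]]$features)

  expect_error(phantom_spec(1), ">= 2")
  expect_error(phantom_spec(10, grid_size = 8), "too small")
  expect_error(phantom_spec(10, idh_mutant_fraction = 1.2), "\\[0, 1\\]")
})

test_that("masks partition the tumor with a strictly interior core", {
  co <- get_cohort(n = 12, grid = 24, seed = 2)
  for (s in co) {
    m <- s$roi_mask
    expect_true(all(m %in% 0:3))
    expect_gt(sum(m == 1L), 0)
    expect_gt(sum(m == 2L), 0)
    expect_gt(sum(m == 3L), 0)
    # core voxels are never adjacent to background: strictly inside the rim
    core <- which(m == 1L, arr.ind = TRUE)
    for (ax in 1:3) {
      for (dlt in c(-1L, 1L)) {
        nb <- core
        nb[, ax] <- pmin(pmax(nb[, ax] + dlt, 1L), dim(m)[ax])
        expect_true(all(m[nb] %in% c(1L, 2L)))
      }
    }
    # volumes share the mask's shape and are finite
    for (v in s$volumes) {
      expect_identical(dim(v), dim(m))
      expect_true(all(is.finite(v)))
    }
    expect_true(all(is.finite(s$features)))
  }
})

test_that("tumor voxels form one connected component", {
  co <- get_cohort(n = 6, grid = 24, seed = 3)
  for (s in co) {
    m <- s$roi_mask > 0L
    seeds <- which(m, arr.ind = TRUE)
    # flood fill from one tumor voxel (6-connectivity)
    visited <- array(FALSE, dim(m))
    queue <- list(seeds[1, ])
    visited[seeds[1, 1], seeds[1, 2], seeds[1, 3]] <- TRUE
    while (length(queue) > 0) {
      v <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (ax in 1:3) for (dlt in c(-1L, 1L)) {
        w <- v; w[ax] <- w[ax] + dlt
        if (all(w >= 1L) && all(w <= dim(m)) &&
            m[w[1], w[2], w[3]] && !visited[w[1], w[2], w[3]]) {
          visited[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1]] <- w
        }
      }
    }
    expect_identical(sum(visited), sum(m))
  }
})

test_that("mismatch signal is planted, null at zero effect, monotone", {
  # null case: no class difference at mismatch_effect = 0
  co0 <- generate_cohort(phantom_spec(100, grid_size = 16, seed = 4,
                                      mismatch_effect = 0))
  idh <- vapply(co0, function(s) s$idh_label, integer(1))
  d0 <- vapply(co0, tumor_interior_diff, numeric(1))
  expect_gt(t.test(d0[idh == 1], d0[idh == 0])$p.value, 0.01)

  # monotonicity in the effect (3 levels, n = 100)
  gaps <- vapply(c(0, 1, 2), function(eff) {
    co <- generate_cohort(phantom_spec(100, grid_size = 16, seed = 4,
                                       mismatch_effect = eff))
    idh <- vapply(co, function(s) s$idh_label, integer(1))
    d <- vapply(co, tumor_interior_diff, numeric(1))
    mean(d[idh == 1]) - mean(d[idh == 0])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_lt(abs(gaps[1]), 0.2)
})

test_that("necrosis effect inflates high-grade cores", {
  co <- generate_cohort(phantom_spec(100, grid_size = 16, seed = 3,
                                     necrosis_effect = 2))
  gr <- vapply(co, function(s) s$grade_label, integer(1))
  core <- vapply(co, function(s) sum(s$roi_mask == 1L), numeric(1))
  expect_gt(mean(core[gr == 1]), mean(core[gr == 0]))
})

test_that("extract_patch crops around the ROI midpoint with zero padding", {
  g <- 64L
  s <- list(volumes = list(t1 = array(seq_len(g^3), rep(g, 3))),
            roi_mask = array(0L, rep(g, 3)), subject_id = "sub-xyz")
  # symmetric ROI: 0-based bbox [28, 36] -> midpoint 32
  s$roi_mask[29:37, 29:37, 29:37] <- 2L
  p <- extract_patch(s, 32L)
  # 0-based crop [16, 48) -> R indices 17..48
  expect_identical(p$volumes$t1, s$volumes$t1[17:48, 17:48, 17:48] + 0)
  expect_identical(dim(p$roi_mask), rep(32L, 3L))

  # midpoint near the boundary: zero padding on the low side, center kept
  s2 <- list(volumes = list(t1 = array(1, rep(16L, 3))),
             roi_mask = array(0L, rep(16L, 3)), subject_id = "sub-edge")
  s2$roi_mask[6, 6, 6] <- 1L   # 0-based midpoint (5,5,5)
  p2 <- extract_patch(s2, 32L)
  # crop [-11, 21): 11 zero-padded planes, midpoint at patch center (16)
  expect_identical(dim(p2$volumes$t1), rep(32L, 3L))
  expect_true(all(p2$volumes$t1[1:11, , ] == 0))
  expect_identical(p2$roi_mask[17, 17, 17], 1L)  # 0-based (16,16,16)

  s3 <- s2; s3$roi_mask[] <- 0L
  expect_error(extract_patch(s3, 8L), "sub-edge")
})

test_that("feature table plants informative columns and is 101 wide", {
  co <- get_cohort(n = 200, grid = 16, seed = 5)
  # null case: no planted effect -> ~ no extreme t statistics
  ft0 <- make_feature_table(co, n_informative = 0L, effect = 0, seed = 9L)
  expect_identical(ncol(ft0$features), 101L)
  expect_identical(colnames(ft0$features)[100:101], c("age", "sex"))
  # exceedance of the 0.999 |t| quantile, mean rate over 10 seeds <= 1%
  rate <- mean(vapply(1:10, function(sd) {
    ft <- make_feature_table(co, n_informative = 0L, effect = 0, seed = sd)
    tstat <- apply(ft$features[, 1:99], 2, function(x) {
      unname(t.test(x[ft$idh == 1], x[ft$idh == 0])$statistic)
    })
    mean(abs(tstat) > qnorm(0.999))
  }, numeric(1)))
  expect_lte(rate, 0.01)

  # planted columns carry the largest point-biserial correlations
  co400 <- get_cohort(n = 400, grid = 16, seed = 6)
  hits <- vapply(1:10, function(sd) {
    ft <- make_feature_table(co400, n_informative = 10L, effect = 2,
                             seed = sd)
    cors <- vapply(seq_len(99L), function(j) {
      max(abs(cor(ft$features[, j], ft$idh)),
          abs(cor(ft$features[, j], ft$grade)))
    }, numeric(1))
    top10 <- order(cors, decreasing = TRUE)[1:10]
    length(intersect(top10, 1:10))
  }, numeric(1))
  expect_gte(mean(hits >= 9), 0.9)

  # age is wildtype-shifted (older implies wildtype)
  ft <- make_feature_table(co400, seed = 7L)
  expect_gt(mean(ft$features[ft$idh == 0, "age"]),
            mean(ft$features[ft$idh == 1, "age"]))
  expect_error(make_feature_table(co, n_informative = 100L), "99")
})
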