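# Loss oracles: independent direct-formula evaluation, frozen derived values,
# the closed-form optimum of the uncertainty weights, and head contracts.

# independent oracle: literal transcription of the printed formulas
oracle_wce <- function(y, a, g, b) {
  -a * (1 - y)^g * log(y) + b * (-y * log(y) - (1 - y) * log(1 - y))
}
oracle_joint <- function(L, g) sum(L / (2 * g^2)) + sum(log(g))

test_that("weighted_ce matches hand/formula evaluation to 1e-6", {
  # frozen derived cases (hand arithmetic)
  expect_equal(weighted_ce(0.5, loss_config(alpha = 1, gamma = 2, beta = 1)),
               0.25 * log(2) + log(2), tolerance = 1e-9)
  expect_equal(weighted_ce(0.5, loss_config(alpha = 1, gamma = 2, beta = 1)),
               0.866434, tolerance = 1e-6)
  # exact value 0.2680527 (the six-digit 0.268052 is a truncation)
  expect_equal(weighted_ce(0.8, loss_config(alpha = 2, gamma = 2, beta = 0.5)),
               oracle_wce(0.8, 2, 2, 0.5), tolerance = 1e-9)
  expect_lt(abs(weighted_ce(0.8, loss_config(alpha = 2, gamma = 2,
                                             beta = 0.5)) - 0.268052), 1e-6)
  # y_t -> 1: loss -> 0 (entropy term vanishes like -e*log(e))
  expect_lt(weighted_ce(1 - 1e-9, loss_config()), 1e-5)
  # >= 20 random tuples against the oracle
  set.seed(1)
  for (i in 1:25) {
    y <- runif(1, 0.02, 0.98)
    a <- runif(1, 0.2, 5)
    g <- sample(0:4, 1)
    b <- runif(1, 0, 2)
    expect_equal(weighted_ce(y, loss_config(alpha = a, gamma = g, beta = b)),
                 oracle_wce(y, a, g, b), tolerance = 1e-6)
  }
  # conventional form switch
  expect_equal(weighted_ce(0.7, loss_config(alpha = 1.5, gamma = 2, beta = 0.3,
                                            form = "conventional")),
               -1.5 * 0.09 * log(0.7) - 0.3 * log(0.7), tolerance = 1e-9)
  # clamping warns
  expect_warning(weighted_ce(1.2, loss_config()), "clamping")
})

test_that("weighted_ce with beta=0 is strictly decreasing in y_t", {
  cfg <- loss_config(alpha = 1.3, gamma = 2, beta = 0)
  ys <- seq(0.01, 0.99, length.out = 200)
  expect_true(all(diff(weighted_ce(ys, cfg)) < 0))
})

test_that("joint_loss matches hand evaluation and closed-form optimum", {
  # gamma = (1,1) reduces to the mean
  expect_equal(joint_loss(0.4, 0.6, c(1, 1)), 0.5, tolerance = 1e-12)
  # frozen derived case
  expect_equal(joint_loss(0.8, 0.6, c(2, 1)), 0.8 / 8 + 0.6 / 2 + log(2),
               tolerance = 1e-12)
  expect_equal(joint_loss(0.8, 0.6, c(2, 1)), 1.093147, tolerance = 1e-6)
  # random tuples against the oracle
  set.seed(2)
  for (i in 1:25) {
    L <- runif(2, 0, 3)
    g <- runif(2, 0.3, 3)
    expect_equal(joint_loss(L[1], L[2], g), oracle_joint(L, g),
                 tolerance = 1e-6)
  }
  # closed-form calculus oracle: minimizer gamma_i^2 = L_i with per-task
  # minimum 1/2 + log(L_i)/2; at L_i = 1 the optimum is gamma = 1, value 0.5
  for (L in c(0.5, 1, 2)) {
    opt <- stats::optimize(function(g) joint_loss(L, 1, c(g, 1)), c(0.05, 10))
    expect_equal(opt$minimum, sqrt(L), tolerance = 1e-3)
    # per-task minimum value 1/2 + log(L)/2 (task 2 contributes 1/2 at L=1)
    expect_equal(joint_loss(L, 1, c(sqrt(L), 1)),
                 (0.5 + 0.5 * log(L)) + 0.5, tolerance = 1e-12)
  }
  expect_equal(joint_loss(1, 1, c(1, 1)), 1 / 2 + 1 / 2, tolerance = 1e-12)
  expect_error(joint_loss(1, 1, c(-1, 1)), "positive")
  expect_error(uncertainty_weights(c(0, 1)), "positive")
})

test_that("joint loss gradient wrt gamma matches -L/gamma^3 + 1/gamma", {
  set.seed(3)
  for (i in 1:5) {
    L <- runif(2, 0.1, 2)
    g <- runif(2, 0.5, 2)
    # numerical gradient of the numeric form
    h <- 1e-6
    for (t in 1:2) {
      gp <- g; gp[t] <- g[t] + h
      gm <- g; gm[t] <- g[t] - h
      num <- (joint_loss(L[1], L[2], gp) - joint_loss(L[1], L[2], gm)) / (2 * h)
      expect_equal(num, -L[t] / g[t]^3 + 1 / g[t], tolerance = 1e-5)
    }
    # tape version agrees (chain rule through log-parameterization:
    # dL/dlog_gamma = gamma * dL/dgamma)
    uw <- uncertainty_weights(g)
    root <- ns$ag_joint_loss(ns$ag_tensor(matrix(L[1], 1, 1)),
                             ns$ag_tensor(matrix(L[2], 1, 1)), uw)
    expect_equal(root$value[1L], oracle_joint(L, g), tolerance = 1e-9)
    ns$ag_backward(root)
    expect_equal(uw$log_gamma$grad[, 1L],
                 g * (-L / g^3 + 1 / g), tolerance = 1e-6)
  }
})

test_that("tape weighted_ce agrees with the numeric implementation", {
  set.seed(4)
  for (i in 1:10) {
    y <- runif(1, 0.05, 0.95)
    a <- runif(1, 0.5, 3); b <- runif(1, 0, 1.5)
    node <- ns$ag_weighted_ce(ns$ag_tensor(matrix(y, 1, 1)), a, 2, b)
    expect_equal(node$value[1L],
                 weighted_ce(y, loss_config(alpha = a, gamma = 2, beta = b)),
                 tolerance = 1e-9)
  }
})

test_that("heads produce normalized two-task probabilities", {
  set.seed(5)
  heads <- heads_init(12L)
  p <- predict_heads(rnorm(12), heads)
  expect_identical(dim(p), c(2L, 2L))
  expect_equal(unname(rowSums(p)), c(1, 1), tolerance = 1e-12)
  # zero logits -> 0.5 (softmax symmetry)
  heads0 <- heads_init(12L)
  for (t in c("idh", "grade")) {
    heads0[[t]]$W$value[] <- 0
    heads0[[t]]$b$value[] <- 0
  }
  expect_equal(as.vector(predict_heads(rnorm(12), heads0)),
               rep(0.5, 4), tolerance = 1e-12)
})
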