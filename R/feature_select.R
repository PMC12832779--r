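# Tabular feature standardization and Lasso-based selection.
#
# Selection runs per task: within each of five cross-validation folds an
# L1-penalized logistic model is fit on the fold's training part with the
# penalty chosen by held-out binomial deviance on a 50-point log-spaced grid;
# nonzero-coefficient features are pooled (union) across folds, an
# unpenalized logistic refit on the pooled survivors assigns Wald p-values,
# and survivors with p > 0.05 are dropped. Age and sex are always retained
# when the two task selections are combined.

#' Standardize a feature table on training rows
#'
#' Columns are centered and scaled using mean and population (n-denominator)
#' standard deviation fitted on `fit_rows` only; the same transform is applied
#' to all rows, so held-out rows use training statistics. Zero-variance
#' columns map to 0 with a warning.
#'
#' @param table numeric matrix (subjects x features, named columns) or a
#'   [make_feature_table()] result.
#' @param fit_rows indices of the rows used to fit the statistics (default:
#'   all rows).
#' @return list of class `feature_table_std` with `matrix` (all rows,
#'   standardized), `feature_names`, and `standardization_stats`
#'   (`mean`, `sd` per feature, fitted on `fit_rows`).
#' @export
standardize <- function(table, fit_rows = NULL) {
  X <- if (inherits(table, "mtg_feature_table")) table$features else table
  if (!is.matrix(X)) X <- as.matrix(X)
  if (anyNA(X)) stop("feature table contains missing values")
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(X))
  if (length(fit_rows) == 0L) stop("fit_rows must be nonempty")
  Xf <- X[fit_rows, , drop = FALSE]
  mu <- colMeans(Xf)
  sdv <- sqrt(colMeans(sweep(Xf, 2L, mu)^2))
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance column(s) mapped to 0")
    sdv[zero] <- 1
  }
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  Z[, zero] <- 0
  structure(list(matrix = Z, feature_names = colnames(X),
                 standardization_stats = list(mean = mu, sd = sdv),
                 fit_rows = fit_rows), class = "feature_table_std")
}

binom_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated Lasso feature selection for one task
#'
#' @param table a [standardize()]d table, a [make_feature_table()] result or a
#'   numeric matrix (standardized internally in the latter cases).
#' @param labels binary 0/1 vector, one per row.
#' @param n_folds number of cross-validation folds.
#' @param lambda_grid optional penalty grid; default 50 log-spaced values
#'   below the data-derived maximum.
#' @param p_cutoff Wald p-value filter applied after pooling (default 0.05).
#' @param pool `"union"` (default) or `"intersection"` of per-fold selections.
#' @param family `"gaussian"` (Lasso regression on the 0/1 label, the
#'   radiomics-standard reading; default) or `"binomial"` (logistic Lasso;
#'   note the unpenalized refit can suffer complete separation with strong
#'   features).
#' @param seed RNG seed controlling fold assignment.
#' @return list of class `lasso_selection`: `selected` (column indices),
#'   `p_values` (for pooled survivors), `per_fold` (per-fold index lists),
#'   `feature_names`, `n_features`.
#' @export
lasso_select <- function(table, labels, n_folds = 5L, lambda_grid = NULL,
                         p_cutoff = 0.05, pool = c("union", "intersection"),
                         family = c("gaussian", "binomial"), seed = 1L) {
  pool <- match.arg(pool)
  family <- match.arg(family)
  X <- if (inherits(table, "feature_table_std")) table$matrix
       else standardize(table)$matrix
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels are single-class; cannot select")
  if (min(table(labels)) < n_folds) {
    stop("need at least n_folds (", n_folds, ") examples of each class")
  }
  with_rng(seed, {
    fold <- stratified_folds(labels, n_folds)
    if (is.null(lambda_grid)) {
      yc <- labels - mean(labels)
      lmax <- max(abs(crossprod(X, yc))) / length(labels)
      lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 50L))
    }
    per_fold <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], labels[tr],
                            family = family, alpha = 1,
                            lambda = lambda_grid, standardize = FALSE)
      ph <- stats::predict(fit, X[!tr, , drop = FALSE], type = "response")
      dev <- apply(ph, 2L, function(p) {
        if (family == "binomial") binom_deviance(labels[!tr], p)
        else sum((labels[!tr] - p)^2)
      })
      best <- which.min(dev)
      cf <- as.matrix(stats::coef(fit))[-1L, best]   # drop intercept
      per_fold[[f]] <- which(cf != 0)
    }
    pooled <- if (pool == "union") {
      sort(unique(unlist(per_fold)))
    } else {
      sort(Reduce(intersect, per_fold))
    }
    p_values <- stats::setNames(numeric(0), character(0))
    selected <- integer(0)
    if (length(pooled) > 0L) {
      df <- data.frame(y = labels, X[, pooled, drop = FALSE])
      refit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                           family = if (family == "binomial") {
                                             stats::binomial()
                                           } else {
                                             stats::gaussian()
                                           }))
      sm <- suppressWarnings(summary(refit)$coefficients)
      pv <- rep(NA_real_, length(pooled))
      names(pv) <- colnames(df)[-1L]
      hit <- intersect(rownames(sm), names(pv))
      pv[hit] <- sm[hit, 4L]
      p_values <- stats::setNames(pv, colnames(X)[pooled])
      selected <- pooled[!is.na(pv) & pv <= p_cutoff]
    }
    structure(list(selected = selected, p_values = p_values,
                   per_fold = per_fold, pooled = pooled,
                   feature_names = colnames(X), n_features = ncol(X)),
              class = "lasso_selection")
  })
}

#' Combine per-task selections
#'
#' Set union of the two tasks' selected columns, order-stable by original
#' column index; clinical columns (age, sex) are always retained.
#'
#' @param sel_idh,sel_grade [lasso_select()] results (or integer index
#'   vectors).
#' @param clinical indices of the always-kept clinical columns; defaults to
#'   the columns named `"age"` and `"sex"` when names are available, else the
#'   last two columns.
#' @return list of class `selection_result` with `selected_indices` per task,
#'   `union_indices` (including clinical), and the per-fold provenance and
#'   p-values when available.
#' @export
combine_tasks <- function(sel_idh, sel_grade, clinical = NULL) {
  get_idx <- function(s) if (inherits(s, "lasso_selection")) s$selected else as.integer(s)
  i1 <- get_idx(sel_idh); i2 <- get_idx(sel_grade)
  if (is.null(clinical)) {
    nms <- if (inherits(sel_idh, "lasso_selection")) sel_idh$feature_names else NULL
    clinical <- if (!is.null(nms)) {
      which(nms %in% c("age", "sex"))
    } else if (inherits(sel_idh, "lasso_selection")) {
      (sel_idh$n_features - 1L):sel_idh$n_features
    } else {
      integer(0)
    }
  }
  structure(list(
    selected_indices = list(idh = sort(i1), grade = sort(i2)),
    union_indices = sort(unique(c(i1, i2, clinical))),
    clinical_indices = sort(clinical),
    per_fold = list(
      idh = if (inherits(sel_idh, "lasso_selection")) sel_idh$per_fold,
      grade = if (inherits(sel_grade, "lasso_selection")) sel_grade$per_fold),
    p_values = list(
      idh = if (inherits(sel_idh, "lasso_selection")) sel_idh$p_values,
      grade = if (inherits(sel_grade, "lasso_selection")) sel_grade$p_values)),
    class = "selection_result")
}
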