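# Synthetic multimodal glioma phantom cohorts.
#
# Each phantom subject carries four modality volumes (T1, T1CE, T2, FLAIR), a
# three-compartment tumor mask (1 = necrotic core, 2 = enhancing, 3 = edema,
# concentric ellipsoids inside a brain ellipsoid), binary IDH and grade
# labels, and a 101-element tabular feature vector. Two signals are planted:
# IDH-mutant subjects get tumor-interior T2 hyperintensity with matching
# FLAIR suppression (the T2-FLAIR mismatch sign), scaled by mismatch_effect;
# high-grade subjects get a necrotic core inflated in volume by
# (1 + necrosis_effect). Class marginals default to the 80/20 wildtype/mutant
# and 80/20 higher/lower-grade composition of a large public glioma cohort,
# with wildtype co-occurring with higher grade.

with_rng <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Phantom cohort specification
#'
#' @param n_subjects number of subjects (>= 2).
#' @param grid_size voxels per axis (cubic volumes, >= 16).
#' @param idh_mutant_fraction proportion of IDH-mutant subjects.
#' @param high_grade_fraction proportion of higher-grade subjects.
#' @param mismatch_effect amplitude (intensity units, >= 0) of the planted
#'   tumor-interior T2-up / FLAIR-down mismatch in mutants.
#' @param necrosis_effect necrotic-core volume inflation factor for
#'   high-grade subjects: core volume is multiplied by `1 + necrosis_effect`.
#' @param noise_sd additive Gaussian intensity noise (pre-standardization).
#' @param coupling `P(lower grade | IDH mutant)`: strength of the
#'   mutant/lower-grade association (0.9 by default).
#' @param seed integer; identical spec + seed gives a bit-identical cohort.
#' @return validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_subjects, grid_size = 32L,
                         idh_mutant_fraction = 0.2,
                         high_grade_fraction = 0.8,
                         mismatch_effect = 2, necrosis_effect = 2,
                         noise_sd = 0.2, coupling = 0.9, seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (grid_size < 16) {
    stop("grid_size ", grid_size, " too small to contain a 3-compartment ",
         "tumor; need >= 16")
  }
  for (f in c(idh_mutant_fraction, high_grade_fraction, coupling)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  if (mismatch_effect < 0 || necrosis_effect < 0 || noise_sd < 0) {
    stop("effects and noise_sd must be >= 0")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 grid_size = as.integer(grid_size),
                 idh_mutant_fraction = idh_mutant_fraction,
                 high_grade_fraction = high_grade_fraction,
                 mismatch_effect = mismatch_effect,
                 necrosis_effect = necrosis_effect,
                 noise_sd = noise_sd, coupling = coupling,
                 seed = as.integer(seed)), class = "phantom_spec")
}

# deterministic stratified 2x2 label table from the marginals and coupling
phantom_labels <- function(spec) {
  n <- spec$n_subjects
  n_mut <- round(n * spec$idh_mutant_fraction)
  n_high <- round(n * spec$high_grade_fraction)
  n_low <- n - n_high
  mut_low <- round(spec$coupling * n_mut)
  mut_low <- min(max(mut_low, n_mut - n_high, 0L), n_mut, n_low)
  mut_high <- n_mut - mut_low
  wild_low <- n_low - mut_low
  wild_high <- n_high - mut_high
  idh <- c(rep(1L, mut_low + mut_high), rep(0L, wild_low + wild_high))
  grade <- c(rep(0L, mut_low), rep(1L, mut_high),
             rep(0L, wild_low), rep(1L, wild_high))
  ord <- sample.int(n)
  list(idh = idh[ord], grade = grade[ord])
}

# tissue intensity means (arbitrary units, z-scored within brain later).
# FLAIR tracks T2 with a compartment-independent offset so that, without a
# planted mismatch, tumor-interior T2-FLAIR contrast carries no class signal
# (the stated null); grade information lives in the necrotic-core size seen
# by T1/T1CE contrast and the mask geometry.
phantom_intensities <- list(
  t1 = c(brain = 1.0, edema = 0.80, enh = 0.90, core = 0.60),
  t1ce = c(brain = 1.0, edema = 0.90, enh = 1.80, core = 0.50),
  t2 = c(brain = 1.0, edema = 1.50, enh = 1.30, core = 1.60),
  flair = c(brain = 0.9, edema = 1.40, enh = 1.20, core = 1.50))

phantom_subject <- function(spec, idh, grade, id) {
  g <- spec$grid_size
  ax <- seq_len(g) - (g + 1) / 2
  rb <- 0.45 * g
  # squared normalized distance from volume center (brain ellipsoid)
  d_brain <- outer(outer((ax / rb)^2, (ax / (0.9 * rb))^2, `+`),
                   (ax / rb)^2, `+`)
  brain <- d_brain <= 1
  # tumor geometry: random center and anisotropic radii, kept inside brain
  ctr <- stats::runif(3, -0.18 * g, 0.18 * g)
  base_r <- stats::runif(1, 0.16, 0.22) * g
  rad <- base_r * stats::runif(3, 0.85, 1.15)
  rad <- pmin(rad, g / 2 - abs(ctr) - 1)        # stay inside the volume
  du <- outer(outer(((ax - ctr[1]) / rad[1])^2,
                    ((ax - ctr[2]) / rad[2])^2, `+`),
              ((ax - ctr[3]) / rad[3])^2, `+`)
  core_scale <- 0.35 * (1 + spec$necrosis_effect * grade)^(1 / 3)
  core_scale <- min(core_scale, 0.9 * 0.65)
  mask <- array(0L, dim = c(g, g, g))
  mask[du <= 1] <- 3L
  mask[du <= 0.65^2] <- 2L
  mask[du <= core_scale^2] <- 1L
  if (!any(mask == 1L)) {
    cv <- pmin(pmax(round(ctr + (g + 1) / 2), 1L), g)
    mask[cv[1], cv[2], cv[3]] <- 1L
  }
  mask[!brain] <- 0L
  # voxelized interiority: any core voxel whose 6-neighborhood leaves
  # {core, enhancing} is relabeled enhancing, so the core stays strictly
  # inside the rim after discretization
  core_idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(core_idx) > 1L) {
    bad <- rep(FALSE, nrow(core_idx))
    for (ax in 1:3) {
      for (dlt in c(-1L, 1L)) {
        nb <- core_idx
        nb[, ax] <- nb[, ax] + dlt
        inb <- nb[, ax] >= 1L & nb[, ax] <= g
        lab <- rep(0L, nrow(nb))
        lab[inb] <- mask[nb[inb, , drop = FALSE]]
        bad <- bad | !(lab %in% c(1L, 2L))
      }
    }
    if (any(bad) && !all(bad)) {
      mask[core_idx[bad, , drop = FALSE]] <- 2L
    }
  }

  vols <- lapply(names(phantom_intensities), function(m) {
    mu <- phantom_intensities[[m]]
    v <- array(0, dim = c(g, g, g))
    v[brain] <- mu["brain"]
    v[mask == 3L] <- mu["edema"]
    v[mask == 2L] <- mu["enh"]
    v[mask == 1L] <- mu["core"]
    if (idh == 1L) {
      interior <- mask == 1L | mask == 2L
      if (m == "t2") v[interior] <- v[interior] + 0.5 * spec$mismatch_effect
      if (m == "flair") v[interior] <- v[interior] - 0.5 * spec$mismatch_effect
    }
    if (spec$noise_sd > 0) {
      v[brain] <- v[brain] + stats::rnorm(sum(brain), sd = spec$noise_sd)
    }
    # z-score within the brain mask
    bv <- v[brain]
    s <- stats::sd(bv)
    v[brain] <- (bv - mean(bv)) / if (s > 0) s else 1
    v
  })
  names(vols) <- names(phantom_intensities)
  structure(list(volumes = vols, roi_mask = mask, idh_label = idh,
                 grade_label = grade, features = NULL, subject_id = id),
            class = "phantom_subject")
}

#' Generate a synthetic phantom cohort
#'
#' @param spec a [phantom_spec()].
#' @return list of `phantom_subject` objects (class `phantom_cohort`), each
#'   with four z-scored modality volumes, a compartment mask, both labels and
#'   a 101-element feature row (planted with the defaults of
#'   [make_feature_table()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_rng(spec$seed, {
    lab <- phantom_labels(spec)
    subjects <- lapply(seq_len(spec$n_subjects), function(i) {
      phantom_subject(spec, lab$idh[i], lab$grade[i],
                      sprintf("sub-%03d", i))
    })
    ft <- make_feature_table(subjects, seed = spec$seed + 1L)
    for (i in seq_along(subjects)) {
      subjects[[i]]$features <- ft$features[i, ]
    }
    structure(subjects, class = "phantom_cohort", spec = spec)
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  idh <- vapply(x, function(s) s$idh_label, integer(1))
  gr <- vapply(x, function(s) s$grade_label, integer(1))
  cat("phantom cohort:", length(x), "subjects,", spec$grid_size, "^3 voxels\n")
  cat("  IDH mutant:", sum(idh), " higher grade:", sum(gr), "\n")
  invisible(x)
}

#' Extract an ROI-centered cubic patch
#'
#' The patch is centered on the midpoint of the ROI bounding box; regions
#' falling outside the volume are zero-padded (mask included), so the ROI
#' midpoint stays at the patch center exactly.
#'
#' @param subject a `phantom_subject` (or any list with `volumes` and
#'   `roi_mask`).
#' @param patch_size cubic patch edge length (reference scale: 128).
#' @return the subject with cropped `volumes` and `roi_mask`.
#' @export
extract_patch <- function(subject, patch_size = 128L) {
  mask <- subject$roi_mask
  idx <- which(mask > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("subject ", subject$subject_id %||% "<unnamed>",
         " has an empty ROI mask")
  }
  p <- as.integer(patch_size)
  dims <- dim(mask)
  # 0-based bounding-box midpoint, patch spans [mid - p/2, mid + p/2)
  mid0 <- floor((apply(idx, 2L, min) - 1L + apply(idx, 2L, max) - 1L) / 2)
  start0 <- mid0 - p %/% 2L
  crop1 <- function(vol) {
    out <- array(0, dim = rep(p, 3L))
    src_lo <- pmax(start0, 0L)
    src_hi <- pmin(start0 + p - 1L, dims - 1L)
    if (any(src_hi < src_lo)) return(out)
    dst_lo <- src_lo - start0
    out[(dst_lo[1] + 1L):(dst_lo[1] + src_hi[1] - src_lo[1] + 1L),
        (dst_lo[2] + 1L):(dst_lo[2] + src_hi[2] - src_lo[2] + 1L),
        (dst_lo[3] + 1L):(dst_lo[3] + src_hi[3] - src_lo[3] + 1L)] <-
      vol[(src_lo[1] + 1L):(src_hi[1] + 1L),
          (src_lo[2] + 1L):(src_hi[2] + 1L),
          (src_lo[3] + 1L):(src_hi[3] + 1L)]
    out
  }
  subject$volumes <- lapply(subject$volumes, crop1)
  m <- crop1(mask)
  storage.mode(m) <- "integer"
  subject$roi_mask <- m
  subject
}

#' Synthetic tabular feature table (radiomic stand-in)
#'
#' 99 radiomic-like columns plus age and sex. `n_informative` columns are
#' shifted by `effect` (in standard deviations) between classes, split
#' between the IDH and grade labels; the rest are pure noise. Age is shifted
#' upward for IDH-wildtype subjects (older patients are more often wildtype);
#' sex is independent noise.
#'
#' @param subjects a `phantom_cohort` or list of subjects with labels.
#' @param n_informative number of planted informative columns (<= 99).
#' @param effect standardized between-class mean shift of planted columns.
#' @param seed RNG seed.
#' @return list of class `mtg_feature_table` with `features` (n x 101 named
#'   matrix), `idh`, `grade`, and `informative` (planted column indices per
#'   task).
#' @export
make_feature_table <- function(subjects, n_informative = 10L, effect = 1.5,
                               seed = 1L) {
  if (n_informative > 99L) stop("n_informative must be <= 99")
  idh <- vapply(subjects, function(s) s$idh_label, integer(1))
  grade <- vapply(subjects, function(s) s$grade_label, integer(1))
  n <- length(idh)
  with_rng(seed, {
    X <- matrix(stats::rnorm(n * 99L), n, 99L)
    n_idh <- ceiling(n_informative / 2)
    idx_idh <- seq_len(n_idh)
    idx_grade <- if (n_informative > n_idh) (n_idh + 1L):n_informative else integer(0)
    for (j in idx_idh) X[, j] <- X[, j] + effect * (idh - 0.5)
    for (j in idx_grade) X[, j] <- X[, j] + effect * (grade - 0.5)
    age <- stats::rnorm(n, mean = 52 + 10 * (1 - idh), sd = 10)
    sex <- stats::rbinom(n, 1L, 0.6)
    prefixes <- rep(c("firstorder", "glszm", "gldm", "glcm", "ngtdm",
                      "glrlm", "shape"), length.out = 99L)
    feats <- cbind(X, age, sex)
    colnames(feats) <- c(sprintf("%s_f%02d", prefixes, seq_len(99L)),
                         "age", "sex")
    structure(list(features = feats, idh = idh, grade = grade,
                   informative = list(idh = idx_idh, grade = idx_grade)),
              class = "mtg_feature_table")
  })
}
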