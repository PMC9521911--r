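#' Segmentation phantom with known region structure
#'
#' Builds a gray8 volume whose background is split into vertical bands (one
#' per mixture component, widths proportional to the weights), each filled
#' with Gaussian intensities at the stated mean/sd, plus optional spherical
#' nodules. The returned mask labels background bands `1..B` and nodules
#' `B+1, ...`, so threshold-recovery and segmentation-accuracy tests have
#' exact ground truth. With `sds = 0` the regions are constant and a single
#' Otsu threshold separates them exactly.
#'
#' @param shape volume shape `(slices, rows, cols)`; default `c(9, 64, 64)`,
#'   1 mm isotropic.
#' @param means,sds,weights background mixture components (gray8 units);
#'   weights must sum to 1.
#' @param nodules optional list of `list(center = c(s, r, c), radius, mean,
#'   sd)` spherical inserts (radius in voxels/mm).
#' @param seed integer seed; generation is a pure function of the arguments
#'   and seed.
#' @return list with `volume` (a gray8 [ct_volume]) and `mask`
#'   (a [label_mask]).
#' @export
make_segmentation_phantom <- function(shape = c(9, 64, 64),
                                      means = c(60, 180), sds = c(10, 10),
                                      weights = NULL, nodules = NULL,
                                      seed = NULL) {
  if (length(shape) != 3L || any(shape < 1)) stop_param("invalid shape")
  B <- length(means)
  if (length(sds) != B) stop_param("means and sds must have equal length")
  if (is.null(weights)) weights <- rep(1 / B, B)
  if (length(weights) != B || abs(sum(weights) - 1) > 1e-9 || any(weights <= 0)) {
    stop_param("weights must be positive and sum to 1")
  }
  gen <- function() {
    vox <- array(0, dim = shape)
    lab <- array(0L, dim = shape)
    edges <- c(0, round(cumsum(weights) * shape[3]))
    edges[B + 1L] <- shape[3]
    for (b in seq_len(B)) {
      cols <- (edges[b] + 1L):edges[b + 1L]
      n <- shape[1] * shape[2] * length(cols)
      vox[, , cols] <- stats::rnorm(n, means[b], sds[b])
      lab[, , cols] <- b
    }
    if (!is.null(nodules)) {
      grid_s <- slice.index(vox, 1); grid_r <- slice.index(vox, 2)
      grid_c <- slice.index(vox, 3)
      for (i in seq_along(nodules)) {
        nd <- nodules[[i]]
        if (nd$radius <= 0) stop_param("nodule radius must be positive")
        inside <- (grid_s - nd$center[1])^2 + (grid_r - nd$center[2])^2 +
          (grid_c - nd$center[3])^2 <= nd$radius^2
        if (!any(inside)) stop_param("nodule ", i, " lies outside the volume")
        vox[inside] <- stats::rnorm(sum(inside), nd$mean, nd$sd %||% 0)
        lab[inside] <- B + i
      }
    }
    vox <- round_half_away(pmin(pmax(vox, 0), 255))
    storage.mode(vox) <- "integer"
    list(volume = ct_volume(vox, c(1, 1, 1), domain = "gray8"),
         mask = label_mask(lab))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# separable Gaussian smoothing of a 3D array (reflect padding)
gauss_smooth3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(a, ax) {
    n <- dim(a)[ax]
    idx <- pmin(pmax(abs(seq(1L - r, n + r)), 1L), n)
    idx[idx > n] <- 2L * n - idx[idx > n]
    out <- a * 0
    for (o in seq_along(k)) {
      sel <- idx[o:(o + n - 1L)]
      out <- out + k[o] * switch(ax,
        a[sel, , , drop = FALSE],
        a[, sel, , drop = FALSE],
        a[, , sel, drop = FALSE])
    }
    out
  }
  for (ax in 1:3) x <- smooth_axis(x, ax)
  x
}

# per-class texture generator settings: smoothing scale (voxels) controls the
# co-occurrence contrast; the three ranges are disjoint by construction
texture_class_params <- function(class) {
  switch(class,
    benign    = list(generator = "smooth_blob", sigma = 2.5),
    malignant = list(generator = "speckle",     sigma = 0),
    ambiguous = list(generator = "mixed",       sigma = 0.8),
    stop_param("unknown class: ", class)
  )
}

#' Textured nodule patch with a known class
#'
#' Generates a cubic gray8 patch of side `2 * radius + 1` voxels whose
#' spatial texture encodes the class: `benign` is a smooth correlated
#' Gaussian field (low co-occurrence contrast), `malignant` is unsmoothed
#' speckle (high contrast), `ambiguous` is mildly smoothed (intermediate).
#' All three share the same marginal mean and standard deviation, so only
#' the spatial correlation — hence the GLCM — distinguishes them.
#'
#' @param class one of `"benign"`, `"malignant"`, `"ambiguous"`.
#' @param radius patch half-width in voxels (1 mm isotropic); must be >= 1.
#' @param mean_intensity,sd_intensity target gray8 marginal moments.
#' @param seed integer seed.
#' @return list with `patch` (integer 3D array) and `label` (the class).
#' @export
make_texture_nodule <- function(class, radius = 6, mean_intensity = 128,
                                sd_intensity = 40, seed = NULL) {
  class <- match.arg(class, fusion_classes)
  if (radius < 1) stop_param("radius must be >= 1")
  side <- 2L * as.integer(radius) + 1L
  pars <- texture_class_params(class)
  gen <- function() {
    x <- array(stats::rnorm(side^3), dim = rep(side, 3L))
    x <- gauss_smooth3(x, pars$sigma)
    x <- (x - mean(x)) / stats::sd(x) * sd_intensity + mean_intensity
    x <- round_half_away(pmin(pmax(x, 0), 255))
    storage.mode(x) <- "integer"
    x
  }
  patch <- if (is.null(seed)) gen() else with_seed(seed, gen())
  list(patch = patch, label = class)
}

#' Labelled phantom dataset for end-to-end classification tests
#'
#' Generates `3 * n_per_class` phantoms (class-balanced, classes
#' interleaved), each a background mixture volume with one spherical textured
#' nodule embedded near the centre (in-plane jitter of a few voxels). The
#' manifest records per-volume id, class, seed and nodule geometry. Every
#' volume is reproducible from its own recorded seed.
#'
#' @param n_per_class volumes per class (>= 1).
#' @param shape volume shape, default `c(9, 64, 64)` at 1 mm isotropic.
#' @param radius nodule radius in voxels.
#' @param seed master seed; per-volume seeds derive from it.
#' @param means,sds background mixture (see [make_segmentation_phantom]).
#' @return list with `volumes` (list of [ct_volume]), `masks` (list of
#'   [label_mask]; nodule label is the highest label), `labels` (factor) and
#'   `manifest` (data frame).
#' @export
make_dataset <- function(n_per_class = 50L, shape = c(9, 64, 64), radius = 6,
                         seed = 1L, means = c(60, 180), sds = c(10, 10)) {
  n_per_class <- as_count(n_per_class, "n_per_class")
  total <- 3L * n_per_class
  classes <- rep(fusion_classes, n_per_class)
  vol_seed <- seed * 1000L + seq_len(total)
  volumes <- vector("list", total)
  masks <- vector("list", total)
  centers <- matrix(0L, total, 3L)
  nodule_label <- length(means) + 1L
  radius <- as.integer(radius)
  for (i in seq_len(total)) {
    res <- with_seed(vol_seed[i], {
      centre <- c(ceiling(shape[1] / 2),
                  ceiling(shape[2] / 2) + sample(-4:4, 1),
                  ceiling(shape[3] / 2) + sample(-4:4, 1))
      list(ph = make_segmentation_phantom(shape, means = means, sds = sds),
           nod = make_texture_nodule(classes[i], radius = radius),
           centre = centre)
    })
    vox <- res$ph$volume$voxels
    lab <- res$ph$mask$labels
    gs <- slice.index(vox, 1); gr <- slice.index(vox, 2); gc <- slice.index(vox, 3)
    inside <- (gs - res$centre[1])^2 + (gr - res$centre[2])^2 +
      (gc - res$centre[3])^2 <= radius^2
    w <- which(inside, arr.ind = TRUE)
    pidx <- cbind(w[, 1] - res$centre[1], w[, 2] - res$centre[2],
                  w[, 3] - res$centre[3]) + radius + 1L
    vox[w] <- res$nod$patch[pidx]
    lab[w] <- nodule_label
    volumes[[i]] <- ct_volume(vox, c(1, 1, 1), domain = "gray8")
    masks[[i]] <- label_mask(lab)
    centers[i, ] <- res$centre
  }
  manifest <- data.frame(id = seq_len(total), class = classes,
                         seed = vol_seed, center_slice = centers[, 1],
                         center_row = centers[, 2], center_col = centers[, 3],
                         radius = radius)
  list(volumes = volumes, masks = masks,
       labels = factor(classes, levels = fusion_classes), manifest = manifest)
}

#' Feature sequence for a masked nodule
#'
#' Convenience wrapper for the end-to-end pipeline: crop the volume to the
#' nodule's bounding box (plus margin), quantize, and build the fusion
#' feature sequence.
#'
#' @param vol gray8 [ct_volume].
#' @param mask [label_mask]; the nodule is `label`.
#' @param label nodule label in the mask.
#' @param mode,L,slices_per_vs,max_len passed to [build_feature_sequence].
#' @param margin crop margin in voxels.
#' @return a `feature_sequence`.
#' @export
nodule_feature_sequence <- function(vol, mask, label, mode = "glcm3d", L = 32L,
                                    slices_per_vs = 3L, margin = 2L,
                                    max_len = NULL) {
  crop <- crop_to_mask(vol, mask, label, margin = margin)
  q <- quantize(crop, L)
  build_feature_sequence(q, mode = mode, L = L, slices_per_vs = slices_per_vs,
                         max_len = max_len)
}
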