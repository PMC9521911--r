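#' Quantize gray values
#'
#' Maps 8-bit gray values to `L` levels by `floor(v * L / 256)`, a monotone
#' map onto \[0, L−1\]. `L = 256` is the identity.
#'
#' @param vol a [ct_volume] with `domain = "gray8"`, or an integer array in
#'   \[0, 255\].
#' @param L target level count, 2..256.
#' @return a [ct_volume] with `domain = "quantized"` (or a bare array when
#'   the input was one).
#' @export
quantize <- function(vol, L) {
  L <- as_count(L, "L", min = 2L)
  if (L > 256L) stop_param("L must be <= 256")
  q <- function(v) {
    out <- (v * L) %/% 256L
    storage.mode(out) <- "integer"
    out
  }
  if (inherits(vol, "ct_volume")) {
    if (vol$domain != "gray8") stop_param("quantize expects a gray8 volume")
    ct_volume(q(vol$voxels), vol$spacing, domain = "quantized", levels = L)
  } else {
    if (any(vol < 0) || any(vol > 255) || any(vol != floor(vol))) {
      stop_param("values must be integers in [0, 255]")
    }
    q(vol)
  }
}

#' Canonical co-occurrence direction sets
#'
#' 2D: the 8 unit chessboard offsets in angular order 0°, 45°, ..., 315°
#' with 0° = east `(dr, dc) = (0, +1)`, angles counter-clockwise in image
#' convention (row index increasing downward). 3D: the 13 unit offsets
#' `(ds, dr, dc)` covering the 26 chessboard neighbours modulo negation
#' (no offset is the negation of another), in lexicographic order.
#'
#' @param dim 2 or 3.
#' @return an object of class `direction_set`: list with `offsets` (a matrix,
#'   one row per offset) and `dim`.
#' @export
direction_offsets <- function(dim) {
  if (!(length(dim) == 1L && dim %in% c(2L, 3L))) stop_param("`dim` must be 2 or 3")
  if (dim == 2L) {
    off <- rbind(
      c(0L, 1L),    #   0 deg: east
      c(-1L, 1L),   #  45 deg: northeast
      c(-1L, 0L),   #  90 deg: north
      c(-1L, -1L),  # 135 deg: northwest
      c(0L, -1L),   # 180 deg: west
      c(1L, -1L),   # 225 deg: southwest
      c(1L, 0L),    # 270 deg: south
      c(1L, 1L)     # 315 deg: southeast
    )
    colnames(off) <- c("dr", "dc")
    rownames(off) <- paste0(seq(0L, 315L, by = 45L), "deg")
  } else {
    g <- as.matrix(expand.grid(dc = -1:1, dr = -1:1, ds = -1:1))[, 3:1]
    g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
    # keep one of each antipodal pair: first nonzero component positive
    keep <- apply(g, 1L, function(o) o[which(o != 0L)[1L]] > 0L)
    off <- g[keep, , drop = FALSE]
    off <- off[order(off[, 1L], off[, 2L], off[, 3L]), , drop = FALSE]
    storage.mode(off) <- "integer"
    rownames(off) <- apply(off, 1L, paste, collapse = ",")
  }
  structure(list(offsets = off, dim = dim), class = "direction_set")
}

#' @export
print.direction_set <- function(x, ...) {
  cat(sprintf("direction_set: %dD, %d offsets\n", x$dim, nrow(x$offsets)))
  print(x$offsets)
  invisible(x)
}

#' Single-offset gray-level co-occurrence matrix
#'
#' `raw[a + 1, b + 1]` counts positions `x` with both `x` and `x + offset`
#' in bounds, value `a` at `x` and `b` at `x + offset`. With
#' `symmetric = TRUE` both pair orders are counted (`raw + t(raw)`); with
#' `normalize = TRUE` the counts are divided by their total (an image with
#' no valid pairs yields the all-zero matrix).
#'
#' @param img integer 2D matrix or 3D array, values in \[0, L−1\]. 3D arrays
#'   are indexed `(slice, row, col)`.
#' @param offset integer displacement: `(dr, dc)` for 2D, `(ds, dr, dc)` for
#'   3D.
#' @param L gray-level count.
#' @param symmetric count both pair orders?
#' @param normalize divide by the pair count?
#' @return an `L x L` matrix.
#' @export
glcm_single <- function(img, offset, L, symmetric = FALSE, normalize = FALSE) {
  L <- as_count(L, "L", min = 2L)
  d <- dim(img)
  if (is.null(d)) stop_param("`img` must be a matrix or 3D array")
  if (length(d) != length(offset)) {
    stop_param("offset rank (", length(offset), ") must match image rank (",
               length(d), ")")
  }
  offset <- as.integer(offset)
  idx <- lapply(seq_along(d), function(ax) {
    o <- offset[ax]
    n <- d[ax]
    lo <- max(1L, 1L - o)
    hi <- min(n, n - o)
    if (hi < lo) integer(0) else lo:hi
  })
  if (any(lengths(idx) == 0L)) {
    raw <- matrix(0, L, L)
  } else {
    if (length(d) == 2L) {
      a <- img[idx[[1]], idx[[2]], drop = FALSE]
      b <- img[idx[[1]] + offset[1], idx[[2]] + offset[2], drop = FALSE]
    } else {
      a <- img[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      b <- img[idx[[1]] + offset[1], idx[[2]] + offset[2], idx[[3]] + offset[3],
               drop = FALSE]
    }
    counts <- tabulate(as.vector(a) * L + as.vector(b) + 1L, nbins = L * L)
    raw <- matrix(counts, nrow = L, ncol = L, byrow = TRUE)
  }
  if (symmetric) raw <- raw + t(raw)
  if (normalize) {
    tot <- sum(raw)
    if (tot > 0) raw <- raw / tot
  }
  raw
}

# container for an ordered set of direction-resolved GLCMs
glcm_stack <- function(matrices, L, normalized, source, directions) {
  structure(list(matrices = matrices, L = L, normalized = normalized,
                 source = source, directions = directions),
            class = "glcm_stack")
}

#' @export
print.glcm_stack <- function(x, ...) {
  cat(sprintf("glcm_stack: %d matrices of %d x %d (%s, %s)\n",
              length(x$matrices), x$L, x$L, x$source,
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' 2D GLCM stack for one slice
#'
#' One normalized co-occurrence matrix per direction in angular order
#' 0° to 315°. Directions are kept asymmetric, so the 180° matrix is the
#' transpose of the 0° matrix: all eight senses carry distinct sequence
#' positions for the fusion network.
#'
#' @param slice integer matrix with values in \[0, L−1\], or a single-slice
#'   quantized [ct_volume].
#' @param L gray-level count.
#' @return a `glcm_stack` of 8 matrices.
#' @export
glcm_2d <- function(slice, L = NULL) {
  if (inherits(slice, "ct_volume")) {
    if (is.null(L)) L <- slice$levels
    if (dim(slice$voxels)[1] != 1L) stop_param("glcm_2d expects a single slice")
    slice <- slice$voxels[1, , , drop = TRUE]
  }
  L <- as_count(L, "L", min = 2L)
  ds <- direction_offsets(2L)
  mats <- lapply(seq_len(nrow(ds$offsets)), function(i) {
    glcm_single(slice, ds$offsets[i, ], L, symmetric = FALSE, normalize = TRUE)
  })
  names(mats) <- rownames(ds$offsets)
  glcm_stack(mats, L, normalized = TRUE, source = "slice", directions = ds)
}

#' Partition a volume into volume spaces (VSs)
#'
#' Consecutive, non-overlapping slabs of `slices_per_vs` slices (default 3,
#' giving 1 mm-cubed voxels on 1 mm-isotropic data). A trailing remainder of
#' fewer slices forms a final short VS rather than being dropped; through-
#' plane offsets simply count fewer (or no) pairs there. The VS count is
#' `p = ceiling(n_slices / slices_per_vs)`.
#'
#' @param vol a [ct_volume] or 3D array.
#' @param slices_per_vs slab thickness in slices (default 3).
#' @return list of 3D arrays in ascending slice order.
#' @export
partition_volume_spaces <- function(vol, slices_per_vs = 3L) {
  v <- if (inherits(vol, "ct_volume")) vol$voxels else vol
  slices_per_vs <- as_count(slices_per_vs, "slices_per_vs", min = 1L)
  ns <- dim(v)[1]
  if (ns < 2L) stop_param("volume must have at least 2 slices")
  starts <- seq(1L, ns, by = slices_per_vs)
  lapply(starts, function(s) {
    v[s:min(s + slices_per_vs - 1L, ns), , , drop = FALSE]
  })
}

#' 3D GLCM stack for one volume space
#'
#' 13 normalized co-occurrence matrices in canonical offset order, computed
#' with symmetric accumulation (both orders of each voxel pair) and confined
#' to the slab: no pairs cross VS boundaries.
#'
#' @param vs a 3D array `(slice, row, col)` with values in \[0, L−1\].
#' @param L gray-level count.
#' @return a `glcm_stack` of 13 matrices.
#' @export
glcm_3d_vs <- function(vs, L = NULL) {
  if (inherits(vs, "ct_volume")) {
    if (is.null(L)) L <- vs$levels
    vs <- vs$voxels
  }
  L <- as_count(L, "L", min = 2L)
  ds <- direction_offsets(3L)
  mats <- lapply(seq_len(nrow(ds$offsets)), function(i) {
    glcm_single(vs, ds$offsets[i, ], L, symmetric = TRUE, normalize = TRUE)
  })
  names(mats) <- rownames(ds$offsets)
  glcm_stack(mats, L, normalized = TRUE, source = "volume_space", directions = ds)
}

# row-major flattening of a matrix (stated, fixed vectorization order)
vec_row_major <- function(m) as.vector(t(m))

#' Build a padded feature sequence for the fusion network
#'
#' Assembles the sequence the LSTM fusion classifier consumes:
#'
#' * `"glcm2d"` — 8 steps, one per direction of a single slice, each of
#'   length `f = L^2`;
#' * `"glcm2_5d"` — `n` steps (slices), each the 8-direction stack of that
#'   slice, `f = 8 L^2`;
#' * `"glcm3d"` — `p` steps (volume spaces), each the 13-direction 3D stack,
#'   `f = 13 L^2`;
#' * `"descriptors"` — `p` steps of the 16 Haralick descriptors per
#'   direction, `f = 13 * 16`.
#'
#' Matrices are flattened row-major and directions concatenated in canonical
#' order. Steps are zero-padded to `max_len` with a mask marking real steps;
#' a sequence longer than `max_len` is an explicit error, never a silent
#' truncation.
#'
#' @param x a quantized [ct_volume] (modes 2.5D/3D/descriptors) or a single
#'   quantized slice/matrix (mode `"glcm2d"`).
#' @param mode one of `"glcm2d"`, `"glcm2_5d"`, `"glcm3d"`, `"descriptors"`.
#' @param L gray-level count (defaults to the volume's).
#' @param slices_per_vs VS thickness for the 3D modes.
#' @param max_len pad/validate to this many steps (default: actual length).
#' @return an object of class `feature_sequence`: list with `steps`
#'   (`max_len x f` matrix), `mask` (logical vector), `mode`, `L`, `f`,
#'   `n_real` (real step count).
#' @export
build_feature_sequence <- function(x, mode = c("glcm2d", "glcm2_5d", "glcm3d",
                                               "descriptors"),
                                   L = NULL, slices_per_vs = 3L, max_len = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "ct_volume")) {
    if (is.null(L)) L <- x$levels
    v <- x$voxels
  } else {
    v <- x
    if (is.null(L)) stop_param("`L` is required for bare arrays")
  }
  L <- as_count(L, "L", min = 2L)
  steps <- switch(mode,
    glcm2d = {
      slice <- if (length(dim(v)) == 3L) {
        if (dim(v)[1] != 1L) stop_param("glcm2d mode expects a single slice")
        v[1, , , drop = TRUE]
      } else v
      st <- glcm_2d(slice, L)
      lapply(st$matrices, vec_row_major)
    },
    glcm2_5d = {
      if (length(dim(v)) != 3L) stop_param("glcm2_5d mode expects a volume")
      lapply(seq_len(dim(v)[1]), function(s) {
        st <- glcm_2d(v[s, , , drop = TRUE], L)
        unlist(lapply(st$matrices, vec_row_major), use.names = FALSE)
      })
    },
    glcm3d = {
      vss <- partition_volume_spaces(v, slices_per_vs)
      lapply(vss, function(vs) {
        st <- glcm_3d_vs(vs, L)
        unlist(lapply(st$matrices, vec_row_major), use.names = FALSE)
      })
    },
    descriptors = {
      vss <- partition_volume_spaces(v, slices_per_vs)
      lapply(vss, function(vs) {
        st <- glcm_3d_vs(vs, L)
        unlist(lapply(st$matrices, haralick_descriptors), use.names = FALSE)
      })
    }
  )
  f <- length(steps[[1]])
  n_real <- length(steps)
  if (is.null(max_len)) max_len <- n_real
  if (n_real > max_len) {
    stop_param("sequence has ", n_real, " steps but max_len = ", max_len,
               "; refusing to truncate")
  }
  mat <- matrix(0, nrow = max_len, ncol = f)
  for (i in seq_len(n_real)) mat[i, ] <- steps[[i]]
  structure(list(steps = mat, mask = seq_len(max_len) <= n_real,
                 mode = mode, L = L, f = f, n_real = n_real),
            class = "feature_sequence")
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("feature_sequence: mode %s, %d real steps of %d padded, f = %d\n",
              x$mode, x$n_real, length(x$mask), x$f))
  invisible(x)
}

#' Crop a nodule region from a volume by its mask label
#'
#' Bounding box of `label` in the mask, expanded by `margin` voxels and
#' clipped to the volume, applied to the voxel grid. Used to confine GLCM
#' computation to the detected nodule.
#'
#' @param vol a [ct_volume].
#' @param mask a [label_mask] congruent with `vol`.
#' @param label the mask label to crop to.
#' @param margin extra voxels around the bounding box (default 2).
#' @return a [ct_volume] restricted to the cropped box.
#' @export
crop_to_mask <- function(vol, mask, label, margin = 2L) {
  stopifnot(inherits(vol, "ct_volume"), inherits(mask, "label_mask"))
  check_congruent(vol, mask)
  w <- which(mask$labels == label, arr.ind = TRUE)
  if (nrow(w) == 0L) stop_param("label ", label, " not present in mask")
  d <- dim(vol$voxels)
  lo <- pmax(apply(w, 2L, min) - margin, 1L)
  hi <- pmin(apply(w, 2L, max) + margin, d)
  ct_volume(vol$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
            vol$spacing, domain = vol$domain,
            levels = if (vol$domain == "quantized") vol$levels else NULL)
}
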