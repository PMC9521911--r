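#' Per-slice median filtering
#'
#' Removes impulse noise before segmentation and feature extraction: each
#' output pixel is the median of an odd square window centred on it, computed
#' independently per slice (2D). The median of an odd-sized integer set is a
#' member of the set, so the filter never introduces intensity values absent
#' from the input. Borders use symmetric (reflect) padding with the edge
#' pixel included.
#'
#' @param vol a [ct_volume] (any domain).
#' @param window_side odd integer window side >= 3; the ranked set holds
#'   `window_side^2` pixels, the centre pixel included.
#' @return a [ct_volume] with the same domain, spacing and shape.
#' @export
median_filter <- function(vol, window_side = 3L) {
  stopifnot(inherits(vol, "ct_volume"))
  w <- as_count(window_side, "window_side", min = 3L)
  if (w %% 2L == 0L) stop_param("`window_side` must be odd")
  v <- vol$voxels
  out <- v
  for (s in seq_len(dim(v)[1])) {
    out[s, , ] <- median_filter_slice(v[s, , , drop = TRUE], w)
  }
  # medians of odd integer sets are members of the set
  if (is.integer(v)) storage.mode(out) <- "integer"
  ct_volume(out, vol$spacing, domain = vol$domain,
            levels = if (vol$domain == "quantized") vol$levels else NULL)
}

# vectorized 2D median filter with symmetric padding
median_filter_slice <- function(img, w) {
  p <- (w - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  # symmetric padding indices: mirror about the edge, edge included
  pad_idx <- function(n) c(rev(seq_len(p)), seq_len(n), n + 1L - seq_len(p))
  ri <- pmin(pmax(pad_idx(nr), 1L), nr)
  ci <- pmin(pmax(pad_idx(nc), 1L), nc)
  padded <- img[ri, ci, drop = FALSE]
  k <- w * w
  stack <- matrix(0, nrow = nr * nc, ncol = k)
  j <- 0L
  for (dr in 0:(w - 1L)) {
    for (dc in 0:(w - 1L)) {
      j <- j + 1L
      stack[, j] <- as.vector(padded[dr + seq_len(nr), dc + seq_len(nc)])
    }
  }
  mid <- (k + 1L) %/% 2L
  med <- apply(stack, 1L, function(r) sort.int(r, partial = mid)[mid])
  matrix(med, nrow = nr, ncol = nc)
}

#' Hounsfield-to-gray rescaling
#'
#' Maps a Hounsfield window `[lo, hi]` linearly onto \[0, 255\], clipping
#' values outside the window and rounding half away from zero. The default
#' window −1000 to 400 HU spans aerated lung through soft tissue, the
#' conventional display range for lung CT.
#'
#' @param vol a [ct_volume] with `domain = "hounsfield"`.
#' @param window_lo,window_hi Hounsfield bounds, `window_lo < window_hi`.
#' @return a [ct_volume] with `domain = "gray8"`.
#' @export
rescale_to_gray <- function(vol, window_lo = -1000, window_hi = 400) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$domain != "hounsfield") {
    stop_param("rescale_to_gray requires a hounsfield-domain volume, got '",
               vol$domain, "'")
  }
  if (!(window_lo < window_hi)) stop_param("window_lo must be < window_hi")
  g <- (vol$voxels - window_lo) / (window_hi - window_lo) * 255
  g <- pmin(pmax(g, 0), 255)
  g <- round_half_away(g)
  storage.mode(g) <- "integer"
  ct_volume(g, vol$spacing, domain = "gray8")
}

#' Resample a volume to isotropic voxels
#'
#' Separable linear interpolation along each axis onto a grid with
#' `target_mm` spacing. The new sample count per axis is
#' `round((n - 1) * spacing / target_mm) + 1` (point-based extent, both
#' endpoints preserved); positions beyond the original extent after rounding
#' are clamped to the boundary value. Integer domains are rounded back to
#' integers (half away from zero) after interpolation.
#'
#' @param vol a [ct_volume].
#' @param target_mm positive voxel size in mm for all three axes.
#' @return a [ct_volume] with spacing `c(target_mm, target_mm, target_mm)`.
#' @export
resample_isotropic <- function(vol, target_mm = 1) {
  stopifnot(inherits(vol, "ct_volume"))
  if (length(target_mm) != 1L || !is.finite(target_mm) || target_mm <= 0) {
    stop_param("`target_mm` must be a single positive number")
  }
  v <- vol$voxels
  storage.mode(v) <- "double"
  for (ax in 1:3) {
    n <- dim(v)[ax]
    sp <- vol$spacing[ax]
    if (n == 1L || abs(sp - target_mm) < 1e-12) next
    new_n <- max(1L, as.integer(round((n - 1) * sp / target_mm)) + 1L)
    old_pos <- (seq_len(n) - 1) * sp
    new_pos <- pmin((seq_len(new_n) - 1) * target_mm, old_pos[n])
    v <- interp_axis(v, ax, old_pos, new_pos)
  }
  if (vol$domain %in% c("gray8", "quantized")) {
    v <- round_half_away(v)
    v <- pmin(pmax(v, 0), vol$levels - 1L)
    storage.mode(v) <- "integer"
  }
  ct_volume(v, spacing = rep(target_mm, 3), domain = vol$domain,
            levels = if (vol$domain == "quantized") vol$levels else NULL)
}

# linear interpolation of a 3D array along one axis
interp_axis <- function(v, ax, old_pos, new_pos) {
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(v, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  out <- apply(m, 2L, function(col) {
    stats::approx(old_pos, col, xout = new_pos, rule = 2)$y
  })
  out <- array(out, dim = c(length(new_pos), d[2], d[3]))
  aperm(out, order(perm))
}
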