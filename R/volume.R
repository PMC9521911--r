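#' CT volume container
#'
#' A `ct_volume` is the package's in-memory representation of a volumetric
#' scan: a 3D voxel array indexed `(slice, row, col)` (slice axis first,
#' 0-based coordinates in all documentation), physical spacing in millimetres
#' per axis, and an intensity-domain tag. Three domains are supported:
#'
#' * `"hounsfield"` — calibrated CT attenuation (any real values);
#' * `"gray8"` — 8-bit gray, integers in \[0, 255\];
#' * `"quantized"` — integers in \[0, L−1\] for a stated level count `L`.
#'
#' @param voxels numeric or integer 3D array, dimensions `(slices, rows, cols)`.
#' @param spacing numeric length-3, mm per axis `(slice, row, col)`; all > 0.
#' @param domain one of `"hounsfield"`, `"gray8"`, `"quantized"`.
#' @param levels gray-level count `L`; required for `domain = "quantized"`,
#'   fixed at 256 for `"gray8"`, ignored for `"hounsfield"`.
#' @return an object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(0L, c(3, 4, 4)), spacing = c(1, 1, 1), domain = "gray8")
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1),
                      domain = c("hounsfield", "gray8", "quantized"),
                      levels = NULL) {
  domain <- match.arg(domain)
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop_param("`voxels` must be a 3D array (slice, row, col)")
  }
  if (any(dim(voxels) < 1L)) stop_param("all axis lengths must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_param("`spacing` must be 3 positive finite numbers (mm)")
  }
  if (domain == "gray8") {
    levels <- 256L
  } else if (domain == "quantized") {
    levels <- as_count(levels, "levels", min = 2L)
  } else {
    levels <- NA_integer_
  }
  if (domain %in% c("gray8", "quantized")) {
    rng <- range(voxels)
    if (any(voxels != floor(voxels)) || rng[1] < 0 || rng[2] > levels - 1L) {
      stop_param(sprintf("domain '%s' requires integer voxels in [0, %d]",
                         domain, levels - 1L))
    }
  }
  structure(list(voxels = voxels, spacing = spacing, domain = domain,
                 levels = levels),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d slices x %d rows x %d cols\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (mm): %s\n", paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  domain: %s%s\n", x$domain,
              if (!is.na(x$levels)) sprintf(" (L = %d)", x$levels) else ""))
  cat(sprintf("  intensity range: [%g, %g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Label mask paired with a CT volume
#'
#' Integer labels congruent with a [ct_volume], plus a legend mapping label
#' values to region names. Labels are non-negative small integers.
#'
#' @param labels integer 3D array, same shape as the paired volume.
#' @param legend named character vector or list: names are label values
#'   (as strings), values are region names. Optional.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, legend = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop_param("`labels` must be a 3D array")
  }
  if (any(labels < 0) || any(labels != floor(labels))) {
    stop_param("labels must be non-negative integers")
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, legend = legend), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(x$labels)
  cat(sprintf("label_mask: %d x %d x %d, %d distinct labels\n",
              d[1], d[2], d[3], length(tab)))
  print(tab)
  invisible(x)
}

# internal: check a mask matches a volume's shape
check_congruent <- function(vol, mask) {
  if (!identical(dim(vol$voxels), dim(mask$labels))) {
    stop_param("mask shape does not match volume shape")
  }
  invisible(TRUE)
}
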