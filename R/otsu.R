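#' Gray-level histogram
#'
#' Tallies a quantized image or volume into `L` proportions
#' `p_i = n_i / N`, `i = 0 .. L-1`, the distribution every Otsu quantity is
#' built from.
#'
#' @param img a [ct_volume] in a gray8/quantized domain, or a bare integer
#'   array/matrix/vector with values in \[0, L−1\].
#' @param L gray-level count (defaults to the volume's level count).
#' @return an object of class `gray_histogram`: list with `p` (proportions),
#'   `n` (counts), `N` (total pixels), `L`.
#' @export
gray_histogram <- function(img, L = NULL) {
  if (inherits(img, "ct_volume")) {
    if (!img$domain %in% c("gray8", "quantized")) {
      stop_param("gray_histogram needs a gray8/quantized volume")
    }
    if (is.null(L)) L <- img$levels
    img <- img$voxels
  }
  L <- as_count(L, "L", min = 2L)
  v <- as.vector(img)
  if (any(v != floor(v)) || min(v) < 0 || max(v) > L - 1L) {
    stop_param("intensities must be integers in [0, ", L - 1L, "]")
  }
  n <- tabulate(v + 1L, nbins = L)
  structure(list(p = n / length(v), n = n, N = length(v), L = L),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat(sprintf("gray_histogram: L = %d levels, N = %d pixels\n", x$L, x$N))
  nz <- which(x$n > 0)
  cat(sprintf("  %d non-empty levels in [%d, %d]\n",
              length(nz), min(nz) - 1L, max(nz) - 1L))
  invisible(x)
}

# coerce user input (histogram / volume / array) to a gray_histogram
as_gray_histogram <- function(x, L = NULL) {
  if (inherits(x, "gray_histogram")) x else gray_histogram(x, L)
}

#' Validate a threshold vector
#'
#' Thresholds are `m` strictly increasing integers in \[1, L−1\]. They induce
#' `m + 1` half-open classes: class `k` covers gray levels
#' `[t_{k-1}, t_k)` with `t_0 = 0` and `t_{m+1} = L` (left-inclusive).
#'
#' @param t integer vector of thresholds.
#' @param L gray-level count.
#' @return `t` as an integer vector, invisibly validated.
#' @export
validate_thresholds <- function(t, L) {
  L <- as_count(L, "L", min = 2L)
  if (length(t) > 0) {
    t <- as.numeric(t)
    if (any(t != floor(t)) || any(t < 1) || any(t > L - 1) ||
        (length(t) > 1 && any(diff(t) <= 0))) {
      stop_param("thresholds must be strictly increasing integers in [1, ",
                 L - 1L, "]")
    }
  }
  as.integer(t)
}

#' Per-class probability masses and means
#'
#' For histogram `h` partitioned by thresholds `t` into classes
#' `C_1 .. C_{m+1}`, computes the class masses `w_k = sum_{i in C_k} p_i`,
#' class means `mu_k = sum_{i in C_k} i p_i / w_k`, and the global mean
#' `mu_T`. Empty classes get `mu_k = 0` with `w_k = 0`, so they contribute
#' nothing downstream while avoiding 0/0. The identity
#' `sum_k w_k mu_k = mu_T` holds by construction.
#'
#' @param h a `gray_histogram` (or anything [gray_histogram] accepts).
#' @param t threshold vector (may be empty for the single-class partition).
#' @param L gray-level count when `h` is a bare array.
#' @return list with `w`, `mu` (length `m + 1`) and `mu_T`.
#' @export
class_stats <- function(h, t, L = NULL) {
  h <- as_gray_histogram(h, L)
  t <- validate_thresholds(t, h$L)
  edges <- c(0L, t, h$L)
  k <- length(edges) - 1L
  i <- 0:(h$L - 1L)
  ip <- i * h$p
  cls <- findInterval(i, edges, left.open = FALSE, rightmost.closed = FALSE)
  w <- vapply(seq_len(k), function(j) sum(h$p[cls == j]), numeric(1))
  mu <- vapply(seq_len(k), function(j) {
    if (w[j] > 0) sum(ip[cls == j]) / w[j] else 0
  }, numeric(1))
  list(w = w, mu = mu, mu_T = sum(ip))
}

#' Between-class variance (the Otsu objective)
#'
#' The fitness maximized by threshold selection:
#' `sum_k w_k (mu_k - mu_T)^2`, summed over all `m + 1` classes induced by
#' the `m` thresholds. It is zero iff every non-empty class shares the global
#' mean, and equals the total histogram variance minus the pooled
#' within-class variance.
#'
#' @inheritParams class_stats
#' @return scalar fitness >= 0.
#' @export
between_class_variance <- function(h, t, L = NULL) {
  cs <- class_stats(h, t, L)
  sum(cs$w * (cs$mu - cs$mu_T)^2)
}

#' Exhaustive multi-level Otsu threshold search
#'
#' Enumerates every strictly increasing vector of `m` integer thresholds in
#' \[1, L−1\] and returns the one maximizing [between_class_variance]. Ties
#' are broken by the lexicographically smallest vector. The search space has
#' `choose(L-1, m)` candidates; above `max_candidates` the function refuses
#' and points to [wsa_otsu], which handles large spaces stochastically.
#'
#' @inheritParams class_stats
#' @param m threshold count, `1 <= m <= L - 1` (0 allowed: empty vector).
#' @param max_candidates guard on the enumeration size.
#' @return list with `thresholds` (integer vector) and `fitness`.
#' @export
exhaustive_otsu <- function(h, m, L = NULL, max_candidates = 5e5) {
  h <- as_gray_histogram(h, L)
  m <- as_count(m, "m", min = 0L)
  if (m > h$L - 1L) stop_param("m must be <= L - 1 = ", h$L - 1L)
  if (m == 0L) {
    return(list(thresholds = integer(0), fitness = 0))
  }
  n_cand <- choose(h$L - 1L, m)
  if (n_cand > max_candidates) {
    stop_param("exhaustive search over ", format(n_cand), " candidates exceeds ",
               "max_candidates = ", format(max_candidates),
               "; use wsa_otsu() for large threshold spaces")
  }
  # cumulative sums let each candidate be scored in O(m)
  cp <- cumsum(h$p)                       # cp[j]  = P(v <  j), j = 1..L
  cip <- cumsum((0:(h$L - 1L)) * h$p)     # cip[j] = E contribution below j
  mu_T <- cip[h$L]
  score <- function(t) {
    edges <- c(0L, t, h$L)
    s <- 0
    for (k in seq_len(length(edges) - 1L)) {
      lo <- edges[k]; hi <- edges[k + 1L]
      w <- cp[hi] - if (lo > 0L) cp[lo] else 0
      if (w > 0) {
        mu <- (cip[hi] - if (lo > 0L) cip[lo] else 0) / w
        s <- s + w * (mu - mu_T)^2
      }
    }
    s
  }
  combos <- utils::combn(seq_len(h$L - 1L), m)
  best <- -Inf; best_t <- combos[, 1L]
  for (j in seq_len(ncol(combos))) {
    f <- score(combos[, j])
    if (f > best) {         # strict >: combn is lexicographic, so ties keep
      best <- f             # the lexicographically smallest vector
      best_t <- combos[, j]
    }
  }
  list(thresholds = as.integer(best_t), fitness = best)
}

#' Apply thresholds to segment an image
#'
#' Assigns label `k - 1` (0-based) to intensities in `[t_{k-1}, t_k)`, the
#' same half-open convention as [class_stats], giving `m + 1` possible
#' labels for `m` thresholds.
#'
#' @param img a [ct_volume] in gray8/quantized domain, or an integer array.
#' @param t threshold vector.
#' @param L gray-level count when `img` is a bare array.
#' @return a [label_mask] with labels `0 .. m`.
#' @export
apply_thresholds <- function(img, t, L = NULL) {
  if (inherits(img, "ct_volume")) {
    if (is.null(L)) L <- img$levels
    img <- img$voxels
  }
  L <- as_count(L, "L", min = 2L)
  t <- validate_thresholds(t, L)
  a <- img
  if (is.null(dim(a))) {
    dim(a) <- c(1L, 1L, length(a))
  } else if (length(dim(a)) == 2L) {
    dim(a) <- c(1L, dim(img))  # prepend unit slice axis; layout is preserved
  }
  lab <- array(findInterval(a, c(0L, t, L), left.open = FALSE) - 1L, dim = dim(a))
  label_mask(lab, legend = stats::setNames(
    as.list(paste0("class_", seq_len(length(t) + 1L) - 1L)),
    as.character(seq_len(length(t) + 1L) - 1L)))
}
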